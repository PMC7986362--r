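#' Flag non-wear episodes in an epoch series
#'
#' Extended stationary episodes are interpreted as the device being off the
#' wrist. Contiguous runs of stationary epochs lasting at least
#' `min_gap_min` minutes are flagged `wear = FALSE`; everything else is worn.
#'
#' @param epochs an [epoch_series()] with a logical `stationary` column (set
#'   by [compute_vm_epochs()] on raw traces or by the epoch-tier generator).
#' @param min_gap_min minimum stationary run length, minutes (default 60).
#' @return The series with its `wear` column set.
#' @export
detect_nonwear <- function(epochs, min_gap_min = 60) {
  stopifnot(inherits(epochs, "epoch_series"))
  if (!"stationary" %in% names(epochs)) {
    stop("epochs must carry a 'stationary' indicator")
  }
  es <- epoch_length(epochs)
  st <- !is.na(epochs$stationary) & epochs$stationary
  r <- rle(st)
  run_min <- r$lengths * es / 60
  nonwear_run <- r$values & run_min >= min_gap_min
  epochs$wear <- !inverse.rle(list(lengths = r$lengths, values = nonwear_run))
  epochs
}

weekday_abbrev <- function(dates) {
  # locale-independent weekday from the epoch: 1970-01-01 was a Thursday
  wd <- (as.integer(as.Date(dates)) + 4L) %% 7L   # 0 = Sunday
  c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")[wd + 1L]
}

parse_weekdays <- function(s) {
  s <- trimws(as.character(s %||% ""))
  if (!nzchar(s)) return(character())
  trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
}

#' Label calendar days as dialysis or non-dialysis
#'
#' A date whose weekday belongs to the participant's dialysis weekday pattern
#' is a dialysis day; controls (empty pattern) get non-dialysis throughout.
#' First and last days with partial coverage (the device-fitting and return
#' visits) are marked `excluded`.
#'
#' @param days Date vector, ascending.
#' @param participant one cohort-table row (uses `dialysis_weekdays`).
#' @param coverage optional minutes of data per day; first/last days with
#'   fewer than `full_day_min` minutes are excluded.
#' @param full_day_min minutes required for an edge day to count (default
#'   1440, i.e. only complete edge days are kept).
#' @return character vector of day types.
#' @export
label_day_types <- function(days, participant, coverage = NULL,
                            full_day_min = 1440) {
  pat <- parse_weekdays(participant$dialysis_weekdays)
  wd <- weekday_abbrev(days)
  out <- ifelse(wd %in% pat, "dialysis", "non-dialysis")
  n <- length(days)
  if (!is.null(coverage) && n > 0L) {
    if (coverage[1L] < full_day_min) out[1L] <- "excluded"
    if (coverage[n] < full_day_min) out[n] <- "excluded"
  }
  out
}

#' Assess wear quality against the excellent-wear criterion
#'
#' Excellent wear requires at least 72 h of worn data and at least one worn
#' minute in each of the 24 one-hour clock periods, accumulated across the
#' whole record. `excellent_both_daytypes` applies the same criterion within
#' the dialysis-day subset and the non-dialysis-day subset separately; it is
#' the cohort inclusion rule.
#'
#' @param grid a [minute_grid()].
#' @param min_hours wear-time threshold in hours (default 72).
#' @return list of class `wear_report`: `total_wear_h`, `wear_h_by_daytype`,
#'   `hourly_coverage` (24 logicals per day type and overall),
#'   `excellent_overall`, `excellent_both_daytypes`.
#' @export
assess_wear <- function(grid, min_hours = 72) {
  stopifnot(inherits(grid, "minute_grid"))
  keep <- grid$days$day_type != "excluded"
  wear <- grid$wear[keep, , drop = FALSE]
  dt <- grid$days$day_type[keep]
  hour_of_min <- rep(0:23, each = 60L)
  cover <- function(w) {
    if (nrow(w) == 0L) return(rep(FALSE, 24L))
    worn_by_min <- colSums(w, na.rm = TRUE) > 0L
    as.vector(tapply(worn_by_min, hour_of_min, any))
  }
  wear_h <- function(w) sum(w, na.rm = TRUE) / 60
  total <- wear_h(wear)
  byd <- list(dialysis = wear_h(wear[dt == "dialysis", , drop = FALSE]),
              `non-dialysis` = wear_h(wear[dt == "non-dialysis", , drop = FALSE]))
  cov_all <- cover(wear)
  cov_d <- cover(wear[dt == "dialysis", , drop = FALSE])
  cov_n <- cover(wear[dt == "non-dialysis", , drop = FALSE])
  excellent_overall <- total >= min_hours && all(cov_all)
  # same total-hours threshold, but hourly coverage must hold within each
  # day-type subset separately
  excellent_both <- total >= min_hours && all(cov_d) && all(cov_n)
  structure(list(total_wear_h = total,
                 wear_h_by_daytype = byd,
                 hourly_coverage = list(overall = cov_all, dialysis = cov_d,
                                        `non-dialysis` = cov_n),
                 excellent_overall = excellent_overall,
                 excellent_both_daytypes = excellent_both),
            class = "wear_report")
}

#' @export
print.wear_report <- function(x, ...) {
  cat(sprintf("<wear_report> %.1f h worn; excellent overall: %s; on both day types: %s\n",
              x$total_wear_h, x$excellent_overall, x$excellent_both_daytypes))
  invisible(x)
}

#' Impute missing minutes from same-clock-time donors, by day type
#'
#' Every unworn or missing minute is replaced by the mean of the worn values
#' at the same clock minute on the other days of the same day type (dialysis
#' donors never inform non-dialysis minutes and vice versa). States are
#' imputed as the modal state at that minute within day type. Minutes with no
#' same-type donor anywhere stay missing and are excluded from summaries.
#' Worn minutes are never altered.
#'
#' @param grid a [minute_grid()].
#' @return The grid with missing minutes filled and `imputed` flags set.
#' @export
impute_minute_grid <- function(grid) {
  stopifnot(inherits(grid, "minute_grid"))
  for (dtype in c("dialysis", "non-dialysis")) {
    rows <- which(grid$days$day_type == dtype)
    if (length(rows) == 0L) next
    w <- grid$wear[rows, , drop = FALSE]
    v <- grid$vm[rows, , drop = FALSE]
    donor <- w & !is.na(v)
    vd <- v; vd[!donor] <- 0
    ndon <- colSums(donor)
    col_mean <- ifelse(ndon > 0L, colSums(vd) / pmax(ndon, 1L), NA_real_)
    need <- !donor
    if (any(need)) {
      fill <- matrix(rep(col_mean, each = length(rows)),
                     nrow = length(rows))[need]
      grid$vm[rows, ][need] <- fill
      grid$imputed[rows, ][need] <- !is.na(fill)
    }
    # modal state per clock minute among donor days
    s <- grid$state[rows, , drop = FALSE]
    s_donor <- s; s_donor[!donor] <- NA_integer_
    cnt <- vapply(1:5, function(k) colSums(s_donor == k, na.rm = TRUE),
                  numeric(1440L))
    modal <- max.col(cnt, ties.method = "first")
    modal[rowSums(cnt) == 0L] <- NA_integer_
    sm <- matrix(rep(modal, each = length(rows)), nrow = length(rows))
    grid$state[rows, ][!donor] <- sm[!donor]
  }
  grid
}
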