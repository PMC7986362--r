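#' Construct a per-participant one-minute grid
#'
#' The pipeline's central exchange object: per participant, a days x 1440
#' matrix of vector magnitude (mg), behaviour state, wear mask and imputation
#' mask, with each day labelled dialysis / non-dialysis / excluded.
#'
#' States are stored as integer codes into [behaviour_states()] (NA allowed).
#'
#' @param participant_id character id.
#' @param days data.frame with columns `date` (Date) and `day_type`
#'   (`"dialysis"`, `"non-dialysis"` or `"excluded"`).
#' @param vm,state,wear,imputed days x 1440 matrices (vm numeric mg, state
#'   integer codes, wear/imputed logical).
#' @return Object of class `minute_grid`.
#' @export
minute_grid <- function(participant_id, days, vm, state, wear, imputed) {
  nd <- nrow(days)
  dims <- lapply(list(vm, state, wear, imputed), dim)
  if (!all(vapply(dims, function(d) identical(d, c(nd, 1440L)), TRUE))) {
    stop("all matrices must be days x 1440 and congruent")
  }
  if (any(!is.na(vm) & vm < 0)) stop("vm must be >= 0 where present")
  if (!all(days$day_type %in% c("dialysis", "non-dialysis", "excluded"))) {
    stop("invalid day_type")
  }
  structure(list(participant_id = as.character(participant_id),
                 days = days, vm = vm, state = state,
                 wear = wear, imputed = imputed),
            class = "minute_grid")
}

#' @export
print.minute_grid <- function(x, ...) {
  cat(sprintf("<minute_grid> %s: %d days (%d dialysis), %.1f%% worn\n",
              x$participant_id, nrow(x$days),
              sum(x$days$day_type == "dialysis"),
              100 * mean(x$wear, na.rm = TRUE)))
  invisible(x)
}

#' Build a minute grid from a 30-s (or finer) epoch series
#'
#' Per-minute vector magnitude is the mean of that minute's worn epochs (12
#' five-second or 2 thirty-second epochs); the per-minute state is the
#' majority state of its epochs, ties resolved toward the earlier epoch. A
#' minute is worn when at least half of its epochs are worn; unworn minutes
#' carry no vm.
#'
#' @param epochs an [epoch_series()] with `wear` (and optionally `label`)
#'   columns, as produced by [detect_nonwear()] or the epoch-tier generator.
#' @param participant one row of a cohort table (for id and the dialysis
#'   weekday pattern used by [label_day_types()]).
#' @param state_col which column carries the behaviour state
#'   (`"label"` for generator truth, `"predicted"` after classification).
#' @return A [minute_grid()] covering whole calendar days; `imputed` all
#'   FALSE.
#' @export
build_minute_grid <- function(epochs, participant, state_col = "label") {
  stopifnot(inherits(epochs, "epoch_series"))
  es <- epoch_length(epochs)
  per_min <- round(60 / es)
  t0 <- as.numeric(epochs$start)
  day <- date_of(epochs$start)
  minute <- floor((t0 %% 86400) / 60)
  udays <- sort(unique(day))
  nd <- length(udays)
  di <- match(day, udays)
  idx <- (di - 1L) * 1440L + minute + 1L

  wear <- if ("wear" %in% names(epochs)) epochs$wear else rep(TRUE, nrow(epochs))
  vm <- epochs$vm_mg
  # per-minute aggregation
  n_ep <- tabulate(idx, nbins = nd * 1440L)
  n_worn <- tabulate(idx[wear], nbins = nd * 1440L)
  sum_vm <- rep(0, nd * 1440L)
  ok <- wear & !is.na(vm)
  sv <- tapply(vm[ok], idx[ok], sum)
  sum_vm[as.integer(names(sv))] <- sv
  worn_min <- n_ep > 0L & n_worn * 2L >= n_ep
  vm_min <- ifelse(worn_min & n_worn > 0L, sum_vm / pmax(n_worn, 1L), NA_real_)
  vm_min[n_ep == 0L] <- NA_real_

  st_min <- rep(NA_integer_, nd * 1440L)
  if (state_col %in% names(epochs)) {
    lab <- as.integer(as_behaviour_state(epochs[[state_col]]))
    # majority over epochs in the minute; ties -> earlier epoch's state
    ord <- order(idx, t0)
    li <- lab[ord]; ii <- idx[ord]
    present <- !is.na(li)
    cnt <- matrix(0L, nrow = nd * 1440L, ncol = 5L)
    for (s in 1:5) {
      sel <- present & li == s
      if (any(sel)) {
        tb <- tabulate(ii[sel], nbins = nd * 1440L)
        cnt[, s] <- tb
      }
    }
    has <- rowSums(cnt) > 0L
    if (any(has)) {
      # earliest epoch's state per minute, used to break majority ties
      first_lab <- rep(NA_integer_, nd * 1440L)
      fi <- ii[present]; fl <- li[present]
      keep <- !duplicated(fi)
      first_lab[fi[keep]] <- fl[keep]
      amax <- max.col(cnt, ties.method = "first")
      mx <- cnt[cbind(seq_len(nrow(cnt)), amax)]
      ntie <- rowSums(cnt == mx & cnt > 0L)
      tie <- has & ntie > 1L & !is.na(first_lab)
      tie[tie] <- cnt[cbind(which(tie), first_lab[tie])] == mx[tie]
      amax[tie] <- first_lab[tie]
      st_min[has] <- amax[has]
    }
  }

  vm_m <- matrix(vm_min, nrow = nd, ncol = 1440L, byrow = TRUE)
  st_m <- matrix(st_min, nrow = nd, ncol = 1440L, byrow = TRUE)
  wr_m <- matrix(worn_min, nrow = nd, ncol = 1440L, byrow = TRUE)
  day_type <- label_day_types(udays, participant, coverage = rowSums(!is.na(vm_m)))
  minute_grid(participant_id = participant$id,
              days = data.frame(date = udays, day_type = day_type),
              vm = vm_m, state = st_m, wear = wr_m,
              imputed = matrix(FALSE, nd, 1440L))
}
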