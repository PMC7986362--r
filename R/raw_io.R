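#' Construct a raw triaxial acceleration trace
#'
#' A `raw_trace` holds timestamped x/y/z samples in gravity units (g) together
#' with device metadata. Timestamps are timezone-naive local clock time
#' (represented as POSIXct in UTC so that no daylight-saving arithmetic is
#' ever applied); all time-of-day logic in the pipeline is wall-clock.
#'
#' @param device_id character device identifier.
#' @param sample_rate_hz nominal sampling rate, > 0.
#' @param start_time POSIXct start of recording.
#' @param samples data.frame with columns `t` (POSIXct, strictly increasing),
#'   `x`, `y`, `z` (numeric, g).
#' @param dynamic_range_g absolute measurement range in g (default 8).
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(device_id, sample_rate_hz, start_time, samples,
                      dynamic_range_g = 8) {
  stopifnot_scalar_number(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  stopifnot_scalar_number(dynamic_range_g, "dynamic_range_g", positive = TRUE)
  if (!is.data.frame(samples) || !all(c("t", "x", "y", "z") %in% names(samples))) {
    stop("samples must be a data.frame with columns t, x, y, z")
  }
  n <- nrow(samples)
  if (n > 1L) {
    dt <- diff(as.numeric(samples$t))
    if (any(dt <= 0)) {
      stop("integrity error: non-monotonic timestamps at row ",
           which(dt <= 0)[1L] + 1L)
    }
  }
  for (ax in c("x", "y", "z")) {
    v <- samples[[ax]]
    if (any(!is.na(v) & abs(v) > dynamic_range_g)) {
      stop("samples exceed dynamic range on axis ", ax)
    }
  }
  structure(
    list(device_id = as.character(device_id),
         sample_rate_hz = as.numeric(sample_rate_hz),
         start_time = as.POSIXct(start_time, tz = "UTC"),
         dynamic_range_g = as.numeric(dynamic_range_g),
         samples = samples[, c("t", "x", "y", "z")]),
    class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> device %s, %.4g Hz, %d samples, range +/-%g g\n",
              x$device_id, x$sample_rate_hz, nrow(x$samples),
              x$dynamic_range_g))
  invisible(x)
}

time_fmt <- "%Y-%m-%dT%H:%M:%OS"

format_time_naive <- function(t, digits = 3) {
  op <- options(digits.secs = digits)
  on.exit(options(op))
  format(as.POSIXct(t, tz = "UTC"), format = time_fmt, tz = "UTC")
}

parse_time_naive <- function(s) {
  op <- options(digits.secs = 6)
  on.exit(options(op))
  as.POSIXct(s, format = time_fmt, tz = "UTC")
}

#' Write a raw trace to a CSV dialect
#'
#' The on-disk format is plain CSV with `t,x,y,z` data rows preceded by
#' `#`-prefixed metadata header lines (`device_id`, `sample_rate_hz`,
#' `start_time`, `dynamic_range_g`). Time is written as ISO-8601 with
#' millisecond resolution; axes are written with a declared fixed decimal
#' precision so round trips are exact to half an ulp of that precision.
#'
#' @param trace a [raw_trace()].
#' @param path output file path.
#' @param precision decimal digits for the acceleration columns (default 6,
#'   i.e. a maximum round-trip error of 5e-7 g).
#' @return `path`, invisibly.
#' @export
write_raw_trace <- function(trace, path, precision = 6) {
  stopifnot(inherits(trace, "raw_trace"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("# device_id: ", trace$device_id),
    paste0("# sample_rate_hz: ", format(trace$sample_rate_hz, digits = 15)),
    paste0("# start_time: ", format_time_naive(trace$start_time)),
    paste0("# dynamic_range_g: ", format(trace$dynamic_range_g, digits = 15)),
    paste0("# precision: ", precision),
    "t,x,y,z"), con)
  if (nrow(trace$samples) > 0L) {
    fmt <- paste0("%.", precision, "f")
    writeLines(paste(format_time_naive(trace$samples$t),
                     sprintf(fmt, trace$samples$x),
                     sprintf(fmt, trace$samples$y),
                     sprintf(fmt, trace$samples$z), sep = ","), con)
  }
  invisible(path)
}

read_header_fields <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z_0-9]+)\\s*:\\s*(.*)$", hdr))
  out <- list()
  for (m in kv) if (length(m) == 3L) out[[m[2L]]] <- trimws(m[3L])
  out
}

#' Read a raw trace written by [write_raw_trace()]
#'
#' Rows with unparseable numeric fields raise an integrity error naming the
#' first offending data row; they are never silently skipped.
#'
#' @param path file path.
#' @param dialect input dialect; only `"csv"` is supported.
#' @return A [raw_trace()].
#' @export
read_raw_trace <- function(path, dialect = "csv") {
  dialect <- match.arg(dialect, "csv")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- read_header_fields(lines)
  req <- c("device_id", "sample_rate_hz", "start_time")
  if (!all(req %in% names(meta))) {
    stop("format error: missing header field(s): ",
         paste(setdiff(req, names(meta)), collapse = ", "))
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L || body[1L] != "t,x,y,z") {
    stop("format error: expected column line 't,x,y,z'")
  }
  data_lines <- body[-1L]
  n <- length(data_lines)
  if (n == 0L) {
    samples <- data.frame(t = as.POSIXct(character(), tz = "UTC"),
                          x = numeric(), y = numeric(), z = numeric())
  } else {
    parts <- strsplit(data_lines, ",", fixed = TRUE)
    bad_shape <- which(lengths(parts) != 4L)
    if (length(bad_shape) > 0L) {
      stop("integrity error: malformed row ", bad_shape[1L])
    }
    m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
    tcol <- m[, 1L]
    # epoch-seconds or ISO-8601
    tnum <- suppressWarnings(as.numeric(tcol))
    if (all(!is.na(tnum))) {
      t <- as.POSIXct(tnum, origin = "1970-01-01", tz = "UTC")
    } else {
      t <- parse_time_naive(tcol)
      if (anyNA(t)) {
        stop("integrity error: unparseable timestamp at row ",
             which(is.na(t))[1L])
      }
    }
    num <- suppressWarnings(apply(m[, 2:4, drop = FALSE], 2L, as.numeric))
    num <- matrix(num, ncol = 3L)
    if (anyNA(num)) {
      stop("integrity error: unparseable numeric field at row ",
           which(rowSums(is.na(num)) > 0)[1L])
    }
    dt <- diff(as.numeric(t))
    if (length(dt) && any(dt <= 0)) {
      stop("integrity error: non-monotonic timestamps at row ",
           which(dt <= 0)[1L] + 1L)
    }
    samples <- data.frame(t = t, x = num[, 1L], y = num[, 2L], z = num[, 3L])
  }
  raw_trace(device_id = meta$device_id,
            sample_rate_hz = as.numeric(meta$sample_rate_hz),
            start_time = parse_time_naive(meta$start_time),
            samples = samples,
            dynamic_range_g = as.numeric(meta$dynamic_range_g %||% "8"))
}

#' Construct an epoch series
#'
#' Equal-length, non-overlapping epochs carrying the ENMO vector magnitude in
#' milligravity (mg) and optional wear/stationarity flags, behaviour labels
#' and classification features (columns prefixed `feat_`).
#'
#' @param epochs data.frame with at least `start` (POSIXct) and `vm_mg`
#'   (non-negative mg). Optional columns: `wear`, `stationary` (logical),
#'   `label` (behaviour-state factor), `feat_*` (numeric).
#' @param epoch_s epoch length in seconds.
#' @return data.frame of class `epoch_series` with attribute `epoch_s`.
#' @export
epoch_series <- function(epochs, epoch_s) {
  stopifnot_scalar_number(epoch_s, "epoch_s", positive = TRUE)
  stopifnot(is.data.frame(epochs), all(c("start", "vm_mg") %in% names(epochs)))
  if (any(!is.na(epochs$vm_mg) & epochs$vm_mg < 0)) stop("vm_mg must be >= 0")
  if (nrow(epochs) > 1L && any(diff(as.numeric(epochs$start)) < epoch_s - 1e-9)) {
    stop("epochs overlap or are out of order")
  }
  if ("label" %in% names(epochs)) epochs$label <- as_behaviour_state(epochs$label)
  structure(epochs, epoch_s = as.numeric(epoch_s),
            class = c("epoch_series", "data.frame"))
}

#' @rdname epoch_series
#' @param x an `epoch_series`.
#' @export
epoch_length <- function(x) attr(x, "epoch_s")

#' Write/read an epoch series as delimited text
#'
#' Fixed column order (`start,vm_mg,wear,stationary,label`, then any feature
#' columns), with the epoch length in a `#`-prefixed header line.
#'
#' @param series an [epoch_series()].
#' @param path file path.
#' @return `path` invisibly (writer); an `epoch_series` (reader).
#' @export
write_epoch_series <- function(series, path) {
  stopifnot(inherits(series, "epoch_series"))
  df <- as.data.frame(series)
  df$start <- format_time_naive(df$start)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# epoch_length_s: ",
                    format(epoch_length(series), digits = 15)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_epoch_series
#' @export
read_epoch_series <- function(path) {
  lines <- readLines(path)
  meta <- read_header_fields(lines)
  if (is.null(meta$epoch_length_s)) stop("format error: missing epoch_length_s")
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  df$start <- parse_time_naive(df$start)
  for (cl in intersect(c("wear", "stationary"), names(df))) {
    df[[cl]] <- as.logical(df[[cl]])
  }
  epoch_series(df, epoch_s = as.numeric(meta$epoch_length_s))
}

parse_tristate <- function(x) {
  out <- rep(NA, length(x))
  x <- trimws(as.character(x))
  out[x %in% c("TRUE", "true", "1")] <- TRUE
  out[x %in% c("FALSE", "false", "0")] <- FALSE
  out
}

#' Read a cohort metadata table
#'
#' One participant per row. `dialysis_weekdays` is a semicolon-separated
#' subset of `Mon..Sun` (empty for controls). Optional boolean columns are
#' tri-state: empty cells become missing (`NA`), never a default.
#'
#' @param path delimited file with header:
#'   `id,age,sex,dialysis_weekdays,slot,leg_weakness,breathlessness,
#'   listed_transplant,arrhythmia,cvd_or_dm,wear_season`.
#' @return data.frame of participant records, one row per participant.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  req <- c("id", "age", "sex")
  if (!all(req %in% names(df))) {
    stop("format error: cohort table must have columns ",
         paste(req, collapse = ", "))
  }
  dup <- df$id[duplicated(df$id)]
  if (length(dup) > 0L) {
    stop("integrity error: duplicate participant id: ", dup[1L])
  }
  out <- data.frame(id = df$id,
                    age = as.numeric(df$age),
                    sex = df$sex,
                    stringsAsFactors = FALSE)
  if (any(is.na(out$age) | out$age < 18 | out$age > 110)) {
    stop("integrity error: age outside [18, 110]")
  }
  out$dialysis_weekdays <- df$dialysis_weekdays %||% ""
  out$slot <- df$slot %||% NA_character_
  out$slot[!nzchar(trimws(out$slot))] <- NA_character_
  for (cl in c("leg_weakness", "breathlessness", "listed_transplant",
               "arrhythmia", "cvd_or_dm")) {
    out[[cl]] <- if (cl %in% names(df)) parse_tristate(df[[cl]]) else NA
  }
  out$wear_season <- if ("wear_season" %in% names(df)) df$wear_season else NA_character_
  out
}

#' @rdname read_cohort_table
#' @param cohort cohort data.frame as returned by [read_cohort_table()] or
#'   [generate_cohort()].
#' @export
write_cohort_table <- function(cohort, path) {
  df <- cohort
  for (cl in names(df)) {
    if (is.logical(df[[cl]])) {
      df[[cl]] <- ifelse(is.na(df[[cl]]), "", as.character(df[[cl]]))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write/read a minute grid as a long delimited table
#'
#' Columns: `participant_id,date,day_type,minute,vm,state,wear,imputed`.
#'
#' @param grid a [minute_grid()].
#' @param path file path.
#' @export
write_minute_grid <- function(grid, path) {
  stopifnot(inherits(grid, "minute_grid"))
  nd <- nrow(grid$days)
  long <- data.frame(
    participant_id = grid$participant_id,
    date = rep(as.character(grid$days$date), each = 1440L),
    day_type = rep(as.character(grid$days$day_type), each = 1440L),
    minute = rep(0:1439, times = nd),
    vm = as.vector(t(grid$vm)),
    state = as.vector(t(matrix(behaviour_states()[grid$state], nrow = nd))),
    wear = as.vector(t(grid$wear)),
    imputed = as.vector(t(grid$imputed)))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_minute_grid
#' @export
read_minute_grid <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  days <- unique(long[, c("date", "day_type")])
  nd <- nrow(days)
  stopifnot(nrow(long) == nd * 1440L)
  to_mat <- function(v) matrix(v, nrow = nd, ncol = 1440L, byrow = TRUE)
  st <- long$state
  st[!is.na(st) & !nzchar(st)] <- NA
  minute_grid(participant_id = long$participant_id[1L],
              days = data.frame(date = as.Date(days$date),
                                day_type = days$day_type),
              vm = to_mat(long$vm),
              state = to_mat(match(st, behaviour_states())),
              wear = to_mat(as.logical(long$wear)),
              imputed = to_mat(as.logical(long$imputed)))
}
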