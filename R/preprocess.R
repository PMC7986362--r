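#' Resample a raw trace onto a uniform time grid
#'
#' Linear interpolation at the declared sampling rate; gaps longer than
#' `max_gap_s` are not interpolated and are left missing.
#'
#' @param trace a [raw_trace()].
#' @param rate_hz target rate (defaults to the trace's declared rate).
#' @param max_gap_s gaps longer than this are left `NA` (default 1 s).
#' @return A [raw_trace()] on a uniform grid (samples inside long gaps NA).
#' @export
resample_trace <- function(trace, rate_hz = NULL, max_gap_s = 1) {
  stopifnot(inherits(trace, "raw_trace"))
  rate_hz <- rate_hz %||% trace$sample_rate_hz
  t <- as.numeric(trace$samples$t)
  if (length(t) < 2L) return(trace)
  grid <- seq(t[1L], t[length(t)], by = 1 / rate_hz)
  out <- data.frame(t = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"))
  for (ax in c("x", "y", "z")) {
    out[[ax]] <- stats::approx(t, trace$samples[[ax]], xout = grid,
                               method = "linear", rule = 2)$y
  }
  # blank out interpolation across long gaps
  gaps <- which(diff(t) > max_gap_s)
  if (length(gaps) > 0L) {
    for (gi in gaps) {
      inside <- grid > t[gi] & grid < t[gi + 1L]
      out$x[inside] <- NA_real_
      out$y[inside] <- NA_real_
      out$z[inside] <- NA_real_
    }
  }
  raw_trace(trace$device_id, rate_hz, out$t[1L], out, trace$dynamic_range_g)
}

#' Detect stationary windows in a raw trace
#'
#' Consecutive non-overlapping windows in which the per-axis sample standard
#' deviation is below threshold on all three axes. Their axis means are the
#' input to unit-sphere autocalibration.
#'
#' @param trace a [raw_trace()] (uniformly sampled).
#' @param window_s window length in seconds (default 10).
#' @param sd_threshold_mg per-axis sd threshold in mg (default 13).
#' @return data.frame with `start`, `end` (POSIXct) and `mx`, `my`, `mz`
#'   (mean acceleration per axis, g); zero rows when nothing is stationary.
#' @export
detect_stationary_epochs <- function(trace, window_s = 10, sd_threshold_mg = 13) {
  stopifnot(inherits(trace, "raw_trace"))
  n_per <- round(window_s * trace$sample_rate_hz)
  s <- trace$samples
  n_win <- floor(nrow(s) / n_per)
  empty <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      mx = numeric(), my = numeric(), mz = numeric())
  if (n_win == 0L) return(empty)
  idx <- rep(seq_len(n_win), each = n_per)
  used <- seq_len(n_win * n_per)
  win_stat <- function(v, f) {
    m <- tapply(v[used], idx, mean)
    sd_ <- tapply(v[used], idx, stats::sd)
    list(mean = as.numeric(m), sd = as.numeric(sd_))
  }
  sx <- win_stat(s$x); sy <- win_stat(s$y); sz <- win_stat(s$z)
  thr <- sd_threshold_mg / 1000
  ok <- !is.na(sx$sd) & !is.na(sy$sd) & !is.na(sz$sd) &
    sx$sd < thr & sy$sd < thr & sz$sd < thr
  if (!any(ok)) return(empty)
  starts <- s$t[(which(ok) - 1L) * n_per + 1L]
  data.frame(start = starts,
             end = starts + window_s,
             mx = sx$mean[ok], my = sy$mean[ok], mz = sz$mean[ok])
}

#' Fit a unit-sphere autocalibration model
#'
#' Iteratively fits per-axis offset and gain so that the calibrated means of
#' stationary windows lie on the 1-g sphere (the device at rest measures
#' exactly gravity). Requires a minimum number of stationary windows and
#' orientation coverage on both signs of every axis; otherwise the identity
#' model is returned with `fitted = FALSE`.
#'
#' @param stationary data.frame from [detect_stationary_epochs()].
#' @param min_points minimum stationary windows (default 50).
#' @param max_iter,tol_mg iteration cap and convergence tolerance on the
#'   residual change (default 100 iterations, 0.1 mg).
#' @return list of class `calibration_model`: `offset`, `gain` (length-3),
#'   `fitted`, `n_stationary_epochs`, `residual_before`, `residual_after`
#'   (mean absolute deviation of the calibrated norm from 1 g, in mg).
#' @export
fit_calibration <- function(stationary, min_points = 50, max_iter = 100,
                            tol_mg = 0.1) {
  p <- as.matrix(stationary[, c("mx", "my", "mz")])
  identity_model <- function(res) {
    structure(list(offset = c(0, 0, 0), gain = c(1, 1, 1), fitted = FALSE,
                   n_stationary_epochs = nrow(p),
                   residual_before = res, residual_after = res),
              class = "calibration_model")
  }
  resid_mg <- function(m) {
    cal <- sweep(sweep(m, 2L, c(0, 0, 0)), 2L, c(1, 1, 1), `*`)
    mean(abs(sqrt(rowSums(cal^2)) - 1)) * 1000
  }
  if (nrow(p) == 0L) return(identity_model(NA_real_))
  res0 <- mean(abs(sqrt(rowSums(p^2)) - 1)) * 1000
  coverage <- all(apply(p, 2L, function(v) any(v > 0.3) && any(v < -0.3)))
  if (nrow(p) < min_points || !coverage) return(identity_model(res0))

  offset <- c(0, 0, 0); gain <- c(1, 1, 1)
  prev <- res0
  for (it in seq_len(max_iter)) {
    cal <- sweep(sweep(p, 2L, offset), 2L, gain, `*`)
    nrm <- sqrt(rowSums(cal^2))
    target <- cal / nrm
    for (ax in 1:3) {
      co <- stats::coef(stats::lm.fit(cbind(1, p[, ax]), target[, ax]))
      gain[ax] <- co[2L]
      offset[ax] <- -co[1L] / co[2L]
    }
    cal <- sweep(sweep(p, 2L, offset), 2L, gain, `*`)
    res <- mean(abs(sqrt(rowSums(cal^2)) - 1)) * 1000
    if (abs(prev - res) < tol_mg) break
    prev <- res
  }
  if (any(gain < 0.5 | gain > 1.5)) return(identity_model(res0))
  structure(list(offset = offset, gain = gain, fitted = TRUE,
                 n_stationary_epochs = nrow(p),
                 residual_before = res0, residual_after = res),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> fitted=%s offset=(%.4f,%.4f,%.4f) g gain=(%.4f,%.4f,%.4f); residual %.2f -> %.2f mg (n=%d)\n",
    x$fitted, x$offset[1], x$offset[2], x$offset[3],
    x$gain[1], x$gain[2], x$gain[3],
    x$residual_before, x$residual_after, x$n_stationary_epochs))
  invisible(x)
}

#' Apply a calibration model to a raw trace
#'
#' Each sample is mapped axis-wise to `(value - offset) * gain`.
#'
#' @param trace a [raw_trace()].
#' @param model a `calibration_model` from [fit_calibration()].
#' @return The calibrated [raw_trace()].
#' @export
apply_calibration <- function(trace, model) {
  stopifnot(inherits(trace, "raw_trace"), inherits(model, "calibration_model"))
  s <- trace$samples
  s$x <- (s$x - model$offset[1L]) * model$gain[1L]
  s$y <- (s$y - model$offset[2L]) * model$gain[2L]
  s$z <- (s$z - model$offset[3L]) * model$gain[3L]
  out <- raw_trace(trace$device_id, trace$sample_rate_hz, trace$start_time,
                   s, trace$dynamic_range_g * max(model$gain) + 1)
  out$calibrated <- TRUE
  out
}

#' Summarise a calibrated trace into ENMO epochs
#'
#' Per sample, the truncated Euclidean norm minus one:
#' `vm = max(0, sqrt(x^2+y^2+z^2) - 1 g)`; per epoch, the mean sample vm in
#' mg. An `abs` variant (absolute value instead of truncation) is exposed for
#' sensitivity analyses. A partial trailing epoch is dropped. Epochs are also
#' flagged `stationary` when every axis' sample sd falls below
#' `sd_threshold_mg`, feeding non-wear detection.
#'
#' @param trace a calibrated [raw_trace()].
#' @param epoch_s epoch length in seconds (default 5).
#' @param negatives `"truncate"` (default) or `"abs"`.
#' @param sd_threshold_mg stationarity threshold for the epoch flag.
#' @return An [epoch_series()] with `vm_mg` and `stationary`.
#' @export
compute_vm_epochs <- function(trace, epoch_s = 5, negatives = c("truncate", "abs"),
                              sd_threshold_mg = 13) {
  stopifnot(inherits(trace, "raw_trace"))
  stopifnot_scalar_number(epoch_s, "epoch_s", positive = TRUE)
  negatives <- match.arg(negatives)
  s <- trace$samples
  n_per <- round(epoch_s * trace$sample_rate_hz)
  n_ep <- floor(nrow(s) / n_per)
  if (n_ep == 0L) {
    return(epoch_series(data.frame(start = as.POSIXct(character(), tz = "UTC"),
                                   vm_mg = numeric(), stationary = logical()),
                        epoch_s))
  }
  used <- seq_len(n_ep * n_per)
  idx <- rep(seq_len(n_ep), each = n_per)
  vm <- sqrt(s$x[used]^2 + s$y[used]^2 + s$z[used]^2) - 1
  vm <- if (negatives == "truncate") pmax(vm, 0) else abs(vm)
  vm_ep <- as.numeric(tapply(vm, idx, mean, na.rm = TRUE)) * 1000
  thr <- sd_threshold_mg / 1000
  stat_ax <- function(v) as.numeric(tapply(v[used], idx, stats::sd)) < thr
  stationary <- stat_ax(s$x) & stat_ax(s$y) & stat_ax(s$z)
  stationary[is.na(stationary)] <- FALSE
  vm_ep[is.nan(vm_ep)] <- NA_real_
  epoch_series(data.frame(start = s$t[(seq_len(n_ep) - 1L) * n_per + 1L],
                          vm_mg = vm_ep, stationary = stationary),
               epoch_s)
}
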