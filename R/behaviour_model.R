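#' Extract 30-s epoch features for behaviour classification
#'
#' For raw traces, computes the conventional wrist-accelerometry feature
#' family per 30-s epoch: mean and sd of the (truncated) vector magnitude,
#' per-axis means and sds, axis covariances, mean pitch and roll from the
#' gravity direction, dominant frequency and its power share, spectral power
#' in fixed bands (0.3-1, 1-3, 3-5 Hz) and the 1-s-lag autocorrelation of
#' the vector magnitude. For epoch-tier input the generator's `feat_*`
#' columns are passed through unchanged (that tier draws features directly
#' from class-conditional distributions).
#'
#' @param x a [raw_trace()] (calibrated) or an epoch-tier [epoch_series()].
#' @param epoch_s epoch length for raw input (default 30).
#' @return data.frame with `start`, one column per feature, and `valid`
#'   (FALSE when fewer than half the epoch's samples are present).
#' @export
extract_features <- function(x, epoch_s = 30) {
  if (inherits(x, "epoch_series")) {
    fc <- grep("^feat_", names(x), value = TRUE)
    if (length(fc) == 0L) stop("epoch series carries no feat_ columns")
    out <- as.data.frame(x)[, c("start", fc)]
    out$valid <- TRUE
    return(out)
  }
  stopifnot(inherits(x, "raw_trace"))
  s <- x$samples
  rate <- x$sample_rate_hz
  n_per <- round(epoch_s * rate)
  n_ep <- floor(nrow(s) / n_per)
  feat_cols <- c("mean_vm", "sd_vm", "mean_x", "mean_y", "mean_z",
                 "sd_x", "sd_y", "sd_z", "cov_xy", "cov_xz", "cov_yz",
                 "pitch", "roll", "dom_freq", "dom_power_share",
                 "band_low", "band_mid", "band_high", "autocorr_1s")
  blank <- stats::setNames(rep(NA_real_, length(feat_cols)), feat_cols)
  res <- vector("list", n_ep)
  lag1 <- round(rate)
  for (i in seq_len(n_ep)) {
    j <- ((i - 1L) * n_per + 1L):(i * n_per)
    xx <- s$x[j]; yy <- s$y[j]; zz <- s$z[j]
    ok <- !is.na(xx) & !is.na(yy) & !is.na(zz)
    if (mean(ok) < 0.5) {
      res[[i]] <- blank
      next
    }
    xx <- xx[ok]; yy <- yy[ok]; zz <- zz[ok]
    vm <- pmax(sqrt(xx^2 + yy^2 + zz^2) - 1, 0) * 1000
    mx <- mean(xx); my <- mean(yy); mz <- mean(zz)
    pitch <- atan2(mx, sqrt(my^2 + mz^2)) * 180 / pi
    roll <- atan2(my, sqrt(mx^2 + mz^2)) * 180 / pi
    # pooled per-axis power spectrum (the vm magnitude rectifies oscillation
    # about the gravity axis to twice its frequency, so frequency features
    # come from the axes themselves)
    nfft <- length(xx)
    sp <- (Mod(stats::fft(xx - mx))^2 + Mod(stats::fft(yy - my))^2 +
             Mod(stats::fft(zz - mz))^2) / nfft
    freqs <- (seq_len(nfft) - 1L) * rate / nfft
    half <- freqs > 0 & freqs <= rate / 2
    pw <- sp[half]; fq <- freqs[half]
    v <- vm - mean(vm)
    dom_i <- which.max(pw)
    total_pw <- sum(pw)
    band <- function(lo, hi) sum(pw[fq >= lo & fq < hi])
    ac <- if (length(v) > lag1 && stats::sd(v) > 0) {
      stats::cor(v[-seq_len(lag1)], v[seq_len(length(v) - lag1)])
    } else 0
    res[[i]] <- c(
      mean_vm = mean(vm), sd_vm = stats::sd(vm),
      mean_x = mx, mean_y = my, mean_z = mz,
      sd_x = stats::sd(xx), sd_y = stats::sd(yy), sd_z = stats::sd(zz),
      cov_xy = stats::cov(xx, yy), cov_xz = stats::cov(xx, zz),
      cov_yz = stats::cov(yy, zz),
      pitch = pitch, roll = roll,
      dom_freq = if (total_pw > 0) fq[dom_i] else 0,
      dom_power_share = if (total_pw > 0) pw[dom_i] / total_pw else 0,
      band_low = band(0.3, 1), band_mid = band(1, 3), band_high = band(3, 5),
      autocorr_1s = ac)
  }
  mat <- do.call(rbind, res)
  out <- as.data.frame(mat)
  out$valid <- !is.na(mat[, "mean_vm"])
  starts <- s$t[(seq_len(n_ep) - 1L) * n_per + 1L]
  cbind(data.frame(start = starts), out)
}

#' Train a balanced random forest of behaviour classifiers
#'
#' Each tree is grown on a bootstrap sample in which every class is
#' down-sampled to the rarest class's count, so the forest is not dominated
#' by the sedentary/sleep majority. Out-of-bag predictions over the full
#' training set are accumulated into a 5x5 confusion matrix (true x
#' predicted) that later becomes the HMM emission model.
#'
#' @param features data.frame of numeric feature columns plus a `label`
#'   column (behaviour-state factor).
#' @param n_trees number of trees (default 100).
#' @param seed integer seed.
#' @param mtry features tried per split (default `sqrt(p)`).
#' @return list of class `behaviour_model` with elements `forest` (a ranger
#'   fit), `feature_names`, `states`, `oob_confusion`, `oob_accuracy`; HMM
#'   components are added by [estimate_hmm()].
#' @export
train_balanced_rf <- function(features, n_trees = 100, seed = 1, mtry = NULL,
                              probability = FALSE) {
  stopifnot("label" %in% names(features))
  label <- as_behaviour_state(features$label)
  present <- levels(droplevels(label))
  if (length(present) < 2L) stop("training error: need >= 2 classes")
  cnt <- table(factor(label, levels = present))
  if (any(cnt < 10L)) {
    stop("training error: class '", names(cnt)[which(cnt < 10L)[1L]],
         "' has fewer than 10 epochs")
  }
  fn <- setdiff(names(features), c("label", "start", "valid", "wear"))
  x <- features[, fn, drop = FALSE]
  df <- data.frame(x, .label = droplevels(label))
  frac <- rep(min(cnt) / nrow(df), length(present))
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = n_trees,
    mtry = mtry %||% max(1L, floor(sqrt(length(fn)))),
    sample.fraction = frac, replace = TRUE,
    seed = seed, num.threads = 1L,
    keep.inbag = TRUE,
    probability = probability,
    respect.unordered.factors = TRUE)
  oob <- if (probability) {
    pr <- fit$predictions
    lab <- colnames(pr)[max.col(pr, ties.method = "first")]
    lab[!is.finite(rowSums(pr))] <- NA
    factor(lab, levels = levels(df$.label))
  } else {
    fit$predictions
  }
  conf <- table(true = factor(as.character(label), levels = behaviour_states()),
                predicted = factor(as.character(oob), levels = behaviour_states()))
  conf <- matrix(as.integer(conf), 5L, 5L,
                 dimnames = list(true = behaviour_states(),
                                 predicted = behaviour_states()))
  structure(list(forest = fit, feature_names = fn,
                 states = behaviour_states(),
                 classes_present = present,
                 oob_confusion = conf,
                 oob_accuracy = sum(diag(conf)) / sum(conf)),
            class = "behaviour_model")
}

#' @export
print.behaviour_model <- function(x, ...) {
  cat(sprintf("<behaviour_model> %d trees, OOB accuracy %.3f%s\n",
              x$forest$num.trees, x$oob_accuracy,
              if (!is.null(x$hmm)) ", HMM attached" else ""))
  invisible(x)
}

#' Estimate HMM smoothing parameters from labelled sequences
#'
#' Transitions are row-normalised bigram counts over the true label
#' sequences plus a smoothing pseudo-count `alpha`; the prior is the
#' normalised state frequency; the emission matrix P(observed label | true
#' state) is the row-normalised out-of-bag confusion plus `alpha`.
#' `alpha = 0` is legal only when every bigram (and confusion cell's row)
#' has been observed, since Viterbi decoding works in log space.
#'
#' @param label_sequences list of behaviour-state vectors (one per
#'   continuous bout of labelled wear, e.g. per participant-day).
#' @param oob_confusion 5x5 true x predicted count matrix.
#' @param alpha pseudo-count (default 1).
#' @return list with `prior`, `transitions`, `emission` (all strictly
#'   positive, rows summing to 1).
#' @export
estimate_hmm <- function(label_sequences, oob_confusion, alpha = 1) {
  S <- length(behaviour_states())
  big <- matrix(0, S, S, dimnames = list(behaviour_states(), behaviour_states()))
  freq <- rep(0, S)
  for (seq_ in label_sequences) {
    s <- as.integer(as_behaviour_state(seq_))
    freq <- freq + tabulate(s, nbins = S)
    if (length(s) > 1L) {
      for (k in seq_len(length(s) - 1L)) big[s[k], s[k + 1L]] <- big[s[k], s[k + 1L]] + 1
    }
  }
  if (alpha == 0 && (any(big == 0) || any(oob_confusion == 0))) {
    stop("alpha = 0 requires every bigram and confusion cell to be observed")
  }
  norm_rows <- function(m) {
    out <- sweep(m + alpha, 1L, rowSums(m + alpha), `/`)
    dimnames(out) <- list(behaviour_states(), behaviour_states())
    out
  }
  prior <- (freq + alpha) / sum(freq + alpha)
  list(prior = stats::setNames(prior, behaviour_states()),
       transitions = norm_rows(big),
       emission = norm_rows(oob_confusion))
}

#' Viterbi time smoothing of predicted behaviour labels
#'
#' Decodes the maximum a-posteriori true-state path given the forest's
#' per-epoch argmax labels, under the HMM's prior, transition and emission
#' matrices, in log space. Ties break toward the lowest state index.
#'
#' @param observed vector of predicted behaviour labels.
#' @param model a `behaviour_model` with an `hmm` component, or a list with
#'   `prior`, `transitions`, `emission`.
#' @return factor vector of smoothed states (empty for empty input).
#' @export
viterbi_smooth <- function(observed, model) {
  hmm <- if (!is.null(model$hmm)) model$hmm else model
  if (length(observed) == 0L) return(as_behaviour_state(character()))
  obs <- as.integer(as_behaviour_state(observed))
  path <- .viterbi_path(obs, log(hmm$prior), log(hmm$transitions),
                        log(hmm$emission))
  as_behaviour_state(behaviour_states()[path])
}

#' Evaluate predicted against true behaviour sequences
#'
#' @param predicted,truth equal-length behaviour-state vectors.
#' @return list with `accuracy`, `kappa` (Cohen), `per_class`
#'   (precision/recall per state) and `confusion` (true x predicted).
#' @export
evaluate_model <- function(predicted, truth) {
  p <- as_behaviour_state(predicted)
  t_ <- as_behaviour_state(truth)
  if (length(p) != length(t_)) stop("length mismatch")
  conf <- table(true = t_, predicted = p)
  n <- sum(conf)
  acc <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 1
  per_class <- data.frame(
    state = behaviour_states(),
    precision = diag(conf) / pmax(colSums(conf), 1L),
    recall = diag(conf) / pmax(rowSums(conf), 1L),
    row.names = NULL)
  per_class$precision[colSums(conf) == 0L] <- NA_real_
  per_class$recall[rowSums(conf) == 0L] <- NA_real_
  list(accuracy = acc, kappa = kappa, per_class = per_class, confusion = conf)
}

#' Predict and smooth behaviour states for an epoch series
#'
#' Applies the forest to each worn epoch's features, then Viterbi-smooths
#' each continuous stretch (per calendar day) of predictions. Unworn epochs
#' receive no prediction. The default observation model feeds the forest's
#' argmax labels through the OOB-confusion emission matrix; with
#' `mode = "probs"` (requires a probability forest) the forest's
#' class-probability vectors are used directly as per-epoch likelihoods.
#'
#' @param model a trained `behaviour_model` with `hmm` attached.
#' @param epochs an [epoch_series()] with feature columns and `wear`.
#' @param mode `"labels"` (default) or `"probs"`.
#' @param prob_floor probability floor applied before taking logs in
#'   `"probs"` mode.
#' @return the series with a `predicted` column (behaviour-state factor).
#' @export
predict_behaviour <- function(model, epochs, mode = c("labels", "probs"),
                              prob_floor = 1e-4) {
  stopifnot(inherits(model, "behaviour_model"))
  mode <- match.arg(mode)
  feats <- as.data.frame(epochs)[, model$feature_names, drop = FALSE]
  wear <- if ("wear" %in% names(epochs)) epochs$wear else rep(TRUE, nrow(epochs))
  pred <- rep(NA_character_, nrow(epochs))
  use_probs <- mode == "probs"
  if (use_probs && model$forest$treetype != "Probability estimation") {
    stop("mode = 'probs' requires a forest trained with probability = TRUE")
  }
  probs <- NULL
  if (any(wear)) {
    raw <- predict(model$forest, data = feats[wear, , drop = FALSE],
                   num.threads = 1L)$predictions
    if (use_probs) {
      probs <- matrix(prob_floor, nrow = sum(wear), ncol = 5L,
                      dimnames = list(NULL, behaviour_states()))
      probs[, colnames(raw)] <- pmax(raw, prob_floor)
      pred[wear] <- colnames(probs)[max.col(probs, ties.method = "first")]
    } else {
      pred[wear] <- as.character(raw)
    }
  }
  if (!is.null(model$hmm)) {
    day <- date_of(epochs$start)
    wi <- which(wear)
    for (d in unique(day)) {
      i <- which(day == d & wear & !is.na(pred))
      if (!length(i)) next
      if (use_probs) {
        ll <- log(probs[match(i, wi), , drop = FALSE])
        path <- .viterbi_path_ll(ll, log(model$hmm$prior),
                                 log(model$hmm$transitions))
        pred[i] <- behaviour_states()[path]
      } else {
        pred[i] <- as.character(viterbi_smooth(pred[i], model))
      }
    }
  }
  epochs$predicted <- as_behaviour_state(pred)
  epochs
}
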