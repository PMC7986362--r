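# Shared fixture builders. Everything is generated in code; no data files.

# constant-orientation raw trace of n seconds at rate hz
make_trace <- function(n_s = 60, rate = 25, xyz = c(0, 0, 1), noise_sd = 0,
                       t0 = as.POSIXct("2017-01-02 00:00:00", tz = "UTC")) {
  n <- n_s * rate
  tt <- t0 + (seq_len(n) - 1) / rate
  s <- data.frame(t = tt,
                  x = xyz[1] + rnorm(n, 0, noise_sd),
                  y = xyz[2] + rnorm(n, 0, noise_sd),
                  z = xyz[3] + rnorm(n, 0, noise_sd))
  raw_trace("TEST", rate, t0, s)
}

# well-spread unit-sphere stationary means, optionally miscalibrated:
# observed = true / gain + offset (per axis)
make_sphere_points <- function(n = 200, offset = c(0, 0, 0), gain = c(1, 1, 1),
                               jitter = 5e-4) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  u <- u + matrix(rnorm(3 * n, 0, jitter), ncol = 3)
  obs <- sweep(sweep(u, 2, gain, `/`), 2, offset, `+`)
  data.frame(start = as.POSIXct("2017-01-02", tz = "UTC") + seq_len(n) * 10,
             end = as.POSIXct("2017-01-02", tz = "UTC") + seq_len(n) * 10 + 10,
             mx = obs[, 1], my = obs[, 2], mz = obs[, 3])
}

# hand-built minute grid: vm/state/wear as days x 1440 matrices
make_grid <- function(day_types, vm = 10, state = "sedentary", wear = TRUE,
                      id = "T01", dates = NULL) {
  nd <- length(day_types)
  expand <- function(x, mode) {
    if (is.matrix(x)) return(x)
    matrix(x, nd, 1440L)
  }
  st <- expand(if (is.character(state)) match(state, behaviour_states()) else state)
  dates <- dates %||% (as.Date("2017-01-02") + seq_len(nd) - 1L)
  minute_grid(id,
              data.frame(date = dates, day_type = day_types),
              expand(vm), st, expand(wear),
              matrix(FALSE, nd, 1440L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 30-s epoch series over whole days with given per-epoch state labels
make_epochs <- function(labels, vm = 10, wear = TRUE, stationary = FALSE,
                        t0 = as.POSIXct("2017-01-02 00:00:00", tz = "UTC")) {
  n <- length(labels)
  epoch_series(data.frame(
    start = t0 + (seq_len(n) - 1) * 30,
    vm_mg = rep_len(vm, n),
    wear = rep_len(wear, n),
    stationary = rep_len(stationary, n),
    label = labels), epoch_s = 30)
}

# independent oracle: exhaustive maximum a-posteriori path search.
# Scores every one of S^T paths directly from the matrices and returns the
# best path, its score, and the margin to the runner-up (for tie detection).
path_log_score <- function(path, obs, prior, trans, emis) {
  T_ <- length(obs)
  sc <- log(prior[path[1]]) + sum(log(emis[cbind(path, obs)]))
  if (T_ > 1) {
    sc <- sc + sum(log(trans[cbind(path[-T_], path[-1])]))
  }
  sc
}

brute_force_viterbi <- function(obs, prior, trans, emis) {
  T_ <- length(obs); S <- length(prior)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  score <- log(prior[paths[, 1]]) + log(emis[cbind(paths[, 1], obs[1])])
  if (T_ > 1) {
    for (t_ in 2:T_) {
      score <- score + log(trans[cbind(paths[, t_ - 1], paths[, t_])]) +
        log(emis[cbind(paths[, t_], obs[t_])])
    }
  }
  ord <- order(score, decreasing = TRUE)
  list(path = as.integer(paths[ord[1], ]),
       score = score[ord[1]],
       margin = if (length(ord) > 1) score[ord[1]] - score[ord[2]] else Inf)
}

# a decoded path agrees with the oracle when it attains the maximal score;
# away from numerical ties the paths themselves must coincide
viterbi_agrees <- function(fast, obs, prior, trans, emis, tol = 1e-9) {
  bf <- brute_force_viterbi(obs, prior, trans, emis)
  sc <- path_log_score(as.integer(fast), obs, prior, trans, emis)
  if (abs(sc - bf$score) > tol) return(FALSE)
  if (bf$margin > tol && !identical(as.integer(fast), bf$path)) return(FALSE)
  TRUE
}

# random row-stochastic matrix with strictly positive entries
rand_stoch <- function(S) {
  m <- matrix(stats::runif(S * S, 0.05, 1), S, S)
  sweep(m, 1, rowSums(m), `/`)
}

# labelled class-conditional Gaussian feature sets (the epoch-tier family)
sim_features <- function(n_per_class, sep, classes = behaviour_states(),
                         seed = 1) {
  set.seed(seed)
  cfg <- generator_config(feature_separation = sep)
  mu <- dialacc:::feature_class_means(cfg)
  lab <- rep(classes, each = n_per_class)
  idx <- match(lab, behaviour_states())
  f <- mu[idx, , drop = FALSE] + matrix(rnorm(length(lab) * 5), length(lab))
  df <- as.data.frame(f)
  names(df) <- paste0("feat_", 1:5)
  df$label <- lab
  df
}
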