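#' Summarise a participant's minute grid
#'
#' Per day type and overall: mean vector magnitude over non-missing minutes,
#' and hours/day spent in each behaviour state (minutes in state / 60,
#' averaged over that type's included days). The overall summary is the mean
#' over all included days (not the mean of the two day-type values), i.e. a
#' wear-time-weighted reading.
#'
#' @param grid an imputed [minute_grid()] (the participant should have
#'   passed the excellent-wear criterion; see [assess_wear()]).
#' @return data.frame of class `activity_summary`: one row per day type plus
#'   `overall`, with `mean_vm`, `<state>_h` columns and `n_days`.
#' @export
summarize_participant <- function(grid) {
  stopifnot(inherits(grid, "minute_grid"))
  keep <- grid$days$day_type != "excluded"
  one <- function(rows) {
    if (length(rows) == 0L) return(NULL)
    vm <- grid$vm[rows, , drop = FALSE]
    st <- grid$state[rows, , drop = FALSE]
    hrs <- vapply(1:5, function(s) {
      sum(st == s, na.rm = TRUE) / 60 / length(rows)
    }, 0)
    out <- data.frame(mean_vm = mean(vm, na.rm = TRUE), n_days = length(rows))
    out[paste0(behaviour_states(), "_h")] <- as.list(hrs)
    out
  }
  rows_d <- which(keep & grid$days$day_type == "dialysis")
  rows_n <- which(keep & grid$days$day_type == "non-dialysis")
  parts <- list(dialysis = one(rows_d), `non-dialysis` = one(rows_n),
                overall = one(which(keep)))
  parts <- parts[!vapply(parts, is.null, TRUE)]
  out <- do.call(rbind, parts)
  out <- cbind(data.frame(participant_id = grid$participant_id,
                          day_type = names(parts), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  class(out) <- c("activity_summary", "data.frame")
  out
}

#' Group means with standard errors
#'
#' Mean and SE (= sd / sqrt(n)) per group for each outcome column; groups
#' with a single member report the mean with a missing SE, and empty groups
#' are omitted with a warning.
#'
#' @param df data.frame of per-participant values.
#' @param outcomes character vector of outcome column names.
#' @param grouping name of a factor column (or NULL for one overall group).
#' @return data.frame with `group`, `n`, and `<outcome>_mean` / `<outcome>_se`
#'   columns.
#' @export
group_mean_se <- function(df, outcomes, grouping = NULL) {
  g <- if (is.null(grouping)) {
    factor(rep("all", nrow(df)))
  } else if (is.factor(df[[grouping]])) {
    df[[grouping]]
  } else {
    factor(df[[grouping]])
  }
  lev <- levels(g)
  empty <- lev[!lev %in% as.character(unique(g[!is.na(g)]))]
  if (length(empty)) warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
  lev <- setdiff(lev, empty)
  rows <- lapply(lev, function(l) {
    i <- which(g == l)
    out <- data.frame(group = l, n = length(i), stringsAsFactors = FALSE)
    for (oc in outcomes) {
      v <- df[[oc]][i]
      v <- v[!is.na(v)]
      out[[paste0(oc, "_mean")]] <- mean(v)
      out[[paste0(oc, "_se")]] <- if (length(v) >= 2L) {
        stats::sd(v) / sqrt(length(v))
      } else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}

#' Paired dialysis versus non-dialysis day test
#'
#' Classical paired t-test on within-participant differences
#' (dialysis minus non-dialysis) for one outcome.
#'
#' @param summaries an [summarize_participant()] stack (rows for both day
#'   types per participant).
#' @param outcome outcome column name (e.g. `"mean_vm"`).
#' @return list: `mean_difference`, `t`, `df`, `p`, `n`; when the
#'   differences have zero variance around a nonzero mean, `p` is reported
#'   as 0 with `degenerate = TRUE`.
#' @export
paired_daytype_test <- function(summaries, outcome) {
  d <- summaries[summaries$day_type == "dialysis", c("participant_id", outcome)]
  n_ <- summaries[summaries$day_type == "non-dialysis", c("participant_id", outcome)]
  m <- merge(d, n_, by = "participant_id", suffixes = c("_d", "_n"))
  diffs <- m[[paste0(outcome, "_d")]] - m[[paste0(outcome, "_n")]]
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 2L) stop("need >= 2 participants with both day types")
  if (stats::sd(diffs) == 0) {
    if (mean(diffs) == 0) {
      return(list(mean_difference = 0, t = 0, df = length(diffs) - 1L,
                  p = 1, n = length(diffs), degenerate = FALSE))
    }
    return(list(mean_difference = mean(diffs), t = Inf,
                df = length(diffs) - 1L, p = 0, n = length(diffs),
                degenerate = TRUE))
  }
  tt <- stats::t.test(diffs)
  list(mean_difference = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, n = length(diffs),
       degenerate = FALSE)
}

#' Covariate-adjusted marginal means by group
#'
#' Fits `outcome ~ group + age + sex + leg_weakness` by least squares and
#' reports each group's estimated marginal mean: the model prediction at the
#' cohort-average covariate values (age at its mean, sex and leg weakness at
#' their observed proportions). Heterogeneity p comes from the group-term F
#' test; the trend p from re-coding the ordered groups 0, 1, 2, ... as a
#' numeric slope.
#'
#' @param df data.frame with the outcome, `group`, and covariate columns.
#' @param outcome outcome column name.
#' @param group grouping column name (factor; ordered for the trend test).
#' @param adjust_for covariate column names (default age, sex,
#'   leg_weakness).
#' @return list: `marginal` (data.frame group / n / emmean / se),
#'   `p_heterogeneity`, `p_trend`, `model`.
#' @export
adjusted_marginal_means <- function(df, outcome, group,
                                    adjust_for = c("age", "sex", "leg_weakness")) {
  dat <- df[, c(outcome, group, adjust_for)]
  dat <- dat[stats::complete.cases(dat), ]
  dat[[group]] <- droplevels(factor(dat[[group]]))
  fml <- stats::as.formula(paste(outcome, "~", group, "+",
                                 paste(adjust_for, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  if (anyNA(stats::coef(fit))) {
    stop("rank deficiency: aliased term(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  # reference grid: each group at the cohort-average covariate values;
  # factors/logicals enter at their observed proportions via model-matrix
  # column means
  mm <- stats::model.matrix(fit)
  asg <- attr(mm, "assign")
  term_lab <- attr(stats::terms(fit), "term.labels")
  grp_cols <- which(asg == which(term_lab == group))
  lev <- levels(dat[[group]])
  X <- matrix(rep(colMeans(mm), length(lev)), nrow = length(lev), byrow = TRUE,
              dimnames = list(lev, colnames(mm)))
  contr <- stats::contrasts(dat[[group]])          # treatment coding
  X[, grp_cols] <- contr[lev, , drop = FALSE]
  est <- as.vector(X %*% stats::coef(fit))
  se <- sqrt(diag(X %*% stats::vcov(fit) %*% t(X)))
  marginal <- data.frame(group = lev,
                         n = as.vector(table(dat[[group]])[lev]),
                         emmean = est, se = se, row.names = NULL)
  fit0 <- stats::lm(stats::as.formula(paste(outcome, "~",
                                            paste(adjust_for, collapse = " + "))),
                    data = dat)
  p_het <- stats::anova(fit0, fit)$`Pr(>F)`[2L]
  dat$.trend <- as.numeric(factor(dat[[group]], levels = lev)) - 1
  fit_tr <- stats::lm(stats::as.formula(paste(outcome, "~ .trend +",
                                              paste(adjust_for, collapse = " + "))),
                      data = dat)
  p_trend <- summary(fit_tr)$coefficients[".trend", "Pr(>|t|)"]
  list(marginal = marginal, p_heterogeneity = p_het, p_trend = p_trend,
       model = fit)
}

#' Spearman correlations between activity measures and questionnaire scores
#'
#' Rank correlations (average ranks for ties) with two-sided p-values for
#' every activity-measure x questionnaire-score pair. Pairs with fewer than
#' 3 complete observations or a constant column are flagged undefined.
#'
#' @param df data.frame holding both sets of columns.
#' @param activity_cols,score_cols column name vectors.
#' @return data.frame: `activity`, `score`, `rho`, `p`, `n`, `defined`.
#' @export
questionnaire_correlations <- function(df, activity_cols, score_cols) {
  rows <- list()
  for (a in activity_cols) for (s in score_cols) {
    x <- df[[a]]; y <- df[[s]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        activity = a, score = s, rho = NA_real_, p = NA_real_, n = n,
        defined = FALSE, stringsAsFactors = FALSE)
      next
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                           exact = FALSE))
    rows[[length(rows) + 1L]] <- data.frame(
      activity = a, score = s, rho = unname(ct$estimate), p = ct$p.value,
      n = n, defined = TRUE, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Time-of-day profile curves
#'
#' Per clock bin, the mean across participants of the participant's bin mean
#' (vector magnitude, or the fraction of minutes spent in a state), with a
#' 95% confidence interval of +/- 1.96 SE across participants. Day types
#' can be profiled separately.
#'
#' @param grids list of imputed [minute_grid()]s.
#' @param bin_min bin width in minutes; must divide 1440 (default 10).
#' @param outcome `"vm"` or a behaviour-state name (profiles the fraction
#'   of minutes in that state).
#' @param day_type `"dialysis"`, `"non-dialysis"` or `"all"`.
#' @return data.frame: `bin_start_min`, `mean`, `se`, `ci_lo`, `ci_hi`, `n`.
#' @export
time_of_day_profile <- function(grids, bin_min = 10,
                                outcome = "vm", day_type = "all") {
  if (1440 %% bin_min != 0) stop("bin_min must divide 1440")
  nb <- 1440L %/% bin_min
  bin_of <- rep(seq_len(nb), each = bin_min)
  per_part <- vapply(grids, function(g) {
    rows <- if (day_type == "all") {
      which(g$days$day_type != "excluded")
    } else {
      which(g$days$day_type == day_type)
    }
    if (length(rows) == 0L) return(rep(NA_real_, nb))
    v <- if (outcome == "vm") {
      g$vm[rows, , drop = FALSE]
    } else {
      s <- match(outcome, behaviour_states())
      (g$state[rows, , drop = FALSE] == s) * 1
    }
    day_bin <- colMeans(v, na.rm = TRUE)          # mean over days, per minute
    as.vector(tapply(day_bin, bin_of, mean, na.rm = TRUE))
  }, numeric(nb))
  n <- rowSums(!is.na(per_part))
  m <- rowMeans(per_part, na.rm = TRUE)
  se <- apply(per_part, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_
  })
  data.frame(bin_start_min = (seq_len(nb) - 1L) * bin_min,
             mean = m, se = se,
             ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se, n = n)
}

#' Greedy matched-control selection
#'
#' For each case, in randomised order, selects up to `k` unused controls
#' with exactly matching sex and wear season and the nearest age within
#' `age_caliper` years; controls are used at most once across all sets.
#' Cases with no eligible control are reported unmatched.
#'
#' @param cases,pool data.frames with `id`, `age`, `sex`, `wear_season`.
#' @param k maximum controls per case (default 5).
#' @param age_caliper maximum absolute age difference in years (default 3).
#' @param seed integer seed for the case order.
#' @return list: `sets` (data.frame case_id / control_id / age_diff) and
#'   `unmatched` (case ids).
#' @export
match_controls <- function(cases, pool, k = 5, age_caliper = 3, seed = 1) {
  if (k <= 0) stop("parameter error: k must be > 0")
  if (any(cases$id %in% pool$id)) stop("pool must be disjoint from cases")
  set.seed(seed)
  order_ <- sample.int(nrow(cases))
  used <- rep(FALSE, nrow(pool))
  sets <- list(); unmatched <- character()
  for (ci in order_) {
    case <- cases[ci, ]
    elig <- which(!used &
                    pool$sex == case$sex &
                    pool$wear_season == case$wear_season &
                    abs(pool$age - case$age) <= age_caliper)
    if (length(elig) == 0L) {
      unmatched <- c(unmatched, case$id)
      next
    }
    take <- elig[order(abs(pool$age[elig] - case$age))][seq_len(min(k, length(elig)))]
    used[take] <- TRUE
    sets[[length(sets) + 1L]] <- data.frame(
      case_id = case$id, control_id = pool$id[take],
      age_diff = pool$age[take] - case$age, stringsAsFactors = FALSE)
  }
  list(sets = if (length(sets)) do.call(rbind, sets) else
    data.frame(case_id = character(), control_id = character(),
               age_diff = numeric()),
    unmatched = unmatched)
}
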