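rtrunc_norm <- function(n, mean, sd, lo, hi) {
  # inverse-CDF truncated normal: deterministic given the RNG stream
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

season_of <- function(dates) {
  m <- as.integer(format(as.Date(dates), "%m"))
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")[m]
}

# Per-participant activity model. Overall true vector magnitude is
#   cohort mean + slope * (age - mean age) + deficit * (leg - leg fraction)
#   + participant noise,
# expressed as a relative factor rho applied to the day-type profile means.
# Behaviour hours scale with sqrt(rho) (part of the gradient is moving less
# often, part is moving less intensely); active-state epoch intensity is then
# solved per day type so each participant's true day-type vector magnitude is
# hit exactly, with sedentary hours absorbing the active-hour change.
participant_truth <- function(cohort, config) {
  sm <- state_means(config)
  act <- c("walking", "light_tasks", "moderate")
  rows <- list()
  for (dtype in c("dialysis", "non-dialysis")) {
    h <- config$behaviour_day_profile[[dtype]]
    vm_dt <- config$day_profile_vm[[dtype]]
    a <- sqrt(cohort$rho)
    h_act <- outer(a, h[act])                     # n x 3 active hours
    sed <- h[["sedentary"]] + (1 - a) * sum(h[act])
    sleep <- rep(h[["sleep"]], nrow(cohort))
    vm_target <- vm_dt * cohort$rho
    floor_vm <- (sed * sm[["sedentary"]] + sleep * sm[["sleep"]]) / 24
    vm_target <- pmax(vm_target, floor_vm + 0.3)
    denom <- as.vector(h_act %*% sm[act])
    b <- (24 * vm_target - sed * sm[["sedentary"]] - sleep * sm[["sleep"]]) / denom
    b <- pmax(b, 0.05)
    rows[[dtype]] <- data.frame(
      id = cohort$id, day_type = dtype,
      vm_true = vm_target,
      walking_h = h_act[, "walking"],
      light_tasks_h = h_act[, "light_tasks"],
      moderate_h = h_act[, "moderate"],
      sedentary_h = sed, sleep_h = sleep,
      intensity_mult = b,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Generate a synthetic dialysis cohort with known truth
#'
#' Draws demographics, dialysis schedules, clinical flags and per-participant
#' true activity from a [generator_config()]. The returned truth table gives,
#' per participant and day type, the true mean vector magnitude and the true
#' expected hours per behaviour state, for use in recovery tests.
#'
#' Age and the leg-weakness flag shift each participant's true overall
#' activity by `age_activity_slope` mg/year and
#' `leg_weakness_activity_deficit` mg respectively (both centred so the
#' cohort mean is preserved), on top of residual participant-level noise with
#' sd `participant_sd`. A handful of clinical flags are left missing to
#' mirror real cohort tables (tri-state booleans).
#'
#' @param config a [generator_config()].
#' @return list with `cohort` (one row per participant) and `truth` (two
#'   rows per participant: dialysis and non-dialysis).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_participants
  set.seed(derive_seed(config$seed, 1L))
  ad <- config$age_distribution
  age <- rtrunc_norm(n, ad[["mean"]], ad[["sd"]], ad[["min"]], ad[["max"]])
  n_f <- round(config$female_fraction * n)
  sex <- sample(c(rep("female", n_f), rep("male", n - n_f)))
  n_leg <- round(config$leg_weakness_fraction * n)
  # stratify the leg-weakness flag across age thirds so the age and
  # leg-weakness activity gradients stay orthogonal in any one cohort draw
  terts <- stats::quantile(age, c(1 / 3, 2 / 3))
  third <- findInterval(age, terts) + 1L
  leg <- rep(FALSE, n)
  alloc <- floor(table(third) * config$leg_weakness_fraction)
  short <- n_leg - sum(alloc)
  if (short > 0) {
    bump <- sample.int(3L, abs(short))
    for (b in bump) alloc[b] <- alloc[b] + 1L
  }
  for (k in 1:3) {
    i <- which(third == k)
    leg[sample(i, min(alloc[k], length(i)))] <- TRUE
  }
  pattern <- sample(c("Mon;Wed;Fri", "Tue;Thu;Sat"), n, replace = TRUE)
  n_morning <- round(config$slot_split * n)
  slot <- sample(c(rep("morning", n_morning), rep("afternoon", n - n_morning)))
  start <- config$start_date +
    7L * sample.int(config$start_spread_weeks + 1L, n, replace = TRUE) - 7L

  breath <- stats::runif(n) < 0.49
  cvd_dm <- stats::runif(n) < 0.58
  transplant <- stats::runif(n) < 0.14
  arrhythmia <- stats::runif(n) < 0.47
  cvd_dm[sample.int(n, 1L)] <- NA
  transplant[sample.int(n, 1L)] <- NA
  arrhythmia[sample.int(n, min(5L, n))] <- NA

  eps <- stats::rnorm(n, 0, config$participant_sd)
  eps <- eps - mean(eps)   # the cohort is the finite study population
  delta <- config$age_activity_slope * (age - mean(age)) +
    config$leg_weakness_activity_deficit * (leg - mean(leg)) + eps
  cohort_mean_vm <- config$activity_scale[["mean"]]
  rho <- pmin(pmax(1 + delta / cohort_mean_vm, 0.25), 2.5)

  cohort <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    age = age, sex = sex,
    dialysis_weekdays = pattern,
    slot = slot,
    leg_weakness = leg,
    breathlessness = breath,
    listed_transplant = transplant,
    arrhythmia = arrhythmia,
    cvd_or_dm = cvd_dm,
    start_date = start,
    wear_season = season_of(start),
    rho = rho,
    stringsAsFactors = FALSE)
  truth <- participant_truth(cohort, config)
  list(cohort = cohort, truth = truth)
}
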