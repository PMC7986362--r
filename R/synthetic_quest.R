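cut_levels <- function(z, n_levels) {
  # map a standard-normal latent onto ordinal levels 1..n (higher = better)
  br <- stats::qnorm(seq_len(n_levels - 1L) / n_levels)
  findInterval(z, br) + 1L
}

#' Generate questionnaire responses linked to true activity
#'
#' KCCQ physical-limitation (and other domain) item levels and EQ-5D-3L
#' domain levels are drawn from a latent health score that mixes the
#' participant's standardised true activity with noise at a configurable
#' strength, so that limitation scores and activity share a controllable
#' rank correlation (strength 0 gives independence; strength near 1 gives
#' near-monotone agreement).
#'
#' @param participant one cohort row.
#' @param true_activity the participant's true overall vector magnitude, mg.
#' @param config the [generator_config()] (uses `questionnaire_strength` and
#'   `activity_scale`).
#' @param seed integer seed.
#' @return list with `kccq` (see [kccq_response()]) and `eq5d`
#'   ([eq5d_response()]).
#' @export
generate_questionnaires <- function(participant, true_activity, config, seed) {
  stopifnot(true_activity > 0)
  set.seed(seed)
  s <- config$questionnaire_strength
  z_act <- (true_activity - config$activity_scale[["mean"]]) /
    config$activity_scale[["sd"]]
  latent <- s * z_act + sqrt(max(0, 1 - s^2)) * stats::rnorm(1L)
  item <- function(k, n_levels = 5L, jitter = 0.6) {
    z <- (latent + stats::rnorm(k, 0, jitter)) / sqrt(1 + jitter^2)
    cut_levels(z, n_levels)
  }
  kccq <- kccq_response(
    physical_limitation = item(6L),
    symptoms = item(8L),
    quality_of_life = item(3L),
    social_limitation = item(4L))
  lv3 <- function(k, jitter = 0.6) 4L - item(k, 3L, jitter)  # 1 best .. 3 worst
  mob <- lv3(3L)
  eq5d <- eq5d_response(
    mobility = mob[1L], self_care = mob[2L], usual_activities = mob[3L],
    pain_discomfort = cut_levels(stats::rnorm(1L), 3L),
    anxiety_depression = cut_levels(stats::rnorm(1L), 3L),
    vas = min(100L, max(1L, round(60 + 15 * latent + stats::rnorm(1L, 0, 8)))))
  list(kccq = kccq, eq5d = eq5d)
}

control_profiles <- list(
  healthy = list(vm = 28.1,
                 hours = c(walking = 2.70, light_tasks = 1.30, moderate = 1.10,
                           sedentary = 10.30, sleep = 8.60),
                 age = c(mean = 64.1, sd = 9.5), female = 0.35),
  cvd_dm = list(vm = 23.4,
                hours = c(walking = 2.20, light_tasks = 1.05, moderate = 0.85,
                          sedentary = 11.30, sleep = 8.60),
                age = c(mean = 65.0, sd = 8.8), female = 0.34),
  heart_failure = list(vm = 22.9,
                       hours = c(walking = 2.00, light_tasks = 1.00,
                                 moderate = 0.80, sedentary = 11.60,
                                 sleep = 8.60),
                       age = c(mean = 67.0, sd = 6.6), female = 0.22))

#' Generate a matched-control candidate pool
#'
#' Controls have no dialysis schedule and conventional night-sleep timing.
#' The scenario fixes the pool's true mean vector magnitude (apparently
#' healthy 28.1 mg, prior CVD and/or diabetes 23.4 mg, heart failure
#' 22.9 mg) and demographic mix; ages are confined to 45-75 years (the range
#' in which population controls are available for matching). Each control
#' gets a wear season, an age-gradient plus noise on true activity, and
#' `wear_days` days of epoch-tier data when `with_epochs = TRUE`.
#'
#' @param scenario `"healthy"`, `"cvd_dm"` or `"heart_failure"`.
#' @param n pool size.
#' @param config a [generator_config()] (state distributions, feature and
#'   non-wear settings are shared with the cohort generator).
#' @param seed integer seed.
#' @param wear_days days of data per control (default 7).
#' @param with_epochs generate epoch series (default TRUE).
#' @return list with `controls` (data.frame), `truth` (per-control true mean
#'   vm) and `epochs` (named list of [epoch_series()], if requested).
#' @export
generate_control_pool <- function(scenario = c("healthy", "cvd_dm", "heart_failure"),
                                  n, config, seed, wear_days = 7L,
                                  with_epochs = TRUE) {
  scenario <- match.arg(scenario)
  stopifnot(n > 0)
  prof <- control_profiles[[scenario]]
  set.seed(derive_seed(seed, 91L))
  age <- rtrunc_norm(n, prof$age[["mean"]], prof$age[["sd"]], 45, 75)
  n_f <- round(prof$female * n)
  sex <- sample(c(rep("female", n_f), rep("male", n - n_f)))
  start <- config$start_date +
    7L * sample.int(config$start_spread_weeks + 1L, n, replace = TRUE) - 7L
  eps <- stats::rnorm(n, 0, 3)
  delta <- config$age_activity_slope * (age - mean(age)) + eps - mean(eps)
  rho <- pmin(pmax(1 + delta / prof$vm, 0.3), 2.5)
  controls <- data.frame(
    id = sprintf("C%s%04d", toupper(substr(scenario, 1L, 1L)), seq_len(n)),
    age = age, sex = sex,
    dialysis_weekdays = "",
    slot = NA_character_,
    leg_weakness = FALSE, breathlessness = FALSE,
    listed_transplant = NA, arrhythmia = NA,
    cvd_or_dm = scenario != "healthy",
    start_date = start,
    wear_season = season_of(start),
    rho = rho,
    stringsAsFactors = FALSE)

  cfg2 <- config
  cfg2$behaviour_day_profile <- list(dialysis = prof$hours,
                                     `non-dialysis` = prof$hours)
  cfg2$day_profile_vm <- c(dialysis = prof$vm, `non-dialysis` = prof$vm)
  cfg2$wear_days <- as.integer(wear_days)
  truth <- participant_truth(controls, cfg2)
  truth <- truth[truth$day_type == "non-dialysis", ]
  epochs <- NULL
  if (with_epochs) {
    epochs <- stats::setNames(vector("list", n), controls$id)
    for (i in seq_len(n)) {
      epochs[[i]] <- generate_participant_epochs(
        controls[i, ], truth, cfg2, seed = derive_seed(seed, 5000L + i))
    }
  }
  list(controls = controls, truth = truth, epochs = epochs)
}
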