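#' Generator configuration for the synthetic dialysis cohort
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' describe a thrice-weekly haemodialysis cohort of 73 participants wearing
#' the device for 12 full days: five-state behaviour schedules whose
#' day-type mean hours and mean vector magnitude match the cohort the
#' package's statistics are designed for, ~4-h dialysis sessions in a
#' morning or afternoon slot with near-zero activity, early waking before
#' morning sessions, an age gradient and a leg-weakness deficit in overall
#' activity, occasional non-wear gaps, and device miscalibration at the raw
#' tier.
#'
#' Two fidelity tiers are supported: `"epoch"` (30-s epochs with vector
#' magnitude, class-conditional Gaussian feature vectors and true labels;
#' cohort-scale) and `"raw"` (triaxial samples at `raw_rate_hz`; intended
#' for spans of at most `max_raw_days` days, used to exercise calibration
#' and ENMO preprocessing).
#'
#' @param n_participants cohort size (default 73).
#' @param wear_days complete wear days per participant (default 12).
#' @param behaviour_day_profile list mapping day type to mean hours/day per
#'   behaviour state; each profile must sum to 24 h.
#' @param day_profile_vm named vector: true cohort mean vector magnitude
#'   (mg) on dialysis and non-dialysis days.
#' @param dialysis_session_hours session length (default 4).
#' @param slot_split proportion of participants with a morning slot.
#' @param slot_windows list of `c(start_min, end_min)` clock windows for the
#'   morning and afternoon slots (defaults 07:30-11:30 and 13:00-17:00).
#' @param age_distribution `c(mean, sd, min, max)` in years.
#' @param female_fraction,leg_weakness_fraction cohort proportions.
#' @param age_activity_slope mg of overall vector magnitude per year of age
#'   (negative: older participants are less active).
#' @param leg_weakness_activity_deficit mg difference attached to the
#'   leg-weakness flag.
#' @param participant_sd residual between-participant sd of overall vector
#'   magnitude, mg.
#' @param activity_scale `c(mean, sd)` used to standardise activity when
#'   linking questionnaires to it.
#' @param state_vm_distributions list mapping state to `c(mean, sd)` of
#'   30-s-epoch vector magnitude in mg.
#' @param nonwear_rate list: expected `gaps_per_day` and
#'   `gap_min_range = c(lo, hi)` minutes.
#' @param calibration_error `c(offset_sd_g, gain_sd)` applied at raw tier.
#' @param tier `"epoch"` or `"raw"`.
#' @param raw_rate_hz raw-tier sampling rate (default 25; the preprocessing
#'   is rate-agnostic, the device's nominal 100 Hz is kept as metadata).
#' @param max_raw_days refusal threshold for raw-tier synthesis.
#' @param n_features,feature_separation epoch-tier feature dimensionality
#'   and between-class mean separation (in within-class sd units). The
#'   default separation of 4 gives a nearly separable classification task;
#'   ~1.5 emulates a noisy camera-annotation regime.
#' @param day_mult_sd day-level multiplicative sd on active-state intensity.
#' @param sleep_jitter_min sd of day-to-day sleep-duration jitter (minutes).
#' @param questionnaire_strength rank-correlation strength in `[0, 1]`
#'   linking questionnaire limitation scores to true activity.
#' @param camera_subset_n,camera_days size of the labelled ("camera") subset
#'   and labelled days per subset participant.
#' @param start_date first Monday of the study window; participants start on
#'   a week sampled from the following `start_spread_weeks` weeks.
#' @param start_spread_weeks spread of start dates (default 21, i.e. an
#'   October-March fieldwork window).
#' @param seed integer generator seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(
    n_participants = 73,
    wear_days = 12,
    behaviour_day_profile = list(
      dialysis = c(walking = 0.90, light_tasks = 0.57, moderate = 0.45,
                   sedentary = 13.58, sleep = 8.50),
      `non-dialysis` = c(walking = 1.08, light_tasks = 0.78, moderate = 0.64,
                         sedentary = 12.90, sleep = 8.60)),
    day_profile_vm = c(dialysis = 14.8, `non-dialysis` = 16.2),
    dialysis_session_hours = 4,
    slot_split = 0.5,
    slot_windows = list(morning = c(450, 690), afternoon = c(780, 1020)),
    age_distribution = c(mean = 66.5, sd = 14, min = 26, max = 87),
    female_fraction = 22 / 73,
    leg_weakness_fraction = 43 / 73,
    age_activity_slope = -0.22,
    leg_weakness_activity_deficit = -5.1,
    participant_sd = 2.0,
    activity_scale = c(mean = 15.5, sd = 4.7),
    state_vm_distributions = list(
      walking = c(mean = 150, sd = 60),
      light_tasks = c(mean = 45, sd = 18),
      moderate = c(mean = 100, sd = 40),
      sedentary = c(mean = 7, sd = 3),
      sleep = c(mean = 2.5, sd = 1.2)),
    nonwear_rate = list(gaps_per_day = 0.3, gap_min_range = c(45, 180)),
    calibration_error = c(offset_sd_g = 0.01, gain_sd = 0.01),
    tier = c("epoch", "raw"),
    raw_rate_hz = 25,
    max_raw_days = 3,
    n_features = 5,
    feature_separation = 4,
    day_mult_sd = 0.08,
    sleep_jitter_min = 20,
    questionnaire_strength = 0.7,
    camera_subset_n = 25,
    camera_days = 2,
    start_date = as.Date("2016-10-03"),
    start_spread_weeks = 21,
    seed = 20201) {
  tier <- match.arg(tier)
  cfg <- as.list(environment())
  for (dtype in names(cfg$behaviour_day_profile)) {
    h <- cfg$behaviour_day_profile[[dtype]]
    if (!setequal(names(h), behaviour_states())) {
      stop("config error: profile for ", dtype, " must name all five states")
    }
    if (abs(sum(h) - 24) > 1e-8) {
      stop("config error: behaviour hours for ", dtype,
           " sum to ", sum(h), ", not 24")
    }
  }
  props <- c(cfg$slot_split, cfg$female_fraction, cfg$leg_weakness_fraction,
             cfg$questionnaire_strength)
  if (any(props < 0 | props > 1)) stop("config error: proportions must be in [0,1]")
  sds <- c(cfg$participant_sd, cfg$day_mult_sd, cfg$sleep_jitter_min,
           vapply(cfg$state_vm_distributions, function(v) v[["sd"]], 0))
  if (any(sds < 0)) stop("config error: sds must be >= 0")
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> n=%d, %d wear days, tier=%s, seed=%d\n",
              x$n_participants, x$wear_days, x$tier, x$seed))
  invisible(x)
}

state_means <- function(config) {
  vapply(behaviour_states(),
         function(s) config$state_vm_distributions[[s]][["mean"]], 0)
}

state_sds <- function(config) {
  vapply(behaviour_states(),
         function(s) config$state_vm_distributions[[s]][["sd"]], 0)
}

# class-conditional feature means: one unit direction per state scaled by
# feature_separation (within-class covariance is the identity), so any two
# classes sit feature_separation * sqrt(2) apart
feature_class_means <- function(config) {
  p <- config$n_features
  if (p < 5L) stop("config error: n_features must be >= 5")
  mu <- matrix(0, nrow = 5L, ncol = p)
  for (s in 1:5) mu[s, s] <- config$feature_separation
  rownames(mu) <- behaviour_states()
  mu
}
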