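state_codes <- function() stats::setNames(1:5, behaviour_states())

# chop `total` minutes into bout lengths with the given mean (geometric-ish)
chop_bouts <- function(total, mean_len) {
  if (total <= 0L) return(integer())
  out <- integer()
  left <- total
  while (left > 0L) {
    len <- min(left, max(1L, stats::rpois(1L, mean_len)))
    out <- c(out, len)
    left <- left - len
  }
  out
}

#' Generate a one-day behaviour schedule
#'
#' Builds a semi-Markov daily schedule tiling exactly 24 h: a contiguous
#' night-sleep block (with day-to-day jitter around the participant's true
#' sleep hours), on dialysis days a contiguous sedentary session of
#' `dialysis_session_hours` filling the participant's slot window, and the
#' remaining waking time laid out as shuffled bouts of walking, light tasks,
#' moderate activity and sedentary time whose expected durations equal the
#' participant's true hours for that day type. Morning-slot participants
#' wake early (between 04:30 and 06:00) on dialysis days.
#'
#' @param participant one cohort row from [generate_cohort()].
#' @param day a `Date`.
#' @param config the [generator_config()].
#' @param seed integer seed for this day.
#' @param truth the participant's truth rows (both day types) from
#'   [generate_cohort()]; defaults to the cohort profile if omitted.
#' @return list of class `behaviour_schedule`: `day`, `day_type`, `segments`
#'   (start/end minute-of-day and state) and `minute_state` (integer vector
#'   of 1440 state codes).
#' @export
generate_schedule <- function(participant, day, config, seed, truth = NULL) {
  day <- as.Date(day)
  pat <- parse_weekdays(participant$dialysis_weekdays)
  day_type <- if (weekday_abbrev(day) %in% pat) "dialysis" else "non-dialysis"
  set.seed(seed)
  prof <- config$behaviour_day_profile[[day_type]]
  if (!is.null(truth)) {
    tr <- truth[truth$id == participant$id & truth$day_type == day_type, ]
    hours <- c(walking = tr$walking_h, light_tasks = tr$light_tasks_h,
               moderate = tr$moderate_h, sedentary = tr$sedentary_h,
               sleep = tr$sleep_h)
  } else {
    hours <- prof
  }

  sleep_min <- round(hours[["sleep"]] * 60 +
                       stats::rnorm(1L, 0, config$sleep_jitter_min))
  sleep_min <- min(max(sleep_min, 240L), 720L)
  is_dialysis <- day_type == "dialysis"
  morning_session <- is_dialysis && identical(participant$slot, "morning")
  wake <- if (morning_session) {
    round(stats::runif(1L, 270, 360))            # 04:30-06:00
  } else {
    round(min(max(stats::rnorm(1L, 445, 25), 360), 540))
  }
  onset <- min(1440L - sleep_min + wake, 1440L)  # evening sleep onset
  st <- rep.int(state_codes()[["sedentary"]], 1440L)
  if (wake > 0L) st[seq_len(wake)] <- state_codes()[["sleep"]]
  if (onset < 1440L) st[(onset + 1L):1440L] <- state_codes()[["sleep"]]

  session <- NULL
  if (is_dialysis) {
    win <- config$slot_windows[[participant$slot]]
    len <- round(config$dialysis_session_hours * 60)
    slack <- max(0L, (win[2L] - win[1L]) - len)
    s0 <- win[1L] + if (slack > 0L) sample.int(slack + 1L, 1L) - 1L else 0L
    session <- c(s0, s0 + len)
  }

  free <- setdiff((wake + 1L):onset, if (!is.null(session)) (session[1L] + 1L):session[2L])
  M <- length(free)
  act <- c(walking = 10, light_tasks = 15, moderate = 8)  # mean bout minutes
  target <- vapply(names(act), function(s) {
    max(0, round(hours[[s]] * 60 * stats::rnorm(1L, 1, 0.05)))
  }, 0)
  if (sum(target) > 0.85 * M) target <- floor(target * (0.85 * M) / sum(target))
  bouts <- list()
  for (s in names(act)) {
    lens <- chop_bouts(target[[s]], act[[s]])
    if (length(lens)) bouts <- c(bouts, lapply(lens, function(l) c(state_codes()[[s]], l)))
  }
  sed_left <- M - sum(target)
  lens <- chop_bouts(sed_left, 35)
  if (length(lens)) {
    bouts <- c(bouts, lapply(lens, function(l) c(state_codes()[["sedentary"]], l)))
  }
  if (length(bouts)) {
    bouts <- bouts[sample.int(length(bouts))]
    lay <- unlist(lapply(bouts, function(b) rep.int(b[1L], b[2L])))
    st[free] <- lay[seq_len(M)]
  }

  st <- as.integer(st)
  r <- rle(st)
  ends <- cumsum(r$lengths)
  segments <- data.frame(start_min = c(0L, utils::head(ends, -1L)),
                         end_min = ends,
                         state = behaviour_states()[r$values],
                         stringsAsFactors = FALSE)
  structure(list(day = day, day_type = day_type, segments = segments,
                 minute_state = st, session = session),
            class = "behaviour_schedule")
}

rgamma_mean_sd <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Synthesise accelerometer data for one scheduled day
#'
#' At the `"epoch"` tier, emits 2880 thirty-second epochs carrying vector
#' magnitude drawn from the state's epoch-level distribution (active states
#' scaled by the participant's intensity multiplier and a day-level
#' multiplier), class-conditional Gaussian feature vectors, the true label,
#' and a true wear mask with non-wear gaps inserted at the configured rate
#' (non-wear epochs are stationary with near-zero vector magnitude). At the
#' `"raw"` tier, emits a triaxial trace whose 5-s ENMO means match the
#' state distributions, built from a slowly drifting orientation on the unit
#' sphere, magnitude oscillation during active states, brief still windows
#' during sleep/sedentary time (for autocalibration), and the configured
#' gain/offset miscalibration.
#'
#' @param schedule a [generate_schedule()] result.
#' @param config the [generator_config()].
#' @param seed integer seed.
#' @param intensity_mult participant x day-type active-intensity multiplier
#'   (from the truth table; default 1).
#' @param tier `"epoch"` or `"raw"` (defaults to `config$tier`).
#' @return An [epoch_series()] (epoch tier) or [raw_trace()] (raw tier).
#' @export
synthesize_signal <- function(schedule, config, seed, intensity_mult = 1,
                              tier = NULL) {
  stopifnot(inherits(schedule, "behaviour_schedule"))
  tier <- tier %||% config$tier
  set.seed(seed)
  if (tier == "epoch") {
    synth_epoch_day(schedule, config, intensity_mult)
  } else {
    synth_raw_day(schedule, config, intensity_mult)
  }
}

nonwear_mask_minutes <- function(config) {
  n_gaps <- stats::rpois(1L, config$nonwear_rate$gaps_per_day)
  mask <- rep(FALSE, 1440L)
  if (n_gaps > 0L) {
    rng <- config$nonwear_rate$gap_min_range
    for (i in seq_len(n_gaps)) {
      len <- round(stats::runif(1L, rng[1L], rng[2L]))
      s0 <- sample.int(1440L - len, 1L)
      mask[s0:(s0 + len - 1L)] <- TRUE
    }
  }
  mask
}

synth_epoch_day <- function(schedule, config, intensity_mult) {
  st_min <- schedule$minute_state
  st_ep <- rep(st_min, each = 2L)                # 2880 thirty-second epochs
  n <- length(st_ep)
  sm <- state_means(config); ss <- state_sds(config)
  day_mult <- max(0.2, stats::rnorm(1L, 1, config$day_mult_sd))
  active <- st_ep <= 3L
  mult <- ifelse(active, intensity_mult * day_mult, 1)
  vm <- numeric(n)
  for (s in 1:5) {
    i <- which(st_ep == s)
    if (length(i)) vm[i] <- rgamma_mean_sd(length(i), sm[s], ss[s]) * mult[i]
  }
  mu <- feature_class_means(config)
  feats <- mu[st_ep, , drop = FALSE] +
    matrix(stats::rnorm(n * config$n_features), n)
  colnames(feats) <- paste0("feat_", seq_len(config$n_features))

  nw_min <- nonwear_mask_minutes(config)
  nw <- rep(nw_min, each = 2L)
  vm[nw] <- rgamma_mean_sd(sum(nw), 0.6, 0.3)
  stationary <- nw
  t0 <- as.POSIXct(as.numeric(as.POSIXct(paste(schedule$day, "00:00:00"),
                                         tz = "UTC")) + (seq_len(n) - 1L) * 30,
                   origin = "1970-01-01", tz = "UTC")
  df <- data.frame(start = t0, vm_mg = vm,
                   wear = !nw, stationary = stationary,
                   label = behaviour_states()[st_ep],
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(feats))
  epoch_series(df, epoch_s = 30)
}

# random unit vector
runit3 <- function() {
  v <- stats::rnorm(3L)
  v / sqrt(sum(v^2))
}

synth_raw_day <- function(schedule, config, intensity_mult) {
  rate <- config$raw_rate_hz
  st_min <- schedule$minute_state
  n_per_min <- rate * 60
  n <- 1440L * n_per_min
  sm <- state_means(config); ss <- state_sds(config)
  osc_freq <- c(walking = 2, light_tasks = 1, moderate = 2.5,
                sedentary = 0.3, sleep = 0.1)
  noise_sd <- 0.002                              # g, per axis
  # per-5-s-block target ENMO, drawn from the state's distribution and
  # corrected for the small perpendicular-noise inflation
  blocks_per_min <- 12L
  st_block <- rep(st_min, each = blocks_per_min)
  nb <- length(st_block)
  e_block <- numeric(nb)
  day_mult <- max(0.2, stats::rnorm(1L, 1, config$day_mult_sd))
  for (s in 1:5) {
    i <- which(st_block == s)
    if (!length(i)) next
    m <- sm[s] * (if (s <= 3L) intensity_mult * day_mult else 1)
    e_block[i] <- rgamma_mean_sd(length(i), m, ss[s] * (if (s <= 3L) intensity_mult else 1))
  }
  e_block <- pmax(0, e_block - 1000 * noise_sd^2) / 1000   # to g

  # still windows: frozen orientation, no noise (stationary, for calibration)
  still_min <- rep(FALSE, 1440L)
  i <- 1L
  while (i <= 1440L) {
    s <- st_min[i]
    if (s >= 4L) {                               # sedentary or sleep
      run <- i
      while (run <= 1440L && st_min[run] == s) run <- run + 1L
      run_len <- run - i
      pos <- i
      while (pos < run) {
        still_len <- min(run - pos, sample(5:15, 1L))
        move_len <- sample(5:20, 1L)
        if (s == 5L || stats::runif(1L) < 0.4) {
          still_min[pos:(pos + still_len - 1L)] <- TRUE
        }
        pos <- pos + still_len + move_len
      }
      i <- run
    } else i <- i + 1L
  }

  nw_min <- nonwear_mask_minutes(config)
  still_min[nw_min] <- TRUE
  e_block[rep(nw_min, each = blocks_per_min)] <- 0

  # orientation: piecewise random walk on the sphere; frozen during still
  # minutes, redrawn after each still window
  u <- matrix(0, nrow = 1440L, ncol = 3L)
  cur <- runit3()
  drift <- c(0.06, 0.05, 0.06, 0.02, 0.01)       # rad/min by state
  for (m2 in seq_len(1440L)) {
    if (m2 > 1L && still_min[m2] && !still_min[m2 - 1L]) cur <- runit3()
    if (!still_min[m2]) {
      step <- stats::rnorm(3L, 0, drift[st_min[m2]])
      cur <- cur + step
      cur <- cur / sqrt(sum(cur^2))
    }
    u[m2, ] <- cur
  }

  tsec <- (seq_len(n) - 1L) / rate
  blk <- rep(seq_len(nb), each = rate * 5L)
  minute_of <- rep(seq_len(1440L), each = n_per_min)
  f <- osc_freq[st_min[minute_of]]
  # magnitude modulation preserves the norm's mean at 1 + e
  mag <- 1 + e_block[blk] * (1 - cos(2 * pi * f * tsec))
  sig <- u[minute_of, ] * mag
  still_sample <- still_min[minute_of]
  noise <- matrix(stats::rnorm(3L * n, 0, noise_sd), ncol = 3L)
  noise[still_sample, ] <- 0
  sig <- sig + noise

  # device miscalibration: observed = true / gain + offset
  ce <- config$calibration_error
  gain <- 1 + stats::rnorm(3L, 0, ce[["gain_sd"]])
  offset <- stats::rnorm(3L, 0, ce[["offset_sd_g"]])
  obs <- sweep(sweep(sig, 2L, gain, `/`), 2L, offset, `+`)

  t0 <- as.numeric(as.POSIXct(paste(schedule$day, "00:00:00"), tz = "UTC"))
  tr <- raw_trace(device_id = "SYN-AX3",
                  sample_rate_hz = rate,
                  start_time = as.POSIXct(t0, origin = "1970-01-01", tz = "UTC"),
                  samples = data.frame(
                    t = as.POSIXct(t0 + tsec, origin = "1970-01-01", tz = "UTC"),
                    x = obs[, 1L], y = obs[, 2L], z = obs[, 3L]),
                  dynamic_range_g = 8)
  tr$truth <- list(offset = offset, gain = gain,
                   nonwear_minutes = nw_min, still_minutes = still_min,
                   minute_state = st_min)
  tr
}

#' Synthesise a participant's full epoch-tier record
#'
#' Runs [generate_schedule()] and [synthesize_signal()] over
#' `config$wear_days` consecutive days from the participant's start date.
#'
#' @param participant one cohort row.
#' @param truth the cohort truth table.
#' @param config the [generator_config()].
#' @param seed integer seed for this participant.
#' @return An [epoch_series()] spanning all wear days.
#' @export
generate_participant_epochs <- function(participant, truth, config, seed) {
  days <- participant$start_date + seq_len(config$wear_days) - 1L
  out <- vector("list", length(days))
  for (i in seq_along(days)) {
    sch <- generate_schedule(participant, days[i], config,
                             seed = derive_seed(seed, i), truth = truth)
    tr <- truth[truth$id == participant$id & truth$day_type == sch$day_type, ]
    out[[i]] <- synthesize_signal(sch, config, seed = derive_seed(seed, 1000L + i),
                                  intensity_mult = tr$intensity_mult,
                                  tier = "epoch")
  }
  df <- do.call(rbind, lapply(out, as.data.frame))
  epoch_series(df, epoch_s = 30)
}

#' Synthesise a short raw-tier record
#'
#' Raw synthesis is refused for spans longer than `config$max_raw_days`
#' (cohort-scale validation runs at the epoch tier; the raw tier exists to
#' exercise calibration and ENMO preprocessing on hours-to-days spans).
#'
#' @inheritParams generate_participant_epochs
#' @param n_days number of days (must be <= `config$max_raw_days`).
#' @return list of [raw_trace()] objects, one per day.
#' @export
generate_participant_raw <- function(participant, truth, config, seed,
                                     n_days = 1L) {
  if (n_days > config$max_raw_days) {
    stop("raw-tier synthesis refused for ", n_days, " days (max ",
         config$max_raw_days, "); use tier = 'epoch' for cohort-scale spans")
  }
  days <- participant$start_date + seq_len(n_days) - 1L
  lapply(seq_along(days), function(i) {
    sch <- generate_schedule(participant, days[i], config,
                             seed = derive_seed(seed, i), truth = truth)
    tr <- truth[truth$id == participant$id & truth$day_type == sch$day_type, ]
    synthesize_signal(sch, config, seed = derive_seed(seed, 2000L + i),
                      intensity_mult = tr$intensity_mult, tier = "raw")
  })
}
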