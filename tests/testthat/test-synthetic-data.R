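test_that("default cohort matches its demographic calibration and is deterministic", {
  cfg <- generator_config()
  gen <- generate_cohort(cfg)
  expect_equal(nrow(gen$cohort), 73L)
  expect_equal(sum(gen$cohort$sex == "female"), 22L)
  expect_equal(sum(gen$cohort$leg_weakness), 43L)
  expect_true(all(gen$cohort$age >= 26 & gen$cohort$age <= 87))
  expect_true(all(nzchar(gen$cohort$dialysis_weekdays)))

  gen2 <- generate_cohort(cfg)
  expect_identical(gen$cohort, gen2$cohort)
  expect_identical(gen$truth, gen2$truth)
})

test_that("profiles that do not tile 24 h are rejected", {
  prof <- list(
    dialysis = c(walking = 1, light_tasks = 1, moderate = 1,
                 sedentary = 12, sleep = 8),
    `non-dialysis` = c(walking = 1.08, light_tasks = 0.78, moderate = 0.64,
                       sedentary = 12.90, sleep = 8.60))
  expect_error(generator_config(behaviour_day_profile = prof), "sum to")
})

test_that("with flat gradients, participant truth varies only by the configured noise", {
  cfg <- generator_config(n_participants = 1000, age_activity_slope = 0,
                          leg_weakness_activity_deficit = 0,
                          participant_sd = 2, seed = 303)
  gen <- generate_cohort(cfg)
  ov <- gen$truth$vm_true[gen$truth$day_type == "non-dialysis"]
  # truth is vm * rho with rho = 1 + eps/15.5: implied sd = 16.2/15.5 * 2
  expect_equal(mean(ov), 16.2, tolerance = 0.01)
  expect_equal(sd(ov), 16.2 / 15.5 * 2, tolerance = 0.1)
})

test_that("schedules tile 24 h and place dialysis blocks in the slot window", {
  cfg <- generator_config()
  gen <- generate_cohort(cfg)
  p_morning <- gen$cohort[gen$cohort$slot == "morning", ][1, ]
  pat <- strsplit(p_morning$dialysis_weekdays, ";")[[1]]
  found_dialysis <- FALSE
  for (d in 0:6) {
    day <- p_morning$start_date + d
    sch <- generate_schedule(p_morning, day, cfg, seed = 100 + d,
                             truth = gen$truth)
    expect_equal(sum(sch$segments$end_min - sch$segments$start_min), 1440)
    expect_equal(length(sch$minute_state), 1440L)
    if (sch$day_type == "dialysis") {
      found_dialysis <- TRUE
      expect_true(sch$session[1] >= 450 && sch$session[2] <= 690)
      expect_true(all(sch$minute_state[(sch$session[1] + 1):sch$session[2]] ==
                        match("sedentary", behaviour_states())))
      # early waking before a morning session: activity present in 04:30-06:00
      expect_true(any(sch$minute_state[271:360] != match("sleep", behaviour_states())))
    }
  }
  expect_true(found_dialysis)
})

test_that("per-state hours over many days converge to truth (law of large numbers)", {
  cfg <- generator_config()
  gen <- generate_cohort(cfg)
  p <- gen$cohort[1, ]
  tr <- gen$truth[gen$truth$id == p$id & gen$truth$day_type == "non-dialysis", ]
  # a guaranteed non-dialysis date for either weekday pattern
  sunday <- p$start_date + (7 - as.POSIXlt(p$start_date)$wday) %% 7
  n_days <- 500
  mins <- matrix(0, n_days, 5)
  for (i in seq_len(n_days)) {
    sch <- generate_schedule(p, sunday, cfg, seed = i, truth = gen$truth)
    mins[i, ] <- tabulate(sch$minute_state, nbins = 5)
  }
  hrs <- colMeans(mins) / 60
  truth_h <- c(tr$walking_h, tr$light_tasks_h, tr$moderate_h,
               tr$sedentary_h, tr$sleep_h)
  mc_se <- apply(mins / 60, 2, sd) / sqrt(n_days)
  for (s in 1:5) {
    expect_lt(abs(hrs[s] - truth_h[s]), pmax(2 * mc_se[s], 0.02))
  }
  # sleep hours within 0.1 h of the configured truth
  expect_lt(abs(hrs[5] - tr$sleep_h), 0.1)
})

test_that("epoch tier emits 2880 30-s epochs per day with truthful labels", {
  cfg <- generator_config(nonwear_rate = list(gaps_per_day = 0,
                                              gap_min_range = c(45, 60)))
  gen <- generate_cohort(cfg)
  sch <- generate_schedule(gen$cohort[1, ], gen$cohort$start_date[1] + 1, cfg,
                           seed = 3, truth = gen$truth)
  ep <- synthesize_signal(sch, cfg, seed = 4, intensity_mult = 1)
  expect_s3_class(ep, "epoch_series")
  expect_equal(nrow(ep), 2880L)
  expect_equal(epoch_length(ep), 30)
  expect_identical(as.integer(ep$label),
                   rep(sch$minute_state, each = 2L))
  expect_true(all(ep$wear))
})

test_that("a degenerate sedentary day with zero noise gives constant epoch vm", {
  svd <- list(walking = c(mean = 150, sd = 0), light_tasks = c(mean = 45, sd = 0),
              moderate = c(mean = 100, sd = 0), sedentary = c(mean = 7, sd = 0),
              sleep = c(mean = 2.5, sd = 0))
  cfg <- generator_config(state_vm_distributions = svd, day_mult_sd = 0,
                          nonwear_rate = list(gaps_per_day = 0,
                                              gap_min_range = c(45, 60)))
  sch <- structure(list(
    day = as.Date("2017-01-03"), day_type = "non-dialysis",
    segments = data.frame(start_min = 0L, end_min = 1440L, state = "sedentary"),
    minute_state = rep(match("sedentary", behaviour_states()), 1440L),
    session = NULL), class = "behaviour_schedule")
  ep <- synthesize_signal(sch, cfg, seed = 5, intensity_mult = 1)
  expect_true(all(ep$vm_mg == 7))
})

test_that("questionnaire generation hits the configured correlation strengths", {
  n <- 500
  act <- seq(5, 30, length.out = n)
  rho_at <- function(strength, seed0) {
    cfg <- generator_config(questionnaire_strength = strength)
    fss <- vapply(seq_len(n), function(i) {
      q <- generate_questionnaires(list(id = i), act[i], cfg, seed = seed0 + i)
      score_kccq(q$kccq)$fss
    }, 0)
    suppressWarnings(cor(fss, act, method = "spearman"))
  }
  expect_lt(abs(rho_at(0, 1000)), 0.1)
  expect_gt(rho_at(1, 2000), 0.8)
  # determinism
  cfg <- generator_config()
  q1 <- generate_questionnaires(list(id = 1), 15, cfg, seed = 42)
  q2 <- generate_questionnaires(list(id = 1), 15, cfg, seed = 42)
  expect_identical(q1, q2)
})

test_that("control pools match their scenario calibration", {
  cfg <- generator_config()
  pool <- generate_control_pool("healthy", n = 318, cfg, seed = 9,
                                with_epochs = FALSE)
  expect_equal(nrow(pool$controls), 318L)
  expect_true(all(pool$controls$dialysis_weekdays == ""))
  expect_true(all(pool$controls$wear_season %in%
                    c("winter", "spring", "summer", "autumn")))
  expect_equal(mean(pool$truth$vm_true), 28.1, tolerance = 0.02)
  # dialysis cohort to healthy-control activity ratio ~ 15.5 / 28.1
  expect_equal(15.5 / mean(pool$truth$vm_true), 0.55, tolerance = 0.01)

  pool2 <- generate_control_pool("healthy", n = 318, cfg, seed = 9,
                                 with_epochs = FALSE)
  expect_identical(pool$controls, pool2$controls)

  hf <- generate_control_pool("heart_failure", n = 50, cfg, seed = 10,
                              with_epochs = FALSE)
  expect_equal(mean(hf$truth$vm_true), 22.9, tolerance = 0.1)
})

test_that("raw-tier synthesis is refused beyond the configured span", {
  cfg <- generator_config()
  gen <- generate_cohort(cfg)
  expect_error(generate_participant_raw(gen$cohort[1, ], gen$truth, cfg,
                                        seed = 1, n_days = 10),
               "refused")
})
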