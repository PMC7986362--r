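test_that("participant summaries convert minutes faithfully", {
  g <- make_grid(rep(c("dialysis", "non-dialysis"), 2), vm = 15.5)
  sm <- summarize_participant(g)
  expect_equal(sm$mean_vm[sm$day_type == "dialysis"], 15.5)
  expect_equal(sm$mean_vm[sm$day_type == "non-dialysis"], 15.5)
  expect_equal(sm$mean_vm[sm$day_type == "overall"], 15.5)

  # 60 walking minutes per day -> 1.0 h/day walking
  st <- matrix(match("sedentary", behaviour_states()), 2, 1440)
  st[, 601:660] <- match("walking", behaviour_states())
  g2 <- make_grid(rep("non-dialysis", 2), state = st)
  sm2 <- summarize_participant(g2)
  expect_equal(sm2$walking_h[sm2$day_type == "overall"], 1)
  # complete grids conserve the 24-h day across the five states
  hours <- sm2[sm2$day_type == "overall", paste0(behaviour_states(), "_h")]
  expect_equal(sum(unlist(hours)), 24, tolerance = 1e-9)
})

test_that("group means and SEs follow the sd/sqrt(n) definition", {
  df <- data.frame(g = c("a", "a", "b", "c", "c"), v = c(10, 20, 7, 5, 5))
  out <- group_mean_se(df, "v", "g")
  a <- out[out$group == "a", ]
  expect_equal(a$v_mean, 15)
  expect_equal(a$v_se, 5)                         # sd 7.071.. / sqrt(2)
  expect_true(is.na(out$v_se[out$group == "b"]))  # single member
  expect_equal(out$v_se[out$group == "c"], 0)     # zero variance
  df$g <- factor(df$g, levels = c("a", "b", "c", "d"))
  expect_warning(group_mean_se(df, "v", "g"), "empty")
  # invariant to participant order
  out2 <- suppressWarnings(group_mean_se(df[sample(1:5), ], "v", "g"))
  expect_equal(out2[out2$group == "a", ]$v_mean, 15)
})

test_that("paired day-type tests match hand-computed t statistics", {
  mk <- function(d, n) {
    rbind(data.frame(participant_id = paste0("P", seq_along(d)),
                     day_type = "dialysis", mean_vm = d),
          data.frame(participant_id = paste0("P", seq_along(n)),
                     day_type = "non-dialysis", mean_vm = n))
  }
  # identical values: t = 0, p = 1
  same <- paired_daytype_test(mk(c(10, 12, 14), c(10, 12, 14)), "mean_vm")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # differences {1,2,3}: t = 2 / (1/sqrt(3)) = 2 sqrt(3)
  tt <- paired_daytype_test(mk(c(11, 14, 17), c(10, 12, 14)), "mean_vm")
  expect_equal(tt$mean_difference, 2, tolerance = 1e-12)
  expect_equal(tt$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(tt$p, 2 * pt(2 * sqrt(3), df = 2, lower.tail = FALSE),
               tolerance = 1e-9)

  # zero-variance nonzero differences are flagged degenerate
  deg <- paired_daytype_test(mk(c(11, 13), c(10, 12)), "mean_vm")
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
})

test_that("a simulated dialysis deficit is detected with near-certain power", {
  # n = 73 participants, true within-person day-type deficit 1.4 mg, sd 1
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    nd <- rnorm(73, 16.2, 3)
    d <- nd - rnorm(73, 1.4, 1)
    sm <- rbind(data.frame(participant_id = sprintf("P%02d", 1:73),
                           day_type = "dialysis", mean_vm = d),
                data.frame(participant_id = sprintf("P%02d", 1:73),
                           day_type = "non-dialysis", mean_vm = nd))
    if (paired_daytype_test(sm, "mean_vm")$p < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("adjusted marginal means equal raw means absent confounding and de-confound otherwise", {
  set.seed(12)
  n <- 300
  df <- data.frame(group = factor(sample(c("g1", "g2"), n, TRUE)),
                   age = rnorm(n, 65, 10),
                   sex = sample(c("male", "female"), n, TRUE),
                   leg_weakness = sample(c(TRUE, FALSE), n, TRUE))
  df$y <- 10 + rnorm(n)
  fit <- adjusted_marginal_means(df, "y", "group")
  raw <- tapply(df$y, df$group, mean)
  expect_equal(fit$marginal$emmean, as.vector(raw[fit$marginal$group]),
               tolerance = 0.05)

  # outcome driven purely by age; group assignment correlated with age
  df2 <- df
  df2$group <- factor(ifelse(df2$age + rnorm(n, 0, 5) > 65, "old", "young"))
  df2$y <- 30 - 0.3 * df2$age + rnorm(n, 0, 0.5)
  unadj <- diff(tapply(df2$y, df2$group, mean))
  adj <- adjusted_marginal_means(df2, "y", "group")
  g_diff <- diff(adj$marginal$emmean)
  # the adjusted contrast is the group coefficient; test against its own SE
  g_se <- summary(adj$model)$coefficients[2, 2]
  expect_gt(abs(unadj), 1)                        # confounded difference
  expect_lt(abs(g_diff), 3 * g_se)                # adjusted ~ 0

  # exact linear outcome: equal marginal means, zero residual variance
  df3 <- df
  df3$y <- 2 + 0.1 * df3$age
  fit3 <- suppressWarnings(adjusted_marginal_means(df3, "y", "group"))
  expect_equal(diff(fit3$marginal$emmean), 0, tolerance = 1e-10)
  expect_lt(suppressWarnings(summary(fit3$model)$sigma), 1e-10)

  # aliased terms are named
  df4 <- df
  df4$dup <- df4$age
  expect_error(adjusted_marginal_means(df4, "y", "group",
                                       adjust_for = c("age", "dup")),
               "alias")
})

test_that("adjusted marginal means agree with emmeans", {
  skip_if_not_installed("emmeans")
  set.seed(30)
  n <- 150
  df <- data.frame(group = factor(sample(c("a", "b", "c"), n, TRUE)),
                   age = rnorm(n, 65, 12),
                   sex = sample(c("male", "female"), n, TRUE),
                   leg_weakness = sample(c(TRUE, FALSE), n, TRUE))
  df$y <- 5 + 2 * (df$group == "b") - 0.1 * df$age +
    0.8 * df$leg_weakness + rnorm(n)
  ours <- adjusted_marginal_means(df, "y", "group")
  fit <- lm(y ~ group + age + sex + leg_weakness, data = df)
  em <- as.data.frame(emmeans::emmeans(fit, "group",
                                       weights = "proportional"))
  expect_equal(ours$marginal$emmean, em$emmean, tolerance = 1e-8)
  expect_equal(ours$marginal$se, em$SE, tolerance = 1e-8)
})

test_that("Spearman correlations match hand-ranked values", {
  df <- data.frame(a = 1:6, up = c(2, 4, 5, 7, 8, 11), down = c(9, 7, 6, 5, 4, 2))
  out <- questionnaire_correlations(df, "a", c("up", "down"))
  expect_equal(out$rho[out$score == "up"], 1)
  expect_equal(out$rho[out$score == "down"], -1)

  # pairs (1,2),(2,1),(3,3): rho = 1 - 6*2/(3*8) = 0.5
  df2 <- data.frame(x = c(1, 2, 3), y = c(2, 1, 3))
  out2 <- questionnaire_correlations(df2, "x", "y")
  expect_equal(out2$rho, 0.5, tolerance = 1e-9)

  const <- data.frame(x = c(1, 2, 3), y = c(4, 4, 4))
  expect_false(questionnaire_correlations(const, "x", "y")$defined)
})

test_that("time-of-day profiles reflect the construction of the day", {
  g1 <- make_grid(rep(c("dialysis", "non-dialysis"), 2), vm = 10)
  g2 <- make_grid(rep(c("dialysis", "non-dialysis"), 2), vm = 10)
  prof <- time_of_day_profile(list(g1, g2), bin_min = 10)
  expect_equal(nrow(prof), 144L)
  expect_true(all(prof$mean == 10))
  expect_true(all(prof$se == 0))
  expect_error(time_of_day_profile(list(g1), bin_min = 7), "divide")

  # state-probability curves across the five states partition unity
  st <- matrix(rep(1:5, length.out = 1440 * 2), 2, 1440, byrow = TRUE)
  g3 <- make_grid(rep("non-dialysis", 2), state = st)
  tot <- Reduce(`+`, lapply(behaviour_states(), function(s) {
    time_of_day_profile(list(g3), bin_min = 60, outcome = s)$mean
  }))
  expect_equal(tot, rep(1, 24))
})

test_that("morning-slot cohorts dip during the dialysis session window", {
  cfg <- generator_config(n_participants = 6, wear_days = 6, slot_split = 1,
                          seed = 505)
  gen <- generate_cohort(cfg)
  grids <- lapply(seq_len(6), function(i) {
    ep <- generate_participant_epochs(gen$cohort[i, ], gen$truth, cfg,
                                      seed = 600 + i)
    ep <- detect_nonwear(ep)
    impute_minute_grid(build_minute_grid(ep, gen$cohort[i, ]))
  })
  d <- time_of_day_profile(grids, bin_min = 60, day_type = "dialysis")
  n <- time_of_day_profile(grids, bin_min = 60, day_type = "non-dialysis")
  session_bins <- 9:11                   # 08:00-11:00 within the 07:30-11:30 slot
  expect_lt(mean(d$mean[session_bins]), mean(n$mean[session_bins]))
  # early waking: morning-slot dialysis days are more active at 04:00-06:00
  expect_gt(mean(d$mean[5:6]), mean(n$mean[5:6]))
})

test_that("greedy matching honours k, calipers, exactness and no reuse", {
  cases <- data.frame(id = sprintf("P%d", 1:10),
                      age = c(90, seq(50, 74, length.out = 9)),
                      sex = rep(c("male", "female"), 5),
                      wear_season = "winter", stringsAsFactors = FALSE)
  set.seed(2)
  pool <- data.frame(id = sprintf("C%d", 1:400),
                     age = runif(400, 45, 75),
                     sex = sample(c("male", "female"), 400, TRUE),
                     wear_season = sample(c("winter", "spring"), 400, TRUE),
                     stringsAsFactors = FALSE)
  m <- match_controls(cases, pool, k = 5, age_caliper = 3, seed = 7)
  expect_identical(m$unmatched, "P1")              # age 90 beyond any caliper
  tab <- table(m$sets$case_id)
  expect_true(all(tab == 5))
  expect_false(any(duplicated(m$sets$control_id)))
  expect_true(all(abs(m$sets$age_diff) <= 3))
  merged <- merge(m$sets, cases, by.x = "case_id", by.y = "id")
  merged <- merge(merged, pool, by.x = "control_id", by.y = "id",
                  suffixes = c("_case", "_ctrl"))
  expect_true(all(merged$sex_case == merged$sex_ctrl))
  expect_true(all(merged$wear_season_case == merged$wear_season_ctrl))
  m2 <- match_controls(cases, pool, k = 5, age_caliper = 3, seed = 7)
  expect_identical(m$sets, m2$sets)
  expect_error(match_controls(cases, pool, k = 0), "parameter")
})
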