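test_that("raw-trace features capture rest and periodicity", {
  t0 <- as.POSIXct("2017-01-02", tz = "UTC")
  rate <- 25; n <- 30 * rate
  still <- raw_trace("T", rate, t0, data.frame(
    t = t0 + (seq_len(n) - 1) / rate, x = 0, y = 0, z = 1))
  f <- extract_features(still)
  expect_equal(nrow(f), 1L)
  expect_true(f$valid)
  expect_equal(f$mean_vm, 0)
  expect_equal(f$sd_vm, 0)
  expect_lt(f$dom_power_share, 1e-9)

  # a pure 2 Hz oscillation on x dominates the spectrum at 2 Hz
  tt <- (seq_len(n) - 1) / rate
  osc <- raw_trace("T", rate, t0, data.frame(
    t = t0 + tt, x = 0.3 * sin(2 * pi * 2 * tt), y = 0, z = 1))
  fo <- extract_features(osc)
  expect_equal(fo$dom_freq, 2, tolerance = 0.05)
  expect_gt(fo$dom_power_share, 0.5)

  # epochs with under half their samples present are invalid
  gappy <- still
  gappy$samples$x[1:(n * 0.6)] <- NA
  expect_false(extract_features(gappy)$valid)
})

test_that("epoch-tier feature extraction is a passthrough", {
  cfg <- generator_config()
  gen <- generate_cohort(cfg)
  sch <- generate_schedule(gen$cohort[1, ], gen$cohort$start_date[1], cfg,
                           seed = 1, truth = gen$truth)
  ep <- synthesize_signal(sch, cfg, seed = 2, intensity_mult = 1)
  f <- extract_features(ep)
  expect_identical(f$feat_1, ep$feat_1)
  expect_identical(f$feat_5, ep$feat_5)
})

test_that("balanced forests separate well-separated classes and balance their bootstraps", {
  df <- sim_features(100, sep = 4, classes = c("walking", "sedentary"))
  m <- train_balanced_rf(df, n_trees = 60, seed = 2)
  expect_gt(m$oob_accuracy, 0.95)
  # every tree's bootstrap drew the same count from each class
  inbag <- m$forest$inbag.counts
  lab <- factor(df$label)
  counts <- vapply(inbag, function(ib) tapply(ib, lab, sum), numeric(2))
  expect_true(all(counts == counts[1, 1][[1]]))
})

test_that("permuted labels leave out-of-bag accuracy at chance", {
  df <- sim_features(120, sep = 4)
  set.seed(5)
  df$label <- sample(df$label)
  m <- train_balanced_rf(df, n_trees = 100, seed = 6)
  n <- sum(m$oob_confusion)
  ci <- qbinom(c(0.005, 0.995), n, 0.2) / n
  expect_gte(m$oob_accuracy, ci[1])
  expect_lte(m$oob_accuracy, ci[2])
})

test_that("scarce classes are refused with the class named", {
  df <- sim_features(50, sep = 4, classes = c("walking", "sedentary"))
  df <- rbind(df, transform(df[1:5, ], label = "sleep"))
  expect_error(train_balanced_rf(df), "sleep")
  expect_error(train_balanced_rf(df[df$label == "walking", ]), ">= 2 classes")
})

test_that("HMM estimates match hand-computed bigram and confusion smoothing", {
  # single sequence A,A,B over two used states: one A->A and one A->B bigram
  seqs <- list(c("walking", "walking", "light_tasks"))
  conf <- diag(c(2, 1, 0, 0, 0))
  hmm <- estimate_hmm(seqs, conf, alpha = 1)
  expect_equal(hmm$transitions["walking", "walking"], (1 + 1) / (2 + 5))
  expect_equal(hmm$transitions["walking", "light_tasks"], (1 + 1) / (2 + 5))
  expect_equal(sum(hmm$transitions["walking", ]), 1)
  expect_equal(unname(hmm$prior["walking"]), (2 + 1) / (3 + 5))

  # alpha = 0 is rejected when bigrams or confusion cells are unobserved
  expect_error(estimate_hmm(seqs, conf, alpha = 0), "alpha")

  # near-zero alpha with an identity confusion tends to an identity emission
  conf_full <- diag(100, 5)
  hmm2 <- estimate_hmm(list(rep(behaviour_states(), 20)), conf_full,
                       alpha = 1e-9)
  expect_equal(unname(diag(hmm2$emission)), rep(1, 5), tolerance = 1e-8)
})

test_that("Viterbi decoding equals exhaustive enumeration (200 random instances)", {
  set.seed(42)
  mismatches <- 0L
  for (i in 1:200) {
    S <- sample(2:4, 1)
    T_ <- sample(2:8, 1)
    prior <- { p <- runif(S, 0.05, 1); p / sum(p) }
    trans <- rand_stoch(S)
    emis <- rand_stoch(S)
    obs <- sample.int(S, T_, replace = TRUE)
    fast <- dialacc:::.viterbi_path(obs, log(prior), log(trans), log(emis))
    if (!viterbi_agrees(fast, obs, prior, trans, emis)) {
      mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("Viterbi special cases behave analytically", {
  # uniform prior and transitions: the path is the per-observation argmax of
  # the emission column
  emis <- rbind(c(0.7, 0.1, 0.1, 0.05, 0.05),
                c(0.1, 0.6, 0.1, 0.1, 0.1),
                c(0.1, 0.1, 0.6, 0.1, 0.1),
                c(0.05, 0.1, 0.1, 0.65, 0.1),
                c(0.05, 0.1, 0.1, 0.1, 0.65))
  hmm <- list(prior = rep(0.2, 5),
              transitions = matrix(0.2, 5, 5), emission = emis)
  obs <- c("walking", "sleep", "moderate", "sedentary", "light_tasks")
  out <- viterbi_smooth(obs, list(hmm = hmm))
  expect_identical(as.character(out), obs)

  # sticky transitions smooth one discordant observation to its neighbours
  sticky <- matrix(0.001 / 4, 5, 5); diag(sticky) <- 0.999
  hmm2 <- list(prior = rep(0.2, 5), transitions = sticky, emission = emis)
  obs2 <- rep("sedentary", 9); obs2[5] <- "walking"
  out2 <- viterbi_smooth(obs2, list(hmm = hmm2))
  expect_true(all(as.character(out2) == "sedentary"))

  expect_length(viterbi_smooth(character(), list(hmm = hmm2)), 0L)
})

test_that("HMM smoothing does not reduce accuracy on noisy semi-Markov sequences", {
  set.seed(31)
  states <- behaviour_states()
  # sticky truth dynamics with 20% symmetric observation noise
  trans <- matrix(0.02 / 4, 5, 5); diag(trans) <- 0.98
  emis <- matrix(0.2 / 4, 5, 5); diag(emis) <- 0.8
  acc_before <- acc_after <- numeric(50)
  hmm <- list(prior = rep(0.2, 5), transitions = trans, emission = emis)
  for (k in 1:50) {
    n <- 300
    truth <- integer(n); truth[1] <- sample.int(5, 1)
    for (t_ in 2:n) truth[t_] <- sample.int(5, 1, prob = trans[truth[t_ - 1], ])
    obs <- vapply(truth, function(s) sample.int(5, 1, prob = emis[s, ]), 0L)
    sm <- viterbi_smooth(states[obs], list(hmm = hmm))
    acc_before[k] <- mean(obs == truth)
    acc_after[k] <- mean(as.integer(sm) == truth)
  }
  expect_gte(mean(acc_after), mean(acc_before))
  expect_gt(mean(acc_after), mean(acc_before) + 0.02)  # typically improves
})

test_that("model evaluation reproduces hand-computed metrics", {
  x <- rep(c("walking", "sedentary"), each = 10)
  ev <- evaluate_model(x, x)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$kappa, 1)

  # exactly half matching on two balanced classes: accuracy .5, kappa 0
  truth <- rep(c("walking", "sedentary"), each = 10)
  pred <- c(rep(c("walking", "sedentary"), each = 5),
            rep(c("sedentary", "walking"), each = 5))
  ev2 <- evaluate_model(pred, truth)
  expect_equal(ev2$accuracy, 0.5)
  expect_equal(ev2$kappa, 0)

  # confusion {AA:40, AB:10, BA:20, BB:30} -> accuracy 0.70
  truth3 <- c(rep("walking", 50), rep("sedentary", 50))
  pred3 <- c(rep("walking", 40), rep("sedentary", 10),
             rep("walking", 20), rep("sedentary", 30))
  expect_equal(evaluate_model(pred3, truth3)$accuracy, 0.70)
  expect_error(evaluate_model(pred3[-1], truth3), "length")
})

test_that("training is reproducible and probability mode agrees at high separation", {
  df <- sim_features(60, sep = 4)
  m1 <- train_balanced_rf(df, n_trees = 40, seed = 9)
  m2 <- train_balanced_rf(df, n_trees = 40, seed = 9)
  expect_identical(m1$oob_confusion, m2$oob_confusion)

  mp <- train_balanced_rf(df, n_trees = 40, seed = 9, probability = TRUE)
  hmm <- estimate_hmm(list(df$label), mp$oob_confusion, alpha = 1)
  m1$hmm <- hmm; mp$hmm <- hmm
  ep <- make_epochs(df$label, vm = 10)
  for (i in 1:5) ep[[paste0("feat_", i)]] <- df[[paste0("feat_", i)]]
  p_lab <- predict_behaviour(m1, ep)
  p_prob <- predict_behaviour(mp, ep, mode = "probs")
  agree <- mean(as.character(p_lab$predicted) == as.character(p_prob$predicted))
  expect_gt(agree, 0.95)
  expect_error(predict_behaviour(m1, ep, mode = "probs"), "probability")
})
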