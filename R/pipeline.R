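#' Save / load a behaviour model bundle
#'
#' The HMM components (prior, transitions, emission) and the OOB confusion
#' are stored as plain-text tab-separated matrices with a small JSON-free
#' metadata file; the tree ensemble itself is stored as an RDS blob
#' (`forest.rds`) since decision forests have no portable text encoding.
#'
#' @param model a `behaviour_model` with `hmm` attached.
#' @param dir bundle directory (created if needed).
#' @return `dir`, invisibly (writer); a `behaviour_model` (reader).
#' @export
write_model_bundle <- function(model, dir) {
  stopifnot(inherits(model, "behaviour_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) utils::write.table(
    m, file.path(dir, f), sep = "\t", quote = FALSE, col.names = NA)
  wm(model$oob_confusion, "oob_confusion.tsv")
  if (!is.null(model$hmm)) {
    wm(model$hmm$transitions, "hmm_transitions.tsv")
    wm(model$hmm$emission, "hmm_emission.tsv")
    utils::write.table(data.frame(state = names(model$hmm$prior),
                                  prior = model$hmm$prior),
                       file.path(dir, "hmm_prior.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(c(paste0("states: ", paste(model$states, collapse = ",")),
               paste0("features: ", paste(model$feature_names, collapse = ",")),
               paste0("oob_accuracy: ", format(model$oob_accuracy, digits = 10))),
             file.path(dir, "meta.txt"))
  saveRDS(model$forest, file.path(dir, "forest.rds"))
  invisible(dir)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(dir) {
  rm_ <- function(f) as.matrix(utils::read.table(
    file.path(dir, f), sep = "\t", header = TRUE, row.names = 1L,
    check.names = FALSE))
  meta <- read_header_fields(paste0("# ", readLines(file.path(dir, "meta.txt"))))
  model <- structure(list(
    forest = readRDS(file.path(dir, "forest.rds")),
    feature_names = strsplit(meta$features, ",")[[1L]],
    states = strsplit(meta$states, ",")[[1L]],
    oob_confusion = rm_("oob_confusion.tsv"),
    oob_accuracy = as.numeric(meta$oob_accuracy)),
    class = "behaviour_model")
  if (file.exists(file.path(dir, "hmm_prior.tsv"))) {
    pr <- utils::read.table(file.path(dir, "hmm_prior.tsv"), sep = "\t",
                            header = TRUE)
    model$hmm <- list(prior = stats::setNames(pr$prior, pr$state),
                      transitions = rm_("hmm_transitions.tsv"),
                      emission = rm_("hmm_emission.tsv"))
  }
  model
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates the cohort and its epoch-tier records, trains the balanced
#' random forest + HMM on the labelled ("camera") subset, then for every
#' participant runs non-wear detection, behaviour prediction with Viterbi
#' smoothing, minute-grid construction, the excellent-wear check,
#' stratified imputation and per-participant summarisation.
#'
#' @param config a [generator_config()].
#' @param seed integer master seed (drives generation, training and
#'   prediction).
#' @param keep_grids keep the per-participant minute grids in the result
#'   (default TRUE; turn off to save memory).
#' @param progress print a line per stage.
#' @return list: `cohort`, `truth`, `model`, `summaries` (stacked
#'   [summarize_participant()] rows for included participants),
#'   `wear_reports`, `included` (ids passing the excellent-wear criterion
#'   on both day types), `grids` (if kept).
#' @export
run_cohort_pipeline <- function(config = generator_config(), seed = config$seed,
                                keep_grids = TRUE, progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  gen <- generate_cohort(config)
  cohort <- gen$cohort; truth <- gen$truth
  n <- nrow(cohort)

  say("generating %d participants x %d days (epoch tier)", n, config$wear_days)
  epochs <- vector("list", n)
  for (i in seq_len(n)) {
    epochs[[i]] <- generate_participant_epochs(
      cohort[i, ], truth, config, seed = derive_seed(seed, 100L + i))
  }
  names(epochs) <- cohort$id

  say("training balanced random forest on %d-participant labelled subset",
      config$camera_subset_n)
  set.seed(derive_seed(seed, 7L))
  subset_ids <- sample(cohort$id, min(config$camera_subset_n, n))
  lab_feats <- list(); lab_seqs <- list()
  for (id in subset_ids) {
    ep <- epochs[[id]]
    day <- date_of(ep$start)
    lab_days <- sort(unique(day))[seq_len(config$camera_days)]
    sel <- day %in% lab_days & ep$wear
    df <- as.data.frame(ep)[sel, c(grep("^feat_", names(ep), value = TRUE),
                                   "label")]
    lab_feats[[id]] <- df
    for (d in lab_days) {
      lab_seqs[[paste(id, d)]] <- ep$label[day == d & ep$wear]
    }
  }
  train_df <- do.call(rbind, lab_feats)
  model <- train_balanced_rf(train_df, n_trees = 100,
                             seed = derive_seed(seed, 8L))
  model$hmm <- estimate_hmm(lab_seqs, model$oob_confusion, alpha = 1)

  say("predicting, QC and summarising")
  summaries <- list(); reports <- list(); grids <- list()
  for (i in seq_len(n)) {
    id <- cohort$id[i]
    ep <- detect_nonwear(epochs[[i]], min_gap_min = 60)
    ep <- predict_behaviour(model, ep)
    grid <- build_minute_grid(ep, cohort[i, ], state_col = "predicted")
    reports[[id]] <- assess_wear(grid)
    if (!reports[[id]]$excellent_both_daytypes) next
    grid <- impute_minute_grid(grid)
    summaries[[id]] <- summarize_participant(grid)
    if (keep_grids) grids[[id]] <- grid
    epochs[[i]] <- NA  # free memory as we go
  }
  included <- names(summaries)
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  list(cohort = cohort, truth = truth, model = model,
       summaries = summaries, wear_reports = reports,
       included = included,
       subset_ids = subset_ids,
       grids = if (keep_grids) grids else NULL)
}

#' Summarise a generated control pool
#'
#' Runs the summary pipeline (non-wear detection, minute-grid construction,
#' imputation, per-participant summaries) for each control, without
#' dialysis-day stratification (controls have no dialysis schedule, so every
#' day is non-dialysis).
#'
#' @param pool result of [generate_control_pool()] with epochs.
#' @return data.frame: one overall [summarize_participant()] row per
#'   control, merged with the pool's demographics.
#' @export
summarize_control_pool <- function(pool) {
  stopifnot(!is.null(pool$epochs))
  rows <- vector("list", nrow(pool$controls))
  for (i in seq_len(nrow(pool$controls))) {
    ctrl <- pool$controls[i, ]
    ep <- detect_nonwear(pool$epochs[[ctrl$id]], min_gap_min = 60)
    grid <- build_minute_grid(ep, ctrl, state_col = "label")
    grid <- impute_minute_grid(grid)
    sm <- summarize_participant(grid)
    rows[[i]] <- sm[sm$day_type == "overall", ]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  merge(out, pool$controls[, c("id", "age", "sex", "wear_season")],
        by.x = "participant_id", by.y = "id")
}

#' Cohort-level recovery summaries from a pipeline run
#'
#' Convenience extraction of the headline cohort statistics: overall /
#' dialysis-day / non-dialysis-day mean vector magnitude, mean hours per
#' behaviour state, and subgroup means by age third and leg weakness.
#'
#' @param run result of [run_cohort_pipeline()].
#' @return named list of cohort means.
#' @export
cohort_headline_stats <- function(run) {
  sm <- run$summaries
  ov <- sm[sm$day_type == "overall", ]
  ov <- merge(ov, run$cohort[, c("id", "age", "leg_weakness")],
              by.x = "participant_id", by.y = "id")
  terts <- stats::quantile(ov$age, c(1 / 3, 2 / 3))
  age_third <- cut(ov$age, breaks = c(-Inf, terts, Inf),
                   labels = c("youngest", "middle", "oldest"))
  state_h <- paste0(behaviour_states(), "_h")
  out <- list(
    vm_overall = mean(ov$mean_vm),
    vm_dialysis = mean(sm$mean_vm[sm$day_type == "dialysis"]),
    vm_nondialysis = mean(sm$mean_vm[sm$day_type == "non-dialysis"]),
    vm_youngest_third = mean(ov$mean_vm[age_third == "youngest"]),
    vm_oldest_third = mean(ov$mean_vm[age_third == "oldest"]),
    vm_leg_weakness = mean(ov$mean_vm[ov$leg_weakness]),
    vm_no_leg_weakness = mean(ov$mean_vm[!ov$leg_weakness]),
    n_included = nrow(ov))
  for (s in state_h) out[[paste0("hours_", sub("_h$", "", s))]] <- mean(ov[[s]])
  out
}
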