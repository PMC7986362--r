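#!/usr/bin/env Rscript
# Stage 2 -- train the behaviour classifier on the camera-annotated subset.
#
# Uses the 25-participant labelled subset (two labelled days each, the
# schedule a wearable camera sub-study would yield) to fit the balanced
# random forest, estimate the HMM smoothing matrices from the label
# sequences and the out-of-bag confusion, and report validation metrics.
# The model bundle is written for stage 3.

library(dialacc)

seed <- 20201
in_dir <- "results/simulated"
cfg <- generator_config(seed = seed)
cohort <- read_cohort_table(file.path(in_dir, "cohort.csv"))

set.seed(derive_seed(seed, 7))
subset_ids <- sample(cohort$id, cfg$camera_subset_n)

feats <- list(); seqs <- list()
for (id in subset_ids) {
  ep <- read_epoch_series(file.path(in_dir, "epochs", paste0(id, ".csv")))
  day <- dialacc:::date_of(ep$start)
  lab_days <- unique(day)[seq_len(cfg$camera_days)]
  sel <- day %in% lab_days & ep$wear
  feats[[id]] <- as.data.frame(ep)[sel, c(grep("^feat_", names(ep), value = TRUE),
                                          "label")]
  for (d in lab_days) seqs[[paste(id, d)]] <- ep$label[day == d & ep$wear]
}
train_df <- do.call(rbind, feats)
message(sprintf("training on %d labelled 30-s epochs from %d participants",
                nrow(train_df), length(subset_ids)))

model <- train_balanced_rf(train_df, n_trees = 100, seed = derive_seed(seed, 8))
model$hmm <- estimate_hmm(seqs, model$oob_confusion, alpha = 1)
print(model)
print(round(model$oob_confusion / rowSums(model$oob_confusion), 3))

write_model_bundle(model, "results/behaviour_model")
writeLines(subset_ids, "results/behaviour_model/camera_subset_ids.txt")
message("model bundle written to results/behaviour_model")
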