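#!/usr/bin/env Rscript
# Stage 1 -- simulate the study cohort.
#
# Generates the default synthetic dialysis cohort (73 participants, 12 full
# wear days, thrice-weekly dialysis in morning or afternoon slots) at the
# epoch tier, plus per-participant questionnaire responses tied to true
# activity. Writes the cohort table, the generator truth table and one epoch
# file per participant. Later stages only read these files.

library(dialacc)

seed <- 20201
out_dir <- "results/simulated"
dir.create(file.path(out_dir, "epochs"), recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = seed)
gen <- generate_cohort(cfg)
cohort <- gen$cohort

message(sprintf("cohort: %d participants, mean age %.1f, %d%% female, %d%% leg weakness",
                nrow(cohort), mean(cohort$age),
                round(100 * mean(cohort$sex == "female")),
                round(100 * mean(cohort$leg_weakness))))

# questionnaires keyed to each participant's true overall activity
ov <- (3 * gen$truth$vm_true[gen$truth$day_type == "dialysis"] +
         4 * gen$truth$vm_true[gen$truth$day_type == "non-dialysis"]) / 7
q <- lapply(seq_len(nrow(cohort)), function(i) {
  resp <- generate_questionnaires(cohort[i, ], ov[i], cfg,
                                  seed = derive_seed(seed, 9000 + i))
  ks <- score_kccq(resp$kccq)
  es <- score_eq5d(resp$eq5d)
  data.frame(id = cohort$id[i],
             kccq_physical = ks$domains[["physical_limitation"]],
             kccq_fss = ks$fss, kccq_clinical = ks$clinical_status,
             eq5d_mobility = es$domain_levels[["mobility"]],
             eq5d_usual = es$domain_levels[["usual_activities"]],
             eq5d_vas = es$vas)
})
scores <- do.call(rbind, q)
write.csv(scores, file.path(out_dir, "questionnaire_scores.csv"),
          row.names = FALSE)

write_cohort_table(cohort, file.path(out_dir, "cohort.csv"))
write.csv(gen$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)

for (i in seq_len(nrow(cohort))) {
  ep <- generate_participant_epochs(cohort[i, ], gen$truth, cfg,
                                    seed = derive_seed(seed, 100 + i))
  write_epoch_series(ep, file.path(out_dir, "epochs",
                                   paste0(cohort$id[i], ".csv")))
}
message(sprintf("wrote %d epoch files under %s/epochs", nrow(cohort), out_dir))
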