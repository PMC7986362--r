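#!/usr/bin/env Rscript
# Stage 4 -- cohort statistics.
#
# Group means with SEs by age third, sex, leg weakness and day type; paired
# dialysis versus non-dialysis t-tests; covariate-adjusted marginal means
# for the flags the unadjusted contrasts cannot settle (breathlessness,
# transplant listing, arrhythmias, CVD/diabetes); Spearman correlations of
# activity with questionnaire scores; and time-of-day profile curves by
# dialysis slot.

library(dialacc)

summ <- read.csv("results/participant_summaries.csv")
class(summ) <- c("activity_summary", "data.frame")
cohort <- read_cohort_table("results/simulated/cohort.csv")
scores <- read.csv("results/simulated/questionnaire_scores.csv")

ov <- merge(summ[summ$day_type == "overall", ], cohort,
            by.x = "participant_id", by.y = "id")
ov$age_third <- cut(ov$age, quantile(ov$age, c(0, 1/3, 2/3, 1)),
                    include.lowest = TRUE,
                    labels = c("youngest", "middle", "oldest"))
outcomes <- c("mean_vm", paste0(behaviour_states(), "_h"))

tabs <- list(all = group_mean_se(ov, outcomes),
             age = group_mean_se(ov, outcomes, "age_third"),
             sex = group_mean_se(ov, outcomes, "sex"),
             leg = group_mean_se(ov, outcomes, "leg_weakness"))
main_table <- do.call(rbind, Map(function(t, n) cbind(stratum = n, t),
                                 tabs, names(tabs)))
write.csv(main_table, "results/table_activity_by_subgroup.csv",
          row.names = FALSE)
message("activity by subgroup:")
print(main_table[, c("stratum", "group", "n", "mean_vm_mean", "mean_vm_se")],
      digits = 3)

# day-type contrasts: per-group display values plus paired tests
bydt <- group_mean_se(summ[summ$day_type != "overall", ], outcomes, "day_type")
write.csv(bydt, "results/table_activity_by_daytype.csv", row.names = FALSE)
tests <- do.call(rbind, lapply(outcomes, function(oc) {
  t_ <- paired_daytype_test(summ, oc)
  data.frame(outcome = oc, mean_difference = t_$mean_difference,
             t = t_$t, p = t_$p)
}))
write.csv(tests, "results/paired_daytype_tests.csv", row.names = FALSE)
message("paired dialysis vs non-dialysis tests:")
print(tests, digits = 3)

# adjusted marginal means for the secondary clinical flags
adj_rows <- list()
for (flag in c("breathlessness", "listed_transplant", "arrhythmia", "cvd_or_dm")) {
  ok <- !is.na(ov[[flag]])
  df <- ov[ok, ]
  df$grp <- factor(ov[[flag]][ok], levels = c(FALSE, TRUE),
                   labels = c("no", "yes"))
  fit <- adjusted_marginal_means(df, "mean_vm", "grp")
  adj_rows[[flag]] <- cbind(flag = flag, fit$marginal,
                            p_het = fit$p_heterogeneity)
}
adj <- do.call(rbind, adj_rows)
write.csv(adj, "results/adjusted_marginal_means.csv", row.names = FALSE)
message("adjusted marginal means (age, sex, leg weakness):")
print(adj, digits = 3)

# questionnaire correlations
qdf <- merge(ov, scores, by.x = "participant_id", by.y = "id")
cors <- questionnaire_correlations(
  qdf, activity_cols = c("mean_vm", "walking_h", "sedentary_h"),
  score_cols = c("kccq_physical", "kccq_fss", "kccq_clinical", "eq5d_vas"))
write.csv(cors, "results/questionnaire_correlations.csv", row.names = FALSE)
message("Spearman correlations with questionnaire scores:")
print(cors, digits = 2)

# time-of-day profiles by slot and day type
grid_files <- list.files("results/grids", full.names = TRUE)
ids <- sub("\\.csv$", "", basename(grid_files))
grids <- lapply(grid_files, read_minute_grid)
slot <- cohort$slot[match(ids, cohort$id)]
prof_rows <- list()
for (sl in c("morning", "afternoon")) for (dt in c("dialysis", "non-dialysis")) {
  pr <- time_of_day_profile(grids[slot == sl], bin_min = 10, day_type = dt)
  prof_rows[[paste(sl, dt)]] <- cbind(slot = sl, day_type = dt, pr)
}
profiles <- do.call(rbind, prof_rows)
write.csv(profiles, "results/timeofday_profiles.csv", row.names = FALSE)
m <- profiles[profiles$slot == "morning" & profiles$day_type == "dialysis", ]
message(sprintf("morning-slot dialysis days: mean vm %.1f mg at 04:00-06:00 vs %.1f mg at 09:00-11:00",
                mean(m$mean[m$bin_start_min >= 240 & m$bin_start_min < 360]),
                mean(m$mean[m$bin_start_min >= 540 & m$bin_start_min < 660])))
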