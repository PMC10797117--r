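#!/usr/bin/env Rscript
# Run the 22-phantom cohort with per-subject disease severity drawn from
# [0.05, 0.45] and compute every cohort statistic: inter-patient
# correlations of median T1(TE) with median PBF and QDP, mean +/- SD local
# correlations, mean relative defect/normal T1 difference, and the
# correlation of per-subject local coefficients with median T1.

suppressMessages(library(lungqmri))

cfg <- default_config()
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

co <- run_cohort(cfg, n_subjects = 22L, seed = 1L)

write.csv(co$table, file.path(out, "cohort_table.csv"), row.names = FALSE)
write.csv(co$interpatient, file.path(out, "interpatient.csv"), row.names = FALSE)
write.csv(co$local_mean, file.path(out, "local_mean.csv"), row.names = FALSE)
jsonlite::write_json(
  list(seed = co$seed, config_hash = co$config_hash,
       delta_t1_mean = as.list(stats::setNames(co$delta_t1_mean,
                                               paste0("te", cfg$te_list))),
       n_defect_shorter = co$n_defect_shorter,
       rho_regcorr = co$rho_regcorr, rho_subcorr = co$rho_subcorr),
  file.path(out, "cohort_stats.json"), auto_unbox = TRUE, digits = NA)

cat("inter-patient correlations (Spearman):\n")
print(co$interpatient[, c("te", "kind", "rho", "p", "significant")],
      row.names = FALSE, digits = 3)
cat("\nmean +/- SD local correlations:\n")
print(co$local_mean, row.names = FALSE, digits = 3)
cat(sprintf("\nmean dT1 per TE (%%): %s\n",
            paste(sprintf("%.1f", co$delta_t1_mean), collapse = ", ")))
cat(sprintf("defect T1 shorter in %d/22 subjects; rho_regcorr = %.2f, rho_subcorr = %.2f\n",
            co$n_defect_shorter, co$rho_regcorr, co$rho_subcorr))
cat("\nsign structure: median T1 correlates positively with PBF and negatively\n")
cat("with QDP across subjects; defect voxels carry shorter T1 within subjects.\n")
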