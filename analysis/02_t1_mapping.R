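#!/usr/bin/env Rscript
# Fit per-voxel T1 at every echo time for the subject simulated in
# 01_simulate.R (regenerated from its seed) and tabulate the per-TE lung
# medians against the ground truth.

suppressMessages(library(lungqmri))

cfg <- default_config()
out <- "results/subject01"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
subj <- make_subject(cfg, seed = 11L, defect_fraction = 0.2)
lung <- subj$truth$labels > 0L

rows <- lapply(subj$ir, function(series) {
  tm <- map_t1(series, lung)
  write_nifti_map(tm$t1, tm$grid,
                  file.path(out, sprintf("t1_te%04d.nii.gz", tm$te)))
  med <- median_t1(tm, lung)
  truth_med <- median(observed_t1(subj$truth, series$te)[lung])
  data.frame(te_us = tm$te, n_valid = tm$n_valid,
             median_t1_ms = as.numeric(med), truth_median_ms = truth_med,
             rel_err_pct = 100 * abs(as.numeric(med) - truth_med) / truth_med)
})
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "t1_medians.csv"), row.names = FALSE)
print(tab, row.names = FALSE, digits = 4)
cat("ground-truth median T1 rises with TE as the short-T2* parenchyma signal\n")
cat("decays; the fitted medians track it closely at short TE but are biased\n")
cat("increasingly low at long TE, where the signal amplitude has decayed\n")
cat("towards the noise floor and fewer fits survive the validity checks\n")
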