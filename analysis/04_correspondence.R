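#!/usr/bin/env Rscript
# Relate the T1 and perfusion maps of subject01 through both correspondence
# routes: identity-deformation voxel matching and the registration-free
# 10 x 10 equal-volume subdivision; write the per-area table and the
# per-TE local correlations.

suppressMessages(library(lungqmri))

cfg <- default_config()
out <- "results/subject01"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
subj <- make_subject(cfg, seed = 11L, defect_fraction = 0.2)

b <- run_subject(subj, cfg)
summary_json(b$summary, file.path(out, "summary.json"))

# per-area table at TE1: median T1, median PBF, defect fraction
tm <- b$t1_maps[[1]]
rows <- list()
for (side in 1:2) {
  su <- b$subdivision$ute[[side]]
  sd_ <- b$subdivision$dce[[side]]
  t1a <- area_summary(ifelse(tm$valid, tm$t1, NA_real_), su)
  pba <- area_summary(b$slab$pbf, sd_)
  dfa <- area_summary(b$slab$defect + 0, sd_, fun = mean)
  rows[[side]] <- data.frame(side = c("left", "right")[side],
                             area = seq_len(100L), median_t1 = t1a,
                             median_pbf = pba, defect_fraction = dfa)
}
areas <- do.call(rbind, rows)
write.csv(areas, file.path(out, "areas_te70.csv"), row.names = FALSE)

for (pt in b$summary$per_te)
  cat(sprintf("TE %4d us: rho_regPBF = %5.2f  rho_subPBF = %5.2f  rho_subQDP = %5.2f  dT1 = %5.1f%% (%s)\n",
              pt$te, pt$rho_regPBF, pt$rho_subPBF, pt$rho_subQDP,
              pt$delta_t1, pt$defect_direction))
cat("local T1-PBF coupling is positive and T1-QDP coupling negative, as the\n")
cat("coupled defect design (short T1 where flow is low) implies\n")
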