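#!/usr/bin/env Rscript
# Simulate one synthetic subject: lungs with a 20% perfusion-defect burden,
# IR-UTE TI series at five echo times and a 20-frame DCE series, and write
# every image plus a JSON sidecar under results/subject01/.

suppressMessages(library(lungqmri))

cfg <- default_config()
out <- "results/subject01"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

subj <- make_subject(cfg, seed = 11L, defect_fraction = 0.2)
truth <- subj$truth

cat(sprintf("phantom: %d lung voxels, defect fraction %.3f (target 0.200)\n",
            sum(truth$labels > 0), truth$defect_fraction))

write_nifti_map(truth$labels, truth$grid, file.path(out, "lung_labels.nii.gz"))
write_nifti_map(truth$defect + 0, truth$grid, file.path(out, "defect_truth.nii.gz"))
write_nifti_map(truth$pbf, truth$grid, file.path(out, "pbf_truth.nii.gz"))
for (series in subj$ir)
  write_nifti_map(series$stack, truth$grid,
                  file.path(out, sprintf("ir_te%04d.nii.gz", series$te)))
write_nifti_map(subj$dce$stack[, , , 1], truth$grid,
                file.path(out, "dce_frame01.nii.gz"),
                slice_thickness = subj$dce$slice_thickness)

write_sidecar(list(seed = subj$seed, config_hash = config_hash(cfg),
                   te_list = cfg$te_list, ti_list = cfg$ti_list,
                   dce_dt = cfg$dce_dt, dce_nt = cfg$dce_nt,
                   snr = cfg$snr, truth_params = truth$params),
              file.path(out, "sidecar.json"))
write_config(cfg, file.path(out, "config.yaml"))
cat("wrote phantom images and sidecar to", out, "\n")
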