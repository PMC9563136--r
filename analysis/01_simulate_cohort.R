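#!/usr/bin/env Rscript
# Step 1 -- Cohort anatomy.
#
# Generates the default 20-patient synthetic pelvis cohort (80^3 grid,
# 2.5 mm isotropic) and records per-patient structure volumes and the
# bladder-PTV overlap fraction. The overlap is drawn uniformly in [0, 0.3]
# per patient, so the cohort contains both well-separated bladders and the
# high-overlap anatomy where preset bladder goals become unachievable.
#
# Output: results/cohort_manifest.csv

suppressPackageStartupMessages(library(planqc))
dir.create("results", showWarnings = FALSE)

n_patients <- 20
master_seed <- 1
voxel_cc <- prod(rep(2.5, 3)) / 1000   # voxel volume in cm^3

rows <- lapply(seq_len(n_patients), function(p) {
  pseed <- planqc:::mix_seed(master_seed, p)
  ph <- generate_phantom(c(80, 80, 80), 2.5, seed = pseed)
  m <- ph$masks
  data.frame(
    patient_id = sprintf("P%03d", p),
    seed = pseed,
    ptv_cc = sum(m$PTV) * voxel_cc,
    ctv_cc = sum(m$CTV) * voxel_cc,
    bladder_cc = sum(m$bladder) * voxel_cc,
    femur_head_L_cc = sum(m$femur_head_L) * voxel_cc,
    femur_head_R_cc = sum(m$femur_head_R) * voxel_cc,
    small_bowel_cc = sum(m$small_bowel) * voxel_cc,
    body_cc = sum(m$body) * voxel_cc,
    bladder_ptv_overlap = sum(m$bladder & m$PTV) / sum(m$bladder))
})
manifest <- do.call(rbind, rows)
write.csv(manifest, "results/cohort_manifest.csv", row.names = FALSE)

cat(sprintf("Simulated %d patients; PTV volume %.0f-%.0f cc, bladder-PTV overlap %.2f-%.2f\n",
            n_patients, min(manifest$ptv_cc), max(manifest$ptv_cc),
            min(manifest$bladder_ptv_overlap),
            max(manifest$bladder_ptv_overlap)))
cat(sprintf("High-overlap patients (> 0.2): %d of %d\n",
            sum(manifest$bladder_ptv_overlap > 0.2), n_patients))
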