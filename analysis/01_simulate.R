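#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort and its imaging-side inputs.
#
# Produces, under results/: the parcellation (NIfTI labels), per-subject FC
# features and outcomes (CSV), control/patient RSN probability maps (NIfTI),
# tumor segmentations summarized as a frequency map, and a manifest.

suppressPackageStartupMessages(library(rsnpfs))

cfg_path <- commandArgs(trailingOnly = TRUE)[1]
cfg <- load_run_config(if (is.na(cfg_path)) NULL else cfg_path)
out_dir <- file.path(cfg$paths$results_dir, "simulate")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message("simulating cohort: ", cfg$cohort$n_subjects, " subjects, seed ", cfg$seed)
outcome <- do.call(outcome_spec, cfg$outcome)
cohort <- simulate_cohort(n_subjects = cfg$cohort$n_subjects,
                          n_timepoints = cfg$cohort$n_timepoints,
                          voxels_per_network = cfg$cohort$voxels_per_network,
                          grid_shape = cfg$cohort$grid_shape,
                          outcome = outcome, seed = cfg$seed)
print(cohort)
message(sprintf("PFS: mean %.1f, median %.1f months; %d/%d clipped at %g",
                mean(cohort$pfs_months), median(cohort$pfs_months),
                sum(cohort$pfs_months > cfg$clip_cap), nrow(cohort$fc),
                cfg$clip_cap))

parc_file <- file.path(out_dir, "parcellation.nii.gz")
write_parcellation_nifti(cohort$parcellation, parc_file)
fc_file <- file.path(out_dir, "fc_features.csv")
outcome_file <- file.path(out_dir, "outcomes.csv")
write_cohort_csv(cohort, fc_file, outcome_file)

# probability maps under a disease-burden attenuation profile: association
# networks most affected
att <- rep(0.9, 15)
att[match(c("DMN", "DAN", "FPN", "VAN"), rsn_networks())] <- c(0.4, 0.5, 0.5, 0.6)
maps <- simulate_probability_maps(cohort$parcellation, attenuation = att,
                                  seed = derive_seed(cfg$seed, 31L))
map_files <- character()
for (g in rsn_networks()) {
  f <- file.path(out_dir, sprintf("prob_control_%s.nii.gz", g))
  write_map_nifti(maps$control[[g]], cohort$parcellation$grid_shape, f)
  f2 <- file.path(out_dir, sprintf("prob_patient_%s.nii.gz", g))
  write_map_nifti(maps$patient[[g]], cohort$parcellation$grid_shape, f2)
  map_files <- c(map_files, f, f2)
}

seg <- simulate_segmentations(cfg$cohort$n_subjects, cohort$parcellation,
                              seed = derive_seed(cfg$seed, 32L))
freq_file <- file.path(out_dir, "tumor_frequency.nii.gz")
write_map_nifti(tumor_frequency_map(seg$masks),
                cohort$parcellation$grid_shape, freq_file)

write_manifest(out_dir, cfg, cfg$seed,
               c(parc_file, fc_file, outcome_file, freq_file, map_files))
message("stage 1 written to ", out_dir)
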