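#!/usr/bin/env Rscript
# Stage 5: map-level analyses — tumor frequency, voxelwise PFS association
# with per-network averages, per-network Cliff's delta between control and
# patient probability maps, and projection of network feature weights onto
# the probability maps.

suppressPackageStartupMessages(library(rsnpfs))

cfg_path <- commandArgs(trailingOnly = TRUE)[1]
cfg <- load_run_config(if (is.na(cfg_path)) NULL else cfg_path)
sim_dir <- file.path(cfg$paths$results_dir, "simulate")
sel_dir <- file.path(cfg$paths$results_dir, "selection")
out_dir <- file.path(cfg$paths$results_dir, "maps")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# regenerate the deterministic inputs that carry raw structure
cohort <- simulate_cohort(n_subjects = cfg$cohort$n_subjects,
                          n_timepoints = cfg$cohort$n_timepoints,
                          voxels_per_network = cfg$cohort$voxels_per_network,
                          grid_shape = cfg$cohort$grid_shape,
                          outcome = do.call(outcome_spec, cfg$outcome),
                          seed = cfg$seed)
parc <- cohort$parcellation
seg <- simulate_segmentations(cfg$cohort$n_subjects, parc,
                              seed = derive_seed(cfg$seed, 32L))
pfs <- clip_outcomes(cohort$pfs_months + seg$pfs_shift -
                       min(cohort$pfs_months + seg$pfs_shift) + 0.5,
                     cfg$clip_cap)

files <- character()
assoc <- voxelwise_pfs_association(seg$masks, pfs)
f <- file.path(out_dir, "pfs_association.nii.gz")
write_map_nifti(ifelse(is.na(assoc), 0, assoc), parc$grid_shape, f)
files <- c(files, f)
per_net <- average_map_per_network(assoc, parc)
message("per-RSN PFS association (most negative = shortest PFS):")
print(round(sort(per_net), 3))
f <- file.path(out_dir, "pfs_association_per_network.csv")
write.csv(data.frame(network = names(per_net), mean_r = as.numeric(per_net)),
          f, row.names = FALSE)
files <- c(files, f)

# Cliff's delta between control and patient probability maps
att <- rep(0.9, 15)
att[match(c("DMN", "DAN", "FPN", "VAN"), rsn_networks())] <- c(0.4, 0.5, 0.5, 0.6)
maps <- simulate_probability_maps(parc, attenuation = att,
                                  seed = derive_seed(cfg$seed, 31L))
es <- network_effect_sizes(maps$control, maps$patient, parc)
message("largest effect sizes:")
print(head(es[order(-es$delta), ], 5))
f <- file.path(out_dir, "network_effect_sizes.csv")
write.csv(es, f, row.names = FALSE)
files <- c(files, f)

# project the stage-2 network feature weights onto the probability maps
net_w <- read.csv(file.path(sel_dir, "network_feature_weights.csv"))
proj <- project_weights_to_voxels(net_w$weight, maps$control)
f <- file.path(out_dir, "feature_weight_projection.nii.gz")
write_map_nifti(proj, parc$grid_shape, f)
files <- c(files, f)

write_manifest(out_dir, cfg, cfg$seed, files)
message("stage 5 written to ", out_dir)
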