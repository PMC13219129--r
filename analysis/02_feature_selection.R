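#!/usr/bin/env Rscript
# Stage 2: MRMR feature selection on the full cohort (descriptive pass; the
# predictive pipeline re-runs MRMR inside every LOOCV fold) plus the PCA
# variance diagnostic and network-level feature weights.

suppressPackageStartupMessages(library(rsnpfs))

cfg_path <- commandArgs(trailingOnly = TRUE)[1]
cfg <- load_run_config(if (is.na(cfg_path)) NULL else cfg_path)
sim_dir <- file.path(cfg$paths$results_dir, "simulate")
out_dir <- file.path(cfg$paths$results_dir, "selection")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

fc <- as.matrix(read.csv(file.path(sim_dir, "fc_features.csv"),
                         check.names = FALSE)[, -1])
outcomes <- read.csv(file.path(sim_dir, "outcomes.csv"))
y <- clip_outcomes(outcomes$pfs_months, cfg$clip_cap)

rk <- mrmr_rank(fc, y, k = cfg$selection$k, scheme = cfg$selection$scheme)
labels <- fc_pair_labels()$label
message("top ", cfg$selection$k, " MRMR features:")
message("  ", paste(labels[rk$selected], collapse = ", "))
ve <- variance_explained_check(fc, cfg$selection$k)
message(sprintf("top %d PCs explain %.1f%% of feature variance",
                cfg$selection$k, 100 * ve))

rank_file <- file.path(out_dir, "mrmr_ranking.json")
jsonlite::write_json(list(order = rk$order, scores = rk$scores,
                          k = rk$k, scheme = rk$scheme,
                          selected_labels = labels[rk$selected],
                          pca_variance_explained = ve),
                     rank_file, auto_unbox = TRUE, digits = NA)

# network-level averages of the per-feature relevance-style weights
net_w <- average_network_feature_weights(rk$relevance)
w_file <- file.path(out_dir, "network_feature_weights.csv")
write.csv(data.frame(network = names(net_w), weight = as.numeric(net_w)),
          w_file, row.names = FALSE)
message("strongest networks: ",
        paste(names(sort(net_w, decreasing = TRUE))[1:3], collapse = ", "))

write_manifest(out_dir, cfg, cfg$seed, c(rank_file, w_file))
message("stage 2 written to ", out_dir)
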