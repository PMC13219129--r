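#!/usr/bin/env Rscript
# Stage 3: the predictive pipeline — nested LOOCV with per-fold MRMR,
# augmentation-backed ANN training with random restarts, and the linear
# baseline on identical folds. Regenerates the cohort from the config seed
# (the raw time series are needed for augmentation).

suppressPackageStartupMessages(library(rsnpfs))

cfg_path <- commandArgs(trailingOnly = TRUE)[1]
cfg <- load_run_config(if (is.na(cfg_path)) NULL else cfg_path)
out_dir <- file.path(cfg$paths$results_dir, "prediction")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- simulate_cohort(n_subjects = cfg$cohort$n_subjects,
                          n_timepoints = cfg$cohort$n_timepoints,
                          voxels_per_network = cfg$cohort$voxels_per_network,
                          grid_shape = cfg$cohort$grid_shape,
                          outcome = do.call(outcome_spec, cfg$outcome),
                          seed = cfg$seed)

message("running nested LOOCV (widths ", paste(cfg$model$widths, collapse = "/"),
        ", ", cfg$model$restarts, " restarts per config) ...")
t0 <- Sys.time()
res <- loocv_run(cohort, widths = cfg$model$widths, losses = cfg$model$losses,
                 restarts = cfg$model$restarts, k = cfg$selection$k,
                 aug_spec = do.call(augmentation_spec, cfg$augmentation),
                 cap = cfg$clip_cap, seed = derive_seed(cfg$seed, 41L),
                 control = list(max_iter = cfg$model$max_iter))
message(sprintf("LOOCV done in %.1f min", as.numeric(Sys.time() - t0, units = "mins")))
print(res)
message("hidden widths chosen per fold: ",
        paste(sprintf("%d x %s", table(res$best_widths),
                      names(table(res$best_widths))), collapse = ", "))

lb <- linear_baseline(cohort, k = cfg$selection$k, cap = cfg$clip_cap)
message(sprintf("linear baseline: MAE %.2f months (ANN: %.2f)",
                lb$metrics$mae, res$metrics$mae))

pred_file <- file.path(out_dir, "predictions.csv")
write.csv(data.frame(subject = seq_along(res$predicted),
                     actual_pfs = res$actual, ann_pred = res$predicted,
                     linear_pred = lb$predicted),
          pred_file, row.names = FALSE)
metrics_file <- file.path(out_dir, "metrics.json")
jsonlite::write_json(list(ann = res$metrics, linear = lb$metrics,
                          fold_features = apply(res$fold_features, 2, identity,
                                                simplify = FALSE)),
                     metrics_file, auto_unbox = TRUE, digits = NA)
write_manifest(out_dir, cfg, cfg$seed, c(pred_file, metrics_file))
message("stage 3 written to ", out_dir)
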