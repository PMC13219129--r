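#' Write a voxel map or parcelation labels to NIfTI
#'
#' @param values Numeric/integer voxel vector of length `prod(grid_shape)`.
#' @param grid_shape 3 grid dimensions.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(values, grid_shape, path) {
  arr <- array(as.numeric(values), dim = grid_shape)
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Read a voxel map from NIfTI
#'
#' @param path NIfTI file path.
#' @return List: `values` (voxel vector), `grid_shape`.
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = as.numeric(img), grid_shape = dim(img))
}

#' Write a parcellation as an integer label NIfTI
#'
#' Voxels carry the 1-based network index (0 = background).
#'
#' @param parcellation An `rsn_parcellation`.
#' @param path Output path.
#' @export
write_parcellation_nifti <- function(parcellation, path) {
  validate_parcellation(parcellation)
  lab <- integer(prod(parcellation$grid_shape))
  for (g in seq_along(parcellation$voxel_ids)) {
    lab[parcellation$voxel_ids[[g]]] <- g
  }
  write_map_nifti(lab, parcellation$grid_shape, path)
}

#' Extract per-ROI voxel time series from a 4D volume
#'
#' Pulls each network's voxelwise time series out of a 4D image (x, y, z,
#' time) using the parcellation's voxel indices, yielding the
#' [subject_timeseries()] container the connectivity stage consumes.
#'
#' @param img A 4D numeric array, or a path to a 4D NIfTI file.
#' @param parcellation An `rsn_parcellation` on the same grid.
#' @param subject_id Subject label.
#' @return A [subject_timeseries()] object.
#' @export
extract_subject_timeseries <- function(img, parcellation,
                                       subject_id = "subject") {
  validate_parcellation(parcellation)
  if (is.character(img)) img <- as.array(RNifti::readNifti(img))
  stopifnot(length(dim(img)) == 4L)
  if (!all(dim(img)[1:3] == parcellation$grid_shape)) {
    stopf("image grid %s does not match parcellation grid %s",
          paste(dim(img)[1:3], collapse = "x"),
          paste(parcellation$grid_shape, collapse = "x"))
  }
  n_vox <- prod(parcellation$grid_shape)
  Tn <- dim(img)[4]
  flat <- matrix(as.numeric(img), n_vox, Tn)  # voxels x timepoints
  blocks <- lapply(parcellation$voxel_ids, function(ids) {
    flat[ids, , drop = FALSE]
  })
  subject_timeseries(blocks, subject_id)
}

#' Serialize a trained model to JSON
#'
#' Stores layer shapes, flattened parameters, normalization constants and
#' the configuration, sufficient to reload and predict.
#'
#' @param model An `ann_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
ann_save_json <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  obj <- list(
    config = unclass(model$config),
    shapes = lapply(model$params, dim),
    parameters = lapply(model$params, as.numeric),
    norm = model$norm,
    validation_loss = model$validation_loss,
    train_loss = model$train_loss
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model serialized with [ann_save_json()]
#'
#' @param path JSON path.
#' @return An `ann_model` usable with [ann_predict()].
#' @export
ann_load_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(ann_config, obj$config[setdiff(names(obj$config), "n_hidden")])
  params <- lapply(names(obj$shapes), function(nm) {
    matrix(obj$parameters[[nm]], obj$shapes[[nm]][1], obj$shapes[[nm]][2])
  })
  names(params) <- names(obj$shapes)
  norm <- obj$norm
  if (!is.null(norm)) norm <- lapply(norm, as.numeric)
  structure(list(params = params, config = cfg, norm = norm,
                 validation_loss = obj$validation_loss,
                 train_loss = obj$train_loss),
            class = "ann_model")
}

#' Write a cohort's FC features and outcomes to CSV
#'
#' @param cohort An `fc_cohort`.
#' @param features_path,outcomes_path Output CSV paths.
#' @export
write_cohort_csv <- function(cohort, features_path, outcomes_path) {
  fc <- as.data.frame(cohort$fc)
  fc <- cbind(subject = vapply(cohort$subjects, `[[`, "", "subject_id"), fc)
  utils::write.csv(fc, features_path, row.names = FALSE)
  out <- data.frame(subject = fc$subject,
                    pfs_months = cohort$pfs_months,
                    os_months = cohort$os_months,
                    pfs_event = cohort$pfs_event,
                    os_event = cohort$os_event)
  utils::write.csv(out, outcomes_path, row.names = FALSE)
  invisible(NULL)
}

run_config_defaults <- function() {
  list(
    seed = 1L,
    cohort = list(n_subjects = 45L, n_timepoints = 160L,
                  voxels_per_network = 40L, grid_shape = c(20L, 20L, 20L)),
    outcome = unclass(outcome_spec()),
    selection = list(k = 15L, scheme = "difference"),
    model = list(widths = c(5L, 10L), losses = "mse", restarts = 5L,
                 max_iter = 150L),
    augmentation = list(timepoint_fraction_range = c(0.70, 0.80),
                        voxel_fraction_range = c(0.70, 0.80),
                        n_augmented_range = c(10L, 500L),
                        val_fraction_range = c(0.05, 0.20)),
    clip_cap = 24,
    paths = list(results_dir = "results")
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults)) stopf("unknown config key: %s", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) stopf("config key %s must be a mapping", full)
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a declarative run configuration
#'
#' Reads a YAML config, validates every key against the documented schema
#' (unknown keys are rejected with their path), and fills unset keys with
#' the package defaults. An empty or missing-file path yields the full
#' default configuration.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return Named configuration list.
#' @export
load_run_config <- function(path = NULL) {
  defaults <- run_config_defaults()
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(defaults)
  merge_config(defaults, user)
}

#' Write a reproducibility manifest
#'
#' Records the configuration, master seed, package and R versions, and an
#' md5 checksum per produced file, sufficient to reproduce the stage.
#'
#' @param dir Output directory (manifest written as `manifest.json`).
#' @param config The run configuration list.
#' @param seed Master seed used.
#' @param files Character vector of produced file paths.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, seed, files = character()) {
  files <- files[file.exists(files)]
  manifest <- list(
    package = "rsnpfs",
    package_version = as.character(utils::packageVersion("rsnpfs")),
    r_version = as.character(getRversion()),
    seed = seed,
    config = config,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
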