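#' NIfTI and sidecar serialization
#'
#' Sessions, masks and fitted models are exchanged as NIfTI-1 volumes
#' (RAS+, 0-based voxel indices, time as the 4th dimension) with YAML
#' sidecars for scalar metadata, motion traces as 6-column TSV and events
#' as BIDS-style TSV.
#'
#' @name nfb_io
NULL

.VOXEL_MM <- 3.75

.as_nifti <- function(arr) {
  RNifti::asNifti(arr, pixdim = rep(.VOXEL_MM, 3))
}

#' Write a session to a directory
#'
#' Per run: `run-<r>_bold.nii.gz`, `run-<r>_events.tsv`,
#' `run-<r>_motion.tsv`; plus one NIfTI per mask and a `session.yaml`
#' sidecar holding the design parameters and the ground-truth phantom
#' configuration.
#'
#' @param session an `nfb_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_nifti <- function(session, dir) {
  stopifnot(inherits(session, "nfb_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(session$volumes)) {
    RNifti::writeNifti(.as_nifti(session$volumes[[r]]),
                       file.path(dir, sprintf("run-%d_bold.nii.gz", r)))
    write_events(session$design$runs[[r]],
                 file.path(dir, sprintf("run-%d_events.tsv", r)))
    write_motion_tsv(session$motion[[r]],
                     file.path(dir, sprintf("run-%d_motion.tsv", r)))
  }
  for (nm in names(session$masks)) {
    RNifti::writeNifti(.as_nifti(1 * session$masks[[nm]]),
                       file.path(dir, sprintf("mask-%s.nii.gz", nm)))
  }
  gt <- unclass(session$ground_truth)
  yaml::write_yaml(list(
    method = session$design$method,
    start_emotion = session$design$start_emotion,
    tr_s = session$design$tr_s,
    n_dummy = session$design$n_dummy,
    ground_truth = gt
  ), file.path(dir, "session.yaml"))
  invisible(dir)
}

#' Read a session written by [write_session_nifti()]
#'
#' @param dir session directory.
#' @return An `nfb_session` (design rebuilt from the sidecar parameters).
#' @export
read_session_nifti <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "session.yaml"))
  gt <- meta$ground_truth
  config <- phantom_config(
    grid_dims = unlist(gt$grid_dims), baseline = gt$baseline,
    noise_sd = gt$noise_sd, ar1_coef = gt$ar1_coef,
    drift_amplitude = gt$drift_amplitude,
    planted_effects = lapply(gt$planted_effects, function(e)
      list(voxels = unlist(e$voxels), condition = e$condition, psc = e$psc)),
    motion_sd = unlist(gt$motion_sd), seed = gt$seed)
  design <- build_session_design(meta$method, meta$start_emotion,
                                 meta$tr_s, meta$n_dummy)
  runs <- sort(list.files(dir, pattern = "^run-\\d+_bold\\.nii\\.gz$"))
  volumes <- lapply(runs, function(f) {
    arr <- RNifti::readNifti(file.path(dir, f))
    array(as.numeric(arr), dim = dim(arr))
  })
  masks_files <- list.files(dir, pattern = "^mask-.*\\.nii\\.gz$")
  masks <- lapply(masks_files, function(f) {
    arr <- RNifti::readNifti(file.path(dir, f))
    array(as.numeric(arr) > 0.5, dim = dim(arr))
  })
  names(masks) <- sub("^mask-(.*)\\.nii\\.gz$", "\\1", masks_files)
  motion <- lapply(seq_along(runs), function(r)
    as.matrix(read_motion_tsv(file.path(dir,
                                        sprintf("run-%d_motion.tsv", r)))))
  structure(list(volumes = volumes, design = design, masks = masks,
                 motion = motion, ground_truth = config),
            class = "nfb_session")
}

#' Write / read a motion trace as 6-column TSV
#'
#' @param motion per-volume matrix: 3 translations (mm), 3 rotations (rad).
#' @param path file path.
#' @return `path` invisibly; the reader returns a numeric matrix.
#' @export
write_motion_tsv <- function(motion, path) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6)
  utils::write.table(format(motion, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("trans_x", "trans_y", "trans_z",
                                   "rot_x", "rot_y", "rot_z"))
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  as.matrix(utils::read.delim(path))
}

#' Serialize a trained ROI model
#'
#' Writes the selected-voxel mask and the activation statistic map as
#' NIfTI, plus a YAML sidecar (name, target condition, fraction, selection
#' size, statistic summary).
#'
#' @param model an `roi_model`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_roi_model <- function(model, prefix) {
  stopifnot(inherits(model, "roi_model"))
  sel <- array(0, dim = dim(model$roi$mask))
  sel[model$selected_voxels] <- 1
  RNifti::writeNifti(.as_nifti(sel), paste0(prefix, "_selected.nii.gz"))
  stat <- model$stat_map
  stat[is.na(stat)] <- 0
  RNifti::writeNifti(.as_nifti(stat), paste0(prefix, "_stat.nii.gz"))
  yaml::write_yaml(list(
    name = model$roi$name, target_condition = model$roi$target_condition,
    fraction = model$fraction, n_selected = length(model$selected_voxels),
    n_mask = sum(model$roi$mask),
    stat_max = max(model$stat_map, na.rm = TRUE),
    stat_min = min(model$stat_map, na.rm = TRUE)
  ), paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' Serialize a trained SVM model
#'
#' Writes the hyperplane weights as a NIfTI map over the feature mask plus
#' a YAML sidecar (intercept, cost, class orientation, training-store
#' digest).
#'
#' @param model an `svm_model`.
#' @param feature_mask logical 3D array the features were extracted over.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_svm_model <- function(model, feature_mask, prefix) {
  stopifnot(inherits(model, "svm_model"),
            sum(feature_mask) == length(model$w))
  wmap <- array(0, dim = dim(feature_mask))
  wmap[which(feature_mask)] <- model$w
  RNifti::writeNifti(.as_nifti(wmap), paste0(prefix, "_weights.nii.gz"))
  yaml::write_yaml(list(
    b = model$b, C = model$C, class_orientation = model$class_orientation,
    n_examples = length(model$store$label),
    n_per_class = as.list(table(model$store$label)),
    runs_seen = sort(unique(model$store$run_index))
  ), paste0(prefix, ".yaml"))
  invisible(prefix)
}
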