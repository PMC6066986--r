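#' Configuration for the synthetic BOLD phantom
#'
#' The phantom emulates the statistical structure the feedback engine
#' assumes: a constant baseline intensity, HRF-convolved condition boxcars
#' with planted per-voxel percent-signal-change (PSC) effects, additive
#' AR(1) Gaussian noise, a low-frequency (linear + sinusoidal) drift, and a
#' per-volume rigid-motion trace. It does not emulate anatomy, susceptibility
#' artifacts, slice timing or physiological noise.
#'
#' @param grid_dims integer vector of 3 voxel-grid dimensions.
#' @param baseline baseline signal intensity (arbitrary units).
#' @param noise_sd standard deviation of the AR(1) *innovations* (arbitrary
#'   units); the stationary SD is `noise_sd / sqrt(1 - ar1_coef^2)`.
#' @param ar1_coef lag-1 autoregressive coefficient in `[0, 1)`.
#' @param drift_amplitude amplitude of the linear and sinusoidal drift
#'   components per run (arbitrary units).
#' @param planted_effects list of effects, each a list with `voxels` (linear
#'   voxel indices), `condition` (`"tenderness"` or `"anguish"`) and `psc`
#'   (nonnegative fractional PSC amplitude, e.g. 0.02 for 2%).
#' @param motion_sd length-2 numeric: per-volume random-walk innovation SD
#'   for translations (mm) and rotations (rad).
#' @param seed integer seed; generation is a pure function of
#'   (design, config).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_dims = c(16L, 16L, 10L), baseline = 1000,
                           noise_sd = 20, ar1_coef = 0.3,
                           drift_amplitude = 5, planted_effects = list(),
                           motion_sd = c(0.02, 5e-4), seed = 1L) {
  stopifnot(length(grid_dims) == 3, all(grid_dims >= 1),
            noise_sd >= 0, ar1_coef >= 0, ar1_coef < 1, baseline > 0,
            length(motion_sd) == 2)
  n_vox <- prod(grid_dims)
  seen <- list()
  for (eff in planted_effects) {
    stopifnot(all(eff$voxels >= 1), all(eff$voxels <= n_vox),
              eff$condition %in% .EMOTIONS, eff$psc >= 0)
    key <- eff$condition
    prev <- seen[[key]]
    overlap <- intersect(prev$voxels, eff$voxels)
    if (length(overlap) && any(prev$psc[match(overlap, prev$voxels)] != eff$psc)) {
      stop("contradictory planted effects: voxels assigned two different ",
           "PSC amplitudes for condition '", key, "'")
    }
    seen[[key]] <- list(voxels = c(prev$voxels, eff$voxels),
                        psc = c(prev$psc, rep(eff$psc, length(eff$voxels))))
  }
  structure(list(
    grid_dims = as.integer(grid_dims), baseline = baseline,
    noise_sd = noise_sd, ar1_coef = ar1_coef,
    drift_amplitude = drift_amplitude, planted_effects = planted_effects,
    motion_sd = motion_sd, seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Default phantom masks
#'
#' Three masks on the phantom grid, mirroring the roles the engine needs: a
#' 1,000-voxel septo-hypothalamic box (target ROI for tenderness), a small
#' right-amygdala box (target ROI for anguish), and a broad feature-selection
#' mask that excludes a designated sensorimotor/visuospatial slab.
#'
#' @param grid_dims grid dimensions (the default layout assumes at least
#'   16 x 16 x 10).
#' @return Named list of logical 3D arrays: `septo_hypothalamic`,
#'   `right_amygdala`, `feature_mask`.
#' @export
default_masks <- function(grid_dims = c(16L, 16L, 10L)) {
  stopifnot(all(grid_dims >= c(16, 16, 10)))
  empty <- array(FALSE, dim = grid_dims)
  septo <- empty
  septo[4:13, 4:13, 1:10] <- TRUE          # 1,000 voxels
  amyg <- empty
  amyg[14:16, 4:9, 3:7] <- TRUE            # 90 voxels
  feat <- array(TRUE, dim = grid_dims)
  feat[, (grid_dims[2] - 1):grid_dims[2], ] <- FALSE  # sensorimotor slab out
  list(septo_hypothalamic = septo, right_amygdala = amyg, feature_mask = feat)
}

#' Plant region-level ROI effects
#'
#' Samples a fraction of each target ROI and plants a positive PSC effect
#' there: tenderness in the septo-hypothalamic mask, anguish in the right
#' amygdala. These are the voxels the training-run mapping should recover.
#'
#' @param masks list from [default_masks()].
#' @param psc fractional PSC amplitude.
#' @param fraction fraction of each ROI's voxels that carry the effect.
#' @param seed sampling seed.
#' @return List of planted-effect descriptors for [phantom_config()].
#' @export
plant_roi_effects <- function(masks, psc = 0.02, fraction = 0.10, seed = 1L) {
  withr::with_seed(seed, {
    lapply(list(c("septo_hypothalamic", "tenderness"),
                c("right_amygdala", "anguish")), function(pair) {
      vox <- which(masks[[pair[1]]])
      n <- ceiling(fraction * length(vox))
      list(voxels = sort(sample(vox, n)), condition = pair[2], psc = psc)
    })
  })
}

#' Plant distributed discriminative patterns for SVM decoding
#'
#' Two disjoint voxel sets inside the feature mask, one responding to
#' tenderness and one to anguish, so the two conditions are linearly
#' separable in PSC feature space with controllable margin.
#'
#' @param masks list from [default_masks()].
#' @param psc fractional PSC amplitude of each pattern.
#' @param n_voxels voxels per pattern.
#' @param seed sampling seed.
#' @return List of planted-effect descriptors for [phantom_config()].
#' @export
plant_svm_effects <- function(masks, psc = 0.02, n_voxels = 60L, seed = 1L) {
  withr::with_seed(seed, {
    vox <- which(masks$feature_mask)
    pick <- sample(vox, 2 * n_voxels)
    list(
      list(voxels = sort(pick[seq_len(n_voxels)]),
           condition = "tenderness", psc = psc),
      list(voxels = sort(pick[n_voxels + seq_len(n_voxels)]),
           condition = "anguish", psc = psc)
    )
  })
}

#' Seeded random components of one run (noise, motion)
#'
#' A single RNG block shared by open-loop generation and the closed-loop
#' simulator, so both draw identical noise for identical (config, run).
#' @noRd
.run_randoms <- function(config, n_time, run_index) {
  n_vox <- prod(config$grid_dims)
  run_seed <- (config$seed + 1000003L * run_index) %% .Machine$integer.max
  withr::with_seed(run_seed, {
    innov <- matrix(stats::rnorm(n_time * n_vox, sd = config$noise_sd),
                    nrow = n_time, ncol = n_vox)
    noise <- if (config$ar1_coef > 0) {
      apply(innov, 2, function(x)
        as.numeric(stats::filter(x, config$ar1_coef, method = "recursive")))
    } else innov
    motion <- apply(matrix(stats::rnorm(n_time * 6), n_time, 6), 2, cumsum) *
      rep(config$motion_sd, each = 3)[col(matrix(0, n_time, 6))]
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    list(noise = noise, motion = motion)
  })
}

#' Deterministic low-frequency drift over a run (length n_time)
#' @noRd
.run_drift <- function(config, n_time, tr_s) {
  t_s <- (seq_len(n_time) - 1) * tr_s
  span <- max(t_s) - min(t_s)
  config$drift_amplitude *
    (2 * (t_s - mean(t_s)) / max(span, 1) + sin(2 * pi * t_s / 200))
}

#' Task-signal PSC matrix for one run: time x voxel, restricted to voxels
#' with planted effects (other voxels are zero and omitted).
#' `multipliers` is a named list (per condition) of per-block amplitude
#' scale factors; closed-loop simulation varies these.
#' @noRd
.run_signal_psc <- function(schedule, config, multipliers = NULL) {
  n_time <- schedule$n_dummy + schedule$n_volumes
  regs <- list()
  for (cond in .EMOTIONS) {
    mult <- if (is.null(multipliers)) 1 else multipliers[[cond]]
    regs[[cond]] <- condition_regressor(schedule, cond, amplitudes = mult)
  }
  vox <- sort(unique(unlist(lapply(config$planted_effects, `[[`, "voxels"))))
  psc <- matrix(0, nrow = n_time, ncol = length(vox))
  for (eff in config$planted_effects) {
    j <- match(eff$voxels, vox)
    psc[, j] <- psc[, j] + eff$psc * regs[[eff$condition]]
  }
  list(voxels = vox, psc = psc)
}

#' Assemble one run's data matrix (time x voxel) from its components.
#' @noRd
.assemble_run <- function(schedule, config, randoms, multipliers = NULL) {
  n_time <- schedule$n_dummy + schedule$n_volumes
  drift <- .run_drift(config, n_time, schedule$tr_s)
  data <- config$baseline + drift + randoms$noise
  sig <- .run_signal_psc(schedule, config, multipliers)
  if (length(sig$voxels)) {
    data[, sig$voxels] <- data[, sig$voxels] + config$baseline * sig$psc
  }
  data
}

.matrix_to_4d <- function(data, grid_dims) {
  aperm(array(t(data), dim = c(grid_dims, nrow(data))), c(1, 2, 3, 4))
}

#' Generate a synthetic neurofeedback session
#'
#' Every voxel's series follows
#' `baseline * (1 + sum_c psc_c(v) * (boxcar_c convolved with HRF)(t)) +
#' drift(t) + AR(1) noise`; dummy volumes carry baseline, drift and noise
#' but no task signal. Identical `(design, config)` give bit-identical
#' output, and the ground truth is retained on the returned object.
#'
#' @param design an `nfb_design` from [build_session_design()].
#' @param config a [phantom_config()].
#' @param masks named list of logical mask arrays (defaults to
#'   [default_masks()] on the config grid).
#' @return An object of class `nfb_session`: list with `volumes` (list of
#'   4D arrays `x,y,z,t`, one per run, `t = n_dummy + n_volumes`), `design`,
#'   `masks`, `motion` (list of per-run T x 6 matrices) and `ground_truth`
#'   (the config).
#' @export
generate_session <- function(design, config, masks = NULL) {
  stopifnot(inherits(design, "nfb_design"), inherits(config, "phantom_config"))
  if (is.null(masks)) masks <- default_masks(config$grid_dims)
  for (m in masks) stopifnot(all(dim(m) == config$grid_dims))
  volumes <- list()
  motion <- list()
  for (r in 1:4) {
    sched <- design$runs[[r]]
    n_time <- sched$n_dummy + sched$n_volumes
    randoms <- .run_randoms(config, n_time, r)
    data <- .assemble_run(sched, config, randoms)
    volumes[[r]] <- .matrix_to_4d(data, config$grid_dims)
    motion[[r]] <- randoms$motion
  }
  structure(list(volumes = volumes, design = design, masks = masks,
                 motion = motion, ground_truth = config),
            class = "nfb_session")
}

#' Noise-free expected PSC at a voxel and volume
#'
#' The ground-truth fractional signal change of the convolution model,
#' used as the oracle when validating feedback and GLM recovery.
#'
#' @param session an `nfb_session` (or pass `design`/`config` explicitly).
#' @param voxel linear voxel index, or a length-3 `(x, y, z)` index.
#' @param volume 1-based volume index over the run's full timeline
#'   (dummies included).
#' @param run run index 1--4.
#' @param condition optionally restrict to one condition's contribution.
#' @return Fractional PSC (0 for voxels with no planted effect).
#' @export
expected_psc <- function(session, voxel, volume, run = 1, condition = NULL) {
  stopifnot(inherits(session, "nfb_session"))
  config <- session$ground_truth
  if (length(voxel) == 3) {
    voxel <- voxel[1] + (voxel[2] - 1) * config$grid_dims[1] +
      (voxel[3] - 1) * prod(config$grid_dims[1:2])
  }
  stopifnot(voxel >= 1, voxel <= prod(config$grid_dims))
  sched <- session$design$runs[[run]]
  total <- 0
  for (eff in config$planted_effects) {
    if (!is.null(condition) && eff$condition != condition) next
    if (!(voxel %in% eff$voxels)) next
    reg <- condition_regressor(sched, eff$condition)
    total <- total + eff$psc * reg[volume]
  }
  total
}

#' @export
print.nfb_session <- function(x, ...) {
  d <- x$ground_truth$grid_dims
  cat(sprintf("<nfb_session> %s, grid %dx%dx%d, %d runs x %d volumes (+%d dummy), %d planted effect(s)\n",
              x$design$method, d[1], d[2], d[3], length(x$volumes),
              x$design$runs[[1]]$n_volumes, x$design$n_dummy,
              length(x$ground_truth$planted_effects)))
  invisible(x)
}
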