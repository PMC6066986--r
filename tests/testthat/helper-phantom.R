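# Shared fixture builders. Everything is generated in code; the small grid
# keeps per-test sessions under a second while preserving the block design.

# stationary-SD-1x-effect noise level: planted amplitude (baseline * psc)
# equals the stationary SD of the AR(1) noise (voxelwise CNR ~ 1)
cnr1_noise_sd <- function(baseline = 1000, psc = 0.02, ar1 = 0.3) {
  baseline * psc * sqrt(1 - ar1^2)
}

# masks on a small grid: two disjoint "ROI" boxes plus a feature mask that
# excludes a designated sensorimotor slab
small_masks <- function(grid = c(8, 8, 4)) {
  empty <- array(FALSE, dim = grid)
  septo <- empty
  septo[2:5, 2:5, 1:3] <- TRUE
  amyg <- empty
  amyg[6:8, 2:4, 1:2] <- TRUE
  feat <- array(TRUE, dim = grid)
  feat[, grid[2], ] <- FALSE
  list(septo_hypothalamic = septo, right_amygdala = amyg,
       feature_mask = feat)
}

small_roi_session <- function(seed = 1, psc = 0.02, noise_sd = 0,
                              ar1 = 0.3, drift = 0,
                              start_emotion = "tenderness") {
  grid <- c(8, 8, 4)
  masks <- small_masks(grid)
  eff <- list(
    list(voxels = which(masks$septo_hypothalamic)[1:10],
         condition = "tenderness", psc = psc),
    list(voxels = which(masks$right_amygdala)[1:6],
         condition = "anguish", psc = psc))
  cfg <- phantom_config(grid_dims = grid, planted_effects = eff,
                        noise_sd = noise_sd, ar1_coef = ar1,
                        drift_amplitude = drift, seed = seed)
  design <- build_session_design("ROI", start_emotion)
  generate_session(design, cfg, masks = masks)
}

small_svm_session <- function(seed = 1, psc = 0.02, noise_sd = 0,
                              ar1 = 0.3, drift = 0) {
  grid <- c(8, 8, 4)
  masks <- small_masks(grid)
  feat <- which(masks$feature_mask)
  eff <- list(
    list(voxels = feat[1:12], condition = "tenderness", psc = psc),
    list(voxels = feat[31:42], condition = "anguish", psc = psc))
  cfg <- phantom_config(grid_dims = grid, planted_effects = eff,
                        noise_sd = noise_sd, ar1_coef = ar1,
                        drift_amplitude = drift, seed = seed)
  design <- build_session_design("SVM", "tenderness")
  generate_session(design, cfg, masks = masks)
}

# independent re-derivation of per-volume labels from the block table,
# sampling a per-second condition timeline (oracle for label_volumes)
oracle_labels <- function(schedule, shift = 0) {
  timeline <- rep(schedule$blocks$condition,
                  times = schedule$blocks$duration_s)
  vapply(seq_len(schedule$n_volumes), function(i) {
    t <- (i - 1 - shift) * schedule$tr_s
    if (t < 0) "discard" else timeline[floor(t) + 1]
  }, character(1))
}

# one-shot recomputation of ROI feedback for every logged sample, straight
# from the stored arrays (oracle for the streaming engine)
oracle_roi_feedback <- function(session, log, shift = 2) {
  models <- log$models
  out <- numeric(nrow(log$samples))
  for (j in seq_len(nrow(log$samples))) {
    smp <- log$samples[j, ]
    sched <- session$design$runs[[smp$run]]
    labels <- label_volumes(sched, shift)
    run <- session$volumes[[smp$run]]
    segs <- rle(labels)
    ends <- cumsum(segs$lengths)
    starts <- ends - segs$lengths + 1
    seg_i <- which(smp$volume >= starts & smp$volume <= ends)
    prev_neutral <- max(which(segs$values == "neutral" & ends < starts[seg_i]))
    base_vols <- starts[prev_neutral]:ends[prev_neutral]
    sel <- models$roi[[smp$condition]]$selected_voxels
    roi_k <- vapply(base_vols, function(i)
      mean(run[, , , sched$n_dummy + i][sel]), numeric(1))
    k <- seq_along(roi_k)
    w <- 1 / (1 + exp(-(k - length(k) / 2)))
    m <- sum(w * roi_k) / sum(w)
    curr <- mean(run[, , , sched$n_dummy + smp$volume][sel])
    out[j] <- (curr - m) / m
  }
  out
}
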