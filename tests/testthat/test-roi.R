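test_that("activation statistic recovers planted amplitudes noise-free", {
  sess <- small_roi_session(psc = 0.02, noise_sd = 0)
  sched <- sess$design$runs[[1]]
  labels <- label_volumes(sched, 2)
  roi <- roi_definition("septo_hypothalamic", sess$masks$septo_hypothalamic,
                        "tenderness")
  stat <- compute_activation_stat(sess$volumes[[1]], labels, roi)
  planted <- sess$ground_truth$planted_effects[[1]]$voxels
  others <- setdiff(which(roi$mask), planted)
  expect_equal(unname(stat[planted]), rep(0.02, length(planted)),
               tolerance = 0.15)
  expect_true(all(abs(stat[others]) < 0.002))
  expect_true(all(is.na(stat[!roi$mask])))
})

test_that("activation statistic is zero on constant data and averages per-block stats", {
  sess <- small_roi_session(psc = 0.02, noise_sd = 5)
  sched <- sess$design$runs[[1]]
  labels <- label_volumes(sched, 2)
  roi <- roi_definition("septo_hypothalamic", sess$masks$septo_hypothalamic,
                        "tenderness")
  const <- array(100, dim = dim(sess$volumes[[1]]))
  stat0 <- compute_activation_stat(const, labels, roi)
  expect_true(all(stat0[roi$mask] == 0))

  # brute-force per-block recomputation oracle
  stat <- compute_activation_stat(sess$volumes[[1]], labels, roi)
  run <- matrix(sess$volumes[[1]], ncol = dim(sess$volumes[[1]])[4])
  run <- run[, sched$n_dummy + seq_along(labels)]
  segs <- rle(labels)
  ends <- cumsum(segs$lengths); starts <- ends - segs$lengths + 1
  v <- which(roi$mask)[7]
  per_block <- c()
  for (s in which(segs$values == "tenderness")) {
    em <- mean(run[v, starts[s]:ends[s]])
    bm <- mean(run[v, starts[s - 1]:ends[s - 1]])
    per_block <- c(per_block, (em - bm) / bm)
  }
  expect_length(per_block, 4)
  expect_equal(stat[v], mean(per_block), tolerance = 1e-12)
})

test_that("voxels with a zero neutral baseline are excluded with a warning", {
  sess <- small_roi_session(psc = 0.02, noise_sd = 0)
  sched <- sess$design$runs[[1]]
  labels <- label_volumes(sched, 2)
  roi <- roi_definition("septo_hypothalamic", sess$masks$septo_hypothalamic,
                        "tenderness")
  vols <- sess$volumes[[1]]
  dead <- which(roi$mask)[1]
  idx <- arrayInd(dead, dim(roi$mask))
  vols[idx[1], idx[2], idx[3], ] <- 0
  expect_warning(stat <- compute_activation_stat(vols, labels, roi),
                 "zero neutral baseline")
  expect_true(is.na(stat[dead]))
})

test_that("top-voxel selection matches an exhaustive sort and honors ties", {
  mask <- array(TRUE, dim = c(10, 10, 10))
  withr::with_seed(3, stat <- array(rnorm(1000), dim = dim(mask)))
  sel <- select_top_voxels(stat, mask, 0.10)
  expect_length(sel, 100)
  expect_equal(sel, sort(order(-as.numeric(stat))[1:100]))

  # all-equal statistics: lowest linear indices win
  flat <- array(1, dim = dim(mask))
  expect_equal(select_top_voxels(flat, mask, 0.10), 1:100)

  # fraction contract: ceiling(fraction * |mask|), subset of the mask
  mask2 <- array(FALSE, dim = c(10, 10, 10)); mask2[1:7, 1, 1] <- TRUE
  sel2 <- select_top_voxels(stat, mask2, 0.5)
  expect_length(sel2, ceiling(0.5 * 7))
  expect_true(all(sel2 %in% which(mask2)))
  expect_error(select_top_voxels(stat, array(FALSE, dim(mask))), "empty")
  expect_error(select_top_voxels(stat, mask, 0))
})

test_that("baseline buffer counts volumes and rejects non-neutral updates", {
  sess <- small_roi_session(noise_sd = 0)
  sched <- sess$design$runs[[1]]
  labels <- label_volumes(sched, 0)
  models <- train_session_models(sess, engine_config("ROI"))
  model <- models$roi$tenderness
  buf <- baseline_buffer()
  expect_error(weighted_baseline_mean(buf), "empty")
  neutral_idx <- which(labels == "neutral")[1:15]   # first 30-s block
  for (i in neutral_idx) {
    buf <- update_baseline(buf, sess$volumes[[1]][, , , sched$n_dummy + i],
                           model)
  }
  expect_length(buf$roi_means, 15)
  expect_error(update_baseline(buf, sess$volumes[[1]][, , , 40], model,
                               condition = "tenderness"),
               "outside a neutral block")
  vol <- array(100, dim = dim(sess$masks$septo_hypothalamic))
  buf2 <- update_baseline(baseline_buffer(), vol, model)
  expect_equal(buf2$roi_means, 100)
})

test_that("weighted baseline mean equals the brute-force weighted mean", {
  buf <- baseline_buffer()
  buf$roi_means <- c(100, 102, 104)
  w <- 1 / (1 + exp(-(1:3 - 3 / 2)))            # independent hand computation
  expect_equal(weighted_baseline_mean(buf), sum(w * c(100, 102, 104)) / sum(w),
               tolerance = 1e-12)
  buf$roi_means <- 107.3
  expect_equal(weighted_baseline_mean(buf), 107.3)   # B = 1: the value itself
})

test_that("PSC feedback is exact, monotone and scale invariant", {
  buf <- baseline_buffer()
  buf$roi_means <- rep(100, 10)
  expect_equal(compute_psc_feedback(100, buf), 0)
  expect_equal(compute_psc_feedback(101, buf), 0.01)
  # strictly increasing in the current ROI mean
  vals <- vapply(seq(99, 103, by = 0.5), compute_psc_feedback, numeric(1),
                 buffer = buf)
  expect_true(all(diff(vals) > 0))
  # multiplying all intensities by c > 0 leaves feedback unchanged
  buf_scaled <- baseline_buffer()
  buf_scaled$roi_means <- buf$roi_means * 7.5
  expect_equal(compute_psc_feedback(101 * 7.5, buf_scaled),
               compute_psc_feedback(101, buf), tolerance = 1e-12)
  empty <- baseline_buffer()
  expect_error(compute_psc_feedback(100, empty))
  zero <- baseline_buffer(); zero$roi_means <- rep(0, 5)
  expect_error(compute_psc_feedback(1, zero), "zero")
})

test_that("streaming feedback equals one-shot recomputation at every volume", {
  sess <- small_roi_session(psc = 0.02, noise_sd = 10)
  cfg <- engine_config("ROI")
  log <- run_session(sess, cfg)
  expect_equal(log$samples$raw_feedback, oracle_roi_feedback(sess, log),
               tolerance = 1e-12)
})

test_that("selection recovers most planted voxels at CNR ~ 1", {
  masks <- small_masks()
  septo <- which(masks$septo_hypothalamic)
  rec <- vapply(1:5, function(s) {
    withr::with_seed(s, planted <- sort(sample(septo, 5)))
    cfg <- phantom_config(grid_dims = c(8, 8, 4), planted_effects = list(
      list(voxels = planted, condition = "tenderness", psc = 0.02)),
      noise_sd = cnr1_noise_sd(), ar1_coef = 0.3, seed = s)
    sess <- generate_session(build_session_design("ROI", "tenderness"), cfg,
                             masks = masks)
    m <- train_session_models(sess, engine_config("ROI"))
    mean(planted %in% m$roi$tenderness$selected_voxels)
  }, numeric(1))
  expect_gte(mean(rec), 0.8)
})
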