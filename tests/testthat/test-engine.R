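test_that("saturation mapping clips, scales linearly and quantizes", {
  expect_equal(map_feedback_to_saturation(-0.5, 0.02), 0)
  expect_equal(map_feedback_to_saturation(0, 0.02), 0)
  expect_equal(map_feedback_to_saturation(0.05, 0.02), 1)
  expect_equal(map_feedback_to_saturation(0.01, 0.02), 0.5)
  expect_equal(map_feedback_to_saturation(c(0.005, 0.015), 0.02),
               c(0.25, 0.75))
  # quantization to n equal levels stays in [0,1] and nondecreasing
  raw <- seq(-0.01, 0.03, by = 0.001)
  s <- map_feedback_to_saturation(raw, 0.02, n_levels = 5)
  expect_true(all(s %in% seq(0, 1, by = 0.25)))
  expect_true(all(diff(s) >= 0))
  expect_error(map_feedback_to_saturation(0.01, 0))
  expect_error(engine_config("ROI", n_levels = 1))
})

test_that("feedback cadence: one sample per TR in emotion blocks, none elsewhere", {
  sess <- small_roi_session(noise_sd = 5)
  cfg <- engine_config("ROI", shift_volumes = 0)
  log <- run_session(sess, cfg)
  s <- log$samples
  # 92 + 92 emotion volumes per feedback run at shift 0
  expect_equal(as.list(table(s$run)), list(`2` = 184L, `3` = 184L,
                                           `4` = 184L))
  for (r in 2:4) {
    expect_equal(sum(s$condition == "tenderness" & s$run == r), 92)
    expect_equal(sum(s$condition == "anguish" & s$run == r), 92)
  }
  # never during neutral blocks and never during dummies
  expect_false(any(s$condition == "neutral"))
  expect_true(all(s$volume >= 1))          # volume index starts after dummies
  # inter-sample interval within a block is exactly one TR (2 s)
  by_block <- split(s$time_s, list(s$run, s$block), drop = TRUE)
  for (ts in by_block) if (length(ts) > 1) expect_equal(diff(ts),
                                                        rep(2, length(ts) - 1))
  # hue follows the block condition; neutral hue never appears
  expect_equal(unname(c(tenderness = "orange",
                        anguish = "purple")[s$condition]), s$hue_target)
  expect_true(all(s$saturation >= 0 & s$saturation <= 1))
})

test_that("ROI and SVM logs share one schema and replay deterministically", {
  roi_log <- run_session(small_roi_session(noise_sd = 5),
                         engine_config("ROI"))
  svm_log <- run_session(small_svm_session(noise_sd = 5),
                         engine_config("SVM"))
  expect_identical(names(roi_log$samples), names(svm_log$samples))
  # replaying the same stored session yields an identical log
  sess <- small_roi_session(noise_sd = 5)
  expect_identical(run_session(sess, engine_config("ROI"))$samples,
                   run_session(sess, engine_config("ROI"))$samples)
})

test_that("method/model mismatches and grid mismatches are rejected", {
  sess <- small_roi_session(noise_sd = 0)
  models <- train_session_models(sess, engine_config("ROI"))
  expect_error(run_session(sess, engine_config("SVM"), models), "method")
  bad <- sess
  bad$masks$septo_hypothalamic <- array(TRUE, dim = c(4, 4, 2))
  expect_error(run_session(bad, engine_config("ROI")), "grid")
})

test_that("mean saturation rises with planted effect amplitude", {
  mean_sat <- function(psc, seed) {
    sess <- small_roi_session(psc = psc, noise_sd = cnr1_noise_sd(),
                              seed = seed)
    mean(run_session(sess, engine_config("ROI"))$samples$saturation)
  }
  sats <- sapply(1:3, function(s) sapply(c(0, 0.01, 0.02, 0.04), mean_sat,
                                         seed = s))
  expect_true(all(diff(rowMeans(sats)) > 0))
})

test_that("closed loop with zero gain reproduces the open loop bit-exactly", {
  masks <- small_masks()
  eff <- list(list(voxels = which(masks$septo_hypothalamic)[1:10],
                   condition = "tenderness", psc = 0.02),
              list(voxels = which(masks$right_amygdala)[1:6],
                   condition = "anguish", psc = 0.02))
  cfg <- phantom_config(grid_dims = c(8, 8, 4), planted_effects = eff,
                        noise_sd = 8, seed = 4)
  design <- build_session_design("ROI", "tenderness")
  ec <- engine_config("ROI")
  cl <- simulate_closed_loop(design, cfg, 0, ec, masks = masks)
  open_sess <- generate_session(design, cfg, masks = masks)
  open_log <- run_session(open_sess, ec)
  expect_identical(cl$log$samples, open_log$samples)
  expect_identical(cl$session$volumes, open_sess$volumes)
  expect_identical(cl$session$motion, open_sess$motion)
})

test_that("closed-loop saturation is nondecreasing over same-emotion blocks, noise-free", {
  masks <- small_masks()
  eff <- list(list(voxels = which(masks$septo_hypothalamic)[1:10],
                   condition = "tenderness", psc = 0.01),
              list(voxels = which(masks$right_amygdala)[1:6],
                   condition = "anguish", psc = 0.01))
  cfg <- phantom_config(grid_dims = c(8, 8, 4), planted_effects = eff,
                        noise_sd = 0, drift_amplitude = 0, seed = 4)
  for (method in c("ROI", "SVM")) {
    design <- build_session_design(method, "tenderness")
    phant <- if (method == "SVM") {
      feat <- which(masks$feature_mask)
      phantom_config(grid_dims = c(8, 8, 4), planted_effects = list(
        list(voxels = feat[1:12], condition = "tenderness", psc = 0.01),
        list(voxels = feat[31:42], condition = "anguish", psc = 0.01)),
        noise_sd = 0, drift_amplitude = 0, seed = 4)
    } else cfg
    ec <- engine_config(method, shift_volumes = 0)
    cl <- simulate_closed_loop(design, phant, 2, ec, masks = masks)
    s <- cl$log$samples
    expect_true(all(s$saturation <= 1))
    bm <- stats::aggregate(saturation ~ run + condition + block, s, mean)
    for (r in 2:4) for (cond in c("tenderness", "anguish")) {
      sub <- bm[bm$run == r & bm$condition == cond, ]
      v <- sub$saturation[order(sub$block)]
      expect_true(all(diff(v) >= -1e-12))
    }
  }
})

test_that("feedback logs round-trip through TSV", {
  log <- run_session(small_roi_session(noise_sd = 5), engine_config("ROI"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feedback_log(log, path)
  back <- read_feedback_log(path)
  expect_equal(back$raw_feedback, log$samples$raw_feedback)
  expect_equal(back$saturation, log$samples$saturation)
  expect_identical(back$condition, log$samples$condition)
  expect_identical(back$hue_target, log$samples$hue_target)
})
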