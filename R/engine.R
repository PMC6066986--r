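#' Real-time feedback engine
#'
#' Streams volumes one per TR, discards dummies, updates baselines during
#' neutral blocks, dispatches emotion-block volumes to the active feedback
#' method (ROI percent signal change or SVM projection), maps feedback to a
#' color-saturation fraction for the virtual-environment interface, and logs
#' one sample per emotion-block volume. The log schema is identical for
#' both methods: the visual interface is method-blind.
#'
#' @name engine
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.HUE <- c(tenderness = "orange", anguish = "purple", neutral = "baseline")

#' Engine configuration
#'
#' @param method `"ROI"` or `"SVM"`.
#' @param tr_s repetition time (s); one feedback update per TR.
#' @param n_dummy leading dummy volumes discarded each run.
#' @param shift_volumes hemodynamic label shift (volumes).
#' @param f_max feedback value mapped to full saturation. `NULL` uses the
#'   method default: 0.02 (2% PSC) for ROI; for SVM, twice the median
#'   absolute training projection, fixed after initial training.
#' @param n_levels optional saturation discretization (>= 2 equal steps);
#'   `NULL` keeps the mapping continuous.
#' @param svm_C soft-margin cost for the SVM method.
#' @return Object of class `engine_config`.
#' @export
engine_config <- function(method = c("ROI", "SVM"), tr_s = 2, n_dummy = 5L,
                          shift_volumes = 2L, f_max = NULL, n_levels = NULL,
                          svm_C = 1) {
  method <- match.arg(method)
  if (!is.null(f_max)) stopifnot(f_max > 0)
  if (!is.null(n_levels)) stopifnot(n_levels >= 2)
  structure(list(method = method, tr_s = tr_s, n_dummy = as.integer(n_dummy),
                 shift_volumes = as.integer(shift_volumes), f_max = f_max,
                 n_levels = n_levels, svm_C = svm_C),
            class = "engine_config")
}

#' Map a raw feedback value to color saturation
#'
#' `s = clip(raw / f_max, 0, 1)`, optionally quantized to `n_levels` equal
#' steps; nondecreasing in `raw`.
#'
#' @param raw raw feedback value (PSC or oriented SVM projection).
#' @param f_max value mapping to full saturation (> 0).
#' @param n_levels optional number of discrete levels (including 0 and 1).
#' @return Saturation fraction in `[0, 1]` (vectorized).
#' @export
map_feedback_to_saturation <- function(raw, f_max, n_levels = NULL) {
  stopifnot(f_max > 0)
  s <- pmin(pmax(raw / f_max, 0), 1)
  if (!is.null(n_levels)) {
    stopifnot(n_levels >= 2)
    s <- round(s * (n_levels - 1)) / (n_levels - 1)
  }
  s
}

#' Per-run streaming state machine shared by the open-loop engine and the
#' closed-loop simulator. Returns an environment whose `step(vol3d, i)`
#' consumes non-dummy volume i; samples and (for SVM) labeled examples
#' accumulate inside.
#' @noRd
.new_streamer <- function(schedule, config, models, f_max) {
  e <- new.env(parent = emptyenv())
  e$labels <- label_volumes(schedule, config$shift_volumes)
  e$block_of <- .block_of_volume(schedule, config$shift_volumes)
  e$samples <- list()
  e$svm_x <- list()
  e$svm_lab <- character(0)
  e$svm_vol <- integer(0)
  e$prev_lab <- "discard"
  e$bufs <- list(tenderness = baseline_buffer(), anguish = baseline_buffer())
  e$frozen_m <- list(tenderness = NULL, anguish = NULL)
  e$neutral_rows <- list()
  e$frozen_bvec <- NULL
  e$vox_feat <- if (config$method == "SVM") which(models$feature_mask) else NULL

  e$step <- function(vol3d, i) {
    lab <- e$labels[i]
    if (lab == "discard") {
      e$prev_lab <- lab
      return(invisible(NULL))
    }
    if (lab == "neutral") {
      if (e$prev_lab != "neutral") {      # neutral-block onset: reset buffers
        if (config$method == "ROI") {
          e$bufs <- list(tenderness = baseline_buffer(),
                         anguish = baseline_buffer())
        } else {
          e$neutral_rows <- list()
        }
      }
      if (config$method == "ROI") {
        for (emo in .EMOTIONS) {
          e$bufs[[emo]] <- update_baseline(e$bufs[[emo]], vol3d,
                                           models$roi[[emo]], "neutral")
        }
      } else {
        e$neutral_rows[[length(e$neutral_rows) + 1]] <- vol3d[e$vox_feat]
      }
    } else {                              # emotion-block volume
      if (e$prev_lab == "neutral") {      # freeze previous-neutral baseline
        if (config$method == "ROI") {
          e$frozen_m <- lapply(e$bufs, weighted_baseline_mean)
        } else {
          e$frozen_bvec <- voxel_baseline_mean(do.call(rbind, e$neutral_rows))
        }
      }
      if (config$method == "ROI") {
        m <- e$frozen_m[[lab]]
        if (is.null(m)) stop("no baseline established before emotion block")
        raw <- (mean(vol3d[models$roi[[lab]]$selected_voxels]) - m) / m
      } else {
        x <- extract_features(vol3d, models$feature_mask, e$frozen_bvec)
        e$svm_x[[length(e$svm_x) + 1]] <- x
        e$svm_lab <- c(e$svm_lab, lab)
        e$svm_vol <- c(e$svm_vol, i)
        raw <- if (is.null(models$svm)) NA_real_ else
          decode_feedback(models$svm, x, lab)
      }
      if (!is.na(raw)) {
        e$samples[[length(e$samples) + 1]] <- data.frame(
          run = schedule$run_index, volume = i,
          time_s = (i - 1) * schedule$tr_s, block = e$block_of[i],
          condition = lab, method = config$method, raw_feedback = raw,
          saturation = map_feedback_to_saturation(raw, f_max,
                                                  config$n_levels),
          hue_target = unname(.HUE[lab]), stringsAsFactors = FALSE)
      }
    }
    e$prev_lab <- lab
    invisible(NULL)
  }
  e
}

.streamer_samples <- function(e) {
  if (!length(e$samples)) return(.empty_samples())
  do.call(rbind, e$samples)
}

.empty_samples <- function() {
  data.frame(run = integer(0), volume = integer(0), time_s = numeric(0),
             block = integer(0), condition = character(0),
             method = character(0), raw_feedback = numeric(0),
             saturation = numeric(0), hue_target = character(0),
             stringsAsFactors = FALSE)
}

#' Train the feedback models from a session's training run
#'
#' ROI method: fits one [train_roi_model()] per target ROI
#' (septo-hypothalamic / tenderness, right amygdala / anguish) on run 1.
#' SVM method: replays run 1 through the streaming feature extractor and
#' fits the initial linear SVM on its labeled emotion volumes.
#'
#' @param session an `nfb_session` (run 1 is the training run).
#' @param config an [engine_config()].
#' @return A models list: `method`, plus `roi` (named list of `roi_model`)
#'   or `svm` (`svm_model`) + `feature_mask`.
#' @export
train_session_models <- function(session, config) {
  stopifnot(inherits(session, "nfb_session"), inherits(config, "engine_config"))
  sched <- session$design$runs[[1]]
  labels <- label_volumes(sched, config$shift_volumes)
  run1 <- session$volumes[[1]]
  if (config$method == "ROI") {
    rois <- list(
      tenderness = roi_definition("septo_hypothalamic",
                                  session$masks$septo_hypothalamic,
                                  "tenderness"),
      anguish = roi_definition("right_amygdala",
                               session$masks$right_amygdala, "anguish"))
    list(method = "ROI",
         roi = lapply(rois, function(r)
           train_roi_model(run1, labels, r, n_dummy = config$n_dummy)))
  } else {
    models0 <- list(method = "SVM", svm = NULL,
                    feature_mask = session$masks$feature_mask)
    st <- .new_streamer(sched, config, models0, f_max = 1)
    for (i in seq_len(sched$n_volumes)) {
      st$step(run1[, , , config$n_dummy + i], i)
    }
    store <- add_training_examples(training_store(), do.call(rbind, st$svm_x),
                                   st$svm_lab, run_index = 1L,
                                   volume_index = st$svm_vol)
    models0$svm <- svm_train(store, C = config$svm_C)
    models0
  }
}

.resolve_f_max <- function(config, models) {
  config$f_max %||%
    if (config$method == "ROI") 0.02 else models$svm$f_max_suggest
}

#' Run the engine over a stored session
#'
#' Replays runs 2--4 volume by volume: dummies are discarded, neutral blocks
#' update baselines and keep the interface at baseline hue (saturation 0,
#' no sample logged), and every emotion-block volume yields one feedback
#' sample. With the SVM method the model is cumulatively retrained on each
#' finished run's labeled volumes before the next run. Deterministic given
#' inputs.
#'
#' @param session an `nfb_session`.
#' @param config an [engine_config()]; its method must match the models.
#' @param models from [train_session_models()]; `NULL` trains them from the
#'   session's run 1.
#' @return Object of class `nfb_feedback_log`: list with `samples` (one row
#'   per emotion-block volume of runs 2--4), `f_max`, `config`, and the
#'   final `models`.
#' @export
run_session <- function(session, config, models = NULL) {
  stopifnot(inherits(session, "nfb_session"), inherits(config, "engine_config"))
  grid <- dim(session$volumes[[1]])[1:3]
  for (m in session$masks) {
    if (!all(dim(m) == grid)) stop("mask grid does not match volume grid")
  }
  if (is.null(models)) models <- train_session_models(session, config)
  if (models$method != config$method) {
    stop("models were trained for method ", models$method,
         " but config requests ", config$method)
  }
  f_max <- .resolve_f_max(config, models)
  all_samples <- list()
  for (r in 2:4) {
    sched <- session$design$runs[[r]]
    st <- .new_streamer(sched, config, models, f_max)
    run <- session$volumes[[r]]
    for (i in seq_len(sched$n_volumes)) {
      st$step(run[, , , config$n_dummy + i], i)
    }
    all_samples[[r]] <- .streamer_samples(st)
    if (config$method == "SVM") {
      models$svm <- retrain_cumulative(models$svm, do.call(rbind, st$svm_x),
                                       st$svm_lab, run_index = r)
    }
  }
  structure(list(samples = do.call(rbind, all_samples), f_max = f_max,
                 config = config, models = models),
            class = "nfb_feedback_log")
}

#' Closed-loop simulation with a synthetic responder
#'
#' Generates the session block by block while the engine runs, so the
#' "participant" can respond to the feedback: within each feedback run, an
#' emotion block's planted amplitude is scaled by
#' `1 + responder_gain * (mean saturation of the previous block of the same
#' emotion in that run)`; the first block of each emotion uses the base
#' amplitude, and `responder_gain = 0` reproduces the open-loop session and
#' log bit for bit. Run 1 is generated open loop and used for training.
#'
#' @param design an `nfb_design`.
#' @param phantom a [phantom_config()] giving the base planted amplitudes.
#' @param responder_gain nonnegative feedback gain of the simulated
#'   responder.
#' @param config an [engine_config()].
#' @param masks mask list; defaults to [default_masks()] on the phantom
#'   grid.
#' @return List with `session` (the generated `nfb_session`) and `log`
#'   (the `nfb_feedback_log`).
#' @export
simulate_closed_loop <- function(design, phantom, responder_gain, config,
                                 masks = NULL) {
  stopifnot(inherits(design, "nfb_design"), inherits(phantom, "phantom_config"),
            responder_gain >= 0, inherits(config, "engine_config"))
  if (is.null(masks)) masks <- default_masks(phantom$grid_dims)
  volumes <- vector("list", 4)
  motion <- vector("list", 4)

  sched1 <- design$runs[[1]]
  r1 <- .run_randoms(phantom, sched1$n_dummy + sched1$n_volumes, 1)
  data1 <- .assemble_run(sched1, phantom, r1)
  volumes[[1]] <- .matrix_to_4d(data1, phantom$grid_dims)
  motion[[1]] <- r1$motion
  session <- structure(list(volumes = volumes, design = design, masks = masks,
                            motion = motion, ground_truth = phantom),
                       class = "nfb_session")
  models <- train_session_models(session, config)
  f_max <- .resolve_f_max(config, models)

  all_samples <- list()
  for (r in 2:4) {
    sched <- design$runs[[r]]
    n_time <- sched$n_dummy + sched$n_volumes
    randoms <- .run_randoms(phantom, n_time, r)
    mult <- lapply(.EMOTIONS, function(emo)
      rep(1, sum(sched$blocks$condition == emo)))
    names(mult) <- .EMOTIONS
    st <- .new_streamer(sched, config, models, f_max)
    data <- matrix(NA_real_, n_time, prod(phantom$grid_dims))
    next_i <- 1L

    for (b in seq_len(nrow(sched$blocks))) {
      cond <- sched$blocks$condition[b]
      if (cond %in% .EMOTIONS) {
        j <- sum(sched$blocks$condition[seq_len(b)] == cond)
        if (j > 1) {
          prev_b <- utils::tail(which(sched$blocks$condition[seq_len(b - 1)]
                                      == cond), 1)
          done <- .streamer_samples(st)
          prev_sat <- done$saturation[done$block == prev_b]
          mult[[cond]][j] <- 1 + responder_gain *
            (if (length(prev_sat)) mean(prev_sat) else 0)
        }
      }
      # generate this block's volumes (amplitudes of later blocks cannot
      # influence earlier times: the HRF convolution is strictly causal)
      full <- .assemble_run(sched, phantom, randoms, multipliers = mult)
      v0 <- sched$blocks$onset_s[b] / sched$tr_s + 1
      v1 <- v0 + sched$blocks$duration_s[b] / sched$tr_s - 1
      rows <- if (b == 1) seq_len(sched$n_dummy + v1) else
        sched$n_dummy + (v0:v1)
      data[rows, ] <- full[rows, ]
      while (next_i <= v1) {
        vol3d <- array(data[sched$n_dummy + next_i, ], dim = phantom$grid_dims)
        st$step(vol3d, next_i)
        next_i <- next_i + 1L
      }
    }
    all_samples[[r]] <- .streamer_samples(st)
    if (config$method == "SVM") {
      models$svm <- retrain_cumulative(models$svm, do.call(rbind, st$svm_x),
                                       st$svm_lab, run_index = r)
    }
    session$volumes[[r]] <- .matrix_to_4d(data, phantom$grid_dims)
    session$motion[[r]] <- randoms$motion
  }
  log <- structure(list(samples = do.call(rbind, all_samples), f_max = f_max,
                        config = config, models = models),
                   class = "nfb_feedback_log")
  list(session = session, log = log)
}

#' @export
print.nfb_feedback_log <- function(x, ...) {
  cat(sprintf("<nfb_feedback_log> %s method, %d samples over runs %s, f_max = %g\n",
              x$config$method, nrow(x$samples),
              paste(unique(x$samples$run), collapse = ","), x$f_max))
  invisible(x)
}

#' Write a feedback log as TSV
#'
#' One row per feedback sample; numeric columns at full precision so a
#' round trip through [read_feedback_log()] is lossless.
#'
#' @param log an `nfb_feedback_log` (or its `samples` data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feedback_log <- function(log, path) {
  samples <- if (inherits(log, "nfb_feedback_log")) log$samples else log
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    paste(names(samples), collapse = "\t"),
    do.call(sprintf, c(list("%d\t%d\t%.10g\t%d\t%s\t%s\t%.17g\t%.17g\t%s"),
                       samples))
  ), con, sep = "\n")
  invisible(path)
}

#' Read a feedback log TSV
#' @param path log path.
#' @return Data frame of samples.
#' @export
read_feedback_log <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
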