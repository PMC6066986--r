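#' ROI percent-signal-change feedback
#'
#' The ROI method maps, from the training run, the 10% most active voxels
#' inside an a-priori region of interest (septo-hypothalamic area for
#' tenderness, right amygdala for anguish), then during feedback runs emits
#' per-volume percent signal change of the mean over those voxels relative
#' to a sigmoid-weighted mean of the previous neutral block:
#' `f = (ROI_curr - m) / m` with `m = sum_k sig(k) ROI_k / sum_k sig(k)`,
#' where `ROI_k` is the selected-voxel mean of the k-th baseline volume and
#' `B` the number of volumes in the previous neutral block. The sigmoid
#' down-weights early baseline volumes still contaminated by the previous
#' block's hemodynamic decay.
#'
#' @name roi_feedback
NULL

#' Define a target region of interest
#'
#' @param name region identifier (e.g. `"septo_hypothalamic"`).
#' @param mask logical 3D array, nonempty.
#' @param target_condition the emotion this ROI gives feedback for.
#' @return Object of class `roi_definition`.
#' @export
roi_definition <- function(name, mask,
                           target_condition = c("tenderness", "anguish")) {
  target_condition <- match.arg(target_condition)
  stopifnot(is.array(mask), length(dim(mask)) == 3, any(mask))
  structure(list(name = name, mask = mask,
                 target_condition = target_condition),
            class = "roi_definition")
}

#' Per-voxel activation statistic from a training run
#'
#' For each block of the ROI's target emotion, computes per-voxel
#' `(block mean - preceding neutral mean) / preceding neutral mean` and
#' averages over the target blocks (four in the printed design). Defined
#' only inside the mask; voxels whose neutral mean is zero in any block are
#' excluded (`NA`) with a warning.
#'
#' @param run_volumes 4D array of one run (dummies included).
#' @param labels per-volume condition labels from [label_volumes()].
#' @param roi a [roi_definition()].
#' @param n_dummy leading dummy volumes in `run_volumes`.
#' @return 3D array of statistics, `NA` outside the mask.
#' @export
compute_activation_stat <- function(run_volumes, labels, roi, n_dummy = 5L) {
  stopifnot(inherits(roi, "roi_definition"),
            length(dim(run_volumes)) == 4,
            dim(run_volumes)[4] == length(labels) + n_dummy,
            all(dim(run_volumes)[1:3] == dim(roi$mask)))
  vox <- which(roi$mask)
  n_vox <- length(vox)
  mat <- matrix(run_volumes, ncol = dim(run_volumes)[4])[vox, , drop = FALSE]
  mat <- mat[, n_dummy + seq_along(labels), drop = FALSE]

  segs <- .label_segments(labels)
  target <- which(segs$condition == roi$target_condition)
  if (!length(target)) stop("labels contain no '", roi$target_condition,
                            "' block")
  per_block <- matrix(NA_real_, n_vox, length(target))
  for (j in seq_along(target)) {
    s <- target[j]
    if (s == 1 || segs$condition[s - 1] != "neutral") {
      stop("target block at segment ", s, " is not preceded by a neutral block")
    }
    emo_mean <- rowMeans(mat[, segs$start[s]:segs$end[s], drop = FALSE])
    base_mean <- rowMeans(mat[, segs$start[s - 1]:segs$end[s - 1],
                              drop = FALSE])
    per_block[, j] <- ifelse(base_mean == 0, NA_real_,
                             (emo_mean - base_mean) / base_mean)
  }
  stat_vals <- rowMeans(per_block)
  if (anyNA(stat_vals)) {
    warning(sum(is.na(stat_vals)),
            " voxel(s) had a zero neutral baseline and were excluded")
  }
  stat <- array(NA_real_, dim = dim(roi$mask))
  stat[vox] <- stat_vals
  stat
}

#' Contiguous segments (blocks) of a label vector
#' @noRd
.label_segments <- function(labels) {
  r <- rle(labels)
  end <- cumsum(r$lengths)
  data.frame(condition = r$values, start = end - r$lengths + 1, end = end,
             stringsAsFactors = FALSE)
}

#' Select the most active voxels of a region
#'
#' Returns the `ceiling(fraction * |mask|)` voxels with the largest
#' (most positive) statistic. Ties and `NA` statistics are broken by
#' ascending linear voxel index, so selection is deterministic.
#'
#' @param stat_map 3D statistic array (e.g. from
#'   [compute_activation_stat()]).
#' @param mask logical 3D array restricting the candidate set.
#' @param fraction fraction of mask voxels to keep, in `(0, 1]`; 0.10 by
#'   default.
#' @return Sorted integer vector of linear voxel indices.
#' @export
select_top_voxels <- function(stat_map, mask, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  vox <- which(mask)
  if (!length(vox)) stop("empty mask")
  n_sel <- ceiling(fraction * length(vox))
  s <- stat_map[vox]
  s[is.na(s)] <- -Inf
  ord <- order(-s, vox)
  sort(vox[ord[seq_len(n_sel)]])
}

#' Train an ROI feedback model from a training run
#'
#' Convenience wrapper: activation statistic plus top-fraction selection.
#'
#' @inheritParams compute_activation_stat
#' @param fraction fraction of ROI voxels to select.
#' @return Object of class `roi_model`: `roi`, `selected_voxels` (linear
#'   indices), `fraction`, `stat_map`.
#' @export
train_roi_model <- function(run_volumes, labels, roi, fraction = 0.10,
                            n_dummy = 5L) {
  stat <- compute_activation_stat(run_volumes, labels, roi, n_dummy)
  sel <- select_top_voxels(stat, roi$mask, fraction)
  structure(list(roi = roi, selected_voxels = sel, fraction = fraction,
                 stat_map = stat), class = "roi_model")
}

#' @export
print.roi_model <- function(x, ...) {
  cat(sprintf("<roi_model> %s (%s): %d / %d voxels selected (top %.0f%%)\n",
              x$roi$name, x$roi$target_condition, length(x$selected_voxels),
              sum(x$roi$mask), 100 * x$fraction))
  invisible(x)
}

#' Create an empty baseline buffer
#'
#' The buffer accumulates, volume by volume, the selected-voxel mean signal
#' of the current neutral block; it is reset at each neutral-block onset.
#' @return Object of class `baseline_buffer` with zero stored volumes.
#' @export
baseline_buffer <- function() {
  structure(list(roi_means = numeric(0)), class = "baseline_buffer")
}

#' Append one neutral volume to a baseline buffer
#'
#' @param buffer a [baseline_buffer()].
#' @param volume 3D array of the current volume.
#' @param model a trained `roi_model` whose selected voxels define the mean.
#' @param condition the volume's labeled condition; anything other than
#'   `"neutral"` is rejected (baselines come only from neutral blocks).
#' @return The updated buffer (`B` incremented by one).
#' @export
update_baseline <- function(buffer, volume, model, condition = "neutral") {
  stopifnot(inherits(buffer, "baseline_buffer"), inherits(model, "roi_model"))
  if (condition != "neutral") {
    stop("baseline update outside a neutral block (condition '", condition,
         "')")
  }
  buffer$roi_means <- c(buffer$roi_means, mean(volume[model$selected_voxels]))
  buffer
}

#' Sigmoid weights over baseline volume index
#'
#' Logistic weights `1 / (1 + exp(-(k - B/2)))` for `k = 1..B`: late
#' baseline volumes, least contaminated by the previous block's
#' hemodynamic decay, weigh most.
#'
#' @param B number of baseline volumes.
#' @return Positive numeric vector of length `B` (unnormalized).
#' @export
sigmoid_weights <- function(B) {
  stopifnot(B >= 1)
  k <- seq_len(B)
  1 / (1 + exp(-(k - B / 2)))
}

#' Sigmoid-weighted baseline mean
#'
#' `m = sum_k sig(k) ROI_k / sum_k sig(k)` over the buffered neutral-block
#' volumes.
#'
#' @param buffer a non-empty [baseline_buffer()].
#' @return Weighted mean signal.
#' @export
weighted_baseline_mean <- function(buffer) {
  stopifnot(inherits(buffer, "baseline_buffer"))
  B <- length(buffer$roi_means)
  if (B < 1) stop("no baseline established: buffer is empty")
  w <- sigmoid_weights(B)
  sum(w * buffer$roi_means) / sum(w)
}

#' Percent-signal-change feedback value
#'
#' `f = (ROI_curr - m) / m` against the sigmoid-weighted baseline mean `m`.
#'
#' @param curr_roi_mean mean signal over the model's selected voxels on the
#'   current volume.
#' @param buffer baseline buffer of the previous neutral block.
#' @return Dimensionless fractional PSC.
#' @export
compute_psc_feedback <- function(curr_roi_mean, buffer) {
  m <- weighted_baseline_mean(buffer)
  if (m == 0) stop("weighted baseline mean is zero: PSC undefined")
  (curr_roi_mean - m) / m
}
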