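#' Linear SVM decoding feedback
#'
#' The SVM method extracts, for every emotion-block volume, a feature vector
#' of per-voxel percent signal change relative to the previous neutral block
#' (restricted to a feature-selection mask), classifies tenderness versus
#' anguish with a linear soft-margin SVM, and feeds back the hyperplane
#' projection `x . w + b`. Training is cumulative: at each run boundary the
#' model is refitted from scratch on every labeled example observed so far.
#'
#' @name svm_feedback
NULL

#' Create an empty cumulative training store
#'
#' Append-only store of labeled feature vectors with run/volume provenance.
#' @return Object of class `training_store`.
#' @export
training_store <- function() {
  structure(list(x = NULL, label = character(0), run_index = integer(0),
                 volume_index = integer(0)), class = "training_store")
}

#' Append labeled examples to a training store
#'
#' @param store a [training_store()].
#' @param x numeric matrix, one row per example (or a single vector).
#' @param labels character vector of `"tenderness"` / `"anguish"` labels.
#' @param run_index run the examples came from.
#' @param volume_index per-example volume indices (optional provenance).
#' @return The extended store.
#' @export
add_training_examples <- function(store, x, labels, run_index = NA_integer_,
                                  volume_index = NA_integer_) {
  stopifnot(inherits(store, "training_store"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(nrow(x) == length(labels), all(labels %in% .EMOTIONS),
            all(is.finite(x)))
  if (!is.null(store$x)) stopifnot(ncol(x) == ncol(store$x))
  store$x <- rbind(store$x, x)
  store$label <- c(store$label, labels)
  store$run_index <- c(store$run_index, rep_len(run_index, nrow(x)))
  store$volume_index <- c(store$volume_index,
                          rep_len(volume_index, nrow(x)))
  store
}

#' Extract a PSC feature vector from a volume
#'
#' `x_v = (volume_v - baseline_v) / baseline_v` for each voxel of the
#' feature mask, where the baseline is the per-voxel sigmoid-weighted mean
#' of the previous neutral block.
#'
#' @param volume 3D array.
#' @param feature_mask logical 3D array.
#' @param neutral_baseline per-voxel baseline vector (length = number of
#'   mask voxels), e.g. from [voxel_baseline_mean()].
#' @return Numeric feature vector of length `sum(feature_mask)`.
#' @export
extract_features <- function(volume, feature_mask, neutral_baseline) {
  if (is.null(neutral_baseline)) stop("no neutral baseline established yet")
  vox <- which(feature_mask)
  stopifnot(length(neutral_baseline) == length(vox))
  if (any(neutral_baseline == 0)) {
    stop("zero baseline at ", sum(neutral_baseline == 0),
         " voxel(s): PSC features undefined")
  }
  (volume[vox] - neutral_baseline) / neutral_baseline
}

#' Per-voxel sigmoid-weighted means of a neutral block
#'
#' Same weighting as the ROI baseline, applied voxelwise: rows of `values`
#' are the neutral block's volumes (masked voxel values), and each voxel's
#' baseline is its [sigmoid_weights()]-weighted mean over those volumes.
#'
#' @param values numeric matrix, `B` rows (baseline volumes) by `p` voxels.
#' @return Length-`p` baseline vector.
#' @export
voxel_baseline_mean <- function(values) {
  stopifnot(is.matrix(values), nrow(values) >= 1)
  w <- sigmoid_weights(nrow(values))
  as.numeric(crossprod(w, values) / sum(w))
}

#' Fit the linear SVM on all stored examples
#'
#' Soft-margin linear SVM (libsvm via \pkg{e1071}), no feature scaling
#' beyond the PSC normalization already in the features. The hyperplane is
#' re-oriented, if necessary, so tenderness examples project positive.
#'
#' @param store a [training_store()] containing both classes.
#' @param C soft-margin cost.
#' @return Object of class `svm_model`: `w`, `b`, `C`,
#'   `class_orientation = "tenderness_positive"`, the `store` it was fitted
#'   on, and `f_max_suggest` (2 x median absolute training projection, a
#'   feedback-to-saturation scale).
#' @export
svm_train <- function(store, C = 1) {
  stopifnot(inherits(store, "training_store"))
  if (length(unique(store$label)) < 2) {
    stop("training store must contain both classes")
  }
  y <- factor(store$label, levels = .EMOTIONS)
  fit <- e1071::svm(store$x, y, kernel = "linear", cost = C, scale = FALSE)
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm orients by order of class appearance; normalize deterministically
  proj <- as.numeric(store$x %*% w) + b
  if (mean(proj[store$label == "tenderness"]) <
      mean(proj[store$label == "anguish"])) {
    w <- -w
    b <- -b
    proj <- -proj
  }
  structure(list(w = w, b = b, C = C,
                 class_orientation = "tenderness_positive",
                 store = store,
                 f_max_suggest = 2 * stats::median(abs(proj))),
            class = "svm_model")
}

#' Cumulative retraining at a run boundary
#'
#' Extends the model's store with the new run's labeled examples and refits
#' from scratch on the concatenation — by construction identical to batch
#' training on all examples observed so far.
#'
#' @param model a fitted `svm_model`.
#' @param x,labels,run_index new examples, as in [add_training_examples()].
#' @return A new `svm_model` over the extended store.
#' @export
retrain_cumulative <- function(model, x, labels, run_index = NA_integer_) {
  stopifnot(inherits(model, "svm_model"))
  store <- add_training_examples(model$store, x, labels, run_index)
  svm_train(store, C = model$C)
}

#' Hyperplane projection of a feature vector
#'
#' @param model an `svm_model`.
#' @param x feature vector, same length as `model$w`.
#' @return `x . w + b`.
#' @export
svm_project <- function(model, x) {
  stopifnot(inherits(model, "svm_model"))
  if (length(x) != length(model$w)) {
    stop("feature vector length ", length(x), " does not match hyperplane (",
         length(model$w), ")")
  }
  sum(x * model$w) + model$b
}

#' Condition-oriented decoding feedback
#'
#' The signed projection, re-oriented so that larger values always mean
#' stronger engagement of the current block's target emotion: tenderness
#' blocks take `+projection`, anguish blocks `-projection` (tenderness is
#' the positive class).
#'
#' @param model an `svm_model`.
#' @param x feature vector.
#' @param current_condition `"tenderness"` or `"anguish"`.
#' @return Scalar feedback value.
#' @export
decode_feedback <- function(model, x,
                            current_condition = c("tenderness", "anguish")) {
  current_condition <- match.arg(current_condition)
  p <- svm_project(model, x)
  if (current_condition == "tenderness") p else -p
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model> linear, %d features, C = %g, %d stored examples (%s)\n",
              length(x$w), x$C, length(x$store$label), x$class_orientation))
  invisible(x)
}
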