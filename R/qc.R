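#' Offline quality control and GLM validation
#'
#' Desk-scale offline stage: motion-artifact flagging at the conventional
#' real-time thresholds (3 mm translation, 0.02 rad rotation), SPM-style
#' discrete-cosine high-pass filtering (cutoff 456 s for SVM sessions,
#' 152 s for ROI sessions — twice the maximum spacing between repetitions
#' of the same stimulus, treated here as configuration constants), and a
#' voxelwise ordinary-least-squares GLM that verifies planted effects are
#' recovered from synthetic sessions.
#'
#' @name offline_qc
NULL

#' Flag motion-corrupted volumes
#'
#' A volume is flagged iff any |translation| exceeds `trans_thresh` or any
#' |rotation| exceeds `rot_thresh`, strictly ("over" the threshold; a
#' parameter exactly at the threshold is not flagged). `mode = "delta"`
#' applies the same rule to frame-to-frame differences instead of absolute
#' parameters (first volume never flagged).
#'
#' @param motion numeric matrix or data frame, one row per volume, 6
#'   columns: translations (mm, 3 axes) then rotations (rad, 3 axes).
#' @param trans_thresh translation threshold in mm.
#' @param rot_thresh rotation threshold in radians.
#' @param mode `"absolute"` (default) or `"delta"`.
#' @return Logical vector, one flag per volume.
#' @export
detect_artifacts <- function(motion, trans_thresh = 3, rot_thresh = 0.02,
                             mode = c("absolute", "delta")) {
  mode <- match.arg(mode)
  stopifnot(trans_thresh > 0, rot_thresh > 0)
  motion <- as.matrix(motion)
  if (ncol(motion) != 6 || !is.numeric(motion) || anyNA(motion)) {
    stop("motion trace must be a numeric matrix with 6 columns and no NA")
  }
  if (mode == "delta") {
    motion <- rbind(0, diff(motion))
  }
  apply(abs(motion[, 1:3, drop = FALSE]) > trans_thresh, 1, any) |
    apply(abs(motion[, 4:6, drop = FALSE]) > rot_thresh, 1, any)
}

#' Discrete-cosine high-pass basis
#'
#' DCT-II columns `cos(pi * (2t + 1) k / (2n))`, `k = 1 .. floor(2 n tr_s /
#' cutoff_s)`: the zero-mean, mutually orthogonal low-frequency functions
#' with period above `cutoff_s` that SPM's high-pass filter regresses out.
#'
#' @param n_volumes series length.
#' @param tr_s sampling interval (s).
#' @param cutoff_s high-pass cutoff period (s).
#' @return `n_volumes` x K matrix (K may be 0 for short series).
#' @export
dct_basis <- function(n_volumes, tr_s, cutoff_s) {
  K <- floor(2 * n_volumes * tr_s / cutoff_s)
  t <- seq_len(n_volumes) - 1
  B <- vapply(seq_len(K), function(k) cos(pi * (2 * t + 1) * k /
                                            (2 * n_volumes)),
              numeric(n_volumes))
  matrix(B, nrow = n_volumes, ncol = K)
}

#' High-pass filter a time series by DCT-basis regression
#'
#' Regresses out the discrete-cosine basis below the cutoff frequency; the
#' series mean is preserved (all basis columns are zero-mean).
#'
#' @param x numeric vector, or matrix with time along rows.
#' @param cutoff_s cutoff period in seconds (must exceed `2 * tr_s`).
#' @param tr_s sampling interval in seconds.
#' @return Filtered series, same shape as `x`.
#' @export
highpass <- function(x, cutoff_s, tr_s) {
  stopifnot(cutoff_s > 2 * tr_s)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  if (n < 2) stop("series must have at least 2 volumes")
  B <- dct_basis(n, tr_s, cutoff_s)
  if (ncol(B) > 0) {
    X <- X - B %*% qr.coef(qr(B), X)
  }
  if (vec) as.numeric(X) else X
}

#' Build a GLM design matrix for one run
#'
#' Columns: intercept, HRF-convolved condition boxcars (tenderness,
#' anguish), DCT drift basis at the method's cutoff, optional centered
#' motion covariates, and one indicator column per artifact-flagged volume.
#' Rejected if rank-deficient, naming the offending columns.
#'
#' @param schedule an `nfb_schedule`.
#' @param cutoff_s high-pass cutoff (s): 152 for ROI designs, 456 for SVM
#'   designs by convention.
#' @param motion optional per-volume 6-column motion trace (non-dummy
#'   volumes, or full run — trimmed automatically).
#' @param artifact_flags optional logical flags (same length convention).
#' @return Object of class `glm_design`: list with `X` (n_volumes x p),
#'   `terms`, `cutoff_s`, `schedule`.
#' @export
build_glm_design <- function(schedule, cutoff_s, motion = NULL,
                             artifact_flags = NULL) {
  stopifnot(inherits(schedule, "nfb_schedule"))
  n <- schedule$n_volumes
  keep <- schedule$n_dummy + seq_len(n)
  X <- cbind(intercept = rep(1, n))
  for (cond in .EMOTIONS) {
    X <- cbind(X, condition_regressor(schedule, cond)[keep])
    colnames(X)[ncol(X)] <- cond
  }
  B <- dct_basis(n, schedule$tr_s, cutoff_s)
  if (ncol(B) > 0) {
    colnames(B) <- sprintf("dct_%02d", seq_len(ncol(B)))
    X <- cbind(X, B)
  }
  .trim <- function(m) {
    m <- as.matrix(m)
    if (nrow(m) == n + schedule$n_dummy) m[keep, , drop = FALSE]
    else if (nrow(m) == n) m
    else stop("covariate rows match neither n_volumes nor the full run")
  }
  if (!is.null(motion)) {
    M <- scale(.trim(motion), center = TRUE, scale = FALSE)
    colnames(M) <- sprintf("motion_%d", 1:6)
    X <- cbind(X, M)
  }
  if (!is.null(artifact_flags)) {
    flags <- as.logical(.trim(matrix(artifact_flags, ncol = 1)))
    for (i in which(flags)) {
      col <- as.numeric(seq_len(n) == i)
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- sprintf("artifact_v%03d", i)
    }
  }
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, terms = colnames(X), cutoff_s = cutoff_s,
                 schedule = schedule), class = "glm_design")
}

#' Fit the voxelwise GLM on one run
#'
#' Ordinary least squares per voxel over the run's non-dummy volumes.
#'
#' @param run_volumes 4D array of one run (dummies included), or a
#'   time-by-voxel matrix of non-dummy volumes.
#' @param design a [build_glm_design()] object.
#' @param n_dummy dummy volumes to discard from a 4D input.
#' @return Object of class `glm_result`: `beta` (terms x voxels), `sigma2`,
#'   `df`, `XtX_inv`, `terms`, `grid_dims` (NULL for matrix input).
#' @export
fit_glm <- function(run_volumes, design, n_dummy = 5L) {
  stopifnot(inherits(design, "glm_design"))
  X <- design$X
  if (length(dim(run_volumes)) == 4) {
    grid_dims <- dim(run_volumes)[1:3]
    Y <- t(matrix(run_volumes, ncol = dim(run_volumes)[4]))
    Y <- Y[n_dummy + seq_len(nrow(X)), , drop = FALSE]
  } else {
    grid_dims <- NULL
    Y <- as.matrix(run_volumes)
  }
  if (nrow(Y) != nrow(X)) stop("volumes and regressors differ in length")
  fit <- stats::lm.fit(X, Y)
  beta <- fit$coefficients
  res <- fit$residuals
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  structure(list(beta = beta, sigma2 = sigma2, df = df,
                 y_ms = colMeans(Y^2),
                 XtX_inv = chol2inv(chol(crossprod(X))),
                 terms = design$terms, grid_dims = grid_dims),
            class = "glm_result")
}

#' Contrast estimate and t-statistic map
#'
#' `t = c'b / sqrt(sigma2 * c' (X'X)^-1 c)` per voxel. The contrast can be
#' a full numeric vector over the design's terms, or a named shorthand
#' assigning weights to a subset of terms (e.g.
#' `c(tenderness = 1, anguish = -1)`).
#'
#' @param result a [fit_glm()] result.
#' @param contrast numeric contrast vector (length = number of terms) or a
#'   named numeric vector over a subset of terms.
#' @return List with `estimate` and `t`, as 3D arrays when the fit came
#'   from a 4D input, else vectors.
#' @export
glm_contrast <- function(result, contrast) {
  stopifnot(inherits(result, "glm_result"))
  p <- length(result$terms)
  cvec <- numeric(p)
  if (!is.null(names(contrast))) {
    idx <- match(names(contrast), result$terms)
    if (anyNA(idx)) stop("unknown terms: ",
                         paste(names(contrast)[is.na(idx)], collapse = ", "))
    cvec[idx] <- contrast
  } else {
    stopifnot(length(contrast) == p)
    cvec <- contrast
  }
  est <- as.numeric(crossprod(cvec, result$beta))
  var_c <- as.numeric(crossprod(cvec, result$XtX_inv %*% cvec))
  t <- est / sqrt(result$sigma2 * var_c)
  # degenerate (noise-free) voxels: residual variance that is zero, or pure
  # rounding noise relative to the data scale, cannot support a t-statistic;
  # a (numerically) zero estimate there is an exact null, +-Inf a perfect fit
  degen <- result$sigma2 * var_c == 0 |
    result$sigma2 < 1e-20 * result$y_ms
  est[degen][abs(est[degen]) < 1e-10 * sqrt(result$y_ms[degen])] <- 0
  t[degen] <- ifelse(est[degen] == 0, 0, sign(est[degen]) * Inf)
  if (!is.null(result$grid_dims)) {
    est <- array(est, dim = result$grid_dims)
    t <- array(t, dim = result$grid_dims)
  }
  list(estimate = est, t = t)
}

#' Summarize session quality control
#'
#' Motion-flag counts per run plus the filter settings used, as a plain
#' list suitable for JSON/YAML serialization.
#'
#' @param session an `nfb_session`.
#' @param trans_thresh,rot_thresh,mode passed to [detect_artifacts()].
#' @param cutoff_s high-pass cutoff recorded in the report (default by
#'   method: 152 s ROI, 456 s SVM).
#' @return Named list: thresholds, cutoff, per-run and total flag counts.
#' @export
qc_report <- function(session, trans_thresh = 3, rot_thresh = 0.02,
                      mode = "absolute", cutoff_s = NULL) {
  stopifnot(inherits(session, "nfb_session"))
  cutoff_s <- cutoff_s %||% if (session$design$method == "ROI") 152 else 456
  flags <- lapply(session$motion, detect_artifacts,
                  trans_thresh = trans_thresh, rot_thresh = rot_thresh,
                  mode = mode)
  list(method = session$design$method,
       trans_thresh_mm = trans_thresh, rot_thresh_rad = rot_thresh,
       artifact_mode = mode, highpass_cutoff_s = cutoff_s,
       flagged_per_run = vapply(flags, sum, integer(1)),
       flagged_total = sum(vapply(flags, sum, integer(1))),
       volumes_per_run = vapply(session$motion, nrow, integer(1)))
}
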