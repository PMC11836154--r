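#' Fit a statistical anatomy atlas by principal component analysis
#'
#' Centers the training feature matrix (geometry coordinates and density
#' features, concatenated) and extracts principal components ordered by
#' decreasing explained variance. The per-component training scores are kept
#' as empirical distributions for inverse-CDF sampling of new subjects.
#'
#' @param features Numeric matrix `n_train x P`, `n_train >= 3`,
#'   `P >= n_train`, no missing or non-finite entries.
#' @return An object of class `hf_atlas` with elements `mean_features`,
#'   `modes` (orthonormal `P x K` loadings), `score_samples` (list of K
#'   centred training score vectors), `sdev`, and `K <= n_train - 1`.
#' @details With a full-rank training matrix the atlas retains
#'   `K = n_train - 1` components and reconstructs every training row from
#'   its own scores exactly. Rank-deficient input (e.g. duplicated rows)
#'   reduces `K` with a warning.
#' @export
#' @examples
#' x <- generate_atlas_training(fixture_spec(n_train = 10, n_features = 12), seed = 1)
#' atlas <- fit_atlas(x)
#' atlas$K
fit_atlas <- function(features) {
  features <- as.matrix(features)
  n <- nrow(features)
  p <- ncol(features)
  if (n < 3) stop("need at least 3 training rows")
  if (p < n) stop("need at least as many features as training rows")
  if (!all(is.finite(features))) stop("non-finite entries in training features")
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  k_max <- n - 1
  tol <- max(pc$sdev) * 1e-8
  k <- as.integer(min(k_max, sum(pc$sdev > tol)))
  if (k < k_max) {
    warning(sprintf("rank-deficient training matrix: retaining %d of %d components", k, k_max))
  }
  structure(
    list(
      mean_features = stats::setNames(pc$center, colnames(features)),
      modes = pc$rotation[, seq_len(k), drop = FALSE],
      score_samples = lapply(seq_len(k), function(j) pc$x[, j] - mean(pc$x[, j])),
      sdev = pc$sdev[seq_len(k)],
      K = k,
      n_train = n,
      feature_names = colnames(features)
    ),
    class = "hf_atlas"
  )
}

#' Project feature vectors onto atlas scores
#'
#' @param atlas An [fit_atlas()] object.
#' @param features Matrix (rows are subjects) or a single feature vector.
#' @return Score matrix `n x K`.
#' @export
atlas_encode <- function(atlas, features) {
  x <- if (is.null(dim(features))) matrix(features, nrow = 1) else as.matrix(features)
  sweep(x, 2, atlas$mean_features) %*% atlas$modes
}

#' Reconstruct feature vectors from atlas scores
#'
#' @param atlas An [fit_atlas()] object.
#' @param scores Score matrix `n x K` (or a length-K vector).
#' @return Feature matrix `n x P` with feature names.
#' @export
atlas_decode <- function(atlas, scores) {
  s <- if (is.null(dim(scores))) matrix(scores, nrow = 1) else as.matrix(scores)
  stopifnot(ncol(s) == atlas$K)
  out <- sweep(s %*% t(atlas$modes), 2, atlas$mean_features, `+`)
  colnames(out) <- atlas$feature_names
  out
}

#' Sample virtual-subject feature vectors from an atlas
#'
#' Each principal-component score is drawn independently from the inverse
#' empirical cumulative distribution of that component's training scores
#' (linear interpolation between order statistics), then mapped back to
#' feature space through the atlas mean and modes. Sampling at quantile 0.5
#' therefore returns the training median of each score.
#'
#' @param atlas An [fit_atlas()] object.
#' @param n Number of subjects to draw.
#' @param quantiles Optional `n x K` matrix of CDF quantiles in `[0, 1]`
#'   overriding the uniform draws (for deterministic probes).
#' @param scores Optional `n x K` matrix of raw PC scores bypassing the
#'   inverse-CDF step entirely (e.g. all zeros returns the mean features).
#' @return Feature matrix `n x P`.
#' @export
#' @examples
#' x <- generate_atlas_training(fixture_spec(n_train = 10, n_features = 12), seed = 1)
#' atlas <- fit_atlas(x)
#' f <- sample_patient_features(atlas, n = 5)
sample_patient_features <- function(atlas, n = 1, quantiles = NULL, scores = NULL) {
  stopifnot(inherits(atlas, "hf_atlas"), n >= 1)
  if (is.null(scores)) {
    u <- if (is.null(quantiles)) {
      matrix(stats::runif(n * atlas$K), n, atlas$K)
    } else {
      q <- as.matrix(quantiles)
      stopifnot(nrow(q) == n, ncol(q) == atlas$K, all(q >= 0), all(q <= 1))
      q
    }
    scores <- vapply(seq_len(atlas$K), function(j) {
      stats::quantile(atlas$score_samples[[j]], probs = u[, j], type = 7, names = FALSE)
    }, numeric(n))
    if (n == 1) scores <- matrix(scores, nrow = 1)
  } else {
    scores <- if (is.null(dim(scores))) matrix(scores, nrow = 1) else as.matrix(scores)
    stopifnot(nrow(scores) == n, ncol(scores) == atlas$K)
  }
  atlas_decode(atlas, scores)
}

#' Areal bone mineral density of a voxelised density volume
#'
#' Computes a DXA-style areal BMD: the total mineral mass inside a
#' region of interest divided by its area projected onto the coronal plane.
#' For a uniform slab of density `rho` (g/cm^3) and thickness `t` (cm) along
#' the projection axis this reduces to `rho * t`, and the result is
#' homogeneous of degree 1 in density.
#'
#' @param density 3-D numeric array of volumetric densities (g/cm^3),
#'   indexed `[x, y, z]` with x medio-lateral, y antero-posterior (the
#'   projection axis), z cranio-caudal.
#' @param voxel_mm Length-3 voxel edge lengths (mm).
#' @param roi Optional list with integer index vectors `x`, `y`, `z`
#'   selecting the region of interest; defaults to the full volume. An empty
#'   ROI is an error.
#' @return Areal BMD in g/cm^2 (non-negative scalar).
#' @export
#' @examples
#' slab <- array(0.8, dim = c(4, 5, 3)) # 0.8 g/cm^3
#' compute_abmd(slab, voxel_mm = c(1, 2, 1)) # thickness 5 * 2 mm = 1 cm -> 0.8
compute_abmd <- function(density, voxel_mm, roi = NULL) {
  stopifnot(length(dim(density)) == 3, length(voxel_mm) == 3, all(voxel_mm > 0))
  if (any(!is.finite(density)) || any(density < 0)) {
    stop("density must be finite and non-negative")
  }
  d <- dim(density)
  roi <- roi %||% list(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  if (any(lengths(roi[c("x", "y", "z")]) == 0)) stop("empty ROI")
  sub <- density[roi$x, roi$y, roi$z, drop = FALSE]
  voxel_cm <- voxel_mm / 10
  mass_g <- sum(sub) * prod(voxel_cm)
  area_cm2 <- length(roi$x) * length(roi$z) * voxel_cm[1] * voxel_cm[3]
  mass_g / area_cm2
}

#' @export
print.hf_atlas <- function(x, ...) {
  cat(sprintf("<hf_atlas> %d training subjects, %d features, K = %d components\n",
              x$n_train, length(x$mean_features), x$K))
  ev <- x$sdev^2 / sum(x$sdev^2)
  cat(sprintf("  leading explained-variance ratios: %s\n",
              paste(sprintf("%.3f", utils::head(ev, 5)), collapse = " ")))
  invisible(x)
}
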