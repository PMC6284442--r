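# PCA shape models, parallel-analysis component retention, mode
# reconstruction and point-to-surface distances.

# Eigen-spectrum of the sample covariance of the rows of X, via economy SVD of
# the centred matrix (equivalent to the dual/Gram trick when p >> n).
.cov_spectrum <- function(X) {
  n <- nrow(X)
  C <- sweep(X, 2L, colMeans(X))
  sv <- svd(C, nu = 0L)
  list(values = sv$d^2 / (n - 1), vectors = sv$v, centred = C)
}

#' Fit a PCA shape model
#'
#' Eigen-decomposition of the sample covariance of the rows (flattened
#' shapes), computed through the economy SVD of the centred data matrix — the
#' dual (Gram) formulation, exact and cheap when the ambient dimension 3n far
#' exceeds the sample count. Components with relative eigenvalue below 1e-10
#' of the leading one are dropped. Shape parameters (`scores_sd`) are the
#' projections onto each eigenvector divided by the component SD, so each
#' column has sample mean 0 and SD 1 on the fitting data. Eigenvector signs
#' are fixed so the largest-magnitude loading of each component is positive.
#'
#' @param x an `aligned_dataset` (from [groupwise_align()]) or an
#'   n_samples x p data matrix with one flattened shape per row.
#' @return a `shape_model`: `mean_vector`, orthonormal `eigenvectors` (p x m),
#'   `eigenvalues` (descending variances), `scores_sd` (n_samples x m),
#'   `k_retained` (NA until set, e.g. by [parallel_analysis()]), `n_samples`,
#'   `meta` (when available).
#' @export
fit_pca <- function(x) {
  meta <- NULL
  if (inherits(x, "aligned_dataset")) { meta <- x$meta; x <- x$data }
  if (!is.matrix(x) || nrow(x) < 3L)
    stop("need a data matrix with at least 3 rows (samples)", call. = FALSE)
  sp <- .cov_spectrum(x)
  if (max(sp$values) <= 0)
    stop("zero-variance data: PCA undefined", call. = FALSE)
  keep <- sp$values > max(sp$values) * 1e-10
  lam <- sp$values[keep]
  V <- sp$vectors[, keep, drop = FALSE]
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- sp$centred %*% V
  scores_sd <- sweep(scores, 2L, sqrt(lam), `/`)
  structure(list(mean_vector = colMeans(x), eigenvectors = V,
                 eigenvalues = lam, scores_sd = scores_sd,
                 k_retained = NA_integer_, n_samples = nrow(x), meta = meta),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  k <- if (is.na(x$k_retained)) min(3L, length(x$eigenvalues)) else x$k_retained
  cat(sprintf("<shape_model> %d samples, %d components (k_retained = %s)\n",
              x$n_samples, length(x$eigenvalues),
              ifelse(is.na(x$k_retained), "unset", x$k_retained)))
  cat(sprintf("  leading eigenvalues: %s (%.1f%% of variance in first %d)\n",
              paste(format(x$eigenvalues[seq_len(k)], digits = 3), collapse = ", "),
              100 * sum(x$eigenvalues[seq_len(k)]) / tot, k))
  invisible(x)
}

#' Parallel analysis for component retention
#'
#' Compares the observed eigenvalue spectrum against spectra of simulated
#' uncorrelated data of identical size: element-wise independent Gaussians
#' whose per-variable variance matches the observed data. The retained count
#' `k_retained` is the largest j such that every rank up to j has an observed
#' eigenvalue above the simulated criterion value (the rank-wise mean by
#' default, the 95th percentile optionally) — the crossing point of the
#' observed and simulated scree curves.
#'
#' @param x data matrix (rows = samples), `aligned_dataset`, or `shape_model`
#'   paired with `data` (matrix input is canonical).
#' @param n_sim number of simulated datasets (>= 50).
#' @param criterion "mean" or "percentile95".
#' @param seed integer seed; results are reproducible.
#' @return a `parallel_analysis_result`: `observed_eigenvalues`,
#'   `simulated_mean`, `simulated_p95`, `k_retained`, `n_sim`, `criterion`,
#'   `seed`.
#' @export
parallel_analysis <- function(x, n_sim = 100L, criterion = c("mean", "percentile95"),
                              seed = 1L) {
  criterion <- match.arg(criterion)
  if (inherits(x, "aligned_dataset")) x <- x$data
  if (!is.matrix(x)) stop("x must be a data matrix", call. = FALSE)
  if (n_sim < 50L) stop("n_sim must be >= 50", call. = FALSE)
  n <- nrow(x); p <- ncol(x)
  obs <- .cov_spectrum(x)$values
  sds <- apply(x, 2L, stats::sd)
  L <- length(obs)
  sim <- .with_seed(seed, {
    t(vapply(seq_len(n_sim), function(b) {
      Z <- matrix(stats::rnorm(n * p), n, p)
      Z <- sweep(Z, 2L, sds, `*`)
      .cov_spectrum(Z)$values[seq_len(L)]
    }, numeric(L)))
  })
  sim_mean <- colMeans(sim)
  sim_p95 <- apply(sim, 2L, stats::quantile, probs = 0.95, names = FALSE)
  crit <- if (criterion == "mean") sim_mean else sim_p95
  above <- obs > crit
  k <- if (!above[1L]) 0L else {
    firstfail <- which(!above)[1L]
    if (is.na(firstfail)) L else firstfail - 1L
  }
  structure(list(observed_eigenvalues = obs, simulated_mean = sim_mean,
                 simulated_p95 = sim_p95, k_retained = as.integer(k),
                 n_sim = as.integer(n_sim), criterion = criterion,
                 seed = as.integer(seed)),
            class = "parallel_analysis_result")
}

#' @export
print.parallel_analysis_result <- function(x, ...) {
  cat(sprintf("<parallel_analysis> k_retained = %d (criterion = %s, %d simulations)\n",
              x$k_retained, x$criterion, x$n_sim))
  invisible(x)
}

#' Reconstruct a shape along one component
#'
#' Returns `mean + c_sd * sqrt(eigenvalue_j) * eigenvector_j`, i.e. the mean
#' shape deformed `c_sd` standard deviations along mode `mode_index` (the
#' "+3 SD" / "-3 SD" renderings of shape-model practice).
#'
#' @param model a [fit_pca()] shape model.
#' @param mode_index component index, 1-based.
#' @param c_sd deviation in SD units (may be negative).
#' @return a flattened shape vector; use [as_points()] to get an n x 3 matrix.
#' @export
reconstruct_at_sd <- function(model, mode_index, c_sd) {
  stopifnot(inherits(model, "shape_model"))
  m <- length(model$eigenvalues)
  if (mode_index < 1L || mode_index > m)
    stop(sprintf("mode_index must be in 1..%d", m), call. = FALSE)
  model$mean_vector +
    c_sd * sqrt(model$eigenvalues[mode_index]) * model$eigenvectors[, mode_index]
}

#' Unflatten a shape vector to an n x 3 point matrix
#' @param v length-3n shape vector.
#' @return n x 3 matrix.
#' @export
as_points <- function(v) .unvec_points(v)

#' Unsigned point-to-surface distances
#'
#' Closest distance (mm) from each query point to a target surface. If the
#' target carries triangle faces the exact point-to-triangle distance is
#' used; otherwise the nearest point of the target cloud is used and the
#' result is flagged with attribute `method = "nearest_point"` (an upper
#' bound on the true surface distance).
#'
#' @param points n x 3 query matrix.
#' @param target a [shape_sample()] (with or without faces) or an m x 3
#'   matrix (cloud fallback).
#' @return numeric vector of distances, one per query point; attribute
#'   `method` is "point_to_triangle" or "nearest_point".
#' @export
point_to_surface_distance <- function(points, target) {
  .check_points(points)
  if (inherits(target, "shape_sample") && !is.null(target$faces)) {
    d <- .closest_on_mesh(points, target$points, target$faces)$dist
    attr(d, "method") <- "point_to_triangle"
    return(d)
  }
  tp <- if (inherits(target, "shape_sample")) target$points else target
  .check_points(tp, "target")
  if (nrow(tp) == 0L) stop("empty target", call. = FALSE)
  # nearest neighbour in the cloud, blockwise to bound memory
  d <- vapply(seq_len(nrow(points)), function(i) {
    sqrt(min(rowSums(sweep(tp, 2L, points[i, ])^2)))
  }, 0)
  attr(d, "method") <- "nearest_point"
  d
}
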