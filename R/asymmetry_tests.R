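# Distance-based permutational comparison of left vs right shape groups:
# location (mean difference), variance-covariance scale (dispersion) and
# variance-covariance orientation (principal angles between PCA subspaces).

#' Group-location D-statistic
#'
#' Euclidean distance between the multivariate means of two groups.
#'
#' @param left,right matrices with one flattened shape per row, equal column
#'   count.
#' @return scalar distance.
#' @export
location_d <- function(left, right) {
  if (ncol(left) != ncol(right))
    stop("left and right have mismatched dimensionality", call. = FALSE)
  if (nrow(left) < 1L || nrow(right) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  sqrt(sum((colMeans(left) - colMeans(right))^2))
}

#' Variance-covariance scale D-statistic
#'
#' The residual of a sample is its Euclidean distance to its own group mean;
#' the statistic is the absolute difference between the two groups' average
#' residuals (a dispersion comparison).
#'
#' @inheritParams location_d
#' @return scalar statistic.
#' @export
scale_d <- function(left, right) {
  if (ncol(left) != ncol(right))
    stop("left and right have mismatched dimensionality", call. = FALSE)
  if (nrow(left) < 1L || nrow(right) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  res <- function(g) mean(sqrt(rowSums(sweep(g, 2L, colMeans(g))^2)))
  abs(res(left) - res(right))
}

#' Principal angles between two subspaces
#'
#' Canonical angles theta_1 <= ... <= theta_k between the column spans of two
#' orthonormal bases, computed as arccos of the singular values of
#' `t(basis_a) %*% basis_b` (clipped to \[0, 1\]).
#'
#' @param basis_a,basis_b matrices with orthonormal columns, same ambient
#'   dimension and the same number k of columns.
#' @param tol orthonormality tolerance on the Gramian.
#' @return numeric vector of k angles in radians, ascending.
#' @export
principal_angles <- function(basis_a, basis_b, tol = 1e-6) {
  check_on <- function(B, name) {
    G <- crossprod(B)
    if (max(abs(G - diag(ncol(B)))) > tol)
      stop(sprintf("%s is not orthonormal (Gramian deviates by more than %g)",
                   name, tol), call. = FALSE)
  }
  if (nrow(basis_a) != nrow(basis_b) || ncol(basis_a) != ncol(basis_b))
    stop("bases must share ambient dimension and column count", call. = FALSE)
  check_on(basis_a, "basis_a"); check_on(basis_b, "basis_b")
  s <- svd(crossprod(basis_a, basis_b), nu = 0L, nv = 0L)$d
  acos(pmin(pmax(s, 0), 1))
}

#' Grassmann projection metric from principal angles
#'
#' `D_j = sqrt(j - sum_{i<=j} cos^2 theta_i)`: 0 for identical subspaces,
#' sqrt(j) for fully orthogonal ones. `squared = TRUE` returns the unrooted
#' form `j - sum cos^2 theta_i`.
#'
#' @param theta principal angles (ascending), radians.
#' @param j number of leading angles to use (default: all).
#' @param squared return the squared form.
#' @return scalar D_j.
#' @seealso [projection_metric_set()] for the full set D_1..D_k.
#' @export
projection_metric <- function(theta, j = length(theta), squared = FALSE) {
  if (j < 1L || j > length(theta))
    stop(sprintf("j must be in 1..%d", length(theta)), call. = FALSE)
  val <- max(j - sum(cos(theta[seq_len(j)])^2), 0)
  if (squared) val else sqrt(val)
}

#' @rdname projection_metric
#' @export
projection_metric_set <- function(theta, squared = FALSE) {
  vapply(seq_along(theta), function(j) projection_metric(theta, j, squared), 0)
}

#' Permutation p-value
#'
#' `P_perm = N_i / N_perm` where `N_i` counts permuted statistics greater
#' than or equal to the observed one (ties included). With `add_one`,
#' `(N_i + 1) / (N_perm + 1)` is returned instead, which can never be 0.
#'
#' @param n_exceed count(s) N_i.
#' @param n_perm number of permutations N_perm.
#' @param add_one use the add-one (never-zero) form.
#' @return p-value(s).
#' @export
perm_pvalue <- function(n_exceed, n_perm, add_one = FALSE) {
  if (add_one) (n_exceed + 1) / (n_perm + 1) else n_exceed / n_perm
}

# Orthonormal basis of the top-k principal subspace of a group (rows =
# samples), in the coordinates of the supplied matrix.
.group_basis <- function(X, k) {
  C <- sweep(X, 2L, colMeans(X))
  sv <- svd(C, nu = 0L)
  if (k > sum(sv$d > max(sv$d) * 1e-12))
    stop(sprintf("group has rank < k = %d; too few samples for the orientation test", k),
         call. = FALSE)
  sv$v[, seq_len(k), drop = FALSE]
}

# Rotate both groups into the (at most n_total-dimensional) common row space
# so permutation loops work on small matrices. Exact: the reduction is an
# orthonormal change of basis of the span of all rows, preserving every inner
# product and hence all three statistics and the principal angles.
.reduce_rows <- function(left, right) {
  X <- rbind(left, right)
  if (ncol(X) <= nrow(X)) return(list(left = left, right = right))
  sv <- svd(X, nv = 0L)
  coords <- sv$u %*% diag(sv$d, length(sv$d))
  list(left = coords[seq_len(nrow(left)), , drop = FALSE],
       right = coords[nrow(left) + seq_len(nrow(right)), , drop = FALSE])
}

#' Distance-based permutation test of left vs right shape groups
#'
#' Computes the observed D-statistic ("location", "scale" or "orientation")
#' and its null distribution under `n_perm` random relabellings, fully
#' re-computing the statistic on each permuted dataset — for the orientation
#' test both groups' PCA subspaces are re-estimated per permutation and a
#' length-k vector `D_1..D_k` of projection-metric distances is returned,
#' with element-wise p-values. Relabellings are sampled with replacement and
#' the identity relabelling is allowed, matching the Monte-Carlo p-value
#' `N_i / N_perm` (see [perm_pvalue()]).
#'
#' Schemes: `"side_swap"` (default) treats rows as subject-paired and swaps
#' each pair independently with probability 1/2 — the exchangeability that
#' paired left/right data warrant; `"free"` relabels all samples freely while
#' preserving group sizes.
#'
#' @param left,right group matrices, one flattened shape per row; for
#'   `side_swap`, row i of `left` and row i of `right` must belong to the same
#'   subject.
#' @param statistic "location", "scale" or "orientation".
#' @param n_perm number of permutations (a warning is issued below 100).
#' @param scheme "side_swap" or "free".
#' @param seed integer seed.
#' @param k subspace dimension for the orientation statistic (required there;
#'   typically the common parallel-analysis retention of the two sides).
#' @param add_one use the add-one p-value form.
#' @param squared use the squared projection metric.
#' @return a `permutation_result`: `d_observed`, `d_perm` (n_perm x 1 or k),
#'   `n_perm`, `n_exceed`, `p_perm`, `statistic`, `scheme`, `seed`, `k`.
#' @export
permutation_test <- function(left, right,
                             statistic = c("location", "scale", "orientation"),
                             n_perm = 10000L,
                             scheme = c("side_swap", "free"),
                             seed = 1L, k = NULL, add_one = FALSE,
                             squared = FALSE) {
  statistic <- match.arg(statistic)
  scheme <- match.arg(scheme)
  if (ncol(left) != ncol(right))
    stop("left and right have mismatched dimensionality", call. = FALSE)
  if (n_perm < 100L)
    warning("n_perm < 100 gives a very coarse p-value resolution")
  if (scheme == "side_swap" && nrow(left) != nrow(right))
    stop("scheme 'side_swap' requires subject-paired groups of equal size",
         call. = FALSE)
  if (statistic == "orientation") {
    if (is.null(k)) stop("the orientation statistic requires k", call. = FALSE)
    k <- as.integer(k)
  }

  red <- .reduce_rows(left, right)
  L <- red$left; R <- red$right
  nl <- nrow(L); nr <- nrow(R)

  stat_fun <- switch(statistic,
    location = function(a, b) location_d(a, b),
    scale = function(a, b) scale_d(a, b),
    orientation = function(a, b) {
      th <- principal_angles(.group_basis(a, k), .group_basis(b, k))
      projection_metric_set(th, squared = squared)
    })

  d_obs <- stat_fun(L, R)
  len <- length(d_obs)

  d_perm <- .with_seed(.derive_seed(seed, paste0("perm_", statistic)), {
    out <- matrix(NA_real_, n_perm, len)
    if (scheme == "side_swap") {
      for (b in seq_len(n_perm)) {
        sw <- stats::runif(nl) < 0.5
        Lp <- L; Rp <- R
        Lp[sw, ] <- R[sw, , drop = FALSE]
        Rp[sw, ] <- L[sw, , drop = FALSE]
        out[b, ] <- stat_fun(Lp, Rp)
      }
    } else {
      A <- rbind(L, R)
      for (b in seq_len(n_perm)) {
        idx <- sample.int(nl + nr)
        out[b, ] <- stat_fun(A[idx[seq_len(nl)], , drop = FALSE],
                             A[idx[nl + seq_len(nr)], , drop = FALSE])
      }
    }
    out
  })

  n_exceed <- colSums(d_perm >= matrix(d_obs, n_perm, len, byrow = TRUE))
  structure(list(d_observed = d_obs, d_perm = d_perm,
                 n_perm = as.integer(n_perm), n_exceed = n_exceed,
                 p_perm = perm_pvalue(n_exceed, n_perm, add_one),
                 statistic = statistic, scheme = scheme,
                 seed = as.integer(seed),
                 k = if (statistic == "orientation") k else NA_integer_),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s test, scheme = %s, N_perm = %d\n",
              x$statistic, x$scheme, x$n_perm))
  df <- data.frame(D_stat = round(x$d_observed, 4),
                   P_perm = round(x$p_perm, 4))
  rownames(df) <- if (length(x$d_observed) > 1L)
    paste0("D_", seq_along(x$d_observed)) else x$statistic
  print(df)
  invisible(x)
}
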