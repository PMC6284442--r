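# Mirroring, groupwise similarity alignment and surface correspondence.

#' Registration configuration
#'
#' Controls the iterative groupwise similarity alignment. The first three
#' parameters (`sigma`, `n_mean_points`, `lambda_tradeoff`) belong to the
#' Gaussian-mixture registration family used on raw surfaces in the original
#' workflow; they are accepted and logged for config compatibility and
#' provenance but drive no equation here — alignment operates on corresponded
#' points only (see the methods vignette).
#'
#' @param sigma Gaussian scale in mm (compatibility only).
#' @param n_mean_points mean-cloud point count (compatibility only).
#' @param lambda_tradeoff trade-off parameter (compatibility only).
#' @param max_iter maximum alignment iterations (>= 1).
#' @param tol relative change threshold on the total Procrustes distance.
#' @param allow_scaling remove scale by normalising every shape to unit
#'   centroid size (TRUE) or keep native scale (FALSE).
#' @return object of class `registration_config`.
#' @export
registration_config <- function(sigma = 3, n_mean_points = 2000L,
                                lambda_tradeoff = 1e-5,
                                max_iter = 100L, tol = 1e-9,
                                allow_scaling = TRUE) {
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  structure(list(sigma = sigma, n_mean_points = as.integer(n_mean_points),
                 lambda_tradeoff = lambda_tradeoff,
                 max_iter = as.integer(max_iter), tol = tol,
                 allow_scaling = isTRUE(allow_scaling)),
            class = "registration_config")
}

#' Mirror a shape in the sagittal plane
#'
#' Negates the first (x) coordinate; the mirror plane is fixed to x = 0 in the
#' input frame. Applying the operation twice returns the input exactly. For a
#' `shape_sample` with faces, triangle winding is reversed so surface
#' orientation stays consistent, and a `mirrored` attribute is toggled.
#'
#' @param x an n x 3 matrix or a [shape_sample()].
#' @return the mirrored object, same class as the input.
#' @export
mirror_sagittal <- function(x) UseMethod("mirror_sagittal")

#' @export
mirror_sagittal.default <- function(x) {
  .check_points(x)
  x[, 1L] <- -x[, 1L]
  x
}

#' @export
mirror_sagittal.shape_sample <- function(x) {
  x$points[, 1L] <- -x$points[, 1L]
  if (!is.null(x$faces)) x$faces <- x$faces[, c(1L, 3L, 2L), drop = FALSE]
  attr(x, "mirrored") <- !isTRUE(attr(x, "mirrored"))
  x
}

# Rotation into the principal axes of a centred configuration, with axis
# signs fixed by the third moment along each axis; det +1 enforced by
# flipping the axis whose third moment is smallest in magnitude.
.canonical_frame <- function(M) {
  ev <- eigen(crossprod(M), symmetric = TRUE)
  Q <- ev$vectors
  m3 <- colSums((M %*% Q)^3)
  sgn <- ifelse(m3 >= 0, 1, -1)
  Q <- Q %*% diag(sgn)
  if (det(Q) < 0) {
    j <- which.min(abs(m3))
    Q[, j] <- -Q[, j]
  }
  Q
}

# Optimal rotation (Kabsch, reflections excluded) aligning centred X to
# centred target M; returns the 3x3 rotation R such that X %*% R ~ M.
.kabsch <- function(X, M) {
  A <- crossprod(X, M)
  sv <- svd(A)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  sv$u %*% D %*% t(sv$v)
}

#' Groupwise similarity alignment of corresponded shapes
#'
#' Classical iterative groupwise (generalised Procrustes style) alignment:
#' every shape is centred on its centroid and, when `allow_scaling`, scaled to
#' unit centroid size; then the algorithm alternates between (1) computing the
#' mean shape, renormalised to unit centroid size, and (2) rotating each shape
#' onto the mean by the least-squares orthogonal (Kabsch) rotation with
#' determinant correction so no reflection can leak in. Iteration stops when
#' the relative change in the total Procrustes distance falls below `tol` or
#' `max_iter` is reached. All samples must already be in point-wise
#' correspondence (use [correspond_to_reference()] first for raw meshes).
#'
#' @param samples list of [shape_sample()] objects (or n x 3 matrices), all
#'   with the same number of points; at least 2.
#' @param config a [registration_config()].
#' @return an `aligned_dataset`: list with `data` (n_samples x 3n matrix of
#'   flattened aligned shapes), `mean_vector` (= column means of `data`),
#'   `meta` (sample sheet data.frame), `transforms` (per-sample centroid,
#'   scale and rotation applied), `objective` (per-iteration total Procrustes
#'   distance) and the `config`.
#' @export
groupwise_align <- function(samples, config = registration_config()) {
  if (length(samples) < 2L) stop("need at least 2 samples to align", call. = FALSE)
  is_ss <- vapply(samples, inherits, TRUE, "shape_sample")
  pts <- lapply(seq_along(samples), function(i)
    if (is_ss[i]) samples[[i]]$points else samples[[i]])
  np <- vapply(pts, nrow, 0L)
  if (length(unique(np)) != 1L)
    stop("all samples must have the same number of (corresponded) points",
         call. = FALSE)
  ids <- vapply(seq_along(samples), function(i)
    if (is_ss[i]) samples[[i]]$sample_id else sprintf("sample_%d", i), "")

  centroids <- lapply(pts, colMeans)
  cen <- Map(function(p, c) sweep(p, 2L, c), pts, centroids)
  for (i in seq_along(cen)) {
    if (qr(cen[[i]])$rank < 2L)
      stop(sprintf("degenerate (rank-deficient) point set in sample '%s'", ids[i]),
           call. = FALSE)
  }
  sizes <- vapply(cen, function(p) sqrt(sum(p^2)), 0)
  if (config$allow_scaling)
    cen <- Map(function(p, s) p / s, cen, sizes)

  rots <- rep(list(diag(3)), length(cen))
  aligned <- cen
  mean_sh <- Reduce(`+`, aligned) / length(aligned)
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(config$max_iter)) {
    mean_sh <- mean_sh / sqrt(sum(mean_sh^2))  # unit centroid size
    for (i in seq_along(cen)) {
      R <- .kabsch(cen[[i]], mean_sh)
      rots[[i]] <- R
      aligned[[i]] <- cen[[i]] %*% R
    }
    total <- sum(vapply(aligned, function(a) sum((a - mean_sh)^2), 0))
    obj <- c(obj, total)
    if (is.finite(prev) && abs(prev - total) <= config$tol * max(prev, .Machine$double.eps))
      break
    prev <- total
    mean_sh <- Reduce(`+`, aligned) / length(aligned)
  }

  # fix the global rotation gauge: rotate everything so the mean shape sits in
  # its principal axes, axis signs chosen by the sign of the third moment
  # (shapes are generically asymmetric, so this is stable), determinant +1
  Q <- .canonical_frame(Reduce(`+`, aligned) / length(aligned))
  aligned <- lapply(aligned, function(a) a %*% Q)
  rots <- lapply(rots, function(R) R %*% Q)

  data <- do.call(rbind, lapply(aligned, .vec_points))
  rownames(data) <- ids
  meta <- if (all(is_ss)) sample_sheet(samples) else
    data.frame(sample_id = ids, stringsAsFactors = FALSE)
  transforms <- lapply(seq_along(cen), function(i)
    list(sample_id = ids[i], centroid = centroids[[i]],
         scale = if (config$allow_scaling) 1 / sizes[i] else 1,
         rotation = rots[[i]]))
  structure(list(data = data, mean_vector = colMeans(data), meta = meta,
                 transforms = transforms, objective = obj, config = config),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf("<aligned_dataset> %d samples x %d points (%d iterations, objective %.3g)\n",
              nrow(x$data), ncol(x$data) / 3L, length(x$objective),
              utils::tail(x$objective, 1L)))
  invisible(x)
}

# Closest points on a triangle soup for a query matrix P (Ericson's
# closest-point-on-triangle, vectorised over query points per triangle).
# Ties between equidistant triangles break to the lowest triangle index.
.closest_on_mesh <- function(P, V, F) {
  n <- nrow(P)
  best_d2 <- rep(Inf, n)
  best_pt <- matrix(0, n, 3L)
  for (f in seq_len(nrow(F))) {
    a <- V[F[f, 1L], ]; b <- V[F[f, 2L], ]; c <- V[F[f, 3L], ]
    ab <- b - a; ac <- c - a
    ap <- sweep(P, 2L, a)
    d1 <- as.vector(ap %*% ab); d2 <- as.vector(ap %*% ac)
    bp <- sweep(P, 2L, b)
    d3 <- as.vector(bp %*% ab); d4 <- as.vector(bp %*% ac)
    cp <- sweep(P, 2L, c)
    d5 <- as.vector(cp %*% ab); d6 <- as.vector(cp %*% ac)
    va <- d3 * d6 - d5 * d4
    vb <- d5 * d2 - d1 * d6
    vc <- d1 * d4 - d3 * d2
    Q <- matrix(NA_real_, n, 3L)
    # vertex regions
    m <- d1 <= 0 & d2 <= 0
    if (any(m)) Q[m, ] <- matrix(a, sum(m), 3L, byrow = TRUE)
    m2 <- is.na(Q[, 1L]) & d3 >= 0 & d4 <= d3
    if (any(m2)) Q[m2, ] <- matrix(b, sum(m2), 3L, byrow = TRUE)
    m3 <- is.na(Q[, 1L]) & d6 >= 0 & d5 <= d6
    if (any(m3)) Q[m3, ] <- matrix(c, sum(m3), 3L, byrow = TRUE)
    # edge AB
    m4 <- is.na(Q[, 1L]) & vc <= 0 & d1 >= 0 & d3 <= 0
    if (any(m4)) {
      v <- d1[m4] / (d1[m4] - d3[m4])
      Q[m4, ] <- matrix(a, sum(m4), 3L, byrow = TRUE) + outer(as.vector(v), ab)
    }
    # edge AC
    m5 <- is.na(Q[, 1L]) & vb <= 0 & d2 >= 0 & d6 <= 0
    if (any(m5)) {
      w <- d2[m5] / (d2[m5] - d6[m5])
      Q[m5, ] <- matrix(a, sum(m5), 3L, byrow = TRUE) + outer(as.vector(w), ac)
    }
    # edge BC
    m6 <- is.na(Q[, 1L]) & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
    if (any(m6)) {
      w <- (d4[m6] - d3[m6]) / ((d4[m6] - d3[m6]) + (d5[m6] - d6[m6]))
      Q[m6, ] <- matrix(b, sum(m6), 3L, byrow = TRUE) + outer(as.vector(w), c - b)
    }
    # interior
    m7 <- is.na(Q[, 1L])
    if (any(m7)) {
      denom <- va[m7] + vb[m7] + vc[m7]
      v <- vb[m7] / denom; w <- vc[m7] / denom
      Q[m7, ] <- matrix(a, sum(m7), 3L, byrow = TRUE) +
        outer(as.vector(v), ab) + outer(as.vector(w), ac)
    }
    d2q <- rowSums((P - Q)^2)
    upd <- d2q < best_d2  # strict: equidistant later triangles lose
    if (any(upd)) {
      best_d2[upd] <- d2q[upd]
      best_pt[upd, ] <- Q[upd, , drop = FALSE]
    }
  }
  list(points = best_pt, dist = sqrt(pmax(best_d2, 0)))
}

#' Establish correspondence by closest point on a reference surface
#'
#' For each point of `reference_cloud`, the closest point on the sample's
#' triangulated surface is computed (point-to-triangle), yielding a
#' corresponded sample with one point per reference point. This is a
#' deterministic stand-in for dense-correspondence algorithms; ties between
#' equidistant triangles break to the lowest triangle index.
#'
#' @param mesh_sample a [shape_sample()] with faces.
#' @param reference_cloud n_ref x 3 matrix of reference points.
#' @return a [shape_sample()] with `n_ref` points (faces dropped), metadata
#'   copied from `mesh_sample`; attribute `correspondence_dist` carries the
#'   per-point distances moved.
#' @export
correspond_to_reference <- function(mesh_sample, reference_cloud) {
  if (!inherits(mesh_sample, "shape_sample") || is.null(mesh_sample$faces))
    stop("mesh_sample must be a shape_sample with faces; for landmark data use CSV mode and skip correspondence",
         call. = FALSE)
  .check_points(reference_cloud, "reference_cloud")
  res <- .closest_on_mesh(reference_cloud, mesh_sample$points, mesh_sample$faces)
  out <- shape_sample(points = res$points,
                      sample_id = mesh_sample$sample_id,
                      subject_id = mesh_sample$subject_id,
                      side = mesh_sample$side, sex = mesh_sample$sex,
                      age = mesh_sample$age)
  attr(out, "correspondence_dist") <- res$dist
  out
}
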