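# Internal helpers shared across modules.

# Flattening convention used everywhere: a shape with n points is stored as the
# length-3n vector (x1, y1, z1, x2, y2, z2, ...).
.vec_points <- function(points) as.vector(t(points))

.unvec_points <- function(v) {
  stopifnot(length(v) %% 3L == 0L)
  matrix(v, ncol = 3L, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

# Deterministic per-stage seed derivation from one top-level seed. Result is a
# strictly positive 32-bit integer so it can be fed to set.seed() anywhere.
.derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  s <- (abs(as.double(seed)) * 48271 + h * 7919 + 1) %% 2147483646
  as.integer(s) + 1L
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.check_points <- function(points, arg = "points") {
  if (!is.matrix(points) || ncol(points) != 3L)
    stop(sprintf("`%s` must be an n x 3 matrix", arg), call. = FALSE)
  if (!all(is.finite(points)))
    stop(sprintf("`%s` contains non-finite coordinates", arg), call. = FALSE)
  invisible(points)
}

.centroid_size <- function(points) {
  ctr <- colMeans(points)
  sqrt(sum(sweep(points, 2L, ctr)^2))
}

.pkg_version <- function() {
  as.character(utils::packageVersion("shapesym"))
}
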