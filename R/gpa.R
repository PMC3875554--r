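#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid (the standard size measure removed by Procrustes
#' scaling), in physical units, i.e. with the configuration's scale
#' factor applied. `root = FALSE` gives the literal summed-squares
#' reading without the square root.
#'
#' @param config a [landmark_config], or a coordinate matrix.
#' @param root take the square root (default) or return the raw summed
#'   squared distances.
#' @return A positive scalar.
#' @export
centroid_size <- function(config, root = TRUE) {
  if (inherits(config, "landmark_config")) {
    X <- config$points * config$scale
  } else {
    X <- as.matrix(config)
  }
  if (nrow(X) < 2) stop("centroid size needs at least 2 landmarks")
  Xc <- sweep(X, 2, colMeans(X))
  ss <- sum(Xc^2)
  if (ss == 0) stop("all landmarks coincide: centroid size is zero")
  if (root) sqrt(ss) else ss
}

center_unit <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  Xc / sqrt(sum(Xc^2))
}

# optimal rotation of X onto C, restricted to det = +1
rotate_onto <- function(X, C) {
  s <- svd(crossprod(X, C))
  R <- s$u %*% diag(c(1, sign(det(s$v %*% t(s$u))))) %*% t(s$v)
  X %*% R
}

#' Generalized Procrustes analysis with tangent projection
#'
#' Superimposes landmark configurations by generalized least squares:
#' each configuration is centered at the origin, scaled to unit centroid
#' size, and rotated (no reflections) to best fit the current consensus;
#' the consensus is then recomputed as the renormalized mean and the
#' process iterates until the consensus change is below `tol` (default
#' 1e-10) or `max_iter` iterations. Aligned configurations are finally
#' projected orthogonally onto the tangent space at the consensus by
#' removing their component along the consensus vector.
#'
#' @param configs list of [landmark_config] objects (equal landmark
#'   counts), or a list of coordinate matrices.
#' @param tol convergence tolerance on the consensus update.
#' @param max_iter maximum number of iterations (warning on
#'   non-convergence, current state returned).
#' @return An object of class `tangent_shapes`: `coords` (n x 2p matrix
#'   of tangent coordinates, all x then all y), `aligned` (list of
#'   aligned p x 2 configurations), `consensus` (p x 2, unit centroid
#'   size), `centroid_sizes` (pre-scaling, physical units),
#'   `specimen_ids`, `iterations`, `converged`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L) {
  if (length(configs) < 2) stop("GPA needs at least 2 configurations")
  is_cfg <- vapply(configs, inherits, logical(1), "landmark_config")
  mats <- lapply(configs, function(cf)
    if (inherits(cf, "landmark_config")) cf$points else as.matrix(cf))
  ids <- if (all(is_cfg))
    vapply(configs, `[[`, character(1), "specimen_id")
  else paste0("config_", seq_along(configs))
  p <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, integer(1)) != p))
    stop("configurations have unequal landmark counts")
  sizes <- vapply(seq_along(configs), function(i) {
    centroid_size(configs[[i]])
  }, numeric(1))
  A <- lapply(mats, center_unit)
  C <- A[[1]]
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    A <- lapply(A, rotate_onto, C = C)
    Cn <- center_unit(Reduce(`+`, A) / length(A))
    delta <- sqrt(sum((Cn - C)^2))
    C <- Cn
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter,
            " iterations; returning current state")
  A <- lapply(A, rotate_onto, C = C)
  # canonical orientation: principal axes of the consensus with the
  # major axis along y (the anatomical long-axis convention), proper
  # rotation only, sign fixed on the largest-|coordinate| entry --
  # makes the output invariant to arbitrary pre-rotation of the inputs
  V <- eigen(crossprod(C), symmetric = TRUE)$vectors[, 2:1]
  if (det(V) < 0) V[, 2] <- -V[, 2]
  if ((C %*% V)[which.max(abs(C %*% V))] < 0) V <- -V
  C <- C %*% V
  A <- lapply(A, function(X) X %*% V)
  cv <- as.vector(C)
  coords <- t(vapply(A, function(X) {
    x <- as.vector(X)
    x - sum(x * cv) * cv
  }, numeric(2 * p)))
  rownames(coords) <- ids
  structure(
    list(coords = coords, aligned = A, consensus = C,
         centroid_sizes = stats::setNames(sizes, ids),
         specimen_ids = ids, iterations = it, converged = converged),
    class = "tangent_shapes")
}

#' @export
print.tangent_shapes <- function(x, ...) {
  cat("GPA tangent shapes: ", nrow(x$coords), " specimens, ",
      nrow(x$consensus), " landmarks (", x$iterations,
      " iterations, ", if (x$converged) "converged" else "NOT converged",
      ")\n", sep = "")
  invisible(x)
}

#' Principal components of tangent shape coordinates
#'
#' Eigendecomposition of the covariance matrix of the tangent
#' coordinates. Eigenvalues below `1e-10` times the largest are treated
#' as zero; the retained dimension `k` is the smallest number of
#' components whose cumulative share of the non-zero total reaches
#' `threshold` (0.95 by default, matching the "at least 95% of overall
#' variation" retention rule).
#'
#' @param shapes a `tangent_shapes` object from [gpa()].
#' @param threshold proportion of variance to retain, in (0, 1].
#' @return An object of class `shape_pca`: `scores` (n x k), `loadings`
#'   (2p x k, orthonormal columns), `eigenvalues` (all non-zero, in
#'   decreasing order), `k`, `var_explained` (cumulative proportion at
#'   k), `center`.
#' @export
shape_pca <- function(shapes, threshold = 0.95) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("`threshold` must be a proportion in (0, 1]")
  X <- shapes$coords
  if (nrow(X) < 3) stop("PCA needs at least 3 specimens")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  eg <- eigen(stats::cov(Xc), symmetric = TRUE)
  keep <- eg$values > 1e-10 * max(eg$values)
  ev <- eg$values[keep]
  vec <- eg$vectors[, keep, drop = FALSE]
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= threshold - 1e-12)[1]
  scores <- Xc %*% vec[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(scores = scores, loadings = vec[, seq_len(k), drop = FALSE],
         eigenvalues = ev, k = k, var_explained = cum[k], center = ctr),
    class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("Shape PCA: ", length(x$eigenvalues), " non-zero eigenvalues; ",
      x$k, " components retained (",
      sprintf("%.1f%%", 100 * x$var_explained), " of variance)\n",
      sep = "")
  invisible(x)
}
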