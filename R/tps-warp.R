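#' Fit a 2-D thin-plate spline between two landmark configurations
#'
#' Solves the standard TPS interpolation system with kernel
#' `U(r) = r^2 log(r)` (with `U(0) = 0`): the transform maps every
#' reference landmark exactly onto its target, decomposes into an affine
#' part plus non-affine warping weights, and its bending energy is
#' `w' K w` summed over the x and y components (zero exactly when the
#' target is an affine image of the reference).
#'
#' @param reference,target coordinate matrices (same number of rows,
#'   reference with at least 3 non-collinear points) or
#'   [landmark_config] objects.
#' @return An object of class `tps_transform` with elements
#'   `reference`, `target`, `affine` (3 x 2: translation row then the
#'   2 x 2 linear part), `weights` (p x 2) and `bending_energy`.
#' @export
fit_tps <- function(reference, target) {
  R <- if (inherits(reference, "landmark_config")) reference$points else
    as.matrix(reference)
  T_ <- if (inherits(target, "landmark_config")) target$points else
    as.matrix(target)
  p <- nrow(R)
  if (nrow(T_) != p) stop("reference and target differ in landmark count")
  if (p < 3) stop("TPS needs at least 3 reference points")
  K <- tps_kernel_matrix(R, R)
  P <- cbind(1, R)
  if (qr(P)$rank < 3)
    stop("collinear reference landmarks: TPS system is singular")
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(T_, matrix(0, 3, 2))
  sol <- solve(L, rhs)
  w <- sol[seq_len(p), , drop = FALSE]
  a <- sol[p + 1:3, , drop = FALSE]
  be <- sum(diag(t(w) %*% K %*% w))
  structure(list(reference = R, target = T_, affine = a, weights = w,
                 bending_energy = max(0, be)),
            class = "tps_transform")
}

tps_kernel <- function(r2) ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))

tps_kernel_matrix <- function(A, B) {
  # U(|a-b|) = |a-b|^2 log |a-b| = 0.5 * r2 * log(r2)
  r2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  tps_kernel(pmax(r2, 0))
}

#' Evaluate a thin-plate-spline transform at arbitrary points
#'
#' @param transform a `tps_transform` from [fit_tps()].
#' @param points matrix of 2-D points.
#' @return Matrix of warped points, same dimensions.
#' @export
tps_evaluate <- function(transform, points) {
  pts <- as.matrix(points)
  U <- tps_kernel_matrix(pts, transform$reference)
  cbind(1, pts) %*% transform$affine + U %*% transform$weights
}

#' @export
print.tps_transform <- function(x, ...) {
  cat("Thin-plate spline on ", nrow(x$reference),
      " landmarks; bending energy ", format(x$bending_energy), "\n",
      sep = "")
  invisible(x)
}

#' Deformation grid for a thin-plate-spline transform
#'
#' Evaluates the TPS map on a regular grid covering the reference
#' bounding box (with a 10% margin) and returns the deformed grid lines
#' as polylines, with an optional display magnification applied as
#' `reference + magnify * (warped - reference)` (the convention used
#' for exaggerated shape-difference figures, e.g. 10x).
#'
#' @param transform a `tps_transform`.
#' @param density number of grid lines per side (>= 2).
#' @param magnify displacement magnification factor (default 1).
#' @param margin bounding-box margin as a fraction of the range.
#' @param resolution points per polyline.
#' @return A list with `polylines` (list of two-column matrices),
#'   `landmarks` (warped, magnified landmark positions) and the inputs
#'   echoed.
#' @export
warp_grid <- function(transform, density = 24L, magnify = 1,
                      margin = 0.1, resolution = 60L) {
  if (density < 2) stop("`density` must be at least 2")
  R <- transform$reference
  rng_x <- range(R[, 1]); rng_y <- range(R[, 2])
  pad_x <- margin * diff(rng_x); pad_y <- margin * diff(rng_y)
  xs <- seq(rng_x[1] - pad_x, rng_x[2] + pad_x, length.out = density)
  ys <- seq(rng_y[1] - pad_y, rng_y[2] + pad_y, length.out = density)
  fx <- seq(min(xs), max(xs), length.out = resolution)
  fy <- seq(min(ys), max(ys), length.out = resolution)
  warp1 <- function(pts) {
    w <- tps_evaluate(transform, pts)
    pts + magnify * (w - pts)
  }
  vert <- lapply(xs, function(x0) warp1(cbind(x0, fy)))
  horiz <- lapply(ys, function(y0) warp1(cbind(fx, y0)))
  lms <- warp1(R)
  list(polylines = c(vert, horiz), landmarks = lms,
       magnify = magnify, density = density)
}

#' Per-clade mean shapes along the canonical axes of a MANCOVA term
#'
#' Computes the canonical axes of a fitted MANCOVA term (eigenvectors of
#' `E^-1 H`), projects the response scores onto them, regresses the
#' tangent shape coordinates on the canonical scores, and returns the
#' predicted landmark configuration at each group's mean canonical
#' score: the average shape deformation attributable to that term, in
#' consensus units, ready for thin-plate-spline rendering against the
#' consensus.
#'
#' @param shapes the `tangent_shapes` object the scores derive from.
#' @param fit a `mancova_fit` containing the named term.
#' @param term term label, e.g. `"clade"`.
#' @param groups group label per specimen (defaults to the term's
#'   factor in the fit's data when unambiguous).
#' @param expand mirror-expand predicted unique-landmark configurations
#'   to full symmetric bodies (see [mirror_expand()]).
#' @return A list with `predicted` (named list of p x 2 configurations),
#'   `canonical_scores` (n x axes), `axes` (loadings in response space)
#'   and `consensus`.
#' @export
canonical_warp <- function(shapes, fit, term, groups = NULL,
                           expand = FALSE) {
  if (!term %in% names(fit$terms))
    stop("term '", term, "' not in the fitted model")
  if (is.null(groups)) {
    vars <- all.vars(stats::as.formula(paste("~", term)))
    fac <- vars[vapply(vars, function(v)
      is.factor(fit$data[[v]]) || is.character(fit$data[[v]]),
      logical(1))]
    if (length(fac) != 1)
      stop("supply `groups` explicitly for term '", term, "'")
    groups <- as.character(fit$data[[fac]])
  }
  groups <- as.character(groups)
  tr <- fit$terms[[term]]
  cons <- shapes$consensus
  labels <- sort(unique(groups))
  if (length(labels) < 2) {
    pred <- stats::setNames(rep(list(cons), length(labels)), labels)
    return(list(predicted = pred, canonical_scores = NULL, axes = NULL,
                consensus = cons))
  }
  eg <- eigen(solve(tr$E, tr$H))
  n_axes <- min(tr$df_h, fit$p, length(labels) - 1)
  axes <- Re(eg$vectors[, seq_len(n_axes), drop = FALSE])
  cs <- fit$responses %*% axes
  Z <- cbind(1, cs)
  coef <- qr.coef(qr(Z), shapes$coords)
  group_cs <- do.call(rbind, lapply(labels, function(g)
    colMeans(cs[groups == g, , drop = FALSE])))
  pred_dev <- cbind(1, group_cs) %*% coef
  grand <- colMeans(shapes$coords)
  pred <- lapply(seq_along(labels), function(i) {
    v <- as.vector(cons) + (pred_dev[i, ] - grand)
    cfg <- matrix(v, ncol = 2, dimnames = list(NULL, c("x", "y")))
    if (expand) mirror_expand(cfg) else cfg
  })
  names(pred) <- labels
  list(predicted = pred, canonical_scores = cs, axes = axes,
       consensus = cons)
}
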