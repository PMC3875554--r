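#' Bilateral landmark pairing for the 27-landmark body scheme
#'
#' The body plan is bilaterally symmetric, so all landmarks except the
#' pleotelson tip come in left/right homologous pairs. The default
#' pairing mirrors (1,25), (2,24), ..., (11,15), (12,14) and (26,27)
#' across the body midline, defined as the line through landmark 13
#' (pleotelson tip) and the midpoint of landmarks 26 and 27 (medial eye
#' margins). The 13 pairs plus the single midline point partition all 27
#' indices.
#'
#' @param pairs 2-column integer matrix of paired landmark indices.
#' @param midline index of the unpaired midline landmark.
#' @param axis_anterior indices of the two landmarks whose midpoint,
#'   together with the midline landmark, defines the symmetry axis.
#' @return An object of class `bilateral_pairing`.
#' @export
bilateral_pairing <- function(pairs, midline, axis_anterior) {
  pairs <- as.matrix(pairs)
  idx <- sort(c(as.integer(pairs), as.integer(midline)))
  if (any(duplicated(idx)))
    stop("pairing indices overlap")
  if (!identical(idx, seq_len(max(idx))))
    stop("pairs plus midline must partition 1..", max(idx))
  structure(list(pairs = pairs, midline = as.integer(midline),
                 axis_anterior = as.integer(axis_anterior),
                 n = max(idx)),
            class = "bilateral_pairing")
}

#' @rdname bilateral_pairing
#' @export
default_pairing <- function() {
  bilateral_pairing(
    pairs = cbind(c(1:12, 26), c(25:14, 27)),
    midline = 13L,
    axis_anterior = c(26L, 27L))
}

# permutation swapping each landmark with its bilateral partner
pairing_permutation <- function(pairing) {
  perm <- seq_len(pairing$n)
  perm[pairing$pairs[, 1]] <- pairing$pairs[, 2]
  perm[pairing$pairs[, 2]] <- pairing$pairs[, 1]
  perm
}

# reflect points across the line through `a` with unit direction `u`
reflect_across <- function(points, a, u) {
  nrm <- c(-u[2], u[1])
  d <- sweep(points, 2, a)
  d - 2 * (d %*% nrm) %*% rbind(nrm) + rep(a, each = nrow(points))
}

#' Symmetrize a bilateral landmark configuration
#'
#' Reflects the configuration across the body midline (the line through
#' the pleotelson tip and the midpoint of the medial eye landmarks),
#' swaps paired landmark labels, and averages the original with the
#' reflected-relabelled copy. The output is exactly mirror-symmetric
#' about its own midline, and the operation is idempotent.
#'
#' @param config a [landmark_config].
#' @param pairing a [bilateral_pairing]; defaults to the 27-landmark
#'   scheme.
#' @return A symmetrized [landmark_config].
#' @export
symmetrize <- function(config, pairing = default_pairing()) {
  X <- config$points
  if (nrow(X) != pairing$n)
    stop("configuration has ", nrow(X), " landmarks; pairing expects ",
         pairing$n)
  a <- X[pairing$midline, ]
  m <- colMeans(X[pairing$axis_anterior, , drop = FALSE])
  v <- m - a
  len <- sqrt(sum(v^2))
  if (len < 1e-12 * max(1, max(abs(X))))
    stop("degenerate geometry: midline landmark coincides with the ",
         "eye midpoint, symmetry axis undefined")
  u <- v / len
  refl <- reflect_across(X, a, u)
  perm <- pairing_permutation(pairing)
  out <- (X + refl[perm, , drop = FALSE]) / 2
  landmark_config(out, specimen_id = config$specimen_id,
                  scale = config$scale)
}

#' Indices of the unique landmarks under a bilateral pairing
#'
#' One representative per pair (the first member) plus the midline
#' landmark, in ascending index order. For the default 27-landmark
#' scheme this is landmarks 1--13 and 26 (14 points).
#'
#' @param pairing a [bilateral_pairing].
#' @return Integer vector of landmark indices.
#' @export
unique_indices <- function(pairing = default_pairing()) {
  sort(c(pairing$pairs[, 1], pairing$midline))
}

#' Reduce a symmetrized configuration to its unique landmarks
#'
#' After reflect-and-average symmetrization each landmark pair carries a
#' single independent position, so downstream superimposition and
#' ordination operate on the unique landmarks only (one per pair plus
#' the midline point). This is what gives a symmetrized 27-landmark
#' dataset exactly 2*14 - 4 = 24 shape dimensions.
#'
#' @param config a symmetrized [landmark_config].
#' @param pairing a [bilateral_pairing].
#' @return A [landmark_config] with one landmark per pair plus the
#'   midline point.
#' @export
unique_landmarks <- function(config, pairing = default_pairing()) {
  landmark_config(config$points[unique_indices(pairing), , drop = FALSE],
                  specimen_id = config$specimen_id, scale = config$scale)
}

#' Expand a unique-landmark configuration to a full symmetric body
#'
#' Inverse of [unique_landmarks()] for visualization: the unique
#' configuration is rigidly aligned (rotation + translation + scale,
#' ordinary Procrustes) onto the template's unique half, whose symmetry
#' axis is the y axis, then mirrored across that axis. The midline
#' landmark is snapped onto the axis. The reconstruction is exact when
#' the unique points came from a symmetric configuration in template
#' pose; otherwise it is the nearest symmetric rendering and is intended
#' for thin-plate-spline display, not for statistics.
#'
#' @param points matrix of unique-landmark coordinates (rows in the
#'   order given by [unique_indices()]), or a [landmark_config].
#' @param pairing a [bilateral_pairing].
#' @param reference unique-landmark reference whose symmetry axis is the
#'   y axis; defaults to the template's unique half.
#' @return A full symmetric coordinate matrix (`pairing$n` rows).
#' @export
mirror_expand <- function(points, pairing = default_pairing(),
                          reference = NULL) {
  if (inherits(points, "landmark_config")) points <- points$points
  points <- as.matrix(points)
  uidx <- unique_indices(pairing)
  if (nrow(points) != length(uidx))
    stop("expected ", length(uidx), " unique landmarks, got ",
         nrow(points))
  if (is.null(reference))
    reference <- make_template()$points[uidx, , drop = FALSE]
  al <- align_ls(points, reference)
  full <- matrix(NA_real_, pairing$n, 2,
                 dimnames = list(NULL, c("x", "y")))
  full[uidx, ] <- al
  partner <- pairing_permutation(pairing)
  mir <- cbind(-al[, 1], al[, 2])
  full[partner[uidx], ] <- mir
  full[pairing$midline, 1] <- 0
  full
}

# least-squares similarity alignment of X onto Y (rotation only, det +1)
align_ls <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  s <- svd(crossprod(Xc, Yc))
  R <- s$u %*% diag(c(1, sign(det(s$v %*% t(s$u))))) %*% t(s$v)
  Xr <- Xc %*% R
  b <- sum(Xr * Yc) / sum(Xc^2)
  sweep(b * Xr, 2, cy, `+`)
}
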