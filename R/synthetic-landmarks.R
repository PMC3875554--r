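#' Procedural 27-landmark body template
#'
#' A bilaterally symmetric template respecting the landmark semantics of
#' the digitizing scheme: an ellipse-like dorsal outline with the
#' anterior (head) end up. Landmarks 1/25 are the posterior eye margins
#' at the body perimeter, 2--11 (left) and 24--15 (right) the
#' posterior-most points of the body segments, 12/14 the lateral
#' posterior pleotelson points, 13 the posterior-most pleotelson tip on
#' the midline, and 26/27 the medial eye margins, medial to 1/25. The
#' symmetry axis is the y axis; pairs mirror exactly and landmark 13 is
#' the lowest point.
#'
#' The template is procedural (a parameterized outline), not traced from
#' any specimen; only its symmetry and ordering semantics are
#' contractual.
#'
#' @return A [landmark_config] named `"template"` with 27 landmarks.
#' @export
make_template <- function() {
  half_width <- function(y) 0.52 * sqrt(pmax(0, 1 - (y / 1.05)^2))
  seg_y <- seq(0.55, -0.72, length.out = 10)   # segment posterior tips
  pts <- matrix(NA_real_, 27, 2)
  pts[1, ]  <- c(-0.34, 0.78)                   # left eye, perimeter
  pts[25, ] <- c(0.34, 0.78)
  for (j in 1:10) {                             # segments, left 2..11
    w <- half_width(seg_y[j])
    pts[1 + j, ]  <- c(-w, seg_y[j])
    pts[25 - j, ] <- c(w, seg_y[j])
  }
  pts[12, ] <- c(-0.16, -0.88)                  # pleotelson laterals
  pts[14, ] <- c(0.16, -0.88)
  pts[13, ] <- c(0, -1.00)                      # pleotelson tip
  pts[26, ] <- c(-0.12, 0.80)                   # medial eye margins
  pts[27, ] <- c(0.12, 0.80)
  landmark_config(pts, specimen_id = "template", scale = 1)
}

#' Parameters for the landmark-data simulator
#'
#' Defines the known structure injected into simulated specimens:
#' per-clade mean-shape effects (mid-body width multiplier, inter-eye
#' gap offset, pleotelson protrusion offset, all in template units), a
#' sex effect widening the anterior segments of gravid females, an
#' allometric elongation proportional to centered log size, log-normal
#' size variation, isotropic digitization noise and one-sided
#' left/right asymmetry noise.
#'
#' Defaults emulate the study conditions of the motivating system: 84
#' specimens in three clades (totals 15/35/34) spread across the three
#' sex categories, clade effects of a few percent of body size, and
#' digitization noise an order of magnitude smaller.
#'
#' @param n_per_group specimens per clade x sex cell: a single count, or
#'   a clade x sex matrix (rownames = clade labels, colnames = M, F, J).
#' @param clade_effects named list, one entry per clade, each a list
#'   with `mid_body_width` (multiplier), `inter_eye_gap` (offset) and
#'   `pleotelson_protrusion` (offset).
#' @param sex_effect anterior-width multiplier increment applied to
#'   category F.
#' @param allometry_coeff elongation change per unit centered log size.
#' @param size_log_mean,size_log_sd log-normal size distribution
#'   parameters (size in mm per template unit).
#' @param noise_sd isotropic landmark noise sd, template units.
#' @param asym_sd left-right asymmetry noise sd (applied to one body
#'   side only), template units.
#' @param bio_sd amplitude of smooth per-specimen biological shape
#'   variation (template units). Individual variation in real
#'   organisms is spatially integrated, not independent per landmark;
#'   it is emulated as random coefficients on low-order polynomial
#'   deformation fields with geometrically decaying amplitudes
#'   (`bio_decay` per mode), which gives the decaying eigen-spectrum
#'   real datasets show. Set to 0 for pure landmark noise.
#' @param bio_decay per-mode geometric decay of the field amplitudes.
#' @param seed RNG seed.
#' @return An object of class `morpho_sim_params`.
#' @export
morpho_sim_params <- function(
    n_per_group = NULL,
    clade_effects = list(
      D = list(mid_body_width = 0.988, inter_eye_gap = -0.008,
               pleotelson_protrusion = 0.000),
      E = list(mid_body_width = 1.006, inter_eye_gap = 0.008,
               pleotelson_protrusion = 0.010),
      F = list(mid_body_width = 1.010, inter_eye_gap = 0.016,
               pleotelson_protrusion = -0.004)),
    sex_effect = 0.05,
    allometry_coeff = 0.15,
    size_log_mean = log(10),
    size_log_sd = 0.25,
    noise_sd = 0.005,
    asym_sd = 0.01,
    bio_sd = 0.04,
    bio_decay = 0.7,
    seed = 1L) {
  clades <- names(clade_effects)
  if (is.null(clades) || anyDuplicated(clades))
    stop("`clade_effects` must be a named list with distinct clade labels")
  sexes <- c("M", "F", "J")
  if (is.null(n_per_group)) {
    # near-even split of clade totals 15/35/34 across sex categories
    totals <- if (length(clades) == 3) c(15L, 35L, 34L) else
      rep(10L, length(clades))
    n_per_group <- t(vapply(totals, function(tt) {
      base <- tt %/% 3L
      extra <- tt %% 3L
      base + as.integer(seq_len(3) <= extra)
    }, integer(3)))
    dimnames(n_per_group) <- list(clades, sexes)
  }
  if (length(n_per_group) == 1L)
    n_per_group <- matrix(as.integer(n_per_group), length(clades), 3,
                          dimnames = list(clades, sexes))
  n_per_group <- as.matrix(n_per_group)
  if (!identical(dim(n_per_group), c(length(clades), 3L)))
    stop("`n_per_group` must be scalar or a clade x sex matrix")
  if (any(n_per_group < 1)) stop("n_per_group must be >= 1")
  for (nm in c("sex_effect", "allometry_coeff")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a finite scalar")
  }
  for (nm in c("size_log_sd", "noise_sd", "asym_sd", "bio_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("`", nm, "` must be a non-negative scalar")
  }
  structure(list(n_per_group = n_per_group, clade_effects = clade_effects,
                 sex_effect = sex_effect, allometry_coeff = allometry_coeff,
                 size_log_mean = size_log_mean, size_log_sd = size_log_sd,
                 noise_sd = noise_sd, asym_sd = asym_sd,
                 bio_sd = bio_sd, bio_decay = bio_decay,
                 seed = as.integer(seed)),
            class = "morpho_sim_params")
}

# landmark index groups the effects act on (left side + partners)
.mid_body_lms <- function(pairing) {
  # segment landmarks 4..9 and their partners: the mid-body
  pr <- pairing$pairs
  sel <- pr[, 1] %in% 4:9
  c(pr[sel, 1], pr[sel, 2])
}
.anterior_lms <- function(pairing) {
  pr <- pairing$pairs
  sel <- pr[, 1] %in% c(1, 2, 3)
  c(pr[sel, 1], pr[sel, 2])
}

# smooth non-affine polynomial deformation fields over the template,
# unit RMS; one 27 x 2 displacement matrix per (monomial, direction)
# mode. Degree-1 (affine) variation is excluded: aspect and width
# variation are modeled explicitly by the allometric and clade terms.
.bio_fields <- function(tmpl) {
  degs <- expand.grid(i = 0:3, j = 0:3)
  degs <- degs[degs$i + degs$j >= 2 & degs$i + degs$j <= 3, ]
  degs <- degs[order(degs$i + degs$j), ]
  fields <- list()
  for (r in seq_len(nrow(degs))) {
    v <- tmpl[, 1]^degs$i[r] * tmpl[, 2]^degs$j[r]
    v <- v / sqrt(mean(v^2))
    zero <- numeric(nrow(tmpl))
    fields[[length(fields) + 1L]] <- cbind(v, zero)
    fields[[length(fields) + 1L]] <- cbind(zero, v)
  }
  fields
}

#' Simulate a landmark dataset with known structure
#'
#' Deforms the procedural template per specimen: the clade effect
#' (mid-body width multiplier on the x of mid-body segment landmarks,
#' inter-eye gap offset on the medial eye landmarks, pleotelson
#' protrusion offset on the tip), the sex effect (anterior segment
#' widening for category F), allometric elongation proportional to
#' centered log size, isotropic Gaussian noise on all landmarks, and
#' independent asymmetry noise on the left body side only (so
#' symmetrization has real work to do). Coordinates are finally scaled
#' by the specimen's drawn size. The same seed reproduces the dataset
#' exactly.
#'
#' @param params a [morpho_sim_params] object.
#' @return A list with `dataset` (a `morpho_dataset`), and `truth`
#'   (data frame of specimen id, clade, sex, true size).
#' @export
simulate_landmarks <- function(params) {
  if (!inherits(params, "morpho_sim_params"))
    stop("`params` must be created by morpho_sim_params()")
  pairing <- default_pairing()
  tmpl <- make_template()$points
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)
  clades <- rownames(params$n_per_group)
  sexes <- colnames(params$n_per_group)
  mid_idx <- .mid_body_lms(pairing)
  ant_idx <- .anterior_lms(pairing)
  fields <- .bio_fields(tmpl)
  field_sd <- params$bio_sd * params$bio_decay^(seq_along(fields) - 1)
  configs <- list()
  meta <- list()
  sid <- 0L
  for (cl in clades) {
    eff <- params$clade_effects[[cl]]
    for (sx in sexes) {
      for (r in seq_len(params$n_per_group[cl, sx])) {
        sid <- sid + 1L
        id <- sprintf("S%03d", sid)
        X <- tmpl
        X[mid_idx, 1] <- X[mid_idx, 1] * eff$mid_body_width
        X[26, 1] <- X[26, 1] - eff$inter_eye_gap / 2
        X[27, 1] <- X[27, 1] + eff$inter_eye_gap / 2
        X[13, 2] <- X[13, 2] - eff$pleotelson_protrusion
        if (sx == "F")
          X[ant_idx, 1] <- X[ant_idx, 1] * (1 + params$sex_effect)
        logsize <- stats::rnorm(1, params$size_log_mean,
                                params$size_log_sd)
        elong <- 1 + params$allometry_coeff *
          (logsize - params$size_log_mean)
        X[, 2] <- X[, 2] * elong
        X[, 1] <- X[, 1] / sqrt(elong)   # near-area-preserving
        if (params$bio_sd > 0) {
          a <- stats::rnorm(length(fields), 0, field_sd)
          for (mi in seq_along(fields))
            X <- X + a[mi] * fields[[mi]]
        }
        X <- X + matrix(stats::rnorm(length(X), 0, params$noise_sd),
                        nrow(X), 2)
        left <- c(pairing$pairs[, 1])
        X[left, ] <- X[left, ] +
          matrix(stats::rnorm(2 * length(left), 0, params$asym_sd),
                 length(left), 2)
        size <- exp(logsize)
        configs[[sid]] <- landmark_config(X * size, specimen_id = id)
        meta[[sid]] <- data.frame(
          specimen_id = id,
          locality = paste0(cl, match(sx, sexes)),
          clade = cl, sex = sx, size = size,
          stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, meta)
  dataset <- assemble_dataset(configs,
                              meta[c("specimen_id", "locality",
                                     "clade", "sex")])
  list(dataset = dataset,
       truth = meta[c("specimen_id", "clade", "sex", "size")])
}
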