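test_that("symmetrize fixes symmetric inputs and is idempotent", {
  tmpl <- make_template()
  sym <- symmetrize(tmpl)
  expect_equal(sym$points, tmpl$points, tolerance = 1e-12)

  # arbitrary configurations: output invariant under re-symmetrization
  for (seed in 1:5) {
    set.seed(seed)
    cfg <- landmark_config(tmpl$points + matrix(rnorm(54, 0, 0.05),
                                                27, 2), "x")
    s1 <- symmetrize(cfg)
    s2 <- symmetrize(s1)
    expect_lt(max(abs(s2$points - s1$points)), 1e-9)
  }
})

test_that("noise on one landmark spreads as the mirror-average", {
  tmpl <- make_template()$points
  delta <- c(0.03, -0.02)
  noisy <- tmpl
  noisy[2, ] <- noisy[2, ] + delta
  out <- symmetrize(landmark_config(noisy, "n"))$points
  # axis is the y axis (landmarks 13, 26, 27 untouched): LM2 keeps
  # half of delta, LM24 receives the mirrored half
  expect_equal(out[2, ] - tmpl[2, ],
               c(delta[1] / 2, delta[2] / 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(out[24, ] - tmpl[24, ],
               c(-delta[1] / 2, delta[2] / 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  untouched <- setdiff(1:27, c(2, 24))
  expect_equal(out[untouched, ], tmpl[untouched, ], tolerance = 1e-12)
})

test_that("degenerate symmetry axis is refused", {
  pts <- make_template()$points
  pts[13, ] <- colMeans(pts[c(26, 27), ])
  expect_error(symmetrize(landmark_config(pts, "bad")), "degenerate")
})

test_that("centroid size: hand value, homogeneity, invariances", {
  square <- matrix(c(0, 1, 1, 0, 0, 0, 1, 1), 4, 2)
  expect_equal(centroid_size(square), sqrt(2), tolerance = 1e-12)
  expect_equal(centroid_size(square, root = FALSE), 2)
  expect_equal(centroid_size(square * 3.7), 3.7 * sqrt(2))
  expect_equal(centroid_size(sweep(square, 2, c(5, -2), `+`)), sqrt(2))
  # scale field enters the physical size
  expect_equal(centroid_size(landmark_config(square, "s", scale = 2)),
               2 * sqrt(2))
  expect_error(centroid_size(matrix(1, 4, 2)), "coincide")
})

test_that("GPA collapses similarity-transformed copies to one point", {
  X <- random_configs(1, 14, seed = 3)[[1]]
  copies <- lapply(1:4, function(i) jitter_similarity(X, seed = i))
  sh <- gpa(copies)
  d <- dist(sh$coords)
  expect_lt(max(d), 1e-9)
  # all tangent residuals are zero: every copy is the consensus
  for (A in sh$aligned)
    expect_lt(max(abs(A - sh$consensus)), 1e-9)
})

test_that("GPA is invariant to arbitrary similarity pre-transforms", {
  configs <- random_configs(8, 14, seed = 5)
  sh1 <- gpa(configs)
  moved <- lapply(seq_along(configs), function(i)
    jitter_similarity(configs[[i]], seed = 100 + i))
  sh2 <- gpa(moved)
  expect_equal(sh2$coords, sh1$coords, tolerance = 1e-8,
               ignore_attr = TRUE)
  # consensus equals the (renormalized) mean of aligned configurations
  m <- Reduce(`+`, sh1$aligned) / length(sh1$aligned)
  m <- scale(m, scale = FALSE)
  expect_equal(sh1$consensus, m / sqrt(sum(m^2)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # aligned configurations are centered with unit centroid size
  for (A in sh1$aligned) {
    expect_lt(max(abs(colMeans(A))), 1e-9)
    expect_equal(sum(scale(A, scale = FALSE)^2), 1, tolerance = 1e-9)
  }
})

test_that("GPA matches an independent direct optimizer over rotations", {
  configs <- random_configs(4, 6, seed = 9)
  sh <- gpa(configs)
  ours <- sum(vapply(sh$aligned, function(A)
    sum((A - sh$consensus)^2), numeric(1)))
  pre <- lapply(configs, function(X) {
    Xc <- scale(X, scale = FALSE)
    Xc / sqrt(sum(Xc^2))
  })
  obj <- function(th) {
    rot <- lapply(seq_along(pre), function(i) {
      R <- matrix(c(cos(th[i]), sin(th[i]), -sin(th[i]), cos(th[i])),
                  2, 2)
      pre[[i]] %*% R
    })
    mu <- Reduce(`+`, rot) / length(rot)
    mu <- mu / sqrt(sum(scale(mu, scale = FALSE)^2))
    sum(vapply(rot, function(A) sum((A - mu)^2), numeric(1)))
  }
  set.seed(42)
  best <- min(vapply(1:10, function(s)
    stats::optim(runif(length(pre), 0, 2 * pi), obj,
                 method = "BFGS")$value, numeric(1)))
  expect_equal(ours, best, tolerance = 1e-6)
})

test_that("two-configuration alignment agrees with vegan::procrustes", {
  skip_if_not_installed("vegan")
  A <- random_configs(1, 10, seed = 21)[[1]]
  B <- jitter_similarity(A + matrix(rnorm(20, 0, 0.1), 10, 2),
                         seed = 22)
  sh <- gpa(list(A, B))
  # at the two-configuration GPA optimum the aligned pair is also
  # mutually optimally rotated, so their squared distance must equal
  # vegan's one-onto-the-other Procrustes residual
  ours <- sum((sh$aligned[[1]] - sh$aligned[[2]])^2)
  pr <- vegan::procrustes(
    scale(A, scale = FALSE) / sqrt(sum(scale(A, scale = FALSE)^2)),
    scale(B, scale = FALSE) / sqrt(sum(scale(B, scale = FALSE)^2)),
    scale = FALSE, symmetric = FALSE)
  theirs <- sum((pr$Yrot - pr$X)^2)
  expect_equal(ours, theirs, tolerance = 1e-8)
})

test_that("PCA retention rule and rank behave as specified", {
  sim <- simulate_landmarks(morpho_sim_params(seed = 2))
  sh <- gpa(lapply(lapply(sim$dataset$configs, symmetrize),
                   unique_landmarks))
  pc_all <- shape_pca(sh, threshold = 1)
  expect_equal(length(pc_all$eigenvalues), 24)
  expect_equal(pc_all$k, length(pc_all$eigenvalues))
  pc <- shape_pca(sh, threshold = 0.95)
  expect_gte(pc$var_explained, 0.95)
  cum <- cumsum(pc_all$eigenvalues) / sum(pc_all$eigenvalues)
  expect_true(pc$k == which(cum >= 0.95)[1])
  # loadings orthonormal, scores centered
  expect_equal(crossprod(pc$loadings), diag(pc$k), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(pc$scores))), 1e-9)
  # retained subspace reproduces the covariance it spans
  S <- cov(sweep(sh$coords, 2, colMeans(sh$coords)))
  S_hat <- pc$loadings %*% diag(pc$eigenvalues[seq_len(pc$k)]) %*%
    t(pc$loadings)
  P <- pc$loadings %*% t(pc$loadings)
  expect_equal(P %*% S %*% P, S_hat, tolerance = 1e-8)
  expect_error(shape_pca(sh, threshold = 0), "proportion")
})

test_that("variance on a single direction gives k = 1", {
  sh <- gpa(random_configs(10, 8, seed = 4))
  v <- rnorm(16); v <- v / sqrt(sum(v^2))
  fake <- sh
  fake$coords <- outer(rnorm(10), v)
  pc <- shape_pca(fake, threshold = 0.95)
  expect_equal(pc$k, 1)
  expect_equal(pc$var_explained, 1.0)
})
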