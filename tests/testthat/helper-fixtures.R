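# Shared fixture builders; everything is generated in code.

# a small set of random 2-D configurations (list of matrices)
random_configs <- function(n, p, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(rnorm(2 * p), p, 2))
}

# apply a random similarity transform (rotation, scale, translation)
jitter_similarity <- function(X, seed = 1) {
  set.seed(seed)
  th <- runif(1, 0, 2 * pi)
  s <- exp(rnorm(1, 0, 0.3))
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  s * X %*% R + matrix(rnorm(2), nrow(X), 2, byrow = TRUE)
}

# a tiny well-conditioned MANCOVA design with known group structure
sim_mancova_data <- function(n_per = 10, p = 2, effect = 1, seed = 1,
                             groups = c("a", "b")) {
  set.seed(seed)
  g <- factor(rep(groups, each = n_per))
  mu <- outer(as.integer(g), seq_len(p)) * effect / p
  Y <- mu + matrix(rnorm(length(g) * p), ncol = p)
  size <- rnorm(length(g), 10, 1)
  list(Y = Y, data = data.frame(clade = g,
                                sex = factor(rep(c("M", "F"),
                                                 length.out = length(g))),
                                size = size))
}

# brute-force Type III H per term: E(reduced, term dropped) - E(full),
# both fitted by lm() under sum-to-zero contrasts
oracle_type3 <- function(Y, data, formula, term) {
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  labels <- attr(terms(formula), "term.labels")
  full <- lm(stats::reformulate(labels, response = quote(Y)),
             data = cbind(data, Y = I(Y)))
  red <- lm(stats::reformulate(setdiff(labels, term),
                               response = quote(Y)),
            data = cbind(data, Y = I(Y)))
  E <- crossprod(residuals(full))
  H <- crossprod(residuals(red)) - E
  list(H = H, E = E, lambda = det(E) / det(E + H),
       df_e = df.residual(full))
}

# from-scratch leave-one-out QDA oracle (equal priors), independent of
# the package implementation
oracle_qda_loocv <- function(x, groups) {
  labels <- sort(unique(groups))
  pred <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    sc <- sapply(labels, function(g) {
      idx <- which(groups == g & seq_len(nrow(x)) != i)
      m <- colMeans(x[idx, , drop = FALSE])
      S <- cov(x[idx, , drop = FALSE])
      -0.5 * determinant(S)$modulus[1] -
        0.5 * mahalanobis(x[i, ], m, S)
    })
    pred[i] <- labels[which.max(sc)]
  }
  pred
}

# tiny alignment fixture
tiny_alignment <- function() {
  seq_alignment(c(s1 = "ACGTACGTAC", s2 = "ACGTACGTAC",
                  s3 = "ACGAACGTAC", s4 = "ACGAACGTTC"),
                groups = c(s1 = "g1", s2 = "g1", s3 = "g2", s4 = "g2"))
}
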