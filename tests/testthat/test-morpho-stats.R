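test_that("Rao df formulas reproduce the printed design df exactly", {
  # n = 84, p = 11, lineage(3) + sex(3) + size + two-way interactions:
  # 14 model columns, error df 70
  df_e <- 70; p <- 11
  terms <- list(lineage = 2, sex = 2, size = 1, `lineage:sex` = 4,
                `sex:size` = 2, `lineage:size` = 2)
  want <- list(c(22, 120), c(22, 120), c(11, 60), c(44, 231.5),
               c(22, 120), c(22, 120))
  for (i in seq_along(terms)) {
    r <- rao_wilks(0.5, p, terms[[i]], df_e)
    expect_equal(r$df1, want[[i]][1], info = names(terms)[i])
    expect_equal(round(r$df2, 1), want[[i]][2], info = names(terms)[i])
  }
})

test_that("Wilks lambda matches a model-comparison brute-force oracle", {
  set.seed(31)
  n <- 20
  data <- data.frame(
    clade = factor(rep(c("a", "b"), each = n / 2)),
    size = rnorm(n, 10, 1))
  Y <- matrix(rnorm(n * 2), n, 2) +
    outer(as.integer(data$clade), c(1, -0.5))
  fit <- fit_mancova(Y, data, ~ clade + size)
  for (tm in c("clade", "size")) {
    orc <- oracle_type3(Y, data, ~ clade + size, tm)
    expect_equal(fit$terms[[tm]]$H, orc$H, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit$terms[[tm]]$E, orc$E, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit$terms[[tm]]$wilks_lambda, orc$lambda,
                 tolerance = 1e-8)
    expect_equal(fit$df_e, orc$df_e)
  }
})

test_that("multivariate tests agree with car::Manova Type III SSCPs", {
  skip_if_not_installed("car")
  sim <- sim_mancova_data(n_per = 12, p = 3, effect = 1.5, seed = 8,
                          groups = c("a", "b", "c"))
  Y <- sim$Y; data <- sim$data
  fit <- fit_mancova(Y, data, ~ clade + sex + size)
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  mod <- lm(Y ~ clade + sex + size, data = data)
  mv <- car::Manova(mod, type = 3)
  for (tm in c("clade", "sex", "size")) {
    expect_equal(fit$terms[[tm]]$H, mv$SSP[[tm]], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit$terms[[tm]]$E, mv$SSPE, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("p = 1, df_h = 1 reduces to the univariate partial F test", {
  set.seed(5)
  n <- 30
  data <- data.frame(clade = factor(rep(c("a", "b"), each = n / 2)),
                     size = rnorm(n))
  y <- rnorm(n) + as.integer(data$clade) + 0.3 * data$size
  fit <- fit_mancova(matrix(y), data, ~ clade + size)
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  uni <- anova(lm(y ~ size + clade, data = data))  # clade last: partial
  expect_equal(fit$terms$clade$F, uni["clade", "F value"],
               tolerance = 1e-10)
  expect_equal(fit$terms$clade$p_value, uni["clade", "Pr(>F)"],
               tolerance = 1e-10)
  expect_equal(fit$terms$clade$df1, 1)
  expect_equal(fit$terms$clade$df2, n - 3)
})

test_that("rank-deficient designs and singular E are refused", {
  set.seed(1)
  data <- data.frame(clade = factor(rep(c("a", "b"), 6)),
                     size = rnorm(12))
  data$dup <- as.numeric(data$clade == "a")  # aliased with clade
  Y <- matrix(rnorm(24), 12, 2)
  expect_error(fit_mancova(Y, data, ~ clade + dup), "aliased")
  # p >= df_e makes E unusable
  Yw <- matrix(rnorm(12 * 10), 12, 10)
  expect_error(fit_mancova(Yw, data, ~ clade + size), "fewer PCs")
})

test_that("hierarchical pruning removes null interactions, keeps real ones", {
  set.seed(15)
  n_per <- 20
  g <- expand.grid(clade = c("a", "b"), sex = c("M", "F"))
  data <- data.frame(clade = factor(rep(g$clade, each = n_per)),
                     sex = factor(rep(g$sex, each = n_per)),
                     size = rnorm(4 * n_per, 10, 1))
  base <- cbind(2 * (data$clade == "a"), 1.5 * (data$sex == "F"),
                0.3 * data$size)
  Y_null <- base %*% matrix(rnorm(6, 0, 1), 3, 2) +
    matrix(rnorm(2 * nrow(data)), ncol = 2)
  pr <- prune_and_refit(Y_null, data, ~ clade * sex * size)
  expect_setequal(pr$fit$table$term, c("clade", "sex", "size"))
  expect_true(all(c("clade:sex:size") %in% pr$removed))

  # strong clade x sex interaction: term must be retained
  inter <- 3 * (data$clade == "a") * (data$sex == "F")
  Y_int <- Y_null + cbind(inter, -inter)
  pr2 <- prune_and_refit(Y_int, data, ~ clade * sex * size)
  expect_true("clade:sex" %in% pr2$fit$table$term)
  # a retained higher-order term protects its constituents
  expect_false(any(c("clade", "sex") %in% pr2$removed))
})

test_that("three-way term significant means nothing is pruned", {
  set.seed(77)
  n_per <- 15
  g <- expand.grid(clade = c("a", "b"), sex = c("M", "F"))
  data <- data.frame(clade = factor(rep(g$clade, each = n_per)),
                     sex = factor(rep(g$sex, each = n_per)),
                     size = rnorm(4 * n_per, 0, 1))
  tri <- 4 * (data$clade == "a") * (data$sex == "F") * data$size
  Y <- cbind(tri, -0.5 * tri) + matrix(rnorm(8 * n_per), ncol = 2)
  pr <- prune_and_refit(Y, data, ~ clade * sex * size)
  expect_length(pr$removed, 0)
  expect_true("clade:sex:size" %in% pr$fit$table$term)
})

test_that("residualization removes nuisance structure, keeps clades", {
  set.seed(3)
  n <- 60
  data <- data.frame(
    clade = factor(rep(c("a", "b", "c"), each = n / 3)),
    sex = factor(rep(c("M", "F"), length.out = n)),
    size = rnorm(n, 10, 2))
  clade_shift <- outer(as.integer(data$clade), c(1, -1))
  Y <- clade_shift + 0.5 * cbind(data$size, data$size) +
    matrix(rnorm(2 * n, 0, 0.3), ncol = 2)
  res <- residualize(Y, data, ~ sex + size)
  expect_lt(max(abs(colMeans(res))), 1e-9)
  expect_lt(max(abs(cor(res, data$size))), 1e-9)
  # clade separation survives residualization
  m <- rowsum(res, data$clade) / (n / 3)
  expect_gt(max(dist(m)), 1)
  # size trend is gone but was present before
  expect_gt(max(abs(cor(Y, data$size))), 0.5)
})

test_that("QDA separates perfectly separated clouds in both modes", {
  set.seed(2)
  x <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 2),
             matrix(rnorm(40, 10, 0.1), ncol = 2))
  g <- rep(c("a", "b"), each = 20)
  r <- qda_loocv(x, g)
  expect_equal(unname(r$correct_rate), c(100, 100))
  expect_equal(diag(r$resubstitution$percent), c(a = 100, b = 100))
  expect_equal(rowSums(r$loocv$percent), c(a = 100, b = 100))
})

test_that("QDA LOOCV labels match the from-scratch oracle exactly", {
  set.seed(19)
  sizes <- c(a = 15, b = 18, c = 17)
  x <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    S <- crossprod(matrix(rnorm(9, 0, 0.6), 3, 3)) + diag(3) * 0.3
    mvn <- matrix(rnorm(sizes[i] * 3), ncol = 3) %*% chol(S)
    sweep(mvn, 2, c(i, -i, 0.5 * i) * 0.8, `+`)
  }))
  g <- rep(names(sizes), sizes)
  r <- qda_loocv(x, g)
  expect_identical(r$predicted$loocv, oracle_qda_loocv(x, g))
  # confusion rows are percentages
  expect_equal(unname(rowSums(r$loocv$percent)), rep(100, 3),
               tolerance = 1e-9)
})

test_that("QDA agrees with MASS::qda under equal priors", {
  skip_if_not_installed("MASS")
  set.seed(23)
  x <- rbind(matrix(rnorm(60, 0, 1), ncol = 2),
             matrix(rnorm(70, 1.2, 1.4), ncol = 2))
  g <- rep(c("a", "b"), c(30, 35))
  r <- qda_loocv(x, g)
  m <- MASS::qda(x, g, prior = c(0.5, 0.5))
  expect_identical(r$predicted$resubstitution,
                   as.character(predict(m, x)$class))
  mcv <- MASS::qda(x, g, prior = c(0.5, 0.5), CV = TRUE)
  expect_identical(r$predicted$loocv, as.character(mcv$class))
})

test_that("singular class covariances are reported with the clade name", {
  x <- matrix(rnorm(24), ncol = 4)
  g <- rep(c("a", "b"), each = 3)  # n_k = 3 <= p = 4
  expect_error(qda_loocv(x, g), "clade 'a'")
  # ridge rescues the degenerate case
  set.seed(4)
  x2 <- rbind(matrix(rnorm(30), ncol = 3),
              matrix(rnorm(30, 3), ncol = 3))
  g2 <- rep(c("a", "b"), each = 10)
  expect_s3_class(qda_loocv(x2, g2, ridge = 0.1), "dfa_result")
})

test_that("eta_p_sq grows monotonically with simulated effect size", {
  etas <- vapply(c(0.3, 0.8, 1.6, 3), function(eff) {
    sim <- sim_mancova_data(n_per = 25, p = 2, effect = eff, seed = 99)
    fit <- fit_mancova(sim$Y, sim$data, ~ clade + sex + size)
    fit$terms$clade$eta_p_sq
  }, numeric(1))
  expect_true(all(diff(etas) > 0))
})
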