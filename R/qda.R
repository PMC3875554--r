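#' Quadratic discriminant analysis with equal priors and LOOCV
#'
#' Classifies specimens into clades with class-specific Gaussian
#' densities: `score_k(x) = -1/2 log det(Sigma_k) - 1/2 (x - mu_k)'
#' Sigma_k^{-1} (x - mu_k) + log pi_k`, with equal priors `pi_k`.
#' Assignment is to the highest score; exact ties go to the
#' alphabetically first clade label. The resubstitution table comes from
#' the full fit; leave-one-out cross-validation refits the left-out
#' specimen's class mean and covariance without it (the other classes
#' are unchanged) and re-predicts. Residualization of the inputs is not
#' refit inside the loop; it is a fixed preprocessing step.
#'
#' @param x numeric matrix (n x p) of predictors, typically MANCOVA
#'   residuals of shape scores.
#' @param groups clade labels (factor or character, length n).
#' @param ridge non-negative ridge coefficient; `ridge *
#'   trace(Sigma_k)/p` is added to the diagonal of each class
#'   covariance (default 0, i.e. none).
#' @return An object of class `dfa_result`: `class_means`,
#'   `class_covariances`, `resubstitution`/`loocv` confusion tables in
#'   counts and row percentages, `correct_rate` (percent, both modes),
#'   `predicted` (per-specimen labels, both modes), `posterior`
#'   (resubstitution posterior probabilities).
#' @export
qda_loocv <- function(x, groups, ridge = 0) {
  x <- as.matrix(x)
  groups <- as.character(groups)
  if (length(groups) != nrow(x)) stop("groups and x have different n")
  labels <- sort(unique(groups))
  p <- ncol(x)
  for (g in labels) {
    if (sum(groups == g) <= p)
      stop("class covariance for clade '", g, "' is singular (n = ",
           sum(groups == g), " <= p = ", p, "); reduce dimensions or ",
           "use the ridge option")
  }
  fit <- qda_fit(x, groups, labels, ridge)
  pred_resub <- qda_predict(fit, x)
  pred_cv <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    g <- groups[i]
    sub <- x[groups == g & seq_len(nrow(x)) != i, , drop = FALSE]
    if (nrow(sub) <= p)
      stop("leave-one-out covariance for clade '", g, "' is singular; ",
           "reduce dimensions or use the ridge option")
    fit_i <- fit
    fit_i$means[[g]] <- colMeans(sub)
    fit_i$cov[[g]] <- ridge_cov(stats::cov(sub), ridge)
    pred_cv[i] <- qda_predict(fit_i, x[i, , drop = FALSE])$label
  }
  structure(list(
    class_means = fit$means, class_covariances = fit$cov,
    labels = labels,
    resubstitution = confusion(groups, pred_resub$label, labels),
    loocv = confusion(groups, pred_cv, labels),
    correct_rate = c(
      resubstitution = 100 * mean(pred_resub$label == groups),
      loocv = 100 * mean(pred_cv == groups)),
    predicted = data.frame(actual = groups,
                           resubstitution = pred_resub$label,
                           loocv = pred_cv),
    posterior = pred_resub$posterior),
    class = "dfa_result")
}

ridge_cov <- function(S, ridge) {
  if (ridge > 0) S + diag(ridge * sum(diag(S)) / ncol(S), ncol(S)) else S
}

qda_fit <- function(x, groups, labels, ridge) {
  means <- list(); covs <- list()
  for (g in labels) {
    xg <- x[groups == g, , drop = FALSE]
    means[[g]] <- colMeans(xg)
    covs[[g]] <- ridge_cov(stats::cov(xg), ridge)
  }
  list(means = means, cov = covs, labels = labels)
}

qda_predict <- function(fit, newx) {
  newx <- as.matrix(newx)
  labels <- fit$labels
  prior <- log(1 / length(labels))
  scores <- vapply(labels, function(g) {
    S <- fit$cov[[g]]
    ch <- tryCatch(chol(S), error = function(e)
      stop("class covariance for clade '", g, "' is singular; ",
           "reduce dimensions or use the ridge option"))
    d <- sweep(newx, 2, fit$means[[g]])
    z <- backsolve(ch, t(d), transpose = TRUE)
    -sum(log(diag(ch))) - 0.5 * colSums(z^2) + prior
  }, numeric(nrow(newx)))
  scores <- matrix(scores, nrow = nrow(newx),
                   dimnames = list(NULL, labels))
  # ties resolved to the alphabetically first label (labels are sorted)
  lab <- labels[apply(scores, 1, which.max)]
  post <- t(apply(scores, 1, function(s) {
    e <- exp(s - max(s)); e / sum(e)
  }))
  list(label = lab, scores = scores, posterior = post)
}

confusion <- function(actual, predicted, labels) {
  counts <- table(factor(actual, labels), factor(predicted, labels))
  pct <- 100 * sweep(unclass(counts), 1, rowSums(counts), `/`)
  list(counts = unclass(counts), percent = pct)
}

#' @export
print.dfa_result <- function(x, digits = 2, ...) {
  cat("Quadratic DFA, equal priors (",
      length(x$labels), " clades)\n", sep = "")
  cat("Correct rate: resubstitution ",
      sprintf("%.1f%%", x$correct_rate["resubstitution"]),
      ", LOOCV ", sprintf("%.1f%%", x$correct_rate["loocv"]),
      "\n\nRow-percent confusion (resubstitution):\n", sep = "")
  print(round(x$resubstitution$percent, digits))
  cat("\nRow-percent confusion (LOOCV):\n")
  print(round(x$loocv$percent, digits))
  invisible(x)
}
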