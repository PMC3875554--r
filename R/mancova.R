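#' Rao's F approximation for Wilks' lambda
#'
#' Converts a Wilks' lambda statistic into an approximate F statistic
#' with its numerator and denominator degrees of freedom:
#' `s = min(p, df_h)`;
#' `t = sqrt((p^2 df_h^2 - 4) / (p^2 + df_h^2 - 5))` when the
#' denominator is positive, otherwise 1;
#' `g = df_e - (p - df_h + 1)/2`; `df1 = p * df_h`;
#' `df2 = g*t - (p*df_h - 2)/2`; and
#' `F = ((1 - lambda^(1/t)) / lambda^(1/t)) * (df2/df1)`.
#' The partial eta squared effect size is `1 - lambda^(1/s)`.
#'
#' @param lambda Wilks' lambda (det(E)/det(E+H)).
#' @param p number of response variables.
#' @param df_h hypothesis degrees of freedom for the term.
#' @param df_e error degrees of freedom.
#' @return A list with `F`, `df1`, `df2`, `p_value`, `eta_p_sq`, and the
#'   intermediates `s`, `t`, `g`.
#' @export
rao_wilks <- function(lambda, p, df_h, df_e) {
  s <- min(p, df_h)
  denom <- p^2 + df_h^2 - 5
  t_ <- if (denom > 0) sqrt((p^2 * df_h^2 - 4) / denom) else 1
  g <- df_e - (p - df_h + 1) / 2
  df1 <- p * df_h
  df2 <- g * t_ - (p * df_h - 2) / 2
  lam_t <- lambda^(1 / t_)
  Fst <- (1 - lam_t) / lam_t * (df2 / df1)
  list(F = Fst, df1 = df1, df2 = df2,
       p_value = stats::pf(Fst, df1, df2, lower.tail = FALSE),
       eta_p_sq = 1 - lambda^(1 / s), s = s, t = t_, g = g)
}

# sum-to-zero contrasts for every factor in `data`
effect_coded_matrix <- function(formula, data) {
  fac <- names(Filter(function(v) is.factor(v) || is.character(v), data))
  data[fac] <- lapply(data[fac], as.factor)
  contr <- stats::setNames(
    rep(list("contr.sum"), length(fac)), fac)
  contr <- contr[fac %in% all.vars(formula)]
  mm <- stats::model.matrix(formula, data,
                            contrasts.arg = if (length(contr)) contr)
  mm
}

#' Type III MANCOVA with Wilks' lambda and partial eta squared
#'
#' Fits a multivariate linear model of the responses on the model terms
#' under sum-to-zero (effect) coding, and tests each non-intercept term
#' with a Type III (partial) hypothesis SSCP against the shared error
#' SSCP: `lambda = det(E) / det(E + H)`, converted to an F statistic by
#' Rao's approximation ([rao_wilks()]). With one response and one
#' hypothesis df the test reduces exactly to the univariate partial
#' F test.
#'
#' @param responses numeric matrix of responses (n x p), typically shape
#'   PC scores.
#' @param data data frame of predictors (factors are effect-coded).
#' @param formula right-hand-side model formula, e.g.
#'   `~ clade * sex * size`.
#' @return An object of class `mancova_fit`: `table` (one row per term:
#'   F, df1, df2, p, eta_p_sq, wilks), `terms` (per-term list with H, E
#'   and Rao intermediates), `df_e`, `E`, `formula`, `n`, `p`.
#' @export
fit_mancova <- function(responses, data, formula) {
  Y <- as.matrix(responses)
  n <- nrow(Y); p <- ncol(Y)
  if (nrow(data) != n) stop("responses and data have different n")
  X <- effect_coded_matrix(formula, data)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  df_e <- n - ncol(X)
  if (df_e <= p)
    stop("error df (", df_e, ") must exceed the number of responses (",
         p, "); use fewer PCs or more specimens")
  B <- qr.coef(qrx, Y)
  E <- crossprod(Y - X %*% B)
  detE <- det(E)
  if (!is.finite(detE) || detE <= 0)
    stop("singular error SSCP matrix; use fewer PCs or more specimens")
  XtX_inv <- chol2inv(qr.R(qrx))
  asg <- attr(X, "assign")
  labels <- attr(stats::terms(formula), "term.labels")
  out <- list()
  for (ti in seq_along(labels)) {
    idx <- which(asg == ti)
    Bt <- B[idx, , drop = FALSE]
    Ct <- XtX_inv[idx, idx, drop = FALSE]
    H <- crossprod(Bt, solve(Ct, Bt))
    lambda <- detE / det(E + H)
    rao <- rao_wilks(lambda, p, length(idx), df_e)
    out[[labels[ti]]] <- c(
      list(term = labels[ti], H = H, E = E, wilks_lambda = lambda,
           df_h = length(idx), df_e = df_e), rao)
  }
  tab <- data.frame(
    term = labels,
    F = vapply(out, `[[`, numeric(1), "F"),
    df1 = vapply(out, `[[`, numeric(1), "df1"),
    df2 = vapply(out, `[[`, numeric(1), "df2"),
    p = vapply(out, `[[`, numeric(1), "p_value"),
    eta_p_sq = vapply(out, `[[`, numeric(1), "eta_p_sq"),
    wilks = vapply(out, `[[`, numeric(1), "wilks_lambda"),
    row.names = NULL)
  structure(list(table = tab, terms = out, df_e = df_e, E = E,
                 formula = formula, n = n, p = p, data = data,
                 responses = Y),
            class = "mancova_fit")
}

#' @export
print.mancova_fit <- function(x, ...) {
  cat("Type III MANCOVA (", x$p, " responses, n = ", x$n,
      ", error df = ", x$df_e, ")\n", sep = "")
  tab <- x$table
  tab$F <- sprintf("%.3f", tab$F)
  tab$df2 <- sprintf("%g", round(tab$df2, 1))
  tab$p <- ifelse(tab$p < 1e-4, "<.0001", sprintf("%.4f", tab$p))
  tab$eta_p_sq <- sprintf("%.4f", tab$eta_p_sq)
  tab$wilks <- sprintf("%.4f", tab$wilks)
  print(tab, row.names = FALSE)
  invisible(x)
}

term_factors <- function(label) sort(strsplit(label, ":")[[1]])
term_order <- function(label) length(term_factors(label))
contains_term <- function(big, small)
  all(term_factors(small) %in% term_factors(big))

#' Hierarchical pruning of non-significant interaction terms
#'
#' Fits the full model, then repeatedly removes the least defensible
#' interaction: among interaction terms not contained in any retained
#' higher-order term, the one with the highest order (ties broken by
#' largest p value) is dropped when its p value is at or above `alpha`,
#' and the model is refitted. Main effects are never removed. The final
#' model's term results are returned.
#'
#' @inheritParams fit_mancova
#' @param alpha pruning threshold (default 0.05).
#' @return A list with `fit` (final [fit_mancova()] result), `formula`
#'   (final model formula) and `removed` (labels in removal order).
#' @export
prune_and_refit <- function(responses, data, formula, alpha = 0.05) {
  removed <- character(0)
  labels <- attr(stats::terms(formula), "term.labels")
  repeat {
    fit <- fit_mancova(responses, data,
                       stats::reformulate(labels))
    tab <- fit$table
    inter <- tab$term[vapply(tab$term, term_order, integer(1)) >= 2]
    free <- inter[vapply(inter, function(tm) {
      !any(vapply(setdiff(labels, tm), contains_term, logical(1),
                  small = tm))
    }, logical(1))]
    cand <- free[tab$p[match(free, tab$term)] >= alpha]
    if (!length(cand)) break
    ords <- vapply(cand, term_order, integer(1))
    cand <- cand[ords == max(ords)]
    drop <- cand[which.max(tab$p[match(cand, tab$term)])]
    removed <- c(removed, drop)
    labels <- setdiff(labels, drop)
  }
  list(fit = fit, formula = stats::reformulate(labels),
       removed = removed)
}

#' Residualize shape scores on nuisance predictors
#'
#' Fits the responses on the nuisance terms only (by default sex and
#' size, excluding the lineage factor so that between-clade differences
#' remain in the residuals) under effect coding, and returns the
#' residual matrix. This is the preliminary-model step before
#' discriminant analysis.
#'
#' @param responses numeric matrix (n x p).
#' @param data data frame of predictors.
#' @param formula nuisance model (default `~ sex + size`).
#' @return Residual matrix, same dimensions as `responses`.
#' @export
residualize <- function(responses, data, formula = ~ sex + size) {
  Y <- as.matrix(responses)
  X <- effect_coded_matrix(formula, data)
  qrx <- qr(X)
  res <- Y - X %*% qr.coef(qrx, Y)
  dimnames(res) <- dimnames(Y)
  res
}
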