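#' One-sample Hotelling's T-squared test
#'
#' Multivariate t-test of a mean vector against `mu0`:
#' \deqn{T^2 = n (\bar x - \mu_0)' S^{-1} (\bar x - \mu_0)}
#' transformed to \eqn{F = T^2 (n - p) / (p (n - 1))} on (p, n - p)
#' degrees of freedom. Effect size is reported as partial eta-squared
#' \eqn{T^2 / (T^2 + n - 1)}.
#'
#' @param X n x p matrix of per-subject outcome vectors (e.g., polynomial
#'   coefficients).
#' @param mu0 null mean vector (recycled scalar allowed).
#' @return object of class `mv_test`: `test`, `statistic` (T^2), `F`,
#'   `df1`, `df2`, `p`, `effect_size`, `labels`, `n`.
#' @export
hotelling_one_sample <- function(X, mu0 = 0) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need n > p", call. = FALSE)
  mu0 <- rep_len(mu0, p)
  d <- colMeans(X) - mu0
  if (max(abs(sweep(X, 2, mu0))) < 1e-12) {
    # every observation sits exactly at mu0 (e.g., identical paired
    # conditions): no deviation to test
    T2 <- 0
  } else {
    S <- stats::cov(X)
    Sinv <- safe_solve(S, "covariance matrix is singular")
    T2 <- as.numeric(n * t(d) %*% Sinv %*% d)
  }
  Fval <- T2 * (n - p) / (p * (n - 1))
  mv_result("one-sample Hotelling T2", T2, Fval, p, n - p,
            effect = T2 / (T2 + n - 1), labels = colnames(X), n = n)
}

#' Independent-samples Hotelling's T-squared test
#'
#' Pooled-covariance two-sample test of equal mean vectors;
#' \eqn{F = T^2 (n_1 + n_2 - p - 1) / (p (n_1 + n_2 - 2))} on
#' (p, n1 + n2 - p - 1) df. Effect size \eqn{T^2/(T^2 + n_1 + n_2 - 2)}.
#'
#' @param X1,X2 group matrices with matching columns.
#' @return an `mv_test`.
#' @export
hotelling_two_sample <- function(X1, X2) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  p <- ncol(X1)
  if (ncol(X2) != p) stop("column mismatch", call. = FALSE)
  n1 <- nrow(X1); n2 <- nrow(X2)
  if (n1 + n2 <= p + 1) stop("need n1 + n2 > p + 1", call. = FALSE)
  d <- colMeans(X1) - colMeans(X2)
  Sp <- ((n1 - 1) * stats::cov(X1) + (n2 - 1) * stats::cov(X2)) / (n1 + n2 - 2)
  Spinv <- safe_solve(Sp, "pooled covariance is singular")
  T2 <- as.numeric((n1 * n2) / (n1 + n2) * t(d) %*% Spinv %*% d)
  Fval <- T2 * (n1 + n2 - p - 1) / (p * (n1 + n2 - 2))
  mv_result("two-sample Hotelling T2", T2, Fval, p, n1 + n2 - p - 1,
            effect = T2 / (T2 + n1 + n2 - 2), labels = colnames(X1),
            n = n1 + n2)
}

#' Dependent-samples Hotelling's T-squared test
#'
#' Tests whether the mean difference vector between two matched conditions
#' is zero: exactly [hotelling_one_sample()] applied to `X1 - X2`, with df
#' (p, n - p).
#'
#' @param X1,X2 matched condition matrices (same subjects, same order).
#' @return an `mv_test`.
#' @export
hotelling_paired <- function(X1, X2) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (!all(dim(X1) == dim(X2))) stop("matched rows required", call. = FALSE)
  out <- hotelling_one_sample(X1 - X2, 0)
  out$test <- "paired Hotelling T2"
  out
}

#' Repeated-measures MANOVA (one within-subject factor, m outcomes)
#'
#' Applies orthonormal difference contrasts across the k factor levels to
#' each outcome, stacking the (k-1) * m contrast scores per subject, and
#' tests the stacked mean vector against zero. With a single hypothesis
#' dimension this gives Wilks' \eqn{\Lambda = (1 + T^2/(n-1))^{-1}} with
#' exact F on (q, n - q) df where q = (k-1) m, and partial eta-squared
#' \eqn{1 - \Lambda}.
#'
#' @param Y numeric array n x k x m (subjects x levels x outcomes), or an
#'   n x k matrix for m = 1. No missing cells.
#' @return an `mv_test` with `statistic` = Wilks' Lambda and `T2`.
#' @export
rm_manova <- function(Y) {
  if (is.matrix(Y)) Y <- array(Y, c(nrow(Y), ncol(Y), 1))
  if (anyNA(Y)) stop("incomplete cells", call. = FALSE)
  n <- dim(Y)[1]; k <- dim(Y)[2]; m <- dim(Y)[3]
  if (k < 2) stop("need at least 2 factor levels", call. = FALSE)
  C <- orthonormal_contrasts(k)
  Z <- do.call(cbind, lapply(seq_len(m), function(j) Y[, , j] %*% t(C)))
  q <- ncol(Z)
  if (n <= q) stop("need n > (k-1)*m", call. = FALSE)
  if (max(abs(Z)) < 1e-12) {
    # factor-invariant data: no within-subject variation at all
    T2 <- 0
  } else {
    S <- stats::cov(Z)
    Sinv <- safe_solve(S, "contrast covariance is singular")
    zbar <- colMeans(Z)
    T2 <- as.numeric(n * t(zbar) %*% Sinv %*% zbar)
  }
  lambda <- 1 / (1 + T2 / (n - 1))
  Fval <- T2 * (n - q) / (q * (n - 1))
  out <- mv_result("repeated-measures MANOVA (Wilks)", lambda, Fval, q,
                   n - q, effect = 1 - lambda, labels = NULL, n = n)
  out$T2 <- T2
  out
}

# (k-1) x k matrix with orthonormal rows orthogonal to the unit vector
orthonormal_contrasts <- function(k) {
  H <- stats::contr.helmert(k)          # k x (k-1), columns orthogonal
  H <- sweep(H, 2, sqrt(colSums(H^2)), `/`)
  t(H)
}

#' Repeated-measures ANOVA with sphericity diagnostics
#'
#' One within-subject factor on a complete subject x level table. Reports
#' the uncorrected F on ((k-1), (n-1)(k-1)) df, Mauchly's sphericity test,
#' Greenhouse--Geisser and Huynh--Feldt epsilons, and a corrected p-value.
#' The Huynh--Feldt epsilon is
#' \eqn{\min(1, (n(k-1)\epsilon_{GG} - 2) /
#'      ((k-1)(n - 1 - (k-1)\epsilon_{GG})))}.
#'
#' @param values n x k matrix (subjects x levels).
#' @param correction `"auto"` applies the Huynh--Feldt correction only when
#'   Mauchly's test is significant at `alpha`; `"always"` or `"never"`
#'   override.
#' @param alpha significance level for Mauchly's test under `"auto"`.
#' @return list of class `rm_anova`: `F`, `df1`, `df2`, `p`, `mauchly_w`,
#'   `mauchly_p`, `eps_gg`, `eps_hf`, `df1_corrected`, `df2_corrected`,
#'   `p_corrected`, `correction_applied`, `partial_eta_sq`, `n`, `k`.
#' @export
rm_anova <- function(values, correction = c("auto", "always", "never"),
                     alpha = 0.05) {
  correction <- match.arg(correction)
  values <- as.matrix(values)
  if (anyNA(values)) stop("incomplete cells", call. = FALSE)
  n <- nrow(values); k <- ncol(values)
  if (k < 2) stop("need at least 2 levels", call. = FALSE)
  grand <- mean(values)
  ss_cond <- n * sum((colMeans(values) - grand)^2)
  ss_subj <- k * sum((rowMeans(values) - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  Fval <- if (ss_cond == 0) 0 else (ss_cond / df1) / (ss_err / df2)

  # sphericity on orthonormal contrast scores
  Z <- values %*% t(orthonormal_contrasts(k))
  Sz <- stats::cov(Z)
  eig_mean <- sum(diag(Sz)) / (k - 1)
  eps_gg <- sum(diag(Sz))^2 / ((k - 1) * sum(Sz^2))
  if (k == 2 || max(abs(Z - mean(Z))) < 1e-12) {
    W <- 1; mauchly_p <- 1; eps_gg <- 1
  } else {
    W <- det(Sz) / eig_mean^(k - 1)
    dfw <- k * (k - 1) / 2 - 1
    fcorr <- (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * (n - 1))
    chi <- -(n - 1) * (1 - fcorr) * log(W)
    mauchly_p <- stats::pchisq(chi, dfw, lower.tail = FALSE)
  }
  eps_hf <- min(1, (n * (k - 1) * eps_gg - 2) /
                   ((k - 1) * (n - 1 - (k - 1) * eps_gg)))
  apply_corr <- switch(correction,
                       auto = mauchly_p < alpha,
                       always = TRUE,
                       never = FALSE)
  eps <- if (apply_corr) eps_hf else 1
  p_corr <- stats::pf(Fval, df1 * eps, df2 * eps, lower.tail = FALSE)
  structure(list(
    F = Fval, df1 = df1, df2 = df2,
    p = stats::pf(Fval, df1, df2, lower.tail = FALSE),
    mauchly_w = W, mauchly_p = mauchly_p,
    eps_gg = eps_gg, eps_hf = eps_hf,
    df1_corrected = df1 * eps, df2_corrected = df2 * eps,
    p_corrected = p_corr, correction_applied = apply_corr,
    partial_eta_sq = ss_cond / (ss_cond + ss_err),
    n = n, k = k), class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("rm-ANOVA: F(%.2f, %.2f) = %.3f, p = %.4g%s\n",
              x$df1_corrected, x$df2_corrected, x$F, x$p_corrected,
              if (x$correction_applied)
                sprintf(" (HF eps = %.3f)", x$eps_hf) else ""))
  invisible(x)
}

#' Holm--Bonferroni step-down adjustment
#'
#' Sorts p-values ascending, multiplies the i-th by (m - i + 1), enforces
#' monotonicity with a running maximum, clips at 1, and restores the input
#' order.
#'
#' @param pvals p-values in the unit interval.
#' @return adjusted p-values, same order as the input.
#' @export
holm_bonferroni <- function(pvals) {
  if (any(pvals < 0 | pvals > 1) || anyNA(pvals))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pvals)
  o <- order(pvals)
  adj <- pmin(1, cummax(pvals[o] * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Cohen's d for a one-sample (or paired) t-test
#'
#' @param t t statistic.
#' @param n sample size (so t has n - 1 df).
#' @return |t| / sqrt(n).
#' @export
cohens_d_one_sample <- function(t, n) abs(t) / sqrt(n)

#' Partial eta-squared from an F statistic
#'
#' @param F F statistic.
#' @param df1,df2 its degrees of freedom.
#' @return F * df1 / (F * df1 + df2).
#' @export
partial_eta_sq <- function(F, df1, df2) F * df1 / (F * df1 + df2)

#' Post hoc one-sample t-tests with Holm correction
#'
#' Univariate follow-up to a significant multivariate test: per-column
#' one-sample t-tests of `X` against `mu0`, Holm-adjusted, with Cohen's d
#' and confidence intervals.
#'
#' @param X n x p matrix of per-subject values.
#' @param mu0 null means (recycled).
#' @param level confidence level for the intervals.
#' @return data.frame of class `posthoc_table`: `label`, `mean`, `t`, `df`,
#'   `p`, `p_holm`, `d`, `ci_lower`, `ci_upper`.
#' @export
posthoc_t_tests <- function(X, mu0 = 0, level = 0.95) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  mu0 <- rep_len(mu0, p)
  means <- colMeans(X)
  ses <- apply(X, 2, stats::sd) / sqrt(n)
  tvals <- (means - mu0) / ses
  pvals <- 2 * stats::pt(abs(tvals), n - 1, lower.tail = FALSE)
  tcrit <- stats::qt(1 - (1 - level) / 2, n - 1)
  out <- data.frame(
    label = colnames(X) %||% paste0("V", seq_len(p)),
    mean = means, t = tvals, df = n - 1, p = pvals,
    p_holm = holm_bonferroni(pvals),
    d = cohens_d_one_sample(tvals, n),
    ci_lower = means - tcrit * ses, ci_upper = means + tcrit * ses,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("posthoc_table", "data.frame")
  out
}

#' Box's M test for homogeneity of covariance matrices
#'
#' Chi-squared approximation; each group must have more observations than
#' variables and a nonsingular covariance.
#'
#' @param groups list of n_i x p matrices.
#' @return list: `M`, `chi_sq`, `df`, `p`.
#' @export
box_m <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  groups <- lapply(groups, as.matrix)
  p <- ncol(groups[[1]])
  ns <- vapply(groups, nrow, numeric(1))
  if (any(ns <= p)) stop("each group needs n > p", call. = FALSE)
  g <- length(groups)
  covs <- lapply(groups, stats::cov)
  dets <- vapply(covs, det, numeric(1))
  if (any(dets <= 0)) stop("singular group covariance", call. = FALSE)
  N <- sum(ns)
  Sp <- Reduce(`+`, Map(function(S, n) (n - 1) * S, covs, ns)) / (N - g)
  M <- (N - g) * log(det(Sp)) - sum((ns - 1) * log(dets))
  c1 <- (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (g - 1)) *
    (sum(1 / (ns - 1)) - 1 / (N - g))
  chi <- M * (1 - c1)
  df <- (g - 1) * p * (p + 1) / 2
  list(M = M, chi_sq = chi, df = df,
       p = stats::pchisq(chi, df, lower.tail = FALSE))
}

mv_result <- function(test, statistic, Fval, df1, df2, effect, labels, n) {
  structure(list(test = test, statistic = statistic, F = Fval,
                 df1 = df1, df2 = df2,
                 p = stats::pf(Fval, df1, df2, lower.tail = FALSE),
                 effect_size = effect, labels = labels, n = n),
            class = "mv_test")
}

#' @export
print.mv_test <- function(x, ...) {
  cat(sprintf("%s: F(%d, %d) = %.3f, p = %.4g, eta_p^2 = %.3f\n",
              x$test, x$df1, x$df2, x$F, x$p, x$effect_size))
  invisible(x)
}

safe_solve <- function(S, msg) {
  out <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(out) || !all(is.finite(out)))
    stop(msg, call. = FALSE)
  out
}
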