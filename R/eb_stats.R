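#' Per-protein ordinary least-squares fits
#'
#' Fits the same linear model to every protein (row of `Y`) by solving the
#' normal equations once for the shared design. Returns, per protein, the
#' coefficient estimates, the residual variance `s_g^2` on
#' `d_g = n - rank(X)` degrees of freedom, the unscaled coefficient
#' variances (diagonal of `(X'X)^-1`, shared across proteins) and the
#' average log2 intensity `A_g`.
#'
#' @param Y proteins x observations matrix of normalized log2 intensities;
#'   column order must match the design's row order (checked via names when
#'   both are present).
#' @param X design matrix from [cofactor_design] or [inhibitor_design].
#' @return Object of class `protein_fit`: list with `coefficients`
#'   (proteins x p), `sigma2` (residual variances), `df_residual`,
#'   `unscaled_variances` (length p), `amean`, `design`.
#' @export
fit_linear_models <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (ncol(Y) != nrow(X))
    stop(sprintf("dimension mismatch: %d observation columns in Y vs %d design rows",
                 ncol(Y), nrow(X)))
  if (!is.null(colnames(Y)) && !is.null(rownames(X)) &&
      !identical(colnames(Y), rownames(X)))
    stop("Y column order does not match design row order")
  validate_design(X)
  p <- ncol(X)
  if (nrow(X) <= p) stop("need more observations than coefficients")
  xtx_inv <- chol2inv(chol(crossprod(X)))
  B <- Y %*% X %*% xtx_inv                   # proteins x p
  colnames(B) <- colnames(X)
  resid <- Y - B %*% t(X)
  df <- nrow(X) - p
  s2 <- rowSums(resid^2) / df
  structure(list(coefficients = B,
                 sigma2 = s2,
                 df_residual = df,
                 unscaled_variances = stats::setNames(diag(xtx_inv), colnames(X)),
                 amean = rowMeans(Y),
                 design = X),
            class = "protein_fit")
}

#' @export
print.protein_fit <- function(x, ...) {
  cat(sprintf("protein_fit: %d proteins, %d coefficients, %d residual df\n",
              nrow(x$coefficients), ncol(x$coefficients), x$df_residual))
  invisible(x)
}

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration started from
#' the asymptotic inverse (trigamma(x) ~ 1/x for large x), used when
#' matching moments of log residual variances to the scaled-F hierarchical
#' model.
#'
#' @param y positive target value(s).
#' @param tol convergence tolerance on the relative step.
#' @param maxit maximum Newton iterations.
#' @return x such that `trigamma(x) = y`; `Inf` maps to 0 and values below
#'   trigamma's range to `Inf`.
#' @export
trigamma_inverse <- function(y, tol = 1e-8, maxit = 50L) {
  out <- y
  done <- !is.finite(y) | y <= 0
  out[is.infinite(y)] <- 0
  out[y <= 0 & is.finite(y)] <- Inf
  idx <- which(!done)
  if (!length(idx)) return(out)
  x <- 0.5 + 1 / y[idx]
  for (i in seq_len(maxit)) {
    tri <- trigamma(x)
    step <- tri * (1 - tri / y[idx]) / psigamma(x, deriv = 2L)
    x <- x + step
    x[x <= 0] <- .Machine$double.xmin
    if (max(abs(step) / x) < tol) break
  }
  out[idx] <- x
  out
}

#' Estimate the hierarchical variance prior
#'
#' @description
#' Fits the scaled inverse-chi-square prior of the moderated-t framework to
#' the per-protein residual variances, optionally with an intensity trend:
#' the log variances `z_g = log(s_g^2)` are bias-corrected for the
#' chi-square sampling distribution via digamma/trigamma identities, their
#' location is taken as a lowess curve of `z_g` on the average log2
#' intensity `A_g` (a constant when `trend = FALSE`), and the excess
#' dispersion of `z_g` about that location over the chi-square sampling
#' floor `trigamma(d_g/2)` is inverted through the trigamma function to
#' give the prior degrees of freedom `d0`. The back-transformed location
#' gives the per-protein prior variance `s0^2(A_g)`.
#'
#' When the observed dispersion does not exceed the sampling floor, the
#' prior is effectively infinitely informative: `d0 = Inf` with
#' `s0^2 = exp(location)`.
#'
#' Residual variances of exactly zero (perfect fits) are floored at
#' machine epsilon times the mean variance before taking logs so those
#' proteins still participate in moderation.
#'
#' @param fit a [protein_fit].
#' @param trend fit an intensity-dependent prior (lowess of `z` on `A`)?
#' @param span lowess span for the variance trend.
#' @return Object of class `variance_prior`: list with `df_prior` (scalar,
#'   possibly `Inf`), `var_prior` (per-protein `s0^2(A_g)`), `trend`,
#'   `span`.
#' @export
estimate_variance_prior <- function(fit, trend = TRUE, span = 0.5) {
  stopifnot(inherits(fit, "protein_fit"))
  s2 <- fit$sigma2
  n <- length(s2)
  if (n < 50L)
    warning("fewer than 50 proteins: variance-prior estimates will be unstable")
  dg <- fit$df_residual
  if (dg <= 0) stop("residual degrees of freedom must be positive")
  floor_ <- .Machine$double.eps * mean(s2)
  z <- log(pmax(s2, floor_))
  # E[log chi2_d / d] = digamma(d/2) - log(d/2); correct z to centre on log sigma2
  e <- z - digamma(dg / 2) + log(dg / 2)
  if (trend) {
    lo <- stats::lowess(fit$amean, e, f = span)
    loc <- stats::approx(lo$x, lo$y, xout = fit$amean, rule = 2, ties = mean)$y
  } else {
    loc <- rep(mean(e), n)
  }
  evar <- mean((e - loc)^2) * n / (n - 1L) - trigamma(dg / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(loc + digamma(d0 / 2) - log(d0 / 2))
  } else {
    warning("no excess variance dispersion beyond chi-square sampling: prior df set to Inf")
    d0 <- Inf
    s0 <- exp(loc)
  }
  structure(list(df_prior = d0, var_prior = s0, trend = trend, span = span),
            class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("variance_prior: d0 = %s, s0^2 %s [%.4g, %.4g]\n",
              format(x$df_prior, digits = 4),
              if (x$trend) "trend over" else "constant in",
              min(x$var_prior), max(x$var_prior)))
  invisible(x)
}

#' Squeeze residual variances toward the prior
#'
#' Posterior (moderated) variance
#' `s~_g^2 = (d0 * s0^2(A_g) + d_g * s_g^2) / (d0 + d_g)`, a convex
#' combination of the prior and observed variances; equal to `s0^2` when
#' `d0 = Inf` and to `s_g^2` when `d0 = 0`.
#'
#' @param sigma2 observed residual variances.
#' @param df_residual residual degrees of freedom.
#' @param prior a `variance_prior` (or a list with `df_prior`,
#'   `var_prior`).
#' @return per-protein posterior variances.
#' @export
squeeze_variances <- function(sigma2, df_residual, prior) {
  d0 <- prior$df_prior
  s0 <- prior$var_prior
  if (length(s0) == 1L) s0 <- rep(s0, length(sigma2))
  stopifnot(length(s0) == length(sigma2))
  if (is.infinite(d0)) return(s0)
  (d0 * s0 + df_residual * sigma2) / (d0 + df_residual)
}

#' Moderated t-test on one model coefficient
#'
#' Tests, per protein, the null hypothesis that the given coefficient is
#' zero using the empirical-Bayes moderated t-statistic
#' `t_g = beta_g / (s~_g * sqrt(v_j))` referred to a t distribution with
#' `d0 + d_g` degrees of freedom (standard normal when `d0 = Inf`).
#' P values are two-sided, adjusted across proteins with the
#' Benjamini-Hochberg method, and called significant below `alpha`.
#'
#' @param fit a [protein_fit].
#' @param prior a `variance_prior` from [estimate_variance_prior].
#' @param coefficient coefficient to test: a column name of the design, or
#'   a role name (e.g. `"cofactor_effect"`) resolved via the design roles
#'   when unique.
#' @param alpha adjusted-p significance threshold (default 0.01; calls use
#'   the strict comparison `p_adjusted < alpha`).
#' @return Object of class `moderated_stats`: data.frame with
#'   `protein_id`, `estimate`, `t`, `df_total`, `p_value`, `p_adjusted`,
#'   `significant`, `amean`, plus attributes `coefficient` and `alpha`.
#' @export
moderated_t_test <- function(fit, prior, coefficient, alpha = 0.01) {
  stopifnot(inherits(fit, "protein_fit"))
  j <- resolve_coefficient(fit$design, coefficient)
  beta <- fit$coefficients[, j]
  vj <- fit$unscaled_variances[j]
  s2_post <- squeeze_variances(fit$sigma2, fit$df_residual, prior)
  d0 <- prior$df_prior
  df_total <- d0 + fit$df_residual
  se <- sqrt(s2_post * vj)
  t_ <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  if (any(se == 0))
    warning(sum(se == 0), " protein(s) with zero posterior variance: t set to +/-Inf")
  p <- if (is.infinite(d0)) 2 * stats::pnorm(-abs(t_))
       else 2 * stats::pt(-abs(t_), df = df_total)
  p[is.infinite(t_)] <- 0
  padj <- adjust_bh(p)
  out <- data.frame(
    protein_id = rownames(fit$coefficients) %||% as.character(seq_along(beta)),
    estimate = unname(beta),
    t = unname(t_),
    df_total = df_total,
    p_value = unname(p),
    p_adjusted = unname(padj),
    significant = call_significance(padj, alpha),
    amean = unname(fit$amean),
    stringsAsFactors = FALSE)
  structure(out, class = c("moderated_stats", "data.frame"),
            coefficient = colnames(fit$design)[j], alpha = alpha)
}

resolve_coefficient <- function(design, coefficient) {
  cn <- colnames(design)
  if (coefficient %in% cn) return(match(coefficient, cn))
  roles <- attr(design, "roles")
  if (!is.null(roles) && coefficient %in% roles) {
    hits <- which(roles == coefficient)
    if (length(hits) == 1L) return(hits)
    stop(sprintf("role '%s' matches %d columns; name the column explicitly",
                 coefficient, length(hits)))
  }
  stop(sprintf("coefficient '%s' not found in design (columns: %s)",
               coefficient, paste(cn, collapse = ", ")))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment
#' `p_adj_(i) = min_{j >= i} min(1, m * p_(j) / j)` mapped back to input
#' order. Applied per tested coefficient across proteins, never pooled
#' across coefficients.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return adjusted p values in input order.
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Significance calls
#'
#' Strict threshold on adjusted p values: significant iff
#' `p_adjusted < alpha`.
#'
#' @param p_adjusted adjusted p values (or a `moderated_stats` object).
#' @param alpha threshold (default 0.01).
#' @return logical vector.
#' @export
call_significance <- function(p_adjusted, alpha = 0.01) {
  stopifnot(alpha > 0, alpha <= 1)
  if (inherits(p_adjusted, "moderated_stats")) p_adjusted <- p_adjusted$p_adjusted
  p_adjusted < alpha
}
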