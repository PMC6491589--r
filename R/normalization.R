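#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-column scaling normalization for reporter-ion intensity matrices.
#' For each column against a reference column, per-protein log-ratios
#' `M = log2((y_k/N_k)/(y_r/N_r))` and average log-intensities
#' `A = 0.5 * log2((y_k/N_k) * (y_r/N_r))` are computed; proteins in the
#' upper and lower `trim_m` tails of M and `trim_a` tails of A are
#' discarded, and the column's factor is 2 to the precision-weighted mean
#' of the remaining M values, with weights the inverse asymptotic
#' (delta-method) variance `(N_k - y_k)/(N_k y_k) + (N_r - y_r)/(N_r y_r)`.
#' Factors are rescaled so their geometric mean is 1.
#'
#' @param mat proteins x columns numeric matrix of strictly positive
#'   intensities (zeros are removed by the upstream quality filter).
#' @param trim_m fraction trimmed from each tail of the M distribution
#'   (default 0.30).
#' @param trim_a fraction trimmed from each tail of the A distribution
#'   (default 0.05).
#' @param reference reference column index, or `NULL` to auto-select the
#'   column whose upper-quartile of library-size-scaled intensities is
#'   closest to the mean upper-quartile.
#' @return numeric vector of per-column factors (geometric mean 1).
#' @export
tmm_factors <- function(mat, trim_m = 0.30, trim_a = 0.05, reference = NULL) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("TMM requires at least 2 columns")
  if (any(mat <= 0)) stop("TMM requires strictly positive intensities")
  lib <- colSums(mat)
  if (is.null(reference)) {
    uq <- apply(mat, 2L, stats::quantile, probs = 0.75) / lib
    reference <- which.min(abs(uq - mean(uq)))
  }
  stopifnot(reference >= 1L, reference <= ncol(mat))
  f <- vapply(seq_len(ncol(mat)), function(k) {
    tmm_pair_factor(mat[, k], mat[, reference], lib[k], lib[reference],
                    trim_m, trim_a)
  }, numeric(1L))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(mat)
  f
}

# Doubly-trimmed precision-weighted mean of log-ratios for one column pair.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  # identical columns: no composition bias by construction
  if (max(abs(m)) < 1e-10) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m)
  ra_ <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  keep <- keep & is.finite(m) & is.finite(w) & w > 0
  if (!any(keep)) {
    warning("all proteins trimmed in TMM comparison; factor set to 1")
    return(1)
  }
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Log2-per-million transformation
#'
#' Converts intensities to `log2(1e6 * y[g,k] / effective_size[k])` where
#' the effective size is the column's library size times its normalization
#' factor. No prior count is added by default because upstream filtering
#' guarantees strictly positive intensities; `prior_count` exists for
#' robustness on unfiltered input.
#'
#' @param mat proteins x columns numeric matrix of positive intensities.
#' @param factors per-column normalization factors (default: all 1).
#' @param prior_count constant added to intensities before scaling
#'   (default 0).
#' @return matrix of the same shape on the log2-per-million scale.
#' @export
log2_per_million <- function(mat, factors = NULL, prior_count = 0) {
  mat <- as.matrix(mat)
  if (is.null(factors)) factors <- rep(1, ncol(mat))
  stopifnot(length(factors) == ncol(mat), all(factors > 0))
  if (prior_count == 0 && any(mat <= 0)) {
    bad <- which(mat <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive intensity for protein %s in column %s",
                 rownames(mat)[bad[1L]] %||% bad[1L],
                 colnames(mat)[bad[2L]] %||% bad[2L]))
  }
  eff <- colSums(mat) * factors
  log2(sweep(1e6 * (mat + prior_count), 2L, eff, "/"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Joint TMM + log2-per-million normalization
#'
#' Runs [tmm_factors] and [log2_per_million] jointly across all replicates'
#' columns of an experiment and bundles sizes, factors and the transformed
#' matrix.
#'
#' @inheritParams tmm_factors
#' @inheritParams log2_per_million
#' @return An object of class `tmt_norm`: list with `library_sizes`,
#'   `tmm_factors`, `effective_sizes` and `log2pm` (the transformed
#'   matrix).
#' @export
normalize_reporters <- function(mat, trim_m = 0.30, trim_a = 0.05,
                                reference = NULL, prior_count = 0) {
  mat <- as.matrix(mat)
  f <- tmm_factors(mat, trim_m = trim_m, trim_a = trim_a,
                   reference = reference)
  lib <- colSums(mat)
  structure(list(library_sizes = lib,
                 tmm_factors = f,
                 effective_sizes = lib * f,
                 log2pm = log2_per_million(mat, f, prior_count = prior_count)),
            class = "tmt_norm")
}

#' @export
print.tmt_norm <- function(x, ...) {
  cat(sprintf("TMM/log2-per-million normalization: %d proteins x %d columns\n",
              nrow(x$log2pm), ncol(x$log2pm)))
  cat("factors:", paste(sprintf("%.4f", x$tmm_factors), collapse = " "), "\n")
  invisible(x)
}
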