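# Independent brute-force oracles used to freeze expected values.
# These are written loop-wise, straight from the defining formulas, and
# stay independent of the package's vectorized implementations.

# Benjamini-Hochberg step-up: adj_(i) = min_{j >= i} min(1, m p_(j) / j).
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  cur <- 1
  for (i in m:1) {
    cur <- min(cur, m * p[o[i]] / i)
    adj[o[i]] <- cur
  }
  adj
}

# Least squares through the SVD pseudo-inverse, one protein at a time.
pinv_fit_oracle <- function(y, X) {
  s <- svd(X)
  pinv <- s$v %*% diag(1 / s$d, length(s$d)) %*% t(s$u)
  beta <- drop(pinv %*% y)
  rank <- sum(s$d > max(s$d) * 1e-12)
  res <- y - drop(X %*% beta)
  df <- length(y) - rank
  list(beta = beta, s2 = sum(res^2) / df, df = df)
}

# Doubly-trimmed precision-weighted mean of log-ratios, explicit loops.
tmm_oracle <- function(mat, trim_m = 0.30, trim_a = 0.05, reference) {
  lib <- colSums(mat)
  f <- numeric(ncol(mat))
  for (k in seq_len(ncol(mat))) {
    obs <- mat[, k]
    ref <- mat[, reference]
    M <- log2((obs / lib[k]) / (ref / lib[reference]))
    A <- 0.5 * log2((obs / lib[k]) * (ref / lib[reference]))
    w <- (lib[k] - obs) / (lib[k] * obs) +
      (lib[reference] - ref) / (lib[reference] * ref)
    if (max(abs(M)) < 1e-10) {
      f[k] <- 1
      next
    }
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    num <- 0; den <- 0
    for (g in seq_len(n)) {
      if (rM[g] >= loM && rM[g] <= hiM && rA[g] >= loA && rA[g] <= hiA) {
        num <- num + M[g] / w[g]
        den <- den + 1 / w[g]
      }
    }
    f[k] <- 2^(num / den)
  }
  f / exp(mean(log(f)))
}

# Matrix rank by Gaussian elimination with partial pivoting.
rank_elimination_oracle <- function(X, tol = 1e-10) {
  A <- as.matrix(X)
  scale_ <- max(abs(A))
  rank <- 0L
  row <- 1L
  for (col in seq_len(ncol(A))) {
    if (row > nrow(A)) break
    piv <- which.max(abs(A[row:nrow(A), col])) + row - 1L
    if (abs(A[piv, col]) < tol * scale_) next
    if (piv != row) A[c(piv, row), ] <- A[c(row, piv), ]
    below <- setdiff(seq_len(nrow(A)), seq_len(row))
    for (r in below) A[r, ] <- A[r, ] - A[r, col] / A[row, col] * A[row, ]
    rank <- rank + 1L
    row <- row + 1L
  }
  rank
}

# Small positive intensity matrix for normalization tests.
random_intensity_matrix <- function(n, k, seed = 1) {
  set.seed(seed)
  matrix(2^rnorm(n * k, mean = 10, sd = 2), n, k,
         dimnames = list(sprintf("P%04d", seq_len(n)), paste0("C", seq_len(k))))
}

# 10-row proteinGroups fixture with known filter labels:
# 2 contaminants, 1 reverse, 1 only-by-site, 2 low-peptide, 1 with a zero
# intensity, 3 clean.
filter_fixture_table <- function(layout = cofactor_layout(replicates = "R1")) {
  obs <- layout_observations(layout)
  dial <- maxquant_dialect()
  n <- 10L
  set.seed(11)
  tbl <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                    `Protein IDs` = sprintf("FXP%02d", 1:n),
                    `Gene names` = sprintf("G%02d", 1:n),
                    `Peptides` = c(5, 5, 5, 5, 1, 1, 5, 5, 5, 5))
  for (j in seq_len(nrow(obs))) {
    cn <- adriboquant:::resolve_intensity_column(dial, obs$channel[j], obs$replicate[j])
    tbl[[cn]] <- round(runif(n, 1e5, 1e6), 1)
  }
  int_cols <- grep("^Reporter", names(tbl))
  tbl[7L, int_cols[2L]] <- 0                       # the zero-intensity row
  tbl$`Potential contaminant` <- c("+", "+", "", "", "", "", "", "", "", "")
  tbl$Reverse <- c("", "+", "+", "", "", "", "", "", "", "")  # row 2 doubly flagged
  tbl$`Only identified by site` <- c("", "", "", "+", "", "", "", "", "", "")
  tbl
}
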