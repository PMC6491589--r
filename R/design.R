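#' Design matrices for the two TMT experiment models
#'
#' @description
#' `cofactor_design()` encodes the cofactor-preference model
#'
#' `log2(normalised intensity) ~ cofactor effect (sum encoding) +
#'  log(concentration) effect + replicate effect + intercept`
#'
#' with the cofactor effect coded +1 for 2YnAd channels and -1 for 6YnAd
#' channels (so a positive coefficient means 2YnAd preference), the
#' concentration effect as the natural log of the feeding concentration in
#' mM (shared across cofactors), and 1-of-K replicate dummies with the
#' first replicate absorbed into the intercept.
#'
#' `inhibitor_design()` encodes the PARP-inhibitor model
#'
#' `log2(normalised intensity) ~ inhibitor preference effect +
#'  inhibition effect + replicate bias + intercept`
#'
#' restricted to the channels whose concentration is in
#' `included_concentrations` (default: only the 25 uM and vehicle 0 uM
#' channels, leaving out intermediate doses). Inhibitor preference is coded
#' -1 = Olaparib, +1 = Rucaparib, 0 = no inhibitor (a positive coefficient
#' means higher intensity under Rucaparib); the inhibition effect is 1
#' whenever an inhibitor is present and 0 otherwise.
#'
#' Rows follow the replicate-major observation order of
#' [layout_observations] (filtered, for the inhibitor design). Each column
#' carries a role in attribute `"roles"`: `intercept`, `cofactor_effect`,
#' `log_concentration_effect`, `inhibitor_preference`, `inhibition_effect`
#' or `replicate_bias`.
#'
#' @param layout a [tmt_layout] of the matching type.
#' @return numeric design matrix with observation keys as rownames and a
#'   `"roles"` attribute.
#' @export
cofactor_design <- function(layout) {
  stopifnot(inherits(layout, "tmt_layout"))
  if (layout$type != "cofactor") stop("cofactor_design needs a cofactor layout")
  obs <- layout_observations(layout)
  if (any(obs$conc_mM <= 0))
    stop("cofactor concentrations must be > 0 mM (log undefined at 0)")
  X <- cbind(intercept = rep(1, nrow(obs)),
             cofactor = ifelse(obs$cofactor == "2YnAd", 1, -1),
             log_conc = log(obs$conc_mM),
             replicate_dummies(obs$replicate, layout$replicates))
  rownames(X) <- obs$key
  roles <- c("intercept", "cofactor_effect", "log_concentration_effect",
             rep("replicate_bias", ncol(X) - 3L))
  structure(X, roles = roles)
}

#' @rdname cofactor_design
#' @param included_concentrations concentrations (uM) whose channels enter
#'   the model; must include 0 (the inhibition effect is unidentifiable
#'   without vehicle-control channels).
#' @export
inhibitor_design <- function(layout, included_concentrations = c(0, 25)) {
  stopifnot(inherits(layout, "tmt_layout"))
  if (layout$type != "inhibitor") stop("inhibitor_design needs an inhibitor layout")
  obs <- layout_observations(layout)
  obs <- obs[obs$conc_uM %in% included_concentrations, , drop = FALSE]
  if (!nrow(obs)) stop("no channels at the included concentrations")
  if (!any(obs$conc_uM == 0))
    stop("no zero-concentration channel included: inhibition effect unidentifiable")
  pref <- c(Olaparib = -1, none = 0, Rucaparib = 1)[obs$inhibitor]
  X <- cbind(intercept = rep(1, nrow(obs)),
             inhibitor_pref = unname(pref),
             inhibition = as.numeric(obs$conc_uM > 0),
             replicate_dummies(obs$replicate, layout$replicates))
  rownames(X) <- obs$key
  roles <- c("intercept", "inhibitor_preference", "inhibition_effect",
             rep("replicate_bias", ncol(X) - 3L))
  structure(X, roles = roles)
}

# 0/1 dummies for replicates 2..K; first replicate absorbed into intercept.
replicate_dummies <- function(replicate, levels_) {
  extra <- levels_[-1L]
  if (!length(extra)) {
    out <- matrix(numeric(0), nrow = length(replicate), ncol = 0L)
    return(out)
  }
  out <- vapply(extra, function(r) as.numeric(replicate == r),
                numeric(length(replicate)))
  colnames(out) <- paste0("rep_", extra)
  out
}

#' Design roles
#'
#' @param design a design matrix built by [cofactor_design] or
#'   [inhibitor_design].
#' @return character vector of per-column roles.
#' @export
design_roles <- function(design) {
  roles <- attr(design, "roles")
  if (is.null(roles)) stop("design matrix has no 'roles' attribute")
  roles
}

#' Validate a design matrix
#'
#' Reports rank, condition number and aliased (linearly dependent) columns,
#' and raises an error on rank deficiency.
#'
#' @param design numeric design matrix.
#' @param tol relative tolerance for rank determination.
#' @return invisibly, a list with `rank`, `condition_number` and
#'   `aliased` (character vector of dependent column names, empty when the
#'   design is full rank).
#' @export
validate_design <- function(design, tol = 1e-10) {
  X <- as.matrix(design)
  qr_ <- qr(X, tol = tol)
  aliased <- if (qr_$rank < ncol(X))
    colnames(X)[qr_$pivot[(qr_$rank + 1L):ncol(X)]] else character(0L)
  d <- svd(X, nu = 0L, nv = 0L)$d
  diag_ <- list(rank = qr_$rank,
                condition_number = if (min(d) > 0) max(d) / min(d) else Inf,
                aliased = aliased)
  if (length(aliased))
    stop("rank-deficient design: aliased column(s) ",
         paste(sQuote(aliased), collapse = ", "))
  invisible(diag_)
}

#' Export a design matrix as TSV
#'
#' Writes the matrix with a coefficient-role header row, mirroring the
#' supplementary design-matrix layout of the published analyses.
#'
#' @param design design matrix with roles.
#' @param path output path.
#' @export
write_design <- function(design, path) {
  roles <- design_roles(design)
  out <- data.frame(observation = rownames(design), as.data.frame(design),
                    check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("# roles:", roles), collapse = "\t"), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
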