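#' Remove nuisance-coefficient contributions from the intensity matrix
#'
#' For plotting, the fitted contributions of nuisance coefficients
#' (by default the replicate-bias dummies and the intercept) are
#' subtracted exactly from the normalized log2 intensities:
#' `values = Y - B_bias %*% t(X_bias)`. Because least-squares residuals
#' are orthogonal to the design, refitting the model on the debiased
#' matrix returns (numerically) zero for the removed coefficients and
#' leaves all tested effect estimates unchanged.
#'
#' @param Y proteins x observations log2 matrix the fit was computed on.
#' @param fit the [protein_fit] for `Y`.
#' @param roles coefficient roles to subtract (default replicate bias and
#'   intercept).
#' @return Object of class `debiased_matrix`: list with `values`
#'   (same shape as `Y`) and `removed_roles`.
#' @export
remove_bias <- function(Y, fit, roles = c("replicate_bias", "intercept")) {
  stopifnot(inherits(fit, "protein_fit"))
  Y <- as.matrix(Y)
  X <- fit$design
  design_r <- design_roles(X)
  roles <- unique(roles)
  absent <- setdiff(roles, design_r)
  if (length(absent))
    stop("role(s) absent from design: ", paste(sQuote(absent), collapse = ", "))
  keep <- design_r %in% roles
  values <- if (any(keep)) {
    Y - fit$coefficients[, keep, drop = FALSE] %*% t(X[, keep, drop = FALSE])
  } else Y
  structure(list(values = values, removed_roles = roles),
            class = "debiased_matrix")
}

#' Dose-response profile of one protein
#'
#' Mean debiased log2 intensity per (inhibitor, concentration) condition,
#' averaged across replicates and ordered by concentration — the
#' per-protein descriptive profile over the full dose series (vehicle
#' control included under both inhibitors).
#'
#' @param protein protein identifier (rowname of the debiased matrix).
#' @param debiased a `debiased_matrix` (or a plain log2 matrix).
#' @param layout the inhibitor [tmt_layout].
#' @return data.frame with `inhibitor`, `conc_uM`, `mean_log2`.
#' @export
dose_response_profile <- function(protein, debiased, layout) {
  stopifnot(inherits(layout, "tmt_layout"), layout$type == "inhibitor")
  V <- if (inherits(debiased, "debiased_matrix")) debiased$values else as.matrix(debiased)
  if (!protein %in% rownames(V)) stop(sprintf("unknown protein '%s'", protein))
  y <- V[protein, ]
  obs <- layout_observations(layout)
  stopifnot(identical(obs$key, colnames(V)))
  # vehicle channels contribute a shared baseline point to both arms
  arm <- rep(c("Olaparib", "Rucaparib"),
             each = nrow(layout$channels) %/% 2L)[match(obs$channel, layout$channels$channel)]
  agg <- stats::aggregate(y, by = list(inhibitor = arm, conc_uM = obs$conc_uM),
                          FUN = mean)
  names(agg)[3L] <- "mean_log2"
  agg[order(agg$inhibitor, agg$conc_uM), , drop = FALSE]
}

#' Per-protein inhibitor responses
#'
#' Operationalizes the "response" scatter: for each protein and each
#' inhibitor, the mean debiased log2 intensity at the high dose minus the
#' mean debiased log2 intensity of the vehicle-control (0 uM) channels.
#' Negative values mean the protein's ADP-ribosylation signal drops under
#' inhibition.
#'
#' @param debiased a `debiased_matrix` (or plain log2 matrix).
#' @param layout the inhibitor [tmt_layout].
#' @param high_conc dose defining the response (default 25 uM).
#' @return data.frame with one row per protein: `protein_id`,
#'   `olaparib_response`, `rucaparib_response`.
#' @export
inhibitor_responses <- function(debiased, layout, high_conc = 25) {
  stopifnot(inherits(layout, "tmt_layout"), layout$type == "inhibitor")
  V <- if (inherits(debiased, "debiased_matrix")) debiased$values else as.matrix(debiased)
  obs <- layout_observations(layout)
  stopifnot(identical(obs$key, colnames(V)))
  base_cols <- obs$conc_uM == 0
  if (!any(base_cols)) stop("no vehicle-control (0 uM) channels in layout")
  base <- rowMeans(V[, base_cols, drop = FALSE])
  resp <- function(drug) {
    cols <- obs$inhibitor == drug & obs$conc_uM == high_conc
    if (!any(cols)) stop(sprintf("no %s channels at %g uM", drug, high_conc))
    rowMeans(V[, cols, drop = FALSE]) - base
  }
  data.frame(protein_id = rownames(V) %||% as.character(seq_len(nrow(V))),
             olaparib_response = unname(resp("Olaparib")),
             rucaparib_response = unname(resp("Rucaparib")),
             stringsAsFactors = FALSE)
}

#' Volcano-plot records
#'
#' One record per protein: the tested effect estimate on the x axis and
#' `-log10(adjusted p)` on the y axis, with significance and known-target
#' annotations. An adjusted p of 0 is plotted at a configurable ceiling
#' and flagged as capped. The effect sign follows the design encoding:
#' positive means 2YnAd preference (cofactor model) or higher intensity
#' under Rucaparib (inhibitor model).
#'
#' @param stats a `moderated_stats` object.
#' @param known_targets optional logical vector aligned with `stats`
#'   (from [annotate_known_targets]).
#' @param cap ceiling for `-log10(adjusted p)` (default 16).
#' @return data.frame with `protein_id`, `effect`, `neg_log10_padj`,
#'   `significant`, `known_target`, `capped`.
#' @export
export_volcano <- function(stats, known_targets = NULL, cap = 16) {
  stopifnot(inherits(stats, "moderated_stats"), cap > 0)
  y <- -log10(stats$p_adjusted)
  capped <- !is.finite(y) | y > cap
  y[capped] <- cap
  if (is.null(known_targets)) known_targets <- rep(NA, nrow(stats))
  stopifnot(length(known_targets) == nrow(stats))
  data.frame(protein_id = stats$protein_id,
             effect = stats$estimate,
             neg_log10_padj = y,
             significant = stats$significant,
             known_target = known_targets,
             capped = capped,
             stringsAsFactors = FALSE)
}
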