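#' Run the cofactor-preference analysis end to end
#'
#' Orchestrates the published analysis chain on a cofactor (2YnAd vs
#' 6YnAd) TMT experiment: read -> quality filter -> TMM -> log2-per-million
#' -> cofactor design -> per-protein OLS -> variance prior (trend) ->
#' moderated t on the cofactor coefficient -> BH -> significance calls ->
#' optional known-target annotation -> volcano export. Deterministic given
#' inputs.
#'
#' @param input path to a proteinGroups.txt-style file, a proteinGroups
#'   data.frame, or a `protein_groups` object.
#' @param layout the cofactor [tmt_layout] (ignored when `input` is
#'   already a `protein_groups`).
#' @param dialect a [maxquant_dialect].
#' @param min_peptides quality-filter threshold (default 2).
#' @param trend,span variance-prior settings (default: intensity trend on,
#'   lowess span 0.5).
#' @param alpha adjusted-p significance threshold (default 0.01).
#' @param reference optional known-target accessions: a character vector
#'   or a path readable by [read_reference_accessions].
#' @param output_dir optional directory; when given, result tables are
#'   written as TSV/JSON.
#' @return list of class `cofactor_analysis`: `filter_report`, `norm`,
#'   `design`, `fit`, `prior`, `stats`, `volcano`, `results` (the
#'   per-protein results table), `layout`.
#' @export
run_cofactor_analysis <- function(input, layout = cofactor_layout(),
                                  dialect = maxquant_dialect(),
                                  min_peptides = 2L, trend = TRUE, span = 0.5,
                                  alpha = 0.01, reference = NULL,
                                  output_dir = NULL) {
  pg <- as_protein_groups(input, layout, dialect)
  if (pg$layout$type != "cofactor") stop("cofactor analysis needs a cofactor layout")
  flt <- apply_quality_filters(pg, min_peptides = min_peptides)
  norm <- normalize_reporters(flt$kept$intensities)
  X <- cofactor_design(pg$layout)
  fit <- fit_linear_models(norm$log2pm, X)
  prior <- estimate_variance_prior(fit, trend = trend, span = span)
  stats_ <- moderated_t_test(fit, prior, "cofactor_effect", alpha = alpha)
  known <- annotate_input(flt$kept, reference)
  volcano <- export_volcano(stats_, known_targets = known)
  results <- results_table(flt$kept, stats_, known)
  out <- structure(list(filter_report = flt$report, norm = norm, design = X,
                        fit = fit, prior = prior, stats = stats_,
                        volcano = volcano, results = results,
                        layout = pg$layout),
                   class = "cofactor_analysis")
  if (!is.null(output_dir)) write_cofactor_outputs(out, output_dir)
  out
}

#' Run the PARP-inhibitor analysis end to end
#'
#' As [run_cofactor_analysis], but: all channels (including intermediate
#' doses) pass through filtering and TMM/log2-per-million normalization,
#' while the linear model is restricted to the high-dose and
#' vehicle-control channels; the inhibitor-preference and inhibition
#' coefficients are tested separately (each BH-adjusted across proteins on
#' its own); replicate bias and intercept are subtracted for the
#' plot-ready exports (per-inhibitor response scatter and full
#' dose-response profiles over all concentrations).
#'
#' @inheritParams run_cofactor_analysis
#' @param included_concentrations doses (uM) entering the linear model
#'   (default `c(0, 25)`).
#' @return list of class `inhibitor_analysis`: `filter_report`, `norm`,
#'   `design`, `fit`, `prior`, `stats_preference`, `stats_inhibition`,
#'   `debiased` (modelled channels), `debiased_full` (all channels, for
#'   dose profiles), `responses`, `dose_profiles`, `results`, `layout`.
#' @export
run_inhibitor_analysis <- function(input, layout = inhibitor_layout(),
                                   dialect = maxquant_dialect(),
                                   included_concentrations = c(0, 25),
                                   min_peptides = 2L, trend = TRUE, span = 0.5,
                                   alpha = 0.01, reference = NULL,
                                   output_dir = NULL) {
  pg <- as_protein_groups(input, layout, dialect)
  if (pg$layout$type != "inhibitor") stop("inhibitor analysis needs an inhibitor layout")
  flt <- apply_quality_filters(pg, min_peptides = min_peptides)
  norm <- normalize_reporters(flt$kept$intensities)
  X <- inhibitor_design(pg$layout, included_concentrations)
  Y_model <- norm$log2pm[, rownames(X), drop = FALSE]
  fit <- fit_linear_models(Y_model, X)
  prior <- estimate_variance_prior(fit, trend = trend, span = span)
  stats_pref <- moderated_t_test(fit, prior, "inhibitor_preference", alpha = alpha)
  stats_inh <- moderated_t_test(fit, prior, "inhibition_effect", alpha = alpha)
  deb <- remove_bias(Y_model, fit)
  # debiased values across the full dose series, for descriptive profiles
  full_deb <- debias_full_series(norm$log2pm, fit, pg$layout)
  responses <- inhibitor_responses(full_deb, pg$layout)
  dose_profiles <- do.call(rbind, lapply(rownames(norm$log2pm), function(pid) {
    prof <- dose_response_profile(pid, full_deb, pg$layout)
    cbind(protein_id = pid, prof)
  }))
  rownames(dose_profiles) <- NULL
  known <- annotate_input(flt$kept, reference)
  results <- results_table(flt$kept, stats_pref, known,
                           extra = list(inhibition = stats_inh))
  out <- structure(list(filter_report = flt$report, norm = norm, design = X,
                        fit = fit, prior = prior,
                        stats_preference = stats_pref,
                        stats_inhibition = stats_inh,
                        debiased = deb, debiased_full = full_deb,
                        responses = responses,
                        dose_profiles = dose_profiles, results = results,
                        layout = pg$layout),
                   class = "inhibitor_analysis")
  if (!is.null(output_dir)) write_inhibitor_outputs(out, output_dir)
  out
}

# Subtract intercept + replicate-bias contributions from the full-series
# matrix using coefficients fitted on the modelled channels; exact on the
# modelled channels, first-order on the intermediate doses.
debias_full_series <- function(Y, fit, layout) {
  obs <- layout_observations(layout)
  roles <- design_roles(fit$design)
  bias <- roles %in% c("intercept", "replicate_bias")
  Xb_model <- fit$design[, bias, drop = FALSE]
  # rebuild the bias columns for every observation of the full layout
  Xb_full <- cbind(intercept = rep(1, nrow(obs)),
                   replicate_dummies(obs$replicate, layout$replicates))
  colnames(Xb_full) <- colnames(Xb_model)
  V <- as.matrix(Y) - fit$coefficients[, bias, drop = FALSE] %*% t(Xb_full)
  structure(list(values = V, removed_roles = c("intercept", "replicate_bias")),
            class = "debiased_matrix")
}

as_protein_groups <- function(input, layout, dialect) {
  if (inherits(input, "protein_groups")) return(input)
  if (is.data.frame(input)) return(protein_groups_from_table(input, layout, dialect))
  if (inherits(input, "synthetic_experiment"))
    return(protein_groups_from_table(input$table, input$layout, dialect))
  if (is.character(input) && length(input) == 1L)
    return(read_protein_groups(input, layout, dialect))
  stop("input must be a path, a data.frame or a protein_groups object")
}

annotate_input <- function(pg, reference) {
  if (is.null(reference)) return(rep(NA, nrow(pg$annotations)))
  if (is.character(reference) && length(reference) == 1L && file.exists(reference))
    reference <- read_reference_accessions(reference)
  annotate_known_targets(pg$annotations$protein_ids, reference)
}

results_table <- function(pg, stats_, known, extra = NULL) {
  ann <- pg$annotations
  out <- data.frame(protein_id = ann$protein_id,
                    gene_names = ann$gene_names,
                    estimate = stats_$estimate,
                    t = stats_$t,
                    p_value = stats_$p_value,
                    p_adjusted = stats_$p_adjusted,
                    significant = stats_$significant,
                    amean = stats_$amean,
                    known_target = known,
                    stringsAsFactors = FALSE)
  for (nm in names(extra)) {
    e <- extra[[nm]]
    add <- e[, c("estimate", "t", "p_value", "p_adjusted", "significant")]
    names(add) <- paste(nm, names(add), sep = "_")
    out <- cbind(out, add)
  }
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_cofactor_outputs <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(x$results, file.path(dir, "cofactor_results.tsv"))
  write_tsv(x$volcano, file.path(dir, "cofactor_volcano.tsv"))
  write_design(x$design, file.path(dir, "cofactor_design.tsv"))
  write_filter_report(x$filter_report, file.path(dir, "filter_report.json"))
  invisible(dir)
}

write_inhibitor_outputs <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(x$results, file.path(dir, "inhibitor_results.tsv"))
  write_tsv(x$responses, file.path(dir, "inhibitor_responses.tsv"))
  write_tsv(x$dose_profiles, file.path(dir, "dose_response_profiles.tsv"))
  write_design(x$design, file.path(dir, "inhibitor_design.tsv"))
  write_filter_report(x$filter_report, file.path(dir, "filter_report.json"))
  invisible(dir)
}

#' @export
print.cofactor_analysis <- function(x, ...) {
  cat(sprintf("cofactor analysis: %d proteins retained, %d significant at adjusted p < %g\n",
              x$filter_report$n_kept, sum(x$stats$significant),
              attr(x$stats, "alpha")))
  invisible(x)
}

#' @export
print.inhibitor_analysis <- function(x, ...) {
  cat(sprintf(paste0("inhibitor analysis: %d proteins retained; ",
                     "%d significant preference, %d significant inhibition ",
                     "(adjusted p < %g)\n"),
              x$filter_report$n_kept,
              sum(x$stats_preference$significant),
              sum(x$stats_inhibition$significant),
              attr(x$stats_preference, "alpha")))
  invisible(x)
}
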