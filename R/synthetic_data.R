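#' Configuration for the synthetic proteinGroups generator
#'
#' @description
#' Defines a simulated TMT experiment whose generative model matches the
#' analysis model exactly: per clean protein a baseline log2 abundance, an
#' error variance drawn from a scaled inverse-chi-square prior (or an
#' intensity-dependent trend), additive log2-scale effects wired through
#' the experiment's design encoding, replicate offsets, and Gaussian
#' noise. Intensities are exponentiated (base 2) and columns rescaled to
#' target library sizes; decoy rows (contaminants, reverse hits,
#' low-peptide and zero-intensity proteins) are appended with MaxQuant
#' marker conventions.
#'
#' For the cofactor experiment, a `fraction_responsive` subset of proteins
#' receives a cofactor-preference effect of random sign with log2
#' magnitude `N(effect_mean, effect_sd)`; every protein receives a small
#' concentration slope `N(slope_mean, slope_sd)` (log2 per unit natural-log
#' mM). For the inhibitor experiment the responsive subset receives an
#' inhibition effect of magnitude `N(effect_mean, effect_sd)` with sign
#' `inhibition_sign` (default -1: inhibitors suppress ADP-ribosylation)
#' and, with probability `fraction_preference` among responsive proteins,
#' an inhibitor-preference effect of random sign and the same magnitude
#' law. Intermediate doses are generated with a saturating dose scaling
#' `m(c) = log1p(c/ec50) / log1p(c_max/ec50)` so that effects are exactly
#' the encoded values at the highest dose and zero at the vehicle control.
#'
#' @param experiment `"cofactor"` or `"inhibitor"`.
#' @param n_proteins number of clean (analysable) proteins.
#' @param layout a [tmt_layout]; default built from `experiment`.
#' @param fraction_responsive fraction of clean proteins with a nonzero
#'   primary effect.
#' @param fraction_preference (inhibitor only) fraction of responsive
#'   proteins that additionally prefer one inhibitor.
#' @param effect_mean,effect_sd log2 effect-magnitude distribution.
#' @param inhibition_sign sign of the shared inhibition effect.
#' @param slope_mean,slope_sd (cofactor only) concentration-slope
#'   distribution.
#' @param replicate_offsets per-replicate log2 biases (first should be 0;
#'   it is absorbed into the intercept at analysis time).
#' @param baseline_mean,baseline_sd log2 baseline-abundance distribution.
#' @param d0_true,s02_true scaled inverse-chi-square variance prior
#'   (prior df and scale).
#' @param trend_fun optional function mapping baseline log2 abundance
#'   (centred) to the prior variance scale, overriding `s02_true`.
#' @param n_contaminants,n_reverse,n_low_peptide,n_with_zeros decoy-row
#'   counts.
#' @param library_size_range range of per-column intensity totals for the
#'   clean proteins.
#' @param ec50_uM half-saturation dose for intermediate-concentration
#'   scaling (inhibitor experiment).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(experiment = c("cofactor", "inhibitor"),
                              n_proteins = 5000L,
                              layout = NULL,
                              fraction_responsive = 0.10,
                              fraction_preference = 0.5,
                              effect_mean = 1,
                              effect_sd = 0.25,
                              inhibition_sign = -1,
                              slope_mean = 0,
                              slope_sd = 0.05,
                              replicate_offsets = NULL,
                              baseline_mean = 10,
                              baseline_sd = 2,
                              d0_true = 4,
                              s02_true = 0.05,
                              trend_fun = NULL,
                              n_contaminants = 20L,
                              n_reverse = 20L,
                              n_low_peptide = 20L,
                              n_with_zeros = 20L,
                              library_size_range = c(5e8, 1.5e9),
                              ec50_uM = 1,
                              seed = 1L) {
  experiment <- match.arg(experiment)
  if (is.null(layout))
    layout <- if (experiment == "cofactor") cofactor_layout() else inhibitor_layout()
  stopifnot(inherits(layout, "tmt_layout"), layout$type == experiment)
  if (is.null(replicate_offsets))
    replicate_offsets <- c(0, rep(0.3, length(layout$replicates) - 1L))
  stopifnot(length(replicate_offsets) == length(layout$replicates),
            fraction_responsive >= 0, fraction_responsive <= 1,
            fraction_preference >= 0, fraction_preference <= 1,
            d0_true > 0, s02_true > 0, all(library_size_range > 0),
            n_proteins >= 1)
  structure(as.list(environment()), class = "sim_config")
}

# scaled-inv-chi2(d0, s02): sigma2 = d0 * s02 / chi2_d0
rsinvchisq <- function(n, d0, s02) d0 * s02 / stats::rchisq(n, df = d0)

#' Generate a synthetic MaxQuant-style TMT experiment
#'
#' Draws a proteinGroups-style table plus its ground truth under the
#' configured generative model. Accessions are labelled `SYNPnnnnn` (and
#' `CON__`/`REV__` prefixes for contaminant/reverse decoys) to make the
#' synthetic provenance explicit. Clean-protein columns are rescaled so
#' their sums equal the drawn library sizes; decoy rows are appended
#' afterwards.
#'
#' @param config a [simulation_config].
#' @return list of class `synthetic_experiment` with `table` (data.frame
#'   in MaxQuant proteinGroups schema), `truth` (data.frame of per-protein
#'   true coefficients, variances, responsiveness and decoy class),
#'   `layout` and `config`.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)

  layout <- config$layout
  obs <- layout_observations(layout)
  n <- config$n_proteins
  nobs <- nrow(obs)

  # per-protein truth
  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  s02_g <- if (is.null(config$trend_fun)) rep(config$s02_true, n)
           else config$trend_fun(baseline - mean(baseline))
  sigma2 <- rsinvchisq(n, config$d0_true, s02_g)
  responsive <- stats::runif(n) < config$fraction_responsive
  magnitude <- function(k) stats::rnorm(k, config$effect_mean, config$effect_sd)

  truth <- data.frame(protein_id = sprintf("SYNP%05d", seq_len(n)),
                      responsive = responsive, sigma2 = sigma2,
                      decoy = "clean", stringsAsFactors = FALSE)
  rep_off <- stats::setNames(config$replicate_offsets, layout$replicates)

  if (layout$type == "cofactor") {
    cof <- ifelse(responsive, sample(c(-1, 1), n, replace = TRUE) * magnitude(n), 0)
    slope <- stats::rnorm(n, config$slope_mean, config$slope_sd)
    truth$cofactor_effect <- cof
    truth$log_concentration_effect <- slope
    enc_cof <- ifelse(obs$cofactor == "2YnAd", 1, -1)
    mu <- outer(baseline, rep(1, nobs)) +
      outer(cof, enc_cof) +
      outer(slope, log(obs$conc_mM)) +
      matrix(rep_off[obs$replicate], n, nobs, byrow = TRUE)
  } else {
    inhib <- ifelse(responsive, config$inhibition_sign * abs(magnitude(n)), 0)
    has_pref <- responsive & stats::runif(n) < config$fraction_preference
    pref <- ifelse(has_pref, sample(c(-1, 1), n, replace = TRUE) * abs(magnitude(n)), 0)
    truth$inhibition_effect <- inhib
    truth$inhibitor_preference <- pref
    cmax <- max(obs$conc_uM)
    dose_scale <- log1p(obs$conc_uM / config$ec50_uM) /
      log1p(cmax / config$ec50_uM)
    enc_pref <- c(Olaparib = -1, none = 0, Rucaparib = 1)[obs$inhibitor]
    mu <- outer(baseline, rep(1, nobs)) +
      outer(pref, unname(enc_pref) * dose_scale) +
      outer(inhib, dose_scale) +
      matrix(rep_off[obs$replicate], n, nobs, byrow = TRUE)
  }

  log2_int <- mu + matrix(stats::rnorm(n * nobs, sd = rep(sqrt(sigma2), nobs)),
                          n, nobs)
  intens <- 2^log2_int
  lib <- stats::runif(nobs, config$library_size_range[1L],
                      config$library_size_range[2L])
  intens <- sweep(intens, 2L, lib / colSums(intens), "*")
  colnames(intens) <- obs$key

  # decoy rows: plausible intensities, flagged so the quality filter
  # removes each under a known rule
  n_decoy <- config$n_contaminants + config$n_reverse +
    config$n_low_peptide + config$n_with_zeros
  decoy_class <- rep(c("contaminant", "reverse", "low_peptide", "with_zeros"),
                     times = c(config$n_contaminants, config$n_reverse,
                               config$n_low_peptide, config$n_with_zeros))
  if (n_decoy > 0) {
    d_base <- stats::rnorm(n_decoy, config$baseline_mean, config$baseline_sd)
    d_int <- 2^(outer(d_base, rep(1, nobs)) +
                  matrix(stats::rnorm(n_decoy * nobs, sd = 0.3), n_decoy, nobs))
    d_int <- d_int * stats::median(intens) / stats::median(d_int)
    zero_rows <- which(decoy_class == "with_zeros")
    for (i in zero_rows) d_int[i, sample.int(nobs, 1L)] <- 0
  } else {
    d_int <- matrix(numeric(0), 0L, nobs)
  }

  ids <- c(truth$protein_id,
           sprintf("%s%05d",
                   c(contaminant = "CON__SYNC", reverse = "REV__SYNR",
                     low_peptide = "SYNL", with_zeros = "SYNZ")[decoy_class],
                   seq_len(n_decoy)))
  peptides <- c(sample(2:40, n, replace = TRUE),
                ifelse(decoy_class == "low_peptide", 1L,
                       sample(2:40, n_decoy, replace = TRUE)))
  tbl <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                    `Protein IDs` = ids,
                    `Majority protein IDs` = ids,
                    `Gene names` = sub("^(CON__|REV__)", "", ids),
                    `Peptides` = peptides,
                    `Razor + unique peptides` = peptides)
  all_int <- rbind(intens, d_int)
  for (j in seq_len(nobs)) {
    cn <- resolve_intensity_column(maxquant_dialect(), obs$channel[j],
                                   obs$replicate[j])
    tbl[[cn]] <- all_int[, j]
  }
  mark <- function(cond) ifelse(cond, "+", "")
  cls <- c(rep("clean", n), decoy_class)
  tbl[["Only identified by site"]] <- mark(rep(FALSE, n + n_decoy))
  tbl[["Reverse"]] <- mark(cls == "reverse")
  tbl[["Potential contaminant"]] <- mark(cls == "contaminant")

  if (n_decoy > 0) {
    d_truth <- truth[rep(NA_integer_, n_decoy), , drop = FALSE]
    d_truth$protein_id <- ids[(n + 1L):(n + n_decoy)]
    d_truth$responsive <- FALSE
    d_truth$decoy <- decoy_class
    d_truth[is.na(d_truth)] <- 0
    truth <- rbind(truth, d_truth)
    rownames(truth) <- NULL
  }

  structure(list(table = tbl, truth = truth, layout = layout, config = config),
            class = "synthetic_experiment")
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' @rdname generate_experiment
#' @description `generate_null_experiment()` is the type-I-error harness:
#'   identical generator with all responsive fractions forced to zero, so
#'   every true effect coefficient is exactly 0.
#' @export
generate_null_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$fraction_responsive <- 0
  generate_experiment(config)
}

#' Write a proteinGroups-style table as TSV
#'
#' Schema-compatible with MaxQuant proteinGroups.txt, round-trippable
#' through [read_protein_groups].
#'
#' @param x a `synthetic_experiment` or a proteinGroups-style data.frame.
#' @param path output path.
#' @export
write_protein_groups <- function(x, path) {
  tbl <- if (inherits(x, "synthetic_experiment")) x$table else x
  stopifnot(is.data.frame(tbl))
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("synthetic %s experiment: %d clean + %d decoy rows, %d reporter columns (seed %d)\n",
              x$layout$type, x$config$n_proteins,
              nrow(x$table) - x$config$n_proteins,
              nrow(layout_observations(x$layout)), x$config$seed))
  invisible(x)
}
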