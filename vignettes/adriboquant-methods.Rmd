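---
title: "Models and methods behind adriboquant"
author: "adriboquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind adriboquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adriboquant)
```

## The scientific problem

ADP-ribosylation is a post-translational modification in which PARP enzymes
transfer ADP-ribose from NAD⁺ onto protein side chains. Feeding cells
cell-permeable alkyne-tagged adenosine analogues (2YnAd or 6YnAd) converts a
fraction of the NAD⁺ pool into a clickable analogue, so ADP-ribosylated
proteins can be enriched and quantified by multiplexed (TMT) mass
spectrometry. Two experiment types are supported:

* **Cofactor preference** (TMT6plex): both analogues fed in parallel at a
  dilution series (1, 0.5, 0.25 mM). The question per protein is whether its
  labelling prefers 2YnAd or 6YnAd.
* **PARP-inhibitor response** (TMT10plex): cells treated with Olaparib or
  Rucaparib at 25, 5, 1, 0.2 and 0 µM (vehicle), then dual-labelled. The
  questions are whether a protein's ADP-ribosylation signal responds to
  inhibition at all, and whether it responds differently to the two drugs.

The package consumes MaxQuant `proteinGroups.txt` output (corrected
reporter-ion intensities) and carries the analysis to per-protein moderated
statistics and plot-ready tables.

## Pre-processing

Protein groups are discarded, in this order, when they are flagged as
potential contaminants, reverse (decoy) hits, or only identified by a
modification site; when they have fewer than two peptides; and finally when
any declared (replicate, channel) observation has a zero intensity. Each
group is tallied once under the first rule that removes it, so the
`filter_report` counters reconcile exactly with the kept count. The peptide
filter defaults to MaxQuant's `Peptides` column (all peptides, the literal
reading of "fewer than two peptides"); `Razor + unique peptides` can be
selected through `maxquant_dialect()` instead. No imputation is performed
anywhere: requiring strictly positive intensities in every channel is what
makes the later log transform exact.

## Normalization

Surviving intensities are normalized with the trimmed mean of M-values
(TMM): for each column against a reference column, per-protein log-ratios
`M` and average log-abundances `A` are formed from library-size-scaled
intensities; the top and bottom 30% of `M` and 5% of `A` are trimmed; the
column factor is 2 to the precision-weighted mean of the remaining `M`
(inverse asymptotic variance weights), and factors are rescaled to
geometric mean 1. The reference defaults to the column whose upper-quartile
scaled intensity is closest to the mean upper-quartile; trim fractions are
exposed but default to the method's canonical 30%/5%. Normalization runs
jointly across all replicates' columns of an experiment — including, for
the inhibitor experiment, the intermediate-dose channels, which occupy TMT
channels and therefore contribute to library sizes whether or not they are
modelled.

Normalized values are `log2(1e6 * y / (library size * factor))`
(log2-per-million). No prior count is added by default since zeros were
filtered out; a configurable prior count exists for robustness on
unfiltered input.

## The two linear models

Per protein, the normalized log2 intensities are modelled as linear in a
shared design. For the cofactor experiment:

* cofactor effect, sum-encoded (+1 = 2YnAd, −1 = 6YnAd), so a positive
  coefficient means 2YnAd preference and the coefficient is half the
  symmetric contrast;
* log(concentration) effect: the natural log of the feeding concentration
  in mM, shared across cofactors. The log base only rescales this
  coefficient (and never the t statistic); natural log is used and
  documented here because the choice is otherwise arbitrary;
* replicate bias: 0/1 dummies with the first replicate absorbed into the
  intercept;
* intercept.

For the inhibitor experiment the model is fit only on the high-dose (25 µM)
and vehicle (0 µM) channels — reporters 0, 4, 5 and 9 in the default
channel order — leaving intermediate doses out of inference to avoid
overfitting, while they still pass through normalization and the
descriptive dose-response profiles:

* inhibitor preference: −1 = Olaparib, +1 = Rucaparib, 0 = vehicle, so a
  positive coefficient means higher intensity under Rucaparib;
* inhibition effect: 1 where any inhibitor is present, 0 otherwise;
  negative estimates mean the signal drops under inhibition;
* replicate bias and intercept as above.

`validate_design()` checks rank and reports aliased columns before any
fitting; the classical dummy-variable trap (both replicates' dummies plus
an intercept) is rejected with the offending columns named.

## Empirical-Bayes moderated testing

Per protein the model is fit by ordinary least squares, giving coefficients
`b_g`, residual variance `s²_g` on `d_g = n − rank(X)` degrees of freedom,
and average log2 intensity `A_g`. Residual variances are then shrunk toward
a hierarchical prior: the model treats `σ²_g` as drawn from a scaled
inverse-chi-square prior with degrees of freedom `d₀` and an
intensity-dependent scale `s₀²(A)`. On the log scale, `z_g = log s²_g` has
known chi-square sampling moments (digamma/trigamma identities); the
location of `z` is estimated by a lowess curve on `A_g` (span 0.5 by
default; a constant when `trend = FALSE`), and the excess of the observed
dispersion of `z` over the sampling floor `trigamma(d_g/2)` is inverted
through the trigamma function (Newton iteration from the asymptotic seed,
tolerance 1e-8, at most 50 iterations) to give `d₀`. When the observed
dispersion does not exceed the sampling floor, `d₀ = ∞` and the prior
collapses onto the trend. Perfect fits (`s²_g = 0`) are floored at machine
epsilon times the mean variance so they still participate.

The posterior variance is the convex combination
`s̃²_g = (d₀·s₀²(A_g) + d_g·s²_g) / (d₀ + d_g)`, and the moderated
statistic `t_g = b_g / (s̃_g √v_j)` is referred to a t distribution with
`d₀ + d_g` degrees of freedom (standard normal when `d₀ = ∞`). Setting
`d₀ = 0` reproduces the classical per-protein t test exactly, which the
test suite asserts. Tests are two-sided; each tested coefficient (the
cofactor effect; the inhibitor preference and the inhibition effect,
separately) is Benjamini-Hochberg adjusted across proteins on its own,
never pooled across coefficients, and calls use the strict rule
`adjusted p < 0.01` by default.

## Debiasing and plot exports

For visualization the fitted contributions of the nuisance terms (replicate
bias and intercept by default) are subtracted exactly from the normalized
matrix. Because least-squares residuals are orthogonal to the design, this
changes no tested effect estimate and refitting on the debiased matrix
returns numerically zero nuisance coefficients — asserted to 1e-10 in the
tests. The inhibitor "response" scatter is computed per protein and per
inhibitor as the mean debiased log2 intensity at 25 µM minus the mean over
the vehicle channels; both arms' vehicle controls are pooled as the
baseline since both are DMSO-only conditions, while the per-protein
dose-response profiles keep each arm's own vehicle point as the 0 µM entry.
Averaging over replicates before or after the subtraction is equivalent
because the subtraction is exact. Volcano records carry the signed effect
and `−log10(adjusted p)` capped at 16 for zero p-values (flagged as
capped).

## The synthetic-data generator

`generate_experiment()` emits a MaxQuant-schema proteinGroups table with
ground truth. Intensities are generated on the log2 scale and
exponentiated, so the analysis model is exactly the generative model —
deliberately, to make parameter recovery a sharp test rather than a
robustness study. Defaults, chosen once as typical for TMT proteomics of
cultured cells:

* baseline log2 abundance N(10, 2); column library sizes uniform in
  5e8–1.5e9 (arbitrary MS units), with clean-protein columns rescaled to
  hit them within 0.1%;
* residual variances from a scaled inverse-chi-square prior with `d₀ = 4`,
  `s₀² = 0.05` (residual sd typically ~0.2 log2 units), optionally an
  intensity-dependent scale via `trend_fun`;
* replicate offsets 0 and +0.3 log2 — a realistic technical-replicate bias
  that the replicate dummies must absorb;
* 10% responsive proteins with log2 effect magnitudes N(1, 0.25) of random
  sign (cofactor) or negative inhibition effects plus optional inhibitor
  preference (inhibitor experiment);
* 20 each of contaminant, reverse, one-peptide and zero-injected decoy
  rows, each guaranteed to be removed by a known filter rule (the
  zero-injection replaces exactly one random channel);
* clean peptide counts uniform 2–40; decoy low-peptide rows get exactly 1.

Intermediate inhibitor doses are generated with a saturating scaling
`m(c) = log1p(c/EC50)/log1p(c_max/EC50)` (EC50 = 1 µM), so effects equal
the design encodings at 25 µM and vanish at 0 µM; the analysis never fits
those channels, so this choice only shapes the descriptive profiles. The
generator is byte-reproducible from its seed and restores the caller's RNG
state.

What the generator does **not** emulate — reporter-ion ratio compression,
isotope-impurity cross-talk, peptide-to-protein rollup, missingness that
correlates with abundance — bounds what green tests mean: they validate
the statistical chain under its own assumptions, not MaxQuant's behaviour
on raw spectra.

## Numerical and calibration choices

Problem sizes in the test suite were picked to make sampling noise
negligible relative to the asserted tolerances: variance-prior recovery and
null calibration run at 5000 proteins, the null calibration over 20
generator seeds. For the null calibration, each seed's p-value vector is
checked for uniformity at KS level 0.01; since a correct implementation
fails a level-0.01 test about once per 20 tries, the suite requires at
least 18 of 20 passes (the probability of three or more chance failures is
below 0.001) and a BH-significant fraction at most 0.02 in every seed.

A worked example of the full chain, with the numbers it prints:

```{r example}
cfg <- simulation_config("cofactor", n_proteins = 2000, seed = 42)
sim <- generate_experiment(cfg)
res <- run_cofactor_analysis(sim)
res
res$prior
head(res$results[order(res$results$p_adjusted), ], 5)
```

## Known limitations

* Protein groups are never split; the first accession is the identity.
* No robust empirical Bayes (outlier variances are shrunk like any other),
  no observation weights, no intra-block correlation modelling.
* TMM assumes most proteins are not differential; experiments violating
  that (e.g. global ADP-ribosylome collapse at high inhibitor dose) will
  push factors away from 1 and bias small effects toward zero.
* The published headline retention counts from the original deposited raw
  data require the upstream MaxQuant search and are outside this package's
  scope; the pipeline reproduces the analysis chain, validated on synthetic
  data with known truth.
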