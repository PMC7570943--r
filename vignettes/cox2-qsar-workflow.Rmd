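---
title: "QSAR modelling and ligand triage with cox2qsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QSAR modelling and ligand triage with cox2qsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cox2qsar)
```

## The modelling problem

Selective cyclooxygenase-2 (COX-2) inhibitors relieve inflammation with
fewer gastrointestinal side effects than non-selective NSAIDs, which also
block the constitutive COX-1 isoform. A common strategy for finding new
selective inhibitors starts from a well-characterised pivot (rofecoxib),
collects a series of analogues with measured half-maximal inhibitory
concentrations (IC50, nanomolar), and models activity as a function of
simple pharmacophore descriptor counts emitted by a pharmacophore-alignment
tool: number of atoms (ATM), aromatic features (ARO), hydrogen-bond donors
(DONN) and acceptors (ACC).

Activity is modelled on the pIC50 scale, `pIC50 = -log10(IC50 [M])`, which
homogenises a series spanning four orders of magnitude in concentration.
The model is ordinary multiple linear regression,

    pIC50 = b0 + b1 x1 + ... + bp xp + e,

fitted by least squares on a training series and judged by the multiple
correlation coefficient R, the coefficient of determination R², the
explained variance (adjusted R²), the standard error of estimate SEE, and
the variance ratio F. `cox2qsar` implements this workflow end to end,
together with the desk-scale arithmetic used downstream of the model when
triaging screening candidates (Tanimoto similarity, paired-atom RMSD,
Lipinski rule-of-five counting, and binding free-energy bookkeeping).

The package ships the full printed tables of the study it reproduces —
training set, internal and external validation activities and predictions,
candidate descriptors, physicochemical profiles — as plain CSV fixtures, so
every headline statistic can be recomputed offline (see `?cox2_fixtures`).

## Descriptor selection

Descriptors are screened by their Pearson correlation with pIC50
(`correlation_report()`, `select_descriptors()`). Selection is **sign
blind**: a descriptor correlated at −0.64 (the acceptor count, which
depresses activity) is as informative as one at +0.64, so the retention
rule is `|r| >= cutoff`. The default cutoff of 0.4 is the study's
convention; on the packaged training set it retains all four descriptors
(ATM 0.7651, ARO 0.7358, DONN 0.4743, ACC −0.6399).

A constant descriptor column has no defined correlation; rather than
propagate `NA`, the report raises an error naming the offending column.

## Exhaustive model enumeration

With `n` retained descriptors, `model_leaderboard()` fits every non-empty
subset — `choose(n, p)` models at each size `p`, `2^n − 1 = 15` models for
the default four descriptors — and ranks them. The published account of
this campaign tabulates only three of the four possible three-descriptor
models; the leaderboard here always emits all `choose(n, p)` models, since
an exhaustive enumeration is what the combination count promises. Ranking
defaults to R² descending; ties break toward the smaller subset (parsimony)
and then lexicographic model id, a rule the source leaves unstated.

The quality statistics are computed from the residuals at full precision:

* `R2 = 1 − SSE/SST`, `R = +sqrt(R2)` (multiple correlation is
  non-negative by construction),
* `R2_adj = 1 − (1 − R2)(n − 1)/(n − p − 1)`,
* `SEE = sqrt(SSE/(n − p − 1))` — residual degrees of freedom in the
  denominator, which is what makes the published mono-model F of 25.4183
  and adjusted R² of 0.5623 mutually consistent at n = 20,
* `F = (R2/p) / ((1 − R2)/(n − p − 1))`.

Designs are checked for rank before fitting; a collinear column is
reported by name rather than silently dropped. Fits require
`n > p + 1` so that every statistic above is defined.

## Printed versus refitted coefficients

Published prediction tables are printed from coefficients rounded to four
decimals, while a refit carries full precision; at the fourth decimal the
two can differ (the refit slope of the single-descriptor model is 0.1112
against a printed 0.1111). The package therefore keeps two evaluation
routes:

* `fit_mlr()` — full-precision refit; statistics agree with the published
  table to the printed precision.
* `cox2_equation()` / `qsar_equation()` — "as printed" mode: affine
  evaluation of the published 4-decimal coefficients, which reproduces the
  published prediction and residual tables exactly.

Validation predictions for the held-out molecules were published from
full-precision coefficients and their descriptor counts were never printed,
so those rows ship as data (`cox2_prediction_tables()`) rather than being
recomputed.

## Validation and outlier handling

`residual_table()` tabulates observed − predicted per compound and model;
`flag_outliers()` partitions records at `|residual| > threshold`, with the
study's threshold of 0.4 pIC50 units as default. `external_validation()`
restricts to the held-out external compounds and summarises the maximum
and mean absolute residual. Two historical inconsistencies in the source
tables are preserved verbatim and documented in `?cox2_fixtures` rather
than corrected: celecoxib's activity is listed as 8.4390 in the study table
but validated against 9.2839 (the value implied by its 0.52 nM IC50), and
training molecule 15 is printed as 8.3000 where its 5.00 nM IC50 implies
8.3010.

## Screening filters

* **Tanimoto** (`tanimoto()`, `filter_by_tanimoto()`): `M11/(M01+M10+M11)`
  on equal-length bit vectors; retention is strict (`> cutoff`), default
  cutoff 0.35 (the campaign's final cut; 0.3 is its documented looser
  alternative). Two all-zero fingerprints have no defined similarity; the
  package returns 0 with a warning so batch filtering never aborts.
* **RMSD** (`rmsd()`): root mean square of paired-atom Euclidean
  distances, in Å. No superposition or atom matching is performed — the
  formula is a paired-distance measure, and pose alignment belongs to the
  docking software that produced the coordinates. Inputs must arrive
  index-paired.
* **Lipinski** (`lipinski_violations()`): counts violations of MW ≤ 500
  g/mol, logP ≤ 5, donors ≤ 5, acceptors ≤ 10. The screening stage
  (`run_screen()`) tolerates one violation by default.

## Free-energy bookkeeping

`delta_g_from_ki()` converts an inhibition constant to a binding free
energy with R = 1.987e-3 kcal/(mol K). The source methodology prints the
relation as `dG = −RT ln Ki`, which yields a *positive* number for a
sub-molar Ki — the opposite sign of the favourable (negative) docking
energies reported alongside it. Both conventions are implemented behind a
mode flag; the default is the as-printed sign for fidelity, and
`mode = "thermodynamic"` gives the standard `+RT ln Ki`. The two modes are
exact negations; as a function of Ki the as-printed form is strictly
decreasing and the thermodynamic form strictly increasing.

`mmgbsa_bind()` aggregates MM-GBSA end-state terms: per-term differences
`complex − receptor − ligand`, then the sum of internal, electrostatic,
van der Waals, polar (GB) and non-polar solvation terms plus the entropy
term −TΔS. An entropy term absent from all three states contributes zero
and flags the result (`entropy_included = FALSE`), since end-state MM-GBSA
reports commonly omit it. No molecular dynamics, trajectory parsing or
GB/SA evaluation is performed — published ΔG_bind values derive from
100-ns simulations and are shipped as reference data only
(`cox2_mmgbsa_affinities()`).

## Synthetic data: what it emulates, what it does not

The generators (`generate_training_table()`, `generate_fingerprints()`,
`generate_coordinate_pair()`) are pure functions of an explicit seed; they
never touch the caller's RNG stream. `linear_generator_spec()` defaults to
the study conditions: 20 compounds, descriptor ranges matching the
training set (ATM 29–50, ARO 1–4, DONN 0–3, ACC 2–5), the published
four-descriptor equation as generating coefficients, and Gaussian noise
with SD 0.22 pIC50 units — the residual scale (SEE) of the fitted model.

These tables reproduce the *statistical* regime of the real data: integer
descriptors in realistic ranges, a linear signal of the observed strength,
homoscedastic noise. They do not emulate what makes real descriptor tables
hard: correlated descriptors (aromatic count and atom count co-vary in
real series), heteroscedastic assay error, series effects from shared
scaffolds, or any chemistry. A pipeline that passes on synthetic tables is
verified as *numerically correct*, not as predictive on new chemotypes.

With `noise_sd = 0` the full pipeline is an exact round trip: fitting
recovers the generating coefficients to 1e-6 and R² = 1. At the default
noise the mean fitted R² is checked against an independent Monte-Carlo
reimplementation (120 replicates in the test suite, agreement within
0.05).

## Numerical conventions

* Internal computation is double precision throughout; rounding to 4
  decimals happens only at presentation and in the as-printed equations.
* Comparisons against published 4-decimal values use an absolute tolerance
  of 1e-4 (the printed tables truncate rather than round in places, so a
  stricter band would reject correct arithmetic).
* `pearson()` clamps to [−1, 1] against last-bit overshoot and refuses
  zero-variance input.
* Test problem sizes are chosen to keep the whole suite in seconds:
  oracle-equivalence tables of 5–8 compounds, 120 Monte-Carlo replicates,
  10^4-atom coordinate pairs for the chi-distribution RMSD check.

## End-to-end use

```{r pipeline, eval = FALSE}
run <- run_qsar(cox2_training_set(),
                external = NULL,
                config = qsar_config(correlation_cutoff = 0.4))
run$best_model            # the four-descriptor model, R2 = 0.9250

screen <- run_screen(cox2_equation("tetra"), cox2_candidates(),
                     properties = cox2_properties())
screen$report             # Z-964 (9.5272) > Z-627 (9.3458) > ... ranked
```

A thin command-line front end over the same functions ships at
`system.file("cli", "cox2qsar.R", package = "cox2qsar")` with subcommands
`qsar`, `screen`, `simulate` and `fixtures` (exit codes: 0 success, 2
configuration error, 3 data error, 4 ordering error).

## Limitations

The package computes the desk-scale mathematics of the campaign. It does
not perform pharmacophore extraction, database screening, ADMET/toxicity
prediction, docking, or molecular dynamics, and it does not attempt to
reproduce quantities that depend on those stages (screening hit counts,
docking energies, trajectory-averaged MM-GBSA values). Fingerprint
generation from SMILES is likewise out of scope: fingerprints enter as
bitstrings, so the similarity stage carries no chemistry dependency.
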