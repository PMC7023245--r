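---
title: "Methods: holdout random sampling and neural regression of ddG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: holdout random sampling and neural regression of ddG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddgsampler)
```

## The model

The effect of an amino-acid substitution on protein stability is measured
as the change in unfolding free energy, ddG (kcal/mol); its sign separates
stabilizing from destabilizing mutations. The central modelling assumption
of this package is that **every substitution type** — an ordered pair of
wild-type and mutant residue, e.g. `A>S`, of which there are 380 — **has
its own distribution of energy changes**, independent of the protein and
of the mutated position. One substitution type observed across many
proteins and experimental conditions shows a wide spread of ddG values, so
a point prediction without an uncertainty statement is of limited use. The
package therefore predicts a whole cumulative distribution (CDF) of
admissible energy changes per mutant, and only then reduces it to a point
estimate.

Prediction is a two-stage procedure.

**Stage 1 — holdout random sampler.** The dataset is split into `n_bags`
(default 100) random 75/25 train/test partitions ("bags"). Within each
bag:

1. *Learning.* For every substitution type with at least `min_count`
   (default 3) observations in the training split, the empirical CDF of
   the observed ddG values is stored. Types below the threshold are
   dropped — mutations with low statistics produce unreliable CDFs.
2. *Testing.* Every test record is predicted by Monte-Carlo: `n_mc`
   (default 1000) draws from its type's learned CDF (for a double
   mutation, the element-wise sum of independent draws from both types'
   CDFs). The residuals `r_k = ddG_obs,k - median(draws_k)` define a
   residual distribution `Omega` and a damping weight `k_omega` chosen on
   the grid {0, 0.25, 0.5, 0.75, 1} to maximize the sign accuracy of the
   corrected medians, with ties broken toward the smallest weight.
3. *Scoring.* The bag's sign accuracy is the fraction of test records
   whose corrected median has the observed sign.

Holdouts whose accuracy reaches `0.99 * max(accuracy)` are selected. Their
damping weights are averaged and their residual samples pooled, and every
record's predictive CDF is sampled as

```
E_pred = E_MC + mean(k_omega) * Omega_pooled
```

with each raw draw taken from a uniformly chosen selected holdout (a
mixture over the ensemble — distribution-identical to averaging the CDFs
pointwise, and simpler).

**Stage 2 — neural network.** Each record's corrected predictive CDF is
discretized into `m = 100` quantiles, concatenated with ordinal codes of
its substitution type(s) and an encoding of its protein, and fed to a
network with one hidden layer of 10 ReLU neurons and a linear output
neuron. The network is trained by Levenberg-Marquardt (LM) least squares
with early stopping, and the whole experiment is repeated over 100
independent random 70/15/15 train/test/validation splits; metrics
(Pearson, RMSE, sign accuracy) are reported on the blind 15% validation
split of each repeat.

## Tunable parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `n_bags` | 100 | — | random 75/25 partitions |
| `train_frac` | 0.75 | — | training share per bag |
| `min_count` | 3 | records | smallest per-type sample giving a non-trivial ECDF |
| `n_mc` | 1000 | draws | Monte-Carlo samples per record (median MC error small vs typical spread) |
| `selection_factor` | 0.99 | — | holdout selection threshold, relative to the best accuracy |
| `m_quantiles` | 100 | — | CDF discretization fed to the network |
| `n_hidden` | 10 | neurons | hidden layer width |
| `n_repeats` | 100 | — | repeated random splits |
| `n_restarts` | 3 | — | random initializations per repeat, best test-SSE kept |
| `neutral_threshold` | 0.5 | kcal/mol | optional near-neutral record filter (off by default) |

All of these are config keys of the command-line pipeline
(`default_config()`).

## The synthetic-data generator

No curated thermodynamic dataset ships with the package, so every claim is
exercised against a generator with known ground truth
(`synthetic_config()` / `generate_dataset()`). Its model is the minimal
structure that makes each pipeline stage testable and falsifiable:

* each substitution type `s` has mean effect `mu_s = +/- effect_mean`
  (positive with probability `stability_bias`, default 0.5) and
  within-type spread `effect_sd`;
* each protein carries a shared `Normal(0, protein_effect_sd)` offset;
* a single-mutation record observes
  `mu_s + offset + N(0, effect_sd) + N(0, measurement_noise_sd)`;
* a double-mutation record sums two independent single-substitution draws,
  the protein offset, an epistasis term `N(0, epistasis_sd)` and
  measurement noise.

Defaults (chosen once as a plausible desk-scale world, and then left
alone): 30 substitution types, `effect_mean` 1.5, `effect_sd` 0.5, 10
proteins, `protein_effect_sd` 0.3, `measurement_noise_sd` 0.3,
`epistasis_sd` 0.25, 400 single records. The magnitudes mirror the scale
of experimental ddG data: type-level effects of one-to-two kcal/mol over a
within-type spread of a few tenths, and measurement noise a fraction of
the signal.

What the generator does **not** emulate: the skewed marginal ddG
distribution of real thermodynamic databases, experimental-condition
covariates (pH, temperature), residue-environment features, and
non-Gaussian within-type spread. A green test therefore establishes that
the algorithms recover the structure they assume — not that the method
attains any particular accuracy on real mutation data.

## Numerical choices

* **ECDF conventions.** Evaluation is right-continuous
  (`#{values <= x}/n`); quantiles are type-1 (left-continuous inverse);
  the quantile grid uses mid-point probabilities `(j - 0.5)/m`, avoiding
  the degenerate endpoints; the median averages the central pair for even
  `n` so the sign rule behaves symmetrically.
* **Sampling.** Draws use inverse-transform sampling, which for a step
  ECDF is distribution-identical to acceptance/rejection against the same
  CDF and exact; a naive rejection sampler is kept in the test suite as
  the independent oracle.
* **Sign at zero.** `sign(0) := +1` (stabilizing); the sign rule divides
  by the magnitude of the median, which is undefined at zero, and a fixed
  tie-break keeps accuracy deterministic.
* **Residual fit.** Any least-squares fit of `k_omega` on the residuals
  that define it is degenerate (always 1), so the weight maximizes the
  sampler's own selection metric — sign accuracy — over a 5-point grid;
  ties prefer the smallest correction.
* **LM implementation.** The Jacobian is assembled analytically (ReLU
  subgradient at 0 taken as 0) and the damped normal equations
  `(J'J + lambda I) delta = J'r` are solved through the dual form
  `J'(JJ' + lambda I)^{-1} r` whenever parameters outnumber samples —
  algebraically identical and far cheaper. Features are z-scored on the
  training split only (quantiles in kcal/mol and ordinal codes are badly
  co-scaled otherwise); constant features get unit scale.
* **Damping schedule.** With at least as many samples as parameters the
  classic schedule applies (`lambda0 = 1e-3`, factor 10). When parameters
  outnumber samples — the usual case for a 1051-parameter network on a few
  hundred records — that schedule reaches a sharp, badly generalizing
  minimum within a handful of giant steps. Training then starts strongly
  damped (`lambda0 = n`) and relaxes slowly (factor 1.7), so the iterates
  trace a fine ridge-like shrinkage path from the near-zero
  initialization, and the best-test-SSE iterate (restored at the end)
  selects the stopping point on that path. Early stopping also aborts
  after 6 consecutive test-SSE increases.
* **Restarts.** Small LM-trained networks vary visibly with the initial
  weights; each repeat trains `n_restarts = 3` networks and keeps the one
  with the lowest test-split SSE (model selection, not ensembling).
* **Protein encoding.** One-hot by default. The network's information
  advantage over the sampler median is precisely the protein context,
  and an ordinal protein code hides it behind an arbitrary ordering that
  a 10-neuron layer cannot reliably unfold; with one-hot proteins the
  network matches a well-tuned linear-ridge reference on synthetic data,
  with ordinal codes it does not. `protein_encoding = "ordinal"` restores
  the compact 103-wide input of the original design.
* **In-bag vs out-of-bag prediction.** The source protocol predicts the
  *entire* dataset with the selected holdouts, so a record's own
  observation sits inside its predicted CDF for the ~75% of bags that
  trained on it. That is kept as the default (`oob = FALSE`) for
  faithfulness; `oob = TRUE` restricts each record to holdouts that did
  not train on it — the leakage-free choice when the predictions feed a
  model evaluated on the same records.

## Open design points, and how they were resolved

* The printed holdout selection rule compares against `0.99 *` the
  *minimum* accuracy, which taken literally excludes almost nothing; it is
  read as `0.99 * max`, with `selection_mode = "literal_min"` available.
* Whether the ensemble averages the corrected CDFs or the weight and
  residual distribution separately is unstated; the latter is implemented
  (average `k_omega`, pool residual samples).
* The CDF discretization feeding the network is unstated; the mid-point
  quantile grid is this package's convention.
* The network consumes the *corrected* (residual-adjusted) CDF, not the
  raw Monte-Carlo one.
* Double mutations combine single-type draws additively; the synthetic
  generator's `epistasis_sd` exists precisely to stress that assumption.

## Known limitations

* **Sampler-vs-network dominance is world-dependent.** In the committed
  synthetic world the sampler median is already a nearly unbiased,
  near-optimal predictor (its only blind spots are the protein offsets,
  variance 0.09 kcal^2/mol^2 against a noise floor of ~0.5). A repeat's
  validation split holds 60 records, so even the Bayes-optimal predictor
  (true type mean + true protein offset) beats the sampler baseline in
  only ~80% of repeats — the acceptance criterion demanding >= 80% wins
  sits exactly at that boundary, and the trained network, which matches a
  tuned ridge reference, lands on either side of it depending on the
  realization. The corresponding acceptance test is left asserting the
  stated threshold. When protein context is material (offset sd 0.6,
  no measurement noise) the network dominates in 25/25 repeats.
* The sampler ignores structure: no solvent accessibility, rigidity or
  force-field terms, by design.
* Records whose substitution type never reaches `min_count` observations
  in any selected holdout are reported as uncovered rather than predicted.
* Double-mutation support assumes additivity of single-substitution
  distributions; strong epistasis violates the model and is only
  representable through the pooled residual correction.
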