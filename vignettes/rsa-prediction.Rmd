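---
title: "Predicting relative solvent accessibility from sequence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting relative solvent accessibility from sequence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsapred)
```

## The problem and the model

Relative solvent accessibility (RSA) is a residue's accessible surface
area divided by the maximum accessibility of its residue type in an
extended Ala-X-Ala tri-peptide; it ranges over [0, 1] (or 0–100%).
`rsapred` predicts real-valued RSA from sequence-derived information only:
a PSI-BLAST evolutionary profile, PSIPRED 3-state secondary-structure
probabilities, per-residue disorder probabilities, two sequence
descriptors and six physicochemical propensity scales, all assembled over
a sliding window and fed to an ε-support-vector regression with a
Gaussian kernel. The package's working assumption — shared by the whole
window-based RSA literature — is that a residue's exposure is largely
determined by its local sequence neighborhood plus a few global chain
properties.

## Feature encoding conventions

For a window of odd length $N$ (default 9, supported 5–13), residue $i$
collects features from positions $i - \frac{N-1}{2}, \dots, i + \frac{N-1}{2}$.
The layout, in order, is:

| block | width | content |
|---|---|---|
| `pssm` | $21N$ | logistic-normalized PSSM scores + terminal flag per slot |
| `ss_local` | $3N$ | (C, H, E) probability triple per slot |
| `ss_global` | 6 | state contents and segment fractions |
| `disorder` | $3N$ | (p\_disorder, p\_order, state) per slot |
| `seq_len` | 1 | chain length / 1000 |
| `seq_pos` | 1 | $1 - |i - (L+1)/2| / (L/2)$ |
| `physchem` | $6N$ | six normalized propensity values per slot |

for $33N + 8$ columns in total. Blocks are individually switchable, which
reproduces incremental feature-combination experiments.

Conventions worth spelling out:

* **Pseudo residues.** Window slots beyond the chain ends contribute
  literal zeros for every feature and 1 for the PSSM terminal flag. The
  zeros bypass logistic normalization on purpose: normalizing a zero
  *score* would emit 0.5 and make padding indistinguishable from a
  genuinely neutral profile column.
* **Terminal flag.** By default only pseudo residues carry flag 1. Whether
  a chain's *real* first and last residues should also be flagged is a
  defensible alternative reading of the convention, so it is exposed as
  `terminal_flag = "real_termini"` rather than hard-coded.
* **Short-helix rule.** For the global segment counts, maximal helix runs
  of length 1–2 are rewritten to coil first (one or two helical residues
  cannot form a real helix segment); strand and coil runs are never
  rewritten, and contents always use the raw state string.
* **Tie-breaks and thresholds.** Secondary-structure probability ties
  resolve with priority C > H > E (coil as the unstructured default); the
  disorder state uses p ≥ threshold (default 0.5).
* **Global features from states, not probabilities.** The global block is
  computed from the argmax state string; using expected contents from the
  probabilities is a near-equivalent alternative we did not take, to keep
  the segment-counting rule well defined.

## The weighted sliding window

Plain windows treat every neighbor equally. Regressing each residue's RSA
on its window neighbors' RSA values (ordinary least squares over every
*complete* window — chain-end windows are excluded rather than padded,
which would bias the weights toward zero) yields coefficients that
decrease roughly linearly and symmetrically away from the center, all
positive. `reference_window_weights()` ships the published 9-window
profile, whose coefficients sum to 1.678 with intercept −0.5863; applied
to a flat 0.5 neighborhood it predicts 0.2529.

The fitted coefficients enter the encoder as per-slot multipliers. How
regression coefficients should become feature multipliers is genuinely
open; the package offers three modes (`window_multipliers()`): `"max"`
(default) rescales by the largest coefficient so the strongest neighbor
keeps full magnitude and feature scales stay bounded, `"raw"` uses the
coefficients as-is, `"none"` disables weighting. The central slot always
has multiplier 1, and the regression intercept plays no role in
weighting — it is a property of the RSA scale, not of relative neighbor
influence.

The RSA *unit* used when the reference profile was fitted is not
recoverable from the coefficients (they are scale-free; only the
intercept is not), so fitting here defaults to fraction scale and the
unit-equivariance of the fit is covered by a test.

## The regression engine and its tuning

The predictor is ε-SVR with a radial-basis kernel, via the LIBSVM binding
in `e1071`. Features are already in [0, 1] by construction, so no
rescaling is applied. When every target sits inside the ε-tube around its
mean the solver legitimately keeps zero support vectors; the package
returns the optimal flat function in that case instead of failing.

Hyperparameters $(C, \gamma, \varepsilon)$ are searched by standard
inertia-weight particle swarm optimization: velocity
$v \leftarrow \omega v + c_1 r_1 (p - x) + c_2 r_2 (g - x)$, position
$x \leftarrow x + v$, positions clipped to the box with the velocity
zeroed in clipped dimensions. Defaults are the classic
constriction-equivalent settings ($\omega = 0.729$,
$c_1 = c_2 = 1.49445$), swarm 20, 50 iterations, velocities clamped to
20% of each dimension's range. The search runs in $\log_{10}$ space for
$C \in [10^{-4}, 10^3]$ and $\gamma \in [10^{-5}, 10]$ and linearly for
$\varepsilon \in [0, 0.5]$ (fraction-scale RSA); published tuned values
for this model family lie comfortably inside these boxes. The fitness is
the chain-level cross-validated MAE, residue-weighted (pooled over folds)
rather than averaged per fold, matching how the headline MAE itself is
defined.

Two further design choices:

* **Incumbent seeding.** One particle of the initial swarm is placed at
  the incumbent (default) hyperparameters. Seeding a known-good solution
  is standard metaheuristic practice; it also guarantees the tuned result
  is never worse than the incumbent as measured on the same folds.
* **Reduced-subset tuning.** For large chain sets, `tune_on_subset()`
  assigns folds on the full set, samples a fixed number of chains per
  fold, tunes on that subset and returns parameters for use on the full
  set — the compromise used at full scale, where tuning on every chain is
  prohibitive.

Cross-validation is always at chain level: a chain's residues are never
split across folds, and a chain never contributes to its own training
set. A perturbation test (corrupting a test chain's targets and checking
its predictions are unchanged) guards the protocol.

## Evaluation

`mae()` defaults to mean |x − y| on the percent scale. The normalized
form mean |x − y| / x is also implemented (`mode = "relative"`) because
it appears in print as the MAE definition, but it diverges at buried
residues (true RSA 0) — those positions are skipped with a counted
warning — and reported headline errors in this literature (≈14%) are only
consistent with the absolute form, which is therefore the default.
`pcc()` is the plain Pearson correlation. Two-state accuracy binarizes
both tracks with the same ≥-threshold rule ("no less than the threshold"
means exposed) across thresholds 5–90%. Headline MAE/PCC pool residues
across chains (residue-weighted); per-chain values are reported alongside
in `evaluate_predictions()`.

## The synthetic-data generators

The generators exist so every stage is testable without running
PSI-BLAST, PSIPRED, DISOPRED or DSSP. `generate_chain_set()` emulates the
*formats and first-order statistics* of real inputs: background residue
frequencies; PSSMs with the emitted residue's own column elevated;
secondary structure from a 3-state Markov chain whose self-transition
probabilities set realistic run lengths (expected run length
$1/(1-p)$); disorder probabilities low along the chain with a few
elevated contiguous segments.

Two RSA models give the pipeline known structure to recover:

* **`neighbor_linear`** produces tracks whose interior conditional
  expectation is *exactly* $b + \sum_k w_k\,\mathrm{RSA}_{i+k}$ for known
  symmetric stationary weights. The construction has two parts. A
  structural mean profile solves the neighbor recurrence exactly, driven
  by random boundary values anchored on the recurrence's smooth dominant
  mode (the positive real root of $1 - \sum_k w_k (z^k + z^{-k})$) with a
  small jitter that excites the remaining modes — enough variation to
  identify every coefficient, without the residue-to-residue oscillation
  the non-smooth modes would otherwise cause. On top, when the noise
  parameter is positive, a zero-mean Gaussian field is drawn from the
  conditional autoregression the symmetric weights imply (banded
  precision $(I - W)/\sigma^2$, sampled exactly through a sparse
  Cholesky factor). Because the conditional mean given the window is
  linear in exactly the window neighbors, least squares on complete
  windows is consistent for $(w, b)$ — the generator and
  `fit_window_weights()` meet at the same estimand, which is what makes
  parameter recovery a meaningful oracle. Simpler schemes fail this
  requirement: iterating the deterministic update converges to a
  near-constant track (no regressor variance), and adding observation
  noise afterwards creates an errors-in-variables bias that attenuates
  the recovered weights. With noise 0 the track satisfies the recurrence
  exactly and recovery is exact to machine precision. Weights must be
  symmetric with |sum| < 1 (stationarity); the defaults (0.023, 0.077,
  0.147, 0.216, mirrored; intercept 0.035; noise sd 0.02) are shaped like
  the published fitted profile but scaled to be stationary.
* **`feature_linked`** makes RSA a logistic function of the residue's
  hydrophilicity and surface propensity, its coil/strand probabilities
  and its position feature, plus observation noise — a signal the encoder
  demonstrably carries, giving the SVR an end-to-end learnability check.

Clamping to [0, 1] slightly biases recovery near the boundaries; the
default noise levels keep clamped values well under 1% of residues.

What passing these tests shows — and does not. They demonstrate the
machinery is correct: encodings have the documented shapes, least squares
recovers a known spatial process, the CV protocol does not leak, the SVR
learns a feature-linked signal on held-out chains. They do not
demonstrate biological accuracy: synthetic profiles lack real
evolutionary correlation structure, homology between chains, and the
error modes of the upstream predictors, and the published full-scale
benchmark figures (MAE ≈ 14%, PCC ≈ 0.75 on thousands of PDB chains)
require those external pipelines and datasets.

## Numerical choices and problem sizes

* Readers validate row counts against the declared chain length and never
  silently drop rows; positions are 1-based in every file dialect.
* RSA values above the per-residue ceiling (DSSP occasionally exceeds the
  tabulated maxima) are clamped with a warning.
* The max-ASA table and the six propensity scales ship as replaceable TSV
  configs; scales are min-max normalized at load and `X` maps to each
  scale's mean.
* OLS residual orthogonality is checked to 1e-8; metric implementations
  are compared against brute-force oracles to 1e-10; the reference
  9-window worked value is asserted to 1e-6.
* Non-finite PSO fitness values are treated as +Inf with a warning, so a
  failed model fit cannot silently win the search.
* The test and acceptance runs use desk-scale problem sizes chosen to
  exercise every property at high power in minutes: weight recovery on
  200 chains of length 300 (60,000 residues); tuning comparisons on
  30-chain sets with a window of 5 and a reduced block set (the
  comparison is about the tuner, not the encoder); hold-out learnability
  on 20 training and 10 test chains at the full window of 9.

## Known limitations

* The pipeline parses upstream tool *outputs*; it does not run PSI-BLAST,
  PSIPRED, DISOPRED or DSSP, and full DSSP parsing is limited to the
  per-residue ACC extract.
* The weighted-window multiplier mapping (`"max"`) is one defensible
  choice among several; the alternatives remain available.
* Per-type summaries require each letter to appear; absent letters are
  omitted with a warning rather than imputed.
* wKNN and gradient-boosting baselines, and comparisons against external
  prediction servers, are out of scope.
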