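---
title: "Models and methods behind digiwell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind digiwell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digiwell)
```

digiwell analyses digital real-time PCR (dqPCR) runs on microwell chips:
2,500 partitions of 20 nL, each reporting a quantification cycle (Cq) or no
amplification after a 40-cycle protocol. This vignette explains the models
the package implements, the defaults it ships, the decisions taken where
the methodology was genuinely open, and what the synthetic-data generator
does and does not emulate.

## Poisson digital quantification

Molecules disperse into wells independently and uniformly, so the copy
number in a well is Poisson with rate $\lambda$. Counting $k$ positive
wells among $n'$ effective partitions inverts the zero class:

$$\lambda = -\ln(1 - k/n'), \qquad
\Sigma N = \frac{\log(1 - k/n')}{\log(1 - 1/n')}.$$

$\Sigma N$ is the exact finite-partition estimator; it equals
$\lambda/(-\log(1 - 1/n'))$, is within 0.03% of $\lambda n'$ at
$n' = 2500$, satisfies $\Sigma N \ge k$ with equality only at $k \le 1$,
and is increasing and convex in $k$. At saturation ($k = n'$) the
concentration is unquantifiable and the estimators raise an error rather
than extrapolate.

**Effective partitions.** $n' = n - \text{fail} - \text{dimer}$: failed
wells are unfilled or bubbled partitions; the dimer term is the mean
positive count of no-template controls (NTCs), a real-valued expectation
(e.g. 1.67 per chip) of primer-dimer false positives. Whether the dimer
mean is also subtracted from $k$ is exposed as `subtract_dimers`, because
published low-concentration characterisations of this chip are consistent
with *no* subtraction; `quantify_replicates()` defaults to subtracting when
NTCs are supplied, which is the unbiased choice for recovery.

**One-copy probabilities.** Two conventions are implemented. The
cumulative $P(X \le 1) = e^{-\lambda}(1+\lambda)$ with
$\lambda = k/(n - \text{fail})$ reproduces the published per-level
"1 copy (%)" values (98.5% at $k = 454.5$; 76.5% at $k = 2301$) and is the
default; the conditional $P(X = 1 \mid X \ge 1) =
\lambda e^{-\lambda}/(1 - e^{-\lambda})$ is available and is the quantity
that motivates single-copy anchoring. The conditional form is undefined at
$k = 0$ and errors there.

**Replicates.** Instrument practice reports the *mean* positive count over
triplicate chips (hence non-integer $k$ like 454.50) and applies the
nonlinear transform to the mean. `quantify_replicates()` follows that
order of operations. Note the transform is convex, so transforming the
mean differs slightly from averaging transformed replicates; this is the
likely origin of sub-0.1% discrepancies in published per-level totals, and
the package makes no attempt to undo it.

**Uncertainty.** The interval on $\Sigma N$ uses the standard partition-
statistics normal approximation $\mathrm{var}(\hat\lambda) \approx
(e^{\lambda} - 1)/n'$, mapped through the linear $\lambda \to \Sigma N$
scaling. Simulated coverage at 100 true copies exceeds 90%.

## Standard curves and the single-copy anchor

`fit_standard_curve()` is ordinary least squares of per-level mean Cq on
$\log_{10}$ concentration; efficiency is $E = 10^{-1/\text{slope}} - 1$,
stored as a fraction and reported as percent. (The canonical perfect-
doubling slope is $-3.3219$.) Some print conventions omit the "$-1$", but
only the subtracted form maps slope $\approx -3.59$ to the published
$\approx 90\%$ efficiencies, so that form is used throughout.

**Regime detection.** Scanning from the lowest concentration upward,
`detect_digital_regime()` grows the plateau while consecutive mean-Cq
differences stay under `anchor_tolerance` (default 0.5 cycles — half a
doubling, comfortably above the per-level Cq SDs of 0.2–0.7 cycles while
well below the ~3.6-cycle step a 10-fold dilution produces in the linear
range) despite $\ge$ 2-fold concentration steps. A single lowest level is
not treated as evidence of a plateau.

**Anchoring.** `estimate_single_copy_cq()` pools positive-well Cq values
from runs whose own positive count implies $P(X \le 1) \ge 0.95$. Pooling
defaults to per-well weighting; per-level weighting (each level's mean
counts once) is provided because published single-copy means are not
always reproducible from per-level means under either weighting, and the
choice should be explicit rather than implicit. No attempt is made to
force agreement with any particular published value.

**Copy conversion.** $N = (1+E)^{Cq_1 - Cq}$. The exponent orientation
matters: a ratio form with exponent $(Cq - Cq_1)$ appears in some write-ups
but increases with Cq, contradicting both PCR monotonicity and the
single-cell relation $A = 2^{Cq_1 - Cq}$; digiwell uses $(Cq_1 - Cq)$,
which is consistent with both and makes `percent_of_control()` identical
to the ratio of converted copies.

## Inhibitor quantification

The inhibited reaction is assumed to reach the same detection threshold
$K$ with a reduced efficiency: $K = N(1+E+E')^{Cq'} = N'(1+E)^{Cq'}$,
giving $E' = (1+E)\left[(N'/N)^{1/Cq'} - 1\right]$ — an exact closed-form
inversion, verified by round-trip in the tests. Percent-of-control is
$100\,(1+E)^{Cq_{NIC} - Cq'}$ for bulk assays and the ratio of digital
copy estimates for chips.

**IC50.** No functional form is canonical for heparin inhibition curves,
so `fit_ic50()` uses the field-standard 4-parameter log-logistic on log
concentration with asymptotes fixed at 100/0 by default (percent-of-control
is defined on [0, 100]); `free_asymptotes = TRUE` releases them. The
zero-concentration NIC point is excluded from the abscissa (log 0).
Fitting uses Levenberg–Marquardt (`minpack.lm::nlsLM`) with the start for
log-IC50 interpolated at 50% of control; a flat response (range < 10
percentage points) is rejected as unidentifiable rather than fitted.

Heparin concentrations are handled as *final in-reaction* values; stock
values dilute by 1:20 (`final_inhibitor_concentration()`), mapping stocks
0.02–5.0 IU/mL onto finals 0.001–0.25 IU/mL.

## Cell-loading occupancy

With $N$ cells over $n$ wells: $P_0 = e^{-N/n}$,
$P_1 = (N/n)e^{-N/n}$, $P_{2+} = 1 - P_0 - P_1$ (they partition unity for
every $N$), and the single-cell fraction of occupied wells is
$100\,P_1/(1-P_0)$ — 90.33% at $N = 500$, $n = 2500$, decreasing strictly
in $N$. The occupied-well count inverts to an input-cell estimate by the
same formula as molecular counting. With $n$ fixed at the chip's 2,500
wells the occupancy curves have no free parameters, so
`fit_poisson_occupancy()` reports per-category $R^2$ of observed
proportions against the closed forms — the regression reduces to a
goodness-of-fit summary, with an option to take per-load $N$ from the data
instead of the nominal loads. Nominal loads are treated as exact;
observed proportions use all 2,500 wells (cell-count chips have no fail
category). `recommend_loading()` inverts the single-cell fraction by
bisection; a 100% target is correctly unattainable.

## Expression profiling

Each reactive well is assumed to hold one cell; copies are
$A = 2^{Cq_1 - Cq}$ against a reference-gene single-copy Cq (configurable;
simulator runs supply their own anchor). Geometric means are used
throughout because they equal the arithmetic mean on the Cq scale —
an identity the tests verify exactly. Histograms bin in $\log_{10}$
copies with Freedman–Diaconis bin counts.

**KS testing.** Two-sample comparisons use the standard KS statistic on
log copies; the statistic is invariant under common monotone transforms,
so the log/linear choice is cosmetic for two-sample tests. One-sample
tests against normal/lognormal families estimate moments from the data by
default, which distorts the asymptotic p-value (the Lilliefors effect);
the function accepts known parameters (under which null p-values are
uniform, as the property tests check) and offers a parametric-bootstrap
p-value that re-estimates moments per resample. Pairwise comparisons
across time points are Holm-corrected, with raw p-values retained,
since published single-cell KS tables typically report uncorrected tests.

## The synthetic-data generator

`sim_config()` fixes the modelled instrument: 2,500 wells of 20 nL,
single-copy Cq 26.20, efficiency 89.81%, per-well Cq noise SD 0.4 cycles
(chosen once, inside the 0.19–0.72 range of observed per-level SDs), a
mean of 1.67 primer-dimer false positives per chip with
Cq ~ N(28.80, 5.08) clipped to (0, 40], zero fail rate by default, and a
40-cycle protocol.

**Amplification model.** A well with $m$ molecules at per-well efficiency
$E_w$ crosses the shared threshold $K = (1+E)^{Cq_1}$ at
$Cq = (Cq_1 \ln(1+E) - \ln m)/\ln(1+E_w)$, which reduces to
$Cq_1 - \ln m/\ln(1+E)$ at nominal efficiency — the unique form consistent
with the copy-conversion equations. Wells pushed past cycle 40 are
negative. Partitioning is exactly multinomial (totals conserved), with
Poisson marginals at chip scale.

**Effective template volume.** Converting copies/µL to per-chip copies
requires an effective sampled volume; published per-level positive counts
for this chip imply volumes anywhere between ~0.5 and ~2 µL depending on
the level used. digiwell fixes `sample_volume_ul = 0.5` because that value
reproduces the characteristic dilution-series shape — a linear slope over
the five highest of nine 10-fold levels and a Cq plateau over the four
lowest — which is the feature the analysis actually consumes. Absolute
worked examples operate on positive counts directly and are unaffected.

**Inhibition.** Heparin acts through two channels whose split is a
simulator parameter (the mechanism is not quantified in the literature
this package models): complete per-well inhibition with log-logistic
probability (midpoint `ic50_complete`, default 0.02 IU/mL) and an
efficiency decrement growing with log concentration (`eprime_slope`,
default −0.04 per decade). Chips lose only completely inhibited wells
(late Cq still crosses threshold by cycle 40), while matched bulk
reactions take the efficiency penalty over every cycle — that asymmetry,
not any tuned constant, is what makes the simulated digital readout more
inhibitor-tolerant, and the acceptance tests check the direction, not the
magnitudes.

**EMT scenario.** `emt_scenario()` models a TGF-β1 time course (control,
day 1, 2, 4) in lung-carcinoma-like cells with per-cell lognormal
expression, sdlog 0.8: GAPDH flat at 200 copies, E-cadherin flat at 50
(the null gene), N-cadherin 5→10→20→40 (monotone induction), vimentin
20→80→160→40 (transient induction). 500 cells are loaded per gene ×
condition chip (~453 occupied wells, 90.3% singlets); doublet wells sum
their cells' copies and are excluded from truth-based recovery checks via
the recorded `n_cells_true`.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: fluorescence-curve shapes and Cq-calling
artefacts (Cq values are taken as given), spatial structure in well
failures or cell settling, cell-size–dependent loading bias, reverse-
transcription efficiency, between-chip batch effects, and inhibitor
chemistry beyond the two-channel model. Tests demonstrate the estimators
are correct *under the stated stochastic model*, not that the model
captures every instrument artefact.

## Problem sizes and numerical choices

Simulation-based checks use sizes chosen for tight-but-fast inference:
200-seed recovery experiments with triplicate chips and NTCs at 10/100/
1000 copies, 100-replicate comparisons for precision and inhibition
direction, 10-seed EMT runs, and single fixed-seed runs elsewhere. Ties in
KS tests are tolerated (warnings suppressed, statistic exact); the
log-logistic fit works on log concentration for conditioning; bisection
and root-finding tolerances are 1e-9 on quantities of order 1–10⁴.
Degenerate inputs fail loudly: saturated chips, empty controls, constant
samples for distribution tests, flat inhibition curves, and targets of
100% single-cell fraction all raise informative errors instead of
returning extrapolations.
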