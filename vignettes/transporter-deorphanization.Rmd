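---
title: "Methods: transporter deorphanization analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transporter deorphanization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deorphanr)
```

# The problem

Assigning substrates to orphan solute carriers combines three kinds of
evidence: an exometabolome screen showing which compounds a cell consumes or
secretes; uptake assays of single transporters expressed in *Xenopus*
oocytes, read out by LC-MS of pooled oocyte extracts against GFP-only
controls; and growth phenotypes of deletion strains at the compound's LC50.
`deorphanr` implements the statistics of all three stages plus generators
that simulate each data type with known ground truth, so that every caller's
sensitivity and error rates are measured properties, not hopes.

# Exometabolome screen

For compound $i$ with control replicates $x_{ij}$ and treated replicates
$y_{ij}$:

$$\mathrm{log_2FC}_i = \log_2 \frac{\bar y_i}{\bar x_i}, \qquad
  \mathrm{CV}_g = 100\,\frac{s_g}{\bar g}\ (\%).$$

A compound is *consumed* if $\mathrm{log_2FC} < -\tau$, *secreted* if
$\mathrm{log_2FC} > +\tau$, with $\tau = 0.5$ by default, subject to
$\max(\mathrm{CV_{control}}, \mathrm{CV_{treated}}) < 30\%$; otherwise
*unchanged*. The threshold is applied to the *absolute* fold change: both
signs are biologically meaningful (uptake versus export), so a one-sided
reading of the 0.5 cutoff would discard half the signal. Which group the CV
gate should apply to is genuinely open; gating on the larger of the two is
the conservative choice and is what `classify_direction()` does.

**Zero handling.** When a group mean is exactly zero a pseudo-count — half
the smallest positive response in the table (`pseudo = "auto"`) — is added
to both means. This keeps fold changes finite without perturbing compounds
that have ordinary signal (the pseudo-count is *only* applied when a mean is
zero). Compounds that are zero in both groups are flagged non-evaluable and
counted as unchanged, so the consumed/secreted/unchanged partition always
sums to the number of compounds.

No multiple-testing correction is applied: the screen is a deterministic
dual-threshold filter, not a test. A Benjamini–Hochberg option exists in the
uptake caller (`bh = TRUE`) where p-values do appear, but it is off by
default to match per-comparison reporting.

# Oocyte uptake calls

Pooled responses are divided by the number of oocytes in the pool
(`normalize_per_oocyte()`), putting pools of 7 and 10 oocytes on one scale.
Within every condition, replicates are cleaned by the interquartile method:
values outside $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$ are
removed and the fences recomputed on the survivors until nothing more is
flagged. Two numerical conventions are fixed and documented because they
change results on small samples:

* Quartiles use linear interpolation between order statistics
  (`stats::quantile` type 7).
* Fewer than four values are never filtered (quartiles of $n<4$ are
  meaningless), and the same guard terminates the iteration.
* The fences are iterated to a fixpoint rather than applied once. On
  replicate sets of 5–10 values a single pass is not idempotent several
  percent of the time (removing an extreme value shrinks the IQR and can
  expose a new "outlier"); downstream statistics should not depend on how
  many times the filter happened to be run, so the filter runs until stable.
  `iterate = FALSE` gives the single-pass behaviour.

Each condition is compared to the GFP-only control by a two-sided
pooled-variance Student's *t*-test (`var_equal = FALSE` switches to Welch)
on per-oocyte values, with the screen's pseudo-count rule for zero means.
Direction calling then follows the logic of the assay geometry:

* $p > \alpha$: **none**.
* $p \le \alpha$, log2FC > 0: **import**.
* $p \le \alpha$, log2FC < 0: **export** — but only when the control itself
  shows endogenous background uptake; with an empty control there is nothing
  for an exporter to deplete, and the call is **indeterminate**.

Background presence (`detect_control_background()`) is a one-sided *t*-test
of the control mean above a configurable blank level (default 0); a strictly
positive zero-variance control counts as present, a single control value as
absent (with a warning). Significance stars follow the conventional
$p \le 0.05 / 0.01 / 0.001$ levels; $\alpha$ defaults to 0.05 and is
configurable everywhere it is used.

Degenerate-data conventions for the *t*-tests: with both groups constant and
equal the p-value is 1 (no evidence), constant and different it is 0; fewer
than two values per group yields an indeterminate call rather than an error,
so no condition silently disappears from a report.

# Concentrative versus equilibrative transport

With the substrate in excess and the medium volume far larger than the
oocytes, the medium concentration is treated as the constant
$c_\mathrm{med} = 2$ mM. Per-oocyte amounts convert to intracellular
concentration via $c_\mathrm{in} = \mathrm{amount} / (\kappa V)$ with oocyte
volume $V$ (default 1 µL) and calibration factor $\kappa$ (default unity).
Neither constant is measurable from the data itself; with unity calibration
only ratios to the medium are meaningful, which is exactly what the mode
call uses, so the defaults are stated rather than estimated.

A condition already called *import* is **concentrative** iff
$\log_2(\bar c_\mathrm{in}/c_\mathrm{med}) > 0$ *and* a one-sided one-sample
*t*-test of $c_\mathrm{in} > c_\mathrm{med}$ is significant; otherwise
**equilibrative**. The boundary convention is deliberate: equilibrative
transport cannot exceed the medium, so only a significant excess justifies
the energetically stronger claim, and a non-significant positive excess
stays equilibrative. This makes the concentrative false-call rate at the
$A = 1$ ceiling at most $\alpha$ by construction.

**Background correction.** When the GFP control itself sits significantly
above the medium, endogenous uptake inflates the transporter's apparent
concentration. The correction subtracts the control mean from every
transporter replicate and re-runs the one-sided test on the differences; the
corrected concentration $\max(\bar c_T - \bar c_\mathrm{GFP}, 0)$ is
reported next to the raw one and can never exceed the raw mean. Mean
subtraction (rather than, e.g., pool-wise pairing, which the unpaired pools
do not support) is a design choice; both raw and corrected calls are always
reported so the correction is auditable.

# Growth phenotypes

## Metrics

`fit_growth_metrics()` reports Max OD as the maximum of a 3-point
median-smoothed curve (robust to single-point spikes) and μ\_max from
sliding-window regressions of $\ln \mathrm{OD}$ on time (default window 5
points ≈ 100 min at 20-min sampling), using only windows whose ODs all
exceed `od_floor` (default 0.01, the inoculum scale).

The estimator does not report the raw maximum window slope. For a logistic
curve $\mathrm{d}\ln \mathrm{OD}/\mathrm{d}t = \mu\,(1 - \mathrm{OD}/K)$,
so every window slope underestimates μ by a factor tied to its OD, while
under additive OD noise the *maximum* over hundreds of windows is dominated
by the noisiest (lowest-OD) windows and is strongly inflated. Both biases
disappear by regressing the window slopes on the window-mean OD — a linear
relation for the logistic — weighted by $\mathrm{OD}^2$ (the inverse
variance of log-scale noise), and taking the intercept at
$\mathrm{OD} \to 0$. The extrapolation is exact on noiseless exponential and
logistic curves, and the acceptance suite measures sub-1% median error at an
OD noise SD of 0.02 in triplicate. When the valid windows span too narrow an
OD range for a regression (flat curves), the maximum window slope is used
directly. The best window's start time and $R^2$ are reported for QC. The
estimator is invariant to time shifts and equivariant to time rescaling.
For curves with long lags or diauxic shifts the slope–OD relation is not
linear over the whole range and the extrapolation inherits the logistic
assumption; that is the main modeling caveat for real data.

## LC50

`estimate_lc50()` fits the four-parameter logistic
$m(c) = b + (t - b) / (1 + (c/e)^h)$ by Levenberg–Marquardt least squares
(via `minpack.lm::nls.lm` on the residual function directly) and solves for
the concentration at which the fitted metric is 50% of its fitted
zero-concentration value. If the fit fails, does not converge, or has no 50%
crossing ($b \ge t/2$), monotone linear interpolation of the replicate-mean
relative metric is used and the method is recorded. The LC50 is defined on
Max OD by default — "growth reduced by half" reads most naturally on final
biomass — and can be switched to μ\_max. Strain comparisons
(`compare_strains()`) are per-metric pooled-variance *t*-tests with the
difference reported as mutant − reference.

# Synthetic-data generators

The generators emulate the statistical structure of the three assays; they
are first-class, tested code, and their defaults are the study design
points.

**Serum screen.** Baselines are log-uniform on $[10^4, 10^7]$ (an LC-MS
peak-area scale); replicate noise is multiplicative lognormal with mean
exactly 1 and CV `replicate_cv` (default 15%); true effects multiply the
treated mean by $2^{\pm e}$ with $|e| \sim U(0.8, 2)$; class counts are
exact by construction (`round(frac * n)`), and three replicates per group
mirror a small-replicate screen. Compound classes (metabolite/drug, 70/30)
are annotation only.

**Oocyte assay.** Each condition's expected intracellular concentration is
$c_\mathrm{in} = \mathrm{bg} + A\,c_\mathrm{med}(1 - e^{-k t})$ for
importers (first-order saturable uptake toward the accumulation ratio $A$;
$A = 1$ is the equilibrative ceiling, $A > 1$ concentrative),
$\beta \cdot \mathrm{bg}$ for exporters (export is only measurable against
an endogenous background, which the exporter depletes multiplicatively),
and $\mathrm{bg}$ for inactive conditions and the auto-generated GFP
control, where $\mathrm{bg} = \texttt{background\_ratio} \times
c_\mathrm{med}$. Measured pool responses are
$\mathrm{pool\_size} \times V \times c_\mathrm{in}$ times lognormal noise
(CV 20% by default). Defaults are the assay constants: 2 mM substrate, 3 h
incubation, pools of 10 in triplicate. The kinetic form and the 1 µL oocyte
volume are modeling choices — the assays themselves report single-timepoint
relative responses, and no intracellular kinetics are identifiable from
them — so the generator should be read as a forward model that reproduces
the two import regimes and the exporter logic, not as oocyte physiology.

**Growth.** Logistic curves with dose-inhibited rate and capacity,
$\mu(c) = \mu_0 / (1 + (c/\mathrm{LC50})^h)$ and $K(c)$ likewise, additive
Gaussian OD noise truncated at zero. Defaults: $\mu_0 = 0.4\,h^{-1}$,
$K_0 = 1.2$ OD, inoculum 0.01, 72 h sampled every 20 min, noise SD 0.02,
triplicate, LC50 anchored at 2.45 mM (the acrylic-acid fixture value used
throughout the growth tests) with a 7-point geometric dose series around it.

**What the simulations do not capture:** compound identification errors,
retention-time or adduct artifacts, batch effects between experiment days,
heteroscedasticity beyond the single CV, oocyte mortality or expression
failures, and lag or diauxic phases in growth. Passing recovery tests
therefore demonstrates that the callers are correct and calibrated under the
stated noise model, not that real data meet that model.

# Problem sizes and runtime envelope

The recovery suites use 1,000-compound screens, 500 mixed plus 1,000 null
oocyte conditions, 400 mode conditions, 200 noisy growth curves in
triplicate, and 300-set outlier batteries; the full test suite runs in well
under a minute on one CPU, which makes the ground-truth recovery checks
cheap enough to run on every change.

# Known limitations

* The screen is threshold-based; with two replicates per group the CV gate
  is itself noisy, and the recovery guarantees are stated for three
  replicates per group.
* Export calls require endogenous background; compounds with clean controls
  can only yield import/none/indeterminate, matching the assay geometry.
* Mode calls compare means to a nominal constant medium; a calibration from
  response to absolute concentration, if available, enters only as a scale
  factor.
* α defaults to 0.05 with conventional star levels; stricter or looser
  regimes are a single argument everywhere.
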