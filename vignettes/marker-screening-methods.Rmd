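---
title: "Screening and validating subtype-specific diagnostic markers"
author: "markerscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and validating subtype-specific diagnostic markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerscreen)
```

## The problem

Some tumor subtypes are hard to tell apart under the microscope. Chromophobe
renal cell carcinoma (RCC), the motivating case for this package, is easily
confused with clear cell RCC, papillary RCC, or benign renal oncocytoma in
borderline histologies, and the immunohistochemical (IHC) markers
traditionally used for the distinction are imperfect. A practical route to
better markers is: (1) screen a large expression cohort for genes that are
abundantly expressed in the target subtype and essentially silent in the
subtypes it must be distinguished from; (2) validate candidate proteins by
immunostaining an independent case series and quantify their diagnostic
performance; (3) ask whether an epigenetic mechanism (promoter DNA
methylation) plausibly explains the subtype-restricted expression.
`markerscreen` implements all three stages as reusable, tested components,
plus a synthetic-cohort generator that provides planted ground truth for
every stage.

## Stage 1: the expression screen

Expression values (RSEM/RPKM-style processed RNA-seq abundances) are treated
as opaque non-negative numbers. Before any comparison, every gene's value is
divided by the value of a housekeeping reference gene (TBP by default) in
the same sample (`normalize_by_reference()`). This per-sample ratio removes
library-scale differences without assuming any particular unit, which
matters when cohorts mix RSEM and RPKM quantifications. Samples in which the
reference gene reads zero cannot be normalized and are dropped with a
warning; this keeps the downstream order statistics finite rather than
propagating infinities.

For each gene $g$ and subtype $k$ the screen computes the median
$m_{gk}$ and the $q$-th percentile $P^{(q)}_{gk}$ of normalized expression
over subtype-$k$ samples only. A gene is called a marker for target subtype
$t$ iff

$$ m_{gt} > \theta_{\mathrm{med}} \quad\text{and}\quad
   P^{(95)}_{gk} < \theta_{\mathrm{bg}} \;\; \text{for every background
   subtype } k \ne t, $$

with defaults $\theta_{\mathrm{med}} = 8$, $\theta_{\mathrm{bg}} = 0.15$,
$q = 95$. Both inequalities are strict ("more than", "less than"). The
second condition is evaluated in each background subtype separately — a
gene silent in one background but active in another is useless as a
diagnostic marker. The thresholds are an empirical operating point, not
derived quantities; they are ordinary configuration
(`screen_criteria()`), and `condition_counts()` reports how many genes
clear each condition so a user can judge how selective a chosen operating
point is on their cohort.

### Percentile convention

No single percentile definition is universal. The default here is linear
interpolation between closest order statistics (position
$p = 1 + (q/100)(n-1)$ in the sorted sample — base R's quantile type 7),
the most common default in scientific software. A `nearest-rank` option
(the order statistic at rank $\lceil nq/100 \rceil$) is provided because
genes whose background percentile sits exactly at the threshold can flip
between conventions; the convention travels inside `screen_criteria` so a
report is always internally consistent. Summaries require at least 3
samples per subtype (`min_samples`): below that, medians and 95th
percentiles are order statistics of almost the whole group and screening on
them is meaningless.

## Stage 2: IHC diagnostics

Stained specimens are graded on two ordinal axes: intensity
(negative / weak / strong) and the proportion of positive tumor cells
(none, $<1\%$; partial, $1\text{–}90\%$; diffuse, $\ge 90\%$). Negative
intensity and zero extent imply each other. Published positivity criteria
fuse the two axes in words ("strong diffuse positivity", "weak diffuse or
partial positivity"); `positivity_rule()` makes the fusion explicit as a
set of accepted (intensity, proportion) pairs. Two presets cover the common
cases: `strict` accepts only strong-diffuse staining; `lenient`
additionally accepts weak staining of any extent. Strong-partial staining
belongs to neither preset — it is rare in practice and a user who needs it
can pass an explicit accepted set.

`tabulate_ihc()` turns case-level calls into a 2×2 confusion table against
a target tumor type, and `diagnostic_metrics()` reports sensitivity
$\mathrm{tp}/(\mathrm{tp}+\mathrm{fn})$ and specificity
$\mathrm{tn}/(\mathrm{tn}+\mathrm{fp})$. Two conventions are worth
spelling out:

* **Rounding.** Percentages are displayed rounded half-up to one decimal
  (92.857… → 92.9). Base R's `round()` rounds half to even, which is not
  how diagnostic percentages are conventionally printed; exact ratios are
  retained alongside the display values.
* **Confidence intervals.** 95% intervals use the Wilson score method,
  which remains informative at observed rates of 0% and 100% — exactly
  where good markers live. The interval is an addition of this package;
  observed rates themselves are unaffected.

Tumor types that are not part of the diagnostic contrast (renal oncocytoma,
a benign mimic that shares the target's immunophenotype) are handled by
`positivity_rate()`, which reports a single-type positivity fraction
instead of forcing them into a sensitivity/specificity frame where they
would distort specificity.

## Stage 3: methylation association

For each CpG probe linked to a candidate gene, the package compares beta
values (methylated fraction, in $[0,1]$) across subtypes with the
tie-corrected Kruskal-Wallis test and flags the probe as target-hypomethylated
when the target subtype's median beta sits more than `delta_threshold`
(default 0.25) *below every* background subtype's median — the gap is
aggregated with a minimum over backgrounds, so one permissive background
cannot carry the flag. The link between methylation and expression is
quantified by the Spearman rank correlation of beta with normalized
expression, computed both pooled across all samples and within each
subtype; pooled and within-subtype correlations answer different questions
(between-subtype contrast versus within-subtype dose response) and both are
reported. Midranks are used for ties throughout — beta values are heavily
tied after platform rounding — and p-values use the standard chi-square
(Kruskal-Wallis) and t (Spearman) approximations. Missing betas are
excluded pairwise.

## The synthetic-data generator

Real consortium cohorts cannot ship with a package, so every stage is
validated against synthetic cohorts with planted ground truth
(`sim_config()`, `simulate_expression()`, `simulate_methylation()`,
`simulate_ihc()`). The default configuration emulates a renal-carcinoma-style
design: three subtypes of 40 / 300 / 100 samples, 2000 genes, a strictly
positive reference gene, and 5 planted markers.

* **Null genes** draw a per-gene baseline from a wide log-normal
  (log-mean −2, log-sd 2 on the normalized scale), then per-sample
  log-normal noise (log-sd 0.7) with a 20% point mass at zero (dropout).
  This reproduces the regime the screen exploits — most genes have
  near-zero 95th percentiles in any subtype — while making the two screen
  conditions anti-correlated at the gene level, as they are in real data
  (a gene cannot be both abundant and absent).
* **Planted markers** concentrate normalized values log-normally (log-sd
  0.25) around a hot-subtype median of 15 and are uniform below a ceiling
  of 0.05 in every other sample. These effect sizes sit well clear of the
  8 / 0.15 operating point on both sides, so the screen should recover
  exactly the planted set; the tests assert precision = recall = 1 across
  20 seeds.
* **Coupled CpG probes** are generated as
  $\beta = \mathrm{clamp}(b - s\,z + \varepsilon,\, 0,\, 1)$ with baseline
  $b = 0.60$, shift $s = 0.16$, and $z$ the standardized log normalized
  expression of the linked marker, so high-expressing (hot) samples are
  hypomethylated. The noise scale is derived from the configured target
  Spearman magnitude $\rho^\ast$ (default 0.45, a typical promoter-CpG
  effect size) by inverting
  $\rho(r) = A/\sqrt{1 + B r^2}$ in the noise-to-shift ratio $r$, with
  $A = 0.788$, $B = 1.473$ fitted by simulation at the default cohort
  shape. A closed-form Gaussian-copula mapping was rejected because $z$ is
  strongly bimodal (two expression regimes) and the clamp truncates both
  tails; the fitted mapping recovers the target within about ±0.05 at the
  default design, and a parameter-recovery test asserts ±0.1. Null probes
  draw beta from a symmetric Beta(2, 2), independent of expression, and
  roughly 1% of all entries are set missing.
* **IHC cohorts** are described by per-type, per-marker frequencies over
  grade categories. Counts are realized by deterministic largest-remainder
  apportionment of $n p$ and only the assignment of grades to case ids is
  randomized. This choice is deliberate: when the frequencies are exact
  case fractions of an observed cohort (8/153 weakly positive clear cell
  cases, 13/14 positive oncocytomas), the generated cohort reproduces those
  marginal counts *exactly*, for any seed, so published count tables can be
  re-encoded and their derived percentages recomputed rather than copied.
  Multinomial sampling would reproduce them only in expectation.

Each generator draws from its own seed stream derived deterministically
from the master seed, so adding a generator never perturbs another's
output, and all generators are pure functions of the configuration
(re-running is bit-identical).

What the generator does *not* emulate: batch effects, tumor purity
gradients, platform artifacts, correlated gene-gene structure, or realistic
beta-value distributions at uncoupled loci. Passing the recovery tests
therefore demonstrates the correctness of the screening and association
machinery under the stated statistical structure, not performance on any
real cohort.

## Numerical and design choices

* Id matching is exact and case-sensitive everywhere; silent case-folding
  can merge distinct identifiers.
* Matrices are held dense; the design targets desk-scale cohorts (up to
  roughly 25k genes × 1k samples).
* Screen output ordering is deterministic: target median descending, gene
  id ascending as tie-break.
* `kw_test()` resolves the all-values-identical degenerate case (tie
  correction 0/0) to $H = 0$, $p = 1$ with a warning; `spearman_test()`
  returns `NA` with a warning for constant input.
* Output CSVs carry a `#`-prefixed provenance line (tool version and
  parameters, no timestamp), so identical configurations produce
  byte-identical result files; the timestamp lives only in the `run.json`
  manifest.
* Problem sizes in the test suite: unit tests run on compact cohorts
  (about 60 samples × 200 genes), while recovery properties are asserted
  on the full default design (440 samples × 2000 genes) over 20 seeds —
  large enough for order statistics at the 95th percentile of a 300-sample
  background to be meaningful, small enough to iterate quickly.

## Limitations

The screen is a deterministic filter, not an inference procedure: it
attaches no uncertainty to the hit/no-hit decision, and threshold choice is
left to the user. The methylation stage tests association, not causation —
hypomethylation co-occurring with expression is consistent with, but does
not establish, methylation-driven silencing. Diagnostic metrics are
computed on the case series supplied; transporting them to a different case
mix is the user's responsibility.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7)
sim <- simulate_expression(cfg)
nm <- normalize_by_reference(sim$expression, "TBP")
s <- summarize_by_subtype(nm, sim$annotation, q = 95)
hits <- apply_screen(s, screen_criteria("chromophobe"))
subset(hits, hit)

records <- simulate_ihc(sim_config(1, ihc = ihc_reference_config()))
counts <- tabulate_ihc(records, "BSND", "chromophobe",
                       positivity_rule("strict"),
                       types = c("chromophobe", "clear_cell", "papillary"))
diagnostic_metrics(counts)
```
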