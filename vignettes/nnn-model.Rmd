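---
title: "The next-nearest-neighbor model of antisense inhibition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The next-nearest-neighbor model of antisense inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nnnfit)
```

## The model

An antisense oligomer hybridizes to a stretch of mRNA; the observed outcome
of one experiment is the percent reduction in net accumulated protein,
with a per-experiment measurement error. Motif-counting approaches to
predicting this outcome founder on overlap: a tetramer motif shares
dinucleotides with its neighbors, so motif tallies cannot be added. The
next-nearest-neighbor (NNN) model resolves this by making the overlap
explicit: the inhibitory effect of a target is the sum of contributions of
its **overlapping base triplets**, the smallest sequence unit that reaches
beyond adjacent neighbors.

For experiment $h$ with target sequence $s_h$, cell line $c_h$ and gene
$g_h$, the model is

$$
\mathrm{reduction}_h \;=\; \sum_{t \in \text{64 triplets}} n_t(s_h)\,P_t
\;+\; \mathbb{1}[c_h = \text{sensitive cell}]\ P_{\text{cell}}
\;+\; P_{g_h} \;+\; \varepsilon_h,
\qquad \varepsilon_h \sim N(0, \sigma_h^2),
$$

where $n_t(s)$ counts triplet $t$ in $s$ **treated as a closed circle**.
Dividing each row and response by $\sigma_h$ turns ordinary least squares
into the variance-weighted (chi-square) fit, so the residual sum of squares
of the weighted system is $\chi^2$ and the upper-tail probability
$Q = \Pr(\chi^2_{\nu} > \chi^2_\mathrm{obs})$ measures goodness of fit
($Q > 0.1$ is conventionally adequate).

### Why circular?

A linear $L$-mer has $L-2$ interior triplets plus end windows that would
need their own edge parameters. Closing the sequence into a circle makes
every position start one full triplet, so an $L$-mer always contributes
exactly $L$ counts and no end parameters are needed. The price is that the
two seam windows are approximations; for a 20-mer roughly 2 of 20 triplets
(or 1 of 20 doublets) are affected, a 5–10% end effect that the package
documents but does not model. `count_kmers()` offers a `"linear"` mode for
inspection, but every fitting and scoring path circularizes.

### Identifiability

Circular counts are not free: in a closed circle each dinucleotide is
entered and exited equally often, giving one flow-balance equation per
dinucleotide,
$\sum_Z n(XYZ) - \sum_W n(WXY) = 0$.
These 16 equations have rank 15 (`constraint_matrix()`), so circular
triplet count vectors span only a $64 - 15 = 49$ dimensional space: at most
49 sequences can have linearly independent triplet composition, and only
49 independent combinations of the 64 triplet parameters are determined by
any amount of data. With one cell indicator and four gene indicators the
design has 69 columns; the gene indicators sum to the constant one, which
is itself proportional to the sum of the triplet columns for fixed-length
targets, adding a sixteenth exact dependency. A generic design therefore
has exactly **16 zero singular values** and effective rank 53; with 112
experiments the fit has $112 - 53 = 59$ degrees of freedom. Degrees of
freedom use the effective rank, not the column count — non-identifiable
directions consume no information — and the convention is recorded in every
fit report so alternatives can be compared.

The solver (`svd_fit()`) zeroes singular values below `sv_rel_tolerance`
(default $10^{-8}$) relative to the largest. Structural zeros sit at the
level of machine precision, many orders of magnitude below the smallest
genuine singular value, so any cutoff between the clusters gives identical
results; the default is configurable for ill-conditioned user data. The
returned solution is the minimum-norm one (zero component along the null
space) and the covariance sums only retained modes,
$C = V_r D_r^{-2} V_r^\top$. Consequently **only estimable combinations**
— weight vectors in the design's row space (`is_estimable()`) — have unique
values and standard errors. Whole-sequence predictions with a cell/gene
context are estimable; so are the four homotriplet parameters (AAA, CCC,
GGG, UUU) *against the count space*, because a homotriplet count is not
involved in any flow-balance equation. One subtlety the coarse statement
"five parameters are directly meaningful" glosses over: with all four gene
indicators present, the sixteenth null direction mixes the overall triplet
level with the gene mean, so the bare unit vector on AAA is estimable in
designs without the gene block but not in the full 69-column design. This
is why `recovery_report()` compares sequence-level predictions in an
explicit cell/gene context (estimable for probes of the training length)
and why homotriplet recovery is demonstrated on gene-free fits.

## Scoring and error propagation

`score_sequence()` computes $P(s) = \sum_t n_t(s) P_t$ plus requested
covariate offsets. Because the score of a realizable circular sequence is
estimable, it is invariant to the minimum-norm convention and to rotations
of the circle (both property-tested). Offsets are constants within one
cell/gene context, so rankings inside a context do not depend on them.

Two standard-error modes are reported and labelled:

* `covariance` — $\sqrt{w^\top C w}$ with the full fitted covariance, the
  exact propagated error (used whenever the parameter table carries a
  covariance matrix);
* `rss` — the root-sum-of-squares of component standard errors, ignoring
  covariances. This is the only option for the packaged published table,
  which ships without a covariance matrix; on the original analysis this
  approximation was reported to be about 90% correct on average.

The packaged table stores the published two-decimal values, so
reconstructed sequence parameters can differ from the published per-12-mer
values by accumulated rounding; with at most 12 summands the discrepancy is
bounded by 0.06 and the tests allow ±0.15.

`scan_windows()` applies the same circular scoring to every window of a
linear mRNA — windows are circularized rather than given end triplets, so
window scores are directly comparable to whole-target scores. Rankings
break ties by ascending start; coordinates are 0-based half-open. One
published worked value, the 12-mer (GGGAGU)$_2$, is not reproducible from
the published triplet values by any sign-consistent summation and appears
to contain a transcription slip; the package does not special-case it.

## The synthetic-data generator

`generate_truth()` / `simulate_experiments()` emulate the statistical
structure of the reference database, not cellular mechanism:

* **Targets**: random 20-mers by rejection sampling under the published
  oligomer-selection constraints — G+C fraction in [0.30, 0.85] (the
  antisense strand has the same G+C fraction, so the check is made on the
  target) and no more than three adjacent G's (G-quadruplex avoidance),
  applied to the linear oligomer, not across the counting seam. A target
  G+C fraction is drawn uniformly over the allowed range first so realized
  G+C spreads over the whole range as in the reference set, rather than
  clustering near 0.5. The cap of $10^5$ attempts turns infeasible
  constraint settings into a clear error.
* **Composition**: by default (n = 112, two cells, four genes) the
  reference layout — 26 targets of the first gene measured in *both* cell
  lines (the same sequences, as distinct rows), then 29, 7 and 24
  single-cell targets of the remaining genes. Any other size uses uniform
  random assignment.
* **Truth**: triplet parameters i.i.d. $N(0, 5^2)$ % — matching the spread
  of the published fitted values (roughly $-9$ to $+13$) — a sensitive-cell
  offset of 10.6%, and per-gene offsets of a few percent, defaulting to the
  published ones.
* **Noise**: Gaussian with per-experiment $\sigma$ drawn uniformly from
  3–10% and recorded as the experiment's error. The error distribution of
  the original measurements is unpublished; this range is a configurable
  placeholder sized to typical western-blot quantitation. Gaussian noise
  with known $\sigma$ is the assumption under which the $\chi^2$/Q
  machinery is exact, which is what the generator is meant to validate.

Determinism: all generation flows from integer seeds through R's default
generator, with the caller's RNG state saved and restored, so identical
seeds give byte-identical tables on any platform.

What passing calibration tests on this generator shows: the solver's
$\chi^2$, Q, covariance and estimability logic are correct *under the
model's own assumptions* (linear triplet effects, independent Gaussian
noise, correct errors). What it does not show: that real knockdown data
satisfy those assumptions — real measurements have non-Gaussian tails,
correlated errors within blots, secondary-structure and off-target effects,
and parameter sets fitted on one cell system transfer poorly to others.

## Numerical and interface choices

* Triplet order is lexicographic over A < C < G < U on the mRNA strand,
  5'→3', everywhere (count vectors, parameter tables, design columns); the
  published table is printed in this order.
* DNA input is transliterated T→U on ingest; an explicit
  `target`/`antisense` flag selects strand interpretation, and antisense
  input is reverse-complemented onto the mRNA strand. Ambiguity codes are
  rejected — the model assigns them no semantics.
* The sensitive cell line (the label carrying the indicator 1) defaults to
  the lexicographically first label, overridable; with the reference labels
  this picks A549, matching the published encoding.
* Rows with missing or non-positive errors are rejected, not imputed:
  weighting is integral to the $\chi^2$ statistic.
* Serialized reports carry 12 significant digits; byte-exact round-trips
  are not promised, value-exact ones (at that precision) are tested.

## Problem sizes in the test suite

The statistical property tests use sizes chosen to make their assertions
sharp but cheap: chi-square/dof calibration averages 100 independent
112-experiment replicates (standard error of the mean ratio
$\approx \sqrt{2/59}/10 \approx 0.02$ against an accepted band of
[0.8, 1.2]); the Q-uniformity check uses 200 replicates
(Kolmogorov–Smirnov distance below 0.15, where the null expectation is
$\approx 1/\sqrt{200} \approx 0.07$); z-calibration of recovered
predictions uses 40 replicates × 5 probes. Structural assertions (ranks,
null spaces, invariances) are exact and need no replication.

## Known limitations

* The circular approximation ignores 5–10% end effects by construction.
* Parameters fitted from one database are only as transferable as that
  database: the packaged published values derive from 112 experiments on
  four genes in two cell lines with phosphorothioate 20-mers, and should
  be treated as illustrative outside that setting.
* No secondary-structure, accessibility, genome-uniqueness or off-target
  screening is provided; those are separate steps in antisense design.
* The doublet (NN) model and the in-vitro free-energy scorer are provided
  for comparison only; no thermodynamic parameter values ship with the
  package (the free-energy scorer takes a user-supplied 16-entry table).
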