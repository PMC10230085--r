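---
title: "Models and methods: reference-gene selection and stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: reference-gene selection and stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
library(dplyr)
```

`refstab` implements the full candidate-selection and validation
workflow for qRT-PCR reference genes in multi-tissue panels. This
vignette describes the statistical models behind each stage, the
parameters that matter, the synthetic-data generator the tests rely on,
and the numerical and design choices made where the methodology left
room.

## The screening model

Reference-gene candidates are mined from an RNA-seq abundance matrix
(TPM, transcripts × samples). Two filters apply:

* an **expression floor**: a transcript is kept only if its abundance
  is *strictly greater* than the floor (default 1.5) in *every*
  sample — a reference gene must be measurable everywhere;
* a **coefficient-of-variation screen**: within each tissue group, all
  member samples are pooled and
  $\mathrm{CV}\% = 100 \cdot s/\bar{x}$ is computed per transcript,
  with $s$ the sample ($n-1$) standard deviation. A candidate passes
  when CV is *strictly below* the group's cutoff.

Choices worth making explicit:

* The $n-1$ denominator is used although "standard deviation" alone
  would admit either convention: group sizes are small and the
  unbiased estimator is the statistical default.
* Samples are pooled across the group's tissues and replicates; no
  within-tissue averaging precedes the CV, since the screen is meant
  to capture between-tissue as well as between-replicate variability.
* Both inequalities are strict ("greater than" the floor, "lower
  than" the cutoff), so boundary values fail. Tightening a cutoff can
  therefore never enlarge the pass set — a property the tests assert.
* Non-annotated transcripts are dropped before flagging: only named
  genes can be carried into primer design and validation.
* Gene identity for counting is the transcript ID; two isoforms of
  one gene stay distinct transcripts but collapse to one gene in
  gene-level counts.

The default screen groups (`screen_grouping_default()`) are Brain (the
three brain masses, 15%), Nervous (brain plus the two peripheral
ganglia, 15%), Arm (four arm tissues, 15%) and Adult (all nine
RNA-seq tissues, 20% — relaxed because whole-body variability is
higher). The packaged fixture `table1_cv.tsv` carries a published
example of the screen's output — 77 candidate rows over these four
groups plus 8 previously used reference genes — and is the basis of the
package's fixture-derived acceptance checks.

## Primer amplification efficiency

A dilution series relates Ct linearly to $\log_{10}$(template
concentration). `fit_dilution()` is ordinary least squares (via
`stats::lm`) of mean Ct per dilution point, and the slope $m$ converts
to efficiency by

$$E = \left(10^{-1/m} - 1\right) \times 100,$$

so perfect doubling per cycle ($m = -3.3219$) gives $E = 100\%$.
Replicate Cts are averaged per concentration before fitting (one point
per dilution). The QC band (default 98–102%) is read *inclusively*;
failing assays are flagged, not deleted, so the decision to exclude
stays with the analyst. $r^2$ is reported but not used as a filter —
no threshold is imposed on it.

## The four stability algorithms

All four operate on a complete mean-Ct matrix (genes × samples);
technical replicates are averaged on entry, and missing cells are a
hard error rather than silently imputed, because every one of these
estimators assumes a complete matrix and imputation would bias the
SDs.

**Relative quantities.** geNorm and NormFinder work on linear-scale
quantities $Q_{gj} = E_g^{\min_j C_{gj} - C_{gj}}$, where $E_g$ is the
per-gene amplification factor (2 unless measured efficiencies are
supplied — the upstream QC pins assays near 100%, so 2 is the
operative default). Each gene's maximum quantity is 1; logs are base 2
throughout.

**geNorm.** For genes $j, k$ the pairwise variation is the sample SD
over samples of $\log_2(Q_j/Q_k)$; $M_j$ is the mean over partners.
The gene with the largest $M$ is removed and $M$ recomputed until two
genes remain — these two cannot be distinguished by pairwise ratios
and share rank 1 (ordered by gene ID within the tie, which is
immaterial downstream). A gene's reported stability value is its $M$
in the round of its elimination. The implementation computes pairwise
SDs from the row covariance matrix
($\mathrm{SD}^2(y_j - y_k) = S_{jj} + S_{kk} - 2S_{jk}$); the test
suite checks it against a brute-force double loop over pairs at
$10^{-10}$. `V(n/n+1)` is the SD of
$\log_2(\mathrm{NF}_n/\mathrm{NF}_{n+1})$, with $\mathrm{NF}_n$ the
per-sample geometric mean quantity of the $n$ most stable genes.

**NormFinder.** On $y = \log_2 Q$, each sample's gene-average is
subtracted (removing sample-wide scale shifts) and
$z_i = \widehat{\mathrm{Var}}_j(d_{ij})$ is corrected for the
contribution of the other genes:

$$\hat\sigma_i^2 = \max\!\left(0,\;
 \left(z_i - \frac{\sum_l z_l}{k(k-1)}\right)\frac{k}{k-2}\right),$$

an unbiased estimator of the per-gene variance for $k \ge 3$ genes
(hence the hard minimum of 3); the truncation at 0 is explicit. The
stability value is $\hat\sigma_i$. The *ungrouped* form is the
default: whether tissue groups should enter is a genuine open choice
in multi-tissue panels, and the grouped variant — per-group variance
estimates plus each gene's mean absolute inter-group deviation,
combined additively — is available behind `grouped = TRUE` as this
package's reading of the intra/inter decomposition.

**BestKeeper.** Descriptives on *raw Ct*: arithmetic mean, min, max,
"SD" — the method's published convention is the *mean absolute
deviation* from the arithmetic mean, not the root-mean-square — and
CV% = 100·SD/mean. The BestKeeper index is the per-sample geometric
mean of Ct across genes, and each gene is Pearson-correlated against
it. Ranking is by SD ascending; SD > 1 Ct flags a gene as
inconsistent. Note the documented asymmetry: a constant Ct shift of
one gene leaves geNorm, NormFinder and ΔCt unchanged and leaves
BestKeeper's SD unchanged, but changes BestKeeper's CV% (the mean
moves); the tests pin this behaviour.

**Comparative ΔCt.** For each ordered pair the SD over samples of
$C_i - C_j$; a gene's stability is the mean over partners. Equivalent
to geNorm's first round up to the $\log_2 E$ scale factor, but run
without elimination.

## Comprehensive ranking

Per-method ranks are aggregated by their geometric mean; the final
ranking is ascending in that mean with deterministic ties broken by
gene ID. Ties within a method get the average rank, except geNorm's
final pair, which keeps the joint rank 1 (the next gene is rank 2).
The aggregation depends only on ranks, so it is invariant to monotone
relabeling of any method's stability values and to method order. The
published weighting nuances of the RefFinder web tool are deliberately
reduced to the plain geometric mean of ranks — the aggregation the
motivating workflow actually describes.

## Efficiency-corrected quantification

Relative expression of a target $t$ in sample $j$ against a calibrator
tissue, normalized by references $r$:

$$\mathrm{ratio}_{tj} =
 \frac{E_t^{\,\bar C_{t,\mathrm{cal}} - C_{tj}}}
      {\mathrm{geomean}_r\, E_r^{\,\bar C_{r,\mathrm{cal}} - C_{rj}}}.$$

The calibrator Ct per gene is the across-animal mean in the calibrator
tissue, so ratios are computed per animal against a common baseline
and the calibrator tissue averages to 1 by construction (the
methodology leaves per-animal versus pooled calibration open; the
per-animal form preserves biological replication for the ANOVA). With
all $E = 2$ the formula reduces *exactly* to $2^{-\Delta\Delta C_t}$,
a closed-form identity the tests assert. Measured efficiencies can be
supplied per gene; nominal 100% is the default, mirroring the upstream
QC.

Tissue comparisons run on $\log_2$ ratios — ratios are multiplicative,
and two-tailed parametric testing presumes approximate normality — via
one-way ANOVA followed by all pairwise two-sample pooled-variance $t$
tests with Bonferroni adjustment,
$p_\mathrm{adj} = \min(1, p \cdot n_\mathrm{pairs})$, the family being
the pairwise tissue comparisons of one target gene. With two groups
the ANOVA $F$ equals the squared pooled $t$ — another identity in the
tests.

## The synthetic-data generator

`simulate_ct_matrix()` draws

$$C_{gtar} = B_g + D_{gt} + A_a + \varepsilon_{gtar}$$

with per-gene baselines $B_g \sim U(18, 32)$, tissue effects
$D_{gt} \sim N(0, \sigma^2_{\mathrm{tissue}(g)})$ drawn **once per
(gene, tissue) and shared across animals**, animal effects
$A_a \sim N(0, \sigma_A^2)$ and technical noise
$\varepsilon \sim N(0, \sigma_\epsilon^2)$. Sharing $D_{gt}$ across
animals is deliberate: stability algorithms must see *structured*
tissue-specific instability, as in real panels, not i.i.d. noise. A
fraction of genes is planted "stable" (default
$\sigma_\mathrm{tissue} = 0.1$ Ct) and the rest "unstable" (1.5 Ct);
the returned truth table records class, generative SD, realized SD and
baseline. The default panel mirrors the motivating study design: 12
tissues × 5 animals × technical triplicates, whose averaging is left
to the downstream pipeline exactly as real triplicates would be.

Defaults the methodology does not pin down were chosen once on
field-typical grounds: $\sigma_A = 0.15$ Ct (systematic
specimen-to-specimen offsets of a few tenths of a cycle),
$\sigma_\epsilon = 0.1$ Ct (well-run technical triplicates agree
within ~0.2–0.3 Ct), baselines spanning 18–32 Ct (moderately to
lowly expressed genes).

`simulate_tpm_matrix()` draws lognormal abundances with the log-SD
solving $\mathrm{CV} = \sqrt{e^{\sigma^2} - 1}$, so the realized group
CV converges to the target as samples grow. `simulate_dilution_series()`
generates $C = b + m\log_{10}(\mathrm{conc})$ with
$m = -1/\log_{10}(1 + E/100)$, four-fold dilutions from 10 down to
0.15625 ng/µL by default. All generators are deterministic under a
fixed seed (the global RNG state is left untouched via `withr`).

**What the generator does not emulate** — and hence what passing tests
do not show about real data: amplification artefacts (primer dimers,
inhibition), heteroscedastic noise at high Ct, correlated biological
replicate structure beyond a shared animal offset, batch/plate
effects, and any read-level RNA-seq properties (the TPM generator
produces abundances directly). Planted-truth recovery demonstrates the
estimators' correctness under their own model assumptions, not
robustness to assay pathology.

## Numerical choices, tie-breaks, degenerate inputs

* Pairwise SD matrices are formed from covariance matrices; tiny
  negative variances from floating-point cancellation are clamped to 0
  before the square root.
* geNorm elimination ties (equal maximal $M$) are broken by gene ID,
  making runs reproducible.
* A constant-Ct gene gets BestKeeper SD 0 and rank 1; its correlation
  with the index is undefined and reported as `NA` rather than forced.
* Zero group mean makes a CV undefined; such transcripts are excluded
  with a warning, not silently kept as 0 or `Inf`.
* A non-negative dilution slope is biologically implausible; the
  efficiency value is still returned but flagged with a warning.
* An empty post-floor screen warns rather than errors — an empty
  candidate table is a legitimate (if disappointing) result.

## Problem sizes used in testing

The test suite exercises the oracle comparisons on 4–6-gene matrices,
the planted-recovery property on the default 20-gene, 12 × 5 panel
over 50 seeds, and parameter recovery for NormFinder at $k = 10$,
$n = 200$. For the latter, the 25% recovery bound is applied to
variance estimates averaged over 10 replicate simulations: a single
draw's variance estimate carries ≈12% relative sampling SD, so a
per-draw bound would measure the luck of one seed rather than the
estimator's accuracy; replicate averaging reduces that sampling noise
to ≈4% and makes the bound a test of bias.

## Known limitations

* BestKeeper's ordering statistic is its MAD-based "SD"; published
  workflows sometimes order by the index correlation instead. Both are
  reported; only the ranking convention is fixed.
* The grouped NormFinder variant is one defensible reading of the
  intra/inter decomposition, not a reimplementation of any specific
  release of the original tool.
* `V(n/n+1)` is reported for all $n$, but the package makes no
  recommendation about the optimal number of reference genes beyond
  exposing the sequence.
* The quantification stage assumes the calibrator tissue is measured
  for every gene involved; there is no fallback imputation.
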