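---
title: "Genomic fabrics: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic fabrics: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(gfabric)
```

## The genomic fabric model

A condition's transcriptome is treated as a *fabric*: every gene is located
by three statistically independent coordinates estimated from `n` biological
replicates (the design this package targets is `n = 4`), and biological
conclusions are drawn from how the fabric — not individual expression
values — differs between conditions.

### Preprocessing

`read_expression_set()` loads a genes-by-replicates table (TSV or CSV,
auto-detected). Arrays that probe one gene with several spots keep
spot-level rows plus a spot map. `collapse_and_normalize()` (called
internally by `fabric_profile()`) averages spots within a gene and divides
all values by the median of the per-gene replicate means, so expression is
in units of the median gene and `median(AVE) = 1` exactly.

### The three coordinates

**AVE** is the mean normalized expression of the gene (dimensionless,
units of the median gene).

**REV** is the relative expression variability in percent:

$$\mathrm{REV} = \frac{100\cdot s}{\bar x}\cdot
\frac12\left(\sqrt{\frac{\nu}{\chi^2_{1-\alpha/2;\nu}}} +
\sqrt{\frac{\nu}{\chi^2_{\alpha/2;\nu}}}\right), \qquad \nu = n-1.$$

The bracket is the mid-interval of the chi-square confidence interval of a
standard deviation; at `ν = 3`, `α = 0.05` it equals
`r 0.5 * (sqrt(3 / qchisq(0.975, 3)) + sqrt(3 / qchisq(0.025, 3)))` (≈ 2.1475).
It widens the raw CV to acknowledge how poorly `s` is determined from few
replicates. With multiple spots per gene the spot CVs are pooled as a root
mean square and the degrees of freedom are summed, which narrows the factor.
`alpha` is exposed as a parameter of `fabric_profile()` (default 0.05).

**COR** is the Pearson correlation of log2 expression across replicates for
all gene pairs. Genes with zero variance in any replicate set get `NA`
correlations and are excluded (with a message) from anything that needs
them. Log2 is used because replicate noise is closer to log-normal than
normal on the raw scale.

The three families are independent by construction: AVE is a location, REV
a scaled dispersion (location-free), and COR depends only on the pattern of
replicate deviations, not their size.

### Derived quantities

* `compute_rec()`: `REC = median(REV)/REV − 1`, capped (default 100) when
  `REV = 0`. `compute_prec()` applies the same ratio to set medians.
* `compute_gch()`: `GCH = (REC+1)·exp(4·⟨COR²⟩ − 1)`; with a typical gene
  (`REC = 0`) and the null mean squared correlation ¼ the score is 1, so
  GCH reads as fold-above-typical commanding height. `gene_hierarchy()`
  ranks genes by GCH (ties broken lexicographically for determinism) and
  names the top gene the GMR.
* `regulation_table()`: signed ratio `x` of AVEs (`|x| ≥ 1`, negative for
  down), Welch t-test on log2 normalized values, and the noise-adaptive
  cut-off `CUT = 1 + 2·√((REV_A/100)² + (REV_B/100)²)`. UP/DOWN requires
  both `|x| ≥ CUT` and `p < p_threshold` (default 0.05, uncorrected — the
  per-gene CUT already scales with each gene's measured noise; this is a
  deliberate property of the method, not an oversight).
* `compute_wir()` / `compute_itd()`: expression-weighted regulation
  `AVE_A·sign(x)·(|x|−1)·(1−p)` and the three-coordinate displacement
  `√(d_AVE² + d_REV² + d_COR²)` with `d_AVE = sign(x)(|x|−1)`,
  `d_REV = (REV_B−REV_A)/REV_A` and `d_COR = ½·mean_g|ΔCOR|`. ITD can flag
  genes whose fold change is neutral but whose control or coordination was
  remodeled.
* `pathway_scores()`: `WPR = (100/N)·√(Σ WIR²)` and the analogous PTD over
  each gene set (GMT files via `read_gene_sets()`).
* `classify_pairs()`: SYNERGISTIC / ANTAGONISTIC / INDEPENDENT against the
  critical correlation `r_crit = t/√(n−2+t²)`,
  `t = qt(1−p/2, n−2)`; at `n = 4`, `p = 0.05` this is
  `r round(critical_r(4, 0.05), 3)`. The independence band
  (`independence_threshold`, default 0.05) is a pragmatic zero-band, not a
  significance statement; pairs in neither region are UNCLASSIFIED.
  `expected_false_coordination()` reports the false-positive load implied
  by testing all pairs at once.
* `recovery_report()`: two-letter categories (disease call then treated
  call, `X` = neutral/recovered), the GER score
  `100·(DX+UX−XD−XU−2(DU+UD))/Σ(non-XX)`, and pathway-level PRE and CPR
  built from WPR and PTD ratios, with a qualitative outcome
  (ideal / positive / null / negative).

## The synthetic generator and its scope

`simulation_spec()` + `simulate_study()` draw log2 expression from a
multivariate normal: gene `i` has raw mean `m_i` and coefficient of
variation `cv`, mapped to log-normal parameters
`σ² = log(1+cv²)`, `μ = log(m_i) − σ²/2` so that raw means are unbiased.
Correlation *blocks* (members, ρ) are assembled into the log-scale
correlation matrix; sampling uses an eigen-decomposition square root, so
singular blocks (ρ = 1) are legal, and overlapping contradictory blocks are
projected to the nearest positive semi-definite matrix (with a message).
Optional probe spots multiply log-normal technical noise onto each gene.

`make_three_condition_fixture()` builds a 200-gene reference/disease/treated
study whose designed regulation categories are exact at `cv = 0`: designed
means are placed so that no designed fold change crosses the condition
median (otherwise normalization itself would shift every ratio). It also
plants condition-specific coordination blocks and a "quiet mover" — a gene
whose mean never changes but whose variability and coordination do, giving
it a large ITD while staying NEUTRAL.

What the generator can and cannot support: it reproduces the *model's own
assumptions* (log-normal noise, block correlation), so passing tests show
the estimators recover known parameters and designed structure under those
assumptions. They do not show robustness to real-data pathologies
(outliers, heteroscedastic probes, batch effects), which the generator does
not model.

## Numerical choices

* Problem sizes in tests (200–2000 genes, 4 replicates, 3 conditions) are
  this package's own choices, picked so the suite runs in seconds while
  leaving sampling error well below the asserted tolerances.
* Reported percentages round half-up (`round_half_up()`), matching the
  convention of the field's published tables rather than banker's rounding.
* TSV output writes doubles at 17 significant digits so files round-trip
  bit-exactly.
* At `n = 4` the sample standard deviation is biased:
  `E[s] = c₄(4)·σ ≈ 0.9213·σ`. REV is therefore, on average, about 1.95× —
  not 2.1475× — the true percent CV. The estimator is kept exactly as
  defined; consumers should read REV as a *conservative interval-style*
  variability score, not an unbiased CV estimate.

## Limitations

* Four replicates give very low power for coordination
  (`r_crit ≈ 0.95`) and noisy REC/GCH rankings; hierarchies are best read
  as top-of-list candidates, not precise orderings.
* Welch tests on `n = 4` log2 values are fragile to non-normality; the
  noise-adaptive CUT mitigates but does not remove this.
* PRE and CPR divide by the disease-stage scores; they are undefined when
  the disease leaves a pathway unperturbed.

## End-to-end runs

`run_pipeline()` consumes a list or JSON/YAML config naming the expression
tables (or a `simulate` block), the design, optional gene sets, and
thresholds; it writes per-condition fabric, hierarchy and coordination
tables, regulation and pathway scores versus the reference, the recovery
report, and a `manifest.json` recording every threshold used. The same
stages are reachable from the shell through `inst/cli/gfp.R`.
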