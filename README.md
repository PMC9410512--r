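# gfabric

Transcriptome characterization with the genomic fabric approach: instead of
reducing a condition to a list of differentially expressed genes, each
condition is profiled by three statistically independent feature families
computed for every gene from a small number of biological replicates, and
everything downstream — control scores, regulator hierarchies, coordination
networks, pathway remodeling and treatment-recovery metrics — is derived
from those profiles.

## The model

For a condition with `n` biological replicates (four is the typical design),
after collapsing probe spots to genes and normalizing so the median gene has
unit expression:

- **AVE** — average expression level of the gene, in units of the median
  gene (so `median(AVE) = 1` by construction).
- **REV** — relative expression variability: 100 × the sample coefficient of
  variation, multiplied by the mid-interval chi-square factor
  `½(√(ν/χ²(1−α/2; ν)) + √(ν/χ²(α/2; ν)))` with `ν = n − 1` degrees of
  freedom (`≈ 2.1475` at `ν = 3`, `α = 0.05`). When a gene is probed by
  several spots, the spot CVs are pooled as a root mean square and the
  degrees of freedom summed.
- **COR** — the Pearson correlation of log2 expression across replicates for
  every gene pair, giving the condition's coordination structure.

From these:

- **REC** (relative expression control) `= median(REV)/REV − 1`: positive
  for genes kept under tighter-than-typical control by the cell.
  **PREC** is the same ratio computed over a gene set.
- **GCH** (gene commanding height)
  `= (REC + 1) · exp(4·⟨COR²⟩ − 1)`, where `⟨COR²⟩` averages the squared
  correlation of the gene with every other gene. The top-ranked gene is the
  **GMR** (gene master regulator); the hierarchy is condition-specific.
- **Regulation** between conditions A and B uses the signed expression ratio
  `x` (`|x| ≥ 1`, negative for down-regulation) and a Welch t-test on log2
  values, against a noise-adaptive cut-off
  `CUT = 1 + 2·√((REV_A/100)² + (REV_B/100)²)`: a gene is called UP or DOWN
  only if `|x| ≥ CUT` **and** `p < 0.05`; otherwise NEUTRAL. No
  multiple-testing correction is applied — the cut-off itself already scales
  with the measured noise of each gene.
- **WIR** (weighted individual regulation)
  `= AVE_A · sign(x) · (|x| − 1) · (1 − p)` and **ITD** (individual
  transcriptomic distance)
  `= √(d_AVE² + d_REV² + d_COR²)` capture, respectively, the
  expression-weighted regulation and the full three-coordinate displacement
  of a gene between conditions; a gene can be NEUTRAL by fold change yet
  have a large ITD because its variability or coordination changed.
- **Pathway scores**: `WPR = (100/N)·√(Σ WIR²)` and the analogous `PTD`
  over a gene set of size `N` (quantified members).
- **Coordination**: gene pairs are SYNERGISTIC (`r ≥ r_crit`), ANTAGONISTIC
  (`r ≤ −r_crit`) or INDEPENDENT (`|r|` within a small band around 0), with
  `r_crit = t/√(n−2+t²)` the two-sided critical Pearson correlation
  (`≈ 0.950` at `n = 4`, `p = 0.05`).
- **Recovery** (reference / disease / treated designs): each gene gets a
  two-letter category from its disease and treated calls (e.g. `DX` = down
  in disease, recovered in treatment; `DU` = down in disease, up after
  treatment). The **GER** (gene expression recovery)
  `= 100·(DX+UX−XD−XU−2·(DU+UD)) / (all non-XX)`, and at pathway level
  **PRE** `= (1 − WPR_treated/WPR_disease)·100` and
  **CPR** `= (1 − PTD_treated/PTD_disease)·100` grade the treatment from
  ideal (100) through positive and null to negative.

## Worked example

```r
library(gfabric)
fx <- make_three_condition_fixture(seed = 1)   # NN / IN / IT, ground truth known
fabrics <- lapply(fx$study, fabric_profile)
fabrics$NN
#> Fabric 'NN': 200 genes, 4 replicates; median REV 10.4%, mean REV 10.6%

gene_hierarchy(fabrics$NN, top_k = 5)
#> Gene hierarchy 'NN': 200 ranked genes, GMR = g190 (GCH = 18.30)

reg <- regulation_table(fabrics$NN, fabrics$IN)
head(reg, 3)
#>   gene         x            p      cut call       wir      itd
#> 1 g001 -4.104420 2.184604e-06 1.372580 DOWN -1.582775 3.288762
#> 2 g002 -4.282148 2.556578e-06 1.376897 DOWN -1.775785 3.472496
#> 3 g003 -4.226048 3.633354e-08 1.352956 DOWN -1.649108 3.242471

pathway_scores(reg, fx$sets)
#>         set n_members n_quantified     wpr      ptd
#> 1 pathway40        40           40 34.5405 34.25862

reg_t <- regulation_table(fabrics$NN, fabrics$IT)
recovery_report(reg, reg_t, sets = fx$sets)
#> Recovery report (NN -> IN vs IT):
#>   counts: DX=7 UX=5 XD=2 XU=0 DD=1 UU=0 UD=0 DU=0 XX=185
#>   GER = 66.67%
#>   pathway40: GER = 66.67%, PRE = 80.92%, CPR = 31.75% (positive)
```

The whole pipeline (fabric, hierarchy, coordination edges, regulation,
pathway scores, recovery, plus a JSON manifest recording every threshold)
can be driven from a single config with `run_pipeline()`, or from the shell
via the thin CLI at `inst/cli/gfp.R`.

## Limitations

- REV assumes approximately normal replicate noise for its chi-square
  interval; at `n = 4` the point estimate of the CV is biased low (see the
  note under *Installation and tests*).
- Correlation-based coordination at `n = 4` has very low power
  (`r_crit ≈ 0.95`); `expected_false_coordination()` quantifies the
  implied false-positive load.
- Regulation calls are per-gene with no family-wise correction, faithful to
  the method's design; treat gene lists as ranked candidates, not
  inventories.

See the methods vignette (`vignettes/genomic-fabrics.Rmd`) for derivations,
parameter choices and the scope of the synthetic generator.
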