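#' Signed expression ratio
#'
#' Fold change of condition B over condition A, reported on the signed
#' convention of the field: `x = AVE_B/AVE_A` when that ratio is >= 1, and
#' `-AVE_A/AVE_B` (negative, for down-regulation) otherwise, so `|x| >= 1`
#' always and `x = 1` means no change.
#'
#' @param ave_a,ave_b Positive AVE values (vectorized).
#' @return Signed ratio(s) with `|x| >= 1`.
#' @export
expression_ratio <- function(ave_a, ave_b) {
  stopifnot(all(ave_a > 0), all(ave_b > 0))
  r <- ave_b / ave_a
  ifelse(r >= 1, r, -1 / r)
}

#' Heteroscedastic t-test of expression equality
#'
#' Two-tailed Welch (unequal-variance) t-test on the log2 of the
#' median-normalized replicate values of one gene in two conditions.
#' Degenerate inputs (zero variance on both sides) return p = 1 when the
#' means are equal and p = 0 otherwise.
#'
#' @param values_a,values_b Replicate vectors (linear scale, > 0), length
#'   >= 2 each.
#' @return p-value in \[0, 1\].
#' @export
welch_p <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2,
            all(values_a > 0), all(values_b > 0))
  la <- log2(values_a); lb <- log2(values_b)
  if (stats::sd(la) == 0 && stats::sd(lb) == 0)
    return(if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0)
  stats::t.test(la, lb, var.equal = FALSE)$p.value
}

#' Gene-specific fold-change cut-off (CUT)
#'
#' Noise-adaptive absolute fold-change threshold for one gene:
#' `CUT = 1 + 2 * sqrt(CV_A^2 + CV_B^2)` where `CV = REV/100` in each
#' condition, so that stably expressed genes face a stringent cut-off while
#' noisy genes require a larger ratio. At REV = 0 in both conditions any
#' statistically significant ratio counts as regulation (CUT = 1).
#'
#' @param rev_a,rev_b REV values in percent (>= 0; vectorized).
#' @return CUT value(s) >= 1.
#' @export
fold_change_cut <- function(rev_a, rev_b) {
  stopifnot(all(rev_a >= 0), all(rev_b >= 0))
  1 + 2 * sqrt((rev_a / 100)^2 + (rev_b / 100)^2)
}

#' Regulation call for one gene
#'
#' `UP` when `x >= CUT` with `p < p_threshold`; `DOWN` when `x <= -CUT` with
#' `p < p_threshold`; `NEUTRAL` otherwise. No multiple-testing correction is
#' applied: the criterion is the per-gene p < 0.05 combined with the
#' gene-specific cut-off.
#'
#' @param x Signed expression ratio(s) (`|x| >= 1`).
#' @param p Welch p-value(s).
#' @param cut Gene-specific cut-off(s) (>= 1).
#' @param p_threshold Significance level (default 0.05).
#' @return Character vector in `c("UP", "DOWN", "NEUTRAL")`.
#' @export
classify_regulation <- function(x, p, cut, p_threshold = 0.05) {
  ifelse(p < p_threshold & x >= cut, "UP",
         ifelse(p < p_threshold & x <= -cut, "DOWN", "NEUTRAL"))
}

#' Weighted individual gene regulation (WIR)
#'
#' Signed contribution of one gene to the transcriptome alteration,
#' weighting the absolute departure from the reference expression level by
#' the statistical confidence:
#' `WIR = AVE_A * sign(x) * (|x| - 1) * (1 - p)`.
#' Positive for up-regulated genes, negative for down-regulated ones, 0 at
#' x = 1.
#'
#' @param ave_a Reference-condition AVE (vectorized).
#' @param x Signed expression ratio(s).
#' @param p Welch p-value(s).
#' @return WIR value(s).
#' @export
compute_wir <- function(ave_a, x, p) {
  ave_a * sign(x) * (abs(x) - 1) * (1 - p)
}

#' Individual transcriptomic distance (ITD)
#'
#' Magnitude of the 3D vector whose orthogonal components are the relative
#' changes of the three independent gene characteristics between conditions
#' A and B:
#' \itemize{
#'   \item `d_AVE = sign(x) * (|x| - 1)` (relative expression-level change),
#'   \item `d_REV = (REV_B - REV_A) / REV_A` (0 when both are 0),
#'   \item `d_COR = mean over all other genes g of |COR_B(i,g) - COR_A(i,g)| / 2`,
#'     undefined correlations excluded from the mean.
#' }
#' `ITD = sqrt(d_AVE^2 + d_REV^2 + d_COR^2)`. A gene can be NEUTRAL by the
#' fold-change criterion yet carry a large ITD through its variability and
#' coordination changes.
#'
#' @param gene Gene id.
#' @param fabric_a,fabric_b `gfp_fabric` profiles over the same gene
#'   universe.
#' @param x Signed expression ratio for this gene.
#' @return ITD value (>= 0).
#' @export
compute_itd <- function(gene, fabric_a, fabric_b, x) {
  stopifnot(gene %in% names(fabric_a$ave), gene %in% names(fabric_b$ave))
  d_ave <- sign(x) * (abs(x) - 1)
  ra <- fabric_a$rev[[gene]]; rb <- fabric_b$rev[[gene]]
  d_rev <- if (ra == 0 && rb == 0) 0 else (rb - ra) / ra
  others <- setdiff(names(fabric_a$ave), gene)
  dd <- abs(fabric_b$cor[gene, others] - fabric_a$cor[gene, others])
  d_cor <- if (all(is.na(dd))) 0 else mean(dd, na.rm = TRUE) / 2
  sqrt(d_ave^2 + d_rev^2 + d_cor^2)
}

#' Gene-by-gene comparison of two conditions
#'
#' Builds the full regulation table for B versus A over the genes quantified
#' in both: signed ratio `x`, Welch p-value, gene-specific `CUT`, regulation
#' call, `WIR`, and `ITD`. Gene order follows the reference (A) condition.
#'
#' @param fabric_a Reference-condition `gfp_fabric`.
#' @param fabric_b Comparison-condition `gfp_fabric`.
#' @param p_threshold Significance level for the call (default 0.05).
#' @return An object of class `gfp_regulation`: a data.frame with columns
#'   `gene`, `x`, `p`, `cut`, `call`, `wir`, `itd` and attributes
#'   `comparison`, `p_threshold`.
#' @export
regulation_table <- function(fabric_a, fabric_b, p_threshold = 0.05) {
  stopifnot(inherits(fabric_a, "gfp_fabric"), inherits(fabric_b, "gfp_fabric"))
  genes <- intersect(names(fabric_a$ave), names(fabric_b$ave))
  if (length(genes) < length(fabric_a$ave) ||
      length(genes) < length(fabric_b$ave))
    .note("comparison restricted to %d genes quantified in both conditions",
          length(genes))
  # keep reference order
  genes <- names(fabric_a$ave)[names(fabric_a$ave) %in% genes]
  fa <- .subset_fabric(fabric_a, genes)
  fb <- .subset_fabric(fabric_b, genes)
  x <- expression_ratio(fa$ave, fb$ave)
  p <- vapply(genes, function(g)
    welch_p(fa$values[g, ], fb$values[g, ]), numeric(1))
  cut <- fold_change_cut(fa$rev, fb$rev)
  call <- classify_regulation(x, p, cut, p_threshold)
  wir <- compute_wir(fa$ave, x, p)
  itd <- vapply(seq_along(genes), function(i)
    compute_itd(genes[i], fa, fb, x[i]), numeric(1))
  out <- data.frame(gene = genes, x = unname(x), p = unname(p),
                    cut = unname(cut), call = unname(call),
                    wir = unname(wir), itd = itd,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "comparison") <- c(fabric_a$condition, fabric_b$condition)
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("gfp_regulation", "data.frame")
  out
}

# internal: restrict a fabric to a gene subset, preserving order
.subset_fabric <- function(fab, genes) {
  fab$ave <- fab$ave[genes]
  fab$rev <- fab$rev[genes]
  fab$cor <- fab$cor[genes, genes, drop = FALSE]
  fab$values <- fab$values[genes, , drop = FALSE]
  fab
}

#' Presence/absence comparison of quantified gene sets
#'
#' Genes quantified in only one of two conditions ("turned on/off") are kept
#' out of the numeric ratio pipeline; this reports them separately.
#'
#' @param fabric_a,fabric_b `gfp_fabric` profiles.
#' @return data.frame with columns `gene`, `status`
#'   (`"only_in_A"`/`"only_in_B"`).
#' @export
presence_table <- function(fabric_a, fabric_b) {
  only_a <- setdiff(names(fabric_a$ave), names(fabric_b$ave))
  only_b <- setdiff(names(fabric_b$ave), names(fabric_a$ave))
  data.frame(gene = c(only_a, only_b),
             status = rep(c("only_in_A", "only_in_B"),
                          c(length(only_a), length(only_b))),
             stringsAsFactors = FALSE)
}
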