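#' Collapse probing spots and median-normalize
#'
#' First collapses spot-level rows to one row per gene (the mean over the
#' valid spots probing that gene, per replicate), then divides every value by
#' the median over genes of the per-gene replicate mean, so the median gene
#' has an average expression of exactly 1 in this condition. All downstream
#' fabric characteristics are computed on this scale.
#'
#' @param es A `gfp_expression_set` (spot-level or already gene-level).
#' @return A gene-level, median-normalized `gfp_expression_set`. When the
#'   input carried a spot map, the spot-level (normalized) matrix is kept in
#'   the `spot_values` element so replicate variability can still be pooled
#'   per spot.
#' @export
collapse_and_normalize <- function(es) {
  stopifnot(inherits(es, "gfp_expression_set"))
  if (is.null(es$spot_map)) {
    gene_values <- es$values
    spot_values <- NULL
    spot_map <- NULL
  } else {
    gene_values <- t(vapply(es$spot_map, function(rows) {
      colMeans(es$values[rows, , drop = FALSE])
    }, numeric(ncol(es$values))))
    rownames(gene_values) <- names(es$spot_map)
    spot_values <- es$values
    spot_map <- es$spot_map
  }
  scale <- stats::median(rowMeans(gene_values))
  gene_values <- gene_values / scale
  out <- expression_set(gene_values, es$condition)
  out$normalized <- TRUE
  out$spot_map <- spot_map
  out$spot_values <- if (!is.null(spot_values)) spot_values / scale
  out
}

#' Average expression level (AVE)
#'
#' Mean across replicates of the median-normalized expression, per gene:
#' units are multiples of the median gene's expression in this condition
#' (the median gene has AVE = 1).
#'
#' @param es A collapsed, normalized `gfp_expression_set`.
#' @return Named numeric vector of AVE values.
#' @export
compute_ave <- function(es) {
  stopifnot(inherits(es, "gfp_expression_set"))
  if (!isTRUE(es$normalized))
    .halt("compute_ave expects a collapsed, median-normalized set")
  rowMeans(es$values)
}

# internal: chi-square mid-interval factor for df degrees of freedom
.rev_factor <- function(df, alpha = 0.05) {
  0.5 * (sqrt(df / stats::qchisq(1 - alpha / 2, df)) +
         sqrt(df / stats::qchisq(alpha / 2, df)))
}

#' Relative expression variability (REV)
#'
#' Per gene, the sample coefficient of variation across biological
#' replicates, inflated to the mid-point of its two-sided chi-square
#' confidence interval:
#' `REV = 100 * CV * (sqrt(nu/chisq(1-alpha/2; nu)) + sqrt(nu/chisq(alpha/2; nu))) / 2`
#' with `nu = n - 1` degrees of freedom per spot. Expressed in percent.
#'
#' When the set retains spot-level data, per-spot CVs are pooled as their
#' root mean square and `nu` is summed over the spots probing the gene, so
#' technical replication tightens the interval.
#'
#' @param es A collapsed, normalized `gfp_expression_set`.
#' @param alpha Two-sided interval level (default 0.05 for 95%).
#' @return Named numeric vector of REV values (percent, >= 0). A gene with
#'   identical replicate values has REV = 0.
#' @export
compute_rev <- function(es, alpha = 0.05) {
  stopifnot(inherits(es, "gfp_expression_set"))
  if (!isTRUE(es$normalized))
    .halt("compute_rev expects a collapsed, median-normalized set")
  n <- ncol(es$values)
  if (!is.null(es$spot_map) && !is.null(es$spot_values)) {
    rev <- vapply(es$spot_map, function(rows) {
      v <- es$spot_values[rows, , drop = FALSE]
      cvs <- apply(v, 1, stats::sd) / rowMeans(v)
      df <- length(rows) * (n - 1)
      100 * sqrt(mean(cvs^2)) * .rev_factor(df, alpha)
    }, numeric(1))
  } else {
    cv <- apply(es$values, 1, stats::sd) / rowMeans(es$values)
    rev <- 100 * cv * .rev_factor(n - 1, alpha)
    names(rev) <- rownames(es$values)
  }
  rev
}

#' All-pairs expression correlation (COR)
#'
#' Pearson product-moment correlation between the log2 expressions of every
#' gene pair across the biological replicates of one condition. The diagonal
#' is exactly 1. A gene with zero variance across replicates has no defined
#' correlation: its off-diagonal entries are `NA` and are excluded from any
#' downstream average.
#'
#' @param es A collapsed, normalized `gfp_expression_set`.
#' @return Symmetric genes x genes matrix with unit diagonal.
#' @export
compute_cor <- function(es) {
  stopifnot(inherits(es, "gfp_expression_set"))
  lv <- log2(es$values)
  degenerate <- apply(lv, 1, stats::sd) == 0
  cc <- suppressWarnings(stats::cor(t(lv)))
  if (any(degenerate)) {
    .note("%d gene(s) with zero variance: correlations undefined",
          sum(degenerate))
    cc[degenerate, ] <- NA_real_
    cc[, degenerate] <- NA_real_
  }
  diag(cc) <- 1
  cc
}

#' Relative expression control (REC)
#'
#' `REC_i = median(REV) / REV_i - 1`, the median taken over the whole
#' transcriptome of the condition. REC = 0 is the baseline: positive values
#' mark genes whose expression fluctuations are tightly limited by the
#' homeostatic machinery, negative values mark loosely controlled
#' (adaptable) genes.
#'
#' @param rev Named REV vector for one condition (percent, >= 0).
#' @param cap Finite score assigned to genes with REV = 0, which would
#'   otherwise have unbounded control (default 100). Keeps rankings finite.
#' @return Named numeric vector of REC scores (> -1).
#' @export
compute_rec <- function(rev, cap = 100) {
  stopifnot(length(rev) > 0, all(rev >= 0))
  med <- stats::median(rev)
  out <- ifelse(rev == 0, cap, med / rev - 1)
  names(out) <- names(rev)
  out
}

#' Pathway relative expression control (PREC)
#'
#' `PREC_Gamma = median(REV over all genes) / median(REV over Gamma) - 1`,
#' where each set Gamma is first intersected with the quantified genes.
#' PREC = 0 is the pathway baseline.
#'
#' @param rev Named REV vector over the quantified genes.
#' @param sets A `gfp_gene_sets` collection (or plain named list of ids).
#' @return Named numeric vector, one PREC per set; sets with no quantified
#'   member are skipped with a message.
#' @export
compute_prec <- function(rev, sets) {
  med <- stats::median(rev)
  out <- numeric(0)
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], names(rev))
    if (length(members) == 0) {
      .note("gene set '%s': no quantified member, skipped", nm)
      next
    }
    out[nm] <- med / stats::median(rev[members]) - 1
  }
  out
}

#' Build the fabric profile of one condition
#'
#' Bundles AVE, REV, COR and the transcriptome REV summaries for one
#' condition: the complete per-condition characterization from which every
#' comparison metric is derived.
#'
#' @param es A `gfp_expression_set` (collapsed/normalized or raw; raw sets
#'   are passed through [collapse_and_normalize()] first).
#' @param alpha Chi-square interval level for REV (default 0.05).
#' @return An object of class `gfp_fabric`: list with `condition`, `ave`,
#'   `rev`, `cor`, `n_replicates`, `rev_median`, `rev_mean`, and the
#'   normalized expression matrix `values` (needed by the regulation tests).
#' @export
fabric_profile <- function(es, alpha = 0.05) {
  stopifnot(inherits(es, "gfp_expression_set"))
  if (!isTRUE(es$normalized)) es <- collapse_and_normalize(es)
  rev <- compute_rev(es, alpha = alpha)
  structure(
    list(condition = es$condition,
         ave = compute_ave(es),
         rev = rev,
         cor = compute_cor(es),
         n_replicates = ncol(es$values),
         rev_median = stats::median(rev),
         rev_mean = mean(rev),
         values = es$values),
    class = "gfp_fabric")
}

#' @export
print.gfp_fabric <- function(x, ...) {
  cat(sprintf(
    "Fabric '%s': %d genes, %d replicates; median REV %.1f%%, mean REV %.1f%%\n",
    x$condition, length(x$ave), x$n_replicates, x$rev_median, x$rev_mean))
  invisible(x)
}

#' Write a fabric profile to TSV
#'
#' Writes `<stem>_fabric.tsv` (gene, AVE, REV, REC) and
#' `<stem>_cor.tsv` (the dense symmetric COR matrix keyed by gene order).
#'
#' @param fab A `gfp_fabric`.
#' @param stem Output path stem.
#' @param rec_cap Cap passed to [compute_rec()].
#' @return Named character vector of the two paths, invisibly.
#' @export
write_fabric <- function(fab, stem, rec_cap = 100) {
  stopifnot(inherits(fab, "gfp_fabric"))
  tab <- data.frame(gene = names(fab$ave), AVE = fab$ave, REV = fab$rev,
                    REC = compute_rec(fab$rev, cap = rec_cap))
  p1 <- paste0(stem, "_fabric.tsv")
  utils::write.table(tab, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- paste0(stem, "_cor.tsv")
  cm <- data.frame(gene = rownames(fab$cor), fab$cor, check.names = FALSE)
  utils::write.table(cm, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fabric = p1, cor = p2))
}
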