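#' Gene commanding height (GCH)
#'
#' Scores every gene's transcriptomic influence in one condition by
#' combining its expression control with its expression coordination with
#' all other genes:
#' `GCH_i = (REC_i + 1) * exp(4 * m_i - 1)`,
#' where `m_i` is the mean of the squared correlations of gene i with every
#' other gene (undefined correlations excluded). A gene at baseline control
#' (REC = 0) and average coordination `m = 0.25` scores exactly 1.
#'
#' @param rec Named REC vector (from [compute_rec()]).
#' @param cor Symmetric COR matrix over the same genes.
#' @return Named numeric vector of GCH scores (> 0 where defined; `NA` for a
#'   gene whose correlations are all undefined).
#' @export
compute_gch <- function(rec, cor) {
  stopifnot(identical(names(rec), rownames(cor)))
  n <- length(rec)
  gch <- vapply(seq_len(n), function(i) {
    cc <- cor[i, -i]
    if (all(is.na(cc))) return(NA_real_)
    m <- mean(cc^2, na.rm = TRUE)
    (rec[i] + 1) * exp(4 * m - 1)
  }, numeric(1))
  names(gch) <- names(rec)
  if (anyNA(gch))
    .note("%d gene(s) with undefined coordination excluded from the hierarchy",
          sum(is.na(gch)))
  gch
}

#' Rank genes by commanding height
#'
#' Descending GCH sort; ties broken lexicographically by gene id so the
#' ranking is deterministic. The top-ranked gene is the condition's gene
#' master regulator (GMR).
#'
#' @param gch Named GCH vector (from [compute_gch()]); `NA` entries are
#'   excluded from the ranking.
#' @param top_k How many top genes to expose in the `top` view (default 20);
#'   values beyond the universe return the full ranking.
#' @param condition Optional condition label carried through.
#' @return An object of class `gfp_hierarchy`: list with `condition`, `gch`,
#'   `ranking` (gene ids, best first), `top` (first `top_k`), and `gmr`.
#' @export
rank_genes <- function(gch, top_k = 20, condition = NULL) {
  defined <- !is.na(gch)
  if (!any(defined)) .halt("no gene has a defined GCH score")
  ids <- names(gch)[defined]
  ord <- order(-gch[defined], ids)
  ranking <- ids[ord]
  structure(
    list(condition = condition, gch = gch, ranking = ranking,
         top = utils::head(ranking, top_k), gmr = ranking[1]),
    class = "gfp_hierarchy")
}

#' @export
print.gfp_hierarchy <- function(x, ...) {
  cat(sprintf("Gene hierarchy%s: %d ranked genes, GMR = %s (GCH = %.2f)\n",
              if (!is.null(x$condition)) paste0(" '", x$condition, "'") else "",
              length(x$ranking), x$gmr, x$gch[[x$gmr]]))
  invisible(x)
}

#' Full hierarchy for one condition
#'
#' Convenience wrapper: REC from the fabric's REV, GCH from REC and COR,
#' then the deterministic ranking.
#'
#' @param fabric A `gfp_fabric`.
#' @param top_k Top view size (default 20).
#' @param rec_cap Cap passed to [compute_rec()].
#' @return A `gfp_hierarchy`.
#' @export
gene_hierarchy <- function(fabric, top_k = 20, rec_cap = 100) {
  stopifnot(inherits(fabric, "gfp_fabric"))
  rec <- compute_rec(fabric$rev, cap = rec_cap)
  rank_genes(compute_gch(rec, fabric$cor), top_k = top_k,
             condition = fabric$condition)
}
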