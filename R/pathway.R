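#' Weighted pathway regulation (WPR)
#'
#' Aggregates member WIR values of a gene set Gamma of (quantified) size
#' `{Gamma}` as `WPR = (100 / {Gamma}) * sqrt(sum(WIR_i^2))`. Because of the
#' `1/{Gamma}` prefactor, adding a member with zero alteration strictly
#' decreases the score.
#'
#' @param wir Numeric vector of member WIR values (the quantified members of
#'   the set).
#' @return WPR (>= 0).
#' @export
compute_wpr <- function(wir) {
  if (length(wir) == 0) .halt("empty member vector: no quantified gene in set")
  100 / length(wir) * sqrt(sum(wir^2))
}

#' Pathway transcriptomic distance (PTD)
#'
#' Same aggregation as [compute_wpr()] with member ITD values:
#' `PTD = (100 / {Gamma}) * sqrt(sum(ITD_i^2))`. Ratios of two scores over
#' the same set (the recovery metrics) are independent of the prefactor.
#'
#' @param itd Numeric vector of member ITD values (>= 0).
#' @return PTD (>= 0).
#' @export
compute_ptd <- function(itd) {
  if (length(itd) == 0) .halt("empty member vector: no quantified gene in set")
  100 / length(itd) * sqrt(sum(itd^2))
}

#' Pathway-level alteration scores for a comparison
#'
#' For every gene set, intersects its membership with the genes of a
#' regulation table and aggregates their WIR into WPR and ITD into PTD.
#'
#' @param reg A `gfp_regulation` table (from [regulation_table()]).
#' @param sets A `gfp_gene_sets` collection (or named list of ids).
#' @return An object of class `gfp_pathway_scores`: a data.frame with
#'   columns `set`, `n_members`, `n_quantified`, `wpr`, `ptd`; sets with no
#'   quantified member are skipped with a message. Attribute `comparison`
#'   carries the condition pair.
#' @export
pathway_scores <- function(reg, sets) {
  stopifnot(inherits(reg, "gfp_regulation"))
  rows <- list()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], reg$gene)
    if (length(members) == 0) {
      .note("gene set '%s': no quantified member, skipped", nm)
      next
    }
    sel <- reg$gene %in% members
    rows[[nm]] <- data.frame(
      set = nm, n_members = length(sets[[nm]]),
      n_quantified = length(members),
      wpr = compute_wpr(reg$wir[sel]),
      ptd = compute_ptd(reg$itd[sel]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(set = character(0), n_members = integer(0),
                      n_quantified = integer(0), wpr = numeric(0),
                      ptd = numeric(0))
  attr(out, "comparison") <- attr(reg, "comparison")
  class(out) <- c("gfp_pathway_scores", "data.frame")
  out
}
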