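# the 9 recovery categories: first letter = call vs disease, second = vs treated
.recovery_categories <- c("DX", "UX", "XD", "XU", "DD", "UU", "UD", "DU", "XX")

#' Categorize genes by regulation status before and after treatment
#'
#' Each gene gets a two-letter category: the first letter is its regulation
#' call in the disease-vs-reference comparison, the second its call in the
#' treated-vs-reference comparison, with D = down, U = up, X = neutral.
#' `DX`/`UX` are genes whose normal expression was fully recovered by the
#' treatment, `XD`/`XU` genes newly dysregulated by it, `DD`/`UU` genes
#' unchanged, and `UD`/`DU` genes whose regulation type was flipped.
#'
#' @param reg_disease `gfp_regulation` for disease vs reference.
#' @param reg_treated `gfp_regulation` for treated vs the same reference.
#' @param scope Optional character vector of gene ids (e.g. a pathway).
#' @return Named integer vector of counts over the 9 categories (summing to
#'   the common gene universe, or to the in-scope part of it).
#' @export
categorize_recovery <- function(reg_disease, reg_treated, scope = NULL) {
  genes <- intersect(reg_disease$gene, reg_treated$gene)
  if (length(genes) < length(reg_disease$gene) ||
      length(genes) < length(reg_treated$gene))
    .note("categorization restricted to %d genes present in both tables",
          length(genes))
  if (!is.null(scope)) genes <- intersect(genes, scope)
  letter <- c(UP = "U", DOWN = "D", NEUTRAL = "X")
  c1 <- letter[reg_disease$call[match(genes, reg_disease$gene)]]
  c2 <- letter[reg_treated$call[match(genes, reg_treated$gene)]]
  cat2 <- paste0(c1, c2)
  counts <- vapply(.recovery_categories, function(k) sum(cat2 == k),
                   integer(1))
  counts
}

#' Gene expression recovery (GER)
#'
#' Percent recovery computed from the category counts: recovered genes
#' (`DX`, `UX`) count +1, newly dysregulated genes (`XD`, `XU`) count -1,
#' genes whose regulation was flipped by the treatment (`UD`, `DU`) count
#' -2, over all genes regulated in at least one of the two comparisons:
#' `GER = 100 * (DX + UX - XD - XU - 2*(DU + UD)) /
#'        (DX + DD + DU + UX + UU + UD + XD + XU)`.
#'
#' @param counts Named counts over the 9 categories (as returned by
#'   [categorize_recovery()]; `XX` may be absent).
#' @return GER in percent (<= 100), or `NA` when nothing was or became
#'   regulated.
#' @export
compute_ger <- function(counts) {
  k <- function(nm) if (nm %in% names(counts)) counts[[nm]] else 0
  den <- k("DX") + k("DD") + k("DU") + k("UX") + k("UU") + k("UD") +
    k("XD") + k("XU")
  if (den == 0) return(NA_real_)
  num <- k("DX") + k("UX") - k("XD") - k("XU") - 2 * (k("DU") + k("UD"))
  100 * num / den
}

#' Pathway restoration efficiency (PRE)
#'
#' Percent reduction of the weighted pathway regulation achieved by the
#' treatment: `PRE = (1 - WPR(ref->treated) / WPR(ref->disease)) * 100`.
#' Negative values mean the treatment moved the pathway further from the
#' reference.
#'
#' @param wpr_disease WPR of the reference-to-disease comparison (> 0).
#' @param wpr_treated WPR of the reference-to-treated comparison (>= 0).
#' @return PRE in percent (<= 100), `NA` when `wpr_disease` is 0.
#' @export
compute_pre <- function(wpr_disease, wpr_treated) {
  if (wpr_disease == 0) return(NA_real_)
  (1 - wpr_treated / wpr_disease) * 100
}

#' Comprehensive pathway restoration (CPR)
#'
#' Percent reduction of the pathway transcriptomic distance in response to
#' the treatment: `CPR = (1 - PTD(ref->treated) / PTD(ref->disease)) * 100`,
#' with the outcome classified as:
#' \itemize{
#'   \item `ideal` — treated distance 0, CPR = 100%;
#'   \item `positive` — 0 < treated < disease distance, 0 < CPR < 100%;
#'   \item `null` — distances equal, CPR = 0%;
#'   \item `negative` — treated farther than disease, CPR < 0%.
#' }
#'
#' @param ptd_disease PTD of the reference-to-disease comparison (> 0).
#' @param ptd_treated PTD of the reference-to-treated comparison (>= 0).
#' @return List with `cpr` (percent) and `outcome`; both `NA` when
#'   `ptd_disease` is 0.
#' @export
compute_cpr <- function(ptd_disease, ptd_treated) {
  stopifnot(ptd_treated >= 0)
  if (ptd_disease == 0) return(list(cpr = NA_real_, outcome = NA_character_))
  cpr <- (1 - ptd_treated / ptd_disease) * 100
  outcome <- if (ptd_treated == 0) "ideal"
  else if (ptd_treated < ptd_disease) "positive"
  else if (ptd_treated == ptd_disease) "null"
  else "negative"
  list(cpr = cpr, outcome = outcome)
}

#' Full treatment-recovery report
#'
#' For a (reference, disease, treated) triple: category counts and GER over
#' the whole quantified universe, and per gene set the category counts, GER,
#' WPR pair with PRE, and PTD pair with CPR and its outcome class.
#'
#' @param reg_disease `gfp_regulation` for disease vs reference.
#' @param reg_treated `gfp_regulation` for treated vs reference.
#' @param sets Optional `gfp_gene_sets` collection for pathway-scoped
#'   metrics.
#' @return An object of class `gfp_recovery`: list with `counts` (global),
#'   `ger` (global), and `pathways` (data.frame: `set`, the 9 category
#'   columns, `ger`, `wpr_disease`, `wpr_treated`, `pre`, `ptd_disease`,
#'   `ptd_treated`, `cpr`, `outcome`), plus the `comparison` labels.
#' @export
recovery_report <- function(reg_disease, reg_treated, sets = NULL) {
  counts <- categorize_recovery(reg_disease, reg_treated)
  out <- list(
    comparison = list(disease = attr(reg_disease, "comparison"),
                      treated = attr(reg_treated, "comparison")),
    counts = counts,
    ger = compute_ger(counts),
    pathways = NULL)
  if (!is.null(sets)) {
    ps_d <- pathway_scores(reg_disease, sets)
    ps_t <- pathway_scores(reg_treated, sets)
    common <- intersect(ps_d$set, ps_t$set)
    rows <- lapply(common, function(nm) {
      kc <- categorize_recovery(reg_disease, reg_treated,
                                scope = sets[[nm]])
      wd <- ps_d$wpr[ps_d$set == nm]; wt <- ps_t$wpr[ps_t$set == nm]
      pd <- ps_d$ptd[ps_d$set == nm]; pt <- ps_t$ptd[ps_t$set == nm]
      cpr <- compute_cpr(pd, pt)
      data.frame(set = nm, as.list(kc), ger = compute_ger(kc),
                 wpr_disease = wd, wpr_treated = wt,
                 pre = compute_pre(wd, wt),
                 ptd_disease = pd, ptd_treated = pt,
                 cpr = cpr$cpr, outcome = cpr$outcome,
                 stringsAsFactors = FALSE)
    })
    out$pathways <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  structure(out, class = "gfp_recovery")
}

#' @export
print.gfp_recovery <- function(x, ...) {
  cat(sprintf("Recovery report (%s -> %s vs %s):\n",
              x$comparison$disease[1], x$comparison$disease[2],
              x$comparison$treated[2]))
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=",
                         collapse = " "), "\n")
  cat(sprintf("  GER = %.2f%%\n", x$ger))
  if (!is.null(x$pathways))
    for (i in seq_len(nrow(x$pathways)))
      cat(sprintf("  %s: GER = %.2f%%, PRE = %.2f%%, CPR = %.2f%% (%s)\n",
                  x$pathways$set[i], x$pathways$ger[i], x$pathways$pre[i],
                  x$pathways$cpr[i], x$pathways$outcome[i]))
  invisible(x)
}
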