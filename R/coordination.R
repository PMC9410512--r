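#' Critical Pearson correlation at a significance level
#'
#' The two-tailed critical value of the Pearson coefficient for `n`
#' replicates, from the exact t-distribution of `r * sqrt((n-2)/(1-r^2))`
#' with `n - 2` degrees of freedom: `r_crit = t / sqrt(n - 2 + t^2)` with
#' `t = t(1 - p/2; n - 2)`. At the study design of n = 4 and p < 0.05 this
#' is approximately 0.950, which is why small-replicate coordination calls
#' are so conservative.
#'
#' @param n Number of biological replicates (>= 3).
#' @param p_threshold Two-tailed significance level (default 0.05).
#' @return Critical |r| in \[0, 1).
#' @export
critical_r <- function(n, p_threshold = 0.05) {
  if (n < 3) .halt("correlation inference needs n >= 3 replicates; got %d", n)
  tq <- stats::qt(1 - p_threshold / 2, df = n - 2)
  tq / sqrt(n - 2 + tq^2)
}

#' Classify gene pairs by expression coordination
#'
#' Labels every in-scope pair by its correlation:
#' `SYNERGISTIC` when `COR >= r_critical`, `ANTAGONISTIC` when
#' `COR <= -r_critical`, `INDEPENDENT` when `|COR| <=
#' independence_threshold` (a positive near-zero band, since independent
#' expression is treated as a category of its own, not mere
#' non-significance), `UNCLASSIFIED` otherwise (including undefined
#' correlations). No correction is applied for the number of pairs tested;
#' [expected_false_coordination()] reports the consequence.
#'
#' @param fabric A `gfp_fabric`.
#' @param scope Optional character vector of gene ids restricting the
#'   classification (default: all genes).
#' @param p_threshold Significance level for [critical_r()] (default 0.05).
#' @param independence_threshold Half-width of the independence band
#'   (default 0.05).
#' @return An object of class `gfp_coordination`: list with `condition`,
#'   `genes`, `labels` (symmetric character matrix, `NA` diagonal), `cor`
#'   (the matching correlation submatrix), `r_critical`,
#'   `independence_threshold`, `n_replicates`.
#' @export
classify_pairs <- function(fabric, scope = NULL, p_threshold = 0.05,
                           independence_threshold = 0.05) {
  stopifnot(inherits(fabric, "gfp_fabric"))
  genes <- names(fabric$ave)
  if (!is.null(scope)) {
    missing <- setdiff(scope, genes)
    if (length(missing) > 0)
      .note("%d scope gene(s) not quantified, ignored", length(missing))
    genes <- genes[genes %in% scope]
  }
  rc <- critical_r(fabric$n_replicates, p_threshold)
  cc <- fabric$cor[genes, genes, drop = FALSE]
  labels <- matrix("UNCLASSIFIED", nrow(cc), ncol(cc),
                   dimnames = dimnames(cc))
  labels[!is.na(cc) & cc >= rc] <- "SYNERGISTIC"
  labels[!is.na(cc) & cc <= -rc] <- "ANTAGONISTIC"
  labels[!is.na(cc) & abs(cc) <= independence_threshold] <- "INDEPENDENT"
  diag(labels) <- NA_character_
  structure(
    list(condition = fabric$condition, genes = genes, labels = labels,
         cor = cc, r_critical = rc,
         independence_threshold = independence_threshold,
         n_replicates = fabric$n_replicates),
    class = "gfp_coordination")
}

#' Expected false significant pairs under the null
#'
#' With no correction over `n(n-1)/2` pairwise tests at level p, this many
#' pairs are expected to be called synergistic or antagonistic by chance
#' alone.
#'
#' @param n_genes Number of genes in scope.
#' @param p_threshold Significance level (default 0.05).
#' @return Expected count (numeric).
#' @export
expected_false_coordination <- function(n_genes, p_threshold = 0.05) {
  n_genes * (n_genes - 1) / 2 * p_threshold
}

#' Partner percentages of a hub gene
#'
#' For a hub gene and a scope (a pathway), the percentages of scope members
#' (hub excluded) that are synergistically, antagonistically, or
#' independently expressed with the hub. Percentages are reported half-up to
#' one decimal and need not sum to 100 (unclassified partners exist).
#'
#' @param profile A `gfp_coordination`.
#' @param hub Hub gene id (must be classified in the profile).
#' @param scope Optional character vector of gene ids (default: all profile
#'   genes). Must contain at least one partner besides the hub.
#' @return An object of class `gfp_partner_summary`: list with `hub`,
#'   `condition`, `n_partners`, `pct_synergistic`, `pct_antagonistic`,
#'   `pct_independent`.
#' @export
partner_summary <- function(profile, hub, scope = NULL) {
  stopifnot(inherits(profile, "gfp_coordination"))
  if (!hub %in% profile$genes)
    .halt("hub gene '%s' is not quantified in this profile", hub)
  partners <- if (is.null(scope)) profile$genes else
    intersect(scope, profile$genes)
  partners <- setdiff(partners, hub)
  if (length(partners) == 0)
    .halt("scope contains no partner besides the hub '%s'", hub)
  lab <- profile$labels[hub, partners]
  pct <- function(what) round_half_up(100 * sum(lab == what) / length(lab), 1)
  structure(
    list(hub = hub, condition = profile$condition,
         n_partners = length(partners),
         pct_synergistic = pct("SYNERGISTIC"),
         pct_antagonistic = pct("ANTAGONISTIC"),
         pct_independent = pct("INDEPENDENT")),
    class = "gfp_partner_summary")
}

#' @export
print.gfp_partner_summary <- function(x, ...) {
  cat(sprintf(
    "'%s' partners%s (n = %d): %.1f%% synergistic, %.1f%% antagonistic, %.1f%% independent\n",
    x$hub, if (!is.null(x$condition)) paste0(" in ", x$condition) else "",
    x$n_partners, x$pct_synergistic, x$pct_antagonistic, x$pct_independent))
  invisible(x)
}

#' Network remodeling of a hub across conditions
#'
#' Tracks, per partner gene, the coordination label with the hub across a
#' sequence of conditions (e.g. reference, disease, treated) and flags the
#' transitions: label switches (e.g. synergistic to antagonistic, the
#' signature of network rewiring) and decouplings to independence.
#'
#' @param profiles List of `gfp_coordination` objects over a common gene
#'   universe (>= 2).
#' @param hub Hub gene id.
#' @param scope Optional character vector of partner gene ids.
#' @return data.frame with one row per partner: `partner`, one label column
#'   per condition, `changed` (logical), and `transition` (collapsed label
#'   path, e.g. `"SYNERGISTIC->ANTAGONISTIC->INDEPENDENT"`).
#' @export
remodeling_diff <- function(profiles, hub, scope = NULL) {
  stopifnot(length(profiles) >= 2)
  common <- Reduce(intersect, lapply(profiles, `[[`, "genes"))
  partners <- if (is.null(scope)) common else intersect(scope, common)
  partners <- setdiff(partners, hub)
  if (!hub %in% common)
    .halt("hub gene '%s' is not quantified in every profile", hub)
  labs <- vapply(profiles, function(p) p$labels[hub, partners],
                 character(length(partners)))
  if (length(partners) == 1) labs <- matrix(labs, nrow = 1)
  conds <- vapply(seq_along(profiles), function(k) {
    cd <- profiles[[k]]$condition
    if (is.null(cd)) paste0("condition_", k) else cd
  }, character(1))
  colnames(labs) <- conds
  out <- data.frame(partner = partners, labs, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$changed <- apply(labs, 1, function(z) length(unique(z)) > 1)
  out$transition <- apply(labs, 1, paste, collapse = "->")
  out
}
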