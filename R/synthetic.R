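#' Specification of a synthetic multi-condition study
#'
#' Describes a study to simulate: per condition, per-gene linear-scale mean
#' expression, per-gene coefficient of variation, and a block correlation
#' structure on the log2 scale; optionally several probing spots per gene
#' with multiplicative technical noise. The generative model is log-normal
#' (log2 expression multivariate normal), because microarray intensities are
#' positive and right-skewed and the fabric's correlations are defined on
#' log2 values.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Biological replicates per condition (default 4, the
#'   usual group size of the targeted study designs).
#' @param conditions Named list; each element is a list with `mean` (length
#'   `n_genes` or scalar, linear scale, > 0), `cv` (length `n_genes` or
#'   scalar, >= 0), and optional `blocks`, a list of `list(members =
#'   integer indices, rho = within-block correlation in [-1, 1])`.
#' @param spots_per_gene Probing spots per gene (default 1).
#' @param spot_cv Technical coefficient of variation of spot noise
#'   (default 0).
#' @param seed Integer RNG seed; identical seeds give byte-identical
#'   studies.
#' @return An object of class `gfp_sim_spec`.
#' @export
simulation_spec <- function(n_genes, n_replicates = 4, conditions,
                            spots_per_gene = 1, spot_cv = 0, seed = 1) {
  stopifnot(n_genes >= 1, n_replicates >= 2, length(conditions) >= 1,
            !is.null(names(conditions)), spots_per_gene >= 1, spot_cv >= 0)
  conditions <- lapply(conditions, function(cond) {
    cond$mean <- rep_len(cond$mean, n_genes)
    cond$cv <- rep_len(cond$cv, n_genes)
    stopifnot(all(cond$mean > 0), all(cond$cv >= 0))
    for (b in cond$blocks) {
      m <- length(b$members)
      stopifnot(m >= 2, all(b$members >= 1), all(b$members <= n_genes),
                b$rho >= -1, b$rho <= 1)
      if (b$rho < -1 / (m - 1))
        .halt("block of %d genes with rho = %g is not a valid correlation",
              m, b$rho)
    }
    cond
  })
  structure(list(n_genes = n_genes, n_replicates = n_replicates,
                 conditions = conditions, spots_per_gene = spots_per_gene,
                 spot_cv = spot_cv, seed = as.integer(seed)),
            class = "gfp_sim_spec")
}

# internal: assemble the log-scale correlation matrix from blocks.
# Overlapping blocks can make the assembly indefinite; it is then projected
# to the nearest positive semi-definite matrix (eigenvalue clipping) with a
# message reporting the adjustment magnitude.
.assemble_cor <- function(n_genes, blocks) {
  R <- diag(n_genes)
  for (b in blocks) {
    idx <- b$members
    R[idx, idx] <- b$rho
    diag(R)[idx] <- 1
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    R2 <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    d <- sqrt(diag(R2))
    R2 <- R2 / tcrossprod(d)
    .note("block overlap made the correlation indefinite; projected to PSD (adjustment %.3g)",
          sqrt(sum((R2 - R)^2)))
    R <- R2
    ev <- eigen(R, symmetric = TRUE)
  }
  # factor for sampling; tolerates singular (rho = 1) blocks
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

#' Simulate a multi-condition expression study
#'
#' Draws, per condition, log2 expression from a multivariate normal with the
#' block correlation structure of the spec, exponentiates to the linear
#' scale with the requested per-gene mean and CV, and (optionally) expands
#' each gene into several probing spots with independent multiplicative
#' technical noise. Deterministic given the spec's seed.
#'
#' @param spec A `gfp_sim_spec`.
#' @return Named list of `gfp_expression_set`, one per condition, plus a
#'   `"ground_truth"` attribute (data.frame of per-gene true mean and CV per
#'   condition).
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "gfp_sim_spec"))
  set.seed(spec$seed)
  genes <- sprintf("g%03d", seq_len(spec$n_genes))
  n <- spec$n_replicates
  out <- list()
  truth <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (cname in names(spec$conditions)) {
    cond <- spec$conditions[[cname]]
    sigma_ln <- sqrt(log(1 + cond$cv^2))       # natural-log sd from linear CV
    mu_ln <- log(cond$mean) - sigma_ln^2 / 2   # preserves the linear mean
    fac <- .assemble_cor(spec$n_genes, cond$blocks)
    z <- fac %*% matrix(stats::rnorm(spec$n_genes * n), spec$n_genes, n)
    lnx <- mu_ln + sigma_ln * z
    vals <- exp(lnx)
    rownames(vals) <- genes
    colnames(vals) <- paste0(cname, "_r", seq_len(n))
    spot_map <- NULL
    if (spec$spots_per_gene > 1 || spec$spot_cv > 0) {
      s_ln <- sqrt(log(1 + spec$spot_cv^2))
      k <- spec$spots_per_gene
      spot_vals <- vals[rep(seq_len(spec$n_genes), each = k), , drop = FALSE]
      noise <- exp(matrix(stats::rnorm(length(spot_vals), -s_ln^2 / 2, s_ln),
                          nrow(spot_vals), ncol(spot_vals)))
      spot_vals <- spot_vals * noise
      rownames(spot_vals) <- paste0(rep(genes, each = k), "_s",
                                    rep(seq_len(k), spec$n_genes))
      spot_map <- lapply(seq_len(spec$n_genes), function(i)
        ((i - 1) * k + 1):(i * k))
      names(spot_map) <- genes
      vals <- spot_vals
    }
    out[[cname]] <- expression_set(vals, cname, spot_map = spot_map)
    truth[[paste0("mean_", cname)]] <- cond$mean
    truth[[paste0("cv_", cname)]] <- cond$cv
  }
  attr(out, "ground_truth") <- truth
  out
}

#' Three-condition reference/disease/treated fixture with known truth
#'
#' A 200-gene, 4-replicate NN/IN/IT study in which a designated 40-gene
#' pathway (`pathway40`, genes g001..g040) is regulated in IN and partially
#' restored in IT with designed category counts
#' DX = 7, UX = 5, XD = 2, XU = 0, DD = 1, UU = 0, UD = 0, DU = 0
#' (the rest of the pathway and transcriptome neutral). Designed fold
#' changes are 4x so that at the default low noise the regulation calls are
#' essentially certain; at `cv = 0` the counts are exact by construction.
#' Gene g100 is built as a "quiet mover": its expression ratio stays below
#' its cut-off in IN but its variability explodes (CV 0.05 to 0.5), so its
#' transcriptomic distance exceeds that of the genuinely up-regulated
#' genes — the phenomenon that fold-change-only analyses miss. Each
#' condition carries its own synergistic correlation block, so gene
#' hierarchies are condition-specific.
#'
#' @param seed RNG seed (default 1).
#' @param cv Baseline per-gene coefficient of variation (default 0.05; use 0
#'   for an exactly deterministic fixture).
#' @param treated_profile `"partial"` (default: the designed counts above),
#'   `"full"` (IT designed identical to NN: complete restoration), or
#'   `"worse"` (IT farther from NN than IN is).
#' @return List with `study` (named list of `gfp_expression_set`), `sets`
#'   (a `gfp_gene_sets` with the 40-gene pathway), `design` (a
#'   `gfp_design`), and `truth` (data.frame: gene, fold_in, fold_it,
#'   designed_category for pathway members).
#' @export
make_three_condition_fixture <- function(seed = 1, cv = 0.05,
                                         treated_profile = c("partial",
                                                             "full",
                                                             "worse")) {
  treated_profile <- match.arg(treated_profile)
  n <- 200
  # Means are placed so that no designed fold change ever crosses the
  # condition median (which sits inside a run of unchanged genes at 1.0):
  # the median-normalization scale is then identical across conditions and
  # the designed ratios are recovered exactly at cv = 0.
  base_mean <- c(rep(0.5, 7), rep(2, 5), rep(0.5, 3),     # regulated pathway
                 rep(1, 25),                              # quiet pathway rest
                 2^seq(-2, 2, length.out = n - 40))       # background spread
  fold_in <- rep(1, n); fold_it <- rep(1, n)
  # designed pathway regulation (genes 1..40): down stays below the median,
  # up stays above it
  dx <- 1:7; ux <- 8:12; xd <- 13:14; dd <- 15
  fold_in[dx] <- 0.25; fold_in[ux] <- 4; fold_in[dd] <- 0.25
  fold_it[xd] <- 0.25; fold_it[dd] <- 0.25
  if (treated_profile == "full") {
    fold_it <- rep(1, n)
  } else if (treated_profile == "worse") {
    fold_it <- ifelse(fold_in > 1, fold_in * 2,
                      ifelse(fold_in < 1, fold_in / 2, 1))
    fold_it[16:20] <- 8  # additional newly dysregulated genes
  }
  cv_nn <- rep(cv, n); cv_in <- rep(cv, n); cv_it <- rep(cv, n)
  if (cv > 0) {   # the quiet mover needs variability to move
    cv_in[100] <- 0.5
    cv_it[100] <- 0.3
  }
  blocks <- function(members, rho) list(list(members = members, rho = rho))
  conditions <- list(
    NN = list(mean = base_mean, cv = cv_nn,
              blocks = if (cv > 0) blocks(41:60, 0.9)),
    IN = list(mean = base_mean * fold_in, cv = cv_in,
              blocks = if (cv > 0) blocks(61:80, 0.9)),
    IT = list(mean = base_mean * fold_it, cv = cv_it,
              blocks = if (cv > 0) blocks(81:100, 0.9)))
  spec <- simulation_spec(n_genes = n, n_replicates = 4,
                          conditions = conditions, seed = seed)
  study <- simulate_study(spec)
  genes <- sprintf("g%03d", 1:n)
  sets <- structure(list(pathway40 = genes[1:40]),
                    descriptions = c(pathway40 = "designed 40-gene pathway"),
                    class = "gfp_gene_sets")
  letter <- function(f) ifelse(f > 1, "U", ifelse(f < 1, "D", "X"))
  truth <- data.frame(
    gene = genes, fold_in = fold_in, fold_it = fold_it,
    designed_category = paste0(letter(fold_in), letter(fold_it)),
    stringsAsFactors = FALSE)
  list(study = study, sets = sets,
       design = study_design("NN", "IN", "IT"), truth = truth)
}

#' Write a simulated study to disk
#'
#' One expression TSV per condition, a GMT for the gene sets (when given),
#' and a ground-truth sidecar TSV for test assertions.
#'
#' @param study Named list of `gfp_expression_set` (e.g. from
#'   [simulate_study()]).
#' @param dir Output directory (created if needed).
#' @param sets Optional `gfp_gene_sets`.
#' @param truth Optional data.frame sidecar.
#' @return Named character vector of written paths, invisibly.
#' @export
write_study <- function(study, dir, sets = NULL, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cname in names(study)) {
    p <- file.path(dir, paste0(cname, ".tsv"))
    write_expression_set(study[[cname]], p)
    paths[cname] <- p
  }
  if (!is.null(sets)) {
    p <- file.path(dir, "gene_sets.gmt")
    desc <- attr(sets, "descriptions")
    lines <- vapply(names(sets), function(nm)
      paste(c(nm, if (!is.null(desc)) desc[[nm]] else ".", sets[[nm]]),
            collapse = "\t"), character(1))
    writeLines(lines, p)
    paths["gene_sets"] <- p
  }
  if (!is.null(truth)) {
    p <- file.path(dir, "ground_truth.tsv")
    utils::write.table(truth, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["ground_truth"] <- p
  }
  invisible(paths)
}
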