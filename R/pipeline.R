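#' Run the full fabric pipeline from a config
#'
#' Orchestrates an end-to-end run: load (or simulate) the per-condition
#' expression tables, compute each condition's fabric profile, compare
#' disease and treated conditions against the reference (regulation
#' tables), rank gene hierarchies, classify coordination networks, score
#' pathways, and — when a treated condition is present — produce the
#' recovery report. Every threshold used is recorded in a JSON run
#' manifest so any number in any output can be audited.
#'
#' @param config Either a named list or a path to a JSON/YAML file with
#'   entries:
#' \describe{
#'   \item{expression}{named list/mapping condition label -> expression TSV
#'     path (omit when `simulate` is given).}
#'   \item{simulate}{optional list with `seed` (and optionally `cv`,
#'     `treated_profile`) to run on the built-in three-condition fixture.}
#'   \item{gene_sets}{optional GMT path.}
#'   \item{design}{list with `reference`, `disease`, optional `treated`.}
#'   \item{thresholds}{optional list: `p_threshold` (0.05),
#'     `independence_threshold` (0.05), `rev_alpha` (0.05), `rec_cap`
#'     (100), `top_k` (20).}
#'   \item{out_dir}{output directory.}
#' }
#' @return Invisibly, a named list of written file paths. Writes, under
#'   `out_dir`: `<cond>_fabric.tsv`/`<cond>_cor.tsv`, `<cond>_hierarchy.tsv`,
#'   `<cond>_coordination.tsv` (sparse classified edge list),
#'   `regulation_<ref>_vs_<cond>.tsv`, `pathway_scores_<cond>.tsv`,
#'   `recovery.tsv`, and `manifest.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- .load_config(config)
  th <- .merge_thresholds(cfg$thresholds)
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) .halt("config must name an 'out_dir'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  # --- load or simulate -----------------------------------------------------
  if (!is.null(cfg$simulate)) {
    fx <- make_three_condition_fixture(
      seed = cfg$simulate$seed %||% 1,
      cv = cfg$simulate$cv %||% 0.05,
      treated_profile = cfg$simulate$treated_profile %||% "partial")
    study <- fx$study
    sets <- fx$sets
    design <- fx$design
  } else {
    if (is.null(cfg$expression) || is.null(cfg$design))
      .halt("config must provide 'expression' tables and a 'design'")
    study <- lapply(names(cfg$expression), function(cname)
      read_expression_set(cfg$expression[[cname]], cname))
    names(study) <- names(cfg$expression)
    design <- study_design(cfg$design$reference, cfg$design$disease,
                           cfg$design$treated)
    sets <- if (!is.null(cfg$gene_sets)) read_gene_sets(cfg$gene_sets)
  }
  for (lab in c(design$reference, design$disease, design$treated))
    if (!lab %in% names(study))
      .halt("design condition '%s' has no expression table", lab)

  # --- per-condition fabric, hierarchy, coordination ------------------------
  fabrics <- lapply(study, fabric_profile, alpha = th$rev_alpha)
  for (cname in names(fabrics)) {
    paths <- c(paths, write_fabric(fabrics[[cname]],
                                   file.path(out_dir, cname),
                                   rec_cap = th$rec_cap))
    hier <- gene_hierarchy(fabrics[[cname]], top_k = th$top_k,
                           rec_cap = th$rec_cap)
    hp <- file.path(out_dir, paste0(cname, "_hierarchy.tsv"))
    defined <- hier$ranking
    utils::write.table(
      data.frame(gene = defined, gch = hier$gch[defined],
                 rank = seq_along(defined)),
      hp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[paste0(cname, "_hierarchy")] <- hp

    scope <- if (!is.null(sets)) unique(unlist(sets))
    coord <- classify_pairs(fabrics[[cname]], scope = scope,
                            p_threshold = th$p_threshold,
                            independence_threshold = th$independence_threshold)
    cp <- file.path(out_dir, paste0(cname, "_coordination.tsv"))
    .write_edge_list(coord, cp)
    paths[paste0(cname, "_coordination")] <- cp
  }

  # --- comparisons against the reference ------------------------------------
  ref <- design$reference
  regs <- list()
  for (cname in c(design$disease, design$treated)) {
    reg <- regulation_table(fabrics[[ref]], fabrics[[cname]],
                            p_threshold = th$p_threshold)
    regs[[cname]] <- reg
    rp <- file.path(out_dir, sprintf("regulation_%s_vs_%s.tsv", ref, cname))
    utils::write.table(
      data.frame(gene = reg$gene, x = reg$x, p = reg$p, CUT = reg$cut,
                 call = reg$call, WIR = reg$wir, ITD = reg$itd),
      rp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[sprintf("regulation_%s", cname)] <- rp
    if (!is.null(sets)) {
      ps <- pathway_scores(reg, sets)
      pp <- file.path(out_dir, sprintf("pathway_scores_%s.tsv", cname))
      utils::write.table(as.data.frame(ps), pp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[sprintf("pathway_scores_%s", cname)] <- pp
    }
  }

  # --- recovery --------------------------------------------------------------
  if (!is.null(design$treated)) {
    rec <- recovery_report(regs[[design$disease]], regs[[design$treated]],
                           sets = sets)
    rp <- file.path(out_dir, "recovery.tsv")
    .write_recovery(rec, rp)
    paths["recovery"] <- rp
  } else {
    .note("no treated condition in the design: recovery stage skipped")
  }

  # --- manifest --------------------------------------------------------------
  manifest <- list(
    package = "gfabric",
    version = as.character(utils::packageVersion("gfabric")),
    design = list(reference = design$reference, disease = design$disease,
                  treated = design$treated),
    thresholds = th,
    conditions = names(study),
    n_genes = as.list(vapply(fabrics, function(f) length(f$ave), integer(1))),
    n_replicates = as.list(vapply(fabrics, `[[`, integer(1),
                                  "n_replicates")),
    simulate = cfg$simulate)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  paths["manifest"] <- mp
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: read config from list or JSON/YAML file
.load_config <- function(config) {
  if (is.list(config)) return(config)
  if (!file.exists(config)) .halt("config file '%s' not found", config)
  if (grepl("\\.ya?ml$", config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      .halt("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(config)
  } else {
    jsonlite::read_json(config, simplifyVector = TRUE)
  }
}

.merge_thresholds <- function(th) {
  defaults <- list(p_threshold = 0.05, independence_threshold = 0.05,
                   rev_alpha = 0.05, rec_cap = 100, top_k = 20)
  for (nm in names(th)) defaults[[nm]] <- th[[nm]]
  stopifnot(defaults$p_threshold > 0, defaults$p_threshold <= 1,
            defaults$independence_threshold >= 0,
            defaults$independence_threshold < 1,
            defaults$rev_alpha > 0, defaults$rev_alpha < 1)
  defaults
}

# internal: sparse edge list of classified pairs
.write_edge_list <- function(coord, path) {
  lab <- coord$labels
  keep <- which(upper.tri(lab) & !is.na(lab) & lab != "UNCLASSIFIED",
                arr.ind = TRUE)
  df <- data.frame(
    gene_i = rownames(lab)[keep[, 1]],
    gene_j = colnames(lab)[keep[, 2]],
    cor = coord$cor[keep],
    label = lab[keep],
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_recovery <- function(rec, path) {
  global <- data.frame(scope = "all", t(rec$counts),
                       ger = rec$ger, stringsAsFactors = FALSE)
  out <- global
  if (!is.null(rec$pathways)) {
    pw <- rec$pathways
    names(pw)[names(pw) == "set"] <- "scope"
    for (nm in setdiff(names(pw), names(global))) global[[nm]] <- NA
    out <- rbind(global, pw[names(global)])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
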