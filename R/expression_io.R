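#' Construct an expression set for one condition
#'
#' An expression set is a genes (or probing spots) x replicates matrix of
#' strictly positive, linear-scale expression values for one experimental
#' condition, together with a condition label and, optionally, a spot map
#' assigning multiple probing-spot rows to a single gene.
#'
#' @param values Numeric matrix (rows = genes or spots, columns = biological
#'   replicates), all values finite and > 0, with row names (identifiers) and
#'   column names (replicate labels). At least 2 replicates.
#' @param condition Condition label (e.g. `"NN"`).
#' @param spot_map Optional named list mapping `gene_id` to an integer vector
#'   of row indices of `values` (the spots probing that gene). When supplied,
#'   rows remain spot-level until [collapse_and_normalize()].
#' @return An object of class `gfp_expression_set`: a list with elements
#'   `values`, `condition`, `spot_map`, `gene_ids`, `replicate_labels`, and
#'   a `normalized` flag.
#' @seealso [read_expression_set()], [collapse_and_normalize()]
#' @export
expression_set <- function(values, condition, spot_map = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    .halt("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .halt("'values' must carry row (identifier) and column (replicate) names")
  if (ncol(values) < 2)
    .halt("at least 2 replicates are required; got %d", ncol(values))
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    .halt("non-positive or non-finite value at row '%s', column '%s'",
          rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]])
  if (is.null(spot_map)) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    if (length(dup) > 0)
      .halt("duplicate identifiers without a spot map: %s",
            paste(dup, collapse = ", "))
    gene_ids <- rownames(values)
  } else {
    if (is.null(names(spot_map)) || any(names(spot_map) == ""))
      .halt("spot_map must be a named list (gene_id -> row indices)")
    idx <- unlist(spot_map, use.names = FALSE)
    if (any(idx < 1 | idx > nrow(values)))
      .halt("spot_map references row indices outside the matrix")
    if (anyDuplicated(names(spot_map)))
      .halt("spot_map has duplicated gene ids")
    gene_ids <- names(spot_map)
  }
  structure(
    list(values = values, condition = as.character(condition),
         spot_map = spot_map, gene_ids = gene_ids,
         replicate_labels = colnames(values), normalized = FALSE),
    class = "gfp_expression_set")
}

#' @export
print.gfp_expression_set <- function(x, ...) {
  cat(sprintf("Expression set '%s': %d gene(s), %d replicate(s)%s%s\n",
              x$condition, length(x$gene_ids), ncol(x$values),
              if (!is.null(x$spot_map))
                sprintf(", %d spot rows", nrow(x$values)) else "",
              if (x$normalized) ", median-normalized" else ""))
  invisible(x)
}

# internal: sniff TAB vs comma from the header line
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read an expression table
#'
#' Reads a delimited text file (TAB or comma, auto-detected) with a header
#' row of replicate labels and a first column of gene or spot identifiers,
#' and validates it into an [expression_set()]. Identifiers are
#' case-sensitive. Values must be strictly positive: background subtraction
#' and floor-clipping are assumed to have happened upstream.
#'
#' @param path Path to the expression table.
#' @param condition Condition label to attach.
#' @param spot_map_path Optional path to a two-column TSV (spot_id, gene_id)
#'   mapping spot rows to genes; when given, rows stay spot-level.
#' @return A `gfp_expression_set`.
#' @export
read_expression_set <- function(path, condition, spot_map_path = NULL) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3)
    .halt("'%s': need an identifier column plus >= 2 replicate columns", path)
  ids <- df[[1]]
  num <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) num <- matrix(num, nrow = 1)
  bad <- which(is.na(num) | !is.finite(num) | num <= 0, arr.ind = TRUE)
  if (length(bad) > 0) {
    bad <- matrix(bad, ncol = 2)
    .halt("'%s': non-positive or non-numeric cell at row '%s', column '%s'",
          path, ids[bad[1, 1]], colnames(df)[-1][bad[1, 2]])
  }
  rownames(num) <- ids
  colnames(num) <- colnames(df)[-1]
  spot_map <- NULL
  if (!is.null(spot_map_path)) {
    sm <- utils::read.table(spot_map_path, header = FALSE, sep = "\t",
                            col.names = c("spot_id", "gene_id"),
                            colClasses = "character")
    unknown <- setdiff(sm$spot_id, ids)
    if (length(unknown) > 0)
      .halt("spot map names spots absent from the table: %s",
            paste(utils::head(unknown, 5), collapse = ", "))
    spot_map <- lapply(split(sm$spot_id, sm$gene_id), function(s)
      which(ids %in% s))
    # keep file order of first appearance of each gene
    spot_map <- spot_map[unique(sm$gene_id)]
  }
  expression_set(num, condition, spot_map = spot_map)
}

#' Write an expression set to TSV
#'
#' Inverse of [read_expression_set()]: full stored precision, TAB-separated,
#' identifier column first.
#'
#' @param es A `gfp_expression_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_set <- function(es, path) {
  stopifnot(inherits(es, "gfp_expression_set"))
  df <- data.frame(id = rownames(es$values),
                   format(es$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(es$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection (GMT)
#'
#' GMT dialect: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a set are dropped with a message. An empty file
#' yields an empty (valid) collection.
#'
#' @param path Path to the GMT file.
#' @return An object of class `gfp_gene_sets`: a named list of character
#'   vectors (members), with a `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      .halt("'%s' line %d: expected name, description and >= 1 member", path, k)
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      .note("gene set '%s': %d duplicated member(s) dropped",
            f[1], sum(duplicated(members)))
      members <- unique(members)
    }
    sets[[f[1]]] <- members
    desc[f[1]] <- f[2]
  }
  structure(sets, descriptions = desc, class = "gfp_gene_sets")
}

#' Three-condition study design
#'
#' Fixes which condition labels play the roles of reference (e.g. `"NN"`),
#' disease (`"IN"`) and, optionally, treated (`"IT"`).
#'
#' @param reference,disease Condition labels (required, distinct).
#' @param treated Optional condition label (distinct from the other two).
#' @return An object of class `gfp_design`.
#' @export
study_design <- function(reference, disease, treated = NULL) {
  labels <- c(reference, disease, treated)
  if (anyDuplicated(labels))
    .halt("design labels must be distinct: %s", paste(labels, collapse = ", "))
  structure(list(reference = reference, disease = disease, treated = treated),
            class = "gfp_design")
}
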