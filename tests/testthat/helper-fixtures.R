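# Small in-code fixtures shared across test files.

# gene-level matrix with named dims
toy_matrix <- function(values, genes, reps = paste0("r", seq_len(ncol_)),
                       ncol_ = length(values) / length(genes)) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE)
  rownames(m) <- genes
  colnames(m) <- reps
  m
}

# a normalized 3-gene x 4-replicate expression set built from linear values
toy_es <- function(values, genes, condition = "A") {
  collapse_and_normalize(expression_set(toy_matrix(values, genes), condition))
}

# minimal hand-built fabric object (for unit formulas that only need pieces)
fake_fabric <- function(ave, rev, cor, condition = "A", values = NULL,
                        n_replicates = 4) {
  structure(list(condition = condition, ave = ave, rev = rev, cor = cor,
                 n_replicates = n_replicates,
                 rev_median = stats::median(rev), rev_mean = mean(rev),
                 values = values),
            class = "gfp_fabric")
}

# write a TSV expression table and return its path
write_toy_table <- function(df, sep = "\t", ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# chi-square mid-interval factor, recomputed from the frozen oracle
# quantiles for nu = 3 at 95% (independent of the package's qchisq path)
REV_FACTOR_NU3 <- 0.5 * (sqrt(3 / 9.348404) + sqrt(3 / 0.2157953))
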