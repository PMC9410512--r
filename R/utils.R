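#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used in
#' all printed report values), unlike [base::round()] which rounds half to
#' even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(2.5)        # 3
#' round_half_up(11.745, 2)  # 11.75
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Size of the fabric characterization for n genes
#'
#' Per condition, the fabric holds one AVE and one REV per gene plus one COR
#' per unordered gene pair: `2n + n(n-1)/2` values, against the `n` values of
#' an expression-level-only analysis.
#'
#' @param n_genes Number of quantified genes (positive integer).
#' @return A list with `n_genes`, `n_cor_pairs` (`n(n-1)/2`), `total`
#'   (`2n + n(n-1)/2`), and `fold_increase` (`total / n`, rounded half-up to
#'   an integer).
#' @examples
#' gfp_value_count(10408)
#' @export
gfp_value_count <- function(n_genes) {
  stopifnot(length(n_genes) == 1, n_genes == floor(n_genes), n_genes >= 1)
  pairs <- n_genes * (n_genes - 1) / 2
  total <- 2 * n_genes + pairs
  list(
    n_genes = n_genes,
    n_cor_pairs = pairs,
    total = total,
    fold_increase = round_half_up(total / n_genes)
  )
}

#' Percentage of regulated genes
#'
#' @param n_regulated Count of significantly regulated genes.
#' @param n_total Count of quantified genes.
#' @param digits Decimal places in the reported percentage (default 2,
#'   half-up).
#' @return Percentage as a single number.
#' @examples
#' pct_regulated(579, 10408)   # 5.56
#' @export
pct_regulated <- function(n_regulated, n_total, digits = 2) {
  stopifnot(n_total > 0, n_regulated >= 0, n_regulated <= n_total)
  round_half_up(100 * n_regulated / n_total, digits)
}

# internal: stop with a formatted message, no call
.halt <- function(...) stop(sprintf(...), call. = FALSE)

# internal: message helper used where the spec asks for logged warnings
.note <- function(...) message(sprintf(...))
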