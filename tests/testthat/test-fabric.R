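# per-condition fabric characteristics: AVE, REV, COR, REC, PREC

test_that("spot collapsing averages spots and scaling pins the median gene", {
  vals <- toy_matrix(c(2, 20, 4, 20, 1, 10, 8, 40), genes = paste0("s", 1:4))
  es <- expression_set(vals, "A",
                       spot_map = list(gA = c(1, 2), gB = 3, gC = 4))
  cn <- collapse_and_normalize(es)
  # gene gA replicate 1: mean(2, 4) = 3 before scaling; scale = median of
  # replicate means (3+20, 1+10, 8+40)/2 -> gene means (11.5, 5.5, 24); median 11.5
  expect_equal(unname(cn$values["gA", 1]), 3 / 11.5)
  expect_equal(stats::median(rowMeans(cn$values)), 1, tolerance = 1e-12)

  # a single-gene set always has AVE = 1 after scaling
  one <- toy_es(c(7, 9, 8, 8), genes = "solo")
  expect_equal(unname(compute_ave(one)), 1)
})

test_that("AVE is the replicate mean in units of the median gene", {
  es <- toy_es(c(1, 1, 1, 1,  2, 2, 2, 2,  8, 8, 8, 8),
               genes = c("low", "mid", "high"))
  ave <- compute_ave(es)
  # replicate means (1, 2, 8) scale by median 2 -> (0.5, 1, 4)
  expect_equal(unname(ave), c(0.5, 1, 4))
  expect_equal(stats::median(ave), 1)
  # a gene at 4.31x the median gene has AVE = 4.31
  es2 <- toy_es(c(1, 1, 1, 1,  4.31, 4.31, 4.31, 4.31, 0.2, 0.2, 0.2, 0.2),
                genes = c("median_gene", "prlr_like", "low"))
  expect_equal(unname(compute_ave(es2)["prlr_like"]), 4.31)
  # replicates (2,2,6,6) against a median-gene scale of 2 -> AVE 2
  es3 <- toy_es(c(2, 2, 2, 2,  2, 2, 6, 6, 1, 1, 1, 1),
                genes = c("mid", "var", "low"))
  expect_equal(unname(compute_ave(es3)["var"]), 2)
})

test_that("REV is the chi-square mid-interval CV in percent", {
  # identical replicates: zero variance, REV = 0
  es0 <- toy_es(c(5, 5, 5, 5, 2, 3, 4, 5), genes = c("flat", "v"))
  expect_equal(unname(compute_rev(es0)["flat"]), 0)

  # replicates (8,10,12,10): CV = 16.33%, REV = CV x mid-interval factor
  es <- toy_es(c(8, 10, 12, 10, 1, 1, 1, 1), genes = c("g", "m"))
  cv <- stats::sd(c(8, 10, 12, 10)) / 10
  expect_equal(unname(compute_rev(es)["g"]), 100 * cv * REV_FACTOR_NU3,
               tolerance = 1e-5)
  expect_equal(unname(compute_rev(es)["g"]), 35.07, tolerance = 0.01)

  # CV is scale-invariant: multiplying all replicates by 7 changes nothing
  es7 <- toy_es(7 * c(8, 10, 12, 10, 1, 1, 1, 1), genes = c("g", "m"))
  expect_equal(compute_rev(es7), compute_rev(es))

  # a tighter alpha widens the mid-interval
  expect_gt(unname(compute_rev(es, alpha = 0.01)["g"]),
            unname(compute_rev(es, alpha = 0.05)["g"]))
})

test_that("spot-level REV pools per-spot CVs with summed degrees of freedom", {
  # two spots with identical replicate profiles: pooled CV equals either
  # spot's CV, but nu doubles (6) so the mid-interval factor shrinks
  vals <- toy_matrix(c(8, 10, 12, 10, 16, 20, 24, 20, 1, 1, 1, 1),
                     genes = paste0("s", 1:3))
  es <- expression_set(vals, "A", spot_map = list(g = c(1, 2), m = 3))
  cn <- collapse_and_normalize(es)
  rev <- compute_rev(cn)
  cv <- stats::sd(c(8, 10, 12, 10)) / 10
  fac6 <- 0.5 * (sqrt(6 / stats::qchisq(0.975, 6)) +
                 sqrt(6 / stats::qchisq(0.025, 6)))
  expect_equal(unname(rev["g"]), 100 * cv * fac6, tolerance = 1e-10)
  expect_lt(unname(rev["g"]), 100 * cv * REV_FACTOR_NU3)
})

test_that("COR is the Pearson correlation of log2 profiles", {
  es <- toy_es(c(2^1, 2^2, 2^3, 2^4,
                 2^4, 2^3, 2^2, 2^1,
                 2^1, 2^3, 2^2, 2^4),
               genes = c("up", "down", "mix"))
  cc <- compute_cor(es)
  expect_equal(unname(diag(cc)), rep(1, 3))           # self-correlation = 1
  expect_equal(cc["up", "down"], -1)
  expect_equal(cc["up", "mix"], 0.8)                  # cov 4 over sqrt(5*5)
  expect_true(isSymmetric(cc))
  expect_true(all(abs(cc) <= 1 + 1e-12))
})

test_that("COR agrees with a brute-force Pearson implementation", {
  set.seed(42)
  vals <- matrix(rlnorm(40), 10, 4,
                 dimnames = list(paste0("g", 1:10), paste0("r", 1:4)))
  es <- collapse_and_normalize(expression_set(vals, "A"))
  cc <- compute_cor(es)
  lv <- log2(es$values)
  brute <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(cc[i, j], brute(lv[i, ], lv[j, ]), tolerance = 1e-12)
})

test_that("degenerate genes get undefined correlations, not zeros", {
  es <- toy_es(c(5, 5, 5, 5, 1, 2, 3, 4, 2, 4, 6, 8),
               genes = c("flat", "a", "b"))
  cc <- suppressMessages(compute_cor(es))
  expect_true(is.na(cc["flat", "a"]))
  expect_equal(cc["flat", "flat"], 1)
  expect_false(is.na(cc["a", "b"]))
})

test_that("REC baselines at the median REV and caps zero-variability genes", {
  rev <- c(a = 30, b = 10, c = 60, d = 30, e = 30)   # median 30
  rec <- compute_rec(rev)
  expect_equal(unname(rec["a"]), 0)
  expect_equal(unname(rec["b"]), 2)
  expect_equal(unname(rec["c"]), -0.5)
  expect_equal(unname(compute_rec(c(a = 0, b = 30, c = 40))["a"]), 100)
  expect_equal(unname(compute_rec(c(a = 0, b = 30, c = 40), cap = 7)["a"]), 7)
  # monotone decreasing in REV
  rev2 <- sort(runif(50, 1, 80))
  names(rev2) <- paste0("g", 1:50)
  expect_false(is.unsorted(rev(compute_rec(rev2))))
})

test_that("PREC baselines whole-transcriptome sets and matches REC on singletons", {
  rev <- c(a = 10, b = 20, c = 30, d = 40, e = 50)
  sets <- list(all = names(rev), tight = c("a", "b"), loose = c("d", "e"),
               single = "b", absent = c("zz"))
  prec <- suppressMessages(compute_prec(rev, sets))
  expect_equal(unname(prec["all"]), 0)
  expect_equal(unname(prec["tight"]), 30 / 15 - 1)     # half the global median
  expect_equal(unname(prec["loose"]), 30 / 45 - 1)
  expect_equal(unname(prec["single"]), unname(compute_rec(rev)["b"]))
  expect_false("absent" %in% names(prec))
})

test_that("fabric profiles keep the structural invariants", {
  spec <- simulation_spec(60, conditions = list(A = list(mean = 1, cv = 0.3)),
                          seed = 11)
  fab <- fabric_profile(simulate_study(spec)$A)
  expect_equal(stats::median(fab$ave), 1, tolerance = 1e-9)
  expect_equal(unname(diag(fab$cor)), rep(1, 60))
  expect_true(all(abs(fab$cor) <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(fab$rev_median, stats::median(fab$rev))
  expect_true(all(fab$rev >= 0))
})

test_that("fabric TSV serialization round-trips AVE/REV/REC", {
  spec <- simulation_spec(10, conditions = list(A = list(mean = 1, cv = 0.2)),
                          seed = 3)
  fab <- fabric_profile(simulate_study(spec)$A)
  stem <- tempfile()
  paths <- write_fabric(fab, stem)
  tab <- utils::read.table(paths["fabric"], header = TRUE, sep = "\t")
  expect_equal(tab$AVE, unname(fab$ave), tolerance = 1e-6)
  cm <- utils::read.table(paths["cor"], header = TRUE, sep = "\t",
                          check.names = FALSE)
  expect_equal(as.matrix(cm[, -1]), unname(fab$cor), tolerance = 1e-6,
               ignore_attr = TRUE)
})
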