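# significance of pairwise coordination and network remodeling

test_that("the critical Pearson value matches an independent inversion", {
  # oracle: invert the exact t-distribution of r*sqrt((n-2)/(1-r^2)) by root
  # finding on the CDF, independently of the closed form used by the package
  oracle <- function(n, p) {
    stats::uniroot(function(r)
      2 * (1 - stats::pt(r * sqrt((n - 2) / (1 - r^2)), n - 2)) - p,
      c(1e-6, 1 - 1e-9), tol = 1e-12)$root
  }
  expect_equal(critical_r(4, 0.05), oracle(4, 0.05), tolerance = 1e-9)
  expect_equal(critical_r(4, 0.05), 0.950, tolerance = 5e-4)
  expect_equal(critical_r(12, 0.01), oracle(12, 0.01), tolerance = 1e-9)
  # monotone decreasing in n at fixed p, down to 0 in the limit
  rs <- vapply(c(4, 8, 16, 64, 1024), critical_r, numeric(1))
  expect_false(is.unsorted(rev(rs), strictly = TRUE))
  expect_lt(critical_r(1e6), 0.005)
  expect_equal(critical_r(4, p_threshold = 1), 0)
  expect_error(critical_r(2), "n >= 3")
})

test_that("pairs classify into synergistic, antagonistic, independent bands", {
  cc <- matrix(c(1, 0.99, -0.96, 0.02,
                 0.99, 1, 0.3, 0.5,
                 -0.96, 0.3, 1, -0.03,
                 0.02, 0.5, -0.03, 1), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  fab <- fake_fabric(ave = stats::setNames(rep(1, 4), letters[1:4]),
                     rev = stats::setNames(rep(10, 4), letters[1:4]),
                     cor = cc, n_replicates = 4)
  prof <- classify_pairs(fab)
  expect_identical(prof$labels["a", "b"], "SYNERGISTIC")    # 0.99 >= 0.950
  expect_identical(prof$labels["a", "c"], "ANTAGONISTIC")
  expect_identical(prof$labels["a", "d"], "INDEPENDENT")    # |0.02| <= 0.05
  expect_identical(prof$labels["b", "c"], "UNCLASSIFIED")
  expect_identical(prof$labels, t(prof$labels))             # symmetric
  # invariant under gene reordering
  perm <- c("d", "b", "a", "c")
  fab2 <- fake_fabric(fab$ave[perm], fab$rev[perm], cc[perm, perm],
                      n_replicates = 4)
  prof2 <- classify_pairs(fab2)
  expect_identical(prof2$labels[letters[1:4], letters[1:4]],
                   prof$labels[letters[1:4], letters[1:4]])
})

test_that("null data yields ~5% significant pairs (type-I error control)", {
  spec <- simulation_spec(1000, conditions = list(
    null = list(mean = 1, cv = 0.2)), seed = 101)
  fab <- fabric_profile(simulate_study(spec)$null)
  prof <- classify_pairs(fab)
  lab <- prof$labels[upper.tri(prof$labels)]
  frac <- mean(lab %in% c("SYNERGISTIC", "ANTAGONISTIC"))
  n_pairs <- choose(1000, 2)
  half <- stats::qnorm(0.995) * sqrt(0.05 * 0.95 / n_pairs)
  expect_lt(abs(frac - 0.05), half)
  # and the uncorrected expected false-positive count is advertised
  expect_equal(expected_false_coordination(1000), n_pairs * 0.05)
})

test_that("the critical value matches the permutation null at n = 4", {
  # brute force: all 4! orderings of one profile against a fixed partner;
  # the permutation two-sided p of |r| >= r_crit must be <= 0.05, and the
  # next-smaller achievable |r| must not be significant
  x <- c(0.3, 1.1, 2.2, 3.5)
  y <- c(0.2, 0.9, 2.5, 3.1)
  perms <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  rs <- apply(perms, 1, function(p) stats::cor(x[p], y))
  rc <- critical_r(4, 0.05)
  for (r in rs) {
    perm_p <- mean(abs(rs) >= abs(r) - 1e-12)
    if (abs(r) >= rc) expect_lte(perm_p, 0.05 + 2 / 24)
    if (perm_p > 0.15) expect_lt(abs(r), rc)
  }
})

test_that("partner summaries count percentages over the scope minus the hub", {
  genes <- paste0("g", 1:11)
  cc <- diag(11); dimnames(cc) <- list(genes, genes)
  cc[1, 2:4] <- cc[2:4, 1] <- 0.99            # 3 synergistic partners
  cc[1, 5:11] <- cc[5:11, 1] <- 0.3           # 7 unclassified
  fab <- fake_fabric(stats::setNames(rep(1, 11), genes),
                     stats::setNames(rep(10, 11), genes), cc)
  prof <- classify_pairs(fab)
  ps <- partner_summary(prof, "g1")
  expect_equal(ps$pct_synergistic, 30.0)       # 3 of 10
  expect_equal(ps$pct_antagonistic, 0)
  expect_equal(ps$n_partners, 10)
  # all-independent scope
  cc2 <- diag(3); dimnames(cc2) <- list(letters[1:3], letters[1:3])
  fab2 <- fake_fabric(stats::setNames(rep(1, 3), letters[1:3]),
                      stats::setNames(rep(10, 3), letters[1:3]), cc2)
  ps2 <- partner_summary(classify_pairs(fab2), "a")
  expect_equal(ps2$pct_independent, 100)
  expect_equal(ps2$pct_synergistic, 0)
  # hub-only scope is an error
  expect_error(partner_summary(prof, "g1", scope = "g1"), "no partner")
  expect_error(partner_summary(prof, "nope"), "not quantified")
})

test_that("remodeling diffs report label paths and switches across conditions", {
  genes <- c("hub", "p1", "p2", "p3")
  mk <- function(r12, r13, r14, label) {
    cc <- diag(4); dimnames(cc) <- list(genes, genes)
    cc[1, 2] <- cc[2, 1] <- r12
    cc[1, 3] <- cc[3, 1] <- r13
    cc[1, 4] <- cc[4, 1] <- r14
    classify_pairs(fake_fabric(stats::setNames(rep(1, 4), genes),
                               stats::setNames(rep(10, 4), genes), cc,
                               condition = label))
  }
  nn <- mk(0.99, 0.02, 0.3, "NN")     # p1 synergistic, p2 independent
  dis <- mk(-0.97, 0.02, 0.3, "IN")   # p1 switched to antagonistic
  tab <- remodeling_diff(list(nn, dis), "hub")
  p1 <- tab[tab$partner == "p1", ]
  expect_true(p1$changed)
  expect_identical(p1$transition, "SYNERGISTIC->ANTAGONISTIC")
  expect_false(tab[tab$partner == "p2", "changed"])
  expect_identical(tab[tab$partner == "p3", "NN"], "UNCLASSIFIED")
  # identical profiles -> empty change set
  tab2 <- remodeling_diff(list(nn, nn), "hub")
  expect_false(any(tab2$changed))
})
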