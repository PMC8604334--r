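test_that("median-of-ratios size factors match hand values and DESeq2", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors_median_ratio(m)), c(1, 1))

  m2 <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors_median_ratio(m2)),
               c(1 / sqrt(2), sqrt(2)))

  # gene-order permutation invariance
  expect_equal(size_factors_median_ratio(m2[c(3, 1, 2), ]),
               size_factors_median_ratio(m2))

  # independent cross-check against DESeq2 (rescaled to geometric mean 1)
  set.seed(42)
  big <- matrix(rnbinom(600, mu = 80, size = 5) + 1, 100, 6,
                dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  mine <- size_factors_median_ratio(big)
  ref <- DESeq2::estimateSizeFactorsForMatrix(big)
  ref <- ref / exp(mean(log(ref)))
  # DESeq2 takes the median of log ratios, so with an even gene count the two
  # central values average geometrically instead of arithmetically
  expect_equal(unname(mine), unname(ref), tolerance = 1e-3)

  # no gene expressed everywhere: error advising the fallback, which works
  z <- matrix(c(5, 0, 0, 7), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(size_factors_median_ratio(z), "pseudo_reference")
  expect_length(size_factors_median_ratio(z, pseudo_reference = TRUE), 2)
})

test_that("dispersion estimation recovers moments and shrinks sanely", {
  cm <- count_matrix(matrix(c(5, 15), 1, 2,
                            dimnames = list("g1", c("a", "b"))),
                     c(a = "x", b = "x"))
  raw <- attr(estimate_dispersion(cm, size_factors = c(a = 1, b = 1),
                                  shrink = FALSE), "raw")
  expect_equal(unname(raw), 0.4) # (50 - 10) / 100

  # constant counts within groups: raw 0, floored
  cm0 <- count_matrix(matrix(10, 2, 4, dimnames = list(c("g1", "g2"),
                                                       paste0("s", 1:4))),
                      rep("x", 4))
  d0 <- estimate_dispersion(cm0, size_factors = setNames(rep(1, 4),
                                                         paste0("s", 1:4)),
                            shrink = FALSE)
  expect_true(all(attr(d0, "raw") == 0))
  expect_true(all(d0 >= 1e-8))

  # Poisson data (true phi = 0): median estimate small at n = 8 per group
  sim <- simulate_counts(1000, c(8, 8), dispersion = 0, spike_fraction = 0,
                         libsize_log_sd = 0, seed = 6)
  d <- estimate_dispersion(sim$counts)
  expect_lte(median(d), 0.01)

  expect_error(estimate_dispersion(
    count_matrix(matrix(1:2, 1, 2, dimnames = list("g", c("a", "b"))),
                 c(a = "x", b = "y"))), "singleton")
})

test_that("the exact conditional NB test matches enumeration oracles", {
  # the observed split is the mode: every outcome is included, p = 1
  expect_equal(unname(nb_exact_test(matrix(10, 1, 1), matrix(10, 1, 1),
                                    0.1)), 1)

  # phi = 0 reduces to the two-sided binomial split, enumerated directly
  p <- nb_exact_test(matrix(10, 1, 1), matrix(30, 1, 1), 0)
  lp <- dbinom(0:40, 40, 0.5, log = TRUE)
  oracle <- sum(exp(lp[lp <= lp[11] + 1e-12]))
  expect_equal(unname(p), oracle)

  # NB enumeration oracle at phi > 0 (equal group sizes)
  phi <- 0.05
  ya <- 12
  yb <- 40
  mu_grp <- (ya + yb) / 2 # equal group sizes: each group total has mean 26
  lp2 <- dnbinom(0:(ya + yb), size = 2 / phi, mu = mu_grp, log = TRUE) +
    dnbinom((ya + yb):0, size = 2 / phi, mu = mu_grp, log = TRUE)
  lp2 <- lp2 - max(lp2) - log(sum(exp(lp2 - max(lp2))))
  oracle2 <- sum(exp(lp2[lp2 <= lp2[ya + 1] + 1e-12]))
  p2 <- nb_exact_test(matrix(c(5, 7), 1, 2), matrix(c(19, 21), 1, 2), phi)
  expect_equal(unname(p2), oracle2)

  # overwhelming evidence: tiny p
  expect_lt(unname(nb_exact_test(matrix(c(0, 0), 1, 2),
                                 matrix(c(20, 20), 1, 2), 0.01)), 1e-4)

  # all-zero gene is not testable
  expect_true(is.na(nb_exact_test(matrix(0, 1, 2), matrix(0, 1, 2), 0.1)))
  expect_error(nb_exact_test(matrix(1, 1, 1), matrix(1, 1, 1), -0.1),
               "non-negative")
})

test_that("the Wald NB test behaves at the null, at zeros and under signal", {
  # identical group means, large counts: z ~ 0, p ~ 1
  a <- matrix(rep(c(1000, 1001, 999, 1000), 2), 1)
  p <- nb_wald_test(a[, 1:4, drop = FALSE], a[, 5:8, drop = FALSE], 0.01)
  expect_gt(unname(p), 0.9)

  # all-zero gene: absent from results (NA), not p = 1
  both <- rbind(c(0, 0, 0, 0), c(10, 12, 50, 60))
  pw <- nb_wald_test(both[, 1:2], both[, 3:4], 0.1)
  expect_true(is.na(pw[1]))
  expect_false(is.na(pw[2]))

  # strong signal including a zero group is still detected
  pz <- nb_wald_test(matrix(c(0, 0, 0, 0), 1), matrix(c(60, 80, 70, 90), 1),
                     0.05)
  expect_lt(unname(pz), 1e-4)
})

test_that("the empirical-Bayes tester is deterministic and finds signal", {
  sim <- simulate_counts(1000, c(8, 8), dispersion = 0.1,
                         spike_fraction = 0.1, spike_fc = 4, seed = 51)
  e1 <- eb_posterior_test(sim$counts, seed = 7)
  e2 <- eb_posterior_test(sim$counts, seed = 7)
  expect_identical(e1$posterior_null, e2$posterior_null)

  # >= 90% of spiked genes reach q <= 0.05 at fc 4, n = 8 per group
  spiked <- sim$truth$spiked_gene_ids
  q_spiked <- e1$q[match(spiked, e1$gene_id)]
  expect_gte(mean(q_spiked <= 0.05, na.rm = TRUE), 0.9)

  # a gene with identical counts in every sample favours the null
  flat <- count_matrix(matrix(20, 1, 8, dimnames = list("g1", paste0("s", 1:8))),
                       rep(c("A", "B"), each = 4))
  # add helper genes so priors exist
  mat <- rbind(g1 = rep(20, 8),
               matrix(rnbinom(40 * 8, mu = 50, size = 10), 40, 8,
                      dimnames = list(sprintf("h%02d", 1:40), NULL)))
  colnames(mat) <- paste0("s", 1:8)
  cm <- count_matrix(mat, rep(c("A", "B"), each = 4))
  eb <- eb_posterior_test(cm, seed = 3)
  expect_gt(eb$posterior_null[eb$gene_id == "g1"], 0.5)

  # q respects the cumulative-mean convention: q >= smallest posterior
  ord <- order(e1$posterior_null)
  expect_true(all(diff(e1$q[ord]) >= -1e-12, na.rm = TRUE))

  expect_error(eb_posterior_test(
    count_matrix(matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))),
                 c(x = "G1", y = "G1"))), "2 groups")
})

test_that("bh_adjust reproduces step-up minima and preserves ordering", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.004, 0.03, 0.03, 0.8)),
               c(0.016, 0.04, 0.04, 0.8))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  # q >= p and monotone in the p ordering; NA stays NA
  set.seed(8)
  p <- c(runif(50), NA)
  q <- bh_adjust(p)
  expect_true(all(q[!is.na(p)] >= p[!is.na(p)]))
  ord <- order(p[1:50])
  expect_true(all(diff(q[1:50][ord]) >= -1e-12))
  expect_true(is.na(q[51]))
})

test_that("the consensus rule counts methods at the inclusive threshold", {
  # two significant q values with the third method absent: shared
  expect_true(consensus_shared(c(NA, 3.55e-4, 2.18e-3)))
  # only one method under alpha: not shared
  expect_false(consensus_shared(c(0.06, 0.04, 0.2)))
  # boundary: q = 0.05 counts (inclusive), absent counts as not significant
  expect_true(consensus_shared(c(0.05, 0.05, NA)))
  expect_error(consensus_shared(c(NA_real_, NA_real_)), "no method")

  # order invariance and monotonicity in alpha
  q <- c(0.01, 0.2, 0.04)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(consensus_shared(q[perm]), consensus_shared(q))
  }
  alphas <- c(0.001, 0.01, 0.05, 0.1, 0.5)
  flags <- vapply(alphas, function(a) consensus_shared(q, alpha = a),
                  logical(1))
  expect_true(all(diff(as.integer(flags)) >= 0))

  # matrix form matches row-wise application
  qm <- rbind(a = c(0.01, 0.02, NA), b = c(0.2, 0.01, 0.9))
  expect_equal(unname(consensus_shared(qm)), c(TRUE, FALSE))
})

test_that("transform_and_pca matches a brute-force eigendecomposition", {
  set.seed(2)
  m <- matrix(rpois(120, 50), 20, 6,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
  cm <- count_matrix(m, rep(c("A", "B"), each = 3))
  pc <- transform_and_pca(cm)

  sf <- size_factors_median_ratio(cm, pseudo_reference = TRUE)
  lmat <- log2(sweep(m, 2, sf, "/") + 1)
  keep <- apply(lmat, 1, var) > 0
  x <- t(lmat[keep, ])
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(xc) / (nrow(xc) - 1))
  coords <- xc %*% ev$vectors
  k <- ncol(pc$coordinates)
  expect_lte(k, 5)
  expect_equal(abs(unname(pc$coordinates)),
               abs(unname(coords[, seq_len(k)])), tolerance = 1e-8)
  expect_lte(sum(pc$variance_explained), 1 + 1e-12)

  # rank-1 perturbation: one block of genes shifts together, PC1 takes all
  base <- matrix(100, 15, 4, dimnames = list(paste0("g", 1:15),
                                             paste0("s", 1:4)))
  base[1:8, 3:4] <- 400
  pr <- transform_and_pca(count_matrix(base, rep("A", 4)))
  expect_gt(pr$variance_explained[1], 0.99)

  # duplicated identical samples: zero variance, empty with a warning
  dup <- matrix(rep(c(5, 9, 13), 4), 3, 4,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_warning(pd <- transform_and_pca(count_matrix(dup, rep("A", 4))),
                 "zero variance")
  expect_equal(ncol(pd$coordinates), 0)
})
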