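test_that("standard curves fit, invert and report efficiency", {
  # two-point line: slope -10/3, intercept 40
  cv <- fit_standard_curve(c(1e3, 1e6), c(30, 20))
  expect_equal(cv$slope, -10 / 3)
  expect_equal(cv$intercept, 40)
  expect_equal(cv$efficiency, 10^0.3 - 1)

  # inversion: ct 25 -> log10 copies 4.5
  expect_equal(ct_to_copies(cv, 25), 10^4.5)
  expect_equal(ct_to_copies(cv, cv$intercept), 1)

  # noise-free round trip to machine precision
  q <- simulate_qpcr(c(a = 250, b = 9000), ct_noise_sd = 0, seed = 4)
  curve <- fit_standard_curve(q$standards)
  expect_equal(unname(ct_to_copies(curve, q$samples$ct)), c(250, 9000),
               tolerance = 1e-10)

  expect_error(fit_standard_curve(c(100, 100), c(20, 21)), "distinct")
  expect_error(fit_standard_curve(c(-1, 10), c(20, 21)), "positive")
})

test_that("dual-housekeeper normalization is a geometric mean of ratios", {
  n <- normalize_expression(100, 4, 25)
  expect_equal(n$normalized, 10) # ratios 25 and 4 -> geometric mean 10
  expect_equal(n$log10_value, 1)

  id <- normalize_expression(7, 7, 7)
  expect_equal(id$normalized, 1)
  expect_equal(id$log10_value, 0)

  # housekeeper order does not matter
  expect_equal(normalize_expression(100, 4, 25)$normalized,
               normalize_expression(100, 25, 4)$normalized)
  # equivalent form: target / geomean(hk1, hk2)
  expect_equal(normalize_expression(50, 3, 12)$normalized,
               50 / sqrt(3 * 12))

  expect_error(normalize_expression(0, 1, 1, sample_id = "s7"), "s7")
})

test_that("analyze_qpcr averages replicates and normalizes per sample", {
  curve_ct <- function(copies) 40 - (10 / 3) * log10(copies)
  std <- do.call(rbind, lapply(c("TGT", "B2M", "RPL19"), function(t) {
    data.frame(target = t, copies = 10^(2:6), ct = curve_ct(10^(2:6)))
  }))
  ct <- rbind(
    data.frame(sample_id = "s1", target = "TGT",
               ct = curve_ct(1000) + c(-0.1, 0.1), replicate = 1:2),
    data.frame(sample_id = "s1", target = "B2M", ct = curve_ct(400),
               replicate = 1),
    data.frame(sample_id = "s1", target = "RPL19", ct = curve_ct(250),
               replicate = 1))
  res <- analyze_qpcr(ct, std)
  expect_equal(nrow(res), 1)
  expect_equal(res$target_copies, 1000, tolerance = 1e-6)
  expect_equal(res$normalized, 1000 / sqrt(400 * 250), tolerance = 1e-6)

  expect_error(analyze_qpcr(ct[ct$target != "B2M", ], std), "B2M")
})

test_that("welch_t reproduces hand computations and degenerate conventions", {
  w <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, -1.2247, tolerance = 1e-4)
  expect_equal(w$df, 4)
  expect_equal(round(w$p, 3), 0.288)

  ident <- welch_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)

  # common affine transform leaves p unchanged
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(2.0, 4.4, 6.1)
  expect_equal(welch_t(2 * x + 3, 2 * y + 3)$p, welch_t(x, y)$p)
  expect_error(welch_t(1, c(1, 2)), ">= 2 values")
})

test_that("Dunnett T3 reduces, adjusts upward and controls family-wise error", {
  # three identical groups: omnibus and all adjusted p equal 1
  g <- list(a = c(2, 2, 2), b = c(2, 2, 2), c = c(2, 2, 2))
  r <- welch_anova_dunnett_t3(g)
  expect_equal(r$omnibus_p, 1)
  expect_true(all(r$pairwise$p_adj == 1))

  # two groups delegate to welch_t
  two <- welch_anova_dunnett_t3(list(x = c(1, 2, 3), y = c(2, 3, 4)))
  expect_equal(two$pairwise$p_adj, welch_t(c(1, 2, 3), c(2, 3, 4))$p)

  # adjusted p never undercuts the pairwise p
  set.seed(12)
  g3 <- list(a = rnorm(6), b = rnorm(6, 1), c = rnorm(6, 0, 3))
  r3 <- welch_anova_dunnett_t3(g3)
  expect_true(all(r3$pairwise$p_adj >= r3$pairwise$p - 1e-12))

  # control mode restricts the comparisons
  rc <- welch_anova_dunnett_t3(g3, control = "a")
  expect_equal(nrow(rc$pairwise), 2)
  expect_true(all(rc$pairwise$group1 == "a"))

  # null simulation: T3 keeps family-wise error at or below nominal
  set.seed(99)
  fwe <- mean(replicate(1500, {
    gg <- list(a = rnorm(7), b = rnorm(7), c = rnorm(7))
    any(welch_anova_dunnett_t3(gg)$pairwise$p_adj <= 0.05)
  }))
  expect_lte(fwe, 0.05 + 2.576 * sqrt(0.05 * 0.95 / 1500))
  expect_gte(fwe, 0.01)
})

test_that("mann_whitney matches exact enumeration and the approximation", {
  # U = 0, exact two-sided p = 2/6
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3)

  expect_equal(mann_whitney(c(3, 1, 2), c(2, 3, 1))$p, 1) # identical multisets

  # label swap leaves p unchanged
  x <- c(5, 9, 2, 11)
  y <- c(3, 8, 14)
  expect_equal(mann_whitney(x, y)$p, mann_whitney(y, x)$p)

  # exact mode equals wilcox.test's exact distribution when there are no ties
  set.seed(41)
  for (i in 1:15) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    v <- sample(1000, n1 + n2) / 7
    xx <- v[seq_len(n1)]
    yy <- v[-seq_len(n1)]
    expect_equal(mann_whitney(xx, yy)$p,
                 wilcox.test(xx, yy, exact = TRUE)$p.value,
                 tolerance = 1e-12, info = i)
  }

  # large-sample mode equals the tie-corrected normal approximation
  set.seed(42)
  xl <- round(rnorm(15, 10, 2))
  yl <- round(rnorm(18, 11, 2))
  expect_equal(mann_whitney(xl, yl)$p,
               wilcox.test(xl, yl, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-12)
})

test_that("kruskal_wallis matches hand values, enumeration and kruskal.test", {
  # rank-sum hand computation
  k <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)), method = "chisq")
  expect_equal(k$H, 4.5714, tolerance = 1e-4)
  expect_equal(k$df, 2)
  expect_equal(k$p, 0.1017, tolerance = 1e-4)
  expect_equal(k$H, unname(kruskal.test(
    list(c(1, 2), c(3, 4), c(5, 6)))$statistic), tolerance = 1e-10)

  # symmetric interleaving: H ~ 0
  sym <- kruskal_wallis(list(c(1, 6), c(2, 5), c(3, 4)), method = "chisq")
  expect_lt(sym$H, 0.5)

  # exact permutation p equals direct enumeration over all partitions
  direct_exact <- function(groups) {
    vals <- unlist(groups)
    sizes <- lengths(groups)
    N <- length(vals)
    obs <- kruskal_wallis(groups, method = "chisq")$H
    hits <- 0
    tot <- 0
    c1 <- combn(N, sizes[1])
    for (i in seq_len(ncol(c1))) {
      rest <- setdiff(seq_len(N), c1[, i])
      c2 <- combn(rest, sizes[2])
      for (j in seq_len(ncol(c2))) {
        g <- list(vals[c1[, i]], vals[c2[, j]],
                  vals[setdiff(rest, c2[, j])])
        tot <- tot + 1
        if (kruskal_wallis(g, method = "chisq")$H >= obs - 1e-9) {
          hits <- hits + 1
        }
      }
    }
    hits / tot
  }
  g_noties <- list(c(3, 9, 1), c(7, 2, 12), c(5, 11))
  expect_equal(kruskal_wallis(g_noties, method = "exact")$p,
               direct_exact(g_noties), tolerance = 1e-12)
  g_ties <- list(c(3, 9, 1), c(7, 3, 9), c(5, 3))
  expect_equal(kruskal_wallis(g_ties, method = "exact")$p,
               direct_exact(g_ties), tolerance = 1e-12)

  # two-group exact mode agrees with the exact Mann-Whitney p
  g2 <- list(c(4, 8, 15), c(16, 23, 42, 1))
  expect_equal(kruskal_wallis(g2, method = "exact")$p,
               mann_whitney(g2[[1]], g2[[2]], exact = TRUE)$p,
               tolerance = 1e-12)

  # Dunn post hoc: z near 0 for identical mean ranks, p_adj >= p
  kd <- kruskal_wallis(list(c(1, 6), c(2, 5), c(3, 4)), posthoc = "dunn",
                       method = "chisq")
  expect_true(all(abs(kd$pairwise$z) < 1.5))
  expect_true(all(kd$pairwise$p_adj >= kd$pairwise$p - 1e-12))

  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric())), "empty group")
})

test_that("insilico_pcr sizes amplicons exactly and is strand-aware", {
  fw <- "TGTCGCTCTTGATACTCGGC"
  rv <- "AGGCATTTCACTCACAGGGG"
  mid <- random_dna(50, seed = 61)
  tpl <- paste0(fw, mid, revcomp(rv))
  expect_equal(insilico_pcr(tpl, fw, rv), 90)

  # running against the reverse complement finds the same product
  expect_equal(insilico_pcr(revcomp(tpl), fw, rv), 90)

  # no downstream reverse site: no product
  expect_length(insilico_pcr(paste0(fw, mid), fw, rv), 0)
  # reverse site upstream of the forward site does not amplify
  expect_length(insilico_pcr(paste0(revcomp(rv), mid, fw), fw, rv), 0)

  # two forward sites give two products, ascending
  tpl2 <- paste0(fw, random_dna(30, seed = 62), tpl)
  expect_equal(insilico_pcr(tpl2, fw, rv), c(90, 140))

  expect_error(insilico_pcr("ACGTQ", fw, rv), "invalid characters")
})

test_that("times_to_minutes converts 24-h clock strings", {
  expect_equal(times_to_minutes(c("09:46", "00:00", "23:25")),
               c(586L, 0L, 1405L))
  expect_error(times_to_minutes("25:00"), "malformed")
  expect_error(times_to_minutes("9:7"), "malformed")
})
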