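# Tri-method consensus differential expression: median-of-ratios size
# factors, moment/trend dispersion estimation, three simplified
# negative-binomial testers (exact conditional, Wald GLM, empirical-Bayes
# model posterior), BH adjustment and the "shared DEG" consensus rule.
# The testers are simplified re-implementations of the exact-conditional,
# NB-GLM-Wald and model-posterior paradigms; version-exact agreement with any
# external package is not a goal and the consensus treats them as pluggable.

#' Median-of-ratios size factors
#'
#' Per sample, the median over genes (expressed in every sample) of
#' count / geometric-mean reference, rescaled so the factors have geometric
#' mean 1.
#'
#' @param counts a [count_matrix()] or plain genes x samples matrix.
#' @param pseudo_reference if `TRUE`, fall back to a reference built from
#'   genes with at least one positive count (geometric mean over positive
#'   entries), for datasets where no gene is expressed in all samples.
#' @return Named positive numeric vector, geometric mean 1.
#' @export
size_factors_median_ratio <- function(counts, pseudo_reference = FALSE) {
  mat <- if (inherits(counts, "count_matrix")) counts$counts else counts
  all_pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(all_pos)) {
    if (!pseudo_reference) {
      stop("no gene has nonzero counts in every sample; ",
           "re-run with pseudo_reference = TRUE")
    }
    some_pos <- rowSums(mat > 0) > 0
    ref <- apply(mat[some_pos, , drop = FALSE], 1,
                 function(x) exp(mean(log(x[x > 0]))))
    ratios <- mat[some_pos, , drop = FALSE] / ref
    sf <- apply(ratios, 2, function(x) median(x[x > 0]))
  } else {
    sub <- mat[all_pos, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
    sf <- apply(sub / ref, 2, median)
  }
  sf <- sf / geometric_mean(sf)
  setNames(sf, colnames(mat))
}

#' Estimate per-gene NB dispersion (method of moments + trend shrinkage)
#'
#' On size-factor-normalized counts, the raw method-of-moments dispersion is
#' phi = max(0, (pooled within-group variance - mean) / mean^2). Raw values
#' are shrunk toward a log-linear mean-dispersion trend with weight
#' proportional to the residual degrees of freedom:
#' phi = (d * phi_raw + prior_df * phi_trend) / (d + prior_df).
#' Estimates are floored at 1e-8.
#'
#' @param counts a [count_matrix()].
#' @param groups optional group labels (defaults to `counts$groups`).
#' @param size_factors optional size factors (computed if missing).
#' @param prior_df weight of the trend (default 10).
#' @param shrink if `FALSE`, return the raw moment estimates.
#' @return Named per-gene dispersion vector with attributes `raw` and
#'   `trend`.
#' @export
estimate_dispersion <- function(counts, groups = NULL, size_factors = NULL,
                                prior_df = 10, shrink = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  groups <- groups %||% counts$groups
  sizes <- table(groups)
  d <- sum(pmax(sizes - 1, 0))
  if (d == 0) stop("all groups are singletons; dispersion is inestimable")
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(counts)
  norm <- sweep(counts$counts, 2, size_factors, "/")
  m <- rowMeans(norm)
  ss <- 0
  for (g in unique(groups)) {
    sub <- norm[, groups == g, drop = FALSE]
    if (ncol(sub) < 2) next
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  v <- ss / d
  raw <- ifelse(m > 0, pmax(0, (v - m) / m^2), 0)
  if (!shrink) {
    return(structure(setNames(pmax(raw, 1e-8), rownames(norm)),
                     raw = raw, trend = NULL))
  }
  fit_ok <- raw > 0 & m > 0
  if (sum(fit_ok) >= 10) {
    fit <- lm(log(raw[fit_ok]) ~ log(m[fit_ok]))
    trend <- exp(coef(fit)[1] + coef(fit)[2] * log(pmax(m, min(m[m > 0]))))
  } else {
    trend <- rep(max(mean(raw), 1e-8), length(raw))
  }
  phi <- (d * raw + prior_df * trend) / (d + prior_df)
  structure(setNames(pmax(phi, 1e-8), rownames(norm)),
            raw = raw, trend = trend)
}

# Two-sided conditional NB p for a single gene: sums of NB(mu, phi) over n_A
# (resp. n_B) samples at common effective library size are NB with mean
# n_A * mu and dispersion phi / n_A. Conditional on the total, p is the sum
# of probabilities of outcomes no more likely than the observed split.
exact_nb_p_one <- function(ya, yb, na, nb, phi) {
  tot <- ya + yb
  if (tot == 0) return(NA_real_)
  a <- 0:tot
  if (phi <= 0) {
    lp <- dbinom(a, tot, na / (na + nb), log = TRUE)
  } else {
    mu <- tot / (na + nb)
    lp <- dnbinom(a, size = na / phi, mu = na * mu, log = TRUE) +
      dnbinom(tot - a, size = nb / phi, mu = nb * mu, log = TRUE)
    lp <- lp - log(sum(exp(lp - max(lp)))) - max(lp)
  }
  obs <- lp[ya + 1]
  min(1, sum(exp(lp[lp <= obs + 1e-12])))
}

#' Exact conditional NB test (two groups)
#'
#' Counts are scaled to a common effective library size using the size
#' factors and rounded; per gene, group totals are compared conditionally on
#' their sum under a negative binomial with shared mean and the supplied
#' dispersion. With phi = 0 this reduces to the two-sided binomial split.
#'
#' @param counts_A,counts_B genes x samples count matrices for the two
#'   groups.
#' @param phi per-gene dispersion (scalar recycled).
#' @param size_factors named size factors covering the samples of both
#'   groups (equal factors if missing).
#' @return Named per-gene two-sided p values (`NA` for all-zero genes).
#' @export
nb_exact_test <- function(counts_A, counts_B, phi, size_factors = NULL) {
  counts_A <- as.matrix(counts_A)
  counts_B <- as.matrix(counts_B)
  if (any(phi < 0)) stop("dispersion must be non-negative")
  phi <- rep_len(phi, nrow(counts_A))
  if (is.null(size_factors)) {
    size_factors <- setNames(rep(1, ncol(counts_A) + ncol(counts_B)),
                             c(colnames(counts_A), colnames(counts_B)))
  }
  scale_to_common <- function(mat) {
    sf <- if (is.null(colnames(mat))) rep(1, ncol(mat)) else
      size_factors[colnames(mat)]
    if (anyNA(sf) || !length(sf)) sf <- rep(1, ncol(mat))
    round(sweep(mat, 2, sf, "/"))
  }
  ya <- rowSums(scale_to_common(counts_A))
  yb <- rowSums(scale_to_common(counts_B))
  na <- ncol(counts_A)
  nb <- ncol(counts_B)
  p <- vapply(seq_along(ya), function(i) {
    exact_nb_p_one(ya[i], yb[i], na, nb, phi[i])
  }, numeric(1))
  setNames(p, rownames(counts_A))
}

# Per-group NB mean MLE with known dispersion and size-factor offsets, via
# Newton iterations on the log mean; returns the mean and its Fisher
# information (for the Wald SE of the log mean). Vectorized over genes.
nb_group_fit <- function(mat, sf, phi) {
  y_tot <- rowSums(mat)
  m <- pmax(y_tot / sum(sf), 1e-8)
  for (it in 1:50) {
    mu <- outer(m, sf)
    w <- 1 / (1 + phi * mu)
    score <- rowSums((mat - mu) * w)
    info <- rowSums(mu * w)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    m_new <- m * exp(step)
    if (max(abs(step)) < 1e-10) {
      m <- m_new
      break
    }
    m <- m_new
  }
  mu <- outer(m, sf)
  list(mean = m, info = rowSums(mu / (1 + phi * mu)))
}

#' Wald test on a two-group NB log-link model
#'
#' Fits group means by maximum likelihood with known per-gene dispersion and
#' size-factor offsets; the Wald statistic is the log fold change divided by
#' its standard error, referred to the standard normal. Genes with all-zero
#' counts in both groups are not testable and receive `NA`.
#'
#' @inheritParams nb_exact_test
#' @return Named per-gene two-sided p values.
#' @export
nb_wald_test <- function(counts_A, counts_B, phi, size_factors = NULL) {
  counts_A <- as.matrix(counts_A)
  counts_B <- as.matrix(counts_B)
  if (any(phi < 0)) stop("dispersion must be non-negative")
  phi <- rep_len(phi, nrow(counts_A))
  pick_sf <- function(mat) {
    if (is.null(size_factors) || is.null(colnames(mat))) return(rep(1, ncol(mat)))
    sf <- unname(size_factors[colnames(mat)])
    if (anyNA(sf)) rep(1, ncol(mat)) else sf
  }
  sfa <- pick_sf(counts_A)
  sfb <- pick_sf(counts_B)
  testable <- rowSums(counts_A) + rowSums(counts_B) > 0
  p <- rep(NA_real_, nrow(counts_A))
  if (any(testable)) {
    # +0.5 pseudocount on group totals avoids infinite LFC at zero groups
    ca <- counts_A[testable, , drop = FALSE]
    cb <- counts_B[testable, , drop = FALSE]
    ph <- phi[testable]
    fa <- nb_group_fit(ca, sfa, ph)
    fb <- nb_group_fit(cb, sfb, ph)
    eps <- 0.5 / max(sum(sfa), sum(sfb))
    ma <- fa$mean + eps
    mb <- fb$mean + eps
    info_at <- function(m, sf) {
      mu <- outer(m, sf)
      rowSums(mu / (1 + ph * mu))
    }
    lfc <- log(mb) - log(ma)
    se <- sqrt(1 / info_at(ma, sfa) + 1 / info_at(mb, sfb))
    z <- lfc / se
    p[testable] <- 2 * pnorm(-abs(z))
  }
  setNames(p, rownames(counts_A))
}

#' Empirical-Bayes model-posterior test
#'
#' For each gene, compares an equal-mean model against a group-specific-mean
#' model. Marginal likelihoods are Monte-Carlo averages over an empirical
#' prior: (mean, dispersion) pairs sampled (seeded) from the per-gene
#' moment estimates of the data themselves. Under the group-specific model
#' the group means are independent prior draws, so its marginal likelihood
#' factorizes over groups; under the equal-mean model the draw is shared.
#' Model priors are estimated by iterating expected model frequencies. The
#' default q value for a gene is the mean posterior-of-null over all genes
#' with posterior-of-null at most its own (cumulative FDR convention);
#' `fdr_method = "bh"` applies [bh_adjust()] to (1 - posterior) instead.
#'
#' @param counts a [count_matrix()] with >= 2 groups.
#' @param groups optional group labels (defaults to `counts$groups`).
#' @param n_prior_samples number of empirical prior draws.
#' @param seed integer seed for the prior draws.
#' @param size_factors optional size factors.
#' @param fdr_method `"cumulative"` (default) or `"bh"`.
#' @return data.frame with `gene_id`, `posterior_null` and `q` (`NA` for
#'   untestable all-zero genes).
#' @export
eb_posterior_test <- function(counts, groups = NULL, n_prior_samples = 500,
                              seed = 1, size_factors = NULL,
                              fdr_method = c("cumulative", "bh")) {
  stopifnot(inherits(counts, "count_matrix"))
  fdr_method <- match.arg(fdr_method)
  groups <- groups %||% counts$groups
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(counts)
  mat <- counts$counts
  norm <- sweep(mat, 2, unname(size_factors[colnames(mat)]), "/")
  m_hat <- pmax(rowMeans(norm), 1e-8)
  v_hat <- apply(norm, 1, var)
  phi_hat <- pmax((v_hat - m_hat) / m_hat^2, 1e-4)
  testable <- rowSums(mat) > 0
  G <- nrow(mat)
  logmeanexp <- function(x) {
    mx <- max(x)
    mx + log(mean(exp(x - mx)))
  }
  post_null <- rep(NA_real_, G)
  idx_t <- which(testable)
  if (length(idx_t)) {
    draws <- with_seed(derive_seed(seed, "eb"), {
      sample(idx_t, n_prior_samples, replace = TRUE)
    })
    ug <- unique(groups)
    k <- length(ug)
    # log-likelihood of each gene's per-group data under each prior draw
    grp_ll <- array(0, dim = c(length(idx_t), n_prior_samples, k))
    for (gi in seq_len(k)) {
      cols <- which(groups == ug[gi])
      sub <- mat[idx_t, cols, drop = FALSE]
      sfc <- unname(size_factors[colnames(mat)[cols]])
      for (h in seq_len(n_prior_samples)) {
        mu <- outer(rep(m_hat[draws[h]], length(idx_t)), sfc)
        grp_ll[, h, gi] <- rowSums(dnbinom(sub, size = 1 / phi_hat[draws[h]],
                                           mu = mu, log = TRUE))
      }
    }
    l_null <- apply(rowSums(grp_ll, dims = 2), 1, logmeanexp)
    l_de <- rowSums(apply(grp_ll, c(1, 3), logmeanexp))
    pi1 <- 0.1
    for (it in 1:100) {
      lo <- log(1 - pi1) + l_null
      l1 <- log(pi1) + l_de
      mx <- pmax(lo, l1)
      pn <- exp(lo - mx) / (exp(lo - mx) + exp(l1 - mx))
      pi1_new <- min(max(mean(1 - pn), 1e-6), 1 - 1e-6)
      if (abs(pi1_new - pi1) < 1e-10) {
        pi1 <- pi1_new
        break
      }
      pi1 <- pi1_new
    }
    post_null[idx_t] <- pn
  }
  q <- rep(NA_real_, G)
  if (length(idx_t)) {
    if (fdr_method == "cumulative") {
      ord <- order(post_null[idx_t])
      cm <- cumsum(post_null[idx_t][ord]) / seq_along(ord)
      qq <- numeric(length(ord))
      qq[ord] <- cm
      # tied posteriors share the largest cumulative mean among them
      q[idx_t] <- ave(qq, post_null[idx_t], FUN = max)
    } else {
      q[idx_t] <- bh_adjust(1 - post_null[idx_t])
    }
  }
  data.frame(gene_id = rownames(mat), posterior_null = post_null, q = q,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up q values: q_(i) = min over j >= i of p_(j) * m / j, capped at 1
#' and mapped back to input order. `NA` p values stay `NA` and do not count
#' toward m.
#'
#' @param pvals numeric vector of p values in \[0, 1\] (NA allowed).
#' @return q values in input order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p values must be in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- p.adjust(pvals[ok], method = "BH")
  out
}

#' Consensus "shared DEG" rule
#'
#' A gene is a shared DEG when at least `min_methods` of its per-method q
#' values are at most `alpha`. Missing q values (untestable genes) count as
#' not significant.
#'
#' @param q_by_method numeric vector (or matrix, genes x methods) of q
#'   values; `NA` = method did not test the gene.
#' @param alpha significance threshold on q (inclusive).
#' @param min_methods minimum number of concordant methods.
#' @return logical (vector for matrix input).
#' @export
consensus_shared <- function(q_by_method, alpha = 0.05, min_methods = 2) {
  if (is.matrix(q_by_method) || is.data.frame(q_by_method)) {
    m <- as.matrix(q_by_method)
    if (all(is.na(m))) stop("no method produced a q value")
    return(rowSums(m <= alpha, na.rm = TRUE) >= min_methods)
  }
  if (all(is.na(q_by_method))) stop("no method produced a q value")
  sum(q_by_method <= alpha, na.rm = TRUE) >= min_methods
}

#' Run the three-method consensus for one contrast
#'
#' Applies the exact conditional, Wald and empirical-Bayes testers to the
#' `ref` vs `alt` samples of a count matrix, adjusts each method's p values
#' by BH over testable genes (the eb tester supplies its posterior-based q),
#' and flags shared DEGs by the consensus rule.
#'
#' @param counts a [count_matrix()].
#' @param ref,alt reference and alternative group labels.
#' @param alpha,min_methods consensus parameters.
#' @param n_prior_samples,seed passed to [eb_posterior_test()].
#' @param dispersion optional per-gene dispersion; estimated from the two
#'   groups when missing.
#' @return An object of class `contrast_result`: data.frame with `gene_id`,
#'   per-method p/q columns and a logical `shared` column; attributes
#'   `contrast` and `alpha`.
#' @export
run_contrast <- function(counts, ref, alt, alpha = 0.05, min_methods = 2,
                         n_prior_samples = 500, seed = 1, dispersion = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  ia <- group_samples(counts, ref)
  ib <- group_samples(counts, alt)
  sub <- count_matrix(counts$counts[, c(ia, ib), drop = FALSE],
                      setNames(counts$groups[c(ia, ib)],
                               colnames(counts$counts)[c(ia, ib)]))
  sf <- size_factors_median_ratio(sub)
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(sub, size_factors = sf)
  }
  ca <- sub$counts[, sub$groups == ref, drop = FALSE]
  cb <- sub$counts[, sub$groups == alt, drop = FALSE]
  p_exact <- nb_exact_test(ca, cb, dispersion, sf)
  p_wald <- nb_wald_test(ca, cb, dispersion, sf)
  eb <- eb_posterior_test(sub, n_prior_samples = n_prior_samples, seed = seed,
                          size_factors = sf)
  res <- data.frame(
    gene_id = rownames(sub$counts),
    p_exact = p_exact, q_exact = bh_adjust(p_exact),
    p_wald = p_wald, q_wald = bh_adjust(p_wald),
    posterior_null = eb$posterior_null, q_eb = eb$q,
    stringsAsFactors = FALSE)
  res$shared <- consensus_shared(res[, c("q_exact", "q_wald", "q_eb")],
                                 alpha = alpha, min_methods = min_methods)
  attr(res, "contrast") <- c(ref = ref, alt = alt)
  attr(res, "alpha") <- alpha
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Variance-stabilizing transform and PCA overview
#'
#' log2(normalized count + 1) on size-factor-normalized counts (a simplified
#' stand-in for regularized-log transforms), followed by gene-centered PCA of
#' the samples. At most min(n_components, samples - 1) components are
#' returned.
#'
#' @param counts a [count_matrix()].
#' @param n_components maximum number of principal components.
#' @return list with `coordinates` (samples x components), `variance_explained`
#'   (fractions of total variance, sum <= 1) and `groups`.
#' @export
transform_and_pca <- function(counts, n_components = 10) {
  stopifnot(inherits(counts, "count_matrix"))
  if (ncol(counts$counts) < 2) stop("need at least 2 samples")
  sf <- size_factors_median_ratio(counts, pseudo_reference = TRUE)
  lmat <- log2(sweep(counts$counts, 2, sf, "/") + 1)
  keep <- apply(lmat, 1, function(x) var(x) > 0)
  if (!any(keep)) {
    warning("all genes have zero variance; no components to report")
    return(list(coordinates = matrix(0, ncol(lmat), 0,
                                     dimnames = list(colnames(lmat), NULL)),
                variance_explained = numeric(0), groups = counts$groups))
  }
  pc <- prcomp(t(lmat[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(lmat) - 1, ncol(pc$x))
  list(coordinates = pc$x[, seq_len(k), drop = FALSE],
       variance_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       groups = counts$groups)
}
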