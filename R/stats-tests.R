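# Group-comparison statistics for demographics and log10 qPCR data:
# Welch t, Brown-Forsythe & Welch ANOVA with Dunnett T3 post hoc, exact
# Mann-Whitney (ties allowed), Kruskal-Wallis with an exact small-sample
# permutation mode, and Dunn's post hoc.

#' Two-tailed Welch's t test
#'
#' Welch statistic with Satterthwaite degrees of freedom. When both groups
#' have zero variance and equal means, p = 1 by convention.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

# Welch-type pairwise t with Satterthwaite df (no pooling).
welch_pair <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  se2 <- vx + vy
  if (se2 == 0) {
    same <- mean(x) == mean(y)
    return(list(t = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2,
                p = if (same) 1 else 0))
  }
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Heteroscedastic ANOVA with Dunnett T3 post hoc
#'
#' Omnibus: Welch's heteroscedastic one-way ANOVA. Post hoc: Dunnett's T3 —
#' Welch-type pairwise statistics referred to the studentized maximum modulus
#' distribution with per-pair Satterthwaite df. Under independence of the r
#' comparisons the SMM tail gives p_adj = 1 - (2 * F_t(|t|; df) - 1)^r, i.e.
#' a Sidak-style adjustment of the pairwise Welch p. With two groups the
#' result reduces to [welch_t()].
#'
#' @param groups named list of numeric vectors (each length >= 2).
#' @param control optional group name: compare every group to it only
#'   (default: all pairs).
#' @return list with `omnibus_p`, and a data.frame `pairwise` (`group1`,
#'   `group2`, `t`, `df`, `p`, `p_adj`).
#' @export
welch_anova_dunnett_t3 <- function(groups, control = NULL) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) < 2)) stop("every group needs >= 2 values")
  if (length(groups) < 2) stop("need >= 2 groups")
  if (length(groups) == 2) {
    wt <- welch_t(groups[[1]], groups[[2]])
    return(list(omnibus_p = wt$p,
                pairwise = data.frame(group1 = names(groups)[1],
                                      group2 = names(groups)[2],
                                      t = wt$t, df = wt$df, p = wt$p,
                                      p_adj = wt$p,
                                      stringsAsFactors = FALSE)))
  }
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (all(vapply(groups, sd, numeric(1)) == 0) &&
      length(unique(vapply(groups, mean, numeric(1)))) == 1) {
    omnibus <- 1
  } else {
    omnibus <- oneway.test(vals ~ fac, var.equal = FALSE)$p.value
  }
  pairs <- if (is.null(control)) {
    utils::combn(names(groups), 2, simplify = FALSE)
  } else {
    if (!control %in% names(groups)) stop("unknown control group: ", control)
    lapply(setdiff(names(groups), control), function(g) c(control, g))
  }
  r <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    wp <- welch_pair(groups[[pr[1]]], groups[[pr[2]]])
    p_adj <- 1 - (2 * pt(abs(wp$t), wp$df) - 1)^r
    data.frame(group1 = pr[1], group2 = pr[2], t = wp$t, df = wp$df,
               p = wp$p, p_adj = min(1, p_adj), stringsAsFactors = FALSE)
  })
  list(omnibus_p = omnibus, pairwise = do.call(rbind, rows))
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact p by full enumeration of rank assignments (midranks, so ties are
#' handled exactly) when the combined sample size is at most
#' `exact_threshold`; otherwise a normal approximation with tie-corrected
#' variance and no continuity correction. Two-sided exact p counts
#' arrangements with |U - n1 n2 / 2| at least as large as observed.
#'
#' @param x,y numeric vectors (each length >= 1).
#' @param exact use exact enumeration (default: automatic by size).
#' @param exact_threshold maximum combined n for the automatic exact mode.
#' @return list with `U` (statistic of `x`), `p`, `method`.
#' @export
mann_whitney <- function(x, y, exact = NULL, exact_threshold = 20) {
  n1 <- length(x)
  n2 <- length(y)
  if (!n1 || !n2) stop("both groups need >= 1 value")
  n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (is.null(exact)) exact <- n <= exact_threshold
  if (exact) {
    combs <- utils::combn(n, n1)
    Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    if (sigma2 == 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p = p, method = method)
}

# Tie-corrected Kruskal-Wallis H from midranks.
kw_H <- function(rank_sums, sizes, N, tie_term) {
  H <- 12 / (N * (N + 1)) * sum(rank_sums^2 / sizes) - 3 * (N + 1)
  if (tie_term > 0) H <- H / (1 - tie_term / (N^3 - N))
  H
}

# Exact permutation p for the Kruskal-Wallis H with k = 2 or 3 groups:
# dynamic programme over the joint distribution of the rank sums of the
# first k-1 groups (midranks doubled to integers when ties are present).
kw_exact_p <- function(r2, sizes, N, tie_term, H_obs) {
  k <- length(sizes)
  track <- seq_len(k - 1)
  maxs <- vapply(track, function(i) {
    sum(sort(r2, decreasing = TRUE)[seq_len(sizes[i])])
  }, numeric(1))
  if (k == 2) {
    dp <- matrix(0, sizes[1] + 1, maxs[1] + 1)
    dp[1, 1] <- 1
    for (v in r2) {
      shifted <- dp[seq_len(sizes[1]), seq_len(maxs[1] + 1 - v), drop = FALSE]
      dp[-1, -seq_len(v)] <- dp[-1, -seq_len(v), drop = FALSE] + shifted
    }
    cnt <- dp[sizes[1] + 1, ]
    S1 <- which(cnt > 0) - 1
    total <- sum(cnt)
    hits <- 0
    for (s1 in S1) {
      rs <- c(s1, sum(r2) - s1) / 2
      if (kw_H(rs, sizes, N, tie_term) >= H_obs - 1e-9) {
        hits <- hits + cnt[s1 + 1]
      }
    }
    return(hits / total)
  }
  d1 <- sizes[1] + 1
  d2 <- sizes[2] + 1
  dp <- array(0, dim = c(d1, d2, maxs[1] + 1, maxs[2] + 1))
  dp[1, 1, 1, 1] <- 1
  for (v in r2) {
    new <- dp
    add1 <- dp[seq_len(sizes[1]), , seq_len(maxs[1] + 1 - v), ,
               drop = FALSE]
    new[-1, , -seq_len(v), ] <- new[-1, , -seq_len(v), , drop = FALSE] + add1
    add2 <- dp[, seq_len(sizes[2]), , seq_len(maxs[2] + 1 - v),
               drop = FALSE]
    new[, -1, , -seq_len(v)] <- new[, -1, , -seq_len(v), drop = FALSE] + add2
    dp <- new
  }
  cnt <- dp[d1, d2, , ]
  nz <- which(cnt > 0, arr.ind = TRUE)
  total <- sum(cnt)
  hits <- 0
  Ssum <- sum(r2)
  for (i in seq_len(nrow(nz))) {
    s1 <- nz[i, 1] - 1
    s2 <- nz[i, 2] - 1
    rs <- c(s1, s2, Ssum - s1 - s2) / 2
    if (kw_H(rs, sizes, N, tie_term) >= H_obs - 1e-9) {
      hits <- hits + cnt[nz[i, 1], nz[i, 2]]
    }
  }
  hits / total
}

#' Kruskal-Wallis test with exact small-sample mode and Dunn's post hoc
#'
#' Midrank-based H with tie correction. For small designs (k <= 3 groups,
#' total N <= `exact_limit`) the default is the exact permutation p — the
#' probability, over all assignments of the observed values to groups of the
#' given sizes, of an H at least as large as observed (computed by dynamic
#' programming, not sampling). Larger designs use the chi-square
#' approximation with k - 1 df. Dunn's post hoc compares mean ranks with
#' tie-corrected z statistics; pairwise p values are Bonferroni-adjusted for
#' the number of comparisons.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each non-empty).
#' @param posthoc `"none"` or `"dunn"`.
#' @param method `"auto"` (default), `"exact"` or `"chisq"`.
#' @param exact_limit largest total N for the automatic exact mode.
#' @return list with `H`, `df`, `p`, `method` and (for `posthoc = "dunn"`)
#'   a data.frame `pairwise`.
#' @export
kruskal_wallis <- function(groups, posthoc = c("none", "dunn"),
                           method = c("auto", "exact", "chisq"),
                           exact_limit = 25) {
  posthoc <- match.arg(posthoc)
  method <- match.arg(method)
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  sizes <- lengths(groups)
  k <- length(sizes)
  vals <- unlist(groups, use.names = FALSE)
  N <- length(vals)
  r <- rank(vals)
  grp <- rep(seq_len(k), sizes)
  rank_sums <- tapply(r, grp, sum)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  H <- kw_H(rank_sums, sizes, N, tie_term)
  use_exact <- switch(method,
                      exact = TRUE,
                      chisq = FALSE,
                      auto = k <= 3 && N <= exact_limit)
  if (use_exact && k > 3) {
    stop("exact mode supports at most 3 groups; use method = \"chisq\"")
  }
  if (use_exact) {
    r2 <- as.integer(round(2 * r)) # midranks doubled: always integer
    p <- kw_exact_p(r2, sizes, N, tie_term, H)
    used <- "exact permutation"
  } else {
    p <- pchisq(H, df = k - 1, lower.tail = FALSE)
    used <- "chi-square approximation"
  }
  out <- list(H = unname(H), df = k - 1, p = p, method = used)
  if (posthoc == "dunn") {
    mean_ranks <- rank_sums / sizes
    sigma2_base <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
    pairs <- utils::combn(k, 2, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      i <- pr[1]
      j <- pr[2]
      se <- sqrt(sigma2_base * (1 / sizes[i] + 1 / sizes[j]))
      z <- (mean_ranks[i] - mean_ranks[j]) / se
      p_raw <- 2 * pnorm(-abs(z))
      data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
                 z = unname(z), p = unname(p_raw),
                 p_adj = min(1, unname(p_raw) * length(pairs)),
                 stringsAsFactors = FALSE)
    })
    out$pairwise <- do.call(rbind, rows)
  }
  out
}

#' Convert "hh:mm" clock strings to minutes past midnight
#'
#' @param times character vector of 24-h clock strings.
#' @return integer minutes (hh * 60 + mm).
#' @export
times_to_minutes <- function(times) {
  ok <- grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", times)
  if (!all(ok)) {
    stop("malformed time string(s): ", paste(head(times[!ok]), collapse = ", "))
  }
  parts <- strsplit(times, ":", fixed = TRUE)
  vapply(parts, function(p) as.integer(p[1]) * 60L + as.integer(p[2]),
         integer(1))
}
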