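# qPCR quantification: log-linear standard curves, copy-number conversion,
# dual-housekeeper geometric-mean normalization, in-silico PCR.

#' Fit a qPCR standard curve
#'
#' Least-squares fit of Ct = intercept + slope * log10(copies). Amplification
#' efficiency is 10^(-1/slope) - 1 (1.0 = perfect doubling per cycle).
#'
#' @param copies positive copy numbers of the standards (or a two-column
#'   data.frame `copies`, `ct`).
#' @param ct observed Ct values (omit when `copies` is a data.frame).
#' @return An object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `efficiency`.
#' @export
fit_standard_curve <- function(copies, ct = NULL) {
  if (is.data.frame(copies)) {
    ct <- copies$ct
    copies <- copies$copies
  }
  if (any(copies <= 0)) stop("standard copy numbers must be positive")
  if (length(unique(copies)) < 2) {
    stop("need at least 2 distinct copy levels")
  }
  fit <- lm(ct ~ log10(copies))
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else 1
  slope <- unname(coef(fit)[2])
  if (slope >= 0) {
    warning("fitted slope is non-negative; Ct should fall with copy number")
  }
  structure(list(slope = slope,
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve: Ct = %.4f %+.4f * log10(copies); R^2 = %.4f, eff = %.3f\n",
    x$intercept, x$slope, x$r_squared, x$efficiency))
  invisible(x)
}

#' Convert Ct values to copy numbers along a standard curve
#'
#' copies = 10^((ct - intercept) / slope).
#'
#' @param curve a [fit_standard_curve()] result.
#' @param ct Ct values.
#' @return positive copy numbers.
#' @export
ct_to_copies <- function(curve, ct) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Dual-housekeeper geometric-mean normalization
#'
#' normalized = sqrt((target/hk1) * (target/hk2)); log10_value = log10 of it.
#' Algebraically identical to target / geomean(hk1, hk2).
#'
#' @param target,hk1,hk2 positive copy numbers (vectorized).
#' @param sample_id optional ids used in error messages.
#' @return list with `normalized` and `log10_value`.
#' @export
normalize_expression <- function(target, hk1, hk2, sample_id = NULL) {
  bad <- which(target <= 0 | hk1 <= 0 | hk2 <= 0)
  if (length(bad)) {
    nm <- if (is.null(sample_id)) paste("entry", bad) else sample_id[bad]
    stop("non-positive copy number for: ", paste(head(nm), collapse = ", "))
  }
  normalized <- sqrt((target / hk1) * (target / hk2))
  list(normalized = normalized, log10_value = log10(normalized))
}

#' Quantify and normalize a qPCR experiment
#'
#' Technical Ct replicates are averaged per (sample, target) before copy
#' conversion (set `average_replicates = FALSE` to convert first and average
#' copies). Each target is converted through its own standard curve, then
#' normalized to the two housekeeper genes.
#'
#' @param ct_table data.frame with columns `sample_id`, `target`, `ct` (and
#'   optionally `replicate`).
#' @param standards data.frame with columns `target`, `copies`, `ct`.
#' @param housekeepers character vector of exactly two housekeeper target
#'   names.
#' @param average_replicates average Ct before conversion (default) or copies
#'   after.
#' @return data.frame with one row per sample and non-housekeeper target:
#'   `sample_id`, `target`, `target_copies`, `hk1_copies`, `hk2_copies`,
#'   `normalized`, `log10_value`.
#' @export
analyze_qpcr <- function(ct_table, standards, housekeepers = c("B2M", "RPL19"),
                         average_replicates = TRUE) {
  stopifnot(all(c("sample_id", "target", "ct") %in% names(ct_table)),
            all(c("target", "copies", "ct") %in% names(standards)),
            length(housekeepers) == 2)
  missing_hk <- setdiff(housekeepers, ct_table$target)
  if (length(missing_hk)) {
    stop("housekeeper(s) absent from Ct table: ",
         paste(missing_hk, collapse = ", "))
  }
  curves <- lapply(split(standards, standards$target), function(s) {
    fit_standard_curve(s$copies, s$ct)
  })
  no_curve <- setdiff(unique(ct_table$target), names(curves))
  if (length(no_curve)) {
    stop("target(s) without standards: ", paste(no_curve, collapse = ", "))
  }
  copies_of <- function(sub) {
    curve <- curves[[sub$target[1]]]
    if (average_replicates) {
      ct_to_copies(curve, mean(sub$ct))
    } else {
      mean(ct_to_copies(curve, sub$ct))
    }
  }
  per <- lapply(split(ct_table, ct_table[c("sample_id", "target")],
                      drop = TRUE), copies_of)
  key <- do.call(rbind, strsplit(names(per), ".", fixed = TRUE))
  copies <- data.frame(sample_id = key[, 1], target = key[, 2],
                       copies = unlist(per), stringsAsFactors = FALSE)
  targets <- setdiff(unique(copies$target), housekeepers)
  rows <- list()
  for (s in unique(copies$sample_id)) {
    sub <- copies[copies$sample_id == s, ]
    hk1 <- sub$copies[sub$target == housekeepers[1]]
    hk2 <- sub$copies[sub$target == housekeepers[2]]
    if (!length(hk1) || !length(hk2)) {
      stop("sample ", s, " lacks a housekeeper measurement")
    }
    for (tg in targets) {
      tc <- sub$copies[sub$target == tg]
      if (!length(tc)) next
      nn <- normalize_expression(tc, hk1, hk2, sample_id = s)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, target = tg, target_copies = tc,
        hk1_copies = hk1, hk2_copies = hk2,
        normalized = nn$normalized, log10_value = nn$log10_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' In-silico PCR by exact primer matching
#'
#' Finds every exact match of the forward primer with a downstream,
#' non-overlapping exact match of the reverse-complemented reverse primer and
#' reports amplicon lengths (end of reverse site minus start of forward site
#' plus one). Both template orientations are scanned, so the result is
#' invariant under reverse complementation of the template. No mismatch
#' tolerance: primers designed against unique sites match exactly or not at
#' all.
#'
#' @param template nucleotide string over A/C/G/T/N (case-insensitive).
#' @param forward,reverse primer sequences, 5' to 3'.
#' @return integer vector of amplicon lengths, ascending (empty when no
#'   product forms).
#' @export
insilico_pcr <- function(template, forward, reverse) {
  clean <- function(x, allow_n = FALSE) {
    x <- toupper(gsub("\\s", "", x))
    ok <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
    if (!grepl(ok, x)) stop("sequence contains invalid characters")
    x
  }
  template <- clean(template, allow_n = TRUE)
  forward <- clean(forward)
  reverse <- clean(reverse)
  tpl <- Biostrings::DNAString(template)
  sites <- function(primer) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(primer), tpl,
                                  fixed = TRUE)
    cbind(start = Biostrings::start(m), end = Biostrings::end(m))
  }
  rc <- function(p) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(p)))
  }
  amplicons <- function(fwd_sites, rev_sites) {
    out <- integer()
    for (i in seq_len(nrow(fwd_sites))) {
      dn <- rev_sites[rev_sites[, "start"] > fwd_sites[i, "end"], ,
                      drop = FALSE]
      out <- c(out, unname(dn[, "end"] - fwd_sites[i, "start"] + 1L))
    }
    as.integer(out)
  }
  plus <- amplicons(sites(forward), sites(rc(reverse)))
  minus <- amplicons(sites(reverse), sites(rc(forward)))
  sort(c(plus, minus))
}
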