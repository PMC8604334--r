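# Ratio-of-medians fold change with the TPM floor rule, robust-DEG
# designation and Table-style per-contrast summaries.

#' Per-gene median TPM of one sample group
#'
#' @param tpm a [tpm_matrix()].
#' @param group group label.
#' @return Named per-gene medians (even n: mean of the two central values).
#' @export
group_median_tpm <- function(tpm, group) {
  stopifnot(inherits(tpm, "tpm_matrix"))
  idx <- which(tpm$groups == group)
  if (!length(idx)) stop("unknown group label: ", group)
  apply(tpm$tpm[, idx, drop = FALSE], 1, median)
}

#' Median-TPM fold change with the sub-1 floor rule
#'
#' Medians below `floor` are replaced by `floor` before the ratio is taken;
#' the fold change is always larger over smaller, so fc >= 1. Direction is
#' relative to the reference: `"up"` if the floored alternative median
#' exceeds the floored reference median, `"down"` if smaller, and `NA` (fc =
#' 1) when the floored medians are equal. The floor removes spuriously large
#' fold changes driven by near-zero expression.
#'
#' @param m_ref,m_alt non-negative group medians (vectorized).
#' @param floor floor applied to sub-`floor` medians (default 1 TPM).
#' @return list with numeric `fc` and character `direction`.
#' @export
median_fold_change <- function(m_ref, m_alt, floor = 1.0) {
  if (any(m_ref < 0) || any(m_alt < 0)) stop("medians must be non-negative")
  fr <- pmax(m_ref, floor)
  fa <- pmax(m_alt, floor)
  fc <- pmax(fr, fa) / pmin(fr, fa)
  direction <- ifelse(fa > fr, "up", ifelse(fa < fr, "down", NA_character_))
  list(fc = fc, direction = direction)
}

#' Designate robust DEGs by the floored fold-change filter
#'
#' Every shared gene of the contrast receives a record; `robust` is shared
#' AND fc >= `fc_min` (inclusive). Genes whose floored medians are equal
#' (fc = 1) carry no direction and never pass the filter.
#'
#' @param contrast a `contrast_result` from [run_contrast()], or a data.frame
#'   with `gene_id` and logical `shared`.
#' @param tpm a [tpm_matrix()] containing both contrast groups.
#' @param ref,alt group labels (taken from the contrast attribute when
#'   absent).
#' @param fc_min robust fold-change threshold (inclusive; default 1.5).
#' @param tpm_floor median floor (default 1 TPM).
#' @return data.frame with `gene_id`, `median_tpm_ref`, `median_tpm_alt`,
#'   floored medians, `fc`, `direction`, `shared`, `robust`.
#' @export
robust_degs <- function(contrast, tpm, ref = NULL, alt = NULL, fc_min = 1.5,
                        tpm_floor = 1.0) {
  ct <- attr(contrast, "contrast")
  ref <- ref %||% unname(ct["ref"])
  alt <- alt %||% unname(ct["alt"])
  missing <- setdiff(contrast$gene_id, rownames(tpm$tpm))
  if (length(missing)) {
    stop("contrast gene(s) absent from the TPM matrix: ",
         paste(head(missing), collapse = ", "))
  }
  m_ref <- group_median_tpm(tpm, ref)[contrast$gene_id]
  m_alt <- group_median_tpm(tpm, alt)[contrast$gene_id]
  fc <- median_fold_change(m_ref, m_alt, floor = tpm_floor)
  out <- data.frame(
    gene_id = contrast$gene_id,
    median_tpm_ref = unname(m_ref),
    median_tpm_alt = unname(m_alt),
    floored_ref = unname(pmax(m_ref, tpm_floor)),
    floored_alt = unname(pmax(m_alt, tpm_floor)),
    fc = unname(fc$fc),
    direction = unname(fc$direction),
    shared = contrast$shared,
    stringsAsFactors = FALSE)
  out$robust <- out$shared & out$fc >= fc_min
  attr(out, "contrast") <- c(ref = ref, alt = alt)
  out
}

#' Up- or down-regulated robust gene list of a contrast
#'
#' @param degs output of [robust_degs()].
#' @param direction `"up"` or `"down"` (alternative relative to reference).
#' @return character vector of gene ids.
#' @export
robust_gene_list <- function(degs, direction = c("up", "down")) {
  direction <- match.arg(direction)
  degs$gene_id[degs$robust & !is.na(degs$direction) &
                 degs$direction == direction]
}

#' Summarize contrasts in the standard report layout
#'
#' One row per contrast with the shared count, the count surviving the
#' fc >= 1.5 filter, and its split into down- and up-regulated genes
#' (relative to the reference group).
#'
#' @param deg_list named list of [robust_degs()] outputs (names are contrast
#'   labels).
#' @return data.frame with columns `contrast`, `shared`, `after_fc_filter`,
#'   `down`, `up`.
#' @export
deg_summary <- function(deg_list) {
  rows <- lapply(names(deg_list), function(nm) {
    d <- deg_list[[nm]]
    data.frame(contrast = nm,
               shared = sum(d$shared),
               after_fc_filter = sum(d$robust),
               down = sum(d$robust & !is.na(d$direction) &
                            d$direction == "down"),
               up = sum(d$robust & !is.na(d$direction) & d$direction == "up"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Derived fold-ratio lines between two contrasts of a summary
#'
#' Reports how many times more DEGs one contrast yielded than another, before
#' (shared) and after the fold-change filter, rounded to one decimal place —
#' the ratio lines quoted alongside per-contrast DEG counts.
#'
#' @param summary a [deg_summary()]-shaped data.frame (columns `contrast`,
#'   `shared`, `after_fc_filter`).
#' @param numerator,denominator contrast labels.
#' @return list with `before` and `after` ratios (1 d.p.).
#' @export
summary_fold_ratios <- function(summary, numerator, denominator) {
  i <- match(numerator, summary$contrast)
  j <- match(denominator, summary$contrast)
  if (is.na(i) || is.na(j)) stop("contrast label not found in summary")
  list(before = round(summary$shared[i] / summary$shared[j], 1),
       after = round(summary$after_fc_filter[i] / summary$after_fc_filter[j],
                     1))
}
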