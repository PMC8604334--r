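# Lightweight S3 containers shared across modules.

#' Construct a count matrix with sample-to-group labels
#'
#' Genes are rows, samples are columns. Every sample must carry a group label;
#' counts must be non-negative integers (storage mode may be double).
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param groups named character vector mapping sample id to group label, or
#'   an unnamed vector in column order.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `groups`.
#' @export
count_matrix <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have gene rownames and sample colnames")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(names(groups))) {
    if (length(groups) != ncol(counts)) {
      stop("`groups` length must match the number of samples")
    }
    names(groups) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing)) {
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  }
  structure(list(counts = counts,
                 groups = as.character(groups[colnames(counts)])),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                               table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

group_samples <- function(cm, group) {
  idx <- which(cm$groups == group)
  if (!length(idx)) stop("unknown group label: ", group)
  idx
}

#' Construct a TPM matrix
#'
#' Same axes as [count_matrix()]; each column sums to 1e6 (or 0 for an
#' all-zero sample).
#'
#' @param tpm numeric matrix of TPM values, genes x samples.
#' @param groups sample-to-group labels as for [count_matrix()].
#' @return An object of class `tpm_matrix`.
#' @export
tpm_matrix <- function(tpm, groups) {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  cs <- colSums(tpm)
  bad <- cs > 0 & abs(cs - 1e6) / 1e6 > 1e-6
  if (any(bad)) {
    stop("TPM columns must sum to 1e6: ",
         paste(colnames(tpm)[bad], collapse = ", "))
  }
  cm <- count_matrix(tpm, groups) # reuse validation
  structure(list(tpm = tpm, groups = cm$groups), class = "tpm_matrix")
}

#' @export
print.tpm_matrix <- function(x, ...) {
  cat("tpm_matrix:", nrow(x$tpm), "genes x", ncol(x$tpm), "samples\n")
  invisible(x)
}

#' Read a count matrix and sample sheet from TSV files
#'
#' @param counts_path TSV with gene ids in the first column and one column
#'   per sample.
#' @param samples_path TSV with columns `sample_id` and `group`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  tab <- read_tsv(counts_path)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  sheet <- read_tsv(samples_path)
  if (!all(c("sample_id", "group") %in% names(sheet))) {
    stop("sample sheet needs columns `sample_id` and `group`")
  }
  count_matrix(mat, setNames(sheet$group, sheet$sample_id))
}

#' Write a count or TPM matrix as TSV (genes as rows, sample-id header)
#'
#' @param x a `count_matrix` or `tpm_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  mat <- if (inherits(x, "tpm_matrix")) x$tpm else x$counts
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write_tsv(df, path)
}
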