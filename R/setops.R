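# Venn partitioning of gene lists across contrasts sharing one reference.

#' Partition genes by membership signature across contrasts
#'
#' Assigns every gene in the union of the input lists to exactly one region,
#' keyed by its k-character membership signature ("1" = present in that
#' list). Empty regions are included with size 0.
#'
#' @param lists named list (2 to 6 entries) of character gene vectors.
#' @return An object of class `venn_partition`: list with `contrast_names`,
#'   `regions` (named list of gene vectors, one per signature) and `table`
#'   (signature, count, comma-joined genes).
#' @export
venn_partition <- function(lists) {
  if (!length(lists)) stop("empty list map")
  k <- length(lists)
  if (k < 2 || k > 6) stop("between 2 and 6 lists are supported")
  if (is.null(names(lists))) names(lists) <- paste0("set", seq_len(k))
  lists <- lapply(lists, unique)
  universe <- sort(unique(unlist(lists)))
  member <- vapply(lists, function(l) universe %in% l, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  sig <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  all_sigs <- apply(expand.grid(rep(list(0:1), k))[-1, k:1, drop = FALSE], 1,
                    paste, collapse = "")
  regions <- setNames(vector("list", length(all_sigs)), sort(all_sigs))
  for (s in names(regions)) regions[[s]] <- universe[sig == s]
  tab <- data.frame(signature = names(regions),
                    count = vapply(regions, length, integer(1)),
                    genes = vapply(regions, paste, character(1),
                                   collapse = ","),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(contrast_names = names(lists), regions = regions,
                 table = tab),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition over:", paste(x$contrast_names, collapse = ", "), "\n")
  print(x$table[x$table$count > 0, c("signature", "count")], row.names = FALSE)
  invisible(x)
}

#' Genes shared by every list
#'
#' The intersection of all lists; identical to the all-ones region of
#' [venn_partition()].
#'
#' @param lists named list of character gene vectors.
#' @return character vector (sorted).
#' @export
shared_all <- function(lists) {
  if (!length(lists)) stop("empty list map")
  sort(Reduce(intersect, lapply(lists, unique)))
}

#' Write a Venn partition as TSV
#'
#' @param partition a `venn_partition`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_venn_tsv <- function(partition, path) {
  hdr <- paste0("# sets: ", paste(partition$contrast_names, collapse = ", "))
  writeLines(hdr, path)
  suppressWarnings(
    write.table(partition$table, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE, append = TRUE))
  invisible(path)
}
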