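# Shared fixtures and independent oracles, built in code at test time.

# A tiny two-gene flattened model on one chromosome.
toy_models <- function() {
  tx <- data.frame(
    transcript_id = c("TA.1", "TB.1"),
    gene_id = c("GA", "GB"),
    biotype = c("protein_coding", "protein_coding"),
    chrom = "chrT", strand = "+", stringsAsFactors = FALSE)
  tx$exons <- list(cbind(start = c(1000, 1500), end = c(1199, 1799)),
                   cbind(start = 5000, end = 5999))
  class(tx) <- c("transcript_records", "data.frame")
  flatten_gene_models(tx)
}

# Brute-force per-base boolean-mask merge oracle for one gene's exons.
mask_merge <- function(exons) {
  lo <- min(exons[, 1])
  hi <- max(exons[, 2])
  mask <- logical(hi - lo + 1)
  for (i in seq_len(nrow(exons))) {
    mask[(exons[i, 1]:exons[i, 2]) - lo + 1] <- TRUE
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  cbind(start = starts[keep] + lo - 1, end = ends[keep] + lo - 1)
}

# Build transcript_records directly from a list of per-transcript specs.
make_tx <- function(...) {
  specs <- list(...)
  tx <- data.frame(
    transcript_id = vapply(specs, `[[`, character(1), "id"),
    gene_id = vapply(specs, `[[`, character(1), "gene"),
    biotype = vapply(specs, function(s) s$biotype %||% "protein_coding",
                     character(1)),
    chrom = vapply(specs, function(s) s$chrom %||% "chr1", character(1)),
    strand = "+", stringsAsFactors = FALSE)
  tx$exons <- lapply(specs, `[[`, "exons")
  class(tx) <- c("transcript_records", "data.frame")
  tx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Birth-time groups from the bundled demographics table.
birth_time_groups <- function(cohort, grouping) {
  bt <- read.delim(system.file("extdata", "birth_times.tsv",
                               package = "myoseq"))
  sub <- bt[bt$cohort == cohort & bt$grouping == grouping, ]
  lapply(split(sub$time, sub$group)[unique(sub$group)], times_to_minutes)
}
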