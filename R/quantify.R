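# Fragment counting over flattened gene models: NH:i:1 uniqueness filter,
# strict exon-overlap rule, and TPM computation.

# Vectorized core: given per-record aligned blocks, NH and chromosome, return
# per-record assignment (gene id or NA) and a failure reason.
# `blocks` is a GRanges of M-operation ranges with an `idx` metadata column;
# `aligned` is the per-record total of aligned bases.
assign_records <- function(blocks, aligned, nh, chroms, models,
                           min_overlap_fraction = 0.9) {
  n <- length(aligned)
  gene <- rep(NA_character_, n)
  status <- rep("low_overlap", n)
  known <- chroms %in% unique(as.character(
    GenomicRanges::seqnames(models$exons)))
  status[!known] <- "unmatched_chrom"
  blocks <- blocks[known[blocks$idx]]
  if (length(blocks)) {
    hits <- GenomicRanges::findOverlaps(blocks, models$exons,
                                        ignore.strand = TRUE)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      ovw <- GenomicRanges::width(GenomicRanges::pintersect(
        blocks[q], models$exons[s], ignore.strand = TRUE))
      rec <- blocks$idx[q]
      gid <- models$exons$gene_id[s]
      key <- paste(rec, gid, sep = "\r")
      tot <- tapply(ovw, key, sum)
      parts <- strsplit(names(tot), "\r", fixed = TRUE)
      rec_i <- as.integer(vapply(parts, `[`, character(1), 1))
      gid_i <- vapply(parts, `[`, character(1), 2)
      frac <- as.numeric(tot) / aligned[rec_i]
      ok <- frac > min_overlap_fraction
      if (any(ok)) {
        n_ok <- tabulate(rec_i[ok], nbins = n)
        first <- !duplicated(rec_i[ok])
        gene[rec_i[ok][first]] <- gid_i[ok][first]
        status[rec_i[ok][first]] <- "assigned"
        amb <- which(n_ok >= 2)
        gene[amb] <- NA_character_
        status[amb] <- "ambiguous"
      }
    }
  }
  multi <- nh != 1
  gene[multi] <- NA_character_
  status[multi] <- "multimapped"
  list(gene = gene, status = status)
}

#' Assign one aligned mate to a gene by the strict exon-overlap rule
#'
#' A read is assigned to the gene whose merged exons cover strictly more than
#' `min_overlap_fraction` of its aligned (CIGAR M) bases; soft-clipped bases
#' and N gaps are not part of the denominator. Reads with NH != 1 are never
#' assigned. If two or more genes qualify the read is ambiguous and
#' unassigned.
#'
#' @param chrom chromosome of the alignment.
#' @param blocks two-column start/end matrix of aligned blocks (1-based
#'   inclusive).
#' @param nh value of the NH tag (number of reported hits).
#' @param models a `flat_gene_models` object.
#' @param min_overlap_fraction strict lower bound on the exon-overlap
#'   fraction (default 0.9, i.e. the ">90%" rule).
#' @return list with `gene_id` (or `NA`) and `status` (one of `assigned`,
#'   `multimapped`, `ambiguous`, `low_overlap`, `unmatched_chrom`).
#' @export
assign_read <- function(chrom, blocks, nh, models,
                        min_overlap_fraction = 0.9) {
  blocks <- matrix(as.numeric(blocks), ncol = 2)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(blocks[, 1], blocks[, 2]),
                               idx = rep(1L, nrow(blocks)))
  res <- assign_records(gr, sum(blocks[, 2] - blocks[, 1] + 1), nh, chrom,
                        models, min_overlap_fraction)
  list(gene_id = res$gene[1], status = res$status[1])
}

#' Count uniquely mapped fragments per flattened gene
#'
#' Reads a SAM or BAM file (or a [simulate_reads()] object), groups primary
#' alignments into fragments by query name, and counts a fragment for a gene
#' when every mapped mate individually passes [assign_read()] for that same
#' gene. Rejected fragments are tallied by reason, so that assigned plus
#' rejected always equals the fragment total.
#'
#' @param sam path to a SAM/BAM file or a `sim_reads` object.
#' @param models a `flat_gene_models` object.
#' @param min_overlap_fraction strict exon-overlap threshold (default 0.9).
#' @return list with `counts` (named per-gene fragment counts), `log` (named
#'   rejection tallies) and `n_fragments`.
#' @export
count_sample <- function(sam, models, min_overlap_fraction = 0.9) {
  if (inherits(sam, "sim_reads")) {
    tmp <- tempfile(fileext = ".sam")
    write_sam(sam, tmp)
    on.exit(unlink(tmp), add = TRUE)
    sam <- tmp
  }
  if (grepl("\\.sam$", sam, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(bam), add = TRUE)
  } else {
    bam <- sam
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = "NH", flag = flags)
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(rec$qname)
  if (!n) {
    return(list(counts = setNames(integer(nrow(models$genes)),
                                  models$genes$gene_id),
                log = c(assigned = 0L), n_fragments = 0L))
  }
  if (anyNA(rec$pos) || anyNA(rec$cigar)) {
    stop("unparseable alignment record(s): ",
         paste(head(rec$qname[is.na(rec$pos) | is.na(rec$cigar)]),
               collapse = ", "))
  }
  nh <- rec$tag$NH
  if (is.null(nh)) stop("alignments carry no NH tag")
  nh[is.na(nh)] <- 1L
  chroms <- as.character(rec$rname)
  rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    rec$cigar, pos = rec$pos, ops = c("M", "=", "X"))
  widths <- sum(IRanges::width(rng))
  flat <- unlist(rng, use.names = FALSE)
  idx <- rep(seq_len(n), lengths(rng))
  blocks <- GenomicRanges::GRanges(chroms[idx], flat, idx = idx)
  res <- assign_records(blocks, widths, nh, chroms, models,
                        min_overlap_fraction)

  frag <- split(seq_len(n), rec$qname)
  reasons <- c("multimapped", "ambiguous", "unmatched_chrom", "low_overlap")
  counts <- setNames(integer(nrow(models$genes)), models$genes$gene_id)
  tally <- setNames(integer(5L), c(reasons, "discordant_gene"))
  for (i in seq_along(frag)) {
    st <- res$status[frag[[i]]]
    gn <- res$gene[frag[[i]]]
    if (all(st == "assigned")) {
      if (length(unique(gn)) == 1L) {
        counts[gn[1]] <- counts[gn[1]] + 1L
      } else {
        tally["discordant_gene"] <- tally["discordant_gene"] + 1L
      }
    } else {
      r <- reasons[min(match(st, reasons), na.rm = TRUE)]
      tally[r] <- tally[r] + 1L
    }
  }
  list(counts = counts,
       log = c(assigned = sum(counts), tally),
       n_fragments = length(frag))
}

#' Build a count matrix by counting several samples
#'
#' @param sams named list of SAM/BAM paths or `sim_reads` objects (names are
#'   sample ids).
#' @param models a `flat_gene_models` object.
#' @param groups sample-to-group labels (named by sample id).
#' @param min_overlap_fraction strict exon-overlap threshold.
#' @return list with `counts` (a [count_matrix()]) and `logs` (per-sample
#'   rejection tallies).
#' @export
count_samples <- function(sams, models, groups, min_overlap_fraction = 0.9) {
  stopifnot(length(names(sams)) == length(sams))
  per <- lapply(sams, count_sample, models = models,
                min_overlap_fraction = min_overlap_fraction)
  mat <- do.call(cbind, lapply(per, `[[`, "counts"))
  colnames(mat) <- names(sams)
  list(counts = count_matrix(mat, groups),
       logs = lapply(per, `[[`, "log"))
}

#' Compute TPM from gene counts and exonic lengths
#'
#' rate_g = count_g / (exonic_length_g / 1000); TPM_g = rate_g / sum(rates)
#' * 1e6. An all-zero sample yields all-zero TPM.
#'
#' @param counts a [count_matrix()] or a named per-gene count vector.
#' @param lengths a `flat_gene_models` object or named exonic lengths in bp.
#' @return A [tpm_matrix()] (or named vector when `counts` is a vector).
#' @export
compute_tpm <- function(counts, lengths) {
  if (inherits(lengths, "flat_gene_models")) lengths <- exonic_lengths(lengths)
  one <- function(cnt) {
    missing <- setdiff(names(cnt), names(lengths))
    if (length(missing)) {
      stop("counted gene(s) missing from models: ",
           paste(head(missing), collapse = ", "))
    }
    len <- lengths[names(cnt)]
    if (any(len <= 0)) stop("exonic lengths must be positive")
    rate <- cnt / (len / 1000)
    if (sum(rate) == 0) return(rate * 0)
    rate / sum(rate) * 1e6
  }
  if (inherits(counts, "count_matrix")) {
    tpm <- apply(counts$counts, 2, one)
    rownames(tpm) <- rownames(counts$counts)
    tpm_matrix(tpm, setNames(counts$groups, colnames(counts$counts)))
  } else {
    one(counts)
  }
}
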