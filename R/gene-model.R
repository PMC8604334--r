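# Flattened gene models: annotation loading, retained-intron exclusion,
# per-gene exon merging, GFF3 export.

#' Load transcript records from GFF3 or GTF annotation
#'
#' Reads gene/transcript/exon features and groups exons under their parent
#' transcript. The transcript biotype (or `tag`) attribute is carried through
#' so retained-intron transcripts can be excluded downstream. Unknown feature
#' types are ignored.
#'
#' @param path a GFF3 or GTF file, or a character vector of annotation lines
#'   (autodetected dialect).
#' @return A data.frame of class `transcript_records` with columns
#'   `transcript_id`, `gene_id`, `biotype`, `chrom`, `strand` and a list
#'   column `exons` (two-column start/end matrices, 1-based inclusive).
#' @export
load_annotation <- function(path) {
  if (length(path) > 1L || grepl("\n", path[1]) || !file.exists(path[1])) {
    lines <- if (length(path) == 1L) strsplit(path, "\n")[[1]] else path
    fmt <- if (any(grepl("gene_id \"", lines))) ".gtf" else ".gff3"
    tmp <- tempfile(fileext = fmt)
    writeLines(lines, tmp)
    on.exit(unlink(tmp))
    path <- tmp
  }
  fmt <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)

  get_attr <- function(idx, nm) {
    if (!nm %in% names(meta)) return(rep(NA_character_, length(idx)))
    v <- meta[[nm]][idx]
    if (is(v, "List") || is.list(v)) {
      vapply(v, function(e) if (length(e)) as.character(e[1]) else NA_character_,
             character(1))
    } else {
      as.character(v)
    }
  }

  tx_idx <- which(type %in% c("mRNA", "transcript"))
  ex_idx <- which(type == "exon")
  if (!length(ex_idx)) stop("annotation contains no exon features")

  if (fmt == "gtf") {
    tx_id <- get_attr(tx_idx, "transcript_id")
    tx_gene <- get_attr(tx_idx, "gene_id")
    ex_parent <- get_attr(ex_idx, "transcript_id")
    # GTF may omit explicit transcript features; synthesize from exons
    if (!length(tx_idx)) {
      tx_id <- unique(ex_parent)
      tx_gene <- get_attr(ex_idx, "gene_id")[match(tx_id, ex_parent)]
    }
    tx_biotype <- get_attr(tx_idx, "transcript_biotype")
    if (all(is.na(tx_biotype))) tx_biotype <- get_attr(tx_idx, "biotype")
    if (!length(tx_idx)) tx_biotype <- rep(NA_character_, length(tx_id))
  } else {
    tx_id <- get_attr(tx_idx, "ID")
    tx_gene <- get_attr(tx_idx, "Parent")
    ex_parent <- get_attr(ex_idx, "Parent")
    tx_biotype <- get_attr(tx_idx, "biotype")
  }
  tx_tag <- get_attr(tx_idx, "tag")
  tx_biotype <- ifelse(is.na(tx_biotype) | tx_biotype == "",
                       tx_tag, paste(tx_biotype, tx_tag))
  tx_biotype[is.na(tx_biotype)] <- ""
  # Ensembl GFF3 prefixes parents like "transcript:ENST..."
  strip_pfx <- function(x) sub("^(transcript|gene):", "", x)
  tx_id <- strip_pfx(tx_id)
  tx_gene <- strip_pfx(tx_gene)
  ex_parent <- strip_pfx(ex_parent)

  if (anyNA(ex_parent)) {
    stop("exon with no resolvable parent at record(s): ",
         paste(head(ex_idx[is.na(ex_parent)]), collapse = ", "))
  }
  unresolved <- setdiff(unique(ex_parent), tx_id)
  if (length(unresolved) && length(tx_idx)) {
    # exons parented directly on a gene (e.g. flattened GFF re-import):
    # treat each such gene as its own single transcript
    gene_idx <- which(type == "gene")
    gene_ids <- strip_pfx(get_attr(gene_idx, if (fmt == "gtf") "gene_id" else "ID"))
    direct <- unresolved[unresolved %in% gene_ids]
    truly_missing <- setdiff(unresolved, gene_ids)
    if (length(truly_missing)) {
      stop("exon parent(s) not found in annotation: ",
           paste(head(truly_missing), collapse = ", "))
    }
    tx_id <- c(tx_id, direct)
    tx_gene <- c(tx_gene, direct)
    tx_biotype <- c(tx_biotype, rep("", length(direct)))
  } else if (length(unresolved)) {
    stop("exon parent(s) not found in annotation: ",
         paste(head(unresolved), collapse = ", "))
  }

  ex_chrom <- as.character(GenomicRanges::seqnames(gr))[ex_idx]
  ex_strand <- as.character(GenomicRanges::strand(gr))[ex_idx]
  ex_start <- GenomicRanges::start(gr)[ex_idx]
  ex_end <- GenomicRanges::end(gr)[ex_idx]

  ord <- match(ex_parent, tx_id)
  recs <- data.frame(transcript_id = tx_id, gene_id = tx_gene,
                     biotype = tx_biotype, stringsAsFactors = FALSE)
  split_idx <- split(seq_along(ex_idx), ord)
  recs <- recs[as.integer(names(split_idx)), , drop = FALSE]
  recs$chrom <- vapply(split_idx, function(i) ex_chrom[i][1], character(1))
  recs$strand <- vapply(split_idx, function(i) ex_strand[i][1], character(1))
  recs$exons <- lapply(split_idx, function(i) {
    m <- cbind(start = ex_start[i], end = ex_end[i])
    m[order(m[, 1]), , drop = FALSE]
  })
  rownames(recs) <- NULL
  class(recs) <- c("transcript_records", "data.frame")
  recs
}

#' Merge transcripts into flattened, gene-level exon models
#'
#' Transcripts whose biotype (or tag) matches `retained_intron`
#' (case-insensitive) contribute no exons. Remaining exons of each gene are
#' merged into sorted, disjoint intervals; adjacent intervals (gap zero at
#' base level) are merged, since per-base occupancy is identical. Genes whose
#' transcripts are all retained-intron are dropped with a warning, because a
#' zero exonic length is an undefined TPM denominator.
#'
#' @param transcripts a `transcript_records` data.frame from
#'   [load_annotation()].
#' @return An object of class `flat_gene_models`: list with `genes` (a
#'   data.frame with `gene_id`, `chrom`, `strand`, `exonic_length`) and
#'   `exons` (a [GenomicRanges::GRanges] of merged intervals with a `gene_id`
#'   metadata column).
#' @export
flatten_gene_models <- function(transcripts) {
  stopifnot(is.data.frame(transcripts))
  keep <- !grepl("retained_intron", transcripts$biotype, ignore.case = TRUE)
  dropped_genes <- setdiff(transcripts$gene_id, transcripts$gene_id[keep])
  if (length(dropped_genes)) {
    warning("dropping gene(s) with only retained_intron transcripts: ",
            paste(dropped_genes, collapse = ", "))
  }
  tx <- transcripts[keep, , drop = FALSE]
  if (!nrow(tx)) {
    return(structure(list(
      genes = data.frame(gene_id = character(), chrom = character(),
                         strand = character(), exonic_length = integer()),
      exons = GenomicRanges::GRanges()), class = "flat_gene_models"))
  }
  by_gene <- split(seq_len(nrow(tx)), tx$gene_id)
  genes <- lapply(names(by_gene), function(g) {
    i <- by_gene[[g]]
    chroms <- unique(tx$chrom[i])
    if (length(chroms) > 1L) {
      stop("gene ", g, " has transcripts on conflicting chromosomes: ",
           paste(chroms, collapse = ", "))
    }
    ex <- do.call(rbind, tx$exons[i])
    ir <- IRanges::reduce(IRanges::IRanges(ex[, 1], ex[, 2]))
    list(gene_id = g, chrom = chroms, strand = tx$strand[i][1],
         starts = IRanges::start(ir), ends = IRanges::end(ir),
         exonic_length = sum(IRanges::width(ir)))
  })
  gene_df <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    chrom = vapply(genes, `[[`, character(1), "chrom"),
    strand = vapply(genes, `[[`, character(1), "strand"),
    exonic_length = vapply(genes, `[[`, numeric(1), "exonic_length"),
    stringsAsFactors = FALSE)
  n_ex <- vapply(genes, function(g) length(g$starts), integer(1))
  exons <- GenomicRanges::GRanges(
    seqnames = rep(gene_df$chrom, n_ex),
    ranges = IRanges::IRanges(
      unlist(lapply(genes, `[[`, "starts")),
      unlist(lapply(genes, `[[`, "ends"))),
    strand = rep(gene_df$strand, n_ex),
    gene_id = rep(gene_df$gene_id, n_ex))
  structure(list(genes = gene_df, exons = exons), class = "flat_gene_models")
}

#' @export
print.flat_gene_models <- function(x, ...) {
  cat("flat_gene_models:", nrow(x$genes), "genes,",
      length(x$exons), "merged exons\n")
  invisible(x)
}

#' Exonic lengths of flattened gene models
#'
#' @param models a `flat_gene_models` object.
#' @return Named numeric vector of exonic lengths in bp.
#' @export
exonic_lengths <- function(models) {
  setNames(models$genes$exonic_length, models$genes$gene_id)
}

#' Merged exon intervals of one gene
#'
#' @param models a `flat_gene_models` object.
#' @param gene_id gene identifier.
#' @return Two-column matrix of start/end coordinates (1-based inclusive).
#' @export
model_exons <- function(models, gene_id) {
  ex <- models$exons[models$exons$gene_id == gene_id]
  cbind(start = GenomicRanges::start(ex), end = GenomicRanges::end(ex))
}

#' Write flattened gene models as GFF3
#'
#' Emits one `gene` feature per model, one `mRNA` feature (the flattened
#' pseudo-transcript) and one `exon` feature per merged interval, in
#' ascending coordinate order. Output round-trips through
#' [load_annotation()] and [flatten_gene_models()].
#'
#' @param models a `flat_gene_models` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flat_gff <- function(models, path) {
  lines <- "##gff-version 3"
  g <- models$genes
  if (nrow(g)) {
    ord <- order(g$chrom, vapply(seq_len(nrow(g)), function(i) {
      min(GenomicRanges::start(models$exons[models$exons$gene_id == g$gene_id[i]]))
    }, numeric(1)))
    for (i in ord) {
      ex <- model_exons(models, g$gene_id[i])
      gid <- g$gene_id[i]
      tid <- paste0(gid, ".flat")
      lines <- c(
        lines,
        paste(g$chrom[i], "myoseq", "gene", min(ex[, 1]), max(ex[, 2]), ".",
              g$strand[i], ".", paste0("ID=", gid), sep = "\t"),
        paste(g$chrom[i], "myoseq", "mRNA", min(ex[, 1]), max(ex[, 2]), ".",
              g$strand[i], ".",
              paste0("ID=", tid, ";Parent=", gid, ";biotype=flattened"),
              sep = "\t"),
        vapply(seq_len(nrow(ex)), function(j) {
          paste(g$chrom[i], "myoseq", "exon", ex[j, 1], ex[j, 2], ".",
                g$strand[i], ".", paste0("Parent=", tid), sep = "\t")
        }, character(1)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
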