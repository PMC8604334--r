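# Seeded synthetic-data generators with known ground truth. All randomness
# flows from one integer seed through derived per-stream seeds; generators
# never touch the caller's RNG state.

#' Ground-truth record for a simulation
#'
#' @param spiked_gene_ids character vector of truly differential genes.
#' @param spiked_fc named fold changes (>= 1) for spiked genes.
#' @param spiked_direction named `"up"`/`"down"` per spiked gene.
#' @param enriched_term_ids GO term ids planted as enriched.
#' @param seed the seed the simulation was drawn from.
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(spiked_gene_ids = character(),
                      spiked_fc = numeric(),
                      spiked_direction = character(),
                      enriched_term_ids = character(),
                      seed = NA_integer_) {
  if (length(spiked_fc) && any(spiked_fc < 1)) {
    stop("spiked fold changes must be >= 1")
  }
  structure(list(spiked_gene_ids = spiked_gene_ids,
                 spiked_fc = spiked_fc,
                 spiked_direction = spiked_direction,
                 enriched_term_ids = enriched_term_ids,
                 seed = seed),
            class = "sim_truth")
}

#' Simulate a multi-transcript gene annotation
#'
#' Generates a GFF3 annotation in which each gene carries one or more
#' transcripts; a configurable fraction of transcripts is labelled
#' `retained_intron` (such a transcript carries an exon spanning an intron of
#' the gene skeleton, as in real retained-intron isoforms). Unless the
#' fraction is 1, every gene keeps at least one non-retained transcript.
#'
#' @param n_genes number of genes (>= 1).
#' @param transcripts_per_gene transcripts per gene (>= 1).
#' @param retained_intron_fraction probability that a transcript is labelled
#'   retained_intron, in \[0, 1\].
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return An object of class `sim_annotation`: list with `lines` (GFF3
#'   text), `genes` and `transcripts` truth tables.
#' @export
make_annotation <- function(n_genes, transcripts_per_gene = 2,
                            retained_intron_fraction = 0.2, seed = 1) {
  stopifnot(n_genes >= 1, transcripts_per_gene >= 1)
  if (retained_intron_fraction < 0 || retained_intron_fraction > 1) {
    stop("retained_intron_fraction must be in [0, 1]")
  }
  with_seed(derive_seed(seed, "annotation"), {
    genes_per_chrom <- 100L
    lines <- "##gff-version 3"
    gene_rows <- vector("list", n_genes)
    tx_rows <- list()
    cursor <- 1000L
    chrom_i <- 1L
    on_chrom <- 0L
    for (g in seq_len(n_genes)) {
      if (on_chrom >= genes_per_chrom) {
        chrom_i <- chrom_i + 1L
        on_chrom <- 0L
        cursor <- 1000L
      }
      on_chrom <- on_chrom + 1L
      chrom <- sprintf("simChr%d", chrom_i)
      gid <- sprintf("SIMG%05d", g)
      strand <- sample(c("+", "-"), 1)
      k <- sample(2:5, 1)
      widths <- sample(80:300, k, replace = TRUE)
      introns <- if (k > 1) sample(60:400, k - 1, replace = TRUE) else integer()
      starts <- cursor + c(0L, cumsum(widths[-k] + introns))
      ends <- starts + widths - 1L
      retained <- runif(transcripts_per_gene) < retained_intron_fraction
      if (all(retained) && retained_intron_fraction < 1) retained[1] <- FALSE
      gene_rows[[g]] <- data.frame(
        gene_id = gid, chrom = chrom, strand = strand,
        n_transcripts = transcripts_per_gene,
        n_retained = sum(retained), stringsAsFactors = FALSE)
      lines <- c(lines, paste(chrom, "myoseq", "gene", starts[1], ends[k],
                              ".", strand, ".", paste0("ID=", gid),
                              sep = "\t"))
      for (t in seq_len(transcripts_per_gene)) {
        tid <- sprintf("%s.t%d", gid, t)
        if (retained[t]) {
          # exon spanning the intron between two adjacent skeleton exons
          i <- if (k > 1) sample(seq_len(k - 1), 1) else 1L
          ex <- cbind(starts, ends)
          if (k > 1) {
            ex[i, 2] <- ends[i + 1]
            ex <- ex[-(i + 1), , drop = FALSE]
          } else {
            ex[1, 2] <- ex[1, 2] + 200L
          }
          biotype <- "retained_intron"
        } else {
          keep <- runif(k) < 0.8
          if (!any(keep)) keep[sample(k, 1)] <- TRUE
          ex <- cbind(starts[keep], ends[keep])
          biotype <- "protein_coding"
        }
        tx_rows[[length(tx_rows) + 1L]] <- data.frame(
          transcript_id = tid, gene_id = gid, retained = retained[t],
          stringsAsFactors = FALSE)
        lines <- c(lines,
                   paste(chrom, "myoseq", "mRNA", min(ex[, 1]), max(ex[, 2]),
                         ".", strand, ".",
                         paste0("ID=", tid, ";Parent=", gid,
                                ";biotype=", biotype), sep = "\t"),
                   vapply(seq_len(nrow(ex)), function(j) {
                     paste(chrom, "myoseq", "exon", ex[j, 1], ex[j, 2], ".",
                           strand, ".", paste0("Parent=", tid), sep = "\t")
                   }, character(1)))
      }
      cursor <- ends[k] + sample(500:1500, 1)
    }
    structure(list(lines = lines,
                   genes = do.call(rbind, gene_rows),
                   transcripts = do.call(rbind, tx_rows),
                   seed = seed),
              class = "sim_annotation")
  })
}

#' @export
print.sim_annotation <- function(x, ...) {
  cat("sim_annotation:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts (", sum(x$transcripts$retained), "retained_intron )\n")
  invisible(x)
}

#' Write simulated annotation (or any GFF lines) to a file
#'
#' @param x a `sim_annotation` or character vector of lines.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(x, path) {
  lines <- if (inherits(x, "sim_annotation")) x$lines else x
  writeLines(lines, path)
  invisible(path)
}

# Map a transcript-coordinate interval [a, b] (1-based within the
# concatenated merged exons) to genomic (start, end) blocks.
tx_to_blocks <- function(exons, a, b) {
  w <- exons[, 2] - exons[, 1] + 1
  offs <- cumsum(c(0, w[-length(w)]))
  blocks <- NULL
  for (i in seq_len(nrow(exons))) {
    lo <- offs[i] + 1
    hi <- offs[i] + w[i]
    if (b < lo || a > hi) next
    gs <- exons[i, 1] + max(a, lo) - lo
    ge <- exons[i, 1] + min(b, hi) - lo
    blocks <- rbind(blocks, c(gs, ge))
  }
  blocks
}

blocks_to_cigar <- function(blocks) {
  parts <- character()
  for (i in seq_len(nrow(blocks))) {
    if (i > 1) {
      gap <- blocks[i, 1] - blocks[i - 1, 2] - 1
      if (gap > 0) parts <- c(parts, paste0(gap, "N"))
    }
    parts <- c(parts, paste0(blocks[i, 2] - blocks[i, 1] + 1, "M"))
  }
  paste(parts, collapse = "")
}

sam_record <- function(qname, flag, chrom, blocks, nh, rnext = "=",
                       pnext = 0) {
  rl <- sum(blocks[, 2] - blocks[, 1] + 1)
  paste(qname, flag, chrom, blocks[1, 1], 255, blocks_to_cigar(blocks),
        rnext, pnext, 0, strrep("A", rl), strrep("I", rl),
        paste0("NH:i:", nh), sep = "\t")
}

#' Simulate paired-end alignments over flattened gene models
#'
#' Fragments are assigned to genes multinomially by abundance. Clean
#' fragments have both mates fully within the gene's merged exons (spliced
#' CIGARs with N gaps where a mate spans exon junctions) and NH:i:1.
#' A `multimap_fraction` of fragments is written with NH:i:2 plus a secondary
#' alignment; an `offexon_fraction` of the remaining fragments has one mate
#' placed with exon-overlap fraction 0.8 (<= 0.9, so it must fail strict
#' overlap filtering). Ground truth counts only clean fragments.
#'
#' @param models a `flat_gene_models` object.
#' @param abundances non-negative per-gene weights (named, or in
#'   `models$genes` order); must sum to > 0.
#' @param n_fragments number of fragments.
#' @param read_length mate length in bp.
#' @param multimap_fraction fraction of fragments with NH >= 2.
#' @param offexon_fraction fraction of unique fragments with a low-overlap
#'   mate.
#' @param seed integer seed.
#' @return An object of class `sim_reads`: list with `sam_lines`, `truth`
#'   (named clean-fragment counts per gene), `planted` (per-fragment status)
#'   and `n_fragments`.
#' @export
simulate_reads <- function(models, abundances, n_fragments,
                           read_length = 100, multimap_fraction = 0,
                           offexon_fraction = 0, seed = 1) {
  stopifnot(n_fragments >= 1, read_length >= 1)
  gids <- models$genes$gene_id
  if (is.null(names(abundances))) names(abundances) <- gids
  abundances <- abundances[gids]
  if (any(is.na(abundances)) || any(abundances < 0)) {
    stop("abundances must be non-negative and cover all model genes")
  }
  lens <- exonic_lengths(models)
  too_short <- names(lens)[lens < read_length & abundances > 0]
  if (length(too_short)) {
    warning("excluding gene(s) shorter than the read length: ",
            paste(too_short, collapse = ", "))
    abundances[too_short] <- 0
  }
  if (sum(abundances) <= 0) stop("abundances must sum to > 0")
  with_seed(derive_seed(seed, "reads"), {
    frag_gene <- sample(gids, n_fragments, replace = TRUE,
                        prob = abundances / sum(abundances))
    u <- runif(n_fragments)
    status <- ifelse(u < multimap_fraction, "multimapped",
                     ifelse(runif(n_fragments) < offexon_fraction,
                            "offexon", "clean"))
    exon_list <- lapply(gids, function(g) model_exons(models, g))
    names(exon_list) <- gids
    chroms <- setNames(models$genes$chrom, gids)
    sam <- character()
    for (f in seq_len(n_fragments)) {
      g <- frag_gene[f]
      ex <- exon_list[[g]]
      L <- lens[[g]]
      flen <- min(L, 2 * read_length + 50)
      qname <- sprintf("frag%06d", f)
      tstart <- if (L > flen) sample.int(L - flen + 1, 1) else 1L
      b1 <- tx_to_blocks(ex, tstart, tstart + read_length - 1)
      b2 <- tx_to_blocks(ex, tstart + flen - read_length, tstart + flen - 1)
      if (status[f] == "offexon") {
        # one mate anchored at the 3' end, extending past the last exon
        ov <- floor(0.8 * read_length)
        gstart <- ex[nrow(ex), 2] - ov + 1
        b1 <- cbind(gstart, gstart + read_length - 1)
      }
      nh <- if (status[f] == "multimapped") 2L else 1L
      sam <- c(sam,
               sam_record(qname, 99, chroms[[g]], b1, nh, pnext = b2[1, 1]),
               sam_record(qname, 147, chroms[[g]], b2, nh, pnext = b1[1, 1]))
      if (status[f] == "multimapped") {
        shift <- 5000000L
        sam <- c(sam,
                 sam_record(qname, 99 + 256, chroms[[g]], b1 + shift, nh,
                            pnext = b2[1, 1] + shift),
                 sam_record(qname, 147 + 256, chroms[[g]], b2 + shift, nh,
                            pnext = b1[1, 1] + shift))
      }
    }
    sq_len <- tapply(GenomicRanges::end(models$exons),
                     as.character(GenomicRanges::seqnames(models$exons)), max)
    header <- c("@HD\tVN:1.6\tSO:unknown",
                sprintf("@SQ\tSN:%s\tLN:%d", names(sq_len),
                        as.integer(sq_len + 5001000)))
    truth <- table(factor(frag_gene[status == "clean"], levels = gids))
    structure(list(sam_lines = c(header, sam),
                   truth = setNames(as.integer(truth), gids),
                   planted = data.frame(fragment = seq_len(n_fragments),
                                        gene_id = frag_gene, status = status,
                                        stringsAsFactors = FALSE),
                   n_fragments = n_fragments, seed = seed),
              class = "sim_reads")
  })
}

#' Write simulated alignments as a SAM file
#'
#' @param x a `sim_reads` object or character vector of SAM lines.
#' @param path output file (plain-text SAM).
#' @return `path`, invisibly.
#' @export
write_sam <- function(x, path) {
  lines <- if (inherits(x, "sim_reads")) x$sam_lines else x
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a negative-binomial count matrix with spiked DEGs
#'
#' Per-gene baseline means are lognormal; counts are negative binomial with
#' variance mu + phi * mu^2. A `spike_fraction` of genes has its mean
#' multiplied (up) or divided (down) by `spike_fc` in every non-reference
#' group. Per-sample library-size factors are lognormal (sd
#' `libsize_log_sd`) and rescaled to geometric mean 1, so size-factor
#' estimation downstream is non-trivial. Gene lengths are drawn lognormal for
#' TPM computation.
#'
#' @param n_genes number of genes.
#' @param group_sizes integer vector (>= 2 groups) of samples per group; the
#'   first group is the reference.
#' @param baseline_log_mean,baseline_log_sd natural-log scale parameters of
#'   the per-gene baseline mean.
#' @param dispersion NB dispersion phi (scalar or per-gene); 0 gives Poisson.
#' @param spike_fraction fraction of genes that are true DEGs.
#' @param spike_fc fold change (>= 1) applied to spiked genes.
#' @param libsize_log_sd lognormal sd of library-size factors.
#' @param seed integer seed.
#' @return list with `counts` (a [count_matrix()]), `lengths` (named bp
#'   lengths) and `truth` (a [sim_truth()]).
#' @export
simulate_counts <- function(n_genes, group_sizes,
                            baseline_log_mean = log(100),
                            baseline_log_sd = 1, dispersion = 0.1,
                            spike_fraction = 0.1, spike_fc = 4,
                            libsize_log_sd = 0.2, seed = 1) {
  stopifnot(n_genes >= 1, baseline_log_sd > 0)
  if (length(group_sizes) < 2) stop("need at least 2 groups")
  if (spike_fraction < 0 || spike_fraction > 1) {
    stop("spike_fraction must be in [0, 1]")
  }
  if (spike_fc < 1) stop("spike_fc must be >= 1")
  phi <- rep_len(dispersion, n_genes)
  if (any(phi < 0)) stop("dispersion must be non-negative")
  with_seed(derive_seed(seed, "counts"), {
    gids <- sprintf("gene%05d", seq_len(n_genes))
    n_spiked <- floor(spike_fraction * n_genes)
    if (spike_fraction > 0 && n_spiked < 1) {
      warning("spike_fraction * n_genes < 1; no genes spiked")
    }
    spiked <- if (n_spiked >= 1) sort(sample(gids, n_spiked)) else character()
    direction <- setNames(sample(c("up", "down"), length(spiked),
                                 replace = TRUE), spiked)
    base_mean <- exp(rnorm(n_genes, baseline_log_mean, baseline_log_sd))
    names(base_mean) <- gids
    n_samples <- sum(group_sizes)
    groups <- rep(sprintf("G%d", seq_along(group_sizes)), group_sizes)
    sids <- sprintf("s%02d", seq_len(n_samples))
    sf <- exp(rnorm(n_samples, 0, libsize_log_sd))
    sf <- sf / geometric_mean(sf)
    fc_mult <- matrix(1, n_genes, n_samples, dimnames = list(gids, sids))
    nonref <- groups != groups[1]
    if (length(spiked)) {
      mult <- ifelse(direction == "up", spike_fc, 1 / spike_fc)
      fc_mult[spiked, nonref] <- mult
    }
    mu <- base_mean * fc_mult * rep(sf, each = n_genes)
    counts <- matrix(0L, n_genes, n_samples, dimnames = list(gids, sids))
    pois <- phi == 0
    if (any(pois)) {
      counts[pois, ] <- rpois(sum(pois) * n_samples, mu[pois, ])
    }
    if (any(!pois)) {
      counts[!pois, ] <- rnbinom(sum(!pois) * n_samples,
                                 size = 1 / phi[!pois], mu = mu[!pois, ])
    }
    lengths <- setNames(round(exp(rnorm(n_genes, log(2000), 0.5))), gids)
    list(counts = count_matrix(counts, setNames(groups, sids)),
         lengths = lengths,
         truth = sim_truth(spiked_gene_ids = spiked,
                           spiked_fc = setNames(rep(spike_fc,
                                                    length(spiked)), spiked),
                           spiked_direction = direction, seed = seed))
  })
}

#' Simulate a GO annotation with planted enriched terms
#'
#' Every term receives members at a baseline probability; planted terms
#' over-represent the spiked genes of `deg_truth` at the stated odds. Terms
#' cycle through the BP/MF/CC classes.
#'
#' @param genes character vector of gene ids (non-empty).
#' @param n_terms number of GO terms to simulate.
#' @param enriched_terms how many terms to plant as enriched
#'   (<= `n_terms`).
#' @param enrichment_odds odds ratio (>= 1) of spiked-gene membership in
#'   planted terms; 1 gives a null annotation.
#' @param deg_truth a [sim_truth()] carrying spiked gene ids (may be empty).
#' @param seed integer seed.
#' @param base_prob baseline membership probability per (gene, term).
#' @return list with `annotation` (a `go_annotation`, see
#'   [go_annotation()]) and `truth` (a [sim_truth()] with
#'   `enriched_term_ids`).
#' @export
simulate_go <- function(genes, n_terms = 50, enriched_terms = 5,
                        enrichment_odds = 8, deg_truth = NULL, seed = 1,
                        base_prob = 0.05) {
  if (!length(genes)) stop("empty gene list")
  if (enriched_terms > n_terms) stop("enriched_terms must be <= n_terms")
  if (enrichment_odds < 1) stop("enrichment_odds must be >= 1")
  spiked <- if (is.null(deg_truth)) character() else deg_truth$spiked_gene_ids
  with_seed(derive_seed(seed, "go"), {
    term_ids <- sprintf("GO:SIM%04d", seq_len(n_terms))
    classes <- rep(c("BP", "MF", "CC"), length.out = n_terms)
    planted <- if (enriched_terms >= 1) {
      sort(sample(term_ids, enriched_terms))
    } else {
      character()
    }
    p_enriched <- enrichment_odds * base_prob /
      (1 - base_prob + enrichment_odds * base_prob)
    is_spiked <- genes %in% spiked
    rows <- lapply(seq_len(n_terms), function(i) {
      p <- rep(base_prob, length(genes))
      if (term_ids[i] %in% planted) p[is_spiked] <- p_enriched
      member <- runif(length(genes)) < p
      if (!any(member)) return(NULL)
      data.frame(gene_id = genes[member], term_id = term_ids[i],
                 stringsAsFactors = FALSE)
    })
    anno <- go_annotation(
      gene2term = do.call(rbind, rows),
      terms = data.frame(term_id = term_ids, go_class = classes,
                         term_name = sprintf("simulated process %03d",
                                             seq_len(n_terms)),
                         stringsAsFactors = FALSE))
    list(annotation = anno,
         truth = sim_truth(spiked_gene_ids = spiked,
                           enriched_term_ids = planted, seed = seed))
  })
}

#' Simulate qPCR Ct values from a log-linear standard curve
#'
#' Ct = intercept + slope * log10(copies) + Normal(0, ct_noise_sd). A
#' standards table at the given copy levels is generated under the same
#' model.
#'
#' @param true_copies named positive per-sample copy numbers.
#' @param curve_slope Ct change per log10 copies (negative).
#' @param curve_intercept Ct at one copy.
#' @param ct_noise_sd Gaussian Ct noise sd (>= 0).
#' @param seed integer seed.
#' @param standard_copies copy levels for the standards table.
#' @return list with `samples` (sample_id, true_copies, ct) and `standards`
#'   (copies, ct) data frames.
#' @export
simulate_qpcr <- function(true_copies, curve_slope = -10 / 3,
                          curve_intercept = 40, ct_noise_sd = 0.2, seed = 1,
                          standard_copies = 10^(1:6)) {
  if (any(true_copies <= 0)) stop("copy numbers must be positive")
  if (curve_slope >= 0) stop("curve slope must be negative")
  if (ct_noise_sd < 0) stop("ct_noise_sd must be non-negative")
  if (is.null(names(true_copies))) {
    names(true_copies) <- sprintf("sample%02d", seq_along(true_copies))
  }
  with_seed(derive_seed(seed, "qpcr"), {
    ct <- curve_intercept + curve_slope * log10(true_copies) +
      rnorm(length(true_copies), 0, ct_noise_sd)
    std_ct <- curve_intercept + curve_slope * log10(standard_copies) +
      rnorm(length(standard_copies), 0, ct_noise_sd)
    list(samples = data.frame(sample_id = names(true_copies),
                              true_copies = unname(true_copies),
                              ct = unname(ct), stringsAsFactors = FALSE),
         standards = data.frame(copies = standard_copies, ct = std_ct))
  })
}
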