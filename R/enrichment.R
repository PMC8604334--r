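# GO over-representation: expression-based custom background and one-sided
# Fisher (hypergeometric tail) with BH adjustment within each GO class.

#' Construct a GO annotation container
#'
#' @param gene2term data.frame with columns `gene_id`, `term_id`
#'   (many-to-many).
#' @param terms data.frame with columns `term_id`, `go_class` (BP/MF/CC) and
#'   `term_name`.
#' @return An object of class `go_annotation`.
#' @export
go_annotation <- function(gene2term, terms) {
  stopifnot(all(c("gene_id", "term_id") %in% names(gene2term)),
            all(c("term_id", "go_class", "term_name") %in% names(terms)))
  bad <- setdiff(unique(gene2term$term_id), terms$term_id)
  if (length(bad)) {
    stop("annotated term(s) without class metadata: ",
         paste(head(bad), collapse = ", "))
  }
  if (!all(terms$go_class %in% c("BP", "MF", "CC"))) {
    stop("go_class must be one of BP, MF, CC")
  }
  structure(list(gene2term = unique(gene2term[, c("gene_id", "term_id")]),
                 terms = terms),
            class = "go_annotation")
}

#' @export
print.go_annotation <- function(x, ...) {
  cat("go_annotation:", nrow(x$terms), "terms,",
      length(unique(x$gene2term$gene_id)), "genes,",
      nrow(x$gene2term), "gene-term links\n")
  invisible(x)
}

#' Read a GO annotation from two TSV files
#'
#' @param gene2term_path TSV with columns `gene_id`, `term_id`.
#' @param terms_path TSV with columns `term_id`, `go_class`, `term_name`.
#' @return A [go_annotation()].
#' @export
read_go_annotation <- function(gene2term_path, terms_path) {
  go_annotation(read_tsv(gene2term_path), read_tsv(terms_path))
}

#' Read a GAF 2.x gene association file
#'
#' Uses columns 2 (gene id), 5 (GO id) and 9 (aspect: P/F/C mapped to
#' BP/MF/CC). GAF carries no term names, so term ids double as names.
#'
#' @param path GAF file (comment lines starting with `!` are skipped).
#' @return A [go_annotation()].
#' @export
read_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 9
  if (any(short)) stop("GAF records with fewer than 9 columns")
  gene <- vapply(parts, `[`, character(1), 2)
  term <- vapply(parts, `[`, character(1), 5)
  aspect <- vapply(parts, `[`, character(1), 9)
  cls <- c(P = "BP", F = "MF", C = "CC")[aspect]
  if (anyNA(cls)) stop("GAF aspect column must be P, F or C")
  meta <- unique(data.frame(term_id = term, go_class = cls,
                            term_name = term, stringsAsFactors = FALSE))
  dup <- duplicated(meta$term_id)
  go_annotation(data.frame(gene_id = gene, term_id = term,
                           stringsAsFactors = FALSE),
                meta[!dup, ])
}

#' Expression-based enrichment background
#'
#' A gene enters the background when its median TPM is at least `min_median`
#' (inclusive) in at least one of the two compared groups.
#'
#' @param tpm a [tpm_matrix()].
#' @param group_A,group_B the two compared group labels.
#' @param min_median background threshold (default 1.5 TPM).
#' @return character vector of background gene ids.
#' @export
background_genes <- function(tpm, group_A, group_B, min_median = 1.5) {
  ma <- group_median_tpm(tpm, group_A)
  mb <- group_median_tpm(tpm, group_B)
  names(ma)[ma >= min_median | mb >= min_median]
}

#' One-sided Fisher (hypergeometric) GO over-representation
#'
#' For each term annotated to at least one background gene, tests whether the
#' foreground over-represents the term: p = P(X >= k) for X hypergeometric
#' with N background genes, K of them in the term and a foreground of size n.
#' BH adjustment is applied within each GO class by default (use
#' `within_class = FALSE` for a global adjustment). Foreground genes outside
#' the background are dropped with a warning; terms with no background gene
#' are skipped.
#'
#' @param foreground character vector of DEG ids (typically one direction).
#' @param background character vector of background gene ids.
#' @param annotation a [go_annotation()].
#' @param within_class adjust within each GO class (default) or globally.
#' @return data.frame sorted by `p_raw` with columns `term_id`, `term_name`,
#'   `go_class`, `k`, `n`, `K`, `N`, `p_raw`, `p_adj`.
#' @export
fisher_enrich <- function(foreground, background, annotation,
                          within_class = TRUE) {
  stopifnot(inherits(annotation, "go_annotation"))
  background <- unique(background)
  if (!length(background)) stop("empty background")
  foreground <- unique(foreground)
  outside <- setdiff(foreground, background)
  if (length(outside)) {
    warning(length(outside), " foreground gene(s) outside the background ",
            "were dropped")
    foreground <- intersect(foreground, background)
  }
  g2t <- annotation$gene2term
  g2t <- g2t[g2t$gene_id %in% background, , drop = FALSE]
  if (!nrow(g2t)) {
    return(data.frame(term_id = character(), term_name = character(),
                      go_class = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_raw = numeric(),
                      p_adj = numeric()))
  }
  N <- length(background)
  n <- length(foreground)
  K <- table(g2t$term_id)
  in_fg <- g2t$gene_id %in% foreground
  k <- table(factor(g2t$term_id[in_fg], levels = names(K)))
  meta <- annotation$terms[match(names(K), annotation$terms$term_id), ]
  p_raw <- phyper(as.integer(k) - 1, as.integer(K), N - as.integer(K), n,
                  lower.tail = FALSE)
  out <- data.frame(term_id = names(K),
                    term_name = meta$term_name,
                    go_class = meta$go_class,
                    k = as.integer(k), n = n, K = as.integer(K), N = N,
                    p_raw = p_raw, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  if (within_class) {
    for (cl in unique(out$go_class)) {
      sel <- out$go_class == cl
      out$p_adj[sel] <- bh_adjust(out$p_raw[sel])
    }
  } else {
    out$p_adj <- bh_adjust(out$p_raw)
  }
  out <- out[order(out$p_raw, out$term_id), ]
  rownames(out) <- NULL
  out
}
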