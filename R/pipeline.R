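# End-to-end orchestration: counts -> TPM -> consensus DE -> robust filter ->
# Venn -> enrichment, from a single YAML-style configuration, with a run log
# and report-layout summaries.

#' Read a pipeline configuration from YAML
#'
#' Thresholds missing from the file take the workflow defaults:
#' alpha = 0.05, min_methods = 2, fc_min = 1.5, tpm_floor = 1,
#' background_min_median = 1.5, min_overlap_fraction = 0.9.
#'
#' @param path YAML file with `paths` (counts/samples or
#'   annotation/alignments, optional `lengths`, optional `go_annotation`),
#'   `contrasts` (list of `alt:ref` strings or two-element lists), optional
#'   `thresholds` and `seed`.
#' @return A validated config list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  defaults <- list(alpha = 0.05, min_methods = 2, fc_min = 1.5,
                   tpm_floor = 1.0, background_min_median = 1.5,
                   min_overlap_fraction = 0.9)
  th <- cfg$thresholds %||% list()
  for (nm in names(defaults)) th[[nm]] <- th[[nm]] %||% defaults[[nm]]
  if (any(unlist(th) <= 0)) stop("thresholds must be positive")
  cfg$thresholds <- th
  cfg$seed <- cfg$seed %||% 1L
  if (is.null(cfg$contrasts) || !length(cfg$contrasts)) {
    stop("config must list at least one contrast")
  }
  cfg$contrasts <- lapply(cfg$contrasts, function(ct) {
    if (is.character(ct) && length(ct) == 1) ct <- strsplit(ct, ":")[[1]]
    ct <- unname(unlist(ct))
    if (length(ct) != 2) stop("a contrast must be `alt:ref`")
    c(alt = ct[1], ref = ct[2])
  })
  refs <- unique(vapply(cfg$contrasts, `[[`, character(1), "ref"))
  if (length(refs) != 1) {
    stop("all contrasts must share one reference group (found: ",
         paste(refs, collapse = ", "), ")")
  }
  cfg
}

#' Run the full consensus DEG pipeline
#'
#' Starting from a count matrix (or alignments plus annotation), computes
#' TPM, the PCA overview, the three-method consensus per contrast, the
#' floored fold-change filter, up/down Venn partitions across contrasts and
#' (when a GO annotation is supplied) per-contrast per-direction enrichment.
#' All outputs are written as TSV under `out_dir` together with a run log
#' recording every threshold and the seed. Identical configuration and
#' inputs reproduce identical outputs.
#'
#' @param config a config list from [read_pipeline_config()] (or constructed
#'   in code and passed through the same validation), or a path to a YAML
#'   file. For in-code use, `config$data` may directly hold `counts` (a
#'   [count_matrix()]), `lengths` and optionally `go` (a [go_annotation()]).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `tpm`, `pca`, `contrasts`, `degs`,
#'   `summary`, `venn`, `enrichment` and `log`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  th <- config$thresholds
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("seed\t%s", config$seed),
                 vapply(names(th), function(nm) {
                   sprintf("threshold.%s\t%s", nm, th[[nm]])
                 }, character(1)))

  # --- inputs ---------------------------------------------------------------
  data <- config$data %||% list()
  if (is.null(data$counts)) {
    paths <- config$paths %||% list()
    if (!is.null(paths$counts)) {
      data$counts <- read_count_matrix(paths$counts, paths$samples)
      if (!is.null(paths$lengths)) {
        lt <- read_tsv(paths$lengths)
        data$lengths <- setNames(lt[[2]], lt[[1]])
      }
    } else if (!is.null(paths$annotation)) {
      models <- flatten_gene_models(load_annotation(paths$annotation))
      sheet <- read_tsv(paths$samples)
      sams <- setNames(as.list(sheet$path), sheet$sample_id)
      counted <- count_samples(sams, models,
                               setNames(sheet$group, sheet$sample_id),
                               min_overlap_fraction = th$min_overlap_fraction)
      data$counts <- counted$counts
      data$lengths <- exonic_lengths(models)
      write_matrix_tsv(data$counts, file.path(out_dir, "counts.tsv"))
    } else {
      stop("config must provide either a count matrix or alignments")
    }
    if (!is.null(paths$go_annotation)) {
      if (file.exists(paths$go_annotation)) {
        data$go <- if (grepl("\\.gaf$", paths$go_annotation)) {
          read_gaf(paths$go_annotation)
        } else {
          read_go_annotation(paths$go_annotation, paths$go_terms)
        }
      } else {
        log_lines <- c(log_lines,
                       "note\tGO annotation path missing; enrichment skipped")
      }
    }
  }
  counts <- data$counts
  groups <- unique(counts$groups)
  for (ct in config$contrasts) {
    if (!all(ct %in% groups)) {
      stop("contrast group(s) absent from the sample sheet: ",
           paste(setdiff(ct, groups), collapse = ", "))
    }
  }
  if (is.null(data$lengths)) stop("gene lengths are required to compute TPM")

  # --- TPM and PCA ----------------------------------------------------------
  tpm <- compute_tpm(counts, data$lengths)
  write_matrix_tsv(tpm, file.path(out_dir, "tpm.tsv"))
  pca <- transform_and_pca(counts)
  write_tsv(data.frame(sample_id = rownames(pca$coordinates),
                       group = pca$groups, pca$coordinates,
                       check.names = FALSE),
            file.path(out_dir, "pca.tsv"))

  # --- consensus DE + robust filter per contrast -----------------------------
  contrasts <- list()
  degs <- list()
  for (ct in config$contrasts) {
    label <- sprintf("%s_vs_%s", ct["alt"], ct["ref"])
    res <- run_contrast(counts, ref = ct[["ref"]], alt = ct[["alt"]],
                        alpha = th$alpha, min_methods = th$min_methods,
                        seed = config$seed)
    dg <- robust_degs(res, tpm, fc_min = th$fc_min, tpm_floor = th$tpm_floor)
    contrasts[[label]] <- res
    degs[[label]] <- dg
    write_tsv(res, file.path(out_dir, paste0("contrast_", label, ".tsv")))
    write_tsv(dg, file.path(out_dir, paste0("degs_", label, ".tsv")))
  }
  summary <- deg_summary(degs)
  write_tsv(summary, file.path(out_dir, "deg_summary.tsv"))

  # --- Venn partitions across contrasts --------------------------------------
  venn <- list()
  if (length(degs) >= 2) {
    for (dir in c("up", "down")) {
      lists <- lapply(degs, robust_gene_list, direction = dir)
      venn[[dir]] <- venn_partition(lists)
      write_venn_tsv(venn[[dir]], file.path(out_dir,
                                            paste0("venn_", dir, ".tsv")))
    }
  }

  # --- enrichment -----------------------------------------------------------
  enrichment <- list()
  if (!is.null(data$go)) {
    for (label in names(degs)) {
      ct <- config$contrasts[[match(label, names(degs))]]
      bg <- background_genes(tpm, ct[["ref"]], ct[["alt"]],
                             min_median = th$background_min_median)
      for (dir in c("up", "down")) {
        fg <- intersect(robust_gene_list(degs[[label]], dir), bg)
        if (!length(fg)) next
        key <- paste0(label, "_", dir)
        enrichment[[key]] <- fisher_enrich(fg, bg, data$go)
        write_tsv(enrichment[[key]],
                  file.path(out_dir, paste0("enrichment_", key, ".tsv")))
      }
    }
  } else {
    log_lines <- c(log_lines, "note\tno GO annotation supplied; enrichment skipped")
  }

  writeLines(log_lines, file.path(out_dir, "run_log.tsv"))
  invisible(list(tpm = tpm, pca = pca, contrasts = contrasts, degs = degs,
                 summary = summary, venn = venn, enrichment = enrichment,
                 log = log_lines))
}
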