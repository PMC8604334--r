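test_that("load_annotation reads GFF3 and GTF dialects identically", {
  gff <- c("##gff-version 3",
           "chr1\tx\tgene\t100\t500\t.\t+\t.\tID=G1",
           "chr1\tx\tmRNA\t100\t500\t.\t+\t.\tID=T1;Parent=G1;biotype=protein_coding",
           "chr1\tx\texon\t100\t200\t.\t+\t.\tParent=T1",
           "chr1\tx\texon\t300\t500\t.\t+\t.\tParent=T1")
  gtf <- c(paste0("chr1\tx\ttranscript\t100\t500\t.\t+\t.\t",
                  "gene_id \"G1\"; transcript_id \"T1\"; ",
                  "transcript_biotype \"protein_coding\";"),
           "chr1\tx\texon\t100\t200\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T1\";",
           "chr1\tx\texon\t300\t500\t.\t+\t.\tgene_id \"G1\"; transcript_id \"T1\";")
  f1 <- tempfile(fileext = ".gff3")
  f2 <- tempfile(fileext = ".gtf")
  writeLines(gff, f1)
  writeLines(gtf, f2)
  t1 <- load_annotation(f1)
  t2 <- load_annotation(f2)
  expect_equal(nrow(t1), 1)
  expect_equal(nrow(t1$exons[[1]]), 2)
  expect_identical(t1$exons[[1]], t2$exons[[1]])
  expect_identical(t1$gene_id, t2$gene_id)
  expect_identical(t1$transcript_id, t2$transcript_id)

  # an exon pointing at a parent that exists nowhere is an error naming it
  bad <- c(gff, "chr1\tx\texon\t600\t700\t.\t+\t.\tParent=T9")
  f3 <- tempfile(fileext = ".gff3")
  writeLines(bad, f3)
  expect_error(load_annotation(f3), "T9")

  # malformed coordinates do not parse
  mal <- gff
  mal[4] <- "chr1\tx\texon\tabc\t200\t.\t+\t.\tParent=T1"
  f4 <- tempfile(fileext = ".gff3")
  writeLines(mal, f4)
  expect_error(suppressWarnings(load_annotation(f4)))
})

test_that("flatten_gene_models merges intervals and excludes retained introns", {
  # interval arithmetic: overlap and a separate exon
  tx <- make_tx(list(id = "T1", gene = "G1",
                     exons = cbind(start = c(100, 150, 400),
                                   end = c(200, 300, 500))))
  m <- flatten_gene_models(tx)
  expect_equal(model_exons(m, "G1"),
               cbind(start = c(100, 400), end = c(300, 500)))
  expect_equal(unname(exonic_lengths(m)["G1"]), 302)

  # adjacent intervals merge (per-base occupancy identical)
  adj <- make_tx(list(id = "T1", gene = "G1",
                      exons = cbind(start = c(100, 201), end = c(200, 300))))
  expect_equal(model_exons(flatten_gene_models(adj), "G1"),
               cbind(start = 100, end = 300))

  # retained_intron transcripts contribute no exons
  ri <- make_tx(list(id = "T1", gene = "G1",
                     exons = cbind(start = 100, end = 200)),
                list(id = "T2", gene = "G1", biotype = "retained_intron",
                     exons = cbind(start = 100, end = 500)))
  mri <- flatten_gene_models(ri)
  expect_equal(model_exons(mri, "G1"), cbind(start = 100, end = 200))
  expect_equal(unname(exonic_lengths(mri)["G1"]), 101)

  # case-insensitive matching on biotype or tag text
  ri2 <- make_tx(list(id = "T1", gene = "G1",
                      exons = cbind(start = 100, end = 200)),
                 list(id = "T2", gene = "G1", biotype = "Retained_Intron",
                      exons = cbind(start = 100, end = 500)))
  expect_equal(unname(exonic_lengths(flatten_gene_models(ri2))["G1"]), 101)

  # all-retained gene dropped with a warning
  drop <- make_tx(list(id = "T1", gene = "G1", biotype = "retained_intron",
                       exons = cbind(start = 100, end = 200)),
                  list(id = "T2", gene = "G2",
                       exons = cbind(start = 900, end = 999)))
  expect_warning(md <- flatten_gene_models(drop), "G1")
  expect_identical(md$genes$gene_id, "G2")

  # conflicting chromosomes within one gene
  conf <- make_tx(list(id = "T1", gene = "G1", chrom = "chr1",
                       exons = cbind(start = 100, end = 200)),
                  list(id = "T2", gene = "G1", chrom = "chr2",
                       exons = cbind(start = 100, end = 200)))
  expect_error(flatten_gene_models(conf), "conflicting chromosomes")
})

test_that("merging equals the per-base mask oracle on random annotation", {
  ann <- make_annotation(500, transcripts_per_gene = 3,
                         retained_intron_fraction = 0.3, seed = 13)
  f <- tempfile(fileext = ".gff3")
  write_annotation(ann, f)
  tx <- load_annotation(f)
  models <- suppressWarnings(flatten_gene_models(tx))
  retained <- grepl("retained_intron", tx$biotype, ignore.case = TRUE)
  for (g in models$genes$gene_id) {
    keep <- tx$gene_id == g & !retained
    exons <- do.call(rbind, tx$exons[keep])
    expect_equal(unname(model_exons(models, g)), unname(mask_merge(exons)),
                 info = g)
  }
})

test_that("merging is idempotent and invariant to exon order and duplication", {
  tx <- make_tx(list(id = "T1", gene = "G1",
                     exons = cbind(start = c(400, 100, 150, 150),
                                   end = c(500, 200, 300, 300))))
  m1 <- flatten_gene_models(tx)
  # shuffle and duplicate exons
  tx2 <- make_tx(list(id = "T1", gene = "G1",
                      exons = cbind(start = c(150, 400, 100, 400),
                                    end = c(300, 500, 200, 500))))
  m2 <- flatten_gene_models(tx2)
  expect_identical(exonic_lengths(m1), exonic_lengths(m2))
  expect_identical(model_exons(m1, "G1"), model_exons(m2, "G1"))

  # flatten(flatten(x)): re-load the flat model and flatten again
  f <- tempfile(fileext = ".gff3")
  write_flat_gff(m1, f)
  m3 <- flatten_gene_models(load_annotation(f))
  expect_identical(unname(model_exons(m1, "G1")),
                   unname(model_exons(m3, "G1")))
})

test_that("write_flat_gff round-trips, sorts and handles empty models", {
  ann <- make_annotation(20, 2, 0.2, seed = 5)
  f0 <- tempfile(fileext = ".gff3")
  write_annotation(ann, f0)
  models <- suppressWarnings(flatten_gene_models(load_annotation(f0)))
  f <- tempfile(fileext = ".gff3")
  write_flat_gff(models, f)
  back <- flatten_gene_models(load_annotation(f))
  for (g in models$genes$gene_id) {
    expect_identical(unname(model_exons(models, g)),
                     unname(model_exons(back, g)), info = g)
  }

  # exon lines appear in ascending coordinate order per chromosome
  lines <- readLines(f)
  ex <- lines[grepl("\texon\t", lines)]
  starts <- as.integer(vapply(strsplit(ex, "\t"), `[`, character(1), 4))
  chrom <- vapply(strsplit(ex, "\t"), `[`, character(1), 1)
  for (ch in unique(chrom)) {
    expect_false(is.unsorted(starts[chrom == ch]))
  }

  # empty model list: header only
  empty <- suppressWarnings(flatten_gene_models(
    make_tx(list(id = "T1", gene = "G1", biotype = "retained_intron",
                 exons = cbind(start = 1, end = 10)))))
  f2 <- tempfile(fileext = ".gff3")
  write_flat_gff(empty, f2)
  expect_identical(readLines(f2), "##gff-version 3")
})
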