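test_that("GTF parsing converts coordinates and maps pseudogene subtypes", {
  gtf <- c(
    'chr1\tsrc\tgene\t101\t400\t.\t+\t.\tgene_id "g1"; gene_biotype "protein_coding";',
    'chr1\tsrc\ttranscript\t101\t400\t.\t+\t.\tgene_id "g1"; gene_biotype "protein_coding"; transcript_id "g1.t1";',
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; gene_biotype "protein_coding"; transcript_id "g1.t1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; gene_biotype "protein_coding"; transcript_id "g1.t1";',
    'chr1\tsrc\tgene\t1001\t1500\t.\t-\t.\tgene_id "pg1"; gene_biotype "processed_pseudogene";',
    'chr1\tsrc\ttranscript\t1001\t1500\t.\t-\t.\tgene_id "pg1"; gene_biotype "processed_pseudogene"; transcript_id "pg1.t1";',
    'chr1\tsrc\texon\t1001\t1500\t.\t-\t.\tgene_id "pg1"; gene_biotype "processed_pseudogene"; transcript_id "pg1.t1";')
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  cat <- read_gtf(f)

  ex <- cat$exons[cat$exons$gene_id == "g1", ]
  expect_equal(ex$start, c(100L, 300L))
  expect_equal(ex$end, c(200L, 400L))

  ## the single intron is the gap between the exons in half-open coords
  regs <- derive_regions(cat, flank = 0)
  intr <- regs[regs$gene_id == "g1" & regs$region == "intron", ]
  expect_equal(c(intr$start, intr$end), c(200L, 300L))

  pg <- cat$genes[cat$genes$gene_id == "pg1", ]
  expect_true(pg$is_pseudogene)
  expect_equal(pg$subtype, "processed")
  expect_true(cat$genes$subtype[cat$genes$gene_id == "g1"] %in% NA)
})

test_that("empty and malformed GTF inputs are handled", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(0), f)
  cat <- read_gtf(f)
  expect_s3_class(cat, "pg_catalog")
  expect_equal(nrow(cat$genes), 0)

  writeLines(c("# comment", "chr1\tonly\tthree"), f)
  expect_error(read_gtf(f), "line 2")
})

test_that("GTF round-trip preserves ids and coordinates exactly", {
  cfg <- sim_config(n_genes = 20, seed = 42)
  cat1 <- simulate_genome_annotation(cfg)$catalog
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(cat1, f)
  cat2 <- read_gtf(f)
  ord <- function(x) x[order(x$gene_id), ]
  expect_equal(ord(cat2$genes)[, c("gene_id", "chrom", "start", "end",
                                   "strand", "biotype")],
               ord(cat1$genes)[, c("gene_id", "chrom", "start", "end",
                                   "strand", "biotype")])
  expect_equal(
    dplyr::arrange(cat2$exons, gene_id, start),
    dplyr::arrange(cat1$exons, gene_id, start))
})

test_that("pair_parents counts pairs, unique parents and unpaired flags", {
  cat <- toy_catalog()
  ## extend with two more pseudogenes so 3 pseudogenes map to 2 parents
  cat$genes <- dplyr::bind_rows(
    cat$genes,
    dplyr::mutate(cat$genes[2, ], gene_id = "gC", start = 7000L,
                  end = 7500L),
    dplyr::mutate(cat$genes[2, ], gene_id = "gD", start = 8000L,
                  end = 8500L),
    dplyr::mutate(cat$genes[2, ], gene_id = "gE", start = 9000L,
                  end = 9500L),
    dplyr::mutate(cat$genes[1, ], gene_id = "gF", start = 9600L,
                  end = 9900L))
  map <- tibble::tibble(
    pseudogene_id = c("gB", "gC", "gD"),
    parent_gene_id = c("gA", "gA", "gF"))
  out <- pair_parents(cat, map)
  expect_equal(nrow(out$pairs), 3)
  expect_equal(out$pair_summary$n_unique_parents, 2)
  ## 4 pseudogenes, 3 mapped -> one left unpaired
  expect_equal(out$pair_summary$n_pseudogenes, 4)
  expect_equal(out$pair_summary$n_paired, 3)
  expect_true(out$genes$unpaired[out$genes$gene_id == "gE"])
  expect_false(out$genes$unpaired[out$genes$gene_id == "gB"])

  ## a parent id missing from the catalog is skipped with a warning
  expect_warning(
    out2 <- pair_parents(cat, dplyr::bind_rows(
      map, tibble::tibble(pseudogene_id = "gE", parent_gene_id = "nope"))),
    "skipped")
  expect_equal(nrow(out2$pairs), 3)
})

test_that("derived regions match a position-by-position brute-force labeler", {
  cat <- toy_catalog()
  regs <- derive_regions(cat, flank = 100)
  set.seed(1)
  pos <- sample(500:7000, 150)
  for (p in pos) {
    got <- annotate_peaks_regions(
      tibble::tibble(chrom = "chr1", start = p, end = p + 1L), regs)$region
    expect_equal(got, oracle_label_position(p, "chr1", cat, flank = 100),
                 info = paste("position", p))
  }
})

test_that("TSS windows span flank upstream through flank downstream", {
  cat <- toy_catalog()
  regs <- derive_regions(cat, flank = 100)
  tss_a <- regs[regs$gene_id == "gA" & regs$region == "TSS", ]
  expect_equal(c(tss_a$start, tss_a$end), c(900L, 1100L))
  ## minus-strand gene: the TSS is the right end
  tss_b <- regs[regs$gene_id == "gB" & regs$region == "TSS", ]
  expect_equal(c(tss_b$start, tss_b$end), c(6100L, 6300L))
})

test_that("single-exon and two-exon bodies get the expected labels", {
  cat <- toy_catalog()
  regs <- derive_regions(cat, flank = 0)
  ## gB: single exon, no CDS -> whole body is exon
  b <- regs[regs$gene_id == "gB", ]
  expect_equal(b$region[b$start == 5000], "exon")
  expect_false("intron" %in% b$region)
  ## gA: two exons -> one intron over the gap
  a <- regs[regs$gene_id == "gA", ]
  expect_equal(sum(a$region == "intron"), 1)
  ## gene span is fully covered by non-flank regions with no double count
  cover <- a[a$region %in% c("exon", "intron", "5UTR", "3UTR"), ]
  expect_equal(sum(cover$end - cover$start),
               cat$genes$end[1] - cat$genes$start[1])
})
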