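test_that("BED12 records parse into transcript models with CDS offsets", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    # non-coding: one 1000-nt block, thickStart == thickEnd
    "chr1\t0\t1000\tncGene\t0\t+\t0\t0\t0\t1\t1000,\t0,",
    # 2-exon plus-strand transcript, 100 + 200 nt, CDS over both exons
    "chr2\t100\t700\tgeneB|txB\t0\t+\t150\t600\t0\t2\t100,200,\t0,400,",
    # minus-strand single exon with CDS
    "chr3\t100\t400\tgeneC\t0\t-\t150\t350\t0\t1\t300,\t0,"
  ), bed)
  models <- read_annotation(bed)
  expect_equal(nrow(models), 3)

  nc <- models[models$gene_id == "ncGene", ]
  expect_equal(nc$length, 1000)
  expect_equal(nc$cds_start, nc$cds_end)

  b <- models[models$gene_id == "geneB", ]
  expect_equal(b$transcript_id, "txB")
  expect_equal(b$length, 300)
  # thickStart 150 is 50 nt into exon 1; thickEnd 600 is 100 exonic nt +
  # 100 nt into exon 2
  expect_equal(b$cds_start, 50)
  expect_equal(b$cds_end, 200)

  cc <- models[models$gene_id == "geneC", ]
  # minus strand: transcript 0 is the highest genomic base (399);
  # CDS genomic [150, 350) -> transcript [length - 250, length - 50)
  expect_equal(cc$cds_start, 300 - 250)
  expect_equal(cc$cds_end, 300 - 50)
  expect_equal(transcript_to_genome(cc, 0), 399)
})

test_that("malformed BED12 records fail hard with the line number", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t1000\tok\t0\t+\t0\t0\t0\t1\t1000,\t0,",
               "chr1\t0\t1000\tbad\t0\t+\t0\t0\t0"), bed)
  expect_error(read_annotation(bed), "line 2", class = "meripscan_parse_error")

  writeLines("chr1\t0\t1000\tnoexons\t0\t+\t0\t0\t0\t0\t,\t,", bed)
  expect_error(read_annotation(bed), "no exon", class = "meripscan_parse_error")
})

test_that("longest isoform wins, ties break by transcript id", {
  m <- dplyr::bind_rows(
    make_model("gA", transcript_id = "tx_short",
               exons = tibble::tibble(start = 0, end = 500)),
    make_model("gA", transcript_id = "tx_long",
               exons = tibble::tibble(start = 0, end = 1200)),
    make_model("gB", transcript_id = "tx_only",
               exons = tibble::tibble(start = 0, end = 700)),
    make_model("gC", transcript_id = "tx_z",
               exons = tibble::tibble(start = 0, end = 800)),
    make_model("gC", transcript_id = "tx_a",
               exons = tibble::tibble(start = 100, end = 900)))
  sel <- select_longest_isoform(m)
  expect_equal(nrow(sel), 3)
  expect_equal(sel$transcript_id[sel$gene_id == "gA"], "tx_long")
  expect_equal(sel$transcript_id[sel$gene_id == "gB"], "tx_only")
  expect_equal(sel$transcript_id[sel$gene_id == "gC"], "tx_a")
  # deterministic and idempotent
  expect_identical(select_longest_isoform(sel), sel)
  expect_identical(select_longest_isoform(m[sample(nrow(m)), ]) |>
                     dplyr::arrange(gene_id),
                   sel |> dplyr::arrange(gene_id))
})

test_that("read extension keeps the strand-aware 5' end", {
  plus <- tibble::tibble(chrom = "c", start = 1100, end = 1180, strand = "+")
  ext <- extend_reads(plus, 150)
  expect_equal(c(ext$start, ext$end), c(1100, 1250))

  minus <- tibble::tibble(chrom = "c", start = 1100, end = 1180, strand = "-")
  ext <- extend_reads(minus, 150)
  expect_equal(c(ext$start, ext$end), c(1030, 1180))

  same <- extend_reads(plus, 80)
  expect_equal(c(same$start, same$end), c(1100, 1180))

  expect_error(extend_reads(plus, 60), class = "meripscan_config_error")
})

test_that("reads project onto transcript coordinates exon-aware", {
  m <- make_model(exons = tibble::tibble(start = 1000, end = 2000))
  r <- tibble::tibble(chrom = "chr1", start = 1100, end = 1250, strand = "+",
                      sample = "IP", condition = "c")
  tx <- map_to_transcript(r, m)
  expect_equal(c(tx$start, tx$end), c(100, 250))

  # intronic read maps nowhere
  m2 <- make_model(exons = tibble::tibble(start = c(0, 2000),
                                          end = c(1000, 3000)))
  intronic <- tibble::tibble(chrom = "chr1", start = 1200, end = 1350,
                             strand = "+", sample = "IP", condition = "c")
  expect_equal(nrow(map_to_transcript(intronic, m2)), 0)

  # wrong chromosome is silently empty, not an error
  off <- dplyr::mutate(r, chrom = "chrX")
  expect_equal(nrow(map_to_transcript(off, m)), 0)
})

test_that("junction-spanning reads keep only exonic overlap (per-base oracle)", {
  for (strand in c("+", "-")) {
    m <- make_model(strand = strand,
                    exons = tibble::tibble(start = c(100, 700),
                                           end = c(400, 1100)))
    spans <- list(c(350, 500), c(350, 800), c(50, 1200), c(390, 710))
    for (sp in spans) {
      r <- tibble::tibble(chrom = "chr1", start = sp[1], end = sp[2],
                          strand = strand, sample = "IP", condition = "c")
      got <- map_to_transcript(r, m)
      exp <- brute_tx_interval(m, sp[1], sp[2])
      expect_equal(c(got$start, got$end), unname(exp[c("start", "end")]))
      # interval length equals the exonic overlap, not the genomic span
      expect_equal(got$end - got$start, unname(exp["n_exonic"]))
      expect_lte(got$end, m$length)
    }
  }
})

test_that("genome<->transcript round-trip is the identity on both strands", {
  set.seed(42)
  for (strand in c("+", "-")) {
    m <- make_model(strand = strand,
                    exons = tibble::tibble(start = c(200, 900, 2000),
                                           end = c(600, 1500, 2500)))
    pos <- sample.int(m$length, 200) - 1
    g <- transcript_to_genome(m, pos)
    expect_equal(genome_to_transcript_pos(m, g), pos)
  }
})

test_that("BED12 writer round-trips through the reader", {
  m <- dplyr::bind_rows(
    make_model("gP", strand = "+", cds_start = 120, cds_end = 600,
               exons = tibble::tibble(start = c(100, 700), end = c(400, 1100))),
    make_model("gM", strand = "-", cds_start = 50, cds_end = 500,
               exons = tibble::tibble(start = c(10, 800), end = c(500, 1200))))
  path <- withr::local_tempfile(fileext = ".bed")
  write_annotation_bed12(m, path)
  back <- read_annotation(path) |> dplyr::arrange(gene_id)
  m <- m |> dplyr::arrange(gene_id)
  expect_equal(back$length, m$length)
  expect_equal(back$cds_start, m$cds_start)
  expect_equal(back$cds_end, m$cds_end)
  expect_equal(back$exons, m$exons)
})
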