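test_that("the generator is deterministic and honours counts", {
  s1 <- simulate_merip(seed = 1, n_genes = 50, coverage = 5)
  s2 <- simulate_merip(seed = 1, n_genes = 50, coverage = 5)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$sequences, s2$sequences)

  expect_equal(nrow(s1$transcripts), 50)
  expect_equal(length(s1$sequences), 50)
  expect_equal(nrow(s1$sites), 50)  # one site per gene by default

  s3 <- simulate_merip(seed = 2, n_genes = 50, coverage = 5)
  expect_false(identical(s1$reads, s3$reads))
})

test_that("transcript models are internally consistent", {
  sim <- simulate_merip(seed = 3, n_genes = 20, coverage = 2, n_exons = 3)
  m <- sim$transcripts
  expect_true(all(purrr::map_dbl(m$exons, ~ sum(.x$end - .x$start)) == m$length))
  expect_true(all(m$cds_start > 0 & m$cds_end < m$length))
  # multi-exon: genomic span exceeds transcript length
  span <- purrr::map_dbl(m$exons, ~ max(.x$end) - min(.x$start))
  expect_true(all(span > m$length))
  # transcript sequence length matches the model
  expect_equal(unname(nchar(sim$sequences[m$gene_id])), m$length)
  # planted sites carry a GGACU (DNA: GGACT) centred on the site
  for (i in seq_len(nrow(sim$sites))) {
    s <- sim$sites[i, ]
    expect_equal(substr(sim$sequences[[s$gene_id]], s$position - 1, s$position + 3),
                 "GGACT")
  }
})

test_that("planted-site truth reflects the knockdown design", {
  sim <- simulate_merip(seed = 1, n_genes = 200, coverage = 2,
                        fto_target_fraction = 0.5)
  n_resp <- sum(sim$sites$responds)
  # binomial(200, 0.5): within 4 SD of 100
  expect_lt(abs(n_resp - 100), 4 * sqrt(200 * 0.25))
  # responder (FTO-target) sites: hypomethylated under control, restored on
  # knockdown by the knockdown_effect factor, and UTR-located
  resp <- dplyr::filter(sim$sites, responds)
  expect_equal(resp$enrichment_knockdown, resp$enrichment_control * 4)
  expect_true(all(resp$region %in% c("utr5", "utr3")))
  const <- dplyr::filter(sim$sites, !responds)
  expect_equal(const$enrichment_knockdown, const$enrichment_control)
  expect_equal(unique(const$enrichment_control), 8)

  # null knockdown: both conditions have identical expected enrichment
  null <- simulate_merip(seed = 1, n_genes = 10, coverage = 2,
                         knockdown_effect = 1)
  expect_equal(null$sites$enrichment_knockdown, null$sites$enrichment_control)
})

test_that("site placement favours the stop-codon vicinity and separates sites", {
  sim <- simulate_merip(seed = 5, n_genes = 150, coverage = 2)
  near_stop <- with(sim$sites,
    position >= purrr::map_dbl(gene_id, ~ sim$transcripts$cds_end[
      sim$transcripts$gene_id == .x]) - 50)
  expect_gt(mean(near_stop), 0.35)  # ~half of the mixture mass

  multi <- simulate_merip(seed = 6, n_genes = 30, coverage = 2,
                          sites_per_gene = 3)
  seps <- multi$sites |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(min_sep = ifelse(dplyr::n() > 1, min(diff(sort(position))),
                                      Inf))
  expect_true(all(seps$min_sep >= 100))
})

test_that("doubling coverage doubles read counts within noise", {
  lo <- simulate_merip(seed = 7, n_genes = 25, coverage = 10)
  hi <- simulate_merip(seed = 7, n_genes = 25, coverage = 20)
  ratio <- nrow(hi$reads) / nrow(lo$reads)
  expect_lt(abs(ratio - 2), 0.1)
})

test_that("GGACU density under planted sites exceeds background", {
  sim <- simulate_merip(seed = 8, n_genes = 30, coverage = 2)
  dens <- purrr::map_dfr(seq_len(nrow(sim$sites)), function(i) {
    s <- sim$sites[i, ]
    seq <- sim$sequences[[s$gene_id]]
    win <- substr(seq, max(1, s$position - 49), s$position + 50)
    tibble::tibble(
      site_hits = sum(gregexpr("GGACT", win, fixed = TRUE)[[1]] > 0),
      site_len = nchar(win), total_len = nchar(seq),
      total_hits = sum(gregexpr("GGACT", seq, fixed = TRUE)[[1]] > 0))
  })
  site_rate <- sum(dens$site_hits) / sum(dens$site_len)
  bg_rate <- (sum(dens$total_hits) - sum(dens$site_hits)) /
    (sum(dens$total_len) - sum(dens$site_len))
  expect_gt(site_rate, bg_rate)
})

test_that("recovery scoring matches its definition", {
  sites <- tibble::tibble(gene_id = c("g1", "g2"), position = c(500, 300),
                          region = c("cds", "utr3"))
  perfect <- tibble::tibble(gene_id = c("g1", "g2"), start = c(450, 250),
                            end = c(550, 350))
  r <- evaluate_recovery(perfect, sites)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$precision, 1)
  expect_equal(tidy(r)$n_sites, 2)

  none <- evaluate_recovery(perfect[0, ], sites)
  expect_equal(none$sensitivity, 0)
  expect_true(is.na(none$precision))

  # tolerance boundary: site at peak end + tol - 1 is in, + tol is out
  edge <- tibble::tibble(gene_id = "g1", start = 100, end = 200)
  hit <- evaluate_recovery(edge, tibble::tibble(gene_id = "g1", position = 249,
                                                region = "cds"))
  expect_equal(hit$sensitivity, 1)
  miss <- evaluate_recovery(edge, tibble::tibble(gene_id = "g1", position = 250,
                                                 region = "cds"))
  expect_equal(miss$sensitivity, 0)

  expect_error(evaluate_recovery(perfect, sites[0, ]),
               class = "meripscan_input_error")
})

test_that("simulated qPCR and decay tables recover their planted truth", {
  q <- simulate_qpcr(c(MYC = 2), sd = 0, seed = 1,
                     samples = c("control", "treated"))
  fe <- relative_expression(q, "MYC", "HPRT1", "control")
  expect_equal(fe$fold_change[fe$sample == "treated"], 2)

  qm <- simulate_qpcr_m6a(c(shNC = 1, shFTO = 2), sd = 0, seed = 1)
  em <- m6a_enrichment(qm, input_fraction = 0.05, control_sample = "shNC")
  expect_equal(em$relative_m6a[em$sample == "shFTO"], 2)

  d <- simulate_decay(c(g = 3), sd = 0, seed = 1)
  expect_equal(fit_decay(d)$half_life, 3)
  expect_equal(d$value[d$hours == 0], 1)
})

test_that("the written bundle round-trips through the readers", {
  sim <- simulate_merip(seed = 9, n_genes = 6, coverage = 10)
  dir <- withr::local_tempdir()
  paths <- write_sim(sim, dir)
  expect_true(all(file.exists(paths)))

  models <- read_annotation(paths[["annotation"]])
  expect_equal(sort(models$gene_id), sort(sim$transcripts$gene_id))
  expect_equal(models$length[order(models$gene_id)],
               sim$transcripts$length[order(sim$transcripts$gene_id)])

  reads <- read_reads_bed(paths[["reads"]])
  expect_equal(nrow(reads), nrow(sim$reads))
  expect_setequal(unique(reads$sample), c("input", "IP"))
  expect_equal(sort(unique(reads$condition)), c("control", "knockdown"))

  seqs <- Biostrings::readDNAStringSet(paths[["transcripts_fa"]])
  expect_equal(sort(names(seqs)), sort(sim$transcripts$gene_id))
  expect_equal(unname(as.character(seqs[sim$transcripts$gene_id[1]])),
               unname(sim$sequences[sim$transcripts$gene_id[1]]))
})
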