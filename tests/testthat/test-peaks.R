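test_that("one-sided Fisher p matches enumeration and fisher.test", {
  # frozen spec examples, verified against the choose()-based oracle
  expect_equal(fisher_window_test(5, 5, 5, 5), fisher_oracle(5, 5, 5, 5))
  expect_equal(fisher_oracle(5, 5, 5, 5), 0.6718591, tolerance = 1e-6)
  expect_equal(fisher_window_test(10, 0, 0, 10), 1 / 184756)
  expect_equal(fisher_window_test(0, 0, 0, 0), 1)

  # random tables against both the enumeration oracle and stats::fisher.test
  set.seed(7)
  for (i in 1:50) {
    t <- rpois(4, 6)
    p <- fisher_window_test(t[1], t[2], t[3], t[4])
    expect_equal(p, fisher_oracle(t[1], t[2], t[3], t[4]), tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(t, 2, byrow = TRUE),
                             alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_window_test(-1, 0, 0, 0), class = "meripscan_input_error")
})

test_that("one-sided p is monotone decreasing in the window IP count", {
  # margins fixed: move one fragment from input_in to ip_in
  for (tot in c(10, 25)) {
    p <- vapply(0:tot, function(a) {
      fisher_window_test(a, tot - a, tot - a, a)
    }, numeric(1))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("BH q-values reproduce hand-computed step-up adjustments", {
  # all expected vectors computed by hand with q_i = min over tail of p*n/rank
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_equal(bh_fdr(c(0.005, 0.04, 0.04, 0.05)), c(0.02, 0.05, 0.05, 0.05))
  expect_equal(bh_fdr(c(0.5, 0.1, 0.9, 0.2)), c(2 / 3, 0.4, 0.9, 0.4))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "meripscan_input_error")
})

test_that("BH is permutation-equivariant and q >= p", {
  set.seed(11)
  p <- runif(200)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  perm <- sample(200)
  expect_equal(bh_fdr(p[perm])[order(perm)], q)
})

test_that("enrichment score follows (a*d)/(b*c) with the zero-input pseudocount", {
  expect_equal(enrichment_score(40, 10, 8, 10), 5)
  expect_equal(enrichment_score(7, 7, 3, 3), 1)
  # c = 0: half a count added to a and c
  expect_equal(enrichment_score(20, 10, 0, 10), (20.5 * 10) / (10 * 0.5))
  expect_error(enrichment_score(1, 0, 1, 1), class = "meripscan_coverage_error")
})

test_that("enrichment score is invariant under per-library rescaling", {
  set.seed(3)
  for (i in 1:100) {
    a <- rpois(1, 20) + 1; b <- rpois(1, 10) + 1
    c <- rpois(1, 10) + 1; d <- rpois(1, 10) + 1
    s <- runif(1, 0.1, 10); t <- runif(1, 0.1, 10)
    expect_equal(enrichment_score(a * s, b * s, c * t, d * t),
                 enrichment_score(a, b, c, d))
  }
})

test_that("positivity thresholds: FDR strict, log2 ES inclusive", {
  st <- tibble::tibble(q_value = c(0.005, 0.005, 0.02, 0.01),
                       es = c(2, 1.9, 8, 4))
  out <- call_positive_windows(st)
  expect_equal(out$positive, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("overlapping positive windows merge into disjoint peaks", {
  one <- make_winstats("g", c(0, 10), es = c(4, 8), q = c(1e-4, 1e-5))
  pk <- merge_windows(one)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$start, pk$end), c(0, 110))
  expect_equal(pk$n_windows, 2L)
  expect_equal(pk$summit, (10 + 110) / 2)  # midpoint of the higher-ES window
  expect_equal(pk$min_q, 1e-5)

  two <- make_winstats("g", c(0, 200), es = c(4, 4), q = c(1e-4, 1e-4))
  pk2 <- merge_windows(two)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$start, c(0, 200))

  single <- make_winstats("g", 40, es = 4, q = 1e-4)
  pk3 <- merge_windows(single)
  expect_equal(c(pk3$start, pk3$end, pk3$summit), c(40, 140, 90))

  # disjointness + merge idempotence on random window sets
  set.seed(5)
  for (i in 1:20) {
    starts <- sort(sample(seq(0, 1000, 10), 15))
    w <- make_winstats("g", starts, es = runif(15, 2, 9),
                       q = runif(15, 1e-6, 1e-3))
    p1 <- merge_windows(w)
    expect_true(all(p1$start[-1] >= head(p1$end, -1)))
    remerged <- merge_windows(
      make_winstats("g", p1$start, es = p1$max_window_es, q = p1$min_q,
                    window = 0) |>
        dplyr::mutate(end = p1$end))
    expect_equal(remerged$start, p1$start)
    expect_equal(remerged$end, p1$end)
  }
})

test_that("IP identical to input yields no peaks; zero reads do not crash", {
  m <- make_model(exons = tibble::tibble(start = 0, end = 1500))
  set.seed(9)
  starts <- sample.int(1350, 400) - 1
  ip <- make_reads(starts, sample = "IP")
  input <- make_reads(starts, sample = "input")
  call <- call_peaks(dplyr::bind_rows(ip, input), m)
  expect_equal(nrow(call$peaks), 0)
  expect_true(all(abs(call$windows$es - 1) < 1e-12))

  empty <- call_peaks(ip[0, ], m)
  expect_s3_class(empty, "merip_call")
  expect_equal(nrow(empty$peaks), 0)

  expect_error(call_peaks(ip, m), class = "meripscan_input_error")
})

test_that("a strongly enriched site is called as a peak overlapping it", {
  # one gene, one site at 800, 8x enrichment, ~30x coverage
  sim <- simulate_merip(seed = 1, n_genes = 1, coverage = 30, enrichment = 8,
                        knockdown_effect = 1)
  call <- call_peaks(sim$reads, sim$transcripts)
  ctrl <- dplyr::filter(call$peaks, condition == "control")
  expect_gte(nrow(ctrl), 1)
  site <- sim$sites$position[1]
  expect_true(any(ctrl$start - 50 <= site & site < ctrl$end + 50))
  # peaks carry a finite recomputed ES and a summit inside the peak
  expect_true(all(is.finite(ctrl$peak_es)))
  expect_true(all(ctrl$summit >= ctrl$start & ctrl$summit < ctrl$end))
})

test_that("tidy and glance summarise a merip_call", {
  sim <- simulate_merip(seed = 2, n_genes = 4, coverage = 20)
  call <- call_peaks(sim$reads, sim$transcripts)
  td <- tidy(call)
  expect_true(all(c("condition", "gene_id", "start", "end", "peak_es") %in%
                    names(td)))
  gl <- glance(call)
  expect_equal(sort(gl$condition), c("control", "knockdown"))
  expect_true(all(gl$n_peaks <= gl$n_positive))
})
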