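# Small in-code fixtures shared across test files.

# one-row transcript table
make_model <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                       exons = tibble::tibble(start = 1000, end = 2000),
                       cds_start = NULL, cds_end = NULL,
                       transcript_id = paste0(gene_id, ".1")) {
  len <- sum(exons$end - exons$start)
  tibble::tibble(
    gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
    strand = strand, length = len,
    cds_start = cds_start %||% 0, cds_end = cds_end %||% 0,
    exons = list(exons))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

make_reads <- function(starts, length = 80, chrom = "chr1", strand = "+",
                       sample = "IP", condition = "control") {
  tibble::tibble(chrom = chrom, start = starts, end = starts + length,
                 strand = strand, sample = sample, condition = condition)
}

# independent per-base oracle: map every genomic base of [start, end) that
# falls in an exon, return the min/max transcript coordinate
brute_tx_interval <- function(model, gstart, gend) {
  ex <- model$exons[[1]]
  gpos <- gstart:(gend - 1)
  exonic <- gpos[vapply(gpos, function(g) any(g >= ex$start & g < ex$end),
                        logical(1))]
  if (length(exonic) == 0L) return(NULL)
  tx <- genome_to_transcript_pos(model, exonic)
  c(start = min(tx), end = max(tx) + 1, n_exonic = length(exonic))
}

# independent one-sided Fisher oracle: full hypergeometric enumeration with
# binomial coefficients only
fisher_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c            # IP column total
  n <- a + b            # window row total
  xs <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(probs[xs >= a])
}

# windows-with-stats fixture for merge tests
make_winstats <- function(gene_id, starts, es, q, window = 100) {
  tibble::tibble(gene_id = gene_id, start = starts, end = starts + window,
                 es = es, q_value = q)
}
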