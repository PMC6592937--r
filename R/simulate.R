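# Synthetic two-condition MeRIP-seq experiments with known ground truth.
#
# The generator states a small but realistic world: mRNAs with a 5'UTR /
# CDS / 3'UTR architecture (means 200 / 1200 / 800 nt), one synthetic
# chromosome per gene, uniform input coverage, IP fragments (150 nt)
# enriched over fragments covering planted GGACU-bearing sites, single-end
# 80-nt reads taken from the fragment 5' end, and a knockdown condition in
# which responder sites gain methylation (the demethylase-knockdown
# direction). Counts are Poisson by default; a negative-binomial dispersion
# can be switched on.

# run code under a seed without clobbering the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rcount <- function(n, mu, dispersion) {
  if (dispersion > 0) rnbinom(n, mu = mu, size = 1 / dispersion) else rpois(n, mu)
}

# sample k values from a vector, safe for length-1 vectors
pick <- function(v, k = 1L, replace = FALSE) {
  v[sample.int(length(v), k, replace = replace)]
}

#' Simulation parameters for a synthetic MeRIP-seq experiment
#'
#' Defaults describe the emulated library design: 150-nt fragments, 80-nt
#' single-end reads, 30x input coverage, strongly enriched sites (8-fold IP
#' excess), a knockdown that multiplies methylation 4-fold at half of the
#' sites, and Poisson counting noise.
#'
#' @param n_genes Number of genes (one synthetic chromosome each).
#' @param utr5_mean,cds_mean,utr3_mean Mean region lengths (nt).
#' @param length_shape Gamma shape for region-length variability.
#' @param sites_per_gene Planted m6A sites per gene.
#' @param enrichment IP fold-excess of fragments covering a site.
#' @param knockdown_effect Multiplicative methylation gain at responder
#'   sites in the knockdown condition.
#' @param fto_target_fraction Fraction of sites that respond to knockdown.
#' @param coverage Mean input coverage (x).
#' @param fragment_length,read_length Fragment and read sizes (nt).
#' @param dispersion Negative-binomial dispersion; 0 means Poisson.
#' @param n_exons Exons per transcript (1 keeps genome == transcript;
#'   2-4 exercises the coordinate mapping).
#' @param intron_length Intron size in multi-exon mode (nt).
#' @param minus_strand_fraction Fraction of genes placed on the minus strand.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 50,
                       utr5_mean = 200, cds_mean = 1200, utr3_mean = 800,
                       length_shape = 4,
                       sites_per_gene = 1,
                       enrichment = 8,
                       knockdown_effect = 4,
                       fto_target_fraction = 0.5,
                       coverage = 30,
                       fragment_length = 150, read_length = 80,
                       dispersion = 0,
                       n_exons = 1, intron_length = 300,
                       minus_strand_fraction = 0.5) {
  p <- as.list(environment())
  if (p$n_genes < 1 || p$utr5_mean <= 0 || p$cds_mean <= 0 || p$utr3_mean <= 0) {
    abort("degenerate simulation parameters", class = "meripscan_config_error")
  }
  if (p$fragment_length < p$read_length) {
    abort("fragment_length must be >= read_length", class = "meripscan_config_error")
  }
  if (p$fto_target_fraction < 0 || p$fto_target_fraction > 1) {
    abort("fto_target_fraction must lie in [0, 1]", class = "meripscan_config_error")
  }
  if (p$enrichment < 1 || p$knockdown_effect < 1 || p$coverage <= 0) {
    abort("enrichment, knockdown_effect and coverage must be positive (>= 1 for folds)",
          class = "meripscan_config_error")
  }
  structure(p, class = "sim_params")
}

sim_transcripts <- function(p) {
  rlen <- function(n, mean, minimum) {
    pmax(minimum, round(rgamma(n, shape = p$length_shape,
                               scale = mean / p$length_shape)))
  }
  utr5 <- rlen(p$n_genes, p$utr5_mean, 100)
  cds <- 3 * round(rlen(p$n_genes, p$cds_mean, 300) / 3)
  utr3 <- rlen(p$n_genes, p$utr3_mean, 150)
  len <- utr5 + cds + utr3
  strand <- ifelse(runif(p$n_genes) < p$minus_strand_fraction, "-", "+")
  gene_id <- sprintf("G%04d", seq_len(p$n_genes))
  pad <- 200
  exons <- purrr::map(seq_len(p$n_genes), function(i) {
    L <- len[i]
    k <- p$n_exons
    if (k <= 1L) {
      tibble(start = pad, end = pad + L)
    } else {
      cuts <- floor(L * seq_len(k - 1) / k)
      sizes <- diff(c(0, cuts, L))
      gst <- pad + cumsum(c(0, head(sizes, -1) + p$intron_length))
      tibble(start = gst, end = gst + sizes)
    }
  })
  tibble(gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
         chrom = paste0("chr_", gene_id), strand = strand, length = len,
         cds_start = utr5, cds_end = utr5 + cds, exons = exons)
}

site_region <- function(pos, cds_start, cds_end) {
  dplyr::case_when(pos < cds_start ~ "utr5",
                   pos < cds_end ~ "cds",
                   TRUE ~ "utr3")
}

#' Plant m6A sites on synthetic transcripts
#'
#' Constitutive sites are drawn from a mixture favouring the stop-codon
#' vicinity (`[cds_end - 50, cds_end + 150)`, weight 0.5) and the 5'UTR
#' (weight 0.2), with the remaining mass uniform over CDS and 3'UTR — the
#' canonical m6A topography. A `fto_target_fraction` share of sites are
#' demethylase (FTO) targets: they are placed in the UTRs (where FTO
#' knockdown is reported to raise methylation), held at
#' `enrichment / knockdown_effect` in the control condition (the active
#' demethylase keeps them hypomethylated) and restored to the full
#' `enrichment` on knockdown, so knockdown enrichment = control x
#' knockdown_effect. Sites on one gene are kept >= 100 nt apart.
#'
#' @param models Transcript table from the generator.
#' @param p `sim_params`.
#' @return Truth tibble: `gene_id`, `position`, `region`,
#'   `base_enrichment`, `responds`, `enrichment_control`,
#'   `enrichment_knockdown`, `motif_written`.
#' @keywords internal
sim_plant_sites <- function(models, p) {
  draw_pos <- function(L, cds_start, cds_end, responder) {
    zone <- if (responder) {
      sample(c("utr5", "stop_utr3", "utr3"), 1, prob = c(0.4, 0.4, 0.2))
    } else {
      sample(c("stop", "utr5", "cds", "utr3"), 1,
             prob = c(0.5, 0.2, 0.15, 0.15))
    }
    rng <- switch(zone,
      stop = c(max(2, cds_end - 50), min(L - 5, cds_end + 150)),
      stop_utr3 = c(cds_end, min(L - 5, cds_end + 150)),
      utr5 = c(2, max(3, cds_start - 5)),
      cds  = c(cds_start, cds_end - 5),
      utr3 = c(cds_end, L - 5))
    if (rng[2] <= rng[1]) rng <- c(2, L - 5)
    pick(seq(rng[1], rng[2] - 1))
  }
  sites <- purrr::map(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    n <- p$sites_per_gene
    if (n < 1) return(NULL)
    responds <- rbinom(n, 1, p$fto_target_fraction) == 1
    pos <- numeric(0)
    kept <- logical(0)
    for (s in seq_len(n)) {
      for (try in 1:50) {
        cand <- draw_pos(m$length, m$cds_start, m$cds_end, responds[s])
        if (all(abs(cand - pos) >= 100)) {
          pos <- c(pos, cand)
          kept <- c(kept, responds[s])
          break
        }
      }
    }
    if (length(pos) == 0L) return(NULL)
    ord <- order(pos)
    tibble(gene_id = m$gene_id, position = pos[ord], responds = kept[ord],
           region = site_region(pos[ord], m$cds_start, m$cds_end))
  }) |>
    dplyr::bind_rows()
  sites |>
    mutate(base_enrichment = p$enrichment,
           enrichment_control = ifelse(.data$responds,
                                       pmax(1, p$enrichment / p$knockdown_effect),
                                       p$enrichment),
           enrichment_knockdown = p$enrichment,
           motif_written = TRUE) |>
    select("gene_id", "position", "region", "base_enrichment", "responds",
           "enrichment_control", "enrichment_knockdown", "motif_written")
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

sim_sequences <- function(models, sites, p) {
  bases <- c("A", "C", "G", "T")
  tx_seq <- vapply(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    s <- sample(bases, m$length, replace = TRUE)
    at <- sites$position[sites$gene_id == m$gene_id]
    for (a in at) {
      # positions are 0-based; GGACU with the methylated A at `position`
      s[(a - 1):(a + 3)] <- c("G", "G", "A", "C", "T")
    }
    paste(s, collapse = "")
  }, character(1))
  names(tx_seq) <- models$gene_id
  genome <- vapply(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    ex <- m$exons[[1]]
    glen <- max(ex$end) + 200
    g <- sample(bases, glen, replace = TRUE)
    txt <- strsplit(tx_seq[[m$gene_id]], "", fixed = TRUE)[[1]]
    if (m$strand == "-") txt <- rev(chartr("ACGT", "TGCA", txt))
    # lay transcript bases over exons in genomic order
    off <- 0
    for (j in seq_len(nrow(ex))) {
      sz <- ex$end[j] - ex$start[j]
      g[(ex$start[j] + 1):ex$end[j]] <- txt[(off + 1):(off + sz)]
      off <- off + sz
    }
    paste(g, collapse = "")
  }, character(1))
  names(genome) <- models$chrom
  list(transcript = tx_seq, genome = genome)
}

sim_reads_one <- function(models, sites, p, condition) {
  enr_col <- paste0("enrichment_", condition)
  purrr::map(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    L <- m$length
    n_start <- L - p$fragment_length + 1
    rate <- p$coverage / p$fragment_length   # expected fragments per start slot
    frag_starts <- function(n) sample.int(n_start, n, replace = TRUE) - 1L
    inp <- frag_starts(rcount(1, rate * n_start, p$dispersion))
    ip <- frag_starts(rcount(1, rate * n_start, p$dispersion))
    st <- sites[sites$gene_id == m$gene_id, ]
    for (s in seq_len(nrow(st))) {
      e <- st[[enr_col]][s]
      lo <- max(0, st$position[s] - p$fragment_length + 1)
      hi <- min(st$position[s], n_start - 1)
      if (hi < lo || e <= 1) next
      extra <- rcount(1, (e - 1) * rate * (hi - lo + 1), p$dispersion)
      ip <- c(ip, pick(seq(lo, hi), extra, replace = TRUE))
    }
    to_reads <- function(starts, sample_label) {
      if (length(starts) == 0L) {
        return(tibble(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), sample = character(),
                      condition = character()))
      }
      g5 <- transcript_to_genome(m, starts)
      if (m$strand == "+") {
        gs <- g5; ge <- g5 + p$read_length
      } else {
        ge <- g5 + 1; gs <- ge - p$read_length
      }
      tibble(chrom = m$chrom, start = gs, end = ge, strand = m$strand,
             sample = sample_label, condition = condition)
    }
    dplyr::bind_rows(to_reads(sort(inp), "input"), to_reads(sort(ip), "IP"))
  }) |>
    dplyr::bind_rows()
}

#' Simulate a two-condition MeRIP-seq experiment
#'
#' Generates transcript models, sequences with GGACU written at planted
#' sites, and IP/input aligned reads for a control and a knockdown
#' condition, all deterministically from one seed.
#'
#' @param params A [sim_params()] list (or arguments passed to it via `...`).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param conditions Condition labels; the second is the knockdown.
#' @param ... Convenience: forwarded to [sim_params()] when `params` is NULL.
#' @return A list of class `merip_sim`: `transcripts`, `sites` (truth),
#'   `reads`, `sequences` (transcript FASTA as named character),
#'   `genome`, `params`, `seed`.
#' @examples
#' sim <- simulate_merip(seed = 1, n_genes = 5, coverage = 10)
#' dplyr::count(sim$reads, condition, sample)
#' @export
simulate_merip <- function(params = NULL, seed = 1,
                           conditions = c("control", "knockdown"), ...) {
  p <- params %||% sim_params(...)
  stopifnot(inherits(p, "sim_params"), length(conditions) == 2L)
  with_local_seed(seed, {
    models <- sim_transcripts(p)
    sites <- sim_plant_sites(models, p)
    seqs <- sim_sequences(models, sites, p)
    reads <- dplyr::bind_rows(
      sim_reads_one(models, sites, p, "control"),
      sim_reads_one(models, sites, p, "knockdown"))
    reads$condition <- conditions[match(reads$condition,
                                        c("control", "knockdown"))]
    structure(list(transcripts = models, sites = sites, reads = reads,
                   sequences = seqs$transcript, genome = seqs$genome,
                   params = p, seed = seed),
              class = "merip_sim")
  })
}

#' @export
print.merip_sim <- function(x, ...) {
  cat("<merip_sim>\n")
  cat(sprintf("  %d genes, %d planted sites, %d reads, seed %d\n",
              nrow(x$transcripts), nrow(x$sites), nrow(x$reads), x$seed))
  invisible(x)
}

write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    writeLines(substring(s, seq(1, nchar(s), width),
                         pmin(nchar(s), seq(1, nchar(s), width) + width - 1)),
               con)
  }
  invisible(path)
}

#' Write a simulated experiment to disk
#'
#' Emits the standard plain-text bundle: BED12 annotation, per-library BED6
#' reads (name field `sample:condition`), transcript and genome FASTA,
#' truth BED (planted sites with per-condition enrichment), and the
#' parameters as YAML-style key-value lines.
#'
#' @param sim A `merip_sim` from [simulate_merip()].
#' @param dir Output directory.
#' @return Invisibly, the named vector of written paths.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "merip_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(annotation = file.path(dir, "annotation.bed12"),
             reads = file.path(dir, "reads.bed"),
             transcripts_fa = file.path(dir, "transcripts.fa"),
             genome_fa = file.path(dir, "genome.fa"),
             truth = file.path(dir, "truth.bed"),
             params = file.path(dir, "params.yaml"))
  write_annotation_bed12(sim$transcripts, paths["annotation"])
  sim$reads |>
    mutate(name = paste0(.data$sample, ":", .data$condition), score = 0) |>
    select("chrom", "start", "end", "name", "score", "strand") |>
    readr::write_tsv(paths["reads"], col_names = FALSE, progress = FALSE)
  write_fasta(sim$sequences, paths["transcripts_fa"])
  write_fasta(sim$genome, paths["genome_fa"])
  sim$sites |>
    mutate(start = .data$position, end = .data$position + 1,
           name = .data$region) |>
    select("gene_id", "start", "end", "name", "enrichment_control",
           "enrichment_knockdown", "responds") |>
    readr::write_tsv(paths["truth"], col_names = FALSE, progress = FALSE)
  p <- sim$params
  writeLines(c(paste0("seed: ", sim$seed),
               paste0(names(p), ": ", unlist(p))), paths["params"])
  invisible(paths)
}

#' Score called peaks against planted truth
#'
#' A planted site counts as recovered when some called peak on its gene,
#' widened by `tolerance` nt on both sides, contains the site position; a
#' peak counts as true when its widened interval contains some site.
#'
#' @param peaks Peak tibble for one condition (`gene_id`, `start`, `end`).
#' @param sites Truth tibble from [simulate_merip()].
#' @param tolerance Slack in nt (default 50, half a window).
#' @return List of class `recovery_report` with `sensitivity`, `precision`,
#'   `by_region` (per-region sensitivity tibble), `n_sites`, `n_peaks`.
#' @export
evaluate_recovery <- function(peaks, sites, tolerance = 50) {
  if (nrow(sites) == 0L) {
    abort("empty truth set", class = "meripscan_input_error")
  }
  site_hit <- purrr::map_lgl(seq_len(nrow(sites)), function(i) {
    pk <- peaks[peaks$gene_id == sites$gene_id[i], , drop = FALSE]
    any(pk$start - tolerance <= sites$position[i] &
          sites$position[i] < pk$end + tolerance)
  })
  peak_hit <- if (nrow(peaks) == 0L) logical(0) else {
    purrr::map_lgl(seq_len(nrow(peaks)), function(i) {
      st <- sites[sites$gene_id == peaks$gene_id[i], , drop = FALSE]
      any(peaks$start[i] - tolerance <= st$position &
            st$position < peaks$end[i] + tolerance)
    })
  }
  by_region <- tibble(region = sites$region, hit = site_hit) |>
    group_by(.data$region) |>
    summarise(n_sites = dplyr::n(), sensitivity = mean(.data$hit),
              .groups = "drop")
  structure(list(sensitivity = mean(site_hit),
                 precision = if (length(peak_hit)) mean(peak_hit) else NA_real_,
                 by_region = by_region,
                 n_sites = nrow(sites), n_peaks = nrow(peaks)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat(sprintf("  sensitivity %.3f (%d sites), precision %.3f (%d peaks)\n",
              x$sensitivity, x$n_sites, x$precision, x$n_peaks))
  invisible(x)
}

#' @describeIn evaluate_recovery Recovery metrics as a one-row tibble.
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @export
tidy.recovery_report <- function(x, ...) {
  tibble(sensitivity = x$sensitivity, precision = x$precision,
         n_sites = x$n_sites, n_peaks = x$n_peaks)
}

#' Simulate a delta-delta-Cq qPCR table
#'
#' Cq values are `base_cq - log2(quantity)` plus Gaussian noise, in
#' triplicate, for a treated-vs-control design with a reference gene whose
#' quantity is 1 in both samples.
#'
#' @param fold_changes Named numeric: per-gene fold change in the treated
#'   sample relative to control.
#' @param reference Reference gene name (quantity 1 everywhere).
#' @param sd Gaussian Cq noise standard deviation.
#' @param seed Integer seed.
#' @param base_cq Baseline Cq for quantity 1.
#' @param replicates Technical replicates per well.
#' @param samples Labels for the control and treated samples.
#' @return Long Cq tibble (`sample`, `gene`, `replicate`, `cq`).
#' @export
simulate_qpcr <- function(fold_changes, reference = "HPRT1", sd = 0.1,
                          seed = 1, base_cq = 20, replicates = 3,
                          samples = c("control", "treated")) {
  if (sd < 0) abort("noise sd must be >= 0", class = "meripscan_config_error")
  with_local_seed(seed, {
    grid <- tidyr::expand_grid(
      sample = samples,
      gene = c(names(fold_changes), reference),
      replicate = seq_len(replicates))
    grid |>
      mutate(quantity = ifelse(.data$gene == reference, 1,
                               ifelse(.data$sample == samples[2],
                                      fold_changes[.data$gene], 1)),
             cq = base_cq - log2(.data$quantity) + rnorm(dplyr::n(), 0, sd)) |>
      select(-"quantity")
  })
}

#' Simulate a gene-specific m6A-IP qPCR table
#'
#' @param m6a_levels Named numeric: relative m6A level per sample for one
#'   gene (percent-of-input convention).
#' @param gene Gene label.
#' @param input_fraction Fraction of material saved as input.
#' @inheritParams simulate_qpcr
#' @return Long Cq tibble with a `role` column (`IP` / `input`).
#' @export
simulate_qpcr_m6a <- function(m6a_levels, gene = "target",
                              input_fraction = 0.05, sd = 0.1, seed = 1,
                              base_cq = 22, replicates = 3) {
  if (sd < 0) abort("noise sd must be >= 0", class = "meripscan_config_error")
  with_local_seed(seed, {
    grid <- tidyr::expand_grid(sample = names(m6a_levels), gene = gene,
                               role = c("input", "IP"),
                               replicate = seq_len(replicates))
    grid |>
      mutate(cq = ifelse(.data$role == "input", base_cq,
                         base_cq - log2(m6a_levels[.data$sample] * input_fraction)) +
               rnorm(dplyr::n(), 0, sd))
  })
}

#' Simulate an actinomycin-D decay time course
#'
#' Values decay as `exp(-k t)` with multiplicative log-normal noise and are
#' re-normalised to 1 at t = 0.
#'
#' @param half_lives Named numeric (gene -> half-life in h), or a tibble
#'   with `gene`, `condition`, `half_life`.
#' @param timepoints Chase timepoints in hours.
#' @param sd Standard deviation of the log-scale noise.
#' @param seed Integer seed.
#' @return Tibble `gene`, `condition`, `hours`, `value`.
#' @export
simulate_decay <- function(half_lives, timepoints = c(0, 3, 6), sd = 0,
                           seed = 1) {
  if (sd < 0) abort("noise sd must be >= 0", class = "meripscan_config_error")
  hl <- if (is.data.frame(half_lives)) {
    as_tibble(half_lives)
  } else {
    tibble(gene = names(half_lives), condition = "all",
           half_life = unname(half_lives))
  }
  with_local_seed(seed, {
    hl |>
      tidyr::expand_grid(hours = timepoints) |>
      mutate(value = exp(-log(2) / .data$half_life * .data$hours) *
               exp(rnorm(dplyr::n(), 0, sd))) |>
      group_by(.data$gene, .data$condition) |>
      mutate(value = .data$value / .data$value[.data$hours == 0]) |>
      ungroup() |>
      select("gene", "condition", "hours", "value")
  })
}
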