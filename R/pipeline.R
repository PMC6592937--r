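# End-to-end orchestration: simulate (or load) -> call peaks per condition
# -> compare -> metagene -> motif -> recovery, writing a deterministic
# output tree with a manifest and a run log.

default_config <- function() {
  list(window = 100, step = 10, min_frac = 1 / 20, fdr = 0.01,
       min_log2_es = 1, fragment_length = 150, seed = 1,
       motif = "GGACU", tolerance = 50)
}

#' Benchmark simulation preset
#'
#' The standard-world benchmark: 300 genes, one site per gene, 8-fold site
#' enrichment, 30x input coverage, knockdown_effect 4 on half the sites.
#'
#' @return A [sim_params()] object.
#' @export
benchmark_params <- function() {
  sim_params(n_genes = 300, sites_per_gene = 1, enrichment = 8,
             coverage = 30, knockdown_effect = 4, fto_target_fraction = 0.5)
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config),
            class = "meripscan_input_error")
    }
    config <- if (grepl("\\.ya?ml$", config) &&
                  requireNamespace("yaml", quietly = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) {
    abort("config must be a list or a YAML/JSON file path",
          class = "meripscan_config_error")
  }
  cfg <- utils::modifyList(default_config(), config)
  if (cfg$fdr <= 0 || cfg$fdr >= 1) {
    abort("fdr threshold must lie strictly in (0, 1)",
          class = "meripscan_config_error")
  }
  if (cfg$window <= 0 || cfg$step <= 0 || cfg$min_frac < 0 ||
      cfg$min_frac >= 1 || cfg$fragment_length <= 0) {
    abort("thresholds must be positive (min_frac in [0, 1))",
          class = "meripscan_config_error")
  }
  cfg
}

#' Write peaks as BED6+4
#'
#' Columns: gene_id (transcript space), start, end, `gene:peak_n`,
#' `round(100 * log2(peak ES))`, `+`, then min q, peak ES, summit. No header.
#'
#' @param peaks Peak tibble for one condition.
#' @param path Output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- peaks |>
    group_by(.data$gene_id) |>
    mutate(name = paste0(.data$gene_id, ":", dplyr::row_number())) |>
    ungroup() |>
    mutate(score = round(100 * log2(.data$peak_es)),
           strand = "+",
           q = signif(.data$min_q, 6), es = signif(.data$peak_es, 6)) |>
    select("gene_id", "start", "end", "name", "score", "strand",
           "q", "es", "summit")
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Run the full MeRIP-seq analysis pipeline
#'
#' Executes simulate (or load) -> peak calling per condition -> peak-set
#' comparison -> metagene and region profiles -> motif check -> recovery
#' scoring (when ground truth exists), and writes all tables plus a
#' manifest and run log under `out_dir`. Re-running an identical config
#' reproduces identical files.
#'
#' @param config A list, or path to a YAML/JSON file, with any of: `window`,
#'   `step`, `min_frac`, `fdr`, `min_log2_es`, `fragment_length`, `seed`,
#'   `motif`, `tolerance`; plus either `simulate` (a list of [sim_params()]
#'   arguments, or `"benchmark"`) or `inputs` (paths `annotation`, `reads`
#'   — a BED6 with `sample:condition` names — and optional `sequences`
#'   FASTA).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `merip_call`, comparison, profiles,
#'   recovery report and the manifest of written files.
#' @export
run_pipeline <- function(config = list(simulate = "benchmark"),
                         out_dir = tempfile("meripscan_run_")) {
  cfg <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("meripscan run log",
                 paste0("package version: ",
                        as.character(utils::packageVersion("meripscan"))),
                 paste0("seed: ", cfg$seed),
                 paste0("thresholds: window=", cfg$window, " step=", cfg$step,
                        " min_frac=", signif(cfg$min_frac, 4),
                        " fdr=", cfg$fdr, " min_log2_es=", cfg$min_log2_es,
                        " fragment_length=", cfg$fragment_length))

  sim <- NULL
  if (!is.null(cfg$simulate)) {
    p <- if (identical(cfg$simulate, "benchmark")) {
      benchmark_params()
    } else if (inherits(cfg$simulate, "sim_params")) {
      cfg$simulate
    } else {
      do.call(sim_params, as.list(cfg$simulate))
    }
    sim <- simulate_merip(params = p, seed = cfg$seed)
    models <- sim$transcripts
    reads <- sim$reads
    sequences <- sim$sequences
    log_lines <- c(log_lines,
                   paste0("simulated genes: ", nrow(models),
                          "; planted sites: ", nrow(sim$sites),
                          "; reads: ", nrow(reads)))
  } else if (!is.null(cfg$inputs)) {
    for (f in c(cfg$inputs$annotation, cfg$inputs$reads, cfg$inputs$sequences)) {
      if (!file.exists(f)) {
        abort(paste0("missing input file: ", f), class = "meripscan_input_error")
      }
    }
    models <- read_annotation(cfg$inputs$annotation)
    reads <- read_reads_bed(cfg$inputs$reads)
    sequences <- if (!is.null(cfg$inputs$sequences)) cfg$inputs$sequences else NULL
    log_lines <- c(log_lines, paste0("loaded genes: ", nrow(models),
                                     "; reads: ", nrow(reads)))
  } else {
    abort("config needs either `simulate` or `inputs`",
          class = "meripscan_config_error")
  }

  call <- call_peaks(reads, models, window = cfg$window, step = cfg$step,
                     fragment_length = cfg$fragment_length,
                     min_frac = cfg$min_frac, fdr = cfg$fdr,
                     min_log2_es = cfg$min_log2_es)
  manifest <- character(0)
  emit <- function(obj, name, writer = readr::write_tsv) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    manifest <<- c(manifest, name)
    path
  }

  conds <- sort(unique(call$peaks$condition))
  for (cond in conds) {
    pk <- filter(call$peaks, .data$condition == cond)
    emit(pk, paste0("peaks_", cond, ".bed"), write_peaks_bed)
    emit(filter(call$windows, .data$condition == cond) |>
           select("gene_id", "start", "end", "ip_count", "input_count",
                  "ip_norm", "input_norm", "p_value", "q_value", "es",
                  "positive"),
         paste0("windows_", cond, ".tsv"))
  }
  g <- glance(call)
  emit(g, "peak_calling_summary.tsv")
  for (i in seq_len(nrow(g))) {
    log_lines <- c(log_lines,
                   sprintf("condition %s: %d windows tested, %d positive, %d peaks, %d genes skipped",
                           g$condition[i], g$n_windows_tested[i],
                           g$n_positive[i], g$n_peaks[i], g$n_genes_skipped[i]))
  }

  comparison <- profiles <- regions <- motif <- recovery <- NULL
  if (length(conds) == 2L) {
    pa <- filter(call$peaks, .data$condition == conds[1])
    pb <- filter(call$peaks, .data$condition == conds[2])
    if (nrow(pa) && nrow(pb)) {
      comparison <- compare_peak_sets(pa, pb, models = select_longest_isoform(models))
      emit(comparison$common_pairs, "common_peak_pairs.tsv")
      emit(comparison$unique_a, paste0("unique_peaks_", conds[1], ".tsv"))
      emit(comparison$unique_b, paste0("unique_peaks_", conds[2], ".tsv"))
      emit(tidy(comparison), "gene_classes.tsv")
    }
  }
  profiles <- list(); regions <- list()
  for (cond in conds) {
    pk <- filter(call$peaks, .data$condition == cond)
    if (nrow(pk) == 0L) next
    prof <- metagene_profile(pk, models)
    profiles[[cond]] <- prof
    emit(as_tibble(prof), paste0("metagene_", cond, ".tsv"))
    regions[[cond]] <- region_proportions(pk, models)
    emit(regions[[cond]], paste0("regions_", cond, ".tsv"))
  }
  if (!is.null(sequences)) {
    motif <- purrr::map(conds, function(cond) {
      pk <- filter(call$peaks, .data$condition == cond)
      if (nrow(pk) == 0L) return(NULL)
      motif_enrichment(pk, sequences, motif = cfg$motif) |>
        mutate(condition = cond, .before = 1)
    }) |>
      dplyr::bind_rows()
    if (nrow(motif)) emit(motif, "motif_enrichment.tsv")
  }
  if (!is.null(sim) && nrow(sim$sites)) {
    recovery <- purrr::map(conds, function(cond) {
      rep <- evaluate_recovery(filter(call$peaks, .data$condition == cond),
                               sim$sites, tolerance = cfg$tolerance)
      tidy(rep) |> mutate(condition = cond, .before = 1)
    }) |>
      dplyr::bind_rows()
    emit(recovery, "recovery.tsv")
    log_lines <- c(log_lines,
                   sprintf("recovery [%s]: sensitivity %.3f precision %.3f",
                           recovery$condition, recovery$sensitivity,
                           recovery$precision))
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  jsonlite::write_json(list(outputs = c(manifest, "run_log.txt")),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(call = call, comparison = comparison, profiles = profiles,
                 regions = regions, motif = motif, recovery = recovery,
                 sim = sim, out_dir = out_dir,
                 manifest = c(manifest, "run_log.txt", "manifest.json")))
}
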