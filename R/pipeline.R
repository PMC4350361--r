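# End-to-end orchestration: one config, file-based stages, deterministic
# TSV outputs, a summary table and a machine-readable run manifest.

#' Pipeline configuration
#'
#' Collects input paths and thresholds for [run_pipeline()]. Thresholds
#' default to the analysis constants used throughout the package: 2-fold /
#' p < 1e-3 differential calls, minimum 5 counts, a 1 kb TSS binding
#' window, a 0.5 kb validation-candidate window, and a 1 kb bidirectional
#' promoter gap.
#'
#' @param annotation,peaks,counts,metadata Required input paths (GTF,
#'   narrowPeak/BED, counts TSV, metadata TSV).
#' @param coverage,decay,polya_labels Optional inputs: TSS coverage
#'   bedGraph, decay TSV (`gene_id`, `time_min`, `abundance`), training
#'   labels TSV (`gene_id`, `label`).
#' @param out_dir Output directory.
#' @param fc_threshold,p_threshold,min_count,tss_window,validation_window,bidirectional_gap,pseudocount
#'   Analysis thresholds.
#' @param seed Integer seed recorded in the manifest and used for any
#'   stage-level randomness.
#' @return A list of class `lnc_config`.
#' @export
pipeline_config <- function(annotation, peaks, counts, metadata,
                            coverage = NULL, decay = NULL,
                            polya_labels = NULL, out_dir = "lncmyc_out",
                            fc_threshold = 2, p_threshold = 1e-3,
                            min_count = 5, tss_window = 1000,
                            validation_window = 500,
                            bidirectional_gap = 1000, pseudocount = 0.5,
                            seed = 1) {
  cfg <- as.list(environment())
  thr <- c(cfg$fc_threshold, cfg$min_count, cfg$tss_window,
           cfg$validation_window, cfg$bidirectional_gap)
  if (any(thr <= 0) || cfg$p_threshold < 0) abort("thresholds must be positive")
  structure(cfg, class = "lnc_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return An `lnc_config` list.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

check_inputs_exist <- function(cfg) {
  need <- c(annotation = cfg$annotation, peaks = cfg$peaks,
            counts = cfg$counts, metadata = cfg$metadata)
  opt <- c(coverage = cfg$coverage, decay = cfg$decay,
           polya_labels = cfg$polya_labels)
  paths <- c(need, opt[!vapply(opt, is.null, logical(1))])
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing))
    abort(paste0("missing input file(s): ",
                 paste(sprintf("%s (%s)", names(missing), unlist(missing)),
                       collapse = ", ")))
  invisible(TRUE)
}

subset_counts <- function(counts, keep) {
  meta <- sample_meta(counts)
  count_matrix(tibble::as_tibble(counts)[, c("gene_id", meta$name[keep]),
                                         drop = FALSE],
               meta[keep, ])
}

#' Run the full analysis pipeline
#'
#' Executes, from the files named in the config: low-count filtering, CPM
#' normalization and the centered heatmap matrix, differential calling on
#' the ribo-depleted libraries, TSS occupancy at the binding and validation
#' windows, bidirectional-promoter detection and classification,
#' polyadenylation discrimination when both library preps are present (the
#' discriminant is trained on labelled coding genes), and half-life
#' estimation when a decay table is present. Every stage's table is written
#' as TSV into `out_dir`, together with `summary.tsv` and `manifest.json`
#' (package version, seed, thresholds, input checksums). Outputs are
#' deterministic: the same config and seed reproduce byte-identical files.
#'
#' @param cfg An `lnc_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return Invisibly, a named list with every stage result and the summary.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "lnc_config"))
  check_inputs_exist(cfg)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  set.seed(cfg$seed)
  out <- function(f) file.path(cfg$out_dir, f)

  genes <- read_gene_models(cfg$annotation)
  peaks <- read_peaks(cfg$peaks)
  counts <- read_counts(cfg$counts, cfg$metadata)
  meta <- sample_meta(counts)

  # expression and DE on the ribo-depleted libraries
  ribo <- subset_counts(counts, meta$library == "ribo_depleted")
  ribo_f <- filter_low(ribo, min_count = cfg$min_count)
  expr <- cpm(ribo_f, pseudocount = cfg$pseudocount)
  centered <- center_log2fc(expr)
  de <- call_de(ribo_f, fc_threshold = cfg$fc_threshold,
                p_threshold = cfg$p_threshold,
                pseudocount = cfg$pseudocount)
  readr::write_tsv(tibble::as_tibble(de), out("de_results.tsv"))
  readr::write_tsv(heatmap_matrix(centered, de), out("heatmap_matrix.tsv"))

  # occupancy
  occ <- assign_peak_occupancy(genes, peaks, window = cfg$tss_window)
  occ_val <- assign_peak_occupancy(genes, peaks, window = cfg$validation_window)
  readr::write_tsv(tibble::as_tibble(occ), out("occupancy.tsv"))

  detected <- ribo_f$gene_id
  genes_detected <- genes[genes$gene_id %in% detected, ]
  bf <- dplyr::bind_rows(
    bound_fraction(occ, genes_detected, "coding"),
    bound_fraction(occ, genes_detected, "lncRNA")
  )

  # expressed flags (either condition) and bidirectional classification
  expd <- expressed_genes(ribo, min_count = cfg$min_count)
  exp_any <- expd %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(expressed = any(.data$expressed), .groups = "drop")
  pairs <- detect_bidirectional(genes, max_gap = cfg$bidirectional_gap)
  de_all <- call_de(filter_low(ribo, min_count = 0),
                    fc_threshold = cfg$fc_threshold,
                    p_threshold = cfg$p_threshold,
                    pseudocount = cfg$pseudocount)
  bidir <- classify_bidirectional(pairs, exp_any, de_all, occ)
  bidir_tab <- bidirectional_summary(bidir)
  readr::write_tsv(tibble::as_tibble(bidir), out("bidirectional.tsv"))

  candidates <- select_validation_candidates(de, ribo_f, occ_val,
                                             window = cfg$validation_window)
  readr::write_tsv(tibble::tibble(gene_id = candidates),
                   out("validation_candidates.tsv"))

  # polyadenylation (needs both library preps and training labels)
  polya <- NULL
  if (all(c("ribo_depleted", "polyA") %in% meta$library) &&
      !is.null(cfg$polya_labels)) {
    labels <- readr::read_tsv(cfg$polya_labels, col_types = readr::cols(
      gene_id = readr::col_character(), label = readr::col_character()
    ))
    feats <- dplyr::bind_rows(
      polya_features(counts, "high_myc", pseudocount = cfg$pseudocount,
                     min_count = cfg$min_count),
      polya_features(counts, "low_myc", pseudocount = cfg$pseudocount,
                     min_count = cfg$min_count)
    )
    coding_ids <- genes$gene_id[genes$biotype == "coding"]
    train <- feats %>%
      dplyr::inner_join(labels, by = "gene_id") %>%
      dplyr::filter(.data$gene_id %in% coding_ids)
    d <- train_lda(train)
    calls <- classify_polya(d, feats)
    consensus <- polya_consensus(calls)
    psum <- polya_summary(consensus, genes)
    readr::write_tsv(dplyr::left_join(calls, consensus, by = "gene_id"),
                     out("polya_calls.tsv"))
    polya <- list(discriminant = d, calls = calls, consensus = consensus,
                  summary = psum)
  }

  # coverage profile
  profile <- NULL
  if (!is.null(cfg$coverage)) {
    cov <- read_bedgraph(cfg$coverage)
    key <- setNames(de_all$cpm_high + de_all$cpm_low, de_all$gene_id)
    profile <- occupancy_profile(genes_detected, cov, order_by = key)
    readr::write_tsv(tibble::as_tibble(profile), out("tss_profile.tsv"))
  }

  # kinetics
  half_lives <- NULL
  if (!is.null(cfg$decay)) {
    decay <- readr::read_tsv(cfg$decay, col_types = readr::cols(
      gene_id = readr::col_character(), time_min = readr::col_double(),
      abundance = readr::col_double()
    ))
    half_lives <- suppressWarnings(estimate_half_life(decay))
    readr::write_tsv(half_lives, out("half_lives.tsv"))
  }

  lnc_de <- de[de$gene_id %in% genes$gene_id[genes$biotype == "lncRNA"], ]
  summary_tbl <- dplyr::bind_rows(
    tibble::tibble(metric = "detected_genes", value = length(detected)),
    tibble::tibble(metric = "detected_lncRNA",
                   value = sum(genes_detected$biotype == "lncRNA")),
    tibble::tibble(metric = "lncRNA_up", value = sum(lnc_de$direction == "up")),
    tibble::tibble(metric = "lncRNA_down", value = sum(lnc_de$direction == "down")),
    tibble::tibble(metric = paste0("bound_fraction_", bf$biotype),
                   value = bf$fraction),
    tibble::tibble(metric = "n_bidirectional_pairs", value = nrow(pairs)),
    tibble::tibble(metric = paste0("bidir_", bidir_tab$category),
                   value = as.numeric(bidir_tab$n)),
    tibble::tibble(metric = "n_validation_candidates",
                   value = length(candidates)),
    if (!is.null(polya)) {
      tibble::tibble(metric = paste0("non_polya_fraction_", polya$summary$biotype),
                     value = polya$summary$fraction)
    }
  )
  readr::write_tsv(summary_tbl, out("summary.tsv"))

  manifest <- list(
    package = "lncmyc", version = as.character(packageVersion("lncmyc")),
    seed = cfg$seed,
    thresholds = cfg[c("fc_threshold", "p_threshold", "min_count",
                       "tss_window", "validation_window",
                       "bidirectional_gap", "pseudocount")],
    inputs = as.list(tools::md5sum(unlist(c(
      cfg$annotation, cfg$peaks, cfg$counts, cfg$metadata,
      cfg$coverage, cfg$decay, cfg$polya_labels
    ))))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(genes = genes, peaks = peaks, counts = counts, de = de,
                 de_all = de_all, occupancy = occ, occupancy_validation = occ_val,
                 bound_fractions = bf, pairs = pairs, bidirectional = bidir,
                 bidirectional_summary = bidir_tab, candidates = candidates,
                 polya = polya, profile = profile, half_lives = half_lives,
                 summary = summary_tbl))
}
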