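# Synthetic data with planted ground truth: annotation with divergent gene
# pairs, negative-binomial counts under two MYC states (with a global
# amplification factor in the high state), TSS-proximal peaks, dual-library
# polyadenylation structure, and exponential decay series.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the study conditions the package emulates at desk scale:
#' ~2,500 genes split coding/lncRNA, triplicate libraries per MYC state, 15%
#' of genes regulated (55% of those up, |log2 effect| 1.2-3), 18% of lncRNAs
#' non-polyadenylated, a global 2x transcriptional amplification in the
#' high-MYC state and a common negative-binomial dispersion of 0.05. The
#' regulated fraction is kept small so that planted regulation stays a minor
#' share of total RNA mass; within-sample (CPM) normalization then leaves
#' unregulated genes' ratios near 1, as in a real transcriptome where the
#' regulated transcripts are a sliver of library mass.
#'
#' @param n_coding,n_lncRNA Number of coding / lncRNA genes.
#' @param fraction_regulated Fraction of genes with a planted MYC response.
#' @param fraction_up Fraction of regulated genes that are upregulated.
#' @param effect_range Range (log2) from which planted |effect| is drawn.
#' @param fraction_bidirectional_pairs Fraction of lncRNA genes arranged as
#'   head-to-head divergent pairs (TSS gap drawn from 50-900 bp).
#' @param fraction_non_polyA Fraction of lncRNA genes lacking polyadenylation.
#' @param fraction_non_polyA_coding Fraction of coding genes lacking
#'   polyadenylation (small; provides the two classes needed to train the
#'   coding-based discriminant).
#' @param p_bound_regulated,p_bound_null Probability a regulated / unregulated
#'   gene has a planted TSS-proximal peak.
#' @param replicates Replicates per condition per library.
#' @param amplification_factor Global high-MYC RNA-per-cell multiplier
#'   (applied to every gene's expected molecule count before library-size
#'   normalization; >= 1).
#' @param dispersion Common negative-binomial dispersion (> 0; 0 = Poisson).
#' @param mean_log,sd_log Log-normal parameters of baseline expression means.
#' @param polya_residual Residual poly-A-library signal of non-polyadenylated
#'   genes, as a fraction of their ribo-depleted signal (keeps the
#'   discrimination problem non-separable).
#' @param libsize_sd Log-normal sd of per-sample library-size factors.
#' @param half_life_range Range (minutes) of planted transcript half-lives.
#' @param gene_length_range,intergenic_gap_range Layout parameters (bp).
#' @param chrom_length Optional chromosome length cap; layout aborts if genes
#'   cannot be packed within it.
#' @param per_cell_normalized If `TRUE`, expected counts are divided by the
#'   amplification factor in the high-MYC state, emulating spike-in
#'   (per-cell) normalized counts.
#' @param seed Integer seed; every generator draw derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_coding = 1100, n_lncRNA = 1400,
                       fraction_regulated = 0.15, fraction_up = 0.55,
                       effect_range = c(1.2, 3),
                       fraction_bidirectional_pairs = 0.2,
                       fraction_non_polyA = 0.18,
                       fraction_non_polyA_coding = 0.02,
                       p_bound_regulated = 0.85, p_bound_null = 0.35,
                       replicates = 3, amplification_factor = 2,
                       dispersion = 0.05, mean_log = log(200), sd_log = 1,
                       polya_residual = 0.02, libsize_sd = 0.1,
                       half_life_range = c(25, 215),
                       gene_length_range = c(500, 3000),
                       intergenic_gap_range = c(3000, 8000),
                       chrom_length = NULL, per_cell_normalized = FALSE,
                       seed = 1) {
  cfg <- as.list(environment())
  fr <- c(cfg$fraction_regulated, cfg$fraction_up,
          cfg$fraction_bidirectional_pairs, cfg$fraction_non_polyA,
          cfg$fraction_non_polyA_coding)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (cfg$n_coding < 0 || cfg$n_lncRNA < 0) abort("gene counts must be >= 0")
  if (cfg$amplification_factor < 1) abort("amplification_factor must be >= 1")
  if (cfg$dispersion < 0) abort("dispersion must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a gene annotation with planted truth
#'
#' Places genes on one synthetic chromosome without overlap, except for
#' planted divergent (head-to-head) lncRNA pairs whose TSS are separated by a
#' gap drawn uniformly from 50-900 bp. The returned truth table records, per
#' gene: biotype, regulation direction and log2 effect size, MYC binding,
#' polyadenylation status, baseline expression mean, true half-life, and
#' divergent-pair membership.
#'
#' @param cfg A [sim_config()].
#' @return `list(genes = <gene-model tibble>, truth = <truth tibble>)`; the
#'   truth tibble carries `amplification_factor`, `dispersion` and `seed` as
#'   attributes.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_coding + cfg$n_lncRNA
  if (n == 0L) {
    truth <- tibble::tibble(
      gene_id = character(), biotype = character(), regulation = character(),
      effect = double(), myc_bound = logical(), polyadenylated = logical(),
      base_mean = double(), true_half_life = double(), pair_id = character()
    )
    return(list(genes = empty_gene_models(),
                truth = structure(truth,
                                  amplification_factor = cfg$amplification_factor,
                                  dispersion = cfg$dispersion, seed = cfg$seed)))
  }

  biotype <- c(rep("coding", cfg$n_coding), rep("lncRNA", cfg$n_lncRNA))
  gene_id <- sprintf("SIMG%05d", seq_len(n))
  n_pairs <- floor(cfg$fraction_bidirectional_pairs * cfg$n_lncRNA / 2)
  lnc_idx <- which(biotype == "lncRNA")
  paired <- if (n_pairs > 0) sample(lnc_idx, 2 * n_pairs) else integer()
  pair_id <- rep(NA_character_, n)
  if (n_pairs > 0) {
    pair_id[paired] <- rep(sprintf("BP%04d", seq_len(n_pairs)), each = 2)
  }

  # layout units: each divergent pair is placed as one unit (minus gene then
  # plus gene), singles get a random strand
  units <- c(split(paired, pair_id[paired]), as.list(setdiff(seq_len(n), paired)))
  units <- units[sample(length(units))]

  glen <- function(k) sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]), k, replace = TRUE)
  ggap <- function(k) sample(seq(cfg$intergenic_gap_range[1], cfg$intergenic_gap_range[2]), k, replace = TRUE)

  chrom <- "chrS"
  pos <- 10000L
  start <- end <- tss <- integer(n)
  strand <- character(n)
  for (u in units) {
    if (length(u) == 2L) {
      la <- glen(1); lb <- glen(1); gap <- sample(50:900, 1)
      a <- u[1]; b <- u[2]
      strand[a] <- "-"; start[a] <- pos; end[a] <- pos + la
      tss[a] <- end[a] - 1L
      strand[b] <- "+"; start[b] <- tss[a] + gap; end[b] <- start[b] + lb
      tss[b] <- start[b]
      pos <- end[b] + ggap(1)
    } else {
      g <- u[1]; l <- glen(1)
      strand[g] <- sample(c("+", "-"), 1)
      start[g] <- pos; end[g] <- pos + l
      tss[g] <- tss_from_strand(start[g], end[g], strand[g])
      pos <- end[g] + ggap(1)
    }
  }
  if (!is.null(cfg$chrom_length) && pos > cfg$chrom_length) {
    abort(sprintf(paste0("cannot pack %d genes into a %d bp chromosome ",
                         "(need ~%d bp); increase chrom_length"),
                  n, cfg$chrom_length, pos))
  }

  # 1 or 2 exons per gene; two-exon genes get a short internal intron
  exons <- purrr::pmap(list(start, end), function(s, e) {
    if (e - s > 900 && runif(1) < 0.5) {
      b1 <- s + sample(200:400, 1)
      b2 <- b1 + sample(100:300, 1)
      cbind(start = c(s, b2), end = c(b1, e))
    } else cbind(start = s, end = e)
  })

  genes <- tibble::tibble(gene_id = gene_id, biotype = biotype, chrom = chrom,
                          strand = strand, start = start, end = end,
                          tss = tss, exons = exons) %>%
    dplyr::arrange(.data$start)

  regulated <- runif(n) < cfg$fraction_regulated
  up <- runif(n) < cfg$fraction_up
  regulation <- dplyr::case_when(regulated & up ~ "up",
                                 regulated & !up ~ "down",
                                 TRUE ~ "none")
  effect <- ifelse(regulation == "none", 0,
                   runif(n, cfg$effect_range[1], cfg$effect_range[2]) *
                     ifelse(regulation == "up", 1, -1))
  myc_bound <- runif(n) < ifelse(regulated, cfg$p_bound_regulated, cfg$p_bound_null)
  non_pa_frac <- ifelse(biotype == "lncRNA", cfg$fraction_non_polyA,
                        cfg$fraction_non_polyA_coding)
  polyadenylated <- runif(n) >= non_pa_frac
  base_mean <- rlnorm(n, meanlog = cfg$mean_log, sdlog = cfg$sd_log)
  true_half_life <- runif(n, cfg$half_life_range[1], cfg$half_life_range[2])

  truth <- tibble::tibble(
    gene_id = gene_id, biotype = biotype, regulation = regulation,
    effect = effect, myc_bound = myc_bound, polyadenylated = polyadenylated,
    base_mean = base_mean, true_half_life = true_half_life, pair_id = pair_id
  )[match(genes$gene_id, gene_id), ]

  list(genes = genes,
       truth = structure(truth, amplification_factor = cfg$amplification_factor,
                         dispersion = cfg$dispersion, seed = cfg$seed))
}

#' Build a sample design table
#'
#' @param replicates Replicates per condition per library.
#' @param libraries Library preparations to include.
#' @param cell_line Cell line label.
#' @return A sample metadata tibble (see [read_sample_metadata()]).
#' @export
sim_design <- function(replicates = 3,
                       libraries = c("ribo_depleted", "polyA"),
                       cell_line = "SIM1") {
  grid <- tidyr::expand_grid(library = libraries,
                             condition = c("high_myc", "low_myc"),
                             replicate = seq_len(replicates))
  short <- c(ribo_depleted = "ribo", polyA = "polya")
  cond <- c(high_myc = "high", low_myc = "low")
  dplyr::mutate(grid,
                name = paste(short[.data$library], cond[.data$condition],
                             .data$replicate, sep = "_"),
                cell_line = cell_line) %>%
    dplyr::select("name", "condition", "library", "cell_line", "replicate")
}

#' Simulate negative-binomial counts under planted truth
#'
#' Per gene and sample the expected count is the baseline mean, times
#' `2^effect` in high-MYC samples of regulated genes, times the global
#' amplification factor in all high-MYC samples, times the residual fraction
#' in poly-A libraries for non-polyadenylated genes, times a drawn per-sample
#' library-size factor. Counts are negative binomial with the common
#' dispersion (Poisson when the dispersion is zero).
#'
#' @param truth Truth tibble from [simulate_annotation()].
#' @param design Sample metadata tibble with >= 2 replicates per condition
#'   and both conditions present.
#' @param amplification_factor,dispersion Override the values attached to
#'   `truth`.
#' @param polya_residual Residual poly-A signal fraction for
#'   non-polyadenylated genes.
#' @param libsize_sd Log-normal sd of library-size factors.
#' @param per_cell_normalized Emulate spike-in normalized counts (divides the
#'   high-MYC expectation by the amplification factor).
#' @param seed Integer seed.
#' @return An `lnc_counts` tibble with `design` attached as sample metadata.
#' @export
simulate_counts <- function(truth, design,
                            amplification_factor = attr(truth, "amplification_factor") %||% 2,
                            dispersion = attr(truth, "dispersion") %||% 0.05,
                            polya_residual = 0.02, libsize_sd = 0.1,
                            per_cell_normalized = FALSE, seed = 1) {
  design <- validate_sample_metadata(design)
  reps <- dplyr::count(design, .data$condition)
  if (nrow(reps) < 2L)
    abort("design must include both high_myc and low_myc conditions")
  if (any(reps$n < 2L)) abort("need >= 2 replicates per condition")
  set.seed(seed)

  n <- nrow(truth); m <- nrow(design)
  sf <- rlnorm(m, 0, libsize_sd)
  amp <- if (per_cell_normalized) 1 else amplification_factor
  high <- design$condition == "high_myc"
  pa_lib <- design$library == "polyA"
  mu <- outer(truth$base_mean, rep(1, m))
  mu <- mu * outer(2^truth$effect, as.numeric(high), `^`)
  mu <- mu * matrix(rep(ifelse(high, amp, 1), each = n), n, m)
  resid <- outer(!truth$polyadenylated, pa_lib, `&`)
  mu[resid] <- mu[resid] * polya_residual
  mu <- mu * matrix(rep(sf, each = n), n, m)

  counts <- if (dispersion > 0) {
    matrix(rnbinom(n * m, size = 1 / dispersion, mu = mu), n, m)
  } else {
    matrix(rpois(n * m, lambda = mu), n, m)
  }
  tb <- tibble::as_tibble(as.data.frame(counts), .name_repair = "minimal")
  names(tb) <- design$name
  count_matrix(dplyr::bind_cols(tibble::tibble(gene_id = truth$gene_id), tb),
               design)
}

#' Simulate TSS-proximal ChIP-seq peaks
#'
#' Each planted-bound gene gets one peak whose summit is drawn from a normal
#' distribution centered on the TSS (sd `summit_sd`), truncated to
#' `+/- max_offset` bp. Decoy peaks are placed at least `decoy_min_dist` bp
#' from every TSS. Peaks at regulated bound genes receive higher scores.
#'
#' @param genes,truth Output of [simulate_annotation()].
#' @param summit_sd Summit placement sd in bp.
#' @param max_offset Truncation half-width in bp.
#' @param n_decoys Number of TSS-distal decoy peaks.
#' @param decoy_min_dist Minimum decoy-to-TSS distance in bp.
#' @param seed Integer seed.
#' @return A peak tibble (see [read_peaks()]).
#' @export
simulate_peaks <- function(genes, truth, summit_sd = 150, max_offset = 500,
                           n_decoys = round(0.3 * nrow(genes)),
                           decoy_min_dist = 5000, seed = 1) {
  set.seed(seed)
  bound <- truth[truth$myc_bound, ]
  out <- empty_peaks()
  if (nrow(bound) > 0) {
    tssv <- genes$tss[match(bound$gene_id, genes$gene_id)]
    off <- rnorm(nrow(bound), 0, summit_sd)
    while (any(abs(off) > max_offset)) {
      bad <- abs(off) > max_offset
      off[bad] <- rnorm(sum(bad), 0, summit_sd)
    }
    summit <- as.integer(round(tssv + off))
    half_l <- sample(80:200, nrow(bound), replace = TRUE)
    half_r <- sample(80:200, nrow(bound), replace = TRUE)
    score <- pmax(0.5, rnorm(nrow(bound), 5, 1) +
                    3 * (bound$regulation != "none"))
    out <- tibble::tibble(
      peak_id = paste0("peak_", bound$gene_id),
      chrom = genes$chrom[match(bound$gene_id, genes$gene_id)],
      start = pmax(0L, summit - half_l), end = summit + half_r + 1L,
      summit = summit, score = score
    )
  }
  if (n_decoys > 0 && nrow(genes) > 0) {
    span <- max(genes$end) + 50000L
    placed <- integer(0)
    tries <- 0L
    while (length(placed) < n_decoys && tries < 200L) {
      cand <- as.integer(runif(2L * n_decoys, 0, span))
      d <- vapply(cand, function(p) min(abs(p - genes$tss)), numeric(1))
      cand <- cand[d >= decoy_min_dist]
      placed <- head(c(placed, cand), n_decoys)
      tries <- tries + 1L
    }
    if (length(placed)) {
      half <- sample(80:200, length(placed), replace = TRUE)
      out <- dplyr::bind_rows(out, tibble::tibble(
        peak_id = sprintf("decoy_%04d", seq_along(placed)),
        chrom = genes$chrom[1], start = pmax(0L, placed - half),
        end = placed + half + 1L, summit = placed,
        score = pmax(0.1, rnorm(length(placed), 2, 0.5))
      ))
    }
  }
  dplyr::arrange(out, .data$start)
}

#' Simulate transcription-shutoff decay series
#'
#' Relative abundance follows first-order decay, `N(t) = 2^(-t / t_half)`,
#' multiplied by log-normal noise of the given coefficient of variation. The
#' baseline N0 at t = 0 is 1 by construction and is not emitted.
#'
#' @param truth Truth tibble with `true_half_life` (minutes).
#' @param times Sampling times in minutes, strictly positive; defaults to the
#'   standard 30/60/120/240-minute harvest grid.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param seed Integer seed.
#' @return Tibble: `gene_id`, `time_min`, `abundance`.
#' @export
simulate_decay <- function(truth, times = c(30, 60, 120, 240), cv = 0.1,
                           seed = 1) {
  if (cv < 0) abort("cv must be >= 0")
  if (any(times <= 0)) abort("times must be strictly positive")
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  grid <- tidyr::expand_grid(gene_id = truth$gene_id, time_min = times) %>%
    dplyr::left_join(dplyr::select(truth, "gene_id", "true_half_life"),
                     by = "gene_id")
  noise <- if (cv == 0) 1 else exp(rnorm(nrow(grid), -sdlog^2 / 2, sdlog))
  dplyr::transmute(grid, gene_id = .data$gene_id, time_min = .data$time_min,
                   abundance = 2^(-.data$time_min / .data$true_half_life) * noise)
}

#' Write a complete synthetic bundle to a directory
#'
#' Runs the whole generator under one configuration and writes
#' `annotation.gtf`, `peaks.narrowPeak`, `counts.tsv`, `metadata.tsv`,
#' `decay.tsv`, and the planted `truth.tsv` beside them, so that every
#' downstream stage can be run from files and scored against truth.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return Named list of file paths, invisibly; also returns the in-memory
#'   objects in the `objects` element.
#' @export
simulate_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ann <- simulate_annotation(cfg)
  design <- sim_design(replicates = cfg$replicates)
  counts <- simulate_counts(ann$truth, design,
                            amplification_factor = cfg$amplification_factor,
                            dispersion = cfg$dispersion,
                            polya_residual = cfg$polya_residual,
                            libsize_sd = cfg$libsize_sd,
                            per_cell_normalized = cfg$per_cell_normalized,
                            seed = cfg$seed + 1L)
  peaks <- simulate_peaks(ann$genes, ann$truth, seed = cfg$seed + 2L)
  decay <- simulate_decay(ann$truth, cv = 0.1, seed = cfg$seed + 3L)

  paths <- list(
    annotation = file.path(dir, "annotation.gtf"),
    peaks = file.path(dir, "peaks.narrowPeak"),
    counts = file.path(dir, "counts.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    decay = file.path(dir, "decay.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_gene_models(ann$genes, paths$annotation)
  write_peaks(peaks, paths$peaks)
  write_counts(counts, paths$counts, paths$metadata)
  readr::write_tsv(decay, paths$decay)
  readr::write_tsv(tibble::as_tibble(ann$truth), paths$truth)
  invisible(c(paths, list(objects = list(genes = ann$genes, truth = ann$truth,
                                         design = design, counts = counts,
                                         peaks = peaks, decay = decay))))
}
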