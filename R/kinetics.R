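# Transcript half-life from transcription-shutoff (Actinomycin D) decay
# series, and relative quantification by delta-delta-Cq with either cellular
# reference transcripts (geometric-mean aggregation) or a spike-in control.

#' Per-time-point half-life
#'
#' First-order decay gives `t_half = t * ln(2) / (ln(N0) - ln(N))` for a
#' single measurement of relative abundance `N` at time `t` minutes after
#' transcription shutoff, with baseline `N0` at t = 0. Time points with
#' `N >= N0` (no apparent decay) are invalid and return `NA`, which
#' downstream means exclude. The estimate is invariant to rescaling `N0`
#' and `N` by a common factor.
#'
#' @param t Time in minutes (> 0); vectorized.
#' @param n0 Baseline abundance (> 0).
#' @param n Abundance at time `t` (> 0).
#' @return Half-life in minutes, `NA` where `n >= n0`.
#' @export
half_life_single <- function(t, n0, n) {
  if (any(t <= 0)) abort("t must be > 0")
  if (any(n0 <= 0) || any(n <= 0)) abort("abundances must be > 0")
  out <- t * log(2) / (log(n0) - log(n))
  out[n >= n0] <- NA_real_
  out
}

#' Estimate half-lives from decay series
#'
#' For every gene, computes the per-time-point half-life and reports its
#' arithmetic mean over the valid points (the summary used with the
#' standard four-point 30/60/120/240-minute harvest design), along with the
#' number of excluded points and, as an alternative estimator, the
#' log-linear regression slope fit (`t_half = -1/slope` of
#' `log2(N) ~ t`, through the `log2(N0)` intercept left free).
#'
#' @param series Tibble with columns `gene_id`, `time_min`, `abundance`.
#' @param n0 Baseline abundance at t = 0 (default 1).
#' @return Tibble: `gene_id`, `half_life` (mean of valid per-point
#'   estimates), `half_life_reg` (regression alternative), `n_points`,
#'   `n_excluded`. Genes with zero valid points get `NA` with a warning.
#' @export
estimate_half_life <- function(series, n0 = 1) {
  out <- series %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      half_life = {
        hl <- half_life_single(.data$time_min, n0, .data$abundance)
        if (all(is.na(hl))) NA_real_ else mean(hl, na.rm = TRUE)
      },
      half_life_reg = {
        if (dplyr::n() >= 2 && var(.data$time_min) > 0) {
          sl <- unname(coef(lm(log2(.data$abundance) ~ .data$time_min))[2])
          if (is.na(sl) || sl >= 0) NA_real_ else -1 / sl
        } else NA_real_
      },
      n_points = dplyr::n(),
      n_excluded = sum(.data$abundance >= n0),
      .groups = "drop"
    )
  if (any(is.na(out$half_life)))
    warn(paste0("no valid decay points for gene(s): ",
                paste(out$gene_id[is.na(out$half_life)], collapse = ", ")))
  out
}

ddcq_folds <- function(cq, target, references, calibrator, label) {
  need <- c("sample", "gene", "cq")
  if (!all(need %in% names(cq))) abort("cq table needs columns sample, gene, cq")
  if (!all(is.finite(cq$cq))) abort("all Cq values must be finite")
  samples <- unique(cq$sample)
  if (!calibrator %in% samples) abort("calibrator sample not found")
  ref <- cq[cq$gene %in% references, ]
  have <- table(factor(ref$sample, levels = samples))
  if (any(have < length(references))) {
    abort(paste0("missing ", label, " Cq in sample(s): ",
                 paste(names(have)[have < length(references)], collapse = ", ")))
  }
  tgt <- cq[cq$gene == target, ]
  if (!all(samples %in% tgt$sample)) abort("missing target Cq in some sample(s)")
  # arithmetic mean of reference Cqs == geometric mean of reference
  # quantities under amplification efficiency 2
  ref_mean <- tapply(ref$cq, ref$sample, mean)
  dcq <- setNames(as.numeric(tgt$cq[match(samples, tgt$sample)] -
                               ref_mean[samples]), samples)
  ddcq <- dcq - dcq[[calibrator]]
  tibble::tibble(sample = samples, delta_cq = unname(dcq),
                 delta_delta_cq = unname(ddcq), fold = 2^(-unname(ddcq)))
}

#' Relative expression by delta-delta-Cq
#'
#' `dCq = Cq_target - mean(Cq_references)` per sample (with amplification
#' efficiency 2, the arithmetic mean of reference Cqs is equivalent to the
#' geometric mean of reference quantities); `ddCq` subtracts the calibrator
#' sample's `dCq`; the fold change is `2^(-ddCq)`. The calibrator's fold is
#' 1 by construction.
#'
#' @param cq Long tibble: `sample`, `gene`, `cq`.
#' @param target Target gene name.
#' @param references Character vector of reference gene names (>= 1),
#'   typically MYC-insensitive transcripts.
#' @param calibrator Calibrator sample name.
#' @return Tibble: `sample`, `delta_cq`, `delta_delta_cq`, `fold`.
#' @export
qpcr_relative <- function(cq, target, references, calibrator) {
  if (length(references) < 1) abort("need >= 1 reference gene")
  ddcq_folds(cq, target, references, calibrator, "reference")
}

#' Relative nascent transcription with spike-in normalization
#'
#' Nuclear run-on quantification: the same delta-delta-Cq arithmetic as
#' [qpcr_relative()] but normalized to an exogenous spike-in transcript as
#' the sole reference. Because the spike-in is added at a fixed amount per
#' reaction and is independent of the cells, this normalization preserves
#' global (amplification) differences in transcriptional output that
#' cellular reference transcripts would erase.
#'
#' @param cq Long tibble: `sample`, `gene`, `cq`.
#' @param target Target gene name.
#' @param spike Spike-in transcript name.
#' @param calibrator Calibrator sample name.
#' @return Tibble: `sample`, `delta_cq`, `delta_delta_cq`, `fold`.
#' @export
nro_normalize <- function(cq, target, spike, calibrator) {
  ddcq_folds(cq, target, spike, calibrator, "spike-in")
}

#' Pearson correlation with a two-sided p-value
#'
#' Thin wrapper around the t-transform test of the sample Pearson
#' correlation (n - 2 degrees of freedom).
#'
#' @param x,y Numeric vectors, n >= 3, each with nonzero variance.
#' @return Tibble: `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need n >= 3")
  if (var(x) == 0 || var(y) == 0) abort("zero variance input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
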