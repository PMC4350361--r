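# Normalization and differential expression. The DE caller is a
# self-contained negative-binomial exact test with a single common
# dispersion estimated by method of moments; significance uses the
# fold-change > 2 and raw p < 1e-3 rule, with BH FDR reported alongside.

counts_mat <- function(counts) {
  m <- as.matrix(tibble::as_tibble(counts)[, -1])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

#' Counts-per-million normalization
#'
#' CPM is `count * 1e6 / library size` per sample; `log2cpm` is
#' `log2(CPM + pseudocount)`.
#'
#' @param counts An `lnc_counts` tibble (see [count_matrix()]).
#' @param pseudocount Added inside the log2 (default 0.5).
#' @return A long tibble `gene_id`, `sample`, `cpm`, `log2cpm`, classed
#'   `lnc_expr` with the pseudocount attached.
#' @export
cpm <- function(counts, pseudocount = 0.5) {
  m <- counts_mat(counts)
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(paste0("sample(s) with zero total count: ",
                 paste(colnames(m)[tot == 0], collapse = ", ")))
  }
  cpmm <- sweep(m, 2, tot, `/`) * 1e6
  out <- tibble::tibble(
    gene_id = rep(rownames(m), times = ncol(m)),
    sample = rep(colnames(m), each = nrow(m)),
    cpm = as.vector(cpmm),
    log2cpm = log2(as.vector(cpmm) + pseudocount)
  )
  structure(out, pseudocount = pseudocount,
            class = c("lnc_expr", class(out)))
}

#' Remove genes with low counts
#'
#' Keeps genes whose minimum count across all samples is at least
#' `min_count`; genes with less than `min_count` reads in their lowest
#' sample are filtered out.
#'
#' @param counts An `lnc_counts` tibble.
#' @param min_count Minimum per-sample count (default 5).
#' @return The filtered `lnc_counts` tibble.
#' @export
filter_low <- function(counts, min_count = 5) {
  m <- counts_mat(counts)
  keep <- apply(m, 1, min) >= min_count
  count_matrix(tibble::as_tibble(counts)[keep, , drop = FALSE],
               sample_meta(counts))
}

#' Row-centered log2 fold-change matrix
#'
#' For each gene (row), subtracts the mean log2 CPM across the N samples:
#' `log2FC[s, gene] = log2CPM[s, gene] - mean_s'(log2CPM[s', gene])`, the
#' display transform used for expression heatmaps. Every centered row sums
#' to zero by construction.
#'
#' @param expr An `lnc_expr` tibble from [cpm()].
#' @return A wide tibble, `gene_id` plus one centered column per sample.
#' @export
center_log2fc <- function(expr) {
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(expr), "gene_id", "sample", "log2cpm"),
    names_from = "sample", values_from = "log2cpm"
  )
  m <- as.matrix(wide[, -1])
  m <- m - rowMeans(m)
  dplyr::bind_cols(wide[, 1], tibble::as_tibble(as.data.frame(m)))
}

# Common NB dispersion by method of moments: pooled within-condition
# residual variance (on size-factor-normalized counts) against the
# quadratic mean term, phi = sum(v - m) / sum(m^2), truncated at zero.
#' Estimate a common negative-binomial dispersion
#'
#' Method-of-moments estimate pooled across genes and conditions: per gene
#' and condition the sample variance of size-factor-normalized counts is
#' compared with the NB relation `var = mu + phi * mu^2`, and the ratio of
#' summed residuals `sum(var - mu) / sum(mu^2)` over all genes gives phi
#' (truncated at zero). On Poisson data the estimate converges to 0.
#'
#' @param counts An `lnc_counts` tibble.
#' @param lib_sizes Optional library sizes (default column totals).
#' @return A single dispersion value >= 0.
#' @export
estimate_common_dispersion <- function(counts, lib_sizes = NULL) {
  m <- counts_mat(counts)
  meta <- sample_meta(counts)
  ls <- lib_sizes %||% colSums(m)
  sf <- ls / mean(ls)
  y <- sweep(m, 2, sf, `/`)
  num <- 0; den <- 0
  for (cond in unique(meta$condition)) {
    yc <- y[, meta$condition == cond, drop = FALSE]
    if (ncol(yc) < 2) next
    mu <- rowMeans(yc)
    v <- apply(yc, 1, var)
    num <- num + sum(v - mu)
    den <- den + sum(mu^2)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

# Two-sided exact test for a single gene: condition on the total t of the
# two group sums, whose null split follows the conditional distribution of
# SA ~ NB(muA, n1/phi) given SA + SB = t (binomial in the Poisson limit).
nb_exact_p <- function(sA, sB, n1, n2, N1, N2, phi) {
  t <- sA + sB
  if (t == 0) return(1)
  pA <- N1 / (N1 + N2)
  if (t <= 20000L) a <- 0:t else {
    s1 <- n1 / max(phi, 1e-8); s2 <- n2 / max(phi, 1e-8)
    lo <- stats::qnbinom(1e-14, size = s1, mu = t * pA)
    hi <- stats::qnbinom(1e-14, size = s1, mu = t * pA, lower.tail = FALSE)
    a <- max(0, min(lo, sA)):min(t, max(hi, sA))
  }
  if (phi <= 0) {
    logf <- dbinom(a, t, pA, log = TRUE)
  } else {
    s1 <- n1 / phi; s2 <- n2 / phi
    logf <- dnbinom(a, size = s1, mu = t * pA, log = TRUE) +
      dnbinom(t - a, size = s2, mu = t * (1 - pA), log = TRUE)
    logf <- logf - max(logf)
    logf <- logf - log(sum(exp(logf)))
  }
  f <- exp(logf)
  pobs <- f[match(sA, a)]
  min(1, sum(f[f <= pobs * (1 + 1e-10)]))
}

#' Call differential expression between MYC states
#'
#' Per-gene two-sided p-values come from a negative-binomial exact test
#' conditioning on the total count of the two condition groups, with a
#' single common dispersion estimated by method of moments (see
#' [estimate_common_dispersion()]). The fold change is the ratio of
#' condition-mean CPM (high over low MYC) with a pseudocount; a gene is
#' `significant` when the fold change exceeds `fc_threshold` in either
#' direction and the raw p-value is below `p_threshold`. BH-adjusted FDR is
#' reported for context but not thresholded.
#'
#' @param counts An `lnc_counts` tibble from a single library preparation
#'   and cell line, with >= 2 replicates in each condition.
#' @param fc_threshold Fold-change threshold (default 2; applied two-sided,
#'   up if ratio > 2, down if < 0.5).
#' @param p_threshold Raw p-value threshold (default 1e-3).
#' @param pseudocount Pseudocount for the CPM ratio (default 0.5).
#' @param dispersion Optional fixed dispersion; estimated when `NULL`.
#' @param lib_sizes Optional library sizes (default column totals); only
#'   their ratios matter, so rescaling all of them by a common factor leaves
#'   results unchanged.
#' @return A tibble classed `lnc_de`: `gene_id`, `cpm_high`, `cpm_low`,
#'   `log2fc`, `p_value`, `fdr`, `significant`, `direction`; the dispersion
#'   and thresholds are attached as attributes.
#' @export
call_de <- function(counts, fc_threshold = 2, p_threshold = 1e-3,
                    pseudocount = 0.5, dispersion = NULL, lib_sizes = NULL) {
  meta <- sample_meta(counts)
  if (length(unique(meta$library)) > 1)
    abort("mixed library preparations; call_de requires a single library prep")
  if (length(unique(meta$cell_line)) > 1)
    abort("mixed cell lines; call_de requires a single cell line")
  conds <- unique(meta$condition)
  if (length(conds) < 2)
    abort("both high_myc and low_myc conditions are required")
  if (any(table(meta$condition) < 2))
    abort("need >= 2 replicates per condition")

  m <- counts_mat(counts)
  ls <- lib_sizes %||% colSums(m)
  phi <- dispersion %||% estimate_common_dispersion(counts, lib_sizes = ls)

  hi <- meta$condition == "high_myc"
  n1 <- sum(hi); n2 <- sum(!hi)
  N1 <- sum(ls[hi]); N2 <- sum(ls[!hi])
  sA <- rowSums(m[, hi, drop = FALSE])
  sB <- rowSums(m[, !hi, drop = FALSE])

  p <- vapply(seq_len(nrow(m)), function(i) {
    nb_exact_p(sA[i], sB[i], n1, n2, N1, N2, phi)
  }, numeric(1))

  # only library-size ratios matter: rescale supplied sizes to the count
  # total so CPM (and the pseudocount's weight) is scale-free
  ls_cpm <- ls * sum(m) / sum(ls)
  cpmm <- sweep(m, 2, ls_cpm, `/`) * 1e6
  cpm_high <- unname(rowMeans(cpmm[, hi, drop = FALSE]))
  cpm_low <- unname(rowMeans(cpmm[, !hi, drop = FALSE]))
  log2fc <- log2((cpm_high + pseudocount) / (cpm_low + pseudocount))
  significant <- abs(log2fc) > log2(fc_threshold) & p < p_threshold
  direction <- dplyr::case_when(significant & log2fc > 0 ~ "up",
                                significant & log2fc < 0 ~ "down",
                                TRUE ~ "none")
  out <- tibble::tibble(
    gene_id = rownames(m), cpm_high = cpm_high, cpm_low = cpm_low,
    log2fc = log2fc, p_value = p, fdr = p.adjust(p, method = "BH"),
    significant = significant, direction = direction
  )
  structure(out, dispersion = phi, fc_threshold = fc_threshold,
            p_threshold = p_threshold, pseudocount = pseudocount,
            class = c("lnc_de", class(out)))
}

#' Select lncRNA validation candidates
#'
#' Applies the machine-checkable wet-lab candidate filter: significantly
#' upregulated more than `fc_min`-fold, detected with more than `min_reads`
#' reads in every sample (strict), and a binding peak within
#' `+/- window` bp of the TSS. The supplied occupancy must have been
#' computed at that window, otherwise the criterion would not match.
#'
#' @param de An `lnc_de` tibble.
#' @param counts The `lnc_counts` tibble the DE was computed from.
#' @param occupancy A TSS-occupancy tibble from [assign_peak_occupancy()]
#'   computed at `window`.
#' @param fc_min Fold-change floor (default 8).
#' @param min_reads Per-sample read floor, strict `>` (default 5).
#' @param window Required occupancy window in bp (default 500).
#' @return Character vector of selected gene ids.
#' @export
select_validation_candidates <- function(de, counts, occupancy, fc_min = 8,
                                         min_reads = 5, window = 500) {
  w <- attr(occupancy, "window")
  if (is.null(w) || w != window)
    abort(sprintf("occupancy was computed at window %s, expected %d",
                  w %||% "<unknown>", window))
  m <- counts_mat(counts)
  min_per_gene <- apply(m, 1, min)
  detected <- rownames(m)[min_per_gene > min_reads]
  up8 <- de$gene_id[de$significant & de$log2fc > log2(fc_min)]
  bound <- occupancy$gene_id[occupancy$bound]
  sort(intersect(intersect(up8, detected), bound))
}

#' Genes expressed per condition
#'
#' A gene counts as expressed in a condition when every replicate of that
#' condition has at least `min_count` reads.
#'
#' @param counts An `lnc_counts` tibble.
#' @param min_count Per-replicate floor (default 5).
#' @return Tibble `gene_id`, `condition`, `expressed`, plus an `any`
#'   summary via `tidyr::pivot_wider` if needed downstream.
#' @export
expressed_genes <- function(counts, min_count = 5) {
  m <- counts_mat(counts)
  meta <- sample_meta(counts)
  purrr::map_dfr(unique(meta$condition), function(cond) {
    mc <- m[, meta$condition == cond, drop = FALSE]
    tibble::tibble(gene_id = rownames(m), condition = cond,
                   expressed = apply(mc, 1, min) >= min_count)
  })
}

#' Export the expression heatmap matrix
#'
#' Centered log2 fold-change matrix with transcripts ordered by the change
#' in expression (DE log2 fold change, most upregulated first).
#'
#' @param centered Wide centered matrix from [center_log2fc()].
#' @param de An `lnc_de` tibble supplying the ordering key.
#' @return The reordered wide tibble.
#' @export
heatmap_matrix <- function(centered, de) {
  key <- de$log2fc[match(centered$gene_id, de$gene_id)]
  centered[order(-key, centered$gene_id), , drop = FALSE]
}
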