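# Polyadenylation discrimination: per-gene features compare ribo-depleted
# and poly-A library signal, a two-class Fisher linear discriminant trained
# on coding transcripts separates polyadenylated from non-polyadenylated
# genes, and ordinary least squares summarizes the library agreement.

#' Per-gene ribo-vs-polyA features
#'
#' For one condition, computes per gene the mean log2 CPM across
#' ribo-depleted samples (`ribo`) and across poly-A samples (`polya`).
#' Genes are first filtered with [filter_low()] (default minimum 5 counts in
#' the lowest sample) applied to the ribo-depleted samples of the condition:
#' the ribo-depleted library sees transcripts regardless of their poly-A
#' status, so detection is assessed there, while filtering on poly-A counts
#' would discard precisely the non-polyadenylated genes the classifier is
#' meant to find.
#'
#' @param counts An `lnc_counts` tibble containing both library preps.
#' @param condition Condition to use (`"high_myc"` or `"low_myc"`).
#' @param pseudocount Pseudocount for log2 CPM (default 0.5).
#' @param min_count Low-count filter threshold (default 5).
#' @return Tibble: `gene_id`, `condition`, `ribo`, `polya`.
#' @export
polya_features <- function(counts, condition, pseudocount = 0.5,
                           min_count = 5) {
  meta <- sample_meta(counts)
  keep <- meta$condition == condition
  if (!any(keep & meta$library == "ribo_depleted") ||
      !any(keep & meta$library == "polyA"))
    abort("need both ribo_depleted and polyA samples in the condition")
  sub <- count_matrix(
    tibble::as_tibble(counts)[, c("gene_id", meta$name[keep]), drop = FALSE],
    meta[keep, ]
  )
  msub0 <- sample_meta(sub)
  ribo_only <- count_matrix(
    tibble::as_tibble(sub)[, c("gene_id",
                               msub0$name[msub0$library == "ribo_depleted"]),
                           drop = FALSE],
    msub0[msub0$library == "ribo_depleted", ]
  )
  detected <- filter_low(ribo_only, min_count = min_count)$gene_id
  sub <- count_matrix(tibble::as_tibble(sub)[sub$gene_id %in% detected, ,
                                             drop = FALSE], msub0)
  expr <- cpm(sub, pseudocount = pseudocount)
  msub <- sample_meta(sub)
  lib <- setNames(msub$library, msub$name)
  tibble::as_tibble(expr) %>%
    dplyr::mutate(library = unname(lib[.data$sample])) %>%
    dplyr::group_by(.data$gene_id, .data$library) %>%
    dplyr::summarise(mean_log2cpm = mean(.data$log2cpm), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "library", values_from = "mean_log2cpm") %>%
    dplyr::transmute(gene_id = .data$gene_id, condition = condition,
                     ribo = .data$ribo_depleted, polya = .data$polyA)
}

#' Ordinary least-squares fit with diagnostics
#'
#' @param x,y Numeric vectors of equal length, n >= 3; `x` must vary.
#' @return A list of class `lnc_linfit`: `slope`, `intercept`, `r_squared`,
#'   `p_value` (two-sided, from the slope t statistic), `n`, and the
#'   underlying `lm` fit.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need n >= 3")
  if (var(x) == 0) abort("zero variance in x")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2, 4]),
                 n = length(x), fit = fit),
            class = "lnc_linfit")
}

#' @exportS3Method generics::tidy
tidy.lnc_linfit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.lnc_linfit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, p_value = x$p_value, n = x$n)
}

#' @export
print.lnc_linfit <- function(x, ...) {
  cat(sprintf("Linear fit (n = %d): y = %.4f x + %.4f, R^2 = %.4f, p = %.3g\n",
              x$n, x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' Train a two-class Fisher linear discriminant
#'
#' Fits the classical equal-covariance discriminant on the 2-D feature space
#' (`ribo`, `polya`): `w = S^-1 (mu_polyA - mu_non)` with `S` the pooled
#' within-class covariance, and the decision offset at the midpoint of the
#' projected class means shifted by the log prior ratio (equal priors by
#' default). The score `w . v - offset` is positive for the `polyA` side.
#' Because the discriminating direction is dominated by the polyA:ribo
#' log-ratio, the equivalent 1-D ratio threshold is exposed in the fitted
#' object.
#'
#' @param features Tibble with columns `ribo`, `polya`, `label`
#'   (`"polyA"`/`"non_polyA"`), >= 2 examples per class.
#' @param priors Named prior probabilities (default equal).
#' @return A list of class `lnc_lda`: `weights`, `offset`, `means`,
#'   `pooled_cov`, `n`, `priors`.
#' @export
train_lda <- function(features, priors = c(polyA = 0.5, non_polyA = 0.5)) {
  if (!all(c("ribo", "polya", "label") %in% names(features)))
    abort("features must have columns ribo, polya, label")
  lab <- features$label
  if (!all(lab %in% c("polyA", "non_polyA")))
    abort("labels must be 'polyA' or 'non_polyA'")
  n1 <- sum(lab == "polyA"); n0 <- sum(lab == "non_polyA")
  if (n1 < 2 || n0 < 2) abort("need >= 2 training examples per class")
  X <- as.matrix(features[, c("ribo", "polya")])
  X1 <- X[lab == "polyA", , drop = FALSE]
  X0 <- X[lab == "non_polyA", , drop = FALSE]
  mu1 <- colMeans(X1); mu0 <- colMeans(X0)
  S <- ((n1 - 1) * stats::cov(X1) + (n0 - 1) * stats::cov(X0)) / (n1 + n0 - 2)
  if (rcond(S) < 1e-12)
    abort("singular pooled covariance; jitter the features or add data")
  w <- solve(S, mu1 - mu0)
  if (sum(abs(mu1 - mu0)) < 1e-12)
    warn("class means are equal; discriminant has no separating direction")
  offset <- sum(w * (mu1 + mu0) / 2) - log(priors[["polyA"]] / priors[["non_polyA"]])
  structure(list(weights = w, offset = unname(offset),
                 means = rbind(polyA = mu1, non_polyA = mu0),
                 pooled_cov = S, n = c(polyA = n1, non_polyA = n0),
                 priors = priors),
            class = "lnc_lda")
}

#' @exportS3Method generics::tidy
tidy.lnc_lda <- function(x, ...) {
  tibble::tibble(term = c(names(x$weights), "offset"),
                 estimate = c(unname(x$weights), x$offset))
}

#' @exportS3Method generics::glance
glance.lnc_lda <- function(x, ...) {
  tibble::tibble(n_polyA = x$n[["polyA"]], n_non_polyA = x$n[["non_polyA"]],
                 mahalanobis = sqrt(sum(x$weights *
                                          (x$means["polyA", ] - x$means["non_polyA", ]))))
}

#' @export
print.lnc_lda <- function(x, ...) {
  cat(sprintf("Fisher LDA: score = %.4f*ribo + %.4f*polya - %.4f (polyA if > 0)\n",
              x$weights[1], x$weights[2], x$offset))
  cat(sprintf("trained on %d polyA / %d non_polyA examples\n",
              x$n[["polyA"]], x$n[["non_polyA"]]))
  invisible(x)
}

lda_score <- function(d, features) {
  as.vector(as.matrix(features[, c("ribo", "polya")]) %*% d$weights) - d$offset
}

#' Classify polyadenylation status per gene and condition
#'
#' Scores each gene with a trained discriminant; the per-condition call is
#' `polyA` when the score is positive. Use [polya_consensus()] to combine
#' conditions.
#'
#' @param d An `lnc_lda` from [train_lda()].
#' @param features Feature tibble from [polya_features()] (one or more
#'   conditions row-bound).
#' @return Tibble: `gene_id`, `condition`, `score`, `call`.
#' @export
classify_polya <- function(d, features) {
  if (nrow(features) == 0) {
    return(tibble::tibble(gene_id = character(), condition = character(),
                          score = double(), call = character()))
  }
  tibble::tibble(gene_id = features$gene_id, condition = features$condition,
                 score = lda_score(d, features)) %>%
    dplyr::mutate(call = ifelse(.data$score > 0, "polyA", "non_polyA"))
}

#' Consensus polyadenylation call across conditions
#'
#' Conservative rule: a gene is called `non_polyA` only when it is
#' classified `non_polyA` in every condition in which it was tested.
#'
#' @param calls Per-condition calls from [classify_polya()].
#' @return Tibble: `gene_id`, `n_conditions`, `consensus_call`.
#' @export
polya_consensus <- function(calls) {
  calls %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(n_conditions = dplyr::n(),
                     consensus_call = ifelse(all(.data$call == "non_polyA"),
                                             "non_polyA", "polyA"),
                     .groups = "drop")
}

#' Non-polyadenylated fraction by biotype
#'
#' @param consensus Consensus calls from [polya_consensus()].
#' @param genes Gene-model or truth tibble supplying `gene_id`, `biotype`.
#' @return Tibble: `biotype`, `non_polya`, `total`, `fraction`.
#' @export
polya_summary <- function(consensus, genes) {
  consensus %>%
    dplyr::left_join(dplyr::select(genes, "gene_id", "biotype"),
                     by = "gene_id") %>%
    dplyr::group_by(.data$biotype) %>%
    dplyr::summarise(non_polya = sum(.data$consensus_call == "non_polyA"),
                     total = dplyr::n(),
                     fraction = .data$non_polya / .data$total,
                     .groups = "drop")
}
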