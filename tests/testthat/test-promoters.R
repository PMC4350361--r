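test_that("occupancy distances are signed, strand-aware, and boundary-inclusive", {
  genes <- tibble::tibble(
    gene_id = c("at_summit", "edge", "minus"), biotype = "lncRNA",
    chrom = "chr1", strand = c("+", "+", "-"),
    start = c(5000L, 20000L, 40000L), end = c(6000L, 21000L, 41000L)
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$exons <- purrr::map2(genes$start, genes$end,
                             ~cbind(start = .x, end = .y))
  peaks <- tibble::tibble(
    peak_id = c("p0", "p1", "p2"), chrom = "chr1",
    start = c(4950L, 20950L, 40500L), end = c(5051L, 21051L, 40601L),
    summit = c(5000L, 21000L, 40550L), score = 1
  )
  occ <- assign_peak_occupancy(genes, peaks, window = 1000)
  expect_equal(occ$distance[occ$gene_id == "at_summit"], 0)
  expect_true(occ$bound[occ$gene_id == "at_summit"])
  # summit exactly window bp downstream is still bound
  expect_equal(occ$distance[occ$gene_id == "edge"], 1000)
  expect_true(occ$bound[occ$gene_id == "edge"])
  # minus-strand: summit left of TSS is downstream (positive)
  expect_equal(occ$distance[occ$gene_id == "minus"], 40999 - 40550)
  # peak-free chromosome -> unbound, NA distance
  g2 <- genes; g2$chrom <- "chrEmpty"
  occ2 <- assign_peak_occupancy(g2, peaks)
  expect_true(all(is.na(occ2$distance)))
  expect_false(any(occ2$bound))
})

test_that("nearest-peak assignment matches the all-pairs oracle", {
  for (s in 1:20) {
    set.seed(s)
    genes <- random_gene_models(sample(20:150, 1))
    peaks <- random_peaks(sample(10:150, 1))
    occ <- assign_peak_occupancy(genes, peaks, window = 1000)
    ref <- brute_force_occupancy(genes, peaks, window = 1000)
    expect_equal(occ$nearest_peak, ref$nearest_peak, info = paste("seed", s))
    expect_equal(occ$distance, ref$distance, info = paste("seed", s))
    expect_equal(occ$bound, ref$bound, info = paste("seed", s))
  }
})

test_that("bound fractions cover the degenerate cases and recover planted truth", {
  genes <- random_gene_models(20)
  occ0 <- assign_peak_occupancy(genes, lncmyc:::empty_peaks())
  expect_equal(bound_fraction(occ0, genes)$fraction, 0)
  # all bound: peak at each TSS
  pk <- tibble::tibble(peak_id = paste0("q", 1:20), chrom = genes$chrom,
                       start = genes$tss - 10L, end = genes$tss + 11L,
                       summit = genes$tss, score = 1)
  occ1 <- assign_peak_occupancy(genes, pk)
  expect_equal(bound_fraction(occ1, genes)$fraction, 1)
  # planted 60% bound recovered within 2 points at the 1 kb window
  cfg <- sim_config(n_coding = 0, n_lncRNA = 1000,
                    fraction_bidirectional_pairs = 0,
                    p_bound_regulated = 0.6, p_bound_null = 0.6, seed = 55)
  ann <- simulate_annotation(cfg)
  pk2 <- simulate_peaks(ann$genes, ann$truth, seed = 56)
  occ2 <- assign_peak_occupancy(ann$genes, pk2, window = 1000)
  rec <- bound_fraction(occ2, ann$genes, "lncRNA")$fraction
  expect_lt(abs(rec - mean(ann$truth$myc_bound)), 0.02)
})

test_that("bound fraction is monotone non-decreasing in the window", {
  set.seed(60)
  genes <- random_gene_models(100)
  peaks <- random_peaks(80)
  fr <- vapply(c(100, 500, 1000, 5000, 20000), function(w) {
    bound_fraction(assign_peak_occupancy(genes, peaks, window = w),
                   genes)$fraction
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("divergent pairs obey orientation and gap rules", {
  mk <- function(strand_a, start_a, end_a, strand_b, start_b, end_b) {
    g <- tibble::tibble(
      gene_id = c("a", "b"), biotype = "lncRNA", chrom = "chr1",
      strand = c(strand_a, strand_b),
      start = c(start_a, start_b), end = c(end_a, end_b)
    )
    g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
    g$exons <- purrr::map2(g$start, g$end, ~cbind(start = .x, end = .y))
    g
  }
  # divergent, TSS 200 bp apart
  expect_equal(nrow(detect_bidirectional(
    mk("-", 1000L, 2000L, "+", 2199L, 3000L))), 1)
  # convergent (facing) genes do not pair
  expect_equal(nrow(detect_bidirectional(
    mk("+", 1000L, 2000L, "-", 2199L, 3000L))), 0)
  # gap exactly max_gap is inclusive
  g <- mk("-", 1000L, 2000L, "+", 2999L, 4000L)
  expect_equal(detect_bidirectional(g, max_gap = 1000)$gap, 1000L)
  # TSS inside the partner's body disqualifies
  expect_equal(nrow(detect_bidirectional(
    mk("-", 1000L, 2000L, "+", 1999L, 3000L))), 0)
})

test_that("bidirectional detection matches the all-pairs oracle", {
  for (s in 1:20) {
    set.seed(100 + s)
    genes <- random_gene_models(sample(30:120, 1), chroms = "chr1",
                                span = 3e5)
    got <- detect_bidirectional(genes, max_gap = 1000)
    ref <- brute_force_bidirectional(genes, max_gap = 1000)
    expect_equal(as.data.frame(got), as.data.frame(ref),
                 info = paste("seed", s))
  }
})

test_that("promoter categories follow the taxonomy and partition the pairs", {
  pairs <- tibble::tibble(
    gene_a = c("a1", "a2", "a3", "a4", "a5"),
    gene_b = c("b1", "b2", "b3", "b4", "b5"),
    chrom = "chr1", gap = 100L
  )
  expressed <- tibble::tibble(
    gene_id = c("a1", "b1", "a2", "b2", "a3", "b3", "a4"),
    expressed = TRUE
  )
  de <- tibble::tibble(
    gene_id = c("a1", "b1", "a2", "b2", "a3", "b3", "a4"),
    cpm_high = 10, cpm_low = 10,
    log2fc = c(2, 2, 2, -2, 0.1, 0.2, 2),
    p_value = 1e-5, fdr = 1e-4,
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    direction = c("up", "up", "up", "down", "none", "none", "up")
  )
  cls <- classify_bidirectional(pairs, expressed, de)
  expect_equal(as.character(cls$category),
               c("bidirectional_concordant", "bidirectional_discordant",
                 "bidirectional_unregulated", "unidirectional_regulated",
                 "no_transcription"))
  tab <- bidirectional_summary(cls)
  expect_equal(sum(tab$n), nrow(pairs))
  # one expressed + one significant of the two -> discordant
  de2 <- de; de2$significant[de2$gene_id == "b1"] <- FALSE
  de2$direction[de2$gene_id == "b1"] <- "none"
  cls2 <- classify_bidirectional(pairs[1, ], expressed, de2)
  expect_equal(as.character(cls2$category), "bidirectional_discordant")
  # expressed gene missing from the DE table is an error
  expect_error(classify_bidirectional(pairs, expressed, de[-1, ]),
               "missing from DE")
})

test_that("category counts partition random instances exactly", {
  for (s in 1:10) {
    set.seed(200 + s)
    genes <- random_gene_models(80, chroms = "chr1", span = 1.5e5)
    pairs <- detect_bidirectional(genes, max_gap = 2000)
    expressed <- tibble::tibble(gene_id = genes$gene_id,
                                expressed = runif(80) < 0.6)
    de <- tibble::tibble(
      gene_id = genes$gene_id, cpm_high = 10, cpm_low = 10,
      log2fc = rnorm(80), p_value = runif(80), fdr = runif(80),
      significant = runif(80) < 0.3,
      direction = sample(c("up", "down"), 80, replace = TRUE)
    )
    de$direction[!de$significant] <- "none"
    cls <- classify_bidirectional(pairs, expressed, de)
    expect_equal(sum(bidirectional_summary(cls)$n), nrow(pairs))
    expect_false(any(is.na(cls$category)))
  }
})

test_that("TSS profiles bin coverage with strand mirroring", {
  genes <- tibble::tibble(
    gene_id = c("plus", "minus"), biotype = "lncRNA", chrom = "chr1",
    strand = c("+", "-"), start = c(10000L, 10000L), end = c(12000L, 10001L)
  )
  genes$tss <- c(10000L, 10000L)
  genes$exons <- purrr::map2(genes$start, genes$end,
                             ~cbind(start = .x, end = .y))
  uniform <- tibble::tibble(chrom = "chr1", start = 0L, end = 50000L,
                            value = 1)
  prof <- occupancy_profile(genes, uniform, flank = 2000, bin = 50)
  expect_true(all(as.matrix(prof[, -1]) == 1))
  # delta coverage at the TSS lands in the central bin only
  delta <- tibble::tibble(chrom = "chr1", start = 10000L, end = 10001L,
                          value = 50)
  prof2 <- occupancy_profile(genes[1, ], delta, flank = 2000, bin = 50)
  v <- as.numeric(prof2[1, -1])
  expect_equal(which(v != 0), 41L)  # first bin of the downstream half
  expect_equal(v[41], 1)            # 50 / bin width
  # a step upstream of a minus gene mirrors the plus-strand profile
  step <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L, value = 2)
  pp <- as.numeric(occupancy_profile(genes[1, ], step, flank = 2000,
                                     bin = 50)[1, -1])
  pm <- as.numeric(occupancy_profile(genes[2, ], step, flank = 2000,
                                     bin = 50)[1, -1])
  expect_equal(pm, rev(pp))
  expect_error(occupancy_profile(genes, uniform, flank = 2000, bin = 33),
               "divide")
  expect_warning(
    occupancy_profile(genes, tibble::tibble(chrom = "chrX", start = 0L,
                                            end = 10L, value = 1)),
    "coverage")
})

test_that("expression overlap matches brute-force enumeration", {
  idents <- list(A = c("g1", "g2"), B = c("g1", "g2"), C = c("g1", "g2"))
  ov <- expression_overlap(idents)
  expect_equal(glance(ov)$all_fraction, 1)
  disj <- list(A = "g1", B = "g2", C = "g3")
  expect_equal(glance(expression_overlap(disj))$all_fraction, 0)
  expect_equal(glance(expression_overlap(disj))$one_fraction, 1)
  for (s in 1:10) {
    set.seed(300 + s)
    universe <- sprintf("u%03d", 1:300)
    sets <- list(A = sample(universe, 100), B = sample(universe, 100),
                 C = sample(universe, 100))
    ov <- expression_overlap(sets)
    # enumeration oracle
    member <- sapply(sets, function(x) universe %in% x)
    pat <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
    pat <- pat[pat != ""]
    ref <- table(pat)
    got <- setNames(ov$count, ov$region)[names(ref)]
    expect_equal(as.integer(got), as.integer(ref), info = paste("seed", s))
    expect_equal(sum(ov$count), length(unique(unlist(sets))))
  }
})
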