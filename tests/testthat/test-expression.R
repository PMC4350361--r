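test_that("CPM columns are library-size normalized", {
  m <- matrix(c(10, 0, 10, 90), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  meta <- tibble::tibble(name = c("a", "b"),
                         condition = c("high_myc", "low_myc"),
                         library = "ribo_depleted", cell_line = "X",
                         replicate = c(1L, 1L))
  cts <- counts_from_matrix(m, meta)
  expr <- cpm(cts)
  e <- tidyr::pivot_wider(tibble::as_tibble(expr)[, 1:3],
                          names_from = "sample", values_from = "cpm")
  expect_equal(e$a, c(1e6, 0))
  expect_equal(e$b, c(1e5, 9e5))
  # column sums hit 1e6 on random matrices
  set.seed(5)
  mm <- matrix(rpois(300, 50), 30, 10)
  ee <- cpm(counts_from_matrix(mm, tiny_meta(5)))
  tot <- tapply(ee$cpm, ee$sample, sum)
  expect_true(all(abs(tot - 1e6) / 1e6 < 1e-6))
})

test_that("zero-total samples are rejected by name", {
  m <- matrix(c(0, 0, 5, 5), 2, 2,
              dimnames = list(NULL, c("dead", "live")))
  meta <- tibble::tibble(name = c("dead", "live"),
                         condition = c("high_myc", "low_myc"),
                         library = "ribo_depleted", cell_line = "X",
                         replicate = c(1L, 1L))
  expect_error(cpm(counts_from_matrix(m, meta)), "dead")
})

test_that("low-count filter keeps the boundary and respects the minimum rule", {
  m <- rbind(g_keep = c(5, 5, 5, 5, 5, 5),
             g_drop = c(100, 100, 4, 100, 100, 100))
  cts <- counts_from_matrix(m)
  expect_equal(filter_low(cts, 5)$gene_id, "g_keep")
  expect_equal(nrow(filter_low(cts, 0)), 2)
})

test_that("row centering subtracts the sample-mean exactly", {
  m <- matrix(c(2^3 * 10, 2^5 * 10), 1, 2,
              dimnames = list("g", c("a", "b")))
  # engineered so log2cpm values differ by 2 after normalization
  meta <- tibble::tibble(name = c("a", "b"), condition = c("high_myc", "low_myc"),
                         library = "ribo_depleted", cell_line = "X",
                         replicate = c(1L, 1L))
  expr <- tibble::tibble(gene_id = c("g", "g"), sample = c("a", "b"),
                         cpm = c(8, 32), log2cpm = c(3, 5))
  cent <- center_log2fc(expr)
  expect_equal(unlist(cent[1, c("a", "b")], use.names = FALSE), c(-1, 1))
  # constant rows center to zero; all rows sum to ~0
  set.seed(8)
  cts <- counts_from_matrix(matrix(rpois(600, 40), 100, 6))
  cent2 <- center_log2fc(cpm(cts))
  expect_true(all(abs(rowSums(as.matrix(cent2[, -1]))) < 1e-9))
})

test_that("identical counts across conditions give fold change 1 and no call", {
  m <- matrix(rep(c(50, 80), each = 6), 2, 6, byrow = TRUE)
  rownames(m) <- c("flat1", "flat2")
  de <- call_de(counts_from_matrix(m), dispersion = 0.05)
  expect_equal(de$log2fc, c(0, 0))
  expect_equal(de$direction, c("none", "none"))
  expect_equal(de$p_value, c(1, 1), tolerance = 1e-6)
})

test_that("method-of-moments dispersion is near zero on Poisson data", {
  set.seed(11)
  n <- 2000
  mu <- runif(n, 100, 2000)
  m <- matrix(rpois(n * 6, rep(mu, 6)), n, 6)
  cts <- counts_from_matrix(m)
  expect_lte(estimate_common_dispersion(cts), 0.01)
})

test_that("planted 3-log2 effects at mu=200 are recovered at the standard thresholds", {
  truth <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:1000), biotype = "lncRNA",
    regulation = c(rep("up", 50), rep("down", 50), rep("none", 900)),
    effect = c(rep(3, 50), rep(-3, 50), rep(0, 900)),
    myc_bound = FALSE, polyadenylated = TRUE, base_mean = 200,
    true_half_life = 60, pair_id = NA_character_
  )
  cts <- simulate_counts(truth, sim_design(libraries = "ribo_depleted"),
                         amplification_factor = 1, dispersion = 0.05,
                         seed = 1)
  de <- call_de(cts)
  planted <- truth$regulation != "none"
  expect_gte(mean(de$significant[planted]), 0.9)
  # directions recovered
  expect_true(all(de$direction[de$significant & planted][1:10] %in%
                    c("up", "down")))
})

test_that("null genes stay below the significance thresholds when planted mass is balanced", {
  # down-regulated genes carry 8x base mean so the RNA mass added by +3
  # effects equals the mass removed, keeping CPM composition stable
  truth <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:1000), biotype = "lncRNA",
    regulation = c(rep("up", 50), rep("down", 50), rep("none", 900)),
    effect = c(rep(3, 50), rep(-3, 50), rep(0, 900)),
    myc_bound = FALSE, polyadenylated = TRUE,
    base_mean = c(rep(200, 50), rep(1600, 50), rep(200, 900)),
    true_half_life = 60, pair_id = NA_character_
  )
  cts <- simulate_counts(truth, sim_design(libraries = "ribo_depleted"),
                         amplification_factor = 1, dispersion = 0.05,
                         seed = 2)
  de <- call_de(cts)
  nulls <- truth$regulation == "none"
  expect_lte(mean(de$significant[nulls]), 0.005)
})

test_that("calling is invariant to sample order and library-size rescaling", {
  set.seed(31)
  m <- matrix(rnbinom(100 * 6, size = 20, mu = 150), 100, 6)
  cts <- counts_from_matrix(m)
  de1 <- call_de(cts, dispersion = 0.05)
  perm <- c(4, 1, 6, 2, 5, 3)
  meta <- sample_meta(cts)[perm, ]
  cts2 <- counts_from_matrix(m[, perm], meta)
  de2 <- call_de(cts2, dispersion = 0.05)
  expect_equal(de1$p_value, de2$p_value)
  expect_equal(de1$log2fc, de2$log2fc)
  ls <- colSums(m)
  de3 <- call_de(cts, dispersion = 0.05, lib_sizes = ls * 7)
  expect_equal(de1$p_value, de3$p_value)
  expect_equal(de1$log2fc, de3$log2fc)
})

test_that("swapping condition labels negates every log2 fold change", {
  set.seed(33)
  m <- matrix(rnbinom(50 * 6, size = 20, mu = 150), 50, 6)
  cts <- counts_from_matrix(m)
  meta <- sample_meta(cts)
  meta$condition <- ifelse(meta$condition == "high_myc", "low_myc", "high_myc")
  cts_sw <- counts_from_matrix(m, meta)
  expect_equal(call_de(cts_sw, dispersion = 0.05)$log2fc,
               -call_de(cts, dispersion = 0.05)$log2fc)
})

test_that("mixed library preps and single conditions are rejected", {
  m <- matrix(rpois(4 * 6, 100), 4, 6)
  meta <- tiny_meta()
  meta$library[1] <- "polyA"
  expect_error(call_de(counts_from_matrix(m, meta)), "library")
})

test_that("validation-candidate selection enforces all three criteria strictly", {
  genes <- tibble::tibble(
    gene_id = c("hit", "low_fc", "boundary_reads", "far_peak"),
    biotype = "lncRNA", chrom = "chr1", strand = "+",
    start = c(1000L, 11000L, 21000L, 31000L),
    end = c(2000L, 12000L, 22000L, 32000L)
  )
  genes$tss <- genes$start
  genes$exons <- purrr::map2(genes$start, genes$end,
                             ~cbind(start = .x, end = .y))
  peaks <- tibble::tibble(
    peak_id = c("p1", "p2", "p3", "p4"), chrom = "chr1",
    start = c(1050L, 11050L, 21050L, 31451L),
    end = c(1151L, 11151L, 21151L, 31552L),
    summit = c(1100L, 11100L, 21100L, 31501L), score = 5
  )
  occ <- assign_peak_occupancy(genes, peaks, window = 500)
  de <- structure(tibble::tibble(
    gene_id = genes$gene_id,
    cpm_high = c(1000, 300, 1000, 900), cpm_low = c(100, 100, 100, 100),
    log2fc = log2(c(10, 3, 10, 9)), p_value = 1e-6, fdr = 1e-5,
    significant = TRUE, direction = "up"
  ), class = c("lnc_de", "tbl_df", "tbl", "data.frame"))
  m <- matrix(6, 4, 6, dimnames = list(genes$gene_id, NULL))
  m["boundary_reads", 1] <- 5   # ">5 reads" is strict
  cts <- counts_from_matrix(m)
  expect_equal(select_validation_candidates(de, cts, occ), "hit")
  # occupancy computed at the wrong window is refused
  occ2 <- assign_peak_occupancy(genes, peaks, window = 1000)
  expect_error(select_validation_candidates(de, cts, occ2), "window")
  # peak 501 bp away fails the boundary
  expect_false("far_peak" %in% select_validation_candidates(de, cts, occ))
})

test_that("the exact test tracks the reference count-based implementation", {
  skip_if_not_installed("edgeR")
  set.seed(61)
  n <- 500
  mu <- rlnorm(n, log(200), 1)
  eff <- c(rep(2, 30), rep(-2, 30), rep(0, n - 60))
  m <- cbind(matrix(rnbinom(n * 3, size = 20, mu = mu * 2^eff), n, 3),
             matrix(rnbinom(n * 3, size = 20, mu = mu), n, 3))
  de <- call_de(counts_from_matrix(m))
  y <- edgeR::DGEList(counts = m, group = rep(c("high", "low"), each = 3))
  y <- edgeR::estimateCommonDisp(y)
  et <- edgeR::exactTest(y, pair = c("low", "high"))
  expect_gt(cor(log(de$p_value + 1e-300), log(et$table$PValue + 1e-300),
                method = "spearman"), 0.99)
  expect_gt(cor(de$log2fc, et$table$logFC), 0.99)
  # dispersion estimates agree in scale
  expect_equal(attr(de, "dispersion"), y$common.dispersion, tolerance = 0.5)
})
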