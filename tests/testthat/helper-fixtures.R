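# Shared fixture builders. Everything is generated in code at test time.

tiny_meta <- function(n_rep = 3, libraries = "ribo_depleted",
                      cell_line = "X") {
  sim_design(replicates = n_rep, libraries = libraries,
             cell_line = cell_line)
}

# counts tibble from a plain matrix + minimal metadata
counts_from_matrix <- function(m, meta = NULL) {
  if (is.null(colnames(m))) {
    colnames(m) <- if (!is.null(meta)) meta$name else
      paste0("s", seq_len(ncol(m)))
  }
  if (is.null(meta)) {
    half <- ncol(m) / 2
    meta <- tibble::tibble(
      name = colnames(m),
      condition = rep(c("high_myc", "low_myc"), each = half),
      library = "ribo_depleted", cell_line = "X",
      replicate = rep(seq_len(half), 2)
    )
  }
  gid <- rownames(m) %||% paste0("g", seq_len(nrow(m)))
  count_matrix(dplyr::bind_cols(tibble::tibble(gene_id = gid),
                                tibble::as_tibble(as.data.frame(m))),
               meta)
}

`%||%` <- rlang::`%||%`

random_gene_models <- function(n, chroms = c("chr1", "chr2"), span = 1e6) {
  start <- sample.int(span, n)
  len <- sample(200:5000, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  g <- tibble::tibble(
    gene_id = sprintf("G%04d", seq_len(n)),
    biotype = sample(c("coding", "lncRNA"), n, replace = TRUE),
    chrom = sample(chroms, n, replace = TRUE),
    strand = strand, start = start, end = start + len
  )
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g$exons <- purrr::map2(g$start, g$end, ~cbind(start = .x, end = .y))
  g
}

random_peaks <- function(m, chroms = c("chr1", "chr2"), span = 1e6) {
  summit <- sample.int(span, m)
  tibble::tibble(
    peak_id = sprintf("P%04d", seq_len(m)),
    chrom = sample(chroms, m, replace = TRUE),
    start = pmax(0L, summit - 100L), end = summit + 101L,
    summit = summit, score = stats::runif(m, 1, 10)
  )
}

# O(n*m) all-pairs reference for nearest-peak assignment (full distance
# matrix, no sorted scan), mirroring the stated tie-break (smaller summit
# coordinate) and strand-aware sign
brute_force_occupancy <- function(genes, peaks, window) {
  n <- nrow(genes)
  nearest <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    pk <- peaks[peaks$chrom == ch, ]
    if (nrow(pk) == 0) next
    pord <- order(pk$summit, pk$peak_id)
    pk <- pk[pord, ]  # candidate order for tie-breaking only
    D <- abs(outer(genes$tss[gi], pk$summit, "-"))
    best <- max.col(-D, ties.method = "first")
    d <- pk$summit[best] - genes$tss[gi]
    d[genes$strand[gi] == "-"] <- -d[genes$strand[gi] == "-"]
    nearest[gi] <- pk$peak_id[best]
    distance[gi] <- d
  }
  tibble::tibble(gene_id = genes$gene_id, tss = genes$tss,
                 nearest_peak = nearest, distance = distance,
                 bound = !is.na(distance) & abs(distance) <= window)
}

# all-pairs reference for divergent-promoter detection with the same
# greedy smallest-gap/leftmost matching
brute_force_bidirectional <- function(genes, max_gap) {
  mi <- genes[genes$strand == "-", ]
  pl <- genes[genes$strand == "+", ]
  empty <- tibble::tibble(gene_a = character(), gene_b = character(),
                          chrom = character(), gap = integer())
  if (nrow(mi) == 0 || nrow(pl) == 0) return(empty)
  idx <- expand.grid(i = seq_len(nrow(mi)), j = seq_len(nrow(pl)))
  a <- mi[idx$i, ]; b <- pl[idx$j, ]
  gap <- b$tss - a$tss
  ok <- a$chrom == b$chrom & gap >= 0 & gap <= max_gap &
    !(b$tss >= a$start & b$tss < a$end) &
    !(a$tss >= b$start & a$tss < b$end)
  if (!any(ok)) return(empty)
  cand <- tibble::tibble(gene_a = a$gene_id[ok], gene_b = b$gene_id[ok],
                         chrom = a$chrom[ok], gap = as.integer(gap[ok]),
                         left = pmin(a$tss, b$tss)[ok])
  cand <- cand[order(cand$gap, cand$left, cand$gene_a, cand$gene_b), ]
  used <- character(0); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$gene_a[i] %in% used || cand$gene_b[i] %in% used) next
    keep[i] <- TRUE
    used <- c(used, cand$gene_a[i], cand$gene_b[i])
  }
  out <- cand[keep, c("gene_a", "gene_b", "chrom", "gap")]
  out[order(out$chrom, out$gap, out$gene_a), ]
}
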