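# Strand-aware TSS occupancy, bidirectional (divergent) promoter detection
# and functional classification, TSS coverage profiles, and cross-cell-line
# expression overlap.

#' Assign the nearest ChIP-seq peak to every TSS
#'
#' For each gene, finds the peak whose summit is closest to the TSS on the
#' same chromosome (ties broken toward the smaller summit coordinate). The
#' distance is signed relative to the direction of transcription: summit
#' minus TSS, negated on the minus strand, so positive is downstream. A gene
#' is `bound` when `|distance| <= window` (inclusive). Genes on peak-free
#' chromosomes are unbound with `NA` distance.
#'
#' @param genes Gene-model tibble (see [read_gene_models()]).
#' @param peaks Peak tibble (see [read_peaks()]).
#' @param window Binding window in bp around the TSS (default 1000).
#' @return A tibble classed `lnc_occupancy`: `gene_id`, `tss`,
#'   `nearest_peak`, `distance`, `bound`; `window` attached as an attribute.
#' @export
assign_peak_occupancy <- function(genes, peaks, window = 1000) {
  if (window <= 0) abort("window must be > 0")
  out <- tibble::tibble(gene_id = genes$gene_id, tss = genes$tss,
                        nearest_peak = NA_character_,
                        distance = NA_real_, bound = FALSE)
  for (ch in unique(genes$chrom)) {
    pk <- peaks[peaks$chrom == ch, ]
    gi <- which(genes$chrom == ch)
    if (nrow(pk) == 0 || length(gi) == 0) next
    ord <- order(pk$summit, pk$peak_id)
    s <- pk$summit[ord]
    ids <- pk$peak_id[ord]
    tss <- genes$tss[gi]
    j <- findInterval(tss, s)             # s[j] <= tss < s[j+1]
    left <- pmax(j, 1L)
    right <- pmin(j + 1L, length(s))
    dl <- abs(tss - s[left])
    dr <- abs(tss - s[right])
    # prefer left on ties: left summit is the smaller coordinate
    use_left <- (j >= 1L) & (j >= length(s) | dl <= dr)
    pick <- ifelse(use_left, left, right)
    d_signed <- s[pick] - tss
    flip <- genes$strand[gi] == "-"
    d_signed[flip] <- -d_signed[flip]
    out$nearest_peak[gi] <- ids[pick]
    out$distance[gi] <- d_signed
    out$bound[gi] <- abs(d_signed) <= window
  }
  structure(out, window = window, class = c("lnc_occupancy", class(out)))
}

#' Fraction of genes bound at the TSS
#'
#' @param occupancy An `lnc_occupancy` tibble covering the genes of
#'   interest.
#' @param genes Gene-model tibble (supplies biotypes); typically already
#'   restricted to detected genes.
#' @param biotype Optional biotype to restrict to (`"coding"`/`"lncRNA"`).
#' @return One-row tibble: `biotype`, `bound`, `total`, `fraction`.
#' @export
bound_fraction <- function(occupancy, genes, biotype = NULL) {
  ids <- if (is.null(biotype)) genes$gene_id else genes$gene_id[genes$biotype == biotype]
  occ <- occupancy[occupancy$gene_id %in% ids, ]
  tibble::tibble(biotype = biotype %||% "all", bound = sum(occ$bound),
                 total = nrow(occ),
                 fraction = ifelse(nrow(occ) > 0, sum(occ$bound) / nrow(occ), NA_real_))
}

divergent_candidates <- function(genes, max_gap) {
  minus <- genes[genes$strand == "-", ]
  plus <- genes[genes$strand == "+", ]
  if (nrow(minus) == 0 || nrow(plus) == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          chrom = character(), gap = integer()))
  }
  purrr::map_dfr(unique(minus$chrom), function(ch) {
    mi <- minus[minus$chrom == ch, ]
    pl <- plus[plus$chrom == ch, ]
    if (nrow(pl) == 0 || nrow(mi) == 0) return(NULL)
    pl <- pl[order(pl$tss), ]
    purrr::map_dfr(seq_len(nrow(mi)), function(i) {
      a <- mi[i, ]
      lo <- findInterval(a$tss - 1L, pl$tss) + 1L
      hi <- findInterval(a$tss + max_gap, pl$tss)
      if (hi < lo) return(NULL)
      b <- pl[lo:hi, ]
      # divergent: b transcribes rightward from a TSS at/right of a's TSS;
      # neither TSS may lie inside the other gene's body
      ok <- !(b$tss >= a$start & b$tss < a$end) &
        !(a$tss >= b$start & a$tss < b$end)
      b <- b[ok, ]
      if (nrow(b) == 0) return(NULL)
      tibble::tibble(gene_a = a$gene_id, gene_b = b$gene_id, chrom = ch,
                     gap = as.integer(b$tss - a$tss),
                     left = pmin(a$tss, b$tss))
    })
  })
}

greedy_pair_match <- function(cand) {
  if (nrow(cand) == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          chrom = character(), gap = integer()))
  }
  cand <- cand[order(cand$gap, cand$left, cand$gene_a, cand$gene_b), ]
  used <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$gene_a[i] %in% used || cand$gene_b[i] %in% used) next
    keep[i] <- TRUE
    used <- c(used, cand$gene_a[i], cand$gene_b[i])
  }
  out <- cand[keep, c("gene_a", "gene_b", "chrom", "gap")]
  out[order(out$chrom, out$gap, out$gene_a), ]
}

#' Detect bidirectional (divergent) promoters
#'
#' A bidirectional promoter is a minus-strand gene and a plus-strand gene
#' that transcribe away from each other, with a TSS separation of at most
#' `max_gap` bp (inclusive) and neither TSS inside the other gene's body.
#' Each gene joins at most one pair; when a gene has several compatible
#' partners the smallest TSS gap wins, with ties broken toward the leftmost
#' pair.
#'
#' @param genes Gene-model tibble.
#' @param max_gap Maximum TSS separation in bp (default 1000).
#' @return Tibble: `gene_a` (minus strand), `gene_b` (plus strand), `chrom`,
#'   `gap`.
#' @export
detect_bidirectional <- function(genes, max_gap = 1000) {
  greedy_pair_match(divergent_candidates(genes, max_gap))
}

bidir_categories <- c("no_transcription", "unidirectional_unregulated",
                      "unidirectional_regulated", "bidirectional_unregulated",
                      "bidirectional_concordant", "bidirectional_discordant")

#' Classify bidirectional promoters by expression and regulation
#'
#' Implements the divergent-promoter taxonomy: promoters producing 0 (no
#' transcription), 1 (unidirectional) or 2 (bidirectional) transcripts,
#' subdivided by whether MYC regulates the genes involved. With both genes
#' expressed: both significant in the same direction is `concordant`;
#' directions differing or exactly one significant is `discordant`; neither
#' significant is `bidirectional_unregulated`. A promoter is MYC-bound when
#' either TSS is bound. An expression-asymmetry score
#' (`|log2fc_a - log2fc_b|`) is reported alongside the category.
#'
#' @param pairs Pair tibble from [detect_bidirectional()].
#' @param expressed Tibble `gene_id`, `expressed` (logical); genes absent
#'   from the table count as not expressed.
#' @param de An `lnc_de` tibble; every expressed pair member must appear.
#' @param occupancy An `lnc_occupancy` tibble (optional; `myc_bound` is `NA`
#'   when omitted).
#' @return The pair tibble with `myc_bound`, `n_expressed`, `category` and
#'   `asymmetry` columns, classed `lnc_bidir`.
#' @export
classify_bidirectional <- function(pairs, expressed, de, occupancy = NULL) {
  exp_map <- setNames(expressed$expressed, expressed$gene_id)
  is_exp <- function(g) !is.na(exp_map[g]) & exp_map[g]
  e_a <- unname(is_exp(pairs$gene_a))
  e_b <- unname(is_exp(pairs$gene_b))

  need_de <- unique(c(pairs$gene_a[e_a], pairs$gene_b[e_b]))
  miss <- setdiff(need_de, de$gene_id)
  if (length(miss))
    abort(paste0("expressed gene(s) missing from DE table: ",
                 paste(head(miss, 5), collapse = ", ")))

  sig <- setNames(de$significant, de$gene_id)
  dir <- setNames(de$direction, de$gene_id)
  lfc <- setNames(de$log2fc, de$gene_id)
  s_a <- unname(sig[pairs$gene_a]); s_b <- unname(sig[pairs$gene_b])
  d_a <- unname(dir[pairs$gene_a]); d_b <- unname(dir[pairs$gene_b])
  n_expressed <- as.integer(e_a) + as.integer(e_b)

  one_sig <- ifelse(e_a, s_a, s_b)   # significance of the single expressed gene
  category <- dplyr::case_when(
    n_expressed == 0L ~ "no_transcription",
    n_expressed == 1L & one_sig ~ "unidirectional_regulated",
    n_expressed == 1L ~ "unidirectional_unregulated",
    s_a & s_b & d_a == d_b ~ "bidirectional_concordant",
    s_a | s_b ~ "bidirectional_discordant",
    TRUE ~ "bidirectional_unregulated"
  )
  bound <- if (is.null(occupancy)) rep(NA, nrow(pairs)) else {
    bmap <- setNames(occupancy$bound, occupancy$gene_id)
    ba <- unname(bmap[pairs$gene_a]); bb <- unname(bmap[pairs$gene_b])
    dplyr::coalesce(ba, FALSE) | dplyr::coalesce(bb, FALSE)
  }
  asym <- abs(unname(lfc[pairs$gene_a]) - unname(lfc[pairs$gene_b]))
  out <- dplyr::mutate(pairs, myc_bound = bound, n_expressed = n_expressed,
                       category = factor(category, levels = bidir_categories),
                       asymmetry = asym)
  structure(out, class = c("lnc_bidir", class(out)))
}

#' Tabulate bidirectional-promoter categories
#'
#' @param classified An `lnc_bidir` tibble from [classify_bidirectional()].
#' @return Tibble `category`, `n` including zero-count categories; the
#'   counts partition the pair total exactly.
#' @export
bidirectional_summary <- function(classified) {
  tb <- table(classified$category)
  tibble::tibble(category = names(tb), n = as.integer(tb))
}

bin_segments <- function(segs, wstart, nbins, bin) {
  vals <- numeric(nbins)
  if (nrow(segs) == 0) return(vals)
  for (k in seq_len(nrow(segs))) {
    s <- max(segs$start[k], wstart)
    e <- min(segs$end[k], wstart + nbins * bin)
    if (e <= s) next
    b1 <- (s - wstart) %/% bin + 1L
    b2 <- (e - 1L - wstart) %/% bin + 1L
    for (b in b1:b2) {
      bs <- wstart + (b - 1L) * bin
      be <- bs + bin
      ov <- min(e, be) - max(s, bs)
      vals[b] <- vals[b] + ov * segs$value[k]
    }
  }
  vals / bin
}

#' Binned coverage profile around TSS
#'
#' Computes mean coverage in fixed-width bins across
#' `[tss - flank, tss + flank)` for every gene, with minus-strand profiles
#' reversed so the direction of transcription always points rightward. Rows
#' are ordered by the supplied key (typically expression), descending.
#'
#' @param genes Gene-model tibble.
#' @param coverage bedGraph tibble from [read_bedgraph()] (positions not
#'   covered count as zero).
#' @param flank Half-window in bp (default 2000).
#' @param bin Bin width in bp; must divide `2 * flank` (default 50).
#' @param order_by Optional named numeric vector (gene id -> ranking key).
#' @return Tibble `gene_id` plus `bin_1 ... bin_k` columns, classed
#'   `lnc_profile` with `flank` and `bin` attributes.
#' @export
occupancy_profile <- function(genes, coverage, flank = 2000, bin = 50,
                              order_by = NULL) {
  if ((2 * flank) %% bin != 0) abort("bin must divide 2 * flank")
  nbins <- as.integer(2 * flank / bin)
  missing_chrom <- setdiff(unique(genes$chrom), unique(coverage$chrom))
  if (length(missing_chrom) && nrow(genes))
    warn(paste0("no coverage for chromosome(s): ",
                paste(missing_chrom, collapse = ", "), "; profiles are zero"))
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    ws <- genes$tss[i] - flank
    segs <- coverage[coverage$chrom == genes$chrom[i] &
                       coverage$end > ws & coverage$start < ws + 2 * flank, ]
    v <- bin_segments(segs, ws, nbins, bin)
    if (genes$strand[i] == "-") v <- rev(v)
    v
  })
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("bin_", seq_len(nbins))
  out <- dplyr::bind_cols(tibble::tibble(gene_id = genes$gene_id),
                          tibble::as_tibble(as.data.frame(m)))
  if (!is.null(order_by)) {
    key <- unname(order_by[out$gene_id])
    out <- out[order(-key, out$gene_id), ]
  }
  structure(out, flank = flank, bin = bin,
            class = c("lnc_profile", class(out)))
}

#' Cross-cell-line expression overlap
#'
#' Enumerates the Venn partition of expressed-gene sets across cell lines
#' and reports, per region, the number of member lines and gene count,
#' together with the fraction of the union expressed in every line and in
#' exactly one line.
#'
#' @param expressed_sets Named list (cell line -> character vector of
#'   expressed gene ids); at least two lines.
#' @return Tibble `region` (e.g. `"A&B"`), `n_lines`, `count`, classed
#'   `lnc_overlap`, with `all_fraction`, `one_fraction` and `universe`
#'   attributes (use [glance()] for the summary).
#' @export
expression_overlap <- function(expressed_sets) {
  if (length(expressed_sets) < 2) abort("need >= 2 cell lines")
  if (is.null(names(expressed_sets)) || any(!nzchar(names(expressed_sets))))
    abort("expressed_sets must be a named list")
  universe <- unique(unlist(expressed_sets))
  member <- vapply(expressed_sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(expressed_sets)))
  k <- length(expressed_sets)
  combos <- purrr::map(seq_len(2^k - 1), function(code) {
    as.logical(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
  })
  rows <- purrr::map_dfr(combos, function(inc) {
    inside <- if (length(universe)) {
      rowSums(member[, inc, drop = FALSE] == TRUE) == sum(inc) &
        rowSums(member[, !inc, drop = FALSE]) == 0
    } else logical(0)
    tibble::tibble(region = paste(names(expressed_sets)[inc], collapse = "&"),
                   n_lines = sum(inc), count = sum(inside))
  })
  n_univ <- length(universe)
  all_n <- rows$count[rows$n_lines == k]
  one_n <- sum(rows$count[rows$n_lines == 1])
  structure(rows,
            all_fraction = if (n_univ > 0) all_n / n_univ else NA_real_,
            one_fraction = if (n_univ > 0) one_n / n_univ else NA_real_,
            universe = n_univ,
            class = c("lnc_overlap", class(rows)))
}

#' @exportS3Method generics::glance
glance.lnc_overlap <- function(x, ...) {
  tibble::tibble(universe = attr(x, "universe"),
                 all_fraction = attr(x, "all_fraction"),
                 one_fraction = attr(x, "one_fraction"))
}
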