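# All genomic intervals inside the package are 0-based half-open [start, end).
# GTF (1-based inclusive) is converted on read and write; BED-family formats
# already use the internal convention and pass through unchanged.

#' Default Gencode biotype collapse table
#'
#' Maps Gencode-style `gene_type` strings onto the binary biotype set used
#' throughout the package: `coding` (protein-coding genes) versus `lncRNA`
#' (long non-coding classes: lincRNA, antisense, processed transcripts and
#' friends). The table is an argument to [read_gene_models()] so users can
#' supply their own collapse.
#'
#' @return A tibble with columns `source` (Gencode biotype) and `biotype`
#'   (`"coding"` or `"lncRNA"`).
#' @export
default_biotype_map <- function() {
  noncoding <- c(
    "lincRNA", "antisense", "processed_transcript", "sense_intronic",
    "sense_overlapping", "3prime_overlapping_ncrna", "3prime_overlapping_ncRNA",
    "bidirectional_promoter_lncRNA", "macro_lncRNA", "lncRNA", "non_coding",
    "misc_RNA", "TEC"
  )
  tibble::tibble(
    source = c("protein_coding", noncoding),
    biotype = c("coding", rep("lncRNA", length(noncoding)))
  )
}

empty_gene_models <- function() {
  tibble::tibble(
    gene_id = character(), biotype = character(), chrom = character(),
    strand = character(), start = integer(), end = integer(), tss = integer(),
    exons = list()
  )
}

# 1-based inclusive -> 0-based half-open and back
gtf_to_internal <- function(start1, end1) list(start = start1 - 1L, end = end1)
internal_to_gtf <- function(start0, end0) list(start = start0 + 1L, end = end0)

tss_from_strand <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}

parse_gtf_attr <- function(attrs, key) {
  m <- stringr::str_match(attrs, paste0(key, '\\s+"([^"]*)"'))[, 2]
  m
}

#' Read gene models from a GTF file
#'
#' Reads a Gencode-style GTF and returns one row per gene with the biotype
#' collapsed to `coding`/`lncRNA`, coordinates converted to the internal
#' 0-based half-open convention, and the strand-aware transcription start
#' site (`tss`): the leftmost base for `+` genes, the rightmost base for `-`
#' genes. `gene` feature rows define gene bodies; `exon` rows, when present,
#' are attached as an `exons` list-column of 0-based half-open intervals
#' (genes without exon rows get their body as a single exon). Records with
#' strand `"."` are skipped with a warning; malformed lines abort with the
#' offending line number.
#'
#' @param path Path to a GTF file.
#' @param biotype_map Tibble with columns `source`, `biotype`; see
#'   [default_biotype_map()]. Unlisted biotypes fall back to `lncRNA`
#'   ("coding and non-coding" is a binary split here).
#' @return A tibble of gene models: `gene_id`, `biotype`, `chrom`, `strand`,
#'   `start`, `end`, `tss`, `exons`.
#' @export
read_gene_models <- function(path, biotype_map = default_biotype_map()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(empty_gene_models())

  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    bad <- which(nf < 9L)[1]
    abort(sprintf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
                  idx[bad], nf[bad]))
  }
  m <- t(vapply(fields, function(f) f[1:9], character(9)))
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1)) {
    bad <- which(is.na(start1) | is.na(end1))[1]
    abort(sprintf("malformed GTF line %d: non-integer coordinates", idx[bad]))
  }
  strand <- m[, 7]
  if (any(strand == ".")) {
    warn(sprintf("skipping %d GTF record(s) with unknown strand '.'",
                 sum(strand == ".")))
  }
  ok <- strand %in% c("+", "-")
  if (!any(ok)) return(empty_gene_models())

  cc <- gtf_to_internal(start1, end1)
  rec <- tibble::tibble(
    feature = m[ok, 3], chrom = m[ok, 1], strand = strand[ok],
    start = cc$start[ok], end = cc$end[ok],
    gene_id = parse_gtf_attr(m[ok, 9], "gene_id"),
    gene_type = dplyr::coalesce(parse_gtf_attr(m[ok, 9], "gene_type"),
                                parse_gtf_attr(m[ok, 9], "gene_biotype"))
  )
  if (anyNA(rec$gene_id)) abort("GTF record without a gene_id attribute")

  genes <- dplyr::filter(rec, .data$feature == "gene")
  if (nrow(genes) == 0L) {
    # no explicit gene rows: derive gene bodies from exon/transcript spans
    genes <- rec %>%
      dplyr::group_by(.data$gene_id) %>%
      dplyr::summarise(
        chrom = .data$chrom[1], strand = .data$strand[1],
        start = min(.data$start), end = max(.data$end),
        gene_type = .data$gene_type[1], .groups = "drop"
      )
  }
  exon_rec <- dplyr::filter(rec, .data$feature == "exon")
  exon_tbl <- exon_rec %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      exons = list(cbind(start = sort(.data$start),
                         end = .data$end[order(.data$start)])),
      .groups = "drop"
    )

  out <- genes %>%
    dplyr::left_join(biotype_map, by = c(gene_type = "source")) %>%
    dplyr::mutate(biotype = dplyr::coalesce(.data$biotype, "lncRNA")) %>%
    dplyr::left_join(exon_tbl, by = "gene_id") %>%
    dplyr::mutate(
      tss = tss_from_strand(.data$start, .data$end, .data$strand),
      exons = purrr::pmap(list(.data$exons, .data$start, .data$end),
                          function(e, s, x) {
                            if (is.null(e)) cbind(start = s, end = x) else e
                          })
    ) %>%
    dplyr::select("gene_id", "biotype", "chrom", "strand", "start", "end",
                  "tss", "exons")
  if (anyDuplicated(out$gene_id)) abort("duplicate gene_id in GTF")
  if (any(out$start >= out$end)) abort("gene with start >= end")
  out
}

#' Write gene models to a GTF file
#'
#' Inverse of [read_gene_models()]: emits one `gene` row plus one `exon` row
#' per exon, converting internal 0-based half-open coordinates back to GTF
#' 1-based inclusive. `coding` maps to `protein_coding`, `lncRNA` to
#' `lincRNA`, so a read/write round trip preserves the collapsed biotype.
#' Output is deterministic (input row order, LF line endings).
#'
#' @param genes Gene-model tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  src <- c(coding = "protein_coding", lncRNA = "lincRNA")
  lines <- purrr::pmap(
    list(genes$gene_id, genes$biotype, genes$chrom, genes$strand,
         genes$start, genes$end, genes$exons),
    function(id, bt, chrom, strand, s, e, ex) {
      at <- sprintf('gene_id "%s"; gene_type "%s";', id, src[[bt]])
      g <- internal_to_gtf(s, e)
      gene_line <- paste(chrom, "lncmyc", "gene", g$start, g$end, ".",
                         strand, ".", at, sep = "\t")
      xe <- internal_to_gtf(as.integer(ex[, "start"]), as.integer(ex[, "end"]))
      exon_lines <- paste(chrom, "lncmyc", "exon", xe$start, xe$end, ".",
                          strand, ".", at, sep = "\t")
      c(gene_line, exon_lines)
    }
  )
  readr::write_lines(unlist(lines), path)
  invisible(path)
}

empty_peaks <- function() {
  tibble::tibble(peak_id = character(), chrom = character(), start = integer(),
                 end = integer(), summit = integer(), score = double())
}

#' Read ChIP-seq peaks from BED6 or narrowPeak
#'
#' BED is 0-based half-open and passes through unchanged. For narrowPeak
#' (10 columns) the summit is `start + offset` when the column-10 offset is
#' non-negative; otherwise, and for plain BED, the summit falls back to the
#' interval midpoint `floor((start + end) / 2)`. A summit outside the peak is
#' clamped to the interval with a warning.
#'
#' @param path Path to a BED (>= 3 columns) or narrowPeak file.
#' @return A tibble: `peak_id`, `chrom`, `start`, `end`, `summit`, `score`.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(empty_peaks())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1]
    abort(sprintf("malformed BED line %d: fewer than 3 columns", idx[bad]))
  }
  get_col <- function(j) vapply(fields, function(f) if (length(f) >= j) f[j] else NA_character_, character(1))
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("malformed BED line %d: non-integer coordinates", idx[bad]))
  }
  if (any(end <= start)) {
    bad <- which(end <= start)[1]
    abort(sprintf("malformed BED line %d: end <= start", idx[bad]))
  }
  name <- get_col(4)
  name <- ifelse(is.na(name) | name == ".", paste0("peak_", seq_along(start)), name)
  score <- suppressWarnings(as.numeric(get_col(5)))
  score[is.na(score)] <- 0
  offset <- if (max(nf) >= 10L) suppressWarnings(as.integer(get_col(10))) else rep(NA_integer_, length(start))
  mid <- as.integer(floor((start + end) / 2))
  summit <- ifelse(!is.na(offset) & offset >= 0L, start + offset, mid)
  outside <- summit < start | summit >= end
  if (any(outside)) {
    warn(sprintf("%d summit(s) outside their peak interval; clamped", sum(outside)))
    summit <- pmin(pmax(summit, start), end - 1L)
  }
  tibble::tibble(peak_id = name, chrom = get_col(1), start = start, end = end,
                 summit = as.integer(summit), score = score)
}

#' Write peaks as a narrowPeak file
#'
#' Emits the 10-column ENCODE narrowPeak layout with the summit encoded as an
#' offset from `start`; deterministic column order and LF endings.
#'
#' @param peaks Peak tibble from [read_peaks()] or [simulate_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s\t-1\t-1\t%d",
                   peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                   as.integer(round(peaks$score)),
                   formatC(peaks$score, format = "f", digits = 4),
                   peaks$summit - peaks$start)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path TSV with columns `name`, `condition` (`high_myc`/`low_myc`),
#'   `library` (`ribo_depleted`/`polyA`), `cell_line`, `replicate`.
#' @return A validated tibble.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(), condition = readr::col_character(),
    library = readr::col_character(), cell_line = readr::col_character(),
    replicate = readr::col_integer()
  ))
  validate_sample_metadata(meta)
}

validate_sample_metadata <- function(meta) {
  need <- c("name", "condition", "library", "cell_line", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss)) abort(paste0("metadata missing column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(meta$name)) abort("duplicate sample names in metadata")
  if (!all(meta$condition %in% c("high_myc", "low_myc")))
    abort("condition must be 'high_myc' or 'low_myc'")
  if (!all(meta$library %in% c("ribo_depleted", "polyA")))
    abort("library must be 'ribo_depleted' or 'polyA'")
  if (any(meta$replicate < 1L)) abort("replicate must be >= 1")
  tibble::as_tibble(meta)
}

#' Construct a validated count matrix
#'
#' The count container is a tibble whose first column is `gene_id` and whose
#' remaining columns are integer counts, one per sample, with the sample
#' metadata attached as the `"samples"` attribute (retrieved with
#' [sample_meta()]).
#'
#' @param counts Tibble: `gene_id` plus one numeric column per sample.
#' @param meta Sample metadata tibble covering every count column.
#' @return The counts tibble, classed `lnc_counts`, metadata attached.
#' @export
count_matrix <- function(counts, meta) {
  meta <- validate_sample_metadata(meta)
  counts <- tibble::as_tibble(counts)
  if (names(counts)[1] != "gene_id") names(counts)[1] <- "gene_id"
  samples <- names(counts)[-1]
  missing <- setdiff(samples, meta$name)
  if (length(missing))
    abort(paste0("sample(s) in counts absent from metadata: ", paste(missing, collapse = ", ")))
  if (anyDuplicated(counts$gene_id))
    abort(paste0("duplicate gene_id: ", counts$gene_id[duplicated(counts$gene_id)][1]))
  vals <- as.matrix(counts[, -1])
  if (!is.numeric(vals) || anyNA(vals)) abort("counts must be numeric and complete")
  if (any(vals < 0)) abort("negative counts are not allowed")
  if (any(vals != round(vals))) abort("non-integer counts are not allowed")
  meta <- meta[match(samples, meta$name), ]
  structure(counts, samples = meta, class = c("lnc_counts", class(counts)))
}

#' Retrieve the sample metadata attached to a count matrix
#' @param counts An `lnc_counts` tibble.
#' @return The sample metadata tibble.
#' @export
sample_meta <- function(counts) {
  meta <- attr(counts, "samples")
  if (is.null(meta)) abort("counts carry no sample metadata; use count_matrix()")
  meta
}

#' Read a count matrix and its sample metadata
#'
#' @param path Counts TSV: first column gene identifiers, header row sample
#'   names; entries must be non-negative integers.
#' @param metadata Path to a metadata TSV (see [read_sample_metadata()]) or a
#'   metadata tibble.
#' @return An `lnc_counts` tibble (see [count_matrix()]).
#' @export
read_counts <- function(path, metadata) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- strsplit(readr::read_lines(path, n_max = 1), "\t")[[1]]
  counts <- readr::read_tsv(path, col_types = paste0(
    "c", strrep("d", length(header) - 1)))
  meta <- if (is.character(metadata)) read_sample_metadata(metadata) else validate_sample_metadata(metadata)
  count_matrix(counts, meta)
}

#' Write a count matrix (and optionally its metadata) to TSV
#' @param counts An `lnc_counts` tibble.
#' @param path Counts output path.
#' @param meta_path Optional metadata output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, meta_path = NULL) {
  readr::write_tsv(tibble::as_tibble(counts), path)
  if (!is.null(meta_path)) readr::write_tsv(sample_meta(counts), meta_path)
  invisible(path)
}

#' Read a bedGraph coverage file
#'
#' @param path bedGraph path (0-based half-open intervals, fourth column the
#'   coverage value; intervals absent from the file are zero coverage).
#' @return Tibble: `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)
  if (!any(keep)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), value = double()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) abort("malformed bedGraph: fewer than 4 columns")
  tibble::tibble(
    chrom = vapply(fields, `[`, character(1), 1),
    start = as.integer(vapply(fields, `[`, character(1), 2)),
    end = as.integer(vapply(fields, `[`, character(1), 3)),
    value = as.numeric(vapply(fields, `[`, character(1), 4))
  )
}
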