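ALIGNMENT_COLS <- c("read_id", "read_sequence", "count", "ref_id", "start",
                    "end", "strand", "mismatches", "n_hits")

# parse a collapsed-read count suffix such as "read1_x53"; 1 when absent
parse_count_suffix <- function(read_id) {
  m <- regmatches(read_id, regexec("_x([0-9]+)$", read_id))
  vapply(m, function(g) if (length(g) == 2) as.integer(g[2]) else 1L, integer(1))
}

cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read small-RNA read alignments
#'
#' Supported dialects:
#' * `"sam"`: standard SAM, read through Rsamtools; `NM` (mismatches) and
#'   `NH` (number of hits) tags are used when present. Unmapped records are
#'   skipped.
#' * `"tab"`: the package's plain-text dialect, one alignment per row with
#'   tab-separated columns `read_id, read_sequence, count, ref_id,
#'   start (0-based), strand, mismatches, n_hits` and no header.
#'
#' All coordinates are 0-based half-open internally; `end = start +` aligned
#' reference width. A collapsed-read multiplicity may be encoded in the read id
#' as an `_xN` suffix and is parsed into `count` (1 otherwise). When `n_hits`
#' is not provided by the file it is derived by counting alignments sharing a
#' `read_id`.
#'
#' @param path alignment file.
#' @param dialect `"sam"` or `"tab"`.
#' @param genome optional genome tibble (from [read_fasta()]); when supplied,
#'   alignments exceeding reference bounds raise a validation error.
#' @return a tibble with columns `read_id, read_sequence, count, ref_id,
#'   start, end, strand, mismatches, n_hits`.
#' @export
read_alignments <- function(path, dialect = c("sam", "tab"), genome = NULL) {
  dialect <- match.arg(dialect)
  aln <- if (dialect == "sam") read_alignments_sam(path) else read_alignments_tab(path)
  if (!nrow(aln)) return(aln)
  # derive n_hits by read_id grouping where the file did not provide it
  aln <- aln |>
    group_by(.data$read_id) |>
    mutate(n_hits = ifelse(is.na(.data$n_hits), dplyr::n(), .data$n_hits)) |>
    ungroup()
  if (!is.null(genome)) {
    lens <- setNames(nchar(genome$sequence), genome$id)
    ref_len <- lens[aln$ref_id]
    bad <- is.na(ref_len) | aln$end > ref_len | aln$start < 0
    if (any(bad)) {
      abort(sprintf("%d alignment(s) outside reference bounds (first: read '%s' on '%s')",
                    sum(bad), aln$read_id[which(bad)[1]], aln$ref_id[which(bad)[1]]))
    }
  }
  aln
}

read_alignments_sam <- function(path) {
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "seq"),
    tag = c("NM", "NH"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !bitwAnd(res$flag, 4L)
  tibble(
    read_id = res$qname[mapped],
    read_sequence = normalize_seq(as.character(res$seq)[mapped]),
    count = parse_count_suffix(res$qname[mapped]),
    ref_id = as.character(res$rname)[mapped],
    start = res$pos[mapped] - 1L,
    end = res$pos[mapped] - 1L + cigar_ref_width(res$cigar[mapped]),
    strand = as.character(res$strand)[mapped],
    mismatches = dplyr::coalesce(res$tag$NM[mapped] %||% rep(NA_integer_, sum(mapped)), 0L),
    n_hits = as.integer(res$tag$NH[mapped] %||% rep(NA_integer_, sum(mapped)))
  )
}

read_alignments_tab <- function(path) {
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  cols <- readr::cols(
    read_id = readr::col_character(), read_sequence = readr::col_character(),
    count = readr::col_integer(), ref_id = readr::col_character(),
    start = readr::col_integer(), strand = readr::col_character(),
    mismatches = readr::col_integer(), n_hits = readr::col_integer())
  tab <- readr::read_tsv(path, col_names = names(cols$cols), col_types = cols,
                         comment = "#", progress = FALSE)
  tab |>
    mutate(read_sequence = normalize_seq(.data$read_sequence),
           end = .data$start + nchar(.data$read_sequence)) |>
    select(dplyr::all_of(ALIGNMENT_COLS))
}

#' @rdname read_alignments
#' @param alignments an alignment tibble.
#' @export
write_alignments_tab <- function(alignments, path) {
  alignments |>
    select("read_id", "read_sequence", "count", "ref_id", "start",
           "strand", "mismatches", "n_hits") |>
    readr::write_tsv(path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read exclusion annotations (CDS / non-coding RNA intervals)
#'
#' BED input (0-based half-open) is taken as-is; GFF3 (1-based inclusive) is
#' converted to the internal 0-based half-open convention. The feature kind is
#' taken from the BED name column or the GFF3 type column and collapsed onto
#' `{CDS, rRNA, tRNA, other_ncRNA}`.
#'
#' @param path a BED or GFF3 file (format chosen by extension).
#' @return a tibble with columns `ref_id`, `start`, `end`, `kind`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  gr <- rtracklayer::import(path)
  kind_raw <- if (!is.null(gr$type)) as.character(gr$type)
              else if (!is.null(gr$name)) as.character(gr$name)
              else rep("CDS", length(gr))
  kind <- dplyr::case_when(
    grepl("cds|exon|gene|mrna", kind_raw, ignore.case = TRUE) ~ "CDS",
    grepl("rrna", kind_raw, ignore.case = TRUE) ~ "rRNA",
    grepl("trna", kind_raw, ignore.case = TRUE) ~ "tRNA",
    TRUE ~ "other_ncRNA")
  tibble(
    ref_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # GRanges is 1-based inclusive
    end = GenomicRanges::end(gr),
    kind = kind)
}
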