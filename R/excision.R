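#' Filter mapped reads by mismatches, multi-hits, and annotation overlap
#'
#' Keeps alignments with `mismatches <= max_mapping_mismatches`,
#' `n_hits <= max_multi_hits`, and zero overlap (any shared base, either
#' strand) with the exclusion annotations (CDS / rRNA / tRNA / other ncRNA).
#' Input order is preserved.
#'
#' @param alignments alignment tibble (see [read_alignments()]).
#' @param annotations annotation tibble (see [read_annotations()]), or `NULL`.
#' @param params a `plantpin_params` list.
#' @return the filtered alignment tibble.
#' @export
filter_reads <- function(alignments, annotations = NULL,
                         params = default_parameter_set()) {
  params <- as_parameter_set(params)
  keep <- alignments$mismatches <= params$max_mapping_mismatches &
    alignments$n_hits <= params$max_multi_hits
  out <- alignments[keep, , drop = FALSE]
  if (!is.null(annotations) && nrow(annotations) && nrow(out)) {
    q <- GenomicRanges::GRanges(out$ref_id,
                                IRanges::IRanges(out$start + 1L, out$end))
    s <- GenomicRanges::GRanges(annotations$ref_id,
                                IRanges::IRanges(annotations$start + 1L,
                                                 annotations$end))
    hit <- IRanges::overlapsAny(q, s)
    out <- out[!hit, , drop = FALSE]
  }
  out
}

#' Cluster overlapping or nearby reads into potential precursor loci
#'
#' Single-linkage clustering per (reference, strand): alignments overlapping or
#' within `max_gap` nt of the running cluster extent are merged. Each cluster
#' reports its highest-count read as the putative mature (ties broken by
#' earlier start, then read id, for determinism).
#'
#' @param alignments filtered alignment tibble.
#' @param max_gap maximum gap (nt) between reads joined into one cluster.
#' @return a tibble with one row per cluster: `cluster_id, ref_id, strand,
#'   start, end, n_reads, total_count, mature_read_id, mature_start,
#'   mature_end, mature_sequence, mature_count`.
#' @export
cluster_reads <- function(alignments, max_gap = 30L) {
  if (!nrow(alignments)) {
    return(tibble(cluster_id = character(), ref_id = character(),
                  strand = character(), start = integer(), end = integer(),
                  n_reads = integer(), total_count = integer(),
                  mature_read_id = character(), mature_start = integer(),
                  mature_end = integer(), mature_sequence = character(),
                  mature_count = integer()))
  }
  aln <- alignments |> arrange(.data$ref_id, .data$strand, .data$start, .data$end)
  aln <- aln |>
    group_by(.data$ref_id, .data$strand) |>
    mutate(cluster_local = cumsum(
      .data$start > dplyr::lag(cummax(.data$end), default = dplyr::first(.data$start)) + max_gap)) |>
    ungroup()
  aln |>
    group_by(.data$ref_id, .data$strand, .data$cluster_local) |>
    summarise(
      n_reads = dplyr::n(), total_count = sum(.data$count),
      mature_idx = order(-.data$count, .data$start, .data$read_id)[1],
      mature_read_id = .data$read_id[mature_idx],
      mature_start = .data$start[mature_idx],
      mature_end = .data$end[mature_idx],
      mature_sequence = .data$read_sequence[mature_idx],
      mature_count = .data$count[mature_idx],
      start = min(.data$start), end = max(.data$end),
      .groups = "drop") |>
    mutate(cluster_id = sprintf("%s_%s_%d", .data$ref_id,
                                ifelse(.data$strand == "+", "p", "m"),
                                .data$start)) |>
    select("cluster_id", "ref_id", "strand", "start", "end", "n_reads",
           "total_count", "mature_read_id", "mature_start", "mature_end",
           "mature_sequence", "mature_count")
}

#' Excise candidate precursor windows around read clusters and fold them
#'
#' For each cluster two windows are excised, covering the two possible hairpin
#' geometries: the putative mature on the 5' arm (short flank on its 5' side,
#' the remainder of the excision length downstream) and on the 3' arm
#' (mirrored). Windows are capped at `excision_length_max` nt, clipped at
#' chromosome ends, and minus-strand windows are reverse-complemented before
#' folding, so stored sequences are always 5'->3'. Clusters longer than the
#' excision cap are skipped with a notice.
#'
#' @param genome genome tibble from [read_fasta()].
#' @param clusters cluster tibble from [cluster_reads()].
#' @param params a `plantpin_params` list.
#' @param backend folding backend passed to [fold()].
#' @param flank_short flank (nt) kept on the mature-proximal window edge.
#' @return a precursor tibble: `id, cluster_id, ref_id, start, end, strand,
#'   sequence, structure, mfe, mature_start, mature_end` (mature offsets are
#'   0-based within the strand-oriented precursor sequence).
#' @export
excise_candidates <- function(genome, clusters, params = default_parameter_set(),
                              backend = "reference", flank_short = 20L) {
  params <- as_parameter_set(params)
  L <- params$excision_length_max
  glen <- setNames(nchar(genome$sequence), genome$id)
  gseq <- setNames(genome$sequence, genome$id)
  rows <- pmap(clusters, function(cluster_id, ref_id, strand, start, end,
                                  mature_start, mature_end, mature_sequence, ...) {
    if (end - start > L) {
      inform(sprintf("cluster %s spans %d nt > excision cap %d; skipped",
                     cluster_id, end - start, L))
      return(NULL)
    }
    chr_len <- glen[[ref_id]]
    windows <- unique(list(
      c(max(0L, mature_start - flank_short),
        min(chr_len, max(0L, mature_start - flank_short) + L)),
      c(max(0L, min(chr_len, mature_end + flank_short) - L),
        min(chr_len, mature_end + flank_short))))
    arms <- if (strand == "+") c("5p", "3p") else c("3p", "5p")
    out <- list()
    for (w in seq_along(windows)) {
      ws <- windows[[w]][1]; we <- windows[[w]][2]
      if (mature_start < ws || mature_end > we) next
      seq <- slice_genome(gseq[[ref_id]], ws, we, strand)
      m_off <- if (strand == "+") mature_start - ws else we - mature_end
      m_len <- mature_end - mature_start
      out[[w]] <- tibble(
        id = sprintf("%s_w%s", cluster_id, arms[w]),
        cluster_id = cluster_id, ref_id = ref_id,
        start = ws, end = we, strand = strand, sequence = seq,
        mature_start = m_off, mature_end = m_off + m_len)
    }
    bind_rows(out)
  })
  prec <- bind_rows(rows)
  if (!nrow(prec)) {
    return(tibble(id = character(), cluster_id = character(), ref_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  sequence = character(), structure = character(), mfe = double(),
                  mature_start = integer(), mature_end = integer()))
  }
  prec <- distinct(prec, .data$ref_id, .data$start, .data$end, .data$strand,
                   .data$mature_start, .keep_all = TRUE)
  folds <- map(prec$sequence, fold, backend = backend)
  prec$structure <- map_chr(folds, "structure")
  prec$mfe <- map_dbl(folds, "mfe")
  select(prec, "id", "cluster_id", "ref_id", "start", "end", "strand",
         "sequence", "structure", "mfe", "mature_start", "mature_end")
}

#' Extract the miRNA:miRNA* duplex from a folded precursor
#'
#' The star arm is the interval of positions pairing with the mature, shifted
#' by the canonical 2-nt Dicer 3' overhang (configurable via `overhang`).
#' Pairing statistics follow the duplex bookkeeping of the plant constraint
#' tables: `n_paired` counts paired mature positions; unpaired mature runs
#' whose opposite arm is contiguous count as bulges (as do contiguous-mature
#' gaps on the star side), while runs unpaired on both arms (internal loops)
#' count toward `n_unpaired_total`. Returns `NULL` when the mature arm spans
#' the terminal loop (mature positions pairing within the mature itself) or is
#' entirely unpaired.
#'
#' @param structure dot-bracket of the precursor.
#' @param mature_start,mature_end 0-based half-open mature offsets within the
#'   precursor.
#' @param overhang 3' overhang (nt) applied to the star interval.
#' @return a one-row tibble `star_start, star_end, n_paired, n_unpaired_total,
#'   max_consecutive_unpaired, bulge_total, max_consecutive_bulge`, or `NULL`.
#' @export
extract_duplex <- function(structure, mature_start, mature_end, overhang = 2L) {
  pt <- pair_table(structure)
  n <- length(pt)
  mpos <- seq(mature_start + 1L, mature_end) # 1-based positions of the mature
  partners <- pt[mpos]
  paired <- !is.na(partners)
  if (!any(paired)) return(NULL)
  if (any(partners[paired] %in% mpos)) return(NULL) # mature folds onto itself: spans the loop
  star_lo <- min(partners[paired]) + overhang
  star_hi <- max(partners[paired]) + overhang
  star_lo <- max(1L, star_lo); star_hi <- min(n, star_hi)

  n_paired <- sum(paired)
  # classify unpaired mature runs: bulge when the opposite arm is contiguous
  runs <- rle(paired)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  unpaired_total <- 0L; max_unp <- 0L
  bulge_total <- 0L; max_bulge <- 0L
  for (r in seq_along(runs$values)) {
    if (runs$values[r]) next
    len <- runs$lengths[r]
    before <- if (run_start[r] > 1) partners[run_start[r] - 1L] else NA_integer_
    after <- if (run_end[r] < length(mpos)) partners[run_end[r] + 1L] else NA_integer_
    interior <- !is.na(before) && !is.na(after)
    if (interior && abs(before - after) == 1L) {
      bulge_total <- bulge_total + len
      max_bulge <- max(max_bulge, len)
    } else {
      unpaired_total <- unpaired_total + len
      max_unp <- max(max_unp, len)
    }
  }
  # star-side bulges: partner gaps across adjacent paired mature positions
  pp <- which(paired)
  if (length(pp) > 1) {
    adjacent <- diff(pp) == 1L
    gaps <- abs(diff(partners[pp])) - 1L
    star_bulges <- gaps[adjacent & gaps > 0]
    if (length(star_bulges)) {
      bulge_total <- bulge_total + sum(star_bulges)
      max_bulge <- max(max_bulge, max(star_bulges))
    }
  }
  tibble(star_start = star_lo - 1L, star_end = star_hi, # back to 0-based half-open
         n_paired = n_paired, n_unpaired_total = unpaired_total,
         max_consecutive_unpaired = max_unp,
         bulge_total = bulge_total, max_consecutive_bulge = max_bulge)
}

#' Test a duplex against the plant miRNA:miRNA* constraints
#'
#' @param duplex a one-row duplex tibble from [extract_duplex()] (or any list
#'   with the same fields), or `NULL`.
#' @param params a `plantpin_params` list.
#' @return `TRUE` iff `n_paired >= min_paired`, `n_unpaired_total <=
#'   max_unpaired_total`, `max_consecutive_unpaired <= max_unpaired_consecutive`
#'   and `bulge_total <= max_bulge_total`; `FALSE` for `NULL` input.
#' @export
duplex_passes <- function(duplex, params = default_parameter_set()) {
  if (is.null(duplex)) return(FALSE)
  params <- as_parameter_set(params)
  isTRUE(duplex$n_paired >= params$min_paired &&
         duplex$n_unpaired_total <= params$max_unpaired_total &&
         duplex$max_consecutive_unpaired <= params$max_unpaired_consecutive &&
         duplex$bulge_total <= params$max_bulge_total)
}
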