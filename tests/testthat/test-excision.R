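mk_aln <- function(...) {
  rows <- list(...)
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(read_id = r$id, read_sequence = strrep("A", r$end - r$start),
                   count = r$count %||% 1L, ref_id = r$ref %||% "chr1",
                   start = r$start, end = r$end, strand = r$strand %||% "+",
                   mismatches = r$mm %||% 0L, n_hits = r$nh %||% 1L)
  })
}

test_that("read filtering enforces mismatch, multi-hit and annotation rules", {
  aln <- mk_aln(list(id = "ok", start = 100L, end = 121L, mm = 1L),
                list(id = "multi", start = 200L, end = 221L, nh = 21L),
                list(id = "mm2", start = 300L, end = 321L, mm = 2L),
                list(id = "cds_edge", start = 380L, end = 401L),
                list(id = "near_cds", start = 350L, end = 371L))
  ann <- tibble::tibble(ref_id = "chr1", start = 400L, end = 500L, kind = "CDS")
  kept <- filter_reads(aln, ann)
  # 1-nt CDS overlap removes; multi-hit 21 > 20 removes; 2 mismatches removes
  expect_identical(kept$read_id, c("ok", "near_cds"))
  # boundary: exactly 20 hits and 1 mismatch are kept
  expect_identical(nrow(filter_reads(mk_aln(list(id = "b", start = 1L, end = 22L,
                                                 nh = 20L, mm = 1L)), ann)), 1L)
})

test_that("read clustering is single-linkage with argmax-count mature", {
  close_pair <- mk_aln(list(id = "a", start = 100L, end = 121L, count = 100L),
                       list(id = "b", start = 126L, end = 147L, count = 3L))
  expect_identical(nrow(cluster_reads(close_pair, max_gap = 10)), 1L)
  expect_identical(cluster_reads(close_pair, max_gap = 10)$mature_read_id, "a")
  far_pair <- mk_aln(list(id = "a", start = 100L, end = 121L),
                     list(id = "b", start = 171L, end = 192L))
  expect_identical(nrow(cluster_reads(far_pair, max_gap = 10)), 2L)
  # strands never merge
  two_strand <- mk_aln(list(id = "a", start = 100L, end = 121L),
                       list(id = "b", start = 105L, end = 126L, strand = "-"))
  expect_identical(nrow(cluster_reads(two_strand, max_gap = 10)), 2L)
})

test_that("excised windows respect the length cap, clipping and provenance", {
  genome <- tibble::tibble(id = "chr1",
                           sequence = withr::with_seed(1, random_nt(10000)))
  aln <- mk_aln(list(id = "mid", start = 1000L, end = 1021L, count = 10L),
                list(id = "edge", start = 10L, end = 31L, count = 10L))
  prec <- excise_candidates(genome, cluster_reads(aln))
  expect_true(all(prec$end - prec$start <= 300))
  expect_true(all(prec$start >= 0))
  mid <- prec[prec$cluster_id == "chr1_p_1000", ]
  expect_identical(nrow(mid), 2L) # two windows, mature on either arm
  expect_true(all(mid$start <= 1000 & mid$end >= 1021))
  # clipped window near the chromosome start is still emitted
  edge <- prec[prec$cluster_id == "chr1_p_10", ]
  expect_gte(nrow(edge), 1L)
  expect_true(any(edge$start == 0))
  # provenance: every stored sequence re-slices identically from the genome
  for (i in seq_len(nrow(prec))) {
    expect_identical(prec$sequence[i],
                     substr(genome$sequence, prec$start[i] + 1, prec$end[i]))
    # the mature offsets address the genomic read interval within the window
    expect_identical(substr(prec$sequence[i], prec$mature_start[i] + 1,
                            prec$mature_end[i]),
                     substr(genome$sequence, prec$start[i] + prec$mature_start[i] + 1,
                            prec$start[i] + prec$mature_end[i]))
    expect_identical(prec$mature_end[i] - prec$mature_start[i], 21L)
  }
})

test_that("minus-strand windows store the reverse-complemented sequence", {
  genome <- tibble::tibble(id = "chr1",
                           sequence = withr::with_seed(2, random_nt(5000)))
  aln <- mk_aln(list(id = "m", start = 2000L, end = 2021L, strand = "-"))
  prec <- excise_candidates(genome, cluster_reads(aln))
  for (i in seq_len(nrow(prec))) {
    fwd <- substr(genome$sequence, prec$start[i] + 1, prec$end[i])
    expect_identical(prec$sequence[i], plantpin:::revcomp(fwd))
    # the mature offsets address the read within the oriented precursor
    mat <- substr(prec$sequence[i], prec$mature_start[i] + 1, prec$mature_end[i])
    expect_identical(mat, plantpin:::revcomp(substr(genome$sequence, 2001, 2021)))
  }
})

test_that("duplex extraction measures pairing, internal loops and bulges", {
  # perfect 21/21 duplex
  db <- paste0(strrep("(", 21), "....", strrep(")", 21))
  d <- extract_duplex(db, 0L, 21L)
  expect_identical(d$n_paired, 21L)
  expect_identical(d$n_unpaired_total, 0L)
  expect_identical(d$bulge_total, 0L)
  expect_identical(c(d$star_start, d$star_end), c(27L, 46L)) # 2-nt 3' overhang
  # 2-nt symmetric internal loop: unpaired, not bulge
  db2 <- paste0(strrep("(", 8), "..", strrep("(", 10), "....",
                strrep(")", 10), "..", strrep(")", 8))
  d2 <- extract_duplex(db2, 0L, 20L)
  expect_identical(d2$n_unpaired_total, 2L)
  expect_identical(d2$max_consecutive_unpaired, 2L)
  expect_identical(d2$bulge_total, 0L)
  # 2-nt bulge on the mature arm: opposite arm contiguous
  db3 <- paste0(strrep("(", 10), "..", strrep("(", 10), "....", strrep(")", 20))
  d3 <- extract_duplex(db3, 0L, 22L)
  expect_identical(d3$bulge_total, 2L)
  expect_identical(d3$n_unpaired_total, 0L)
  # mature across the terminal loop folds onto itself -> no duplex
  db4 <- paste0(strrep("(", 10), "....", strrep(")", 10))
  expect_null(extract_duplex(db4, 2L, 20L))
  # fully unpaired mature -> no duplex
  expect_null(extract_duplex("..........((((...))))", 0L, 9L))
})

test_that("duplex constraints pass at the boundary and fail one step beyond", {
  ok <- tibble::tibble(star_start = 0L, star_end = 21L, n_paired = 15L,
                       n_unpaired_total = 5L, max_consecutive_unpaired = 3L,
                       bulge_total = 2L, max_consecutive_bulge = 2L)
  expect_true(duplex_passes(ok))
  expect_false(duplex_passes(dplyr::mutate(ok, n_paired = 14L)))
  expect_false(duplex_passes(dplyr::mutate(ok, n_unpaired_total = 6L)))
  expect_false(duplex_passes(dplyr::mutate(ok, max_consecutive_unpaired = 4L)))
  expect_false(duplex_passes(dplyr::mutate(ok, bulge_total = 3L)))
  expect_false(duplex_passes(NULL))
})

test_that("worsening any duplex statistic never turns a failure into a pass", {
  withr::with_seed(99, {
    for (case in 1:200) {
      d <- tibble::tibble(star_start = 0L, star_end = 21L,
                          n_paired = sample(10:22, 1),
                          n_unpaired_total = sample(0:8, 1),
                          max_consecutive_unpaired = sample(0:6, 1),
                          bulge_total = sample(0:4, 1),
                          max_consecutive_bulge = 0L)
      worse <- d
      stat <- sample(c("n_paired", "n_unpaired_total",
                       "max_consecutive_unpaired", "bulge_total"), 1)
      worse[[stat]] <- worse[[stat]] + if (stat == "n_paired") -1L else 1L
      expect_false(!duplex_passes(d) && duplex_passes(worse))
    }
  })
})
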