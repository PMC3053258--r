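#' Specification for the synthetic small-RNA dataset generator
#'
#' Bundles every knob of [make_dataset()] with defaults emulating a plant
#' small-RNA discovery experiment at test scale: ~145-nt stem-loop precursors
#' (65-nt stems, 15-nt loops, close to the plant mean precursor length),
#' Dicer-like read stacks (a dominant mature stack, a low-count star read, a
#' rare loop read, a minority of 5'-jittered reads), coding-like background
#' composition, and miRNA families sharing an identical 2-12 nucleus.
#'
#' @param seed integer seed; the whole dataset is a pure function of the spec.
#' @param n_hairpins number of planted true hairpin loci.
#' @param n_decoys number of planted hairpins placed inside CDS annotation
#'   (their reads must be filtered out downstream).
#' @param stem_length arm length (nt) of each planted stem (>= 15).
#' @param loop_length loop length (nt).
#' @param planted_mismatches point substitutions planted into the 3' arm,
#'   opposite the mature, per duplex.
#' @param mature_length planted mature length (nt).
#' @param genome_length toy genome length (nt).
#' @param n_background number of background (non-hairpin) sequences emitted in
#'   the `background` slot.
#' @param background_length length of each background sequence.
#' @param reads_mature,reads_star,reads_loop collapsed counts of the planted
#'   read stacks.
#' @param read_noise_fraction fraction (of planted read rows) of uniform noise
#'   reads added at random genomic positions.
#' @param n_families,family_size known-mature library composition.
#' @param nucleus_identity when `TRUE`, the known-mature library contains
#'   family mates sharing the planted matures' exact 2-12 nucleus.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_hairpins = 5L, n_decoys = 2L,
                           stem_length = 65L, loop_length = 15L,
                           planted_mismatches = 0L, mature_length = 21L,
                           genome_length = 20000L, n_background = 50L,
                           background_length = 300L, reads_mature = 50L,
                           reads_star = 2L, reads_loop = 1L,
                           read_noise_fraction = 0.05, n_families = 10L,
                           family_size = 10L, nucleus_identity = TRUE) {
  spec <- as.list(environment())
  stopifnot(spec$stem_length >= 15, spec$loop_length >= 3,
            spec$read_noise_fraction >= 0, spec$read_noise_fraction <= 1,
            spec$mature_length <= spec$stem_length)
  structure(spec, class = "synthetic_spec")
}

# sample a coding-like sequence by concatenating sense codons
codon_background <- function(n_nt) {
  codons <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  paste0), c("A", "C", "G", "T"), paste0))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(codons, ceiling(n_nt / 3), replace = TRUE), collapse = "") |>
    substr(1, n_nt)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Generate one planted stem-loop hairpin
#'
#' Builds a random 5' arm, loop, and the reverse complement of the arm as the
#' 3' arm, with `planted_mismatches` point substitutions placed opposite the
#' mature so they stress the duplex constraints. The mature is planted on the
#' 5' arm. Deterministic given the spec seed.
#'
#' @param spec a `synthetic_spec`.
#' @param seed optional seed override for this hairpin.
#' @return list with `sequence`, `mature_start`, `mature_end` (0-based
#'   half-open offsets of the planted mature), `star_start`, `star_end`.
#' @export
make_hairpin <- function(spec = synthetic_spec(), seed = spec$seed) {
  withr::with_seed(seed, make_hairpin_impl(spec))
}

make_hairpin_impl <- function(spec) {
  arm <- random_seq(spec$stem_length)
  loop <- random_seq(spec$loop_length)
  arm3 <- revcomp(arm)
  m_start <- 5L
  m_end <- m_start + spec$mature_length
  if (spec$planted_mismatches > 0) {
    # substitute bases on the 3' arm opposite the mature
    partners <- (2L * spec$stem_length + spec$loop_length) -
      seq(m_start + 1L, m_end) # 1-based positions in full hairpin
    arm3_pos <- partners - spec$stem_length - spec$loop_length # 1-based in arm3
    pick <- sort(sample(arm3_pos, min(spec$planted_mismatches, length(arm3_pos))))
    chars <- strsplit(arm3, "")[[1]]
    for (p in pick) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                 c(chars[p], chartr("ACGT", "TGCA", chars[p]))), 1)
    }
    arm3 <- paste(chars, collapse = "")
  }
  seqn <- paste0(arm, loop, arm3)
  n <- nchar(seqn)
  star_start <- n - m_end + 2L
  star_end <- min(n, n - m_start + 2L)
  list(sequence = seqn, mature_start = m_start, mature_end = m_end,
       star_start = star_start, star_end = star_end)
}

#' Generate a complete synthetic discovery dataset
#'
#' Embeds planted hairpins (alternating strands) and CDS-covered decoy
#' hairpins into a coding-like toy genome, stacks Dicer-like reads over the
#' mature, star and loop of every planted locus (with ±1-nt 5' jitter on a
#' minority mature read), adds uniform noise reads, and builds a known-mature
#' family library plus a truth table. Identical specs yield byte-identical
#' datasets.
#'
#' @param spec a `synthetic_spec`.
#' @return a list with tibbles `genome`, `alignments`, `annotations`,
#'   `matures`, `background`, `truth`, the family list `families`, and the
#'   `spec`.
#' @export
make_dataset <- function(spec = synthetic_spec()) {
  withr::with_seed(spec$seed, make_dataset_impl(spec))
}

make_dataset_impl <- function(spec) {
  hp_len <- 2L * spec$stem_length + spec$loop_length
  n_loci <- spec$n_hairpins + spec$n_decoys
  slot_width <- spec$genome_length %/% max(1L, n_loci)
  if (slot_width < hp_len + 700L) {
    abort("genome too short to host all planted loci without overlap")
  }
  genome_seq <- codon_background(spec$genome_length)

  loci <- list()
  aln_rows <- list()
  ann_rows <- list()
  for (i in seq_len(n_loci)) {
    hp <- make_hairpin_impl(spec)
    is_decoy <- i > spec$n_hairpins
    strand <- if (i %% 2 == 1) "+" else "-"
    pos <- (i - 1L) * slot_width + 350L + sample.int(50L, 1)
    substr(genome_seq, pos + 1L, pos + hp_len) <- if (strand == "+") {
      hp$sequence
    } else {
      revcomp(hp$sequence)
    }
    # planted offsets -> genomic coordinates
    to_genomic <- function(off_start, off_end) {
      if (strand == "+") c(pos + off_start, pos + off_end)
      else c(pos + hp_len - off_end, pos + hp_len - off_start)
    }
    m <- to_genomic(hp$mature_start, hp$mature_end)
    s <- to_genomic(hp$star_start, hp$star_end)
    locus_id <- sprintf("locus%02d", i)
    mature_seq <- substr(hp$sequence, hp$mature_start + 1L, hp$mature_end)
    star_seq <- substr(hp$sequence, hp$star_start + 1L, hp$star_end)
    mk_read <- function(tag, gstart, gend, seqn, count) {
      tibble(read_id = sprintf("%s_%s_x%d", locus_id, tag, count),
             read_sequence = seqn, count = count, ref_id = "chr1",
             start = as.integer(gstart), end = as.integer(gend),
             strand = strand, mismatches = 0L, n_hits = 1L)
    }
    jit <- substr(hp$sequence, hp$mature_start + 2L, hp$mature_end + 1L)
    reads <- list(
      mk_read("mature", m[1], m[2], mature_seq, spec$reads_mature),
      # minority mature read with a 1-nt 5' shift exercises signature tolerance
      mk_read("maturej",
              if (strand == "+") m[1] + 1L else m[1] - 1L,
              if (strand == "+") m[2] + 1L else m[2] - 1L,
              jit, 3L))
    if (spec$reads_star > 0) {
      reads <- c(reads, list(mk_read("star", s[1], s[2], star_seq, spec$reads_star)))
    }
    if (spec$reads_loop > 0) {
      lp <- to_genomic(spec$stem_length + 1L,
                       spec$stem_length + spec$loop_length - 1L)
      loop_seq <- substr(hp$sequence, spec$stem_length + 2L,
                         spec$stem_length + spec$loop_length - 1L)
      reads <- c(reads, list(mk_read("loop", lp[1], lp[2], loop_seq,
                                     spec$reads_loop)))
    }
    aln_rows[[i]] <- bind_rows(reads)
    if (is_decoy) {
      ann_rows[[i]] <- tibble(ref_id = "chr1", start = as.integer(pos - 50L),
                              end = as.integer(pos + hp_len + 50L), kind = "CDS")
    }
    loci[[i]] <- tibble(locus = locus_id, ref_id = "chr1",
                        start = as.integer(pos), end = as.integer(pos + hp_len),
                        strand = strand,
                        mature_start = as.integer(m[1]), mature_end = as.integer(m[2]),
                        star_start = as.integer(s[1]), star_end = as.integer(s[2]),
                        mature_sequence = mature_seq, is_decoy = is_decoy)
  }
  truth <- bind_rows(loci)
  alignments <- bind_rows(aln_rows)

  n_noise <- round(spec$read_noise_fraction * nrow(alignments))
  if (n_noise > 0) {
    noise <- map(seq_len(n_noise), function(j) {
      st <- sample.int(spec$genome_length - 21L, 1)
      tibble(read_id = sprintf("noise%03d_x1", j),
             read_sequence = substr(genome_seq, st + 1L, st + 21L),
             count = 1L, ref_id = "chr1", start = as.integer(st),
             end = as.integer(st + 21L),
             strand = sample(c("+", "-"), 1), mismatches = 0L, n_hits = 1L)
    })
    alignments <- bind_rows(alignments, bind_rows(noise))
  }

  # known-mature families: each family shares an exact 2-12 nucleus
  families <- list()
  mature_lib <- character(0)
  planted <- truth$mature_sequence[!truth$is_decoy]
  for (f in seq_len(spec$n_families)) {
    seed_mature <- if (spec$nucleus_identity && f <= length(planted)) {
      planted[f]
    } else {
      random_seq(spec$mature_length)
    }
    nucleus <- substr(seed_mature, 2, 12)
    members <- vapply(seq_len(spec$family_size), function(k) {
      m <- random_seq(spec$mature_length)
      substr(m, 2, 12) <- nucleus
      m
    }, character(1))
    if (spec$nucleus_identity && f <= length(planted)) members[1] <- seed_mature
    fam_id <- sprintf("fam%02d", f)
    families[[fam_id]] <- members
    mature_lib <- c(mature_lib, setNames(members, sprintf("%s_m%02d", fam_id,
                                                          seq_along(members))))
  }

  background <- tibble(
    id = sprintf("bgr%03d", seq_len(spec$n_background)),
    sequence = vapply(seq_len(spec$n_background),
                      function(i) codon_background(spec$background_length),
                      character(1)))

  list(
    genome = tibble(id = "chr1", sequence = genome_seq),
    alignments = alignments,
    annotations = if (length(ann_rows)) bind_rows(ann_rows) else
      tibble(ref_id = character(), start = integer(), end = integer(),
             kind = character()),
    matures = tibble(id = names(mature_lib), sequence = unname(mature_lib)),
    background = background,
    truth = truth,
    families = families,
    spec = spec)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `genome.fa`, `alignments.tsv` (tab dialect), `annotations.bed`,
#' `matures.fa`, `background.fa` and `truth.tsv` under `dir`.
#'
#' @param dataset result of [make_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$genome, file.path(dir, "genome.fa"))
  write_alignments_tab(dataset$alignments, file.path(dir, "alignments.tsv"))
  ann <- dataset$annotations
  readr::write_tsv(tibble(a = ann$ref_id, b = ann$start, c = ann$end, d = ann$kind),
                   file.path(dir, "annotations.bed"), col_names = FALSE,
                   progress = FALSE)
  write_fasta(dataset$matures, file.path(dir, "matures.fa"))
  write_fasta(dataset$background, file.path(dir, "background.fa"))
  readr::write_tsv(dataset$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
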