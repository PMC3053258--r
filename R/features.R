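#' Length-normalized minimum free energy
#'
#' Dividing the MFE by the precursor length removes the strong linear length
#' dependence of hairpin free energies and makes precursors of different
#' lengths comparable on one scale (kcal/mol per nt, signed, <= 0).
#'
#' @param mfe minimum free energy (kcal/mol, <= 0).
#' @param length precursor length in nt (> 0).
#' @return `mfe / length`.
#' @examples
#' normalized_mfe(-100, 250)
#' @export
normalized_mfe <- function(mfe, length) {
  if (any(length <= 0)) abort("precursor length must be positive")
  mfe / length
}

#' Shuffle a nucleotide sequence preserving composition
#'
#' * `mode = "mono"`: Fisher-Yates permutation; preserves the mononucleotide
#'   histogram exactly.
#' * `mode = "di"`: Euler-path (Altschul-Erickson style) shuffle; preserves the
#'   full 16-entry dinucleotide count table exactly, with the first and last
#'   nucleotides fixed.
#'
#' Uses the current RNG state; seed with [withr::with_seed()] or `set.seed()`
#' for reproducibility.
#'
#' @param sequence a nucleotide string (length >= 2).
#' @param mode `"mono"` or `"di"`.
#' @return the shuffled sequence string.
#' @export
shuffle_sequence <- function(sequence, mode = c("mono", "di")) {
  mode <- match.arg(mode)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2) abort("sequence too short to shuffle")
  if (mode == "mono") {
    return(paste(chars[sample.int(n)], collapse = ""))
  }
  if (n < 4) return(sequence)
  vertices <- unique(chars)
  last_v <- chars[n]
  edges <- split(chars[-1], factor(chars[-n], levels = vertices))
  # pick per-vertex final edges forming an arborescence into the last vertex
  for (attempt in 1:1000) {
    final_edge <- vapply(vertices, function(v) {
      if (v == last_v || !length(edges[[v]])) return(NA_character_)
      sample(edges[[v]], 1)
    }, character(1))
    ok <- TRUE
    for (v in vertices) {
      if (v == last_v || !length(edges[[v]])) next
      cur <- v
      for (step in seq_along(vertices)) {
        cur <- final_edge[[cur]]
        if (is.na(cur) || cur == last_v) break
      }
      if (is.na(cur) || cur != last_v) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) return(sequence) # pathological composition; keep the original
  ordered <- lapply(setNames(vertices, vertices), function(v) {
    e <- edges[[v]]
    if (!length(e)) return(character(0))
    if (v == last_v) return(e[sample.int(length(e))])
    fi <- match(final_edge[[v]], e)
    rest <- e[-fi]
    c(if (length(rest)) rest[sample.int(length(rest))], e[fi])
  })
  ptr <- setNames(rep(1L, length(vertices)), vertices)
  out <- character(n)
  out[1] <- chars[1]
  cur <- chars[1]
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Shuffling-stability p-value of a secondary structure
#'
#' The candidate is folded, `n_shuffles` shuffled versions are folded, and `R`
#' counts shuffles whose MFE is at least as stable (ties count toward `R`,
#' which is conservative). The p-value is `max(R, 1) / (N + 1)`, so the
#' smallest attainable value with N = 999 shuffles is 0.001; a candidate with
#' `p <= threshold` (default 0.05) is called stable (`rel = 1`).
#'
#' @param sequence precursor sequence.
#' @param n_shuffles number of shuffles `N` (999 for real precursors, 499 for
#'   background sets in the shipped parameterization).
#' @param mode shuffling mode, see [shuffle_sequence()].
#' @param seed integer seed making the shuffle ensemble reproducible.
#' @param backend folding backend, see [fold()].
#' @param threshold stability p-value threshold.
#' @return a list with `p_value`, `rel` (0/1), `R`, `n_shuffles`, `mfe`.
#' @export
stability_pvalue <- function(sequence, n_shuffles = 999L, mode = "mono",
                             seed = NULL, backend = "reference",
                             threshold = 0.05) {
  stopifnot(n_shuffles >= 1)
  sequence <- normalize_seq(sequence)
  orig <- fold(sequence, backend = backend, compute_structure = FALSE)$mfe
  gen <- function() {
    vapply(seq_len(n_shuffles), function(i) shuffle_sequence(sequence, mode),
           character(1))
  }
  shuffled <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  mfes <- if (backend == "reference") {
    fold_mfe_batch(shuffled)
  } else {
    map_dbl(shuffled, function(s) fold(s, backend = backend)$mfe)
  }
  R <- sum(mfes <= orig + 1e-9)
  p <- shuffle_pvalue(R, n_shuffles)
  list(p_value = p, rel = as.integer(p <= threshold), R = R,
       n_shuffles = n_shuffles, mfe = orig)
}

#' @rdname stability_pvalue
#' @param R number of shuffles at least as stable as the original.
#' @param N number of shuffle iterations.
#' @export
shuffle_pvalue <- function(R, N) {
  max(R, 1) / (N + 1)
}

#' Is the mature nucleus conserved against a library of known matures?
#'
#' The nucleus is the positional core of the mature (positions 2-12 for
#' plants). Conservation is an exact, alphabet-normalized match of the nucleus
#' subsequence against the same positions of at least one library member.
#'
#' @param mature_sequence candidate mature sequence.
#' @param known_matures character vector (or tibble with a `sequence` column)
#'   of known mature miRNAs.
#' @param positions 1-based inclusive `c(start, end)` nucleus range.
#' @return 1 or 0. A mature shorter than the nucleus range returns 0 with a
#'   notice.
#' @export
nucleus_conserved <- function(mature_sequence, known_matures,
                              positions = c(2L, 12L)) {
  if (is.data.frame(known_matures)) known_matures <- known_matures$sequence
  if (!length(known_matures)) abort("empty known-mature library")
  mature_sequence <- normalize_seq(mature_sequence)
  known_matures <- normalize_seq(known_matures)
  if (nchar(mature_sequence) < positions[2]) {
    inform(sprintf("mature (%d nt) shorter than nucleus range %d-%d; nuc = 0",
                   nchar(mature_sequence), positions[1], positions[2]))
    return(0L)
  }
  nucleus <- substr(mature_sequence, positions[1], positions[2])
  lib <- substr(known_matures[nchar(known_matures) >= positions[2]],
                positions[1], positions[2])
  as.integer(nucleus %in% lib)
}

#' Is at least one read mapped to the star arm?
#'
#' @param duplex duplex tibble from [extract_duplex()].
#' @param reads tibble of reads in precursor coordinates (`start`, `end`,
#'   0-based half-open).
#' @param slack positional slack (nt) allowed on each side of the star
#'   interval.
#' @return 1 or 0.
#' @export
star_present <- function(duplex, reads, slack = 2L) {
  if (is.null(duplex) || !nrow(reads)) return(0L)
  hit <- reads$start >= duplex$star_start - slack &
    reads$end <= duplex$star_end + slack
  as.integer(any(hit))
}

#' Read-signature log-odds of Dicer-consistent processing
#'
#' Each aligned read (weighted by its collapsed count) is classified as
#' consistent when its 5' end falls within `tolerance` nt of the mature or
#' star 5' end, or the read lies inside the terminal loop; all other reads are
#' inconsistent. Under the real-precursor model the number of inconsistent
#' read units `k` follows a geometric law with parameter
#' `signature_geometric_p` (`L_real = p (1-p)^k`); under the background model
#' read starts are uniform over the precursor, so each read unit is consistent
#' with probability `q` = (consistent positions) / (precursor length)
#' (`L_bgr = q^(n-k) (1-q)^k`). The returned component is
#' `log L_real - log L_bgr`.
#'
#' @param precursor_length precursor length (nt).
#' @param duplex duplex tibble from [extract_duplex()].
#' @param mature_start,mature_end mature offsets (0-based half-open).
#' @param reads tibble of reads in precursor coordinates with `start`, `end`,
#'   `count`.
#' @param params a `plantpin_params` list.
#' @return list with `loglik_real`, `loglik_bgr`, `logodds`, `n_units`,
#'   `n_inconsistent`.
#' @export
signature_logodds <- function(precursor_length, duplex, mature_start,
                              mature_end, reads,
                              params = default_parameter_set()) {
  params <- as_parameter_set(params)
  if (!nrow(reads)) abort("signature requires at least one read on the precursor")
  tol <- params$signature_tolerance
  loop <- if (mature_end <= duplex$star_start) {
    c(mature_end, duplex$star_start)
  } else {
    c(duplex$star_end, mature_start)
  }
  loop_len <- max(0L, loop[2] - loop[1])
  consistent <- abs(reads$start - mature_start) <= tol |
    abs(reads$start - duplex$star_start) <= tol |
    (reads$start >= loop[1] & reads$end <= loop[2])
  n <- sum(reads$count)
  k <- sum(reads$count[!consistent])
  p <- params$signature_geometric_p
  q <- ((2 * tol + 1) * 2 + loop_len) / precursor_length
  q <- min(max(q, 1 / precursor_length), 1 - 1 / precursor_length)
  loglik_real <- log(p) + k * log1p(-p)
  loglik_bgr <- (n - k) * log(q) + k * log1p(-q)
  list(loglik_real = loglik_real, loglik_bgr = loglik_bgr,
       logodds = loglik_real - loglik_bgr, n_units = n, n_inconsistent = k)
}

# map genome-space alignments onto a precursor's strand-oriented coordinates
reads_on_precursor <- function(precursor, alignments) {
  hits <- alignments |>
    filter(.data$ref_id == precursor$ref_id,
           .data$strand == precursor$strand,
           .data$start >= precursor$start,
           .data$end <= precursor$end)
  if (!nrow(hits)) {
    return(tibble(read_id = character(), start = integer(), end = integer(),
                  count = integer()))
  }
  if (precursor$strand == "+") {
    tibble(read_id = hits$read_id, start = hits$start - precursor$start,
           end = hits$end - precursor$start, count = hits$count)
  } else {
    tibble(read_id = hits$read_id, start = precursor$end - hits$end,
           end = precursor$end - hits$start, count = hits$count)
  }
}

#' Compute the five-feature vector for each candidate precursor
#'
#' For every precursor row the duplex is extracted and checked against the
#' plant constraints; candidates with a passing duplex get the full feature
#' vector (`abs` MFE, `rel` shuffling stability, `nuc` nucleus conservation,
#' `sig` read signature, `star` star-read presence). Candidates without a
#' passing duplex are returned with `duplex_ok = FALSE` and `NA` features: the
#' expensive shuffling test is not spent on them.
#'
#' @param precursors precursor tibble from [excise_candidates()].
#' @param alignments filtered alignment tibble (genome coordinates).
#' @param known_matures known mature library (character vector or tibble from
#'   [read_fasta()]); may be empty, in which case `nuc` is 0.
#' @param params a `plantpin_params` list.
#' @param seed integer seed; shuffle ensembles use `seed + row index`.
#' @param backend folding backend.
#' @return the precursor tibble extended with duplex statistics and columns
#'   `duplex_ok, abs_mfe, norm_mfe, rel, rel_pvalue, nuc, star,
#'   sig_loglik_real, sig_loglik_bgr, sig_logodds`.
#' @export
compute_features <- function(precursors, alignments,
                             known_matures = character(),
                             params = default_parameter_set(), seed = 1L,
                             backend = "reference") {
  params <- as_parameter_set(params)
  if (is.data.frame(known_matures)) known_matures <- known_matures$sequence
  if (!nrow(precursors)) {
    return(mutate(precursors, duplex_ok = logical(),
                  star_start = integer(), star_end = integer(),
                  n_paired = integer(), n_unpaired_total = integer(),
                  max_consecutive_unpaired = integer(), bulge_total = integer(),
                  abs_mfe = double(), norm_mfe = double(), rel = integer(),
                  rel_pvalue = double(), nuc = integer(), star = integer(),
                  sig_loglik_real = double(), sig_loglik_bgr = double(),
                  sig_logodds = double()))
  }
  rows <- map(seq_len(nrow(precursors)), function(i) {
    pr <- precursors[i, ]
    dup <- extract_duplex(pr$structure, pr$mature_start, pr$mature_end,
                          overhang = params$star_overhang)
    ok <- duplex_passes(dup, params)
    if (params$bifurcation_filter && ok &&
        has_bifurcation(pr$structure)) {
      ok <- FALSE
    }
    base <- tibble(
      id = pr$id,
      duplex_ok = ok,
      star_start = dup$star_start %||% NA_integer_,
      star_end = dup$star_end %||% NA_integer_,
      n_paired = dup$n_paired %||% NA_integer_,
      n_unpaired_total = dup$n_unpaired_total %||% NA_integer_,
      max_consecutive_unpaired = dup$max_consecutive_unpaired %||% NA_integer_,
      bulge_total = dup$bulge_total %||% NA_integer_,
      abs_mfe = abs(pr$mfe),
      norm_mfe = normalized_mfe(pr$mfe, nchar(pr$sequence)))
    if (!ok) {
      return(mutate(base, rel = NA_integer_, rel_pvalue = NA_real_,
                    nuc = NA_integer_, star = NA_integer_,
                    sig_loglik_real = NA_real_, sig_loglik_bgr = NA_real_,
                    sig_logodds = NA_real_))
    }
    reads <- reads_on_precursor(pr, alignments)
    stab <- stability_pvalue(pr$sequence, n_shuffles = params$stability_shuffles,
                             mode = params$shuffle_mode, seed = seed + i,
                             backend = backend,
                             threshold = params$stability_pvalue_threshold)
    mature_seq <- substr(pr$sequence, pr$mature_start + 1L, pr$mature_end)
    nuc <- if (length(known_matures)) {
      nucleus_conserved(mature_seq, known_matures, params$nucleus_positions)
    } else 0L
    star <- star_present(dup, reads, slack = params$star_slack)
    sig <- if (nrow(reads)) {
      signature_logodds(nchar(pr$sequence), dup, pr$mature_start,
                        pr$mature_end, reads, params)
    } else {
      list(loglik_real = NA_real_, loglik_bgr = NA_real_, logodds = NA_real_)
    }
    mutate(base, rel = stab$rel, rel_pvalue = stab$p_value, nuc = nuc,
           star = star, sig_loglik_real = sig$loglik_real,
           sig_loglik_bgr = sig$loglik_bgr, sig_logodds = sig$logodds)
  })
  left_join(precursors, bind_rows(rows), by = "id")
}
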