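# Independent oracles used by the property tests. These re-derive expected
# values from first principles (enumeration, direct counting) and must stay
# independent of the package implementation paths they check.

`%||%` <- rlang::`%||%`

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# --- brute-force folding oracle ----------------------------------------------

oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("GC", "CG", "AT", "TA", "GT", "TG")
}

oracle_pair_energy <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% c("GC", "CG")) -30L else if (p %in% c("AT", "TA")) -20L else -10L
}

# enumerate every nested structure (min hairpin loop 3) of a short sequence
oracle_enumerate <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return("")
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- paste0(".", rec(i + 1L, j))
    ks <- if (j >= i + 4L) (i + 4L):j else integer(0)
    for (k in ks) {
      if (!oracle_can_pair(chars[i], chars[k])) next
      inner <- rec(i + 1L, k - 1L)
      rest <- rec(k + 1L, j)
      out <- c(out, as.vector(outer(paste0("(", inner, ")"), rest, paste0)))
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

# independent dot-bracket parser (simple stack walk)
oracle_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pairs <- list()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    if (chars[i] == ")") {
      pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], i)
      stack <- stack[-length(stack)]
    }
  }
  pairs
}

# total energy (tenths of kcal/mol) of a structure under the reference model
oracle_energy <- function(seq, db) {
  chars <- strsplit(seq, "")[[1]]
  pairs <- oracle_pairs(db)
  if (!length(pairs)) return(0L)
  e <- 0L
  pmat <- do.call(rbind, pairs)
  pset <- paste(pmat[, 1], pmat[, 2])
  for (p in pairs) {
    i <- p[1]; j <- p[2]
    e <- e + oracle_pair_energy(chars[i], chars[j])
    if (paste(i + 1L, j - 1L) %in% pset) {
      gc <- paste0(chars[i], chars[j]) %in% c("GC", "CG") ||
        paste0(chars[i + 1L], chars[j - 1L]) %in% c("GC", "CG")
      e <- e + if (gc) -10L else -5L
    }
    enclosed <- pmat[, 1] > i & pmat[, 2] < j
    if (!any(enclosed)) e <- e + 30L + (j - i - 1L - 3L) # hairpin closing pair
  }
  e
}

# full enumeration fold: minimal energy, ties broken by smallest dot-bracket
oracle_fold <- function(seq) {
  structs <- oracle_enumerate(seq)
  energies <- vapply(structs, function(db) oracle_energy(seq, db), integer(1))
  best <- min(energies)
  cand <- sort(structs[energies == best])
  list(structure = cand[1], mfe = best / 10)
}

# --- other oracles ------------------------------------------------------------

dinucleotide_table <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  di <- paste0(chars[-length(chars)], chars[-1])
  lv <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  table(factor(di, levels = lv))
}

brute_ks_statistic <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- vapply(grid, function(g) mean(x <= g), double(1))
  fy <- vapply(grid, function(g) mean(y <= g), double(1))
  max(abs(fx - fy))
}

# perfect hairpin structure string: k pairs around a loop of l dots
perfect_hairpin_db <- function(k, l) {
  paste0(strrep("(", k), strrep(".", l), strrep(")", k))
}

# a sequence that folds into a clean stem-loop: GC-rich arm + loop + revcomp
perfect_stem_seq <- function(stem, loop_len = 6, seed = 1) {
  withr::with_seed(seed, {
    arm <- paste(sample(c("G", "C", "A", "T"), stem, TRUE,
                        prob = c(0.35, 0.35, 0.15, 0.15)), collapse = "")
    loop <- paste(sample(c("A", "T"), loop_len, TRUE), collapse = "")
    paste0(arm, loop, chartr("ACGT", "TGCA",
                             paste(rev(strsplit(arm, "")[[1]]), collapse = "")))
  })
}
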