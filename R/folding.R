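#' Fold an RNA sequence into its minimum free energy secondary structure
#'
#' Two backends share one contract: deterministic for a fixed backend and
#' sequence, returning a dot-bracket structure of the same length as the
#' input and an MFE in kcal/mol (<= 0 by convention).
#'
#' * `"reference"`: the built-in nearest-neighbor-lite folder (compiled code).
#'   It maximizes a fixed stacking-aware pairing score (G:C stacks weighted
#'   above A:U and G:U, hairpin-loop length penalty, minimum loop 3 nt, G:U
#'   allowed) over all nested structures and breaks ties by the
#'   lexicographically smallest dot-bracket string. Its energy scale orders
#'   structures consistently but is not a reproduction of the Turner model.
#' * `"vienna"`: shells out to a Vienna-compatible `RNAfold` executable
#'   (sequence in, `"structure ( energy)"` line out). A missing executable is
#'   an explicit error, never a silent fallback to the reference backend.
#'
#' @param sequence a single nucleotide string (length >= 10) over
#'   `{A,C,G,T,U,N}`; `T` and `U` are interchangeable.
#' @param backend `"reference"` or `"vienna"`.
#' @param compute_structure when `FALSE` the reference backend skips the
#'   structure traceback and returns only the MFE (used by the shuffling
#'   stability test where thousands of folds are needed).
#' @return a list with elements `sequence`, `structure`, `mfe`.
#' @examples
#' fold("GGGGGAAAACCCCC")
#' @export
fold <- function(sequence, backend = c("reference", "vienna"),
                 compute_structure = TRUE) {
  backend <- match.arg(backend)
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- normalize_seq(sequence)
  check_nucleotides(sequence)
  if (nchar(sequence) < 10) {
    abort(sprintf("sequence too short to fold (%d nt < 10)", nchar(sequence)))
  }
  if (backend == "reference") {
    res <- fold_reference_cpp(sequence, structure = compute_structure)
    list(sequence = sequence, structure = res$structure, mfe = res$mfe)
  } else {
    fold_vienna(sequence)
  }
}

# batch MFE-only folding with the reference backend (no traceback)
fold_mfe_batch <- function(sequences) {
  fold_reference_mfe_many_cpp(normalize_seq(sequences))
}

fold_vienna <- function(sequence) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    abort("external folding backend requested but no 'RNAfold' executable is on the PATH")
  }
  rna <- chartr("T", "U", sequence)
  out <- suppressWarnings(system2(exe, args = "--noPS", input = rna, stdout = TRUE))
  if (length(out) < 2) abort("RNAfold produced no structure line")
  line <- out[length(out)]
  m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", line))[[1]]
  if (!length(m)) abort(sprintf("unparsable RNAfold output: %s", line))
  list(sequence = sequence, structure = m[2], mfe = as.numeric(m[3]))
}

#' Pairing partner table of a dot-bracket structure
#'
#' @param structure a balanced dot-bracket string.
#' @return an integer vector of the same length: `pt[i]` is the 1-based
#'   partner of position `i`, or `NA` for unpaired positions. The table is
#'   symmetric: `pt[pt[i]] == i`.
#' @examples
#' pair_table("(((...)))")
#' @export
pair_table <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  bad <- !chars %in% c("(", ")", ".")
  if (any(bad)) abort(sprintf("invalid dot-bracket character '%s'", chars[which(bad)[1]]))
  pt <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) abort("unbalanced dot-bracket: unmatched ')'")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) abort("unbalanced dot-bracket: unmatched '('")
  pt
}

#' Does a structure contain a bifurcation (multiple outermost helices)?
#'
#' Flanking unpaired positions are ignored; the test is whether more than one
#' helix sits at the top nesting level within the region.
#'
#' @param structure a balanced dot-bracket string.
#' @param region optional 1-based inclusive `c(start, end)` restricting the
#'   test to a substructure.
#' @return `TRUE` if the region contains more than one top-level helix.
#' @examples
#' has_bifurcation("((...))((...))") # TRUE
#' has_bifurcation("..(((...)))...") # FALSE
#' @export
has_bifurcation <- function(structure, region = NULL) {
  pt <- pair_table(structure)
  idx <- if (is.null(region)) seq_along(pt) else seq(region[1], region[2])
  helices <- 0L
  i <- idx[1]
  while (i <= idx[length(idx)]) {
    if (!is.na(pt[i]) && pt[i] > i) {
      helices <- helices + 1L
      i <- pt[i] + 1L
    } else {
      i <- i + 1L
    }
  }
  helices > 1L
}
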