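#' Read sequences from a FASTA file
#'
#' Sequences are uppercased and RNA `U` is mapped to the internal DNA alphabet
#' (`T`); the folding backends convert back to RNA space on their boundary.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id` (the first whitespace-delimited token of
#'   each header) and `sequence`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(sprintf("malformed FASTA '%s': %s",
                                                    path, conditionMessage(e))))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- normalize_seq(as.character(set))
  empty <- !nzchar(seqs) | !nzchar(ids)
  if (any(empty)) {
    abort(sprintf("empty header or sequence for FASTA record %d in %s",
                  which(empty)[1], path))
  }
  check_nucleotides(seqs, sprintf("FASTA record in %s", path))
  tibble(id = ids, sequence = unname(seqs))
}

#' Write a tibble of sequences to FASTA
#'
#' @param sequences a tibble with `id` and `sequence` columns.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(setNames(sequences$sequence, sequences$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read Vienna-style dot-bracket records
#'
#' Records are header / sequence / structure triples, the structure line
#' optionally carrying a trailing parenthesized free energy, e.g.
#' `"(((...))) ( -1.20)"`. Records without an energy suffix are returned with
#' `mfe = NA`.
#'
#' @param path path to a dot-bracket file.
#' @return a tibble with columns `id`, `sequence`, `structure`, `mfe`.
#' @export
read_dotbracket <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr)) abort(sprintf("no dot-bracket records in %s", path))
  recs <- map(seq_along(hdr), function(i) {
    from <- hdr[i]
    to <- if (i < length(hdr)) hdr[i + 1] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) < 3) {
      abort(sprintf("dot-bracket record '%s' is missing sequence or structure",
                    sub("^>", "", block[1])))
    }
    id <- sub("\\s.*$", "", sub("^>", "", block[1]))
    seq <- normalize_seq(block[2])
    struct_line <- block[3]
    m <- regmatches(struct_line, regexec("^([.()]+)(\\s*\\(\\s*(-?[0-9.]+)\\s*\\))?\\s*$",
                                         struct_line))[[1]]
    if (!length(m)) {
      abort(sprintf("unparsable structure line in record '%s': %s", id, struct_line))
    }
    structure_str <- m[2]
    mfe <- if (nzchar(m[4])) as.numeric(m[4]) else NA_real_
    if (nchar(structure_str) != nchar(seq)) {
      abort(sprintf("structure length != sequence length in record '%s'", id))
    }
    pair_table(structure_str) # errors on unbalanced brackets
    tibble(id = id, sequence = seq, structure = structure_str, mfe = mfe)
  })
  bind_rows(recs)
}

#' @rdname read_dotbracket
#' @param records a tibble with `id`, `sequence`, `structure` and optionally
#'   `mfe` columns.
#' @export
write_dotbracket <- function(records, path) {
  lines <- unlist(pmap(list(records$id, records$sequence, records$structure,
                            records$mfe %||% rep(NA_real_, nrow(records))),
                       function(id, seq, st, mfe) {
    energy <- if (is.na(mfe)) "" else sprintf(" (%.2f)", mfe)
    c(paste0(">", id), seq, paste0(st, energy))
  }))
  readr::write_lines(lines, path)
  invisible(path)
}
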