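#' End-to-end discovery: filter, cluster, excise, featurize, score, rank
#'
#' The full pipeline on in-memory inputs: reads are filtered by mismatch,
#' multi-hit and annotation-overlap rules, clustered into potential precursor
#' loci, candidate windows are excised and folded, duplexes extracted and
#' checked against the plant constraints, the five features computed and
#' combined into the Bayesian log-odds score. Deterministic given `seed`, and
#' exit-clean on empty inputs (an empty report is a valid result).
#'
#' @param genome genome tibble ([read_fasta()]).
#' @param alignments alignment tibble ([read_alignments()]).
#' @param annotations optional exclusion annotations ([read_annotations()]).
#' @param known_matures known mature library (tibble or character vector).
#' @param params a `plantpin_params` list (monocot defaults when omitted).
#' @param seed integer seed driving every stochastic step (shuffling).
#' @param threshold report-flag score threshold.
#' @param backend folding backend, see [fold()].
#' @param max_gap read-clustering gap (nt).
#' @return a ranked candidate tibble (see [rank_candidates()]).
#' @examples
#' \donttest{
#' ds <- make_dataset(synthetic_spec(seed = 7, n_hairpins = 2, n_decoys = 0,
#'                                   genome_length = 8000,
#'                                   read_noise_fraction = 0))
#' res <- discover_mirnas(ds$genome, ds$alignments, ds$annotations,
#'                        ds$matures, seed = 7)
#' res[, c("id", "total_score", "passes_threshold")]
#' }
#' @export
discover_mirnas <- function(genome, alignments, annotations = NULL,
                            known_matures = character(),
                            params = default_parameter_set(), seed = 1L,
                            threshold = 0, backend = "reference",
                            max_gap = 30L) {
  params <- as_parameter_set(params)
  filtered <- filter_reads(alignments, annotations, params)
  inform(sprintf("%d / %d alignments kept after mismatch/multi-hit/annotation filters",
                 nrow(filtered), nrow(alignments)))
  clusters <- cluster_reads(filtered, max_gap = max_gap)
  inform(sprintf("%d read cluster(s)", nrow(clusters)))
  precursors <- excise_candidates(genome, clusters, params, backend = backend)
  inform(sprintf("%d candidate window(s) excised", nrow(precursors)))
  features <- compute_features(precursors, filtered, known_matures, params,
                               seed = seed, backend = backend)
  scored <- score_candidates(features, params)
  rank_candidates(scored, threshold = threshold)
}

#' Write a candidate report as TSV with a provenance header
#'
#' The header records the package version, the parameter digest and the seed,
#' so a report can always be tied back to its run conditions.
#'
#' @param report candidate tibble from [discover_mirnas()] or
#'   [rank_candidates()].
#' @param path output TSV path.
#' @param params the parameter set used.
#' @param seed the seed used.
#' @export
write_report <- function(report, path, params = default_parameter_set(),
                         seed = NA_integer_) {
  params <- as_parameter_set(params)
  hdr <- c(
    sprintf("# plantpin %s", as.character(utils::packageVersion("plantpin"))),
    sprintf("# params_digest=%s clade=%s seed=%s", params_digest(params),
            params$clade, seed))
  readr::write_lines(hdr, path)
  readr::write_tsv(report, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' File-based end-to-end run
#'
#' Thin wrapper over [discover_mirnas()] reading every input from disk and
#' writing a provenance-stamped TSV report. Used by the `plantpin` command
#' line script.
#'
#' @param genome_path FASTA genome.
#' @param alignments_path alignment file.
#' @param dialect alignment dialect (`"sam"` or `"tab"`).
#' @param annotations_path optional BED/GFF3 exclusion annotations.
#' @param matures_path optional FASTA of known matures.
#' @param params_path optional parameter JSON (monocot defaults otherwise).
#' @param out_path output TSV.
#' @param seed integer seed.
#' @param threshold score threshold flag.
#' @param backend folding backend.
#' @return the report tibble, invisibly.
#' @export
run_all <- function(genome_path, alignments_path, dialect = "tab",
                    annotations_path = NULL, matures_path = NULL,
                    params_path = NULL, out_path = NULL, seed = 1L,
                    threshold = 0, backend = "reference") {
  genome <- read_fasta(genome_path)
  alignments <- read_alignments(alignments_path, dialect = dialect,
                                genome = genome)
  annotations <- if (!is.null(annotations_path)) read_annotations(annotations_path)
  matures <- if (!is.null(matures_path)) read_fasta(matures_path) else character()
  params <- if (!is.null(params_path)) read_parameter_set(params_path)
            else default_parameter_set()
  report <- discover_mirnas(genome, alignments, annotations, matures, params,
                            seed = seed, threshold = threshold,
                            backend = backend)
  if (!is.null(out_path)) write_report(report, out_path, params, seed)
  invisible(report)
}
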