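#' Default parameter sets for plant and animal miRNA hairpin scoring
#'
#' Returns the full set of trained constants and filter thresholds used by the
#' scorer and the excision/duplex filters. Three presets ship with the package:
#'
#' * `"monocot"` (the default): modified-sigmoid MFE log-odds with
#'   a = 1.339e-12, b = 2.778e-13, c = 45.843; stability log-odds 1.37 / -3.624;
#'   nucleus conservation log-odds 7.63 / -1.17; excision length 300 nt;
#'   duplex constraints paired >= 15, unpaired <= 5, consecutive unpaired <= 3,
#'   bulge <= 2; at most 20 genomic hits per read.
#' * `"dicot"`: sigmoid a = 4.46e-4, b = 9.125e-5, c = 26.929; stability
#'   log-odds 0.63 / -3.17; other values as for monocots.
#' * `"animal_original"`: the original animal parameterization kept for
#'   comparison runs — Gumbel-minimum MFE curves (known: location 32,
#'   scale 5.5; background: location 23, scale 4.8), stability 1.6 / -2.2,
#'   nucleus 3 / -0.6 over positions 2-8, excision length 140 nt, paired >= 14,
#'   at most 5 genomic hits.
#'
#' The star-presence log-odds, the geometric signature parameter and the prior
#' log-ratio are inherited configuration, not clade-estimated values; they can
#' be overridden in the returned list or in a parameter JSON file.
#'
#' @param clade one of `"monocot"`, `"dicot"`, `"animal_original"`.
#' @return a named list of class `plantpin_params`.
#' @examples
#' p <- default_parameter_set("monocot")
#' p$logodds_stable
#' @export
default_parameter_set <- function(clade = c("monocot", "dicot", "animal_original")) {
  clade <- match.arg(clade)
  base <- list(
    clade = clade,
    mfe_mode = "sigmoid",
    sigmoid_a = 1.339e-12, sigmoid_b = 2.778e-13, sigmoid_c = 45.843,
    gumbel_location_real = NA_real_, gumbel_scale_real = NA_real_,
    gumbel_location_bgr = NA_real_, gumbel_scale_bgr = NA_real_,
    logodds_stable = 1.37, logodds_unstable = -3.624,
    logodds_nucleus_conserved = 7.63, logodds_nucleus_nonconserved = -1.17,
    logodds_star_present = 1.6, logodds_star_absent = -0.6,
    signature_geometric_p = 0.7,
    signature_tolerance = 2L,
    log_prior_ratio = 0,
    excision_length_max = 300L,
    min_paired = 15L,
    max_unpaired_total = 5L,
    max_unpaired_consecutive = 3L,
    max_bulge_total = 2L,
    max_multi_hits = 20L,
    max_mapping_mismatches = 1L,
    stability_pvalue_threshold = 0.05,
    stability_shuffles = 999L,
    shuffle_mode = "mono",
    nucleus_positions = c(2L, 12L),
    star_overhang = 2L,
    star_slack = 2L,
    bifurcation_filter = FALSE
  )
  if (clade == "dicot") {
    base$sigmoid_a <- 4.46e-4
    base$sigmoid_b <- 9.125e-5
    base$sigmoid_c <- 26.929
    base$logodds_stable <- 0.63
    base$logodds_unstable <- -3.17
  } else if (clade == "animal_original") {
    base$mfe_mode <- "gumbel"
    base$sigmoid_a <- NA_real_
    base$sigmoid_b <- NA_real_
    base$sigmoid_c <- NA_real_
    base$gumbel_location_real <- 32
    base$gumbel_scale_real <- 5.5
    base$gumbel_location_bgr <- 23
    base$gumbel_scale_bgr <- 4.8
    base$logodds_stable <- 1.6
    base$logodds_unstable <- -2.2
    base$logodds_nucleus_conserved <- 3
    base$logodds_nucleus_nonconserved <- -0.6
    base$excision_length_max <- 140L
    base$min_paired <- 14L
    base$max_unpaired_total <- 8L
    base$max_unpaired_consecutive <- 8L
    base$max_bulge_total <- 5L
    base$max_multi_hits <- 5L
    base$nucleus_positions <- c(2L, 8L)
  }
  structure(base, class = "plantpin_params")
}

validate_parameter_set <- function(params) {
  bad <- character(0)
  num_pos <- function(key) {
    v <- params[[key]]
    if (!is.null(v) && !is.na(v) && v <= 0) bad <<- c(bad, key)
  }
  if (identical(params$mfe_mode, "sigmoid")) num_pos("sigmoid_b")
  num_pos("gumbel_scale_real"); num_pos("gumbel_scale_bgr")
  gp <- params$signature_geometric_p
  if (gp <= 0 || gp >= 1) bad <- c(bad, "signature_geometric_p")
  st <- params$stability_pvalue_threshold
  if (st <= 0 || st >= 1) bad <- c(bad, "stability_pvalue_threshold")
  np <- params$nucleus_positions
  if (length(np) != 2 || np[1] < 1 || np[2] > 23 || np[1] > np[2]) {
    bad <- c(bad, "nucleus_positions")
  }
  for (key in c("excision_length_max", "max_multi_hits", "stability_shuffles")) {
    if (params[[key]] < 1) bad <- c(bad, key)
  }
  if (params$max_mapping_mismatches < 0) bad <- c(bad, "max_mapping_mismatches")
  if (length(bad)) {
    abort(sprintf("invalid parameter value(s): %s", paste(unique(bad), collapse = ", ")))
  }
  invisible(params)
}

#' Read and write parameter sets as JSON
#'
#' The JSON object may contain any subset of the documented keys; missing keys
#' are filled from the preset named by the `"clade"` key (monocot when absent).
#' `write_parameter_set()` followed by `read_parameter_set()` is an identity.
#'
#' @param path file path of the parameter JSON.
#' @param params a `plantpin_params` list.
#' @return `read_parameter_set()` returns a `plantpin_params` list.
#' @export
read_parameter_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_parameter_set(obj)
}

#' @rdname read_parameter_set
#' @export
write_parameter_set <- function(params, path) {
  stopifnot(inherits(params, "plantpin_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Coerce a plain list to a parameter set, filling defaults
#'
#' @param x a named list (possibly empty) of parameter overrides.
#' @return a validated `plantpin_params` list.
#' @export
as_parameter_set <- function(x = list()) {
  if (inherits(x, "plantpin_params")) return(validate_parameter_set(x))
  stopifnot(is.list(x))
  clade <- x$clade %||% "monocot"
  base <- default_parameter_set(clade)
  known <- names(base)
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    warn(sprintf("ignoring unknown parameter key(s): %s", paste(unknown, collapse = ", ")))
    x <- x[intersect(names(x), known)]
  }
  x <- x[!vapply(x, is.null, logical(1))] # JSON null -> preset default
  out <- modifyList(unclass(base), x)
  int_keys <- c("excision_length_max", "min_paired", "max_unpaired_total",
                "max_unpaired_consecutive", "max_bulge_total", "max_multi_hits",
                "max_mapping_mismatches", "stability_shuffles",
                "signature_tolerance", "star_overhang", "star_slack")
  for (k in int_keys) out[[k]] <- as.integer(out[[k]])
  chr_keys <- c("clade", "mfe_mode", "shuffle_mode")
  for (k in setdiff(names(out), c(int_keys, chr_keys, "nucleus_positions",
                                  "bifurcation_filter"))) {
    out[[k]] <- as.numeric(out[[k]])
  }
  out$bifurcation_filter <- as.logical(out$bifurcation_filter)
  out$nucleus_positions <- as.integer(out$nucleus_positions)
  out <- structure(out, class = "plantpin_params")
  validate_parameter_set(out)
}

#' @export
print.plantpin_params <- function(x, ...) {
  cat("<plantpin_params> clade:", x$clade, " MFE mode:", x$mfe_mode, "\n")
  cat(sprintf("  MFE log-odds: %s\n", if (x$mfe_mode == "sigmoid") {
    sprintf("sigmoid a=%.4g b=%.4g c=%.4g", x$sigmoid_a, x$sigmoid_b, x$sigmoid_c)
  } else {
    sprintf("Gumbel real(loc=%g, scale=%g) bgr(loc=%g, scale=%g)",
            x$gumbel_location_real, x$gumbel_scale_real,
            x$gumbel_location_bgr, x$gumbel_scale_bgr)
  }))
  cat(sprintf("  stability %g / %g  nucleus %g / %g (pos %d-%d)  star %g / %g\n",
              x$logodds_stable, x$logodds_unstable,
              x$logodds_nucleus_conserved, x$logodds_nucleus_nonconserved,
              x$nucleus_positions[1], x$nucleus_positions[2],
              x$logodds_star_present, x$logodds_star_absent))
  cat(sprintf("  excision <= %d nt; duplex paired >= %d, unpaired <= %d, consecutive <= %d, bulge <= %d\n",
              x$excision_length_max, x$min_paired, x$max_unpaired_total,
              x$max_unpaired_consecutive, x$max_bulge_total))
  cat(sprintf("  reads: mismatches <= %d, multi-hits <= %d; shuffles %d (%s), p <= %g\n",
              x$max_mapping_mismatches, x$max_multi_hits, x$stability_shuffles,
              x$shuffle_mode, x$stability_pvalue_threshold))
  invisible(x)
}

# short digest of a parameter set for provenance headers
params_digest <- function(params) {
  txt <- paste(names(params), vapply(params, function(v) paste(format(v), collapse = ","),
                                     character(1)), sep = "=", collapse = ";")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% .Machine$integer.max)
}
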