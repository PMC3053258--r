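#' Modified-sigmoid log-odds of the length-normalized MFE
#'
#' `f(x) = a / (b + exp(c * x))`, the parametric form fitted to the binned
#' empirical log-odds of normalized MFE between real and background plant
#' precursors. With `a, c > 0` it is strictly decreasing in `x` (more negative
#' normalized MFE, i.e. more stable folding, scores higher) and bounded above
#' by `a / b`. Overflow of the exponential is handled by returning the
#' asymptote 0.
#'
#' @param x normalized MFE (kcal/mol per nt, signed).
#' @param a,b,c fitted constants (`b > 0`).
#' @return the log-odds contribution (nats).
#' @examples
#' p <- default_parameter_set("monocot")
#' sigmoid_logodds(-0.6, p$sigmoid_a, p$sigmoid_b, p$sigmoid_c)
#' @export
sigmoid_logodds <- function(x, a, b, c) {
  if (b <= 0) abort("sigmoid parameter b must be positive")
  cx <- c * x
  ifelse(cx > 700, 0, a / (b + exp(pmin(cx, 700))))
}

#' Gumbel-minimum cumulative curve used by the original animal MFE model
#'
#' Returns `exp(-exp((x - location) / scale))`: the cumulative-from-above
#' convention of the original parameter table for the minimum extreme-value
#' family (1 as `x -> -Inf`, 0 as `x -> +Inf`). Evaluated at the absolute MFE
#' in the animal comparison mode.
#'
#' @param x absolute MFE (kcal/mol).
#' @param location,scale Gumbel parameters (`scale > 0`).
#' @return a value in `[0, 1]`, monotone decreasing in `x`.
#' @export
gumbel_cdf <- function(x, location, scale) {
  if (scale <= 0) abort("gumbel scale must be positive")
  exp(-exp((x - location) / scale))
}

#' Natural-log ratio of two feature frequencies
#'
#' The discrete log-odds building block of the scorer: the log of the
#' frequency of a binary feature among real precursors over the frequency
#' among background precursors. Frequencies must already be pseudo-counted
#' away from 0 (see [estimate_discrete_frequencies()]).
#'
#' @param p_real,p_bgr frequencies in `(0, 1]`.
#' @return `log(p_real / p_bgr)` (nats).
#' @examples
#' discrete_logodds(0.98, 0.25) # the plant stable-structure log-odds
#' @export
discrete_logodds <- function(p_real, p_bgr) {
  if (any(p_real <= 0) || any(p_bgr <= 0)) {
    abort("frequencies must be positive; apply a pseudo-count before taking log-odds")
  }
  if (any(p_real > 1) || any(p_bgr > 1)) abort("frequencies must be <= 1")
  log(p_real / p_bgr)
}

#' Score candidates with the five-feature Bayesian log-odds model
#'
#' Combines a feature tibble (from [compute_features()]) into per-candidate
#' log-odds components and their total:
#' `component_mfe` (modified sigmoid of the normalized MFE, or the Gumbel
#' tail log-odds in the animal comparison mode), `component_rel`,
#' `component_nuc`, `component_star` (discrete log-odds constants chosen by
#' the binary features), `component_sig` (signature likelihood ratio) and
#' `component_prior` (log prior ratio, 0 by default). The total is exactly
#' the sum of the six components. Candidates with `duplex_ok = FALSE` get
#' `NA` components.
#'
#' @param features feature tibble from [compute_features()].
#' @param params a `plantpin_params` list.
#' @return the input tibble extended with the component columns and
#'   `total_score`.
#' @export
score_candidates <- function(features, params = default_parameter_set()) {
  params <- as_parameter_set(params)
  mfe_component <- function(norm_mfe, abs_mfe) {
    if (params$mfe_mode == "sigmoid") {
      sigmoid_logodds(norm_mfe, params$sigmoid_a, params$sigmoid_b,
                      params$sigmoid_c)
    } else {
      # animal comparison mode: log-odds of the two Gumbel tail curves at |MFE|
      f_real <- gumbel_cdf(abs_mfe, params$gumbel_location_real,
                           params$gumbel_scale_real)
      f_bgr <- gumbel_cdf(abs_mfe, params$gumbel_location_bgr,
                          params$gumbel_scale_bgr)
      eps <- 1e-12
      log(pmax(1 - f_real, eps)) - log(pmax(1 - f_bgr, eps))
    }
  }
  features |>
    mutate(
      component_mfe = ifelse(.data$duplex_ok,
                             mfe_component(.data$norm_mfe, .data$abs_mfe),
                             NA_real_),
      component_rel = ifelse(.data$rel == 1L, params$logodds_stable,
                             params$logodds_unstable),
      component_nuc = ifelse(.data$nuc == 1L, params$logodds_nucleus_conserved,
                             params$logodds_nucleus_nonconserved),
      component_star = ifelse(.data$star == 1L, params$logodds_star_present,
                              params$logodds_star_absent),
      component_sig = dplyr::coalesce(.data$sig_logodds,
                                      ifelse(.data$duplex_ok, 0, NA_real_)),
      component_prior = ifelse(.data$duplex_ok, params$log_prior_ratio, NA_real_),
      total_score = .data$component_mfe + .data$component_rel +
        .data$component_nuc + .data$component_star + .data$component_sig +
        .data$component_prior)
}

#' Rank scored candidates and flag those below a score threshold
#'
#' Rows are sorted by descending total score with a deterministic
#' id-lexicographic tie-break; rows below the threshold (and rows without a
#' score) are flagged, never dropped.
#'
#' @param scored scored tibble from [score_candidates()].
#' @param threshold minimum total score for the `passes_threshold` flag.
#' @return the sorted tibble with a `passes_threshold` column.
#' @export
rank_candidates <- function(scored, threshold = 0) {
  scored |>
    mutate(passes_threshold = !is.na(.data$total_score) &
             .data$total_score >= threshold) |>
    arrange(desc(!is.na(.data$total_score)), desc(.data$total_score), .data$id)
}
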