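#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_hline labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot binned MFE log-odds, optionally with a fitted sigmoid
#'
#' @param object a `binned_logodds` tibble.
#' @param fit optional `sigmoid_fit` overlaid as a curve.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.binned_logodds <- function(object, fit = NULL, ...) {
  df <- as_tibble(object) |> filter(is.finite(.data$logodds))
  p <- ggplot(df, aes(x = .data$bin_center, y = .data$logodds)) +
    geom_point(size = 1) +
    labs(x = "normalized MFE (kcal/mol/nt)", y = "log-odds (nats)",
         title = "Empirical MFE log-odds by bin") +
    theme_minimal()
  if (!is.null(fit)) {
    grid <- tibble(bin_center = seq(min(df$bin_center), max(df$bin_center),
                                    length.out = 200))
    grid$fitted <- predict(fit, grid)
    p <- p + geom_line(data = grid, aes(y = .data$fitted), color = "firebrick")
  }
  p
}

#' Plot a positional conservation profile
#'
#' Bar height is the number of families conserved at each position; the
#' dashed line marks the across-family block threshold.
#'
#' @param object a `conservation_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.conservation_profile <- function(object, ...) {
  ggplot(object$profile, aes(x = .data$position, y = .data$n_conserved)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = object$across_threshold * object$n_families,
               linetype = "dashed") +
    labs(x = "mature position", y = "families conserved",
         title = "Positional nucleus conservation") +
    theme_minimal()
}

#' Plot per-candidate score components
#'
#' Stacked component contributions per candidate, ordered by total score.
#'
#' @param scored a scored candidate tibble ([score_candidates()]).
#' @param top show at most this many candidates.
#' @return a ggplot.
#' @export
plot_score_components <- function(scored, top = 20) {
  df <- scored |>
    filter(!is.na(.data$total_score)) |>
    arrange(desc(.data$total_score)) |>
    head(top) |>
    select("id", dplyr::starts_with("component_")) |>
    tidyr::pivot_longer(-"id", names_to = "component", values_to = "logodds") |>
    mutate(component = sub("component_", "", .data$component))
  ggplot(df, aes(x = stats::reorder(.data$id, .data$logodds, sum),
                 y = .data$logodds, fill = .data$component)) +
    geom_col() +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "log-odds contribution (nats)",
         title = "Score decomposition") +
    theme_minimal()
}
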