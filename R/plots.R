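# ggplot2 autoplot methods for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a diversity profile
#'
#' Effective species number against diversity order, one curve per predator
#' species.
#'
#' @param object A [diversity_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diversity_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$q, y = .data$D,
                               colour = .data$predator_species)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "diversity order q",
                  y = "effective species number",
                  colour = "predator") +
    ggplot2::theme_minimal()
}

#' Plot a diet table
#'
#' Percent index of relative importance per identified prey species.
#'
#' @param object A `diet_table` from [diet_iri()] or [diet_composition()].
#' @param metric Column to plot (default `"pct_iri"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diet_table <- function(object, metric = "pct_iri", ...) {
  sp <- tidy(object) |>
    dplyr::filter(!.data$is_coarse) |>
    dplyr::arrange(.data[[metric]])
  sp$prey_taxon <- factor(sp$prey_taxon, levels = sp$prey_taxon)
  ggplot2::ggplot(sp, ggplot2::aes(x = .data[[metric]],
                                   y = .data$prey_taxon)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = metric, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cut matrix
#'
#' Species-by-enzyme heat map of the fraction of vouchers cut
#' (conservative matching).
#'
#' @param object A [cut_matrix()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cut_matrix <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::mutate(frac_cut = .data$n_conservative / .data$n_total)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$enzyme, y = .data$species,
                                    fill = .data$frac_cut)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "fraction cut") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
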