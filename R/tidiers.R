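#' Tidy a synthetic matrix into one row per populated cell
#'
#' @param x A `synthetic_matrix`.
#' @param complete Include missing cells (see [as_tibble.synthetic_matrix()]).
#' @param ... Unused.
#' @return A tibble: `taxon`, `entity`, `value`, `n_asserted`, `n_inferred`.
#' @method tidy synthetic_matrix
#' @export
tidy.synthetic_matrix <- function(x, complete = FALSE, ...) {
  as_tibble(x, complete = complete)
}

#' One-row summary of a synthetic matrix
#'
#' @param x A `synthetic_matrix`.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, populated/asserted cell counts,
#'   missing fractions, and conflict-cell count.
#' @method glance synthetic_matrix
#' @export
glance.synthetic_matrix <- function(x, ...) {
  stats <- missing_data_stats(x)
  mutate(stats, n_both_cells = sum(x$cells$value == "BOTH"))
}

#' Plot a synthetic matrix as a taxon-by-entity value map
#'
#' A bird's-eye view of the supermatrix: tiles colored by cell value, missing
#' cells blank, with the asserted/inferred distinction available via
#' `fill = "mode"`.
#'
#' @param object A `synthetic_matrix`.
#' @param fill `"value"` (PRESENT/ABSENT/BOTH) or `"mode"` (asserted versus
#'   inferred-only cells).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot synthetic_matrix
#' @export
autoplot.synthetic_matrix <- function(object, fill = c("value", "mode"), ...) {
  fill <- arg_match(fill)
  df <- as_tibble(object)
  if (fill == "mode") {
    df$fill_var <- if_else(df$n_asserted > 0, "asserted", "inferred only")
    legend <- "support"
  } else {
    df$fill_var <- df$value
    legend <- "value"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$entity, y = .data$taxon,
                                   fill = .data$fill_var)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_discrete(limits = object$characters) +
    ggplot2::scale_y_discrete(limits = rev(object$taxa)) +
    ggplot2::labs(x = "synthetic character (anatomical entity)", y = "taxon",
                  fill = legend) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Heat map of entailing-state counts
#'
#' Visualizes the output of [entailing_state_counts()]: how much published
#' evidence bears on each entity in each taxon.
#'
#' @param counts Tibble from [entailing_state_counts()].
#' @return A ggplot object.
#' @export
plot_entailing_state_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$entity, y = .data$taxon,
                                       fill = .data$n_states)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "anatomical entity", y = "taxon",
                  fill = "entailing\nstates") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance
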