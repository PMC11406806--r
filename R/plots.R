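# ggplot2 layers over the report tibbles. Every plot is a thin view of a
# table the corresponding function already returns.

#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_tile geom_vline
#'   facet_wrap facet_grid labs scale_fill_gradient theme_minimal
NULL

#' Plot library composition as stacked bars
#' @param object A `composition_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.composition_report <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$library_id, y = .data$fraction, fill = .data$category)) +
    geom_col() +
    labs(x = NULL, y = "fraction of mapped reads", fill = "category") +
    theme_minimal()
}

#' Plot footprint size distributions
#' @param object A `size_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.size_distribution <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$length, y = .data$fraction, colour = .data$group)) +
    geom_line() +
    facet_wrap(~library_id) +
    labs(x = "footprint length (nt)", y = "fraction of group",
         colour = NULL) +
    theme_minimal()
}

#' Plot a metagene profile
#' @param object A `metagene_profile`.
#' @param ... Unused.
#' @return A ggplot with positions coloured by frame to expose the
#'   3-nt periodicity.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  d <- mutate(as_tibble(object),
              frame = factor(((.data$position %% 3) + 3) %% 3 + 1))
  ggplot(d, aes(x = .data$position, y = .data$density)) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    geom_col(aes(fill = .data$frame)) +
    labs(x = "position relative to landmark (nt, P-site)",
         y = "mean normalized density", fill = "frame") +
    theme_minimal()
}

#' Plot per-size normalized read density around start codons
#'
#' Heatmap of the per-size normalized delta histograms behind an offset
#' table, for 5'- and 3'-mapped ends side by side — the diagnostic view
#' offset calibration is read from.
#'
#' @param object An `offset_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.offset_table <- function(object, ...) {
  d <- attr(object, "density")
  ggplot(d, aes(x = .data$delta, y = factor(.data$length),
                fill = .data$density)) +
    geom_tile() +
    facet_grid(.data$compartment ~ .data$end) +
    scale_fill_gradient(low = "white", high = "firebrick") +
    labs(x = "distance to start codon (nt)", y = "read length (nt)",
         fill = "density") +
    theme_minimal()
}

#' Plot a CDS-count correlation heatmap
#' @param object A `correlation_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.correlation_table <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$library_a, y = .data$library_b, fill = .data$rho)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "Spearman rho") +
    theme_minimal()
}

#' Plot pre/post depletion composition
#' @param object A `depletion_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.depletion_report <- function(object, ...) {
  d <- tidy(object)
  d$stage <- factor(d$stage, levels = c("pre", "post"))
  ggplot(d, aes(x = .data$stage, y = .data$fraction, fill = .data$category)) +
    geom_col() +
    facet_wrap(~library_id) +
    labs(x = NULL, y = "fraction of mapped reads", fill = "category") +
    theme_minimal()
}
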