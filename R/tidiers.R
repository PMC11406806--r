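# broom-style tidiers for the package's result objects.

#' Tidy a composition report
#' @param x A `composition_report`.
#' @param species Return the per-rRNA-species breakdown instead of the
#'   per-category table.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.composition_report <- function(x, species = FALSE, ...) {
  if (species) attr(x, "species") else as_tibble(x)
}

#' One-row-per-library composition summary
#' @param x A `composition_report`.
#' @param ... Unused.
#' @return Tibble: `library_id`, `n_mapped`, `rrna_fraction`,
#'   `informative_fraction`.
#' @export
glance.composition_report <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$library_id) |>
    summarise(
      n_mapped = sum(.data$n),
      rrna_fraction = sum(.data$fraction[.data$category == "rRNA"]),
      informative_fraction = 1 - .data$rrna_fraction,
      .groups = "drop")
}

#' Tidy an offset table
#' @param x An `offset_table`.
#' @param ... Unused.
#' @return The offset rows as a plain tibble.
#' @export
tidy.offset_table <- function(x, ...) as_tibble(x)

#' Summarise an offset table
#' @param x An `offset_table`.
#' @param ... Unused.
#' @return Tibble: per compartment and end, number of sizes, number
#'   determined, and the offset convention.
#' @export
glance.offset_table <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$compartment, .data$end) |>
    summarise(n_sizes = n(),
              n_determined = sum(.data$status == "ok"),
              .groups = "drop") |>
    mutate(convention = attr(x, "convention"))
}

#' Tidy a depletion report
#' @param x A `depletion_report`.
#' @param ... Unused.
#' @return Long tibble of category fractions with a `stage` column
#'   (`pre`/`post`).
#' @export
tidy.depletion_report <- function(x, ...) {
  bind_rows(mutate(as_tibble(x$pre), stage = "pre"),
            mutate(as_tibble(x$post), stage = "post")) |>
    select("stage", dplyr::everything())
}

#' Summarise a depletion report
#' @param x A `depletion_report`.
#' @param ... Unused.
#' @return Tibble with pre/post rRNA fraction, informative fractions, the
#'   informative fold-improvement and reads captured.
#' @export
glance.depletion_report <- function(x, ...) {
  inner_join(
    glance(x$pre) |> select("library_id", rrna_pre = "rrna_fraction"),
    glance(x$post) |> select("library_id", rrna_post = "rrna_fraction"),
    by = "library_id") |>
    inner_join(x$fold_improvement, by = "library_id") |>
    mutate(n_captured = x$n_captured)
}

#' Tidy contaminant regions
#' @param x A `contaminant_regions`.
#' @param by_library Return per-library abundances.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.contaminant_regions <- function(x, by_library = FALSE, ...) {
  if (by_library) attr(x, "by_library") else as_tibble(x)
}

#' Tidy a preservation report
#' @param x A `preservation_report`.
#' @param ... Unused.
#' @return The pairwise Jaccard table.
#' @export
tidy.preservation_report <- function(x, ...) x$pairs

#' Summarise a preservation report
#' @param x A `preservation_report`.
#' @param ... Unused.
#' @return The one-row summary tibble.
#' @export
glance.preservation_report <- function(x, ...) x$summary

#' Tidy a size-split analysis
#' @param x A `size_split`.
#' @param ... Unused.
#' @return The per-gene small/large count table.
#' @export
tidy.size_split <- function(x, ...) x$counts

#' Summarise a size-split analysis
#' @param x A `size_split`.
#' @param ... Unused.
#' @return One-row tibble: correlation and the two enrichment ratios.
#' @export
glance.size_split <- function(x, ...) {
  wide <- tidyr::pivot_wider(select(x$enrichment, "class", "ratio"),
                             names_from = "class", values_from = "ratio",
                             names_prefix = "enrichment_")
  mutate(wide, correlation = x$correlation)
}
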