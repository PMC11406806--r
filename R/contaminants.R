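# Discovery and ranking of recurrent rRNA contaminant regions - an
# algorithmic stand-in for browsing coverage tracks by eye: positions with
# high relative coverage, reproduced in the majority of libraries, merged
# into regions and ranked by averaged abundance.

#' Per-position rRNA coverage
#'
#' `coverage[p]` is the number of reads whose span contains position `p`
#' (0-based), computed per library and per rRNA species.
#'
#' @param alignments Alignment tibble; only reads aligned to rRNA references
#'   are used (categorization is not required).
#' @param rrna rRNA reference tibble.
#' @return Long tibble: `library_id`, `species_id`, `pos` (0-based),
#'   `coverage`.
#' @export
rrna_coverage <- function(alignments, rrna) {
  aln <- ensure_library_id(alignments)
  aln <- aln[!is.na(aln$reference) & aln$reference %in% rrna$species_id, ]
  grid <- tidyr::expand_grid(library_id = unique(ensure_library_id(alignments)$library_id),
                             species_id = rrna$species_id)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    len <- rrna$length[rrna$species_id == grid$species_id[i]]
    sub <- aln[aln$library_id == grid$library_id[i] &
                 aln$reference == grid$species_id[i], ]
    cov <- if (nrow(sub) == 0) integer(len) else {
      as.integer(IRanges::coverage(IRanges::IRanges(sub$start + 1L, sub$end),
                                   width = len))
    }
    tibble(library_id = grid$library_id[i], species_id = grid$species_id[i],
           pos = seq_len(len) - 1L, coverage = cov)
  })
}

#' Call contaminant rRNA regions across libraries
#'
#' A position is "hot" in a library when its coverage reaches `hot_frac`
#' times that library's total rRNA-assigned read count (a relative threshold
#' so libraries of different depth are comparable). Positions hot in more
#' than a `majority` fraction of libraries are kept, merged across gaps of
#' at most `merge_gap` nt, and regions shorter than `min_len` nt are
#' dropped. Per-library region abundance is the fraction of that library's
#' mapped reads overlapping the region by at least half the read length.
#' Regions are ranked by mean abundance (descending) and labelled C1, C2, ...
#'
#' @param alignments Alignment tibble over one or more libraries
#'   (`library_id` column).
#' @param rrna rRNA reference tibble.
#' @param hot_frac Relative hot-position threshold (default 0.005).
#' @param majority Fraction of libraries a position must be hot in
#'   (strictly more than; default 0.5).
#' @param merge_gap Maximum gap bridged when merging hot runs (nt).
#' @param min_len Minimum region length (nt).
#' @param read_overlap Minimum fraction of a read overlapping the region for
#'   abundance attribution (default 0.5).
#' @return A `contaminant_regions` tibble: `region_id`, `species_id`,
#'   `start`, `end`, `length`, `mean_abundance`, `support`; per-library
#'   abundances in `attr(, "by_library")`.
#' @export
call_regions <- function(alignments, rrna, hot_frac = 0.005, majority = 0.5,
                         merge_gap = 5L, min_len = 15L, read_overlap = 0.5) {
  stopifnot(hot_frac > 0, merge_gap >= 0, min_len > 0)
  aln <- ensure_library_id(alignments)
  libs <- sort(unique(aln$library_id))
  cov <- rrna_coverage(aln, rrna)
  rrna_totals <- aln |>
    filter(.data$reference %in% rrna$species_id) |>
    count(.data$library_id, name = "total_rrna")
  cov <- left_join(cov, rrna_totals, by = "library_id") |>
    mutate(hot = .data$coverage >= hot_frac * .data$total_rrna)

  kept <- cov |>
    group_by(.data$species_id, .data$pos) |>
    summarise(frac_hot = sum(.data$hot) / length(libs), .groups = "drop") |>
    filter(.data$frac_hot > majority)

  if (nrow(kept) == 0) {
    warnf("no hot positions at hot_frac = %g; no regions called", hot_frac)
    out <- tibble(region_id = character(), species_id = character(),
                  start = integer(), end = integer(), length = integer(),
                  mean_abundance = numeric(), support = integer())
    out <- new_riboclean_tbl(out, "contaminant_regions")
    attr(out, "by_library") <- tibble(region_id = character(),
                                      library_id = character(),
                                      abundance = numeric())
    return(out)
  }

  regions <- kept |>
    group_by(.data$species_id) |>
    group_modify(function(d, key) {
      ir <- IRanges::reduce(IRanges::IRanges(d$pos + 1L, d$pos + 1L),
                            min.gapwidth = merge_gap + 1L)
      tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }) |>
    ungroup() |>
    mutate(length = .data$end - .data$start) |>
    filter(.data$length >= min_len)

  # per-library abundance: reads with >= read_overlap of their span inside
  lib_totals <- aln |>
    filter(!is.na(.data$reference)) |>
    count(.data$library_id, name = "total")
  rr <- aln[aln$reference %in% rrna$species_id, ]
  by_library <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    sub <- rr[rr$reference == regions$species_id[i], ]
    ov <- interval_overlap(sub$start, sub$end, regions$start[i], regions$end[i])
    hitting <- sub[ov >= read_overlap * (sub$end - sub$start), ]
    counts <- count(hitting, .data$library_id, name = "n_reads")
    tibble(library_id = libs, region_idx = i) |>
      left_join(counts, by = "library_id") |>
      mutate(n_reads = dplyr::coalesce(.data$n_reads, 0L))
  }) |>
    left_join(lib_totals, by = "library_id") |>
    mutate(abundance = .data$n_reads / .data$total)

  # support: libraries in which the region contains at least one hot position
  hot_cov <- filter(cov, .data$hot)
  support <- vapply(seq_len(nrow(regions)), function(i) {
    h <- hot_cov[hot_cov$species_id == regions$species_id[i] &
                   hot_cov$pos >= regions$start[i] &
                   hot_cov$pos < regions$end[i], ]
    length(unique(h$library_id))
  }, integer(1))

  regions$mean_abundance <- by_library |>
    group_by(.data$region_idx) |>
    summarise(m = mean(.data$abundance)) |>
    arrange(.data$region_idx) |>
    pull(.data$m)
  regions$support <- support
  ord <- order(-regions$mean_abundance, regions$species_id, regions$start)
  regions <- regions[ord, ]
  regions$region_id <- sprintf("C%d", seq_len(nrow(regions)))
  id_of_idx <- setNames(regions$region_id, as.character(ord))

  out <- select(regions, "region_id", "species_id", "start", "end",
                "length", "mean_abundance", "support")
  out <- new_riboclean_tbl(out, "contaminant_regions")
  attr(out, "by_library") <- by_library |>
    mutate(region_id = unname(id_of_idx[as.character(.data$region_idx)])) |>
    select("region_id", "library_id", "n_reads", "abundance") |>
    arrange(.data$region_id, .data$library_id)
  out
}

#' Take the top-k contaminant regions by abundance
#'
#' Ties are broken by species id then start coordinate so the selection is
#' deterministic. `k = 24` mirrors a version-1 depletion cocktail, `k = 29`
#' version 2.
#'
#' @param regions A `contaminant_regions` tibble.
#' @param k Number of regions to keep (all regions when `k` exceeds the
#'   number available).
#' @return The top-`k` subset, re-sorted.
#' @export
rank_and_take <- function(regions, k) {
  stopifnot(k >= 1)
  by_lib <- attr(regions, "by_library")
  out <- regions |>
    arrange(desc(.data$mean_abundance), .data$species_id, .data$start) |>
    head(k)
  out <- new_riboclean_tbl(as_tibble(out), "contaminant_regions")
  if (!is.null(by_lib)) {
    attr(out, "by_library") <- by_lib[by_lib$region_id %in% out$region_id, ]
  }
  out
}

#' Cross-condition / cross-species preservation of contaminant regions
#'
#' For every same-species pair of regions between two region sets, the
#' interval Jaccard index is computed; the summary is the fraction of the
#' top-`k` regions of each set that have a partner with Jaccard >= 0.5 in
#' the other. Comparing region sets from different species requires a
#' user-supplied coordinate map (`species_a`, `species_b`, `offset`): set-A
#' coordinates are shifted by `offset` onto set-B's reference.
#'
#' @param set_a,set_b `contaminant_regions` tibbles.
#' @param k Top-k cutoff for the summary (default: all regions).
#' @param coord_map Optional tibble with columns `species_a`, `species_b`,
#'   `offset` for cross-species comparison.
#' @return A `preservation_report` list: `$pairs` (all overlapping pairs
#'   with their Jaccard), `$summary`.
#' @export
preservation_report <- function(set_a, set_b, k = NULL, coord_map = NULL) {
  a <- as_tibble(set_a); b <- as_tibble(set_b)
  if (is.null(coord_map)) {
    if (length(intersect(a$species_id, b$species_id)) == 0) {
      stopf("region sets share no rRNA species; cross-species comparison needs a coordinate map")
    }
  } else {
    m <- match(a$species_id, coord_map$species_a)
    mapped <- !is.na(m)
    a$species_id[mapped] <- coord_map$species_b[m[mapped]]
    a$start[mapped] <- a$start[mapped] + coord_map$offset[m[mapped]]
    a$end[mapped] <- a$end[mapped] + coord_map$offset[m[mapped]]
  }
  pairs <- inner_join(
    select(a, region_a = "region_id", "species_id", start_a = "start", end_a = "end"),
    select(b, region_b = "region_id", "species_id", start_b = "start", end_b = "end"),
    by = "species_id", relationship = "many-to-many") |>
    mutate(jaccard = interval_jaccard(.data$start_a, .data$end_a,
                                      .data$start_b, .data$end_b)) |>
    filter(.data$jaccard > 0)

  k_a <- min(k %||% nrow(a), nrow(a))
  k_b <- min(k %||% nrow(b), nrow(b))
  top_a <- head(arrange(a, desc(.data$mean_abundance)), k_a)$region_id
  top_b <- head(arrange(b, desc(.data$mean_abundance)), k_b)$region_id
  preserved_a <- pairs |> filter(.data$region_a %in% top_a, .data$jaccard >= 0.5)
  preserved_b <- pairs |> filter(.data$region_b %in% top_b, .data$jaccard >= 0.5)
  summary <- tibble(
    k_a = k_a, k_b = k_b,
    fraction_a_preserved = length(unique(preserved_a$region_a)) / max(k_a, 1L),
    fraction_b_preserved = length(unique(preserved_b$region_b)) / max(k_b, 1L)
  )
  structure(list(pairs = pairs, summary = summary),
            class = "preservation_report")
}

#' @export
print.preservation_report <- function(x, ...) {
  cat("<preservation_report>\n")
  print(x$summary)
  invisible(x)
}

#' Write contaminant regions as BED6
#'
#' Scores are `round(1e4 * mean_abundance)`; names are region ids.
#'
#' @param regions A `contaminant_regions` tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_regions_bed <- function(regions, file) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t+",
                   regions$species_id, regions$start, regions$end,
                   regions$region_id, round(1e4 * regions$mean_abundance))
  writeLines(lines, file)
  invisible(file)
}
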