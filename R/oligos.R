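# Depletion-oligo cocktail design and in-silico subtractive hybridization.

#' Design a depletion-oligo cocktail from ranked contaminant regions
#'
#' One biotinylated DNA oligo per region: the reverse complement of the
#' region's sense sequence, mixed at molar ratios equal to the regions'
#' relative averaged abundances (so the most wasteful fragments get the most
#' capture capacity). Regions longer than `max_len` are trimmed
#' symmetrically to the cap and flagged.
#'
#' @param regions A `contaminant_regions` tibble (typically the output of
#'   [rank_and_take()]).
#' @param rrna rRNA reference tibble with sequences.
#' @param max_len Maximum oligo length in nt (default 60).
#' @return An `oligo_cocktail` tibble: `oligo_id`, `region_id`,
#'   `species_id`, `start`, `end`, `sequence`, `molar_ratio`, `trimmed`.
#' @export
design_cocktail <- function(regions, rrna, max_len = 60L) {
  if (nrow(regions) == 0) stopf("no regions to design oligos for")
  reg <- as_tibble(regions)
  too_long <- (reg$end - reg$start) > max_len
  if (any(too_long)) {
    excess <- (reg$end - reg$start) - max_len
    reg$start[too_long] <- reg$start[too_long] + excess[too_long] %/% 2L
    reg$end[too_long] <- reg$start[too_long] + max_len
    warnf("%d region(s) longer than %d nt trimmed symmetrically",
          sum(too_long), max_len)
  }
  seqs <- setNames(rrna$sequence, rrna$species_id)
  sense <- unname(substring(seqs[reg$species_id], reg$start + 1L, reg$end))
  tibble(
    oligo_id = sprintf("O%02d", seq_len(nrow(reg))),
    region_id = reg$region_id,
    species_id = reg$species_id,
    start = reg$start, end = reg$end,
    sequence = revcomp(as_dna(sense)),
    molar_ratio = reg$mean_abundance / sum(reg$mean_abundance),
    trimmed = too_long
  ) |>
    new_riboclean_tbl("oligo_cocktail")
}

#' Simulate subtractive hybridization against a cocktail
#'
#' A read is captured when it aligns to an oligo's target species and its
#' interval overlaps the oligo target by at least `min_overlap_frac` of the
#' read length (coordinate mode; synthetic reads derive from the reference,
#' so coordinate overlap is an exact proxy for rehybridization). With
#' `mode = "sequence"` (for real reads carrying a `sequence` column) a read
#' is captured when it shares a contiguous exact match of at least
#' `min_match` nt with any oligo target. Captured reads are removed with
#' probability `capture_eff` (1 = deterministic removal).
#'
#' @param alignments Categorized alignment tibble.
#' @param cocktail An `oligo_cocktail`.
#' @param min_overlap_frac Minimum read-overlap fraction for capture
#'   (default 0.8).
#' @param capture_eff Capture efficiency in `[0, 1]`.
#' @param mode `"coordinate"` (default) or `"sequence"`.
#' @param min_match Minimum contiguous match (nt) in sequence mode.
#' @param seed Seed for stochastic capture when `capture_eff < 1`.
#' @return A `depletion_report` list: `$survivors` (alignment tibble),
#'   `$pre`/`$post` composition reports, `$n_captured`,
#'   `$fold_improvement` (post informative fraction over pre, per library).
#' @export
deplete_in_silico <- function(alignments, cocktail, min_overlap_frac = 0.8,
                              capture_eff = 1.0, mode = c("coordinate", "sequence"),
                              min_match = 20L, seed = 1L) {
  mode <- match.arg(mode)
  if (capture_eff < 0 || capture_eff > 1) {
    stopf("capture_eff must be in [0, 1]")
  }
  aln <- ensure_library_id(alignments)
  pre <- compose(aln)

  captured <- rep(FALSE, nrow(aln))
  if (nrow(cocktail) > 0 && capture_eff > 0) {
    if (mode == "coordinate") {
      for (i in seq_len(nrow(cocktail))) {
        on_target <- !is.na(aln$reference) &
          aln$reference == cocktail$species_id[i]
        if (!any(on_target)) next
        ov <- interval_overlap(aln$start[on_target], aln$end[on_target],
                               cocktail$start[i], cocktail$end[i])
        hit <- ov > 0 & ov >= min_overlap_frac * aln$length[on_target]
        captured[which(on_target)[hit]] <- TRUE
      }
    } else {
      if (!"sequence" %in% names(aln)) {
        stopf("sequence mode needs a 'sequence' column on the alignments")
      }
      targets <- as_dna(revcomp(cocktail$sequence))  # back to sense strand
      kmers <- unique(unlist(lapply(targets, function(t) {
        n <- nchar(t)
        if (n < min_match) return(character(0))
        substring(t, 1:(n - min_match + 1L), min_match:n)
      })))
      dict <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
      hits <- Biostrings::vwhichPDict(
        dict, Biostrings::DNAStringSet(as_dna(aln$sequence)))
      captured <- lengths(hits) > 0
    }
    if (capture_eff < 1) {
      withr::with_seed(as.integer(seed), {
        captured <- captured & (runif(length(captured)) < capture_eff)
      })
    }
  }

  survivors <- aln[!captured, ]
  post <- compose(survivors)
  fold <- inner_join(glance(pre), glance(post), by = "library_id",
                     suffix = c("_pre", "_post")) |>
    mutate(fold_improvement =
             .data$informative_fraction_post / .data$informative_fraction_pre) |>
    select("library_id", "informative_fraction_pre",
           "informative_fraction_post", "fold_improvement")

  structure(list(survivors = survivors, pre = pre, post = post,
                 n_captured = sum(captured), fold_improvement = fold,
                 params = list(min_overlap_frac = min_overlap_frac,
                               capture_eff = capture_eff, mode = mode)),
            class = "depletion_report")
}

#' @export
print.depletion_report <- function(x, ...) {
  cat(sprintf("<depletion_report> %d read(s) captured\n", x$n_captured))
  print(x$fold_improvement)
  invisible(x)
}

#' Post-depletion rRNA fraction as a function of cocktail size
#'
#' Depletes with the top-k cocktail for each `k` in `k_grid` and reports the
#' surviving rRNA fraction and the marginal gain of each added oligo —
#' the diminishing-returns curve that shows why cocktails beyond a few dozen
#' oligos stop paying off.
#'
#' @param alignments Categorized alignment tibble.
#' @param regions Ranked `contaminant_regions`.
#' @param rrna rRNA reference tibble.
#' @param k_grid Integer vector of cocktail sizes (0 = undepleted).
#' @param ... Passed to [deplete_in_silico()].
#' @return Tibble: `k`, `rrna_fraction`, `marginal_gain`.
#' @export
diminishing_returns_curve <- function(alignments, regions, rrna,
                                      k_grid = c(0L, 1L, 2L, 5L, 10L, 24L, 29L),
                                      ...) {
  aln <- ensure_library_id(alignments)
  rrna_frac <- function(a) {
    sum(a$category == "rRNA") / sum(a$category != "unmapped")
  }
  out <- purrr::map_dfr(sort(unique(pmin(k_grid, nrow(regions)))), function(k) {
    frac <- if (k == 0) rrna_frac(aln) else {
      cocktail <- design_cocktail(rank_and_take(regions, k), rrna)
      rrna_frac(deplete_in_silico(aln, cocktail, ...)$survivors)
    }
    tibble(k = k, rrna_fraction = frac)
  })
  mutate(out, marginal_gain = dplyr::lag(.data$rrna_fraction) - .data$rrna_fraction)
}

#' Write an oligo cocktail as TSV
#'
#' Column layout mirrors published depletion-oligo supplements:
#' oligo id, target species, target interval, oligo sequence, molar ratio.
#'
#' @param cocktail An `oligo_cocktail`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_cocktail <- function(cocktail, file) {
  readr::write_tsv(select(as_tibble(cocktail), "oligo_id",
                          target_species = "species_id", "start", "end",
                          "sequence", "molar_ratio"), file)
  invisible(file)
}
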