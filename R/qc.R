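# Frame quantification, metagene profiles, size distributions, CDS count
# correlations and in-silico size splitting.

#' Fraction of P-sites in each reading frame
#'
#' Computed over CDS-internal P-sites only (first and last codons are
#' excluded to avoid initiation/termination boundary ambiguity). Frame 1 is
#' in register with annotated start codons.
#'
#' @param psites A `psite_table` from [apply_offsets()].
#' @param annotation A `genome_annotation` (used for the last-codon bound).
#' @param by_compartment Also split fractions per compartment.
#' @return A `frame_report` tibble: `library_id` (, `compartment`), `frame`,
#'   `n`, `fraction`; fractions sum to 1 per group.
#' @export
frame_fractions <- function(psites, annotation, by_compartment = FALSE) {
  n_codons <- setNames(annotation$genes$cds_length %/% 3L,
                       annotation$genes$gene_id)
  ps <- psites |>
    filter(!is.na(.data$frame), !is.na(.data$codon_index)) |>
    mutate(n_cod = n_codons[.data$gene_id]) |>
    filter(.data$codon_index >= 1L, .data$codon_index <= .data$n_cod - 2L)
  if (nrow(ps) == 0) stopf("no CDS-internal P-sites")
  grp <- if (by_compartment) c("library_id", "compartment") else "library_id"
  out <- ps |>
    mutate(frame = factor(.data$frame, levels = 1:3)) |>
    count(dplyr::across(dplyr::all_of(grp)), .data$frame, .drop = FALSE) |>
    group_by(dplyr::across(dplyr::all_of(grp))) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(frame = as.integer(as.character(.data$frame)))
  new_riboclean_tbl(out, "frame_report")
}

#' Metagene profile around start (or stop) codons
#'
#' Per gene, P-site density at each position relative to the landmark is
#' normalized by that gene's mean CDS density, then averaged across genes.
#' Genes whose window overlaps a neighbouring gene's CDS are excluded (the
#' polycistronic-transcript caveat: terminating and initiating ribosomes
#' cannot be told apart across very short spacers), as are genes shorter
#' than the window or with no CDS P-sites; exclusion counts are reported.
#'
#' @param psites A `psite_table`.
#' @param annotation A `genome_annotation`.
#' @param window Half-width of the position window in nt (symmetric).
#' @param align `"start"` or `"stop"`.
#' @return A `metagene_profile` tibble: `position` (nt relative to the
#'   landmark's first nt, P-site coordinates), `density`, `n_genes`;
#'   exclusion counts in `attr(, "excluded")`.
#' @export
metagene <- function(psites, annotation, window = 50L,
                     align = c("start", "stop")) {
  align <- match.arg(align)
  genes <- annotation$genes
  genes <- genes[genes$usable, ]
  if (nrow(genes) == 0) stopf("no usable genes for metagene")

  # landmark: transcript-coordinate of the aligned codon's first nt
  landmark_cds <- if (align == "start") {
    rep(0L, nrow(genes))
  } else {
    genes$cds_length - 3L
  }

  # exclude genes whose genomic window overlaps another gene's CDS
  all_cds <- feature_intervals(annotation) |> filter(.data$feature == "CDS")
  excl_overlap <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    sc <- start_codon_position(g)
    lm <- if (align == "start") sc else {
      # genomic first nt of the stop-adjacent codon
      cds <- g$cds_parts[[1]]
      if (g$strand == "+") cds$end[nrow(cds)] - 3L else cds$start[1] + 2L
    }
    win <- c(lm - window, lm + window + 1L)
    other <- all_cds[all_cds$chromosome == g$chromosome &
                       all_cds$gene_id != g$gene_id, ]
    any(interval_overlap(win[1], win[2], other$start, other$end) > 0)
  }, logical(1))
  excl_short <- genes$cds_length < window
  keep <- !excl_overlap & !excl_short
  genes <- genes[keep, ]
  if (nrow(genes) == 0) stopf("all genes excluded from metagene window")

  ps <- psites |> filter(.data$gene_id %in% genes$gene_id,
                         !is.na(.data$cds_pos))
  lm <- setNames(landmark_cds[keep], genes$gene_id)
  cds_len <- setNames(genes$cds_length, genes$gene_id)
  ps$rel <- ps$cds_pos - lm[ps$gene_id]

  dens <- ps |>
    count(.data$gene_id, name = "total_cds") |>
    mutate(mean_density = .data$total_cds / cds_len[.data$gene_id])
  used_genes <- dens$gene_id[dens$mean_density > 0]
  if (length(used_genes) == 0) {
    stopf("no usable P-sites for metagene after gene exclusions")
  }

  prof <- ps |>
    filter(.data$gene_id %in% used_genes,
           .data$rel >= -window, .data$rel <= window) |>
    count(.data$gene_id, .data$rel) |>
    left_join(dens, by = "gene_id") |>
    mutate(norm = .data$n / .data$mean_density) |>
    group_by(position = .data$rel) |>
    summarise(total = sum(.data$norm), .groups = "drop")

  out <- tibble(position = seq(-window, window)) |>
    left_join(prof, by = "position") |>
    mutate(density = dplyr::coalesce(.data$total, 0) / length(used_genes),
           n_genes = length(used_genes)) |>
    select("position", "density", "n_genes")
  out <- new_riboclean_tbl(out, "metagene_profile")
  attr(out, "excluded") <- c(window_overlap = sum(excl_overlap),
                             too_short = sum(excl_short & !excl_overlap),
                             no_signal = sum(keep) - length(used_genes))
  out
}

#' Footprint size distributions per compartment group
#'
#' Histograms of read length for reads mapping to the nuclear genome, the
#' chloroplast genome, the mitochondrial genome and rRNA. For the
#' chloroplast group a bimodality statistic is attached: the valley-to-peak
#' ratio between the small (20-30 nt) and large (31-40 nt) footprint modes.
#'
#' @param alignments Categorized alignment tibble.
#' @param small,large Inclusive nt ranges of the two chloroplast modes.
#' @return A `size_distribution` tibble: `library_id`, `group`, `length`,
#'   `n`, `fraction`; bimodality statistics in `attr(, "bimodality")`.
#' @export
size_distribution <- function(alignments, small = c(20L, 30L),
                              large = c(31L, 40L)) {
  aln <- ensure_library_id(alignments)
  aln <- aln[aln$category != "unmapped", ]
  aln$group <- dplyr::case_when(
    aln$category == "rRNA" ~ "rRNA",
    TRUE ~ aln$compartment
  )
  out <- aln |>
    count(.data$library_id, .data$group, .data$length) |>
    group_by(.data$library_id, .data$group) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()

  bimod <- out |>
    filter(.data$group == "chloroplast") |>
    group_by(.data$library_id) |>
    group_modify(function(d, key) {
      h <- setNames(rep(0L, large[2] - small[1] + 1L), small[1]:large[2])
      hit <- d$length >= small[1] & d$length <= large[2]
      h[as.character(d$length[hit])] <- d$n[hit]
      lens <- as.integer(names(h))
      in_small <- lens <= small[2]
      pk_s <- lens[in_small][which.max(h[in_small])]
      pk_l <- lens[!in_small][which.max(h[!in_small])]
      between <- h[lens > pk_s & lens < pk_l]
      valley <- if (length(between)) min(between) else NA_integer_
      tibble(peak_small = pk_s, peak_large = pk_l,
             valley_to_peak = valley / min(max(h[in_small]), max(h[!in_small])))
    }) |>
    ungroup()

  out <- new_riboclean_tbl(out, "size_distribution")
  attr(out, "bimodality") <- bimod
  out
}

#' Per-gene CDS counts
#'
#' Counts P-sites (from a `psite_table`) or CDS-assigned reads (from a
#' categorized alignment tibble) per gene and library, completed with zeros
#' over the annotation's gene universe.
#'
#' @param x A `psite_table` or categorized alignment tibble.
#' @param annotation A `genome_annotation`.
#' @return Tibble: `gene_id`, `library_id`, `count`.
#' @export
count_cds <- function(x, annotation) {
  x <- ensure_library_id(x)
  if ("category" %in% names(x)) x <- filter(x, .data$category == "CDS")
  x <- filter(x, !is.na(.data$gene_id))
  libs <- unique(x$library_id)
  if (length(libs) == 0) libs <- "lib1"
  counts <- count(x, .data$gene_id, .data$library_id, name = "count")
  tidyr::expand_grid(gene_id = annotation$genes$gene_id, library_id = libs) |>
    left_join(counts, by = c("gene_id", "library_id")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L))
}

#' Pairwise Spearman correlation of CDS counts across libraries
#'
#' For each library pair, genes with fewer than `min_count` counts in either
#' library are excluded (the low-count filter), then the Spearman rank
#' correlation of log2 counts is computed (rank correlation is invariant to
#' the log, so this matches correlating log2-counts). Pairs with fewer than
#' 3 surviving genes get `NA` with a warning.
#'
#' @param counts Long count tibble from [count_cds()].
#' @param min_count Exclusion threshold (default 10: genes with fewer than
#'   10 counts are excluded).
#' @return A `correlation_table` tibble: `library_a`, `library_b`, `rho`,
#'   `n_genes`; symmetric with unit diagonal.
#' @export
cds_correlation <- function(counts, min_count = 10L) {
  wide <- tidyr::pivot_wider(counts, names_from = "library_id",
                             values_from = "count", values_fill = 0L)
  libs <- setdiff(names(wide), "gene_id")
  out <- purrr::map_dfr(libs, function(a) purrr::map_dfr(libs, function(b) {
    keep <- wide[[a]] >= min_count & wide[[b]] >= min_count
    if (sum(keep) < 3) {
      warnf("cds_correlation: < 3 genes survive the count filter for %s vs %s",
            a, b)
      return(tibble(library_a = a, library_b = b, rho = NA_real_,
                    n_genes = sum(keep)))
    }
    rho <- stats::cor(log2(wide[[a]][keep]), log2(wide[[b]][keep]),
                      method = "spearman")
    tibble(library_a = a, library_b = b, rho = rho, n_genes = sum(keep))
  }))
  new_riboclean_tbl(out, "correlation_table")
}

#' In-silico size splitting of footprints
#'
#' Separates reads into a small and a large size class, counts them per
#' gene, reports the rank correlation of the two per-gene count vectors and
#' each class's start-proximal enrichment: the observed fraction of
#' footprint positions within the first `start_window` nt of the CDS
#' divided by the fraction expected under uniform coverage (> 1 means the
#' class is enriched near start codons).
#'
#' @param alignments Categorized alignment tibble (CDS reads are used).
#' @param annotation A `genome_annotation`.
#' @param small,large Disjoint inclusive length ranges; the chloroplast
#'   defaults are 20-30 / 31-40 nt (use 18-24 / 25-34 for cytosolic
#'   footprints).
#' @param psites Optional `psite_table`; when given, P-site positions are
#'   used for the enrichment statistic, otherwise the read's 5'-end
#'   transcript position.
#' @param start_window Width of the start-proximal window (nt).
#' @return A `size_split` list: `$counts` (gene_id, small, large),
#'   `$correlation` (Spearman rho), `$enrichment` (tibble class/ratio).
#' @export
size_split_analysis <- function(alignments, annotation,
                                small = c(20L, 30L), large = c(31L, 40L),
                                psites = NULL, start_window = 50L) {
  if (small[2] >= large[1]) stopf("size ranges must be disjoint (small below large)")
  aln <- filter(alignments, .data$category == "CDS", !is.na(.data$gene_id))
  aln$class <- dplyr::case_when(
    aln$length >= small[1] & aln$length <= small[2] ~ "small",
    aln$length >= large[1] & aln$length <= large[2] ~ "large",
    TRUE ~ NA_character_
  )
  aln <- filter(aln, !is.na(.data$class))
  counts <- aln |>
    count(.data$gene_id, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (cl in c("small", "large")) {
    if (!cl %in% names(counts)) counts[[cl]] <- 0L
  }
  counts <- tibble(gene_id = annotation$genes$gene_id) |>
    left_join(counts, by = "gene_id") |>
    mutate(across(c("small", "large"), ~ dplyr::coalesce(.x, 0L)))

  rho <- if (sum(counts$small) == 0 || sum(counts$large) == 0) {
    warnf("a size class is empty; correlation undefined")
    NA_real_
  } else {
    stats::cor(counts$small, counts$large, method = "spearman")
  }

  # footprint position within the CDS for the enrichment statistic
  genes <- annotation$genes
  pos_tbl <- if (!is.null(psites)) {
    psites |>
      filter(!is.na(.data$cds_pos)) |>
      mutate(class = dplyr::case_when(
        .data$length >= small[1] & .data$length <= small[2] ~ "small",
        .data$length >= large[1] & .data$length <= large[2] ~ "large",
        TRUE ~ NA_character_)) |>
      filter(!is.na(.data$class)) |>
      select("gene_id", "class", pos = "cds_pos")
  } else {
    p5 <- ifelse(aln$strand == "+", aln$start, aln$end - 1L)
    cds_pos <- rep(NA_integer_, nrow(aln))
    for (g in unique(aln$gene_id)) {
      gi <- which(genes$gene_id == g)
      rows <- which(aln$gene_id == g)
      cds_pos[rows] <- genomic_to_cds(genes[gi, ], p5[rows])
    }
    tibble(gene_id = aln$gene_id, class = aln$class, pos = cds_pos) |>
      filter(!is.na(.data$pos))
  }
  cds_len <- setNames(genes$cds_length, genes$gene_id)
  enrich <- pos_tbl |>
    mutate(len = cds_len[.data$gene_id],
           near = .data$pos < pmin(start_window, .data$len),
           exp_frac = pmin(start_window, .data$len) / .data$len) |>
    group_by(.data$class) |>
    summarise(observed = mean(.data$near),
              expected = mean(.data$exp_frac),
              ratio = .data$observed / .data$expected, .groups = "drop")

  structure(list(counts = counts, correlation = rho, enrichment = enrich),
            class = "size_split")
}

#' @export
print.size_split <- function(x, ...) {
  cat(sprintf("<size_split> small-vs-large per-gene Spearman rho = %.3f\n",
              x$correlation))
  print(x$enrichment)
  invisible(x)
}
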