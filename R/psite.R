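# P-site offset calibration from annotated start codons, and P-site
# placement of reads.
#
# Offset convention (exported in every offset table): d5 is the distance in
# nt from the read 5' end to the first nucleotide of the P-site codon; d3 is
# the number of nt strictly 3' of the P-site codon's last nucleotide. For a
# read of length L covering its P-site codon, d5 + 3 + d3 = L exactly, so
# 5'-anchored and 3'-anchored placement agree whenever the table is
# consistent.

OFFSET_CONVENTION <- "d5 + 3 + d3 = L; d3 counts nt strictly 3' of the P-site codon"

# Transcript-oriented distances from read ends to each covered start codon.
# Returns one row per (read, start codon) pair.
start_codon_deltas <- function(alignments, annotation) {
  aln <- ensure_library_id(alignments)
  genes <- annotation$genes
  genes <- genes[genes$usable & genes$cds_length > 0, ]
  sc <- tibble(
    gene_id = genes$gene_id,
    chromosome = genes$chromosome,
    strand = genes$strand,
    compartment = genes$compartment,
    pos = vapply(seq_len(nrow(genes)),
                 function(i) start_codon_position(genes[i, ]), integer(1))
  )
  out <- vector("list", 0L)
  for (ch in unique(sc$chromosome)) {
    for (str in c("+", "-")) {
      scs <- sc[sc$chromosome == ch & sc$strand == str, ]
      sub <- aln[!is.na(aln$reference) & aln$reference == ch &
                   aln$strand == str, ]
      if (nrow(scs) == 0 || nrow(sub) == 0) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(sub$start + 1L, sub$end),
        IRanges::IRanges(scs$pos + 1L, scs$pos + 1L))
      if (length(ov) == 0) next
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      d5 <- if (str == "+") scs$pos[s] - sub$start[q] else
        (sub$end[q] - 1L) - scs$pos[s]
      out[[length(out) + 1L]] <- tibble(
        library_id = sub$library_id[q],
        compartment = scs$compartment[s],
        length = sub$length[q],
        delta5 = as.integer(d5),
        delta3 = as.integer(sub$length[q] - 3L - d5)
      )
    }
  }
  if (length(out) == 0) return(tibble(library_id = character(),
                                      compartment = character(),
                                      length = integer(), delta5 = integer(),
                                      delta3 = integer()))
  bind_rows(out)
}

#' Estimate size-stratified P-site offsets from both read ends
#'
#' For each (compartment, read length), reads whose span covers an annotated
#' start codon are collected and the distances from the read 5' end
#' (`delta5`) and 3' end (`delta3`) to the start codon are histogrammed in
#' transcript orientation; the modal value of each histogram is the offset
#' (ties break toward the smaller offset). The two ribosome species are
#' calibrated separately: cytosolic 80S footprints have a stable 5' offset
#' while chloroplast 70S footprints are anchored at the 3' end. Sizes with
#' fewer than `min_reads` start-overlapping reads are reported as
#' undetermined rather than borrowed from neighbours.
#'
#' @param alignments Categorized, size-selected alignment tibble.
#' @param annotation A `genome_annotation`.
#' @param min_reads Minimum start-overlapping reads per (compartment,
#'   length) (default 100).
#' @return An `offset_table` tibble: `compartment`, `length`, `end`
#'   (`"5p"`/`"3p"`), `offset`, `n_reads`, `mode_fraction`, `status`;
#'   the per-size normalized delta histograms are in `attr(, "density")` and
#'   the offset convention in `attr(, "convention")`.
#' @export
estimate_offsets <- function(alignments, annotation, min_reads = 100L) {
  deltas <- start_codon_deltas(alignments, annotation)
  # keep only geometries where the P-site codon can lie inside the read
  deltas <- deltas[deltas$delta5 >= 0 & deltas$delta5 <= deltas$length - 3L, ]
  if (nrow(deltas) == 0) {
    warnf("no start-codon-overlapping reads; offset table is empty")
  }
  per_size <- deltas |>
    group_by(.data$compartment, .data$length) |>
    summarise(
      off5 = modal_value(.data$delta5),
      off3 = modal_value(.data$delta3),
      frac5 = modal_fraction(.data$delta5),
      frac3 = modal_fraction(.data$delta3),
      n_reads = n(), .groups = "drop")
  out <- bind_rows(
    per_size |>
      mutate(end = "5p", offset = .data$off5, mode_fraction = .data$frac5),
    per_size |>
      mutate(end = "3p", offset = .data$off3, mode_fraction = .data$frac3)
  ) |>
    mutate(status = if_else(.data$n_reads >= min_reads, "ok", "undetermined"),
           offset = if_else(.data$status == "ok", .data$offset, NA_integer_)) |>
    select("compartment", "length", "end", "offset", "n_reads",
           "mode_fraction", "status") |>
    arrange(.data$compartment, .data$length, .data$end)

  density <- deltas |>
    tidyr::pivot_longer(c("delta5", "delta3"), names_to = "end",
                        values_to = "delta") |>
    mutate(end = if_else(.data$end == "delta5", "5p", "3p")) |>
    count(.data$compartment, .data$length, .data$end, .data$delta) |>
    group_by(.data$compartment, .data$length, .data$end) |>
    mutate(density = .data$n / sum(.data$n)) |>   # per-size normalization
    ungroup()

  out <- new_riboclean_tbl(out, "offset_table")
  attr(out, "density") <- density
  attr(out, "convention") <- OFFSET_CONVENTION
  out
}

#' Position reads at their P-site
#'
#' Uses the anchored end configured per compartment: 5'-anchored placement
#' is `P = read 5' end + offset(5p)`, 3'-anchored is
#' `P = read 3' end - 3 - offset(3p)` (both in transcript orientation, then
#' mapped back to genomic coordinates). Reads whose (compartment, length)
#' offset is undetermined are excluded and counted. The frame index is
#' computed within the covering gene's joined CDS: frame 1 is in register
#' with the annotated start codon.
#'
#' @param alignments Categorized alignment tibble (CDS reads carry the
#'   assigned `gene_id`).
#' @param offsets An `offset_table` from [estimate_offsets()].
#' @param annotation A `genome_annotation`.
#' @param anchors Named character vector compartment -> `"5p"`/`"3p"`.
#' @return A `psite_table` tibble: `library_id`, `read_id`, `chromosome`,
#'   `gene_id`, `compartment`, `strand`, `length`, `p_site` (genomic
#'   position of the P-site codon's first nt), `cds_pos` (0-based within
#'   the joined CDS, NA outside), `codon_index`, `frame` (1/2/3).
#'   `attr(, "n_excluded")` counts reads dropped for undetermined offsets.
#' @export
apply_offsets <- function(alignments, offsets, annotation,
                          anchors = c(nuclear = "5p", chloroplast = "3p",
                                      mitochondrial = "5p")) {
  aln <- ensure_library_id(alignments)
  aln <- aln[aln$category %in% "CDS" & !is.na(aln$gene_id), ]
  aln$anchor <- unname(anchors[aln$compartment])

  off <- as_tibble(offsets) |>
    filter(.data$status == "ok") |>
    select("compartment", "length", end2 = "end", "offset")
  aln <- left_join(aln, off,
                   by = c(compartment = "compartment", length = "length",
                          anchor = "end2"))
  n_excluded <- sum(is.na(aln$offset))
  if (n_excluded > 0) {
    inform(sprintf("apply_offsets: %d read(s) excluded (undetermined offset)",
                   n_excluded))
  }
  aln <- aln[!is.na(aln$offset), ]

  plus <- aln$strand == "+"
  p5 <- ifelse(plus, aln$start, aln$end - 1L)          # genomic 5' nt
  p_site <- ifelse(aln$anchor == "5p",
                   ifelse(plus, p5 + aln$offset, p5 - aln$offset),
                   ifelse(plus, aln$end - 3L - aln$offset,
                          aln$start + 2L + aln$offset))

  genes <- annotation$genes
  cds_pos <- rep(NA_integer_, nrow(aln))
  for (g in unique(aln$gene_id)) {
    gi <- which(genes$gene_id == g)
    if (length(gi) == 0) next
    rows <- which(aln$gene_id == g)
    cds_pos[rows] <- genomic_to_cds(genes[gi, ], p_site[rows])
  }

  out <- tibble(
    library_id = aln$library_id, read_id = aln$read_id,
    chromosome = aln$reference, gene_id = aln$gene_id,
    compartment = aln$compartment, strand = aln$strand,
    length = aln$length, p_site = as.integer(p_site),
    cds_pos = cds_pos,
    codon_index = cds_pos %/% 3L,
    frame = cds_pos %% 3L + 1L
  )
  out <- new_riboclean_tbl(out, "psite_table")
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write an offset table as TSV
#'
#' The offset convention is recorded as a header comment.
#'
#' @param offsets An `offset_table`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_offsets <- function(offsets, file) {
  writeLines(paste0("# offset convention: ", attr(offsets, "convention")), file)
  readr::write_tsv(as_tibble(offsets), file, append = TRUE, col_names = TRUE)
  invisible(file)
}

#' Write P-site positions as BED
#'
#' Single-nucleotide intervals; name is the read id, score the frame.
#'
#' @param psites A `psite_table`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_psites_bed <- function(psites, file) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   psites$chromosome, psites$p_site, psites$p_site + 1L,
                   psites$read_id,
                   ifelse(is.na(psites$frame), 0L, psites$frame),
                   psites$strand)
  writeLines(lines, file)
  invisible(file)
}
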