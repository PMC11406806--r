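# Read ingestion, category assignment and library-composition reporting.

#' Read an alignment file into the package's alignment tibble
#'
#' Accepts SAM/BAM (standard flags; only primary alignments are kept so each
#' read is counted once; soft-clips are excluded from the reference span) or
#' the plain toy alignment TSV dialect with columns
#' `read_id, reference, start, end, strand` (0-based half-open).
#'
#' @param file Path to the alignment file.
#' @param format `"auto"` (by extension), `"tsv"`, `"sam"` or `"bam"`.
#' @return Alignment tibble: `read_id`, `reference`, `start`, `end`,
#'   `strand`, `length`.
#' @export
read_alignments <- function(file, format = c("auto", "tsv", "sam", "bam")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(file))
    format <- if (ext %in% c("sam", "bam")) ext else "tsv"
  }
  if (format == "tsv") {
    out <- readr::read_tsv(file, show_col_types = FALSE)
    check_alignments(out)
    out$start <- as.integer(out$start)
    out$end <- as.integer(out$end)
    out$length <- out$end - out$start
    return(as_tibble(out))
  }
  bam <- if (format == "sam") {
    Rsamtools::asBam(file, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else file
  rec <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar")))[[1]]
  primary <- bitwAnd(rec$flag, bitwOr(256L, 2048L)) == 0L
  unmapped <- bitwAnd(rec$flag, 4L) != 0L
  keep <- primary
  width <- rep(NA_integer_, length(rec$qname))
  ok <- keep & !unmapped
  width[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[ok])
  tibble(
    read_id = rec$qname[keep],
    reference = ifelse(unmapped[keep], NA_character_,
                       as.character(rec$rname[keep])),
    start = ifelse(unmapped[keep], NA_integer_, rec$pos[keep] - 1L),
    end = ifelse(unmapped[keep], NA_integer_,
                 rec$pos[keep] - 1L + width[keep]),
    strand = ifelse(unmapped[keep], NA_character_,
                    ifelse(bitwAnd(rec$flag[keep], 16L) != 0L, "-", "+")),
    length = width[keep]
  )
}

#' Assign each read a category
#'
#' Precedence is rRNA > CDS > UTR5/UTR3 > intergenic. A read is CDS when at
#' least `cds_overlap` of its span overlaps the CDS of a same-strand gene
#' (ties at exactly 50/50 break toward CDS); otherwise the majority feature
#' among UTR5/UTR3/outside wins. Reads on the mitochondrial chromosome are a
#' compartment-level category of their own and reads on rRNA references are
#' labelled per species. Reads on references known to neither the annotation
#' nor the rRNA set raise an error naming the offenders.
#'
#' @param alignments Alignment tibble (see [read_alignments()] /
#'   [toy_align()]).
#' @param annotation A `genome_annotation`.
#' @param rrna rRNA reference tibble ([read_rrna_references()]).
#' @param cds_overlap Minimum fraction of the read span overlapping CDS for
#'   a CDS call (default 0.5).
#' @param quiet Suppress progress messages.
#' @return The input tibble with `category`, `compartment`, `gene_id` and
#'   `rrna_species` columns added.
#' @export
categorize_reads <- function(alignments, annotation, rrna,
                             cds_overlap = 0.5, quiet = FALSE) {
  check_alignments(alignments)
  aln <- as_tibble(alignments)
  if (!"length" %in% names(aln)) aln$length <- aln$end - aln$start

  chrom <- annotation$chromosomes
  known <- c(rrna$species_id, chrom$chromosome)
  bad <- setdiff(unique(aln$reference[!is.na(aln$reference)]), known)
  if (length(bad) > 0) {
    stopf("read(s) on unknown reference(s): %s", paste(bad, collapse = ", "))
  }

  category <- rep("intergenic", nrow(aln))
  compartment <- rep(NA_character_, nrow(aln))
  gene_id <- rep(NA_character_, nrow(aln))
  rrna_species <- rep(NA_character_, nrow(aln))

  category[is.na(aln$reference)] <- "unmapped"

  is_rrna <- aln$reference %in% rrna$species_id
  category[is_rrna] <- "rRNA"
  rrna_species[is_rrna] <- aln$reference[is_rrna]
  compartment[is_rrna] <- rrna$compartment[match(aln$reference[is_rrna],
                                                 rrna$species_id)]

  chr_comp <- setNames(chrom$compartment, chrom$chromosome)
  on_genome <- !is.na(aln$reference) & !is_rrna
  compartment[on_genome] <- unname(chr_comp[aln$reference[on_genome]])
  is_mito <- on_genome & compartment == "mitochondrial"
  category[is_mito] <- "mitochondrial"

  todo <- which(on_genome & !is_mito)
  if (length(todo) > 0) {
    feats <- feature_intervals(annotation)
    hits_all <- vector("list", 0L)
    for (ch in unique(aln$reference[todo])) {
      for (str in c("+", "-")) {
        ridx <- todo[aln$reference[todo] == ch & aln$strand[todo] == str]
        fsub <- feats[feats$chromosome == ch & feats$strand == str, ]
        if (length(ridx) == 0 || nrow(fsub) == 0) next
        rir <- IRanges::IRanges(aln$start[ridx] + 1L, aln$end[ridx])
        fir <- IRanges::IRanges(fsub$start + 1L, fsub$end)
        ov <- IRanges::findOverlaps(rir, fir)
        if (length(ov) == 0) next
        q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
        w <- IRanges::width(IRanges::pintersect(rir[q], fir[s]))
        hits_all[[length(hits_all) + 1L]] <- tibble(
          row = ridx[q], gene_id = fsub$gene_id[s],
          feature = fsub$feature[s], ov = w)
      }
    }
    if (length(hits_all) > 0) {
      hits <- bind_rows(hits_all) |>
        group_by(.data$row, .data$gene_id, .data$feature) |>
        summarise(ov = sum(.data$ov), .groups = "drop") |>
        tidyr::pivot_wider(names_from = "feature", values_from = "ov",
                           values_fill = 0L)
      for (col in c("CDS", "UTR5", "UTR3")) {
        if (!col %in% names(hits)) hits[[col]] <- 0L
      }
      hits$len <- aln$length[hits$row]
      hits <- hits |>
        mutate(f_cds = .data$CDS / .data$len,
               f_u5 = .data$UTR5 / .data$len,
               f_u3 = .data$UTR3 / .data$len,
               total = .data$f_cds + .data$f_u5 + .data$f_u3) |>
        group_by(.data$row) |>
        arrange(desc(.data$f_cds), desc(.data$total), .data$gene_id,
                .by_group = TRUE) |>
        slice(1) |>
        ungroup() |>
        mutate(f_out = pmax(0, 1 - .data$total),
               cat = if_else(.data$f_cds >= cds_overlap, "CDS",
                     if_else(.data$f_u5 >= pmax(.data$f_u3, .data$f_out), "UTR5",
                     if_else(.data$f_u3 >= .data$f_out, "UTR3", "intergenic"))))
      category[hits$row] <- hits$cat
      gene_id[hits$row] <- if_else(hits$cat == "intergenic",
                                   NA_character_, hits$gene_id)
    }
  }

  aln$category <- category
  aln$compartment <- compartment
  aln$gene_id <- gene_id
  aln$rrna_species <- rrna_species
  if (!quiet) {
    inform(sprintf("categorized %d reads (%d rRNA, %d CDS, %d unmapped)",
                   nrow(aln), sum(category == "rRNA"),
                   sum(category == "CDS"), sum(category == "unmapped")))
  }
  aln
}

#' Filter reads by footprint length
#'
#' Inclusive bounds, matching gel size selection (e.g. 20-35 nt for
#' rRNA-depleted or 20-50 nt for undepleted libraries). Idempotent.
#'
#' @param alignments Alignment tibble with a `length` column.
#' @param min_len,max_len Inclusive length bounds (`1 <= min <= max`).
#' @param quiet Suppress the removed-read message.
#' @return The filtered tibble.
#' @export
size_select <- function(alignments, min_len = 20L, max_len = 35L,
                        quiet = FALSE) {
  if (min_len < 1 || min_len > max_len) {
    stopf("size_select needs 1 <= min_len <= max_len")
  }
  keep <- !is.na(alignments$length) &
    alignments$length >= min_len & alignments$length <= max_len
  if (!quiet) {
    inform(sprintf("size_select [%d, %d]: removed %d of %d reads",
                   min_len, max_len, sum(!keep), length(keep)))
  }
  alignments[keep, ]
}

#' Library composition report
#'
#' Per-category (and per-rRNA-species) counts and fractions of total mapped
#' reads, one block per library. The informative fraction is
#' `1 - rRNA fraction`; the fold-change in informative reads between two
#' reports (e.g. before/after depletion) is `glance()`-able.
#'
#' @param alignments Categorized alignment tibble (a `library_id` column
#'   groups libraries; absent means one library `"lib1"`).
#' @return A `composition_report` tibble: `library_id`, `category`,
#'   `compartment`, `n`, `fraction`, with a per-species breakdown in
#'   `attr(, "species")`.
#' @export
compose <- function(alignments) {
  stopifnot("category" %in% names(alignments))
  aln <- ensure_library_id(alignments)
  if (!"compartment" %in% names(aln)) aln$compartment <- NA_character_
  if (!"rrna_species" %in% names(aln)) {
    aln$rrna_species <- if_else(aln$category == "rRNA", aln$reference,
                                NA_character_)
  }
  mapped <- aln[aln$category != "unmapped", ]
  if (nrow(mapped) == 0) stopf("no mapped reads to compose")

  rep_tbl <- mapped |>
    mutate(compartment = if_else(.data$category == "rRNA",
                                 NA_character_, .data$compartment)) |>
    count(.data$library_id, .data$category, .data$compartment) |>
    group_by(.data$library_id) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()

  species <- mapped |>
    filter(.data$category == "rRNA") |>
    count(.data$library_id, species_id = .data$rrna_species) |>
    left_join(count(mapped, .data$library_id, name = "total"),
              by = "library_id") |>
    mutate(fraction = .data$n / .data$total) |>
    select(-"total")

  out <- new_riboclean_tbl(rep_tbl, "composition_report")
  attr(out, "species") <- species
  attr(out, "n_unmapped") <- sum(aln$category == "unmapped")
  out
}

#' Feature proportions among informative reads
#'
#' The conventional feature-accounting view: proportions of mapped footprints
#' across genomic features, calculated after removal of rRNA reads.
#'
#' @param alignments Categorized alignment tibble.
#' @return Tibble: `library_id`, `category`, `n`, `fraction` (fractions over
#'   non-rRNA mapped reads).
#' @export
feature_proportions <- function(alignments) {
  aln <- ensure_library_id(alignments)
  keep <- aln[!aln$category %in% c("rRNA", "unmapped"), ]
  if (nrow(keep) == 0) stopf("no non-rRNA mapped reads")
  keep |>
    count(.data$library_id, .data$category) |>
    group_by(.data$library_id) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
}

#' Write a composition report as TSV and JSON
#'
#' @param report A `composition_report`.
#' @param path_prefix Output prefix; writes `<prefix>.tsv`, `<prefix>.json`
#'   and `<prefix>_species.tsv`.
#' @return The TSV path, invisibly.
#' @export
write_composition <- function(report, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  readr::write_tsv(as_tibble(report), tsv)
  readr::write_tsv(attr(report, "species"), paste0(path_prefix, "_species.tsv"))
  jsonlite::write_json(
    list(composition = as_tibble(report),
         species = attr(report, "species"),
         informative = glance(report)),
    paste0(path_prefix, ".json"), dataframe = "rows", digits = NA)
  invisible(tsv)
}
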