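# Reference I/O and the shared coordinate model.
#
# Conventions used throughout the package:
#  * in-memory intervals are 0-based half-open [start, end);
#  * GFF3 and BED/bedGraph conventions are handled at the file boundary
#    (by rtracklayer), never inside the package;
#  * read positions are interpreted in transcript orientation for offset and
#    metagene work; genomic orientation is retained in alignment tables.

#' Guess the genome compartment of chromosomes from their names
#'
#' Plant genomes carry three translationally active compartments. Annotation
#' files rarely state which chromosome is which, so the assignment is a
#' configurable name mapping; this helper provides the default heuristic
#' (names containing "C"/"Pt"/"chloro" are chloroplast, "M"/"Mt"/"mito" are
#' mitochondrial, everything else nuclear).
#'
#' @param chromosomes Character vector of chromosome names.
#' @return Named character vector mapping each name to
#'   `"nuclear"`, `"chloroplast"` or `"mitochondrial"`.
#' @export
default_compartments <- function(chromosomes) {
  comp <- rep("nuclear", length(chromosomes))
  comp[grepl("(chrc|^pt$|chloro|plastid|^cp)", chromosomes, ignore.case = TRUE)] <- "chloroplast"
  comp[grepl("(chrm|^mt$|mito)", chromosomes, ignore.case = TRUE)] <- "mitochondrial"
  setNames(comp, chromosomes)
}

#' Read a FASTA file into a tibble
#'
#' Sequences are upper-cased and stored in the DNA alphabet (U converted to
#' T); whether the original record used the RNA alphabet is recorded.
#'
#' @param file Path to a FASTA file.
#' @return A tibble with columns `seq_id`, `sequence`, `length`, `was_rna`.
#' @export
read_fasta <- function(file) {
  set <- Biostrings::readBStringSet(file)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stopf("duplicate FASTA identifiers: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  raw <- unname(as.character(set))
  if (any(nchar(raw) == 0)) {
    stopf("empty FASTA record(s): %s", paste(ids[nchar(raw) == 0], collapse = ", "))
  }
  tibble(
    seq_id = ids,
    sequence = as_dna(raw),
    length = nchar(raw),
    was_rna = grepl("[Uu]", raw)
  )
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with an id column (`seq_id` or `species_id`) and a
#'   `sequence` column.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(seqs, file) {
  id_col <- intersect(c("seq_id", "species_id"), names(seqs))[1]
  if (is.na(id_col)) stopf("no seq_id/species_id column to write")
  set <- Biostrings::DNAStringSet(seqs$sequence)
  names(set) <- seqs[[id_col]]
  Biostrings::writeXStringSet(set, file, width = 70L)
  invisible(file)
}

#' Load rRNA reference sequences
#'
#' Thin wrapper around [read_fasta()] that assigns each rRNA species to a
#' genome compartment. By default the species id prefix is used
#' (`Nu_` nuclear-encoded, `Cp_` chloroplast-encoded, `Mt_`
#' mitochondria-encoded); an explicit mapping overrides it.
#'
#' @param file FASTA path (or a tibble already read with [read_fasta()]).
#' @param compartments Optional named character vector `species_id ->`
#'   compartment.
#' @return Tibble with columns `species_id`, `sequence`, `length`,
#'   `compartment`.
#' @export
read_rrna_references <- function(file, compartments = NULL) {
  tbl <- if (is.data.frame(file)) file else read_fasta(file)
  if ("seq_id" %in% names(tbl)) tbl <- rename(tbl, species_id = "seq_id")
  comp <- rep("nuclear", nrow(tbl))
  comp[startsWith(tbl$species_id, "Cp")] <- "chloroplast"
  comp[startsWith(tbl$species_id, "Mt")] <- "mitochondrial"
  if (!is.null(compartments)) {
    hit <- tbl$species_id %in% names(compartments)
    comp[hit] <- unname(compartments[tbl$species_id[hit]])
  }
  tbl$compartment <- comp
  select(tbl, "species_id", "sequence", "length", "compartment")
}

# ---- genome annotation ------------------------------------------------------

new_genome_annotation <- function(chromosomes, genes) {
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d chromosome(s), %d gene(s)\n",
              nrow(x$chromosomes), nrow(x$genes)))
  print(count(x$genes, .data$compartment))
  invisible(x)
}

#' Read a GFF3 genome annotation
#'
#' Parses gene/mRNA/CDS (and optional five_prime_UTR/three_prime_UTR)
#' features into gene models with 0-based half-open intervals held in
#' transcription order. Genes whose joined CDS length is not a positive
#' multiple of 3 are flagged unusable for start-codon work (with a warning)
#' rather than dropped.
#'
#' @param file GFF3 path (1-based closed coordinates on disk).
#' @param compartments Optional named character vector mapping chromosome
#'   name to compartment; defaults to [default_compartments()].
#' @return A `genome_annotation`: list with `chromosomes`
#'   (tibble: chromosome, length, compartment) and `genes`
#'   (tibble: gene_id, chromosome, strand, compartment, cds_parts,
#'   utr5_parts, utr3_parts list-columns of 0-based half-open intervals,
#'   cds_length, usable).
#' @export
read_annotation <- function(file, compartments = NULL) {
  gr <- rtracklayer::import(file, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  df$Parent <- vapply(as.list(df$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))

  lens <- GenomeInfoDb_seqlengths(gr)
  # rtracklayer does not transfer ##sequence-region pragmas to seqinfo
  pragmas <- grep("^##sequence-region", readLines(file, n = 1000L), value = TRUE)
  if (length(pragmas) > 0) {
    fields <- strsplit(trimws(pragmas), "\\s+")
    pl <- setNames(vapply(fields, function(f) as.integer(f[4]), integer(1)),
                   vapply(fields, function(f) f[2], character(1)))
    lens[names(pl)] <- pl
  }
  chrom_names <- unique(df$seqnames)
  missing_len <- chrom_names[!chrom_names %in% names(lens)[!is.na(lens)]]
  if (length(missing_len) > 0) {
    warnf("no ##sequence-region for %s; using max feature end",
          paste(missing_len, collapse = ", "))
    for (ch in missing_len) lens[ch] <- max(df$end[df$seqnames == ch])
  }
  lens <- lens[chrom_names]

  comp_map <- compartments %||% default_compartments(chrom_names)
  unknown <- chrom_names[!chrom_names %in% names(comp_map)]
  if (length(unknown) > 0) {
    stopf("chromosome(s) missing from compartment mapping: %s",
          paste(unknown, collapse = ", "))
  }

  if (any(df$start < 1 | df$end > lens[df$seqnames])) {
    bad <- df[df$start < 1 | df$end > lens[df$seqnames], ]
    stopf("feature(s) outside chromosome bounds: %s",
          paste(utils::head(bad$ID, 5), collapse = ", "))
  }

  genes_df <- df[df$type == "gene", ]
  tx_df <- df[df$type %in% c("mRNA", "transcript"), ]
  tx_parent <- setNames(tx_df$Parent, tx_df$ID)

  resolve_gene <- function(parent) {
    ifelse(parent %in% names(tx_parent), unname(tx_parent[parent]), parent)
  }

  part_tbl <- function(sub, minus) {
    sub <- sub[order(sub$start), ]
    out <- tibble(start = sub$start - 1L, end = sub$end)
    if (minus) out <- out[rev(seq_len(nrow(out))), ]
    out
  }

  feats <- df[df$type %in% c("CDS", "five_prime_UTR", "three_prime_UTR"), ]
  feats$gene <- resolve_gene(feats$Parent)

  genes <- purrr::map_dfr(seq_len(nrow(genes_df)), function(i) {
    gid <- genes_df$ID[i]
    minus <- genes_df$strand[i] == "-"
    sub <- feats[feats$gene == gid & feats$seqnames == genes_df$seqnames[i], ]
    cds <- part_tbl(sub[sub$type == "CDS", ], minus)
    u5 <- part_tbl(sub[sub$type == "five_prime_UTR", ], minus)
    u3 <- part_tbl(sub[sub$type == "three_prime_UTR", ], minus)
    tibble(
      gene_id = gid,
      chromosome = genes_df$seqnames[i],
      strand = genes_df$strand[i],
      cds_parts = list(cds), utr5_parts = list(u5), utr3_parts = list(u3),
      cds_length = sum(cds$end - cds$start)
    )
  })
  genes$compartment <- unname(comp_map[genes$chromosome])
  genes$usable <- genes$cds_length > 0 & genes$cds_length %% 3 == 0
  bad <- genes$gene_id[genes$cds_length > 0 & genes$cds_length %% 3 != 0]
  if (length(bad) > 0) {
    warnf("joined CDS length not a multiple of 3; excluded from start-codon analyses: %s",
          paste(bad, collapse = ", "))
  }

  chromosomes <- tibble(
    chromosome = chrom_names,
    length = as.integer(unname(lens)),
    compartment = unname(comp_map[chrom_names])
  )
  new_genome_annotation(chromosomes,
                        select(genes, "gene_id", "chromosome", "strand",
                               "compartment", "cds_parts", "utr5_parts",
                               "utr3_parts", "cds_length", "usable"))
}

GenomeInfoDb_seqlengths <- function(gr) GenomeInfoDb::seqlengths(gr)

#' Write a genome annotation back to GFF3
#'
#' Emits gene, mRNA, CDS and UTR features with `##sequence-region` pragmas.
#' Round-trips through [read_annotation()] preserve all intervals exactly.
#'
#' @param annotation A `genome_annotation`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_annotation <- function(annotation, file) {
  g <- annotation$genes
  rows <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
    parts <- function(tbl, type) {
      if (nrow(tbl) == 0) return(NULL)
      tibble(start = tbl$start + 1L, end = tbl$end, type = type)
    }
    cds <- g$cds_parts[[i]]; u5 <- g$utr5_parts[[i]]; u3 <- g$utr3_parts[[i]]
    all_parts <- bind_rows(parts(cds, "CDS"),
                           parts(u5, "five_prime_UTR"),
                           parts(u3, "three_prime_UTR"))
    gid <- g$gene_id[i]; tid <- paste0(gid, ".t1")
    span <- range(c(all_parts$start, all_parts$end))
    bind_rows(
      tibble(start = span[1], end = span[2], type = "gene",
             ID = gid, Parent = NA_character_),
      tibble(start = span[1], end = span[2], type = "mRNA",
             ID = tid, Parent = gid),
      mutate(all_parts, ID = NA_character_, Parent = tid)
    ) |>
      mutate(seqnames = g$chromosome[i], strand = g$strand[i])
  })
  gr <- GenomicRanges::GRanges(
    seqnames = rows$seqnames,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand,
    type = rows$type, ID = rows$ID, Parent = rows$Parent,
    phase = ifelse(rows$type == "CDS", 0L, NA_integer_),
    seqinfo = GenomeInfoDb_seqinfo(annotation$chromosomes)
  )
  rtracklayer::export(gr, file, format = "gff3")
  # ensure ##sequence-region pragmas so chromosome lengths round-trip
  lines <- readLines(file)
  if (!any(startsWith(lines, "##sequence-region"))) {
    pragmas <- sprintf("##sequence-region %s 1 %d",
                       annotation$chromosomes$chromosome,
                       annotation$chromosomes$length)
    writeLines(append(lines, pragmas, after = 1L), file)
  }
  invisible(file)
}

GenomeInfoDb_seqinfo <- function(chromosomes) {
  GenomeInfoDb::Seqinfo(seqnames = chromosomes$chromosome,
                        seqlengths = as.integer(chromosomes$length))
}

# ---- per-position coverage tracks ------------------------------------------

#' Write a per-position coverage vector as bedGraph
#'
#' Position `i` of the vector is 0-based reference position `i - 1`; adjacent
#' equal nonzero values are merged into intervals and zero runs are omitted.
#'
#' @param coverage Non-negative numeric vector covering the whole reference.
#' @param file Output path.
#' @param ref_name Reference (chromosome/rRNA species) name.
#' @return `file`, invisibly.
#' @export
write_tracks <- function(coverage, file, ref_name = "ref") {
  if (any(coverage < 0)) stopf("coverage values must be non-negative")
  r <- rle(as.vector(coverage))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  gr <- GenomicRanges::GRanges(
    seqnames = rep(ref_name, sum(keep)),
    ranges = IRanges::IRanges(starts[keep], ends[keep]),
    score = r$values[keep]
  )
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' Read a bedGraph coverage track back into a vector
#'
#' @param file bedGraph path.
#' @param ref_length Length of the reference; positions absent from the file
#'   are zero-filled.
#' @return Numeric vector of length `ref_length`.
#' @export
read_tracks <- function(file, ref_length) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  out <- numeric(ref_length)
  if (length(gr) > 0) {
    st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
    for (i in seq_along(gr)) out[st[i]:en[i]] <- gr$score[i]
  }
  out
}

# ---- gene-model coordinate helpers -----------------------------------------

# Genomic position (0-based) of the first nucleotide of the start codon.
start_codon_position <- function(gene_row) {
  cds <- gene_row$cds_parts[[1]]
  if (nrow(cds) == 0) return(NA_integer_)
  if (gene_row$strand == "+") cds$start[1] else cds$end[1] - 1L
}

# Map genomic positions to 0-based coordinates within the joined CDS of one
# gene (NA outside the CDS). `gpos` is a vector.
genomic_to_cds <- function(gene_row, gpos) {
  cds <- gene_row$cds_parts[[1]]
  if (nrow(cds) == 0) return(rep(NA_integer_, length(gpos)))
  widths <- cds$end - cds$start
  offs <- cumsum(c(0L, widths))[seq_len(nrow(cds))]
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(cds))) {
    inside <- gpos >= cds$start[i] & gpos < cds$end[i]
    if (!any(inside)) next
    out[inside] <- if (gene_row$strand == "+") {
      offs[i] + (gpos[inside] - cds$start[i])
    } else {
      offs[i] + (cds$end[i] - 1L - gpos[inside])
    }
  }
  out
}

# Long table of all annotated feature intervals (used by categorisation and
# by the feature-partition invariant test).
feature_intervals <- function(annotation) {
  g <- annotation$genes
  purrr::map_dfr(seq_len(nrow(g)), function(i) {
    one <- function(tbl, feature) {
      if (nrow(tbl) == 0) return(NULL)
      tibble(gene_id = g$gene_id[i], chromosome = g$chromosome[i],
             strand = g$strand[i], feature = feature,
             start = tbl$start, end = tbl$end)
    }
    bind_rows(one(g$cds_parts[[i]], "CDS"),
              one(g$utr5_parts[[i]], "UTR5"),
              one(g$utr3_parts[[i]], "UTR3"))
  })
}

# Category a read span implies under the majority-overlap rule, given its
# position in transcript coordinates relative to one gene model
# (0 = first nt of CDS). Shared by the generator truth table; the pipeline
# recomputes categories independently from genomic interval overlap.
classify_span <- function(rel5, len, utr5_len, cds_len, utr3_len,
                          cds_overlap = 0.5) {
  a <- rel5; b <- rel5 + len
  f_cds <- interval_overlap(a, b, 0L, cds_len) / len
  f_u5 <- interval_overlap(a, b, -utr5_len, 0L) / len
  f_u3 <- interval_overlap(a, b, cds_len, cds_len + utr3_len) / len
  f_out <- 1 - f_cds - f_u5 - f_u3
  ifelse(f_cds >= cds_overlap, "CDS",
         ifelse(f_u5 >= pmax(f_u3, f_out), "UTR5",
                ifelse(f_u3 >= f_out, "UTR3", "intergenic")))
}
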