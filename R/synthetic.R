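# Synthetic references and footprint libraries. Everything is seeded: the
# same configuration always yields byte-identical FASTQ and truth tables.

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_cds <- function(n_internal_codons) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, STOP_CODONS)
  paste0("ATG",
         paste(sample(sense, n_internal_codons, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1))
}

#' Build toy reference sequences, annotation and rRNA references
#'
#' Constructs a three-compartment toy genome (nuclear chromosome with
#' UTR-flanked single-part CDS genes on both strands; a chloroplast
#' chromosome whose genes sit in polycistron-like clusters separated by very
#' short spacers; a small mitochondrial chromosome) plus the four dominant
#' plant rRNA species (Nu_25S, Nu_18S, Nu_5.8S, Cp_23S; lengths scaled down
#' for desk use). Every CDS starts with ATG, ends with a stop codon and has
#' length divisible by 3. Per-gene lognormal expression weights and the rRNA
#' contaminant fragment specification are generated alongside.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, `genome.fa`, `rrna.fa`,
#'   `annotation.gff3`, `fragments.tsv` and `gene_weights.tsv` are written
#'   there (deterministically for a fixed seed).
#' @return A `toy_references` list: `genome` (tibble seq_id/sequence/length),
#'   `annotation` (`genome_annotation`), `rrna` (rRNA reference tibble),
#'   `fragments` (fragment spec), `gene_weights`.
#' @export
build_toy_references <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    nuc <- build_chromosome(
      "chrN", "NG", config$n_nuclear_genes, codon_range = c(60L, 150L),
      utr_range = c(30L, 60L), spacer_range = c(100L, 200L),
      minus_prob = 0.3, cluster = FALSE)
    if (!is.null(config$nuclear_chrom_len) &&
        nchar(nuc$sequence) > config$nuclear_chrom_len) {
      stopf("infeasible packing: %d nuclear genes need %d nt > limit %d",
            config$n_nuclear_genes, nchar(nuc$sequence),
            config$nuclear_chrom_len)
    }
    chl <- build_chromosome(
      "chrC", "CG", config$n_chloroplast_genes, codon_range = c(40L, 120L),
      utr_range = NULL, spacer_range = c(60L, 150L),
      minus_prob = 0.3, cluster = TRUE, cluster_spacer = c(2L, 9L))
    mit <- build_chromosome(
      "chrM", "MG", config$n_mito_genes, codon_range = c(60L, 100L),
      utr_range = NULL, spacer_range = c(80L, 150L),
      minus_prob = 0.3, cluster = FALSE)

    genome <- tibble(
      seq_id = c("chrN", "chrC", "chrM"),
      sequence = c(nuc$sequence, chl$sequence, mit$sequence),
      length = nchar(c(nuc$sequence, chl$sequence, mit$sequence))
    )
    genes <- bind_rows(nuc$genes, chl$genes, mit$genes)
    comp_map <- c(chrN = "nuclear", chrC = "chloroplast", chrM = "mitochondrial")
    genes$compartment <- unname(comp_map[genes$chromosome])
    genes$usable <- TRUE
    annotation <- new_genome_annotation(
      tibble(chromosome = genome$seq_id, length = genome$length,
             compartment = unname(comp_map[genome$seq_id])),
      genes)

    rrna_len <- c(Nu_25S = 1200L, Nu_18S = 900L, Nu_5.8S = 160L, Cp_23S = 1100L)
    rrna <- tibble(
      species_id = names(rrna_len),
      sequence = vapply(rrna_len, random_dna, character(1)),
      length = unname(rrna_len),
      compartment = c("nuclear", "nuclear", "nuclear", "chloroplast")
    )

    weights <- tibble(
      gene_id = genes$gene_id,
      weight = stats::rlnorm(nrow(genes), 0, config$expression_sdlog)
    )
  })
  fragments <- config$rrna_fragments %||%
    default_fragments(rrna, seed = config$seed)
  bad <- !fragments$species_id %in% rrna$species_id
  if (any(bad)) {
    stopf("fragment species not in rRNA references: %s",
          paste(unique(fragments$species_id[bad]), collapse = ", "))
  }
  refs <- structure(list(genome = genome, annotation = annotation,
                         rrna = rrna, fragments = fragments,
                         gene_weights = weights),
                    class = "toy_references")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genome, file.path(dir, "genome.fa"))
    write_fasta(rrna, file.path(dir, "rrna.fa"))
    write_annotation(annotation, file.path(dir, "annotation.gff3"))
    readr::write_tsv(fragments, file.path(dir, "fragments.tsv"))
    readr::write_tsv(weights, file.path(dir, "gene_weights.tsv"))
  }
  refs
}

#' @export
print.toy_references <- function(x, ...) {
  cat(sprintf("<toy_references> %d chromosomes, %d genes, %d rRNA species, %d fragments\n",
              nrow(x$genome), nrow(x$annotation$genes), nrow(x$rrna),
              nrow(x$fragments)))
  invisible(x)
}

# One chromosome with packed single-part CDS genes. Transcript-orientation
# blocks are reverse-complemented for minus-strand genes so each read is an
# exact substring of the plus strand.
build_chromosome <- function(chrom, prefix, n_genes, codon_range, utr_range,
                             spacer_range, minus_prob, cluster,
                             cluster_spacer = c(2L, 9L), flank = 200L) {
  segs <- list(random_dna(flank))
  pos <- flank
  rows <- vector("list", n_genes)
  i <- 1L
  while (i <= n_genes) {
    size <- if (cluster) min(sample(1:4, 1), n_genes - i + 1L) else 1L
    strand <- sample(c("+", "-"), 1, prob = c(1 - minus_prob, minus_prob))
    for (k in seq_len(size)) {
      u5 <- if (is.null(utr_range)) 0L else sample(utr_range[1]:utr_range[2], 1)
      u3 <- if (is.null(utr_range)) 0L else sample(utr_range[1]:utr_range[2], 1)
      cds_len <- 3L * (sample(codon_range[1]:codon_range[2], 1) + 2L)
      tx <- paste0(if (u5 > 0) random_dna(u5) else "",
                   random_cds((cds_len - 6L) / 3L),
                   if (u3 > 0) random_dna(u3) else "")
      total <- u5 + cds_len + u3
      if (strand == "+") {
        cds <- tibble(start = pos + u5, end = pos + u5 + cds_len)
        utr5 <- if (u5 > 0) tibble(start = pos, end = pos + u5) else tibble(start = integer(), end = integer())
        utr3 <- if (u3 > 0) tibble(start = pos + u5 + cds_len, end = pos + total) else tibble(start = integer(), end = integer())
        segs[[length(segs) + 1L]] <- tx
      } else {
        cds <- tibble(start = pos + u3, end = pos + u3 + cds_len)
        utr5 <- if (u5 > 0) tibble(start = pos + u3 + cds_len, end = pos + total) else tibble(start = integer(), end = integer())
        utr3 <- if (u3 > 0) tibble(start = pos, end = pos + u3) else tibble(start = integer(), end = integer())
        segs[[length(segs) + 1L]] <- revcomp(tx)
      }
      rows[[i]] <- tibble(
        gene_id = sprintf("%s%03d", prefix, i), chromosome = chrom,
        strand = strand, cds_parts = list(cds),
        utr5_parts = list(utr5), utr3_parts = list(utr3),
        cds_length = cds_len)
      pos <- pos + total
      i <- i + 1L
      if (cluster && k < size) {
        sp <- sample(cluster_spacer[1]:cluster_spacer[2], 1)
        segs[[length(segs) + 1L]] <- random_dna(sp)
        pos <- pos + sp
      }
    }
    sp <- sample(spacer_range[1]:spacer_range[2], 1)
    segs[[length(segs) + 1L]] <- random_dna(sp)
    pos <- pos + sp
  }
  segs[[length(segs) + 1L]] <- random_dna(flank)
  list(sequence = paste(segs, collapse = ""), genes = bind_rows(rows))
}
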