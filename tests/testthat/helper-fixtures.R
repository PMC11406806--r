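# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Default stated-world references (79 chloroplast genes, 24 fragments).
default_refs <- function() {
  fixture("default_refs", function() build_toy_references(sim_config()))
}

# Two replicate libraries under the default world, aligned and categorized.
default_libs <- function() {
  fixture("default_libs", function() {
    cfg <- sim_config(n_reads = 30000L)
    refs <- default_refs()
    sims <- lapply(1:2, function(i)
      simulate_library(cfg, refs, seed = 100 + i,
                       library_id = paste0("L", i)))
    aln <- dplyr::bind_rows(lapply(sims, function(s) {
      a <- toy_align(s, refs)
      a$library_id <- s$library_id
      a
    }))
    aln <- categorize_reads(aln, refs$annotation, refs$rrna, quiet = TRUE)
    list(aln = aln, truth = dplyr::bind_rows(lapply(sims, `[[`, "truth")),
         sims = sims)
  })
}

# References rebuilt with a custom fragment specification.
default_refs_with_fragments <- function(fr) {
  build_toy_references(sim_config(rrna_fragments = fr, frag_background = 0))
}

# Hand-built annotation: one plus-strand gene with UTRs, one minus-strand
# CDS-only gene, on a 1000-nt chromosome.
toy_annotation <- function() {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"),
    chromosome = "chr1",
    strand = c("+", "-"),
    compartment = "nuclear",
    cds_parts = list(tibble::tibble(start = 130L, end = 430L),
                     tibble::tibble(start = 600L, end = 900L)),
    utr5_parts = list(tibble::tibble(start = 100L, end = 130L),
                      tibble::tibble(start = integer(), end = integer())),
    utr3_parts = list(tibble::tibble(start = 430L, end = 460L),
                      tibble::tibble(start = integer(), end = integer())),
    cds_length = 300L,
    usable = TRUE
  )
  riboclean:::new_genome_annotation(
    tibble::tibble(chromosome = "chr1", length = 1000L,
                   compartment = "nuclear"),
    genes)
}

toy_rrna <- function(len = 300L) {
  tibble::tibble(species_id = "Nu_18S",
                 sequence = strrep("ACGT", ceiling(len / 4)) |>
                   substr(1, len),
                 length = len, compartment = "nuclear")
}

# Quick alignment-tibble builder.
make_aln <- function(reference, start, end, strand = "+",
                     library_id = "lib1", read_id = NULL) {
  n <- max(length(reference), length(start), length(end), length(strand))
  tibble::tibble(
    read_id = read_id %||% sprintf("r%04d", seq_len(n)),
    reference = rep_len(reference, n),
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)),
    strand = rep_len(strand, n),
    length = as.integer(rep_len(end, n) - rep_len(start, n)),
    library_id = rep_len(library_id, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
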