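# Generator: reference construction, library statistics, determinism and
# the toy aligner.

test_that("toy references have well-formed CDS genes in every compartment", {
  refs <- build_toy_references(sim_config(n_nuclear_genes = 20L, seed = 3L))
  genes <- refs$annotation$genes
  expect_equal(sum(genes$compartment == "nuclear"), 20L)
  expect_equal(sum(genes$compartment == "chloroplast"), 79L)
  expect_true(all(genes$cds_length %% 3 == 0))

  seqs <- setNames(refs$genome$sequence, refs$genome$seq_id)
  for (i in seq_len(nrow(genes))) {
    cds <- genes$cds_parts[[i]]
    s <- unname(substring(seqs[genes$chromosome[i]], cds$start + 1L, cds$end))
    if (genes$strand[i] == "-") s <- riboclean:::revcomp(s)
    expect_equal(substr(s, 1, 3), "ATG")
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in% c("TAA", "TAG", "TGA"))
  }
})

test_that("chloroplast clusters contain polycistron-like short spacers", {
  genes <- default_refs()$annotation$genes
  chl <- genes[genes$compartment == "chloroplast", ]
  bounds <- t(vapply(chl$cds_parts, function(p) c(p$start[1], p$end[1]),
                     integer(2)))
  gaps <- sort(bounds[, 1])[-1] - sort(bounds[, 2])[-nrow(bounds)]
  expect_true(any(gaps <= 9))
})

test_that("reference construction and simulation are seed-deterministic", {
  cfg <- sim_config(n_reads = 2000L, n_nuclear_genes = 8L,
                    n_chloroplast_genes = 10L, n_mito_genes = 2L, seed = 11L)
  r1 <- build_toy_references(cfg)
  r2 <- build_toy_references(cfg)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$fragments, r2$fragments)

  l1 <- simulate_library(cfg, r1, seed = 4L)
  l2 <- simulate_library(cfg, r1, seed = 4L)
  expect_identical(l1$reads, l2$reads)
  expect_identical(l1$truth, l2$truth)
  l3 <- simulate_library(cfg, r1, seed = 5L)
  expect_false(identical(l1$reads$sequence, l3$reads$sequence))

  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(l1, f1); write_fastq(l2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("infeasible gene packing errors", {
  cfg <- sim_config(n_nuclear_genes = 40L, nuclear_chrom_len = 1000L)
  expect_error(build_toy_references(cfg), "infeasible packing")
})

test_that("optimal-digestion geometry puts every 5' end 12 nt before an in-frame codon", {
  cfg <- sim_config(
    n_reads = 2000L, seed = 21L,
    composition = c(rRNA = 0, nuclear_CDS = 1, chloroplast_CDS = 0,
                    UTR = 0, intergenic = 0, mitochondrial = 0),
    frame1_prob = c(nuclear = 1, chloroplast = 1, mitochondrial = 1),
    cyto_size = list(mean = 28, sd = 0, minor_min = 20, minor_max = 24,
                     minor_weight = 0, min = 28, max = 28))
  refs <- default_refs()
  lib <- simulate_library(cfg, refs, seed = 21L)
  tr <- lib$truth
  expect_true(all(tr$length == 28L))
  expect_true(all(tr$d5 == 12L))
  genes <- refs$annotation$genes
  for (i in sample(nrow(tr), 200)) {
    g <- genes[genes$gene_id == tr$gene_id[i], ]
    cds_pos <- riboclean:::genomic_to_cds(g, tr$p_site[i])
    expect_equal(cds_pos %% 3L, 0L)     # in-frame P-site
    p5 <- if (tr$strand[i] == "+") tr$start[i] else tr$end[i] - 1L
    d5 <- abs(tr$p_site[i] - p5)
    expect_equal(d5, 12L)
  }
})

test_that("library composition matches the configured fractions", {
  libs <- default_libs()
  tr <- libs$truth[libs$truth$library_id == "L1", ]
  p <- sim_config()$composition[["rRNA"]]
  n <- nrow(tr)
  sigma <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(tr$source == "rRNA") - p), 3 * sigma)
})

test_that("fragment counts fall inside exact binomial 99% bands", {
  fr <- tibble::tibble(fragment_id = c("F1", "F2", "F3"),
                       species_id = "Nu_25S",
                       start = c(100L, 300L, 500L),
                       end = c(135L, 332L, 540L),
                       abundance = c(0.5, 0.3, 0.2))
  cfg <- sim_config(n_reads = 10000L, seed = 8L,
                    composition = c(rRNA = 1, nuclear_CDS = 0,
                                    chloroplast_CDS = 0, UTR = 0,
                                    intergenic = 0, mitochondrial = 0),
                    rrna_fragments = fr, frag_background = 0)
  lib <- simulate_library(cfg, default_refs_with_fragments(fr), seed = 8L)
  counts <- table(lib$truth$fragment_id)
  for (i in 1:3) {
    ci <- stats::qbinom(c(0.005, 0.995), 10000L, fr$abundance[i])
    expect_gte(counts[[fr$fragment_id[i]]], ci[1])
    expect_lte(counts[[fr$fragment_id[i]]], ci[2])
  }
})

test_that("size histograms converge to the configured mixtures (KS <= 0.02)", {
  cfg <- sim_config(
    n_reads = 50000L, seed = 31L,
    composition = c(rRNA = 0, nuclear_CDS = 0.5, chloroplast_CDS = 0.5,
                    UTR = 0, intergenic = 0, mitochondrial = 0))
  lib <- simulate_library(cfg, default_refs(), seed = 31L)
  tr <- lib$truth

  # independent model pmf for the cytosolic mixture
  m <- cfg$cyto_size
  lens <- m$min:m$max
  pnorm_disc <- function(l, mu, sd, lo, hi) {
    p <- stats::pnorm(l + 0.5, mu, sd) - stats::pnorm(l - 0.5, mu, sd)
    p[l == lo] <- stats::pnorm(lo + 0.5, mu, sd)
    p[l == hi] <- 1 - stats::pnorm(hi - 0.5, mu, sd)
    p
  }
  p_major <- pnorm_disc(lens, m$mean, m$sd, m$min, m$max)
  p_minor <- as.numeric(lens >= m$minor_min & lens <= m$minor_max) /
    (m$minor_max - m$minor_min + 1)
  pmf_cyto <- (1 - m$minor_weight) * p_major + m$minor_weight * p_minor

  obs <- tr$length[tr$source == "nuclear_CDS"]
  ecdf_cyto <- cumsum(tabulate(factor(obs, levels = lens),
                               nbins = length(lens))) / length(obs)
  expect_lt(max(abs(ecdf_cyto - cumsum(pmf_cyto))), 0.02)

  # chloroplast two-component mixture
  cm <- cfg$chloro_size
  lens_c <- cm$small[1]:cm$large[2]
  comp_pmf <- function(range) {
    p <- pnorm_disc(lens_c, mean(range), diff(range) / 4, range[1], range[2])
    p[lens_c < range[1] | lens_c > range[2]] <- 0
    p / sum(p)
  }
  pmf_chl <- cm$small_weight * comp_pmf(cm$small) +
    (1 - cm$small_weight) * comp_pmf(cm$large)
  obs_c <- tr$length[tr$source == "chloroplast_CDS"]
  ecdf_chl <- cumsum(tabulate(factor(obs_c, levels = lens_c),
                              nbins = length(lens_c))) / length(obs_c)
  expect_lt(max(abs(ecdf_chl - cumsum(pmf_chl))), 0.02)
})

test_that("truth P-sites always lie inside the source CDS", {
  libs <- default_libs()
  tr <- libs$truth
  coding <- tr[!is.na(tr$p_site), ]
  genes <- default_refs()$annotation$genes
  for (g in unique(coding$gene_id)) {
    gi <- genes[genes$gene_id == g, ]
    pos <- riboclean:::genomic_to_cds(gi, coding$p_site[coding$gene_id == g])
    expect_false(anyNA(pos))
  }
})

test_that("PCR duplication expands reads and keeps one truth row per read", {
  cfg <- sim_config(n_reads = 3000L, pcr_dup_rate = 0.5, seed = 13L)
  lib <- simulate_library(cfg, default_refs(), seed = 13L)
  expect_gt(nrow(lib$reads), 3000L)
  expect_equal(nrow(lib$truth), nrow(lib$reads))
  expect_true("template_id" %in% names(lib$truth))
  expect_gt(max(table(lib$truth$template_id)), 1L)
})

test_that("toy_align recovers the true placement of every read", {
  libs <- default_libs()
  aln <- libs$aln
  m <- dplyr::inner_join(libs$truth, aln,
                         by = c("read_id", "library_id"),
                         suffix = c(".t", ".a"))
  expect_equal(nrow(m), nrow(libs$truth))
  expect_identical(m$reference.t, m$reference.a)
  expect_identical(m$start.t, m$start.a)
  expect_identical(m$end.t, m$end.a)
  expect_identical(m$strand.t, m$strand.a)
})

test_that("rRNA references take precedence over identical genomic matches", {
  frag <- "ACGTTGCAAGGTTCCAAGGTACGATCGATT"
  genome <- tibble::tibble(
    seq_id = "chr1",
    sequence = paste0(strrep("A", 50), frag, strrep("C", 50)),
    length = 130L)
  rrna <- tibble::tibble(
    species_id = "Nu_18S",
    sequence = paste0(strrep("G", 20), frag, strrep("T", 20)),
    length = 70L, compartment = "nuclear")
  reads <- tibble::tibble(read_id = "r1", sequence = frag)
  out <- toy_align(reads, list(genome = genome, rrna = rrna))
  expect_equal(out$reference, "Nu_18S")
  expect_equal(out$start, 20L)
})

test_that("corrupted reads come back unmapped and counted", {
  refs <- default_refs()
  reads <- tibble::tibble(read_id = c("good", "bad"),
                          sequence = c(substr(refs$rrna$sequence[1], 11, 40),
                                       strrep("ACGTN", 6)))
  expect_message(out <- toy_align(reads, refs), "1 read\\(s\\) unmapped")
  expect_equal(attr(out, "n_unmapped"), 1L)
  expect_true(is.na(out$reference[out$read_id == "bad"]))
  expect_equal(out$reference[out$read_id == "good"], "Nu_25S")
})
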