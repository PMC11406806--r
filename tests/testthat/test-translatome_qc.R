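# Frame quantification, metagene, size distributions, count correlations
# and in-silico size splitting.

# psite-table builder over toy_annotation()'s gene gA (CDS [130, 430)).
make_psites <- function(cds_pos, length = 28L, gene_id = "gA",
                        library_id = "lib1") {
  n <- length(cds_pos)
  tibble::tibble(
    library_id = rep_len(library_id, n),
    read_id = sprintf("p%04d", seq_len(n)),
    chromosome = "chr1", gene_id = rep_len(gene_id, n),
    compartment = "nuclear", strand = "+",
    length = rep_len(length, n),
    p_site = 130L + as.integer(cds_pos),
    cds_pos = as.integer(cds_pos),
    codon_index = as.integer(cds_pos) %/% 3L,
    frame = as.integer(cds_pos) %% 3L + 1L)
}

test_that("frame fractions are exact on constructed P-sites", {
  ann <- toy_annotation()
  ps <- make_psites(c(rep(3L, 60), rep(4L, 25), rep(5L, 15)))
  fr <- frame_fractions(ps, ann)
  expect_equal(fr$fraction, c(0.60, 0.25, 0.15))
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-9)

  # all P-sites on internal frame-1 codons -> frame 1 fraction 1.0
  fr1 <- frame_fractions(make_psites(seq(3L, 290L, by = 3L)), ann)
  expect_equal(fr1$fraction[fr1$frame == 1], 1)

  # first and last codons are excluded
  boundary <- make_psites(c(0L, 1L, 2L, 297L, 298L, 299L))
  expect_error(frame_fractions(boundary, ann), "no CDS-internal P-sites")
})

test_that("frame fractions are invariant under read order permutation", {
  ann <- toy_annotation()
  ps <- make_psites(c(rep(3L, 30), rep(7L, 10), rep(11L, 12)))
  shuffled <- withr::with_seed(3, ps[sample(nrow(ps)), ])
  expect_equal(frame_fractions(ps, ann), frame_fractions(shuffled, ann))
})

test_that("metagene of a single P-site at the start codon is a delta at 0", {
  ann <- toy_annotation()
  genes <- ann$genes[ann$genes$gene_id == "gA", ]
  ann1 <- riboclean:::new_genome_annotation(ann$chromosomes, genes)
  mg <- metagene(make_psites(0L), ann1, window = 20L)
  expect_equal(mg$density[mg$position == 0], 300)  # 1 / (1/300)
  expect_true(all(mg$density[mg$position != 0] == 0))
  expect_equal(mg$n_genes[1], 1L)
})

test_that("periodic input shows lag-3 autocorrelation dominance, uniform input none", {
  ann <- toy_annotation()
  genes <- ann$genes[ann$genes$gene_id == "gA", ]
  ann1 <- riboclean:::new_genome_annotation(ann$chromosomes, genes)

  periodic <- make_psites(rep(seq(0L, 99L) * 3L, times = rep(c(5L, 1L), 50)))
  mgp <- metagene(periodic, ann1, window = 45L)
  inside <- mgp$density[mgp$position >= 0]
  ac <- stats::acf(inside, lag.max = 3, plot = FALSE)$acf[2:4]
  expect_gt(ac[3], ac[1])
  expect_gt(ac[3], ac[2])

  uniform <- make_psites(0:299)
  mgu <- metagene(uniform, ann1, window = 45L)
  inside_u <- mgu$density[mgu$position >= 0]
  expect_equal(stats::sd(inside_u), 0)   # flat: no frame preference at all
})

test_that("genes whose window overlaps a neighbouring CDS are excluded", {
  # two genes 10 nt apart on the same strand
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chromosome = "chr1", strand = "+",
    compartment = "chloroplast",
    cds_parts = list(tibble::tibble(start = 100L, end = 400L),
                     tibble::tibble(start = 410L, end = 710L)),
    utr5_parts = list(tibble::tibble(start = integer(), end = integer()),
                      tibble::tibble(start = integer(), end = integer())),
    utr3_parts = list(tibble::tibble(start = integer(), end = integer()),
                      tibble::tibble(start = integer(), end = integer())),
    cds_length = 300L, usable = TRUE)
  ann <- riboclean:::new_genome_annotation(
    tibble::tibble(chromosome = "chr1", length = 1000L,
                   compartment = "chloroplast"), genes)
  # g2's start-codon window reaches into g1's CDS -> g2 is excluded
  ps2 <- make_psites(3L, gene_id = "g2")
  ps2$p_site <- 413L
  expect_error(metagene(ps2, ann, window = 50L), "no usable P-sites")

  ps1 <- make_psites(3L, gene_id = "g1")
  ps1$p_site <- 103L
  mg <- metagene(ps1, ann, window = 50L)
  expect_equal(mg$n_genes[1], 1L)
  expect_equal(unname(attr(mg, "excluded")["window_overlap"]), 1L)

  # a window small enough to stay inside the spacer keeps both genes
  mg2 <- metagene(ps2, ann, window = 4L)
  expect_equal(unname(attr(mg2, "excluded")["window_overlap"]), 0L)
})

test_that("size distributions split by compartment group and conserve counts", {
  libs <- default_libs()
  sd_ <- size_distribution(libs$aln)
  expect_setequal(unique(sd_$group),
                  c("rRNA", "nuclear", "chloroplast", "mitochondrial"))
  expect_equal(sum(sd_$n), sum(libs$aln$category != "unmapped"))

  nuc <- dplyr::filter(sd_, .data$group == "nuclear",
                       .data$library_id == "L1")
  expect_equal(nuc$length[which.max(nuc$n)], 29L)

  bi <- attr(sd_, "bimodality")
  expect_true(all(bi$peak_small >= 20 & bi$peak_small <= 30))
  expect_true(all(bi$peak_large >= 31 & bi$peak_large <= 40))
  expect_true(all(bi$valley_to_peak < 1))

  # chloroplast histogram has a local maximum in each configured range
  chl <- dplyr::filter(sd_, .data$group == "chloroplast",
                       .data$library_id == "L1")
  h <- setNames(rep(0L, 21), 20:40)
  h[as.character(chl$length[chl$length %in% 20:40])] <-
    chl$n[chl$length %in% 20:40]
  expect_gt(max(h[1:11]), h[["31"]])   # small-mode peak above the boundary
  expect_gt(max(h[12:21]), h[["30"]])  # large-mode peak above the boundary

  empty <- size_distribution(libs$aln[libs$aln$category == "rRNA", ])
  expect_setequal(unique(empty$group), "rRNA")
})

test_that("the low-count filter excludes exactly the intended genes", {
  counts <- tibble::tibble(
    gene_id = rep(sprintf("g%d", 1:5), 2),
    library_id = rep(c("A", "B"), each = 5),
    count = c(9L, 10L, 11L, 3L, 100L,
              50L, 50L, 50L, 50L, 50L))
  suppressWarnings(cc <- cds_correlation(counts, min_count = 10L))
  ab <- dplyr::filter(cc, .data$library_a == "A", .data$library_b == "B")
  expect_equal(ab$n_genes, 3L)   # g1 (9) and g4 (3) excluded
  aa <- dplyr::filter(cc, .data$library_a == "A", .data$library_b == "A")
  expect_equal(aa$rho, 1)
  # symmetric
  ba <- dplyr::filter(cc, .data$library_a == "B", .data$library_b == "A")
  expect_equal(ab$rho, ba$rho)
})

test_that("too few surviving genes yields NA with a warning", {
  counts <- tibble::tibble(gene_id = rep(c("g1", "g2"), 2),
                           library_id = rep(c("A", "B"), each = 2),
                           count = c(100L, 1L, 100L, 1L))
  w <- testthat::capture_warnings(cc <- cds_correlation(counts))
  expect_match(w, "< 3 genes", all = FALSE)
  ab <- dplyr::filter(cc, .data$library_a == "A", .data$library_b == "B")
  expect_true(is.na(ab$rho))
})

test_that("independent replicates correlate strongly over CDS counts", {
  refs <- default_refs()
  cfg <- sim_config(
    n_reads = 30000L, seed = 71L,
    composition = c(rRNA = 0.1, nuclear_CDS = 0.8, chloroplast_CDS = 0.05,
                    UTR = 0.025, intergenic = 0.02, mitochondrial = 0.005))
  aln <- dplyr::bind_rows(lapply(1:2, function(i) {
    lib <- simulate_library(cfg, refs, seed = 710L + i,
                            library_id = paste0("R", i))
    a <- toy_align(lib, refs)
    a$library_id <- paste0("R", i)
    a
  }))
  aln <- categorize_reads(aln, refs$annotation, refs$rrna, quiet = TRUE)
  cc <- cds_correlation(count_cds(aln, refs$annotation))
  r12 <- dplyr::filter(cc, .data$library_a == "R1", .data$library_b == "R2")
  expect_gte(r12$rho, 0.95)
})

test_that("size splitting: class counts correlate when size is gene-independent", {
  libs <- default_libs()
  refs <- default_refs()
  chl <- dplyr::filter(libs$aln, .data$compartment == "chloroplast",
                       .data$category == "CDS")
  ss <- size_split_analysis(chl, refs$annotation)
  expect_gte(ss$correlation, 0.9)
  in_class <- chl$length >= 20L & chl$length <= 40L
  expect_equal(sum(ss$counts$small) + sum(ss$counts$large), sum(in_class))
})

test_that("size splitting flags an empty class and detects start-proximal bias", {
  ann <- toy_annotation()
  all_small <- make_aln("chr1", 200L, 222L, read_id = sprintf("s%02d", 1:20))
  all_small$category <- "CDS"; all_small$gene_id <- "gA"
  all_small$compartment <- "nuclear"
  expect_warning(ss <- size_split_analysis(all_small, ann),
                 "class is empty")
  expect_true(is.na(ss$correlation))

  # small reads piled at the start, large reads spread along the CDS
  small_reads <- make_aln("chr1", 130L + rep(0:9, 5), 152L + rep(0:9, 5),
                          read_id = sprintf("sm%03d", 1:50))
  large_reads <- make_aln("chr1", 130L + seq(0L, 264L, by = 6L),
                          165L + seq(0L, 264L, by = 6L),
                          read_id = sprintf("lg%03d", 1:45))
  aln <- dplyr::bind_rows(small_reads, large_reads)
  aln$category <- "CDS"; aln$gene_id <- "gA"; aln$compartment <- "nuclear"
  ss2 <- size_split_analysis(aln, ann)
  en <- ss2$enrichment
  expect_gt(en$ratio[en$class == "small"], 1)
  expect_gt(en$ratio[en$class == "small"], en$ratio[en$class == "large"])
  expect_error(size_split_analysis(aln, ann, small = c(20L, 31L),
                                   large = c(31L, 40L)), "disjoint")
})
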