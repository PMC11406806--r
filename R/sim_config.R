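# Simulation configuration: the stated world the synthetic libraries live in.

#' Build a simulation configuration
#'
#' Defaults emulate an undepleted, optimally digested plant Ribo-seq library:
#' 85% rRNA contamination dominated by a couple of dozen recurrent fragments,
#' cytosolic footprints around 29 nt with a minor 20-24 nt (empty-A-site)
#' mode, bimodal chloroplast footprints (small 20-30 nt / large 31-40 nt),
#' ~58% of P-sites in frame 1, 5'-anchored cytosolic P-site geometry
#' (d5 = 12 nt) and 3'-anchored chloroplast geometry (d3 = 15 nt for large,
#' 7 nt for small footprints). `seed` fixes all randomness.
#'
#' @param seed Integer seed controlling reference construction and (by
#'   default) library sampling.
#' @param n_reads Number of reads per simulated library.
#' @param composition Named fractions over read categories
#'   (`rRNA`, `nuclear_CDS`, `UTR`, `intergenic`, `chloroplast_CDS`,
#'   `mitochondrial`); must sum to 1.
#' @param frame1_prob Per-compartment probability that a P-site lands in
#'   frame 1 (the two off frames share the remainder equally).
#' @param init_peak Probability that a coding read's P-site is the start
#'   codon (models the initiation peak that start-anchored offset
#'   calibration relies on).
#' @param cyto_size Cytosolic/nuclear footprint size model: a discretised
#'   normal major mode plus a uniform minor mode, as
#'   `list(mean, sd, minor_min, minor_max, minor_weight, min, max)`.
#' @param chloro_size Chloroplast two-component size model:
#'   `list(small = c(lo, hi), large = c(lo, hi), small_weight, dist)` with
#'   `dist` one of `"normal"` (discretised, centred on each range) or
#'   `"uniform"`.
#' @param offsets Per-compartment P-site geometry. Cytosolic/nuclear and
#'   mitochondrial reads are 5'-anchored (`d5`); chloroplast reads are
#'   3'-anchored with `d3_small` for lengths `<= small_max` and `d3_large`
#'   above it. The shared convention is `d5 + 3 + d3 = L`.
#' @param offset_jitter Max +/- nt of jitter applied to the anchored end.
#' @param rrna_fragments Optional tibble of fragment specs
#'   (`fragment_id, species_id, start, end, abundance`); `NULL` means the
#'   default 24-fragment rank-power family built by [default_fragments()].
#' @param frag_background Fraction of rRNA reads drawn as uniform background
#'   rather than from fixed fragments.
#' @param boundary_jitter Max +/- nt on each rRNA fragment end.
#' @param pcr_dup_rate Geometric per-read duplication probability (0 = off);
#'   qualitative PCR-duplication model only.
#' @param n_nuclear_genes,n_chloroplast_genes,n_mito_genes Toy genome gene
#'   counts (79 chloroplast CDS genes by default, the typical land-plant
#'   plastid gene count).
#' @param nuclear_chrom_len Optional hard cap on the nuclear chromosome
#'   length; construction errors if the genes do not fit.
#' @param expression_sdlog Log-sd of the lognormal per-gene expression
#'   weights.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 42L,
                       n_reads = 50000L,
                       composition = c(rRNA = 0.85, nuclear_CDS = 0.09,
                                       chloroplast_CDS = 0.03, UTR = 0.015,
                                       intergenic = 0.01, mitochondrial = 0.005),
                       frame1_prob = c(nuclear = 0.58, chloroplast = 0.58,
                                       mitochondrial = 0.58),
                       init_peak = 0.05,
                       cyto_size = list(mean = 29, sd = 1.5, minor_min = 20,
                                        minor_max = 24, minor_weight = 0.1,
                                        min = 20, max = 40),
                       chloro_size = list(small = c(20L, 30L), large = c(31L, 40L),
                                          small_weight = 0.45, dist = "normal"),
                       offsets = list(
                         nuclear = list(anchor = "5p", d5 = 12L),
                         chloroplast = list(anchor = "3p", d3_small = 7L,
                                            d3_large = 15L, small_max = 30L),
                         mitochondrial = list(anchor = "5p", d5 = 12L)),
                       offset_jitter = 0L,
                       rrna_fragments = NULL,
                       frag_background = 0.02,
                       boundary_jitter = 1L,
                       pcr_dup_rate = 0,
                       n_nuclear_genes = 40L,
                       n_chloroplast_genes = 79L,
                       n_mito_genes = 5L,
                       nuclear_chrom_len = NULL,
                       expression_sdlog = 1) {
  cfg <- list(seed = as.integer(seed), n_reads = as.integer(n_reads),
              composition = composition, frame1_prob = frame1_prob,
              init_peak = init_peak, cyto_size = cyto_size,
              chloro_size = chloro_size, offsets = offsets,
              offset_jitter = as.integer(offset_jitter),
              rrna_fragments = rrna_fragments,
              frag_background = frag_background,
              boundary_jitter = as.integer(boundary_jitter),
              pcr_dup_rate = pcr_dup_rate,
              n_nuclear_genes = as.integer(n_nuclear_genes),
              n_chloroplast_genes = as.integer(n_chloroplast_genes),
              n_mito_genes = as.integer(n_mito_genes),
              nuclear_chrom_len = nuclear_chrom_len,
              expression_sdlog = expression_sdlog)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  needed <- c("rRNA", "nuclear_CDS", "chloroplast_CDS", "UTR", "intergenic",
              "mitochondrial")
  missing <- setdiff(needed, names(cfg$composition))
  if (length(missing) > 0) {
    stopf("composition lacks categories: %s", paste(missing, collapse = ", "))
  }
  check_fractions_sum1(cfg$composition, "composition fractions")
  check_prob(cfg$composition, "composition fractions")
  check_prob(unlist(cfg$frame1_prob), "frame1_prob")
  check_prob(cfg$init_peak, "init_peak")
  check_prob(cfg$frag_background, "frag_background")
  check_prob(cfg$pcr_dup_rate, "pcr_dup_rate")
  if (!is.null(cfg$rrna_fragments)) {
    fr <- cfg$rrna_fragments
    if (sum(fr$abundance) > 1 + 1e-9) stopf("fragment abundances must sum to <= 1")
    if (any(fr$end <= fr$start)) stopf("fragment intervals must be non-empty")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> seed %d, %d reads/library, rRNA %.0f%%\n",
              x$seed, x$n_reads, 100 * x$composition[["rRNA"]]))
  invisible(x)
}

#' Default rRNA contaminant fragment specification
#'
#' Places `n` fragments (25-45 nt, at least 12 nt apart) across the rRNA
#' references, allocated proportionally to reference length, with abundances
#' following a steep rank-power law (`rank^-power`, normalised to
#' `1 - background`). With the defaults the 24 fragment families cover more
#' than 95% of rRNA reads and every family exceeds the default hot-position
#' threshold, mirroring undepleted plant libraries where a few dozen
#' recurrent fragments dominate.
#'
#' @param rrna rRNA reference tibble from [read_rrna_references()] or
#'   [build_toy_references()].
#' @param n Number of fragments.
#' @param power Rank-power-law exponent.
#' @param background Uniform-background share of rRNA reads.
#' @param seed Seed for the (deterministic) length draws.
#' @return Tibble: `fragment_id`, `species_id`, `start`, `end`, `abundance`.
#' @export
default_fragments <- function(rrna, n = 24L, power = 1.2, background = 0.02,
                              seed = 1L) {
  withr::with_seed(child_seed(seed, 7L), {
    per <- pmax(1L, round(n * rrna$length / sum(rrna$length)))
    while (sum(per) > n) per[which.max(per)] <- per[which.max(per)] - 1L
    while (sum(per) < n) per[which.max(rrna$length / per)] <-
        per[which.max(rrna$length / per)] + 1L
    spec <- purrr::map_dfr(seq_len(nrow(rrna)), function(i) {
      k <- per[i]
      slot <- (rrna$length[i] - 60L) %/% k
      len <- sample(25:45, k, replace = TRUE)
      start <- 30L + (seq_len(k) - 1L) * slot
      tibble(species_id = rrna$species_id[i], start = start,
             end = pmin(start + len, rrna$length[i] - 10L))
    })
    # interleave species so every species owns some high-abundance fragments
    spec <- spec[order(stats::ave(seq_len(nrow(spec)), spec$species_id,
                                  FUN = seq_along),
                       spec$species_id), ]
    w <- seq_len(nrow(spec))^(-power)
    spec$abundance <- w / sum(w) * (1 - background)
    spec$fragment_id <- sprintf("F%02d", seq_len(nrow(spec)))
    select(spec, "fragment_id", "species_id", "start", "end", "abundance")
  })
}
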