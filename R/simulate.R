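# Footprint library simulation with per-read truth.

#' Simulate a ribosome-profiling read library
#'
#' Draws reads according to the configured composition. Coding reads place a
#' P-site codon along the CDS (with an initiation peak at the start codon and
#' Bernoulli frame-1 assignment) and then anchor the read at the
#' compartment's anchored end: cytosolic/nuclear and mitochondrial reads have
#' a fixed 5' offset (d5) and a ragged 3' end, chloroplast reads a fixed 3'
#' offset (d3, size-class dependent) and a ragged 5' end — the digestion
#' geometry of 80S vs 70S ribosomes. rRNA reads are drawn from the fixed
#' fragment spectrum (with boundary jitter) plus a uniform background.
#'
#' The truth table records the true placement, geometry and the category the
#' true interval implies under the package's majority-overlap assignment
#' rule, so downstream reports can be checked read-for-read.
#'
#' @param config A [sim_config()].
#' @param refs A `toy_references` from [build_toy_references()].
#' @param seed Seed for library sampling; defaults to `config$seed`. Give
#'   each replicate library its own seed.
#' @param library_id Library label used in read ids and downstream reports.
#' @return A `sim_library` list: `reads` (tibble read_id/sequence) and
#'   `truth` (one row per emitted read).
#' @export
simulate_library <- function(config, refs, seed = config$seed,
                             library_id = "lib1") {
  stopifnot(inherits(config, "sim_config"), inherits(refs, "toy_references"))
  comp <- config$composition
  withr::with_seed(as.integer(seed), {
    n <- config$n_reads
    cats <- sample(names(comp), n, replace = TRUE, prob = comp)
    parts <- list(
      sim_coding(config, refs, sum(cats == "nuclear_CDS"), "nuclear"),
      sim_coding(config, refs, sum(cats == "chloroplast_CDS"), "chloroplast"),
      sim_coding(config, refs, sum(cats == "mitochondrial"), "mitochondrial"),
      sim_utr(config, refs, sum(cats == "UTR")),
      sim_intergenic(config, refs, sum(cats == "intergenic")),
      sim_rrna(config, refs, sum(cats == "rRNA"))
    )
    truth <- bind_rows(parts)
    if (config$pcr_dup_rate > 0) {
      copies <- 1L + stats::rgeom(nrow(truth), 1 - config$pcr_dup_rate)
      truth <- truth[rep(seq_len(nrow(truth)), copies), ]
      truth$template_id <- sprintf("t%06d", rep(seq_along(copies), copies))
    }
    truth <- truth[sample(nrow(truth)), ]
    truth$read_id <- sprintf("%s_r%07d", library_id, seq_len(nrow(truth)))
    truth$library_id <- library_id
  })
  truth$sequence <- extract_sequences(truth, refs)
  aln <- select(truth, "read_id", "reference", "start", "end", "strand")
  truth$category <- categorize_reads(aln, refs$annotation, refs$rrna,
                                     quiet = TRUE)$category
  reads <- tibble(read_id = truth$read_id, sequence = truth$sequence)
  truth <- select(truth, "read_id", "library_id", "source", "category",
                  "compartment", "reference", "start", "end", "strand",
                  "length", "gene_id", "species_id", "fragment_id",
                  "p_site", "frame", "d5", "d3",
                  dplyr::any_of("template_id"))
  structure(list(reads = reads, truth = truth, library_id = library_id),
            class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("<sim_library> %s: %d reads\n", x$library_id, nrow(x$reads)))
  print(count(x$truth, .data$source))
  invisible(x)
}

# -- category generators (internal) ------------------------------------------

empty_truth <- function() {
  tibble(source = character(), compartment = character(),
         reference = character(), start = integer(), end = integer(),
         strand = character(), length = integer(), gene_id = character(),
         species_id = character(), fragment_id = character(),
         p_site = integer(), frame = integer(),
         d5 = integer(), d3 = integer())
}

draw_cyto_lengths <- function(n, m) {
  minor <- runif(n) < m$minor_weight
  len <- ifelse(minor,
                sample(m$minor_min:m$minor_max, n, replace = TRUE),
                round(rnorm(n, m$mean, m$sd)))
  pmin(pmax(as.integer(len), m$min), m$max)
}

draw_chloro_lengths <- function(n, m) {
  small <- runif(n) < m$small_weight
  draw_one <- function(range, k) {
    if (k == 0) return(integer(0))
    if (identical(m$dist, "uniform")) {
      sample(range[1]:range[2], k, replace = TRUE)
    } else {
      mid <- mean(range); sd <- diff(range) / 4
      pmin(pmax(as.integer(round(rnorm(k, mid, sd))), range[1]), range[2])
    }
  }
  out <- integer(n)
  out[small] <- draw_one(m$small, sum(small))
  out[!small] <- draw_one(m$large, sum(!small))
  out
}

sim_coding <- function(config, refs, n, compartment) {
  if (n == 0) return(empty_truth())
  genes <- refs$annotation$genes
  genes <- genes[genes$compartment == compartment, ]
  w <- refs$gene_weights$weight[match(genes$gene_id, refs$gene_weights$gene_id)]
  cds <- purrr::map_dfr(genes$cds_parts, ~ .x[1, ])
  g0 <- cds$start; g1 <- cds$end

  source_name <- switch(compartment, nuclear = "nuclear_CDS",
                        chloroplast = "chloroplast_CDS", "mitochondrial")
  f1 <- config$frame1_prob[[compartment]]
  gen <- function(n) {
    idx <- sample(nrow(genes), n, replace = TRUE, prob = w)
    ncod <- genes$cds_length[idx] %/% 3L
    is_init <- runif(n) < config$init_peak
    codon <- ifelse(is_init, 0L, 1L + floor(runif(n) * (ncod - 2L)))
    u <- runif(n)
    shift <- ifelse(u < f1, 0L, ifelse(u < f1 + (1 - f1) / 2, 1L, 2L))
    p_t <- 3L * codon + shift
    len <- if (compartment == "chloroplast") {
      draw_chloro_lengths(n, config$chloro_size)
    } else {
      draw_cyto_lengths(n, config$cyto_size)
    }
    jit <- if (config$offset_jitter > 0) {
      sample(seq(-config$offset_jitter, config$offset_jitter), n, replace = TRUE)
    } else rep(0L, n)
    off <- config$offsets[[compartment]]
    if (off$anchor == "5p") {
      d5 <- pmax(0L, pmin(off$d5 + jit, len - 3L))
      d3 <- len - 3L - d5
    } else {
      d3 <- ifelse(len <= off$small_max, off$d3_small, off$d3_large)
      d3 <- pmax(0L, pmin(d3 + jit, len - 3L))
      d5 <- len - 3L - d3
    }
    t5 <- p_t - d5
    plus <- genes$strand[idx] == "+"
    a <- ifelse(plus, g0[idx] + t5, g1[idx] - t5 - len)
    b <- a + len
    gp <- ifelse(plus, g0[idx] + p_t, g1[idx] - 1L - p_t)
    tibble(source = source_name, compartment = compartment,
           reference = genes$chromosome[idx],
           start = as.integer(a), end = as.integer(b),
           strand = genes$strand[idx], length = len,
           gene_id = genes$gene_id[idx], species_id = NA_character_,
           fragment_id = NA_character_, p_site = as.integer(gp),
           frame = shift + 1L, d5 = as.integer(d5), d3 = as.integer(d3))
  }
  resample_invalid(gen, n, refs)
}

# Re-draw reads whose span falls off the reference; warn if > 1% needed.
resample_invalid <- function(gen, n, refs, max_iter = 10L) {
  lens <- setNames(c(refs$genome$length, refs$rrna$length),
                   c(refs$genome$seq_id, refs$rrna$species_id))
  out <- gen(n)
  resampled <- 0L
  for (it in seq_len(max_iter)) {
    bad <- out$start < 0L | out$end > lens[out$reference]
    if (!any(bad)) break
    resampled <- resampled + sum(bad)
    out[bad, ] <- gen(sum(bad))
  }
  if (resampled > 0.01 * n) {
    warnf("%d of %d reads resampled for falling off the reference",
          resampled, n)
  }
  out
}

sim_utr <- function(config, refs, n) {
  if (n == 0) return(empty_truth())
  genes <- refs$annotation$genes
  utrs <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    one <- function(tbl, which) {
      if (nrow(tbl) == 0) return(NULL)
      tibble(gene_id = genes$gene_id[i], chromosome = genes$chromosome[i],
             strand = genes$strand[i], which = which,
             start = tbl$start[1], end = tbl$end[1])
    }
    bind_rows(one(genes$utr5_parts[[i]], "UTR5"),
              one(genes$utr3_parts[[i]], "UTR3"))
  })
  utrs <- utrs[(utrs$end - utrs$start) >= 20L, ]
  idx <- sample(nrow(utrs), n, replace = TRUE, prob = utrs$end - utrs$start)
  ulen <- utrs$end[idx] - utrs$start[idx]
  len <- pmin(draw_cyto_lengths(n, config$cyto_size), ulen)
  a <- utrs$start[idx] + floor(runif(n) * (ulen - len + 1L))
  tibble(source = "UTR", compartment = "nuclear",
         reference = utrs$chromosome[idx], start = as.integer(a),
         end = as.integer(a + len), strand = utrs$strand[idx],
         length = len, gene_id = utrs$gene_id[idx],
         species_id = NA_character_, fragment_id = NA_character_,
         p_site = NA_integer_, frame = NA_integer_,
         d5 = NA_integer_, d3 = NA_integer_)
}

sim_intergenic <- function(config, refs, n) {
  if (n == 0) return(empty_truth())
  genes <- refs$annotation$genes
  genes <- genes[genes$chromosome == "chrN", ]
  spans <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    parts <- bind_rows(genes$cds_parts[[i]], genes$utr5_parts[[i]],
                       genes$utr3_parts[[i]])
    tibble(start = min(parts$start), end = max(parts$end))
  })
  chrom_len <- refs$genome$length[refs$genome$seq_id == "chrN"]
  occupied <- IRanges::reduce(IRanges::IRanges(spans$start + 1L, spans$end))
  free <- IRanges::gaps(occupied, start = 1L, end = chrom_len)
  free <- free[IRanges::width(free) >= 60L]
  ft <- tibble(start = IRanges::start(free) - 1L, end = IRanges::end(free))
  idx <- sample(nrow(ft), n, replace = TRUE, prob = ft$end - ft$start)
  flen <- ft$end[idx] - ft$start[idx]
  len <- pmin(draw_cyto_lengths(n, config$cyto_size), flen)
  a <- ft$start[idx] + floor(runif(n) * (flen - len + 1L))
  tibble(source = "intergenic", compartment = "nuclear",
         reference = "chrN", start = as.integer(a),
         end = as.integer(a + len),
         strand = sample(c("+", "-"), n, replace = TRUE),
         length = len, gene_id = NA_character_,
         species_id = NA_character_, fragment_id = NA_character_,
         p_site = NA_integer_, frame = NA_integer_,
         d5 = NA_integer_, d3 = NA_integer_)
}

sim_rrna <- function(config, refs, n) {
  if (n == 0) return(empty_truth())
  fr <- refs$fragments
  bg <- max(0, 1 - sum(fr$abundance))
  pick <- sample(c(fr$fragment_id, "__bg__"), n, replace = TRUE,
                 prob = c(fr$abundance, bg))
  is_bg <- pick == "__bg__"
  b <- config$boundary_jitter
  rlen <- setNames(refs$rrna$length, refs$rrna$species_id)

  out <- empty_truth()
  if (any(!is_bg)) {
    i <- match(pick[!is_bg], fr$fragment_id)
    j1 <- if (b > 0) sample(seq(-b, b), sum(!is_bg), replace = TRUE) else 0L
    j2 <- if (b > 0) sample(seq(-b, b), sum(!is_bg), replace = TRUE) else 0L
    a <- pmax(0L, fr$start[i] + j1)
    e <- pmin(unname(rlen[fr$species_id[i]]), fr$end[i] + j2)
    out <- bind_rows(out, tibble(
      source = "rRNA", compartment = NA_character_,
      reference = fr$species_id[i], start = as.integer(a),
      end = as.integer(e), strand = "+",
      length = as.integer(e - a), gene_id = NA_character_,
      species_id = fr$species_id[i], fragment_id = fr$fragment_id[i],
      p_site = NA_integer_, frame = NA_integer_,
      d5 = NA_integer_, d3 = NA_integer_))
  }
  if (any(is_bg)) {
    k <- sum(is_bg)
    sp <- sample(refs$rrna$species_id, k, replace = TRUE,
                 prob = refs$rrna$length)
    len <- sample(20:50, k, replace = TRUE)
    len <- pmin(len, unname(rlen[sp]))
    a <- floor(runif(k) * (unname(rlen[sp]) - len + 1L))
    out <- bind_rows(out, tibble(
      source = "rRNA", compartment = NA_character_,
      reference = sp, start = as.integer(a), end = as.integer(a + len),
      strand = "+", length = as.integer(len), gene_id = NA_character_,
      species_id = sp, fragment_id = NA_character_,
      p_site = NA_integer_, frame = NA_integer_,
      d5 = NA_integer_, d3 = NA_integer_))
  }
  comp_map <- setNames(refs$rrna$compartment, refs$rrna$species_id)
  out$compartment <- unname(comp_map[out$species_id])
  out
}

# Pull read sequences (transcript orientation) off the references.
extract_sequences <- function(truth, refs) {
  seqs <- setNames(c(refs$genome$sequence, refs$rrna$sequence),
                   c(refs$genome$seq_id, refs$rrna$species_id))
  out <- character(nrow(truth))
  for (ref in unique(truth$reference)) {
    i <- which(truth$reference == ref)
    s <- substring(seqs[[ref]], truth$start[i] + 1L, truth$end[i])
    minus <- truth$strand[i] == "-"
    if (any(minus)) s[minus] <- revcomp(s[minus])
    out[i] <- s
  }
  out
}

# -- FASTQ I/O ----------------------------------------------------------------

#' Write simulated reads as FASTQ
#'
#' Quality strings are constant `'I'`; quality is never used downstream.
#' A `.gz` suffix triggers gzip compression.
#'
#' @param reads Tibble with `read_id` and `sequence` (or a `sim_library`).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fastq <- function(reads, file) {
  if (inherits(reads, "sim_library")) reads <- reads$reads
  set <- Biostrings::DNAStringSet(reads$sequence)
  names(set) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(set, file, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", file))
  invisible(file)
}

#' Read a FASTQ file into a read tibble
#' @param file FASTQ path (optionally gzipped).
#' @return Tibble with `read_id`, `sequence`.
#' @export
read_fastq <- function(file) {
  set <- Biostrings::readDNAStringSet(file, format = "fastq")
  tibble(read_id = sub("\\s.*$", "", names(set)),
         sequence = as.character(set))
}

# -- toy exact-match aligner --------------------------------------------------

#' Exact-match alignment of synthetic reads
#'
#' Substitute for a real aligner on synthetic data only: every simulated read
#' is an exact substring of some reference. Reads matching an rRNA reference
#' are assigned there with precedence over genomic matches; remaining
#' ambiguity is resolved by reference order, then plus before minus strand,
#' then leftmost coordinate. Unmatched reads are kept with `reference = NA`
#' and counted.
#'
#' @param reads Read tibble (`read_id`, `sequence`), a `sim_library`, or a
#'   FASTQ path.
#' @param refs `toy_references` (or any list with `genome` and `rrna`
#'   tibbles).
#' @return Alignment tibble: `read_id`, `reference`, `start`, `end`,
#'   `strand`, `length` (0-based half-open), with attribute `n_unmapped`.
#' @export
toy_align <- function(reads, refs) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  if (inherits(reads, "sim_library")) reads <- reads$reads
  subjects <- tibble(
    name = c(refs$rrna$species_id, refs$genome$seq_id),
    sequence = c(refs$rrna$sequence, refs$genome$sequence)
  )
  subj_sets <- Biostrings::DNAStringSet(subjects$sequence)

  n <- nrow(reads)
  lens <- nchar(reads$sequence)
  best_rank <- rep(Inf, n)
  best_start <- rep(NA_integer_, n)
  best_subj <- rep(NA_integer_, n)
  best_strand <- rep(NA_character_, n)

  valid <- grepl("^[ACGT]+$", reads$sequence)
  for (L in sort(unique(lens[valid]))) {
    sel <- which(lens == L & valid)
    useq <- unique(reads$sequence[sel])
    map <- match(reads$sequence[sel], useq)
    dict_fwd <- Biostrings::PDict(Biostrings::DNAStringSet(useq))
    dict_rev <- Biostrings::PDict(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(useq)))
    u_rank <- rep(Inf, length(useq))
    u_start <- rep(NA_integer_, length(useq))
    u_subj <- rep(NA_integer_, length(useq))
    u_strand <- rep(NA_character_, length(useq))
    for (s in seq_len(nrow(subjects))) {
      for (str in c("+", "-")) {
        dict <- if (str == "+") dict_fwd else dict_rev
        m <- Biostrings::matchPDict(dict, subj_sets[[s]])
        starts <- Biostrings::startIndex(m)
        hit <- which(lengths(starts) > 0)
        if (length(hit) == 0) next
        first <- vapply(starts[hit], min, integer(1)) - 1L
        # composite rank: subject order, then strand, then coordinate
        rank <- (s * 2 + (str == "-")) * 1e9 + first
        upd <- rank < u_rank[hit]
        if (any(upd)) {
          idx <- hit[upd]
          u_rank[idx] <- rank[upd]
          u_start[idx] <- first[upd]
          u_subj[idx] <- s
          u_strand[idx] <- str
        }
      }
    }
    best_rank[sel] <- u_rank[map]
    best_start[sel] <- u_start[map]
    best_subj[sel] <- u_subj[map]
    best_strand[sel] <- u_strand[map]
  }
  out <- tibble(
    read_id = reads$read_id,
    reference = subjects$name[best_subj],
    start = best_start,
    end = best_start + lens,
    strand = best_strand,
    length = lens
  )
  n_unmapped <- sum(is.na(out$reference))
  if (n_unmapped > 0) {
    inform(sprintf("toy_align: %d read(s) unmapped", n_unmapped))
    out$end[is.na(out$reference)] <- NA_integer_
    out$length[is.na(out$reference)] <- lens[is.na(out$reference)]
  }
  attr(out, "n_unmapped") <- n_unmapped
  out
}
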