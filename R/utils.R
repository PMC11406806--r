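# Shared internal helpers: coordinate conventions, sequence utilities,
# validation. All in-memory intervals are 0-based half-open [start, end);
# 1-based closed coordinates exist only at the GFF3/bedGraph/BED boundary.

# DNA reverse complement on plain character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Upper-case and convert RNA (U) to the internal DNA alphabet.
as_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

# Overlap width of [a1,a2) with [b1,b2); zero when disjoint. Vectorised.
interval_overlap <- function(a1, a2, b1, b2) {
  pmax(0L, pmin(a2, b2) - pmax(a1, b1))
}

# Jaccard index of two half-open intervals.
interval_jaccard <- function(a1, a2, b1, b2) {
  inter <- interval_overlap(a1, a2, b1, b2)
  union <- (a2 - a1) + (b2 - b1) - inter
  ifelse(union > 0, inter / union, 0)
}

# Mode of an integer vector with ties broken toward the smallest value.
modal_value <- function(x) {
  if (length(x) == 0) return(NA_integer_)
  tab <- table(x)
  vals <- as.integer(names(tab))
  vals[order(-as.integer(tab), vals)][1]
}

# Fraction of observations at the modal value.
modal_fraction <- function(x) {
  if (length(x) == 0) return(NA_real_)
  max(table(x)) / length(x)
}

# Deterministic child seed (kept < 2^31 so it is a valid R integer).
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))
warnf <- function(fmt, ...) warn(sprintf(fmt, ...))

check_fractions_sum1 <- function(x, what, tol = 1e-9) {
  if (abs(sum(x) - 1) > tol) {
    stopf("%s must sum to 1 (got %.12f)", what, sum(x))
  }
  invisible(x)
}

check_prob <- function(x, what) {
  if (any(x < 0 | x > 1)) stopf("%s must lie in [0, 1]", what)
  invisible(x)
}

# Standard column check for alignment tibbles.
check_alignments <- function(x, cols = c("read_id", "reference", "start", "end", "strand")) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    stopf("alignment table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  invisible(x)
}

# Ensure a library_id column exists (single-library tables default to "lib1").
ensure_library_id <- function(x, default = "lib1") {
  if (!"library_id" %in% names(x)) x$library_id <- default
  x
}

new_riboclean_tbl <- function(x, class) {
  class(x) <- c(class, class(x))
  x
}
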