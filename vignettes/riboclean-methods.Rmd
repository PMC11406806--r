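---
title: "Methods: models, parameters and design choices in riboclean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in riboclean}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`riboclean` implements the computational workflow for optimizing plant
ribosome-profiling libraries: accounting for where reads go, finding and
depleting the recurrent rRNA contaminant fragments that dominate undepleted
libraries, calibrating P-site offsets separately for the cytosolic 80S and
the chloroplast 70S ribosome, and mapping contaminants onto ribosome
structure. This vignette is the package's own account of the underlying
models, the tunable parameters, and the choices made where the design was
genuinely open.

## Coordinate model

All in-memory intervals are 0-based half-open `[start, end)`; 1-based
closed coordinates exist only at the GFF3/BED/bedGraph file boundary,
handled by `rtracklayer` in `read_annotation()`, `write_annotation()`,
`write_tracks()` and `read_tracks()`. Read positions are interpreted in
transcript orientation for offset and metagene work; alignment tables keep
genomic orientation. Compartment (nuclear / chloroplast / mitochondrial)
is a chromosome-name mapping supplied by the user, with a name heuristic
(`default_compartments()`) as fallback, because annotations rarely state
which sequence is the plastid.

## Read categorization

Categories follow the precedence rRNA > CDS > UTR5/UTR3 > intergenic. A
read is CDS when at least 50% of its span overlaps the CDS of a
same-strand gene (`cds_overlap`, configurable); the threshold rule is a
package choice — published composition figures never state one — and ties
at exactly 50/50 break toward CDS to match CDS-dominant reporting.
Below the CDS threshold the majority feature among UTR5, UTR3 and
"outside" wins. Reads on the mitochondrial chromosome form a single
compartment-level category (mitochondrial footprints are negligible in
practice and not worth a per-feature split). Multi-mapped SAM records
contribute only their primary alignment so every read is counted once.
Feature proportions (`feature_proportions()`) are computed after removing
rRNA reads, matching the conventional presentation.

## Contaminant regions

The published procedure for finding contaminant fragments is visual
(inspecting coverage tracks in a genome browser); `call_regions()`
operationalizes it:

* a position is *hot* in a library when its coverage is at least
  `hot_frac` × that library's total rRNA-assigned reads. The threshold is
  relative, not absolute, so libraries of different depth are comparable;
  `hot_frac = 0.005` is the documented default and deliberately a free
  parameter, since the visual criterion it replaces has no single value;
* positions hot in more than `majority` (default 0.5) of libraries are
  kept — the "recurrent across libraries" requirement;
* kept positions are merged across gaps of at most `merge_gap = 5` nt and
  runs shorter than `min_len = 15` nt are dropped;
* per-library region abundance counts reads overlapping the region by at
  least half their length (read attribution is otherwise undefined),
  divided by the library's mapped reads; regions are ranked by mean
  abundance and labelled C1, C2, …

Cross-species preservation comparisons require a user-supplied coordinate
map (a per-species offset); the package does not attempt rRNA orthology
alignment, since even single SNPs are known to defeat cross-species
depletion oligos.

## Oligo design and in-silico depletion

One oligo per region: the exact reverse complement of the region's sense
sequence, trimmed symmetrically to `max_len = 60` nt when necessary, with
molar ratio proportional to the region's mean abundance — the mixing rule
that keeps oligo:target stoichiometry matched when depletion is performed
before any amplification. Biotin/streptavidin chemistry is metadata.

`deplete_in_silico()` models capture as coordinate overlap: a read is
captured when it sits on the oligo's target species and overlaps the
target interval by at least `min_overlap_frac = 0.8` of its length, and is
then removed with probability `capture_eff` (default 1, deterministic).
For synthetic reads, which are literal substrings of the reference,
coordinate overlap is exactly equivalent to rehybridization; for real
reads a sequence mode captures on any contiguous exact match of at least
20 nt with a target — a deliberately stringent hybridization proxy, since
no quantitative hybridization model is available to fit. The
`diminishing_returns_curve()` reports the surviving rRNA fraction as a
function of cocktail size; because top-k cocktails are nested, the curve
is monotone non-increasing by construction.

## P-site offsets

Offsets are estimated from reads overlapping annotated start codons,
stratified by (compartment, read length), using the modal distance from
each read end — the initiation peak at start codons makes the mode the
robust estimator, and ties break toward the smaller offset. The exported
convention is:

> `d5` = nt from the read 5' end to the first nucleotide of the P-site
> codon; `d3` = nt strictly 3' of the P-site codon's last nucleotide;
> hence `d5 + 3 + d3 = L` exactly.

Published 3'-offset values are ambiguous about whether the last read
nucleotide counts; under a different convention every recovered constant
shifts by a fixed ±1. Generator and estimator share this one convention
(it is written into every offset-table header), so recovery targets are
well defined, and the conservation identity makes 5'- and 3'-anchored
placement provably identical for a consistent table — tested exhaustively
for L in 20–40 nt.

Sizes with fewer than `min_reads = 100` start-overlapping reads are
reported as *undetermined* rather than smoothed or borrowed from
neighbours: per-size values are reported directly, and an honest gap is
more useful than an interpolated offset. `apply_offsets()` places each
read at `5' end + d5` (cytosolic/nuclear, mitochondrial) or
`3' end − 3 − d3` (chloroplast), per the compartment's anchored end.

## QC statistics

Frame fractions are computed on P-sites (not raw 5' ends) over
CDS-internal positions; the first and last codons are excluded because
initiating and terminating ribosomes blur the boundary. Metagene profiles
normalize each gene's per-position P-site density by that gene's mean CDS
density before averaging — the normalization is a documented package
choice. Genes whose start-codon window overlaps a neighbouring CDS are
excluded; this is the package's tractable answer to chloroplast
polycistrons, where terminating and initiating ribosomes across a few-nt
spacer cannot be distinguished. Count correlations use Spearman rank
correlation on log2 counts after excluding genes with fewer than 10
counts in either library of a pair (rank correlation is invariant to the
log; it is kept for fidelity to how such panels are plotted). Size-split
analysis separates small and large footprints (chloroplast defaults
20–30 / 31–40 nt), correlates their per-gene counts and reports each
class's start-proximal enrichment (observed vs expected fraction of
positions within the first 50 CDS nt).

## Structure mapping

`exposure_profile()` uses protein-atom proximity as the shielding proxy:
for each rRNA residue's representative atom (phosphorus, else first
atom), protein heavy atoms within `radius = 5` Å are counted, and a
residue is exposed when the count falls below `shield_min = 1`. True
solvent-accessible surface area would need a heavier dependency; the
criterion being operationalized is "not shielded by ribosomal proteins",
for which proximity counting is sufficient and exactly testable against a
brute-force all-pairs oracle. No exposure radius is published; 5 Å (just
above a close-contact distance) is the package default and configurable.
`predict_fragments()` then treats exposed residues as nuclease-accessible
nick sites: every maximal protected run between two consecutive exposed
positions with length in [20, 50] nt — the footprint size-selection
window; longer protected stretches such as the subunit interface would be
size-selected away — is a candidate contaminant, ranked by mean interior
shield count. This predictor is a stated operationalization of an idea,
validated only on constructed toy structures; it has not been calibrated
against real nick maps.

## The synthetic world

The generator's defaults are the stated world of the analyses, chosen
once:

* composition: rRNA 0.85 (the undepleted state), nuclear CDS 0.09,
  chloroplast CDS 0.03, UTR 0.015, intergenic 0.01, mitochondrial 0.005;
* cytosolic sizes: discretised N(29, 1.5) clamped to 20–40 nt plus a
  minor uniform 20–24 nt mode with weight 0.1 (the empty-A-site
  population; its true weight is not published, so 0.1 is the documented
  default, user-tunable);
* chloroplast sizes: two discretised-normal components over 20–30 and
  31–40 nt with small-mode weight 0.45 (the published bimodality is shown
  but not quantified);
* geometry: cytosolic/nuclear and mitochondrial reads 5'-anchored with
  d5 = 12; chloroplast reads 3'-anchored with d3 = 15 (large) / 7 (small,
  the middle of the reported 6–8 nt range). Anchored-end jitter defaults
  to 0, with ±1 available for robustness checks;
* frame-1 probability 0.58 per compartment (the middle of the reported
  55.4–59.9% optimal-digestion range), off-frames equal;
* an initiation peak: with probability 0.05 a coding read's P-site is the
  start codon, otherwise uniform over interior codons. Real metagenes
  have a strong initiation peak and start-anchored modal offset
  estimation requires one; 0.05 is deliberately modest;
* rRNA fragments: 24 families (matching a version-1 cocktail) with
  rank-power-law abundances (`rank^-1.2`, normalised to 0.98) plus 2%
  uniform background and ±1 nt boundary jitter. This makes the top-24
  families carry ≥95% of rRNA reads and keeps every family above the
  default hot threshold — the regime in which a 24-oligo cocktail is the
  right size;
* toy genomes: 40 nuclear genes with UTRs on both strands, 79 chloroplast
  CDS genes (the typical land-plant plastid count) packed into
  polycistron-like clusters with 2–9 nt spacers, 5 mitochondrial genes;
  rRNA references Nu_25S/Nu_18S/Nu_5.8S/Cp_23S at desk-scaled lengths
  (1200/900/160/1100 nt). All CDS are single-part (intron-free) so that
  every simulated read is an exact genomic substring for the toy
  exact-match aligner; `read_annotation()` nonetheless supports
  multi-part CDS fully, and is tested on them;
* per-gene expression weights are lognormal(0, 1), shared across
  replicate libraries of one reference set — this is what makes
  cross-library count correlations high, as for technical replicates;
* PCR duplication is an optional per-read geometric copy model, off by
  default; it exists to demonstrate abundance distortion qualitatively,
  not to model amplification chemistry;
* FASTQ qualities are constant `I` and never used.

What a green test establishes, and what it does not: the synthetic world
has no sequencing errors, no adapters, no multi-mapping ambiguity beyond
exact duplicates, no UMI structure and no hybridization thermodynamics.
Parameter recovery on this world validates the estimators' logic and
conventions (offsets, regions, depletion arithmetic, frame statistics),
not their robustness to real-data noise. The toy exact-match aligner
exists only for this world; real alignments enter through SAM/BAM or the
alignment TSV.

## Numerical and degenerate-input choices

* Modal offsets: ties toward the smaller offset; sizes below `min_reads`
  are `undetermined` (NA), and placement excludes and counts such reads.
* `call_regions()` with a threshold that yields no hot positions returns
  an empty region set with a warning rather than an error.
* `compose()` errors on zero mapped reads; `frame_fractions()` errors when
  no CDS-internal P-sites remain; `metagene()` errors when every gene is
  excluded — silent empty reports would be mistaken for clean ones.
* Correlation pairs with fewer than 3 surviving genes are NA with a
  warning.
* Depletion with an empty cocktail or zero efficiency returns the input
  unchanged; capture efficiencies outside [0, 1] error.
* Region/oligo ranking ties break by species id then start coordinate, so
  every ranked artifact is deterministic.
* All randomness flows from explicit integer seeds; replicate libraries
  take distinct seeds derived from one master seed.

## Known limitations

The categorization rule, hot-position threshold, metagene normalization
and structure-exposure radius are documented operationalizations of
procedures that are typically described qualitatively; their defaults are
sensible but not fitted. Cross-species contaminant comparison requires an
external coordinate map. The in-silico depletion forecast ignores
mismatch tolerance (relevant when applying one species' oligos to
another) and hybridization kinetics. Translation-efficiency analysis and
ORF discovery are out of scope.
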