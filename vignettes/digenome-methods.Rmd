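---
title: "Methods: strand-aware SSB detection for Cas12a base editors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-aware SSB detection for Cas12a base editors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digenomeR)
```

## The measurement model

A cytidine base editor built on catalytically dead Cas12a deaminates
cytosines within the protospacer of a bound site, converting C to U on the
protospacer-containing strand. In vitro treatment of genomic DNA with the
editor followed by USER enzyme (uracil-DNA glycosylase plus endonuclease
VIII) excises each uracil and cleaves the backbone, leaving a single-strand
break (SSB) with a one-nucleotide gap where the edited C stood. Whole-genome
sequencing of this DNA produces a distinctive signature: at a genuine SSB,
many sequencing reads on the nicked strand begin at exactly the same
coordinate — the base immediately 3′ of the gap — while the opposite strand
shows ordinary, staggered read starts. We call this pattern a *straight
alignment*.

Because the lesion is single-stranded, the two strands carry independent
information and must never be pooled: digenomeR therefore builds one 5′-end
pileup per strand. A forward read's 5′ end is its leftmost aligned base; a
reverse read's 5′ end is its rightmost aligned base.

## Calling rule

A position is called as an SSB candidate when, on one strand,

* more than `min_start_count = 5` reads start exactly there (strict
  inequality), and
* those starts are at least `min_ratio = 0.20` of the same-strand depth at
  the position (inclusive).

The count threshold suppresses low-coverage noise; the ratio threshold
suppresses high-coverage regions where even many coincident starts are
unremarkable. The denominator is same-strand depth by default
(`denominator = "same"`), since the opposing strand is uninformative about
a nick; `"both"` is available for comparison. Candidates within
`merge_window = 10` bp on the same strand are merged by single linkage and
represented by the position with the highest start count (ties go to the
leftmost), because a single lesion can shed a few ±1 bp starts through end
repair and alignment wobble.

## Capture rule

Each merged SSB is explained by searching `search_radius = 30` bp on both
strands for the best placement of the 23-nt protospacer such that the nick
falls within the protospacer extended by `nick_slack = 5` bp. Protospacer
positions are numbered 1–23 from the PAM-proximal end; the PAM lies 5′ of
the protospacer, as for Cas12a. A placement is kept when

* the PAM is canonical `TTTN` and the score is ≤ 8, or
* the PAM is PAM-like (`NTTN`, `TNTN` or `TTNN`) and the score is ≤ 7,

where the score is the number of mismatches over positions 1–20 only
(positions 21–23 are ignored, reflecting the PAM-distal tolerance of
Cas12a) plus 2 per bulge. One 1-nt bulge is allowed: an *RNA bulge* (the
genome lacks one protospacer base) or a *DNA bulge* (the genome carries one
extra base). The penalty of 2 makes a bulged alignment strictly worse than
the same alignment with two fewer mismatches, so a bulge is only ever
reported when it genuinely rescues at least two mismatches; ties prefer
ungapped over gapped, RNA over DNA bulges, then the lowest bulge position.
Among placements, the best score wins; remaining ties prefer canonical PAM,
then the placement whose position 10 — the centre of the editing window —
is closest to the nick, then the leftmost.

`enumerate_genome_candidates()` applies the same rule exhaustively
(ungapped) across a genome, which is useful for characterising the target's
potential off-target space independently of any sequencing data.

## Coordinates

All R-level coordinates are 1-based and inclusive, matching Biostrings,
GenomicRanges and the rest of the Bioconductor ecosystem the package
interoperates with; a mixed convention inside one R session invites
off-by-one errors. BED and bedGraph exports convert to the 0-based
half-open convention those formats require.

## Amplicon quantification

`profile_amplicon()` classifies reads of a targeted amplicon as indel-free
(same length as the reference) or indel-carrying; an indel counts toward
`indel_frequency` only when it overlaps the protospacer ± 10 bp, and indel
reads are excluded from base-substitution fractions. The
`site_editing_frequency` is the maximum C→T fraction (G→A on the reference
strand for minus-strand sites) over protospacer positions 8–13, the
editing window of Cas12a cytidine base editors. Derived metrics:

* `relative_activity(f_mm, f_m)` = 100 · f_mm / f_m, the activity at a
  mismatched substrate relative to the matched one;
* `oti_index(f_on, f_offs)` = Σ f_off / f_on, an aggregate off-target
  index;
* `specificity_ratio` compares the matched/mismatched discrimination of a
  variant editor to the wild type:
  (f_m,var / f_mm,var) / (f_m,wt / f_mm,wt).

Each metric raises a classed error when its denominator is zero rather
than returning `Inf`, since a zero matched frequency means the experiment,
not the metric, failed. A warning is emitted below 100 reads, where a
single read moves frequencies by ≥ 1%.

## Sequence logos

`build_pfm()` tallies an L × 4 position frequency matrix (N bases are
excluded per column and tracked in `n_counted`). `information_content()`
uses the classic information-theoretic height: R(l) = 2 − H(l) − e(n) with
the small-sample correction e(n) = 3 / (2·ln 2·n), clamped at 0. Letter
heights are frequency × R(l). `site_logo_sequences()` arranges captured
sites PAM-first (4 nt) followed by the protospacer padded or truncated to
23 nt with N, so bulged sites can enter the same 27-column logo.

## Simulator and its realism

The simulator exists so that every stage can be validated against known
truth, at desk scale, without shipping sequencing data.

* **Genome**: i.i.d. bases at GC fraction `gc = 0.41` (human-like). Real
  genomes have repeats and compositional structure; i.i.d. background is
  deliberately conservative for false-positive checks because it contains
  no repeat-driven pileup artefacts, which is why the null-library test
  demands exactly zero calls.
* **Planted sites**: the protospacer (with chosen mismatches and at most
  one bulge) plus a `TTTV` PAM is written into the genome at explicit or
  random positions, at least `min_site_separation = 1000` bp apart.
* **Digestion**: fragments of length 450 ± 50 (normal, truncated at
  `min_piece = 20`) are dropped uniformly at ~`depth = 30`× (the number of
  fragments is depth·L/(2·read length)); fragments extending past the
  contig end are discarded rather than clipped, because clipping stacks
  artificial 5′ ends on the last base and fakes an SSB. Each planted site
  nicks the fragments that span it with probability `nick_fraction`,
  splitting them into two pieces with a 1-nt gap at the edited C (at
  protospacer position `nick_offset = 10` by default). Single-end 150 bp
  reads are taken from both ends of every piece ≥ 20 bp. Fragments are
  nicked by at most one site, a safe assumption at the enforced 1 kb site
  separation versus 450 bp fragments.
* **Amplicons**: per-position C→T conversion at specified rates plus an
  optional 1-bp deletion rate inside the protospacer.

All randomness is seeded from the configuration, and sub-stages derive
distinct streams from the one seed, so a simulation is byte-reproducible.

What the simulator does not model: PCR duplicates, base-calling error,
mapping ambiguity in repeats, paired-end information, chimeric reads, or
nick translation during library preparation. These mostly *add* noise, so
recovery results here are an upper bound on real-data sensitivity; the
calling thresholds themselves are fixed by the method, not tuned to the
simulator.

## Problem sizes

The package's own acceptance analyses (`scripts/acceptance.R`,
`tests/testthat/test-acceptance.R`) use 1 Mb genomes at 30× — large enough
that a six-site recovery or a zero-false-positive claim is meaningful
(~200,000 reads, ~4 million scored genome positions per library), small
enough to run in seconds. A full human-genome run differs only in input
size; `build_strand_pileup` and `enumerate_genome_candidates` are
vectorised per contig and scale linearly.

## Degenerate inputs and failure modes

Errors are classed conditions (`digenomeR_missing_file`,
`digenomeR_bad_config`, `digenomeR_site_overlap`, …) so callers can handle
them programmatically; the CLI maps them to exit status 1 and usage errors
to 2. Empty read sets produce an empty report with a warning, not an
error. Unsorted SAM input is rejected unless sortedness checking is
disabled, because the pileup assumes per-contig grouping. Reads mapping
off the declared reference raise `digenomeR_read_out_of_bounds` rather
than being silently dropped.

## Limitations

* The caller detects *straight alignments*; nicks in unmappable or
  repetitive regions are invisible regardless of thresholds.
* The capture rule is a hard boundary (counts and cutoffs), not a
  statistical model; borderline sites at exactly 8 mismatches are treated
  identically to perfect matches for capture purposes.
* Only one 1-nt bulge is considered; multi-nucleotide or multiple bulges
  are not scored.
* Amplicon profiling assumes reads are full-length amplicon sequences
  already oriented to the reference; it is not an aligner.
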