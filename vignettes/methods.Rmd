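---
title: "Evaluating degenerate nifH PCR primers in silico: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating degenerate nifH PCR primers in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nifHeval)
```

## The problem

The *nifH* gene (nitrogenase reductase) is the marker of choice for
surveying nitrogen-fixing *Bacteria* and *Archaea*. Because diazotrophs are
deeply divergent, *nifH* primers must be degenerate: one written sequence
with IUPAC ambiguity codes (and often inosine) stands for a mixture of
concrete oligonucleotides. Published primers differ enormously in how much
of known *nifH* diversity they can amplify, and a researcher choosing a
primer set needs a reproducible way to measure *coverage*: the percentage of
database sequences a primer (or primer pair) matches at a given mismatch
budget, normalised by the sequences that actually have data in the binding
region.

nifHeval packages that evaluation pipeline: a curated registry of 51
universal and 35 group-specific *nifH* primers (plus 42 + 19 pairs),
IUPAC-aware mismatch-tolerant scanning, depth-normalised coverage statistics
stratified by phylogenetic group and environment, in-silico PCR, and
nearest-neighbor melting temperatures. Because the curated 23,847-sequence
alignment the published coverage numbers were computed on cannot be
redistributed, the package also ships a synthetic aligned-database generator
with exact ground truth, so that every stage of the pipeline is testable
end-to-end without downloads.

## Coordinates, depth, and the denominator rule

All binding positions are 1-based inclusive nucleotide positions on a
designated reference sequence (for *nifH*, the *Azotobacter vinelandii*
gene). Alignment columns in which the reference has a gap are insertions
relative to the reference and are invisible in reference coordinates.

Marker-gene databases are dominated by PCR amplicons, so sequence depth is
humped: high across the commonly amplified core (~positions 115–476), low at
the termini. A primer binding near a terminus would look artificially bad if
coverage were normalised by the whole database. The denominator for every
coverage cell is therefore the number of records *with nucleotide
representation spanning the primer's binding window*. Two spanning rules are
implemented:

* `"endpoints"` (default): a record counts if it has a nucleotide at the
  first and last window position. Internal alignment gaps are deletions —
  the record still "has data in the region".
* `"all"`: every window position must be a nucleotide.

The default matches how end-trimmed fragments behave; the choice is recorded
in every report header and is switchable because the original tooling's
treatment of partially gapped records is not documented.

## Matching model

A primer hit is Hamming-style against the *ungapped* record sequence: gaps
are skipped, no indels are allowed, and at most *k* positions may fail the
character match. Two characters match when their IUPAC base sets intersect.
Two deliberate conventions:

* **Inosine** is a universal base: it matches any template nucleotide, but
  contributes multiplicity 1 to degeneracy, because a single
  inosine-bearing oligo is synthesized. (Degeneracy is the product of
  per-position multiplicities; a few published values instead counted
  inosine as 4 — the registry records the printed values verbatim and notes
  the convention.)
* **Ambiguous database bases** match by set intersection by default — an `R`
  in a record *could* be the primer's `A` — which is conservative toward
  coverage. `ambiguity = "strict"` treats any ambiguous target base as a
  mismatch instead. The policy is logged in report headers.

Reverse-orientation primers are scanned as their reverse complement against
the sense strand. Per-primer coverage is computed over the primer's own
binding window (hit must start at the window's start column; `tol` relaxes
this, `window = NULL` scans everywhere). With whole-alignment scanning a
highly degenerate primer can hit one record several times; single-primer
coverage counts hit *events*, which is how published values above 100% arise.
Pair coverage counts *records* (a template either amplifies or it does not),
consistent with pair tables never exceeding 100%.

The scanner is verified against an independent brute-force oracle
(`scan_oracle()`): full expansion of the degenerate primer followed by
position-by-position Hamming comparison, taking the minimum over expansions.
The two routes share no scanning code.

## In-silico PCR

`find_amplicons()` scans the forward primer as-is and the reverse primer as
its reverse complement along each ungapped record and enumerates every
correctly oriented, non-overlapping combination within a length cap
(default 2× the pair's expected length; the original pair-search tool's cap
is undocumented, so the cap is an explicit parameter). Expected amplicon
length is the inclusive reference span from the forward binding start to the
reverse binding end; template-relative product length is reported per
record as well, since insertions and deletions make the two differ. Nested
and semi-nested designs are out of scope.

## Melting temperatures

`nn_tm()` sums unified nearest-neighbor stack enthalpies and entropies with
terminal initiation terms and computes the two-state melting temperature
with the CT/4 concentration term (non-self-complementary duplex, equimolar
strands) at the standard primer-analysis conditions: 0.25 µM total oligo,
50 mM Na⁺, 1.5 mM Mg²⁺, 0 mM dNTPs (all tunable via `tm_conditions()`).

The default salt correction is the SantaLucia entropy correction evaluated
at a monovalent-equivalent concentration, treating magnesium through the
von Ahsen rule Na_eq(mM) = Na + 120·√(Mg − dNTP). Against the twenty
degeneracy-1 registry primers with published melting temperatures this
reproduces every value within 1.3 °C. The magnesium-aware inverse-Tm
correction is available as `salt_method = "owczarzy2008"`; it agrees closely
except for the most AT-rich primer, which is why the monovalent-equivalent
variant is the default.

Inosine stacks have no free measured parameter set; the packaged
`nn_inosine.tsv` uses the mean of the four corresponding standard-base
stacks as an explicit approximation (the table is a plain-text file and can
be swapped wholesale via `tm_conditions(inosine_file = ...)`). Consequently
melting ranges of inosine-rich primers are systematically a few degrees
below the vendor-computed published ranges; degeneracy-1 (inosine-free)
values are accurate. Primers written with non-IUPAC base codes (P/K) are
stored verbatim, flagged, and excluded from both matching and
thermodynamics, mirroring their published "NA" melting temperatures.

`tm_range()` enumerates all expansions up to a cap (65,536, covering the
whole registry). Above the cap it uses two-start coordinate descent
(AT-most and GC-most starts, per-position sweeps to a fixpoint). A purely
independent per-position choice is not exactly optimal because neighbor
stacks couple adjacent positions; coordinate descent handles that coupling
and is verified equal to exhaustive enumeration for every registry primer
with degeneracy ≤ 256.

## The synthetic generator: a stated world

`generate_synthetic_db()` emulates the *structure* of a curated
marker-gene alignment, not its biology:

* a random reference (default 882 nt, the approximate *nifH* gene length)
  into which an exact binding site for every requested registry primer is
  planted. Overlapping windows are resolved by base-set intersection;
  contradictory constraints are an error, never a silent compromise;
* fragment spans drawn from an amplicon-like mixture (70% core-covering
  fragments with small end jitter, 15% full length — the genome-derived
  fraction, 15% random subfragments), which produces the canonical humped
  depth profile;
* exact label apportionment: group labels by largest remainder over the
  configured proportions (defaults reflect a proteobacteria-dominated
  database); environment labels are multi-valued and apportioned
  independently per label;
* planted mismatches: for each primer, configured fractions of the
  window-spanning records receive exactly 1, 2, … mismatches, at window
  positions covered by no other planted window and where the primer
  constrains the base (never under N or inosine), substituting a base
  outside the primer's allowed set. A planted mismatch therefore cannot
  silently create or destroy another primer's site; infeasible requests
  error;
* optional insertion columns (gap in the reference, bases in half the
  records) which must leave the reference-coordinate depth profile
  unchanged, and reference-only "dip" positions deleted from every
  non-reference record, reproducing the sharp depth dips that reference
  insertions cause in real alignments (the packaged `fig1_fixture()` puts
  them at positions 199 and 350).

Everything is recorded in a manifest keyed by the seed; generation is
byte-reproducible. `manifest_coverage()` recomputes expected coverage from
the manifest alone (interval stabbing plus the planted-mismatch table), so
the pipeline-wide recovery test compares two independent computations.

A green synthetic test establishes that the scanning, denominator,
stratification and rounding machinery is exact on databases whose ground
truth is known. It does *not* establish anything about real *nifH*
databases: synthetic records are mutated reference fragments, not an
evolved sequence family, so published database-wide coverage percentages
are deliberately not asserted anywhere.

## Numerical and policy choices

* Percentages are rounded half-up to integers (published tables print
  integers); `round(0.5)` banker's rounding is deliberately avoided.
* A zero denominator yields `NA` ("no data available in the target
  region"), distinct from a zero numerator with data present, which is 0.
* Stratified columns are computed at 0 mismatches by default (`k_strata`),
  matching the published convention; database-wide columns at 0/1/2.
* The registry stores suspected publication errors (YAA-poly, nifHRb,
  roeschF-1b, AMR-R) verbatim with a `flagged` annotation — evaluating a
  primer requires evaluating what was published, not what was probably
  intended.
* A binding window printed 3′→5′ (nifH3, "494–478") is normalised on load.
* Seeds: every stochastic entry point takes an explicit integer seed and
  uses an isolated RNG scope, so library state never leaks.

## Known limitations

* Match counting is purely positional; there is no thermodynamic mismatch
  weighting and no special treatment of 3′-terminal mismatches, which are
  known to matter more at the bench.
* Inosine thermodynamics are approximate (see above).
* The synthetic generator plants at most one site per primer per record, so
  multi-site (>100%) coverage arises only in whole-alignment scans of
  crafted templates, not in generated databases.
* Primer-dimer and hairpin screening are out of scope.
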