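# nifHeval

In-silico evaluation of degenerate PCR primers for the *nifH* marker gene.

The *nifH* gene, encoding the nitrogenase reductase subunit, is the standard
marker for identifying nitrogen-fixing *Bacteria* and *Archaea*. Dozens of
"universal" and group-specific *nifH* primers have been published, and their
ability to recover known diazotroph diversity varies from >90% to nearly
nothing. nifHeval is for microbial ecologists choosing (or designing) primer
sets: it packages a curated registry of 51 universal and 35 group-specific
published *nifH* primers, the 42 universal and 19 group-specific pairs built
from them, and the machinery to evaluate any degenerate primer set against
any aligned marker-gene database.

## What it computes

For a degenerate primer *p* (IUPAC codes; inosine I treated as a universal
base that contributes 1 to degeneracy) scanned against an aligned database
with designated reference coordinates:

* **degeneracy** — ∏ per-position IUPAC multiplicity (A/C/G/T/I → 1,
  R/Y/S/W/K/M → 2, B/D/H/V → 3, N → 4);
* **coverage at mismatch budget k** —
  `100 × (hit events with ≤ k mismatches in the binding window) /
  (records with nucleotide representation spanning the window)`,
  rounded half-up; stratifiable by phylogenetic group
  (Pr, Cy, III, IA, Fr, Pb, Ep, IV) and environment (Soil, Mat, Sea).
  Matching is Hamming-style on the ungapped record (gaps skipped, no
  indels), base sets compared by intersection;
* **pair coverage and amplicons** — forward primer scanned as-is, reverse as
  its reverse complement on the sense strand; a record counts when at least
  one correctly oriented product forms; expected amplicon length is the
  inclusive reference span (forward start … reverse end);
* **melting temperature** — unified nearest-neighbor ΔH/ΔS with CT/4
  concentration term and a monovalent-equivalent salt correction
  (0.25 µM oligo, 50 mM Na⁺, 1.5 mM Mg²⁺, 0 dNTP by default), with min–max
  ranges over all expansions of a degenerate primer;
* **depth profiles and denominators** — per-reference-position sequence
  depth, the basis of the depth-normalised denominator rule.

A manifest-driven synthetic aligned-database generator
(`generate_synthetic_db()`, `fig1_fixture()`) provides databases with exact
ground truth (spans, labels, planted per-primer mismatch counts), so the
whole pipeline is verifiable without the original 23,847-sequence database.

## Worked example

```r
library(nifHeval)

p <- nifh_primer("Nh21F", "GCIWTYTAYGGNAARGG", "forward", c(19, 35))
p
#> <nifh_primer> Nh21F  GCIWTYTAYGGNAARGG  (forward, universal, pos 19-35, degeneracy 64)
tm_range(p)
#> <tm_range> Nh21F: 49.0-60.0 degC

# a 100-record synthetic database: sites planted for three registry primers,
# 20% of F2-window-spanning records carry one planted F2 mismatch
cfg <- synth_config(n = 100, seed = 42, primers = c("Nh21F", "F2", "R6"),
                    mm_fractions = list(F2 = c(`1` = 0.2)), span = "amplicon")
sy <- generate_synthetic_db(cfg)
sy$db
#> <aligned_db> 100 records x 882 columns, reference SYNTH_REF (882 nt)
#>  groups: Cy=15 Ep=5 Fr=5 IA=10 III=15 IV=10 Pb=5 Pr=35

f2 <- registry_primer(nifh_primers("all"), "F2")
primer_coverage(sy$db, f2, k = 0)
#>   primer stratum k numerator denominator percent
#> 1     F2     all 0        24          30      80
primer_coverage(sy$db, f2, k = 1)
#>   primer stratum k numerator denominator percent
#> 1     F2     all 1        30          30     100
```

Reading this: 30 of the 100 fragments span F2's binding window 115–131
(the denominator — fragments without data there are not penalised); 6 of
them carry the planted mismatch, so coverage is 24/30 = 80% at zero
mismatches and 100% when one mismatch is allowed — exactly the generator's
ground truth.

```r
pr <- registry_pair(nifh_pairs("universal"), "F2/R6")
pair_coverage(sy$db, pr)
#>    pair stratum k numerator denominator percent
#> 1 F2/R6     all 0        20          22      91
head(find_amplicons(sy$db, pr), 3)
#>          id fwd_ref_start rev_ref_end length_ref length_template fwd_mm rev_mm
#> 1 SYNTH_REF           115         473        359             359      0      0
#> 2   SYN0002           115         473        359             359      0      0
#> 3   SYN0005           115         473        359             359      0      0
```

The predicted F2/R6 product is 359 bp (reference positions 115–473), the
expected length for that pair. The full report bundle — coverage tables for
all 86 primers and 61 pairs, depth profile, primer map — is produced by
`run_full_evaluation(run_config())`, or from the shell via the CLI wrapper
(`inst/cli/nifheval`): `evaluate`, `pairs`, `tm`, `depth`, `map`,
`simulate`, `all`.

## Notes

Published values are kept verbatim: primers suspected to contain
publication errors (YAA-poly, nifHRb, roeschF-1b, AMR-R) are flagged, not
corrected; a handful of printed degeneracies that follow a different
inosine convention (or appear to be misprints) are preserved in
`deg_printed` with notes. See `vignettes/methods.Rmd` for the models,
conventions, and known limitations.
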