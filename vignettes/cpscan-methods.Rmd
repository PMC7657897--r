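---
title: "Methods: E-box scanning and CPS functional classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: E-box scanning and CPS functional classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpscan)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, and the choices made where the
design was genuinely open.

## The biological problem

Soda-lake tilapia of the genus *Alcolapia* excrete nitrogenous waste as
urea rather than ammonia — a necessity at ambient pH around 10, where
ammonia cannot be off-loaded across the gills. Two molecular signatures
accompany this adaptation, and each maps onto a computational analysis:

* **Regulatory**: the first urea-cycle enzyme, carbamoyl-phosphate
  synthetase (CPS III), is expressed in skeletal muscle, suggesting
  control by the myogenic transcription factor MyoD. MyoD binds E-boxes
  (consensus `CANNTG`), prefers `CAG(G/C)TG`, and acts cooperatively at
  *paired* sites. The promoter analysis asks: does the CPS upstream
  region carry a paired MyoD E-box, and do related species carry only
  degraded versions of it?

* **Enzymatic**: fish CPS III hydrolyses glutamine through a Cys-His-Glu
  catalytic triad in its glutamine-amidotransferase (GAT) domain, aided
  by two further glutamine-binding residues; terrestrial CPS I runs on
  free ammonia instead. The protein analysis asks: which of those five
  diagnostic residues does each CPS sequence retain, and what does that
  imply about its nitrogen donor?

## Degenerate motif scanning

A pattern is a string of IUPAC codes; each code denotes a set of bases
(`S` = {G,C}, `N` = {A,C,G,T}). A length-m window matches with mismatch
count d when exactly d of its positions fall outside the corresponding
code's set. This symbol-wise count equals the minimal Hamming distance
over all concrete sequences the pattern stands for, which is what the
test suite's brute-force oracle enumerates.

Decisions worth stating:

* **Subject `N` never matches** any pattern symbol, including pattern
  `N`. An unknown base cannot confirm a motif; the alternative inflates
  hit counts in low-quality assembly stretches.
* **Overlapping hits are all reported** — E-boxes can abut — but
  *pairing* requires non-overlap, since a cooperative pair needs two
  distinct sites.
* **The gap is the number of bases strictly between two hits**
  (`second_start − first_end − 1`). This is the only convention under
  which the published paired site, whose two hexamers span a 31-mer,
  has its two E-boxes "within 19 bases", and it makes the default
  `max_gap = 19` the one quantified pairing distance available. Both are
  configurable.
* **Forward-strand scanning is the default.** Published promoter
  annotations are drawn on the given strand; whether the original survey
  also considered the reverse strand is unstated, so `strands = "both"`
  is available by flag rather than guessed at. Minus-strand hits are
  reported in forward coordinates; the strand-symmetry property (scan of
  the reverse complement with the reverse-complemented pattern gives the
  mirror-image coordinate set) is under test.
* **Near-misses** are windows at Hamming distance 1..k (exact matches
  excluded), each annotated with the offending base and one allowed
  replacement. Distance is substitution-only — the motivating
  observation is a site "a single point mutation" away from functional —
  so indels are out of scope.
* **Ordering** is deterministic: hits sort by (seq_id, start, strand,
  label); paired hits of two near-misses are not reported (only
  exact/exact and the exact/near-miss "presumptive" category have an
  interpretation in this analysis).

Upstream coordinates place the last base of a record immediately 5' of
the TSS: position p of a length-L region lies L − p + 1 bases upstream.
Whether a published distance range measures to a motif's distal or
proximal edge is ambiguous, so both distances are always reported;
`upstream_coords()` and `upstream_to_coords()` are exact inverses.

Internally coordinates are 1-based inclusive; BED output converts to
0-based half-open. The naive O(L·m) scan is adequate at the 3.5 kb scale
this analysis targets; no genome-scale optimisation is attempted.

## CPS classification

Diagnostic positions are **configuration, not constants**: published
alignment figures mark the triad and glutamine-binding residues
graphically without printing residue numbers, so `diagnostic_spec()`
takes reference-anchored 1-based ungapped positions (with a YAML
template under `inst/extdata/` whose placeholder positions sit inside
the conventionally figured 278–397 window and must be filled from figure
inspection or the biochemical literature before production use).

`map_ref_positions()` maps reference position p to the alignment column
holding the reference row's p-th non-gap character. Each sequence's
residue at each mapped column is `match` (equals the expected letter),
`divergent`, or `gap`; `X` counts as divergent with an
"ambiguous residue" flag, since an unknown residue cannot confirm a
match.

The decision table (see `?classify_cps`) is total and deterministic over
all 3^5 = 243 state combinations, which the tests enumerate. Two rules
deserve their rationale:

* **Any gap → `INDETERMINATE`**, even when another residue is already
  divergent. A gap is absence of evidence, not evidence of loss; a
  truncated or badly aligned sequence should not be called
  ammonia-obligate on the strength of the residues it happens to retain.
  This also resolves the one ambiguity in the rule set (divergent triad
  entry plus a gap elsewhere) deterministically.
* **No weighting, no phylogenetic correction.** The classification
  mirrors the qualitative biochemical rule; it considers exactly the
  configured positions.

### The built-in aligner

For single-query use the package carries a global Needleman–Wunsch
aligner with affine gaps (a length-L gap costs
`gap_open + L × gap_extend`; defaults 11 and 1 with BLOSUM62, the common
protein-search settings). The alignment tool behind the original
figures is unstated, so this aligner is a documented stand-in, not a
reproduction. Tie-breaking is fixed — substitution preferred over gap,
gap-in-query over gap-in-reference — so output is deterministic. Tests
check the score against an exhaustive enumeration of the alignment
lattice for sequences up to length 6 and against an independent aligner
implementation at matched gap parameters. The dynamic program is plain
R: at the few-hundred-residue scale of GAT-domain queries, runtime is
negligible.

Column conservation follows the shading rule of alignment figures: the
fraction of rows carrying the modal residue, gaps excluded from
numerator and denominator; all-gap columns are undefined (`NA`), and the
default threshold for calling a column conserved is 1.0 (strict
identity).

## In-silico PCR

An amplicon runs from the 5' end of the forward-primer site to the
template base complementary to the reverse primer's 5' end — inclusive
of both footprints, the standard PCR product definition and the one
under which the published 19 + 361 + 19 = 399 bp product is
reproducible. The 3'-terminal base of each primer must match even when
internal mismatches are budgeted (polymerase extension requires a paired
3' end), the default budget is 0, and all site combinations are
reported with no preferred product. The real coding sequence is not
redistributable here, so the shipped template
(`cps3_cds_synthetic.fasta`) is a synthetic stand-in carrying the true
primer sites at the published geometry; it verifies the computation,
not the accession.

## Synthetic data: what it emulates, and what it does not

`sim_promoter()` draws an i.i.d. background with
P(G) = P(C) = gc/2 and overwrites it with implants at known positions,
returning a truth table. Defaults are the study conditions: 3500 bp
regions; GC 0.41, a typical teleost genome-wide value (no value is
published for these regions). The background has **no dinucleotide
structure, no CpG islands, no repeats** — it is a correctness harness
for the scanner, not a promoter model, so passing recovery tests says
nothing about motif discovery specificity in real genomes. Chance
background occurrences of an implanted motif are deliberately not
suppressed (suppression would bias the background); recovery tests
filter on a brute-force oracle confirming the implants are the only
occurrences.

`sim_protein_family()` copies a reference, clamps the five diagnostic
positions to class-consistent residues, and applies i.i.d. substitutions
elsewhere (default 0.05 per site, a mid-range protein-family divergence).
Because diagnostic sites never receive noise, classifier agreement with
truth must be exact — the recovery test checks the plumbing
(position mapping, state extraction, decision table), not robustness to
divergence at the diagnostic sites themselves. Real families add indels,
rate variation across sites, and phylogenetic correlation, none of which
are modelled. The `AMMONIA_OBLIGATE` default diverges the catalytic Cys
(the canonical CPS I lesion); `obligate_mode = "gln_both"` instead
diverges both glutamine-binding residues (the bullfrog configuration).
Both generators use one explicitly seeded RNG stream per call, record
the seed in output headers, and leave the caller's RNG state untouched.

## Problem sizes and numerical choices

The test suite runs the scanner/oracle equivalence on 1000+ random
instances (sequences ≤ 50 nt, patterns ≤ 8 symbols, mismatch budgets
0–2), the aligner oracle on sequences ≤ 6 residues, classification
recovery on families of 30–60 sequences over a 100–150 residue
reference, and promoter recovery at the full 3500 bp scale; these sizes
were chosen to exercise every code path while keeping the whole suite
around a minute. There is no floating-point subtlety anywhere in the
package — scores and counts are integer-valued throughout (BLOSUM62 is
integral) — so all test comparisons are exact.

## Known limitations

* Motif matching is substitution-only; an indel-containing E-box variant
  is invisible.
* The classifier trusts the supplied alignment or the built-in aligner;
  a misaligned reference row silently shifts every diagnostic column
  (the mapped columns are reported so this can be audited).
* Amplicons are predicted from sequence identity only — no melting
  temperature, secondary-structure or efficiency model.
* The synthetic generators' i.i.d. assumptions are stated above; they
  bound what the green test suite demonstrates about real data.
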