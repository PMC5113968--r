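---
title: "Preparing and benchmarking comparative-modeling inputs with cmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preparing and benchmarking comparative-modeling inputs with cmtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmtools)
```

## Scope

Comparative (homology) modeling predicts a protein's structure from
homologous experimental structures. The modeling engine itself (MODELLER and
its kin) is mature; what routinely goes wrong in practice is the *input
preparation*: sequences extracted from template PDB files disagree with
their coordinates, missing and chemically modified residues are mishandled,
alignments let the target dangle past the template so the engine invents
unsupported terminal loops, and ligands the user wants carried into the
model are dropped or mis-indexed in the alignment file.

`cmtools` implements this preparation layer and the evaluation machinery
needed to benchmark it: PDB parsing into a residue-status model, search
report parsing (BLAST XML, HHsearch hhr), alignment trimming, validation
and identity binning, PIR construction with ligand grafting, the four
standard model-quality scores (RMSD, TM-score, GDT-HA, lDDT), and a
filter-based benchmark protocol, all exercised offline against a synthetic
fixture generator. Running the external programs (search, alignment,
modeling, statistical-potential scoring) is out of scope; their outputs are
inputs here.

## Residue status and sequence extraction

Every polymer position of a chain carries one of three statuses:

* `observed_standard` — a standard amino acid with coordinates;
* `observed_modified` — a chemically altered residue with coordinates
  (selenomethionine and friends);
* `missing` — present in the construct but unresolved (no coordinates).

The same annotated sequence renders differently per pipeline stage:
alignment-stage output masks missing *and* modified positions as `X` so the
aligner treats them as unknowns; PIR-stage output maps missing to `-` and
modified to `.`, which is how the modeling engine distinguishes them.

Detection precedence was an open design point, since both header routes
occur in the wild:

1. `REMARK 465` entries are authoritative when present.
2. Otherwise, if `SEQRES` is present, missing runs are inferred by
   exact-match anchoring of the observed residues inside the SEQRES
   sequence; author numbers for the inferred positions are interpolated.
3. With neither, the chain is assumed complete.

Modified residues come from `MODRES` records first; failing that, any
in-chain HETATM whose code has a known parent amino acid (MSE, SEP, TPO,
PTR, CSO) and whose author number falls inside the chain's polymer range is
treated as modified. Alternate locations collapse to the first conformer —
the pipeline cares about sequence and topology, not conformer geometry.
Insertion codes are part of residue identity and file order is never
re-sorted. Every other HETATM is a ligand record, indexed by its
coordinate-section ordinal; waters are flagged and excluded from listings
unless requested.

## Identity, bins, trimming, coverage

Sequence identity between two gapped sequences is
`100 x (identical both-non-gap columns) / (both-non-gap columns)`, and an
`X` column never counts as identical. This convention matters: BLAST
reports identities over the full alignment length (gap columns included),
so the parsed search-report identity and the recomputed alignment identity
are kept as separate quantities; binning defaults to the recomputed value.

Benchmark bins are lower-inclusive decades over [20, 90): an identity of
exactly 30 belongs to [30,40). Identities outside the range are excluded.

Terminal trimming removes leading and trailing alignment columns up to the
first and last column where the target residue has support from at least
one template — support meaning a non-gap template position that is not a
masked missing residue. With multiple templates, support from *one*
template suffices; requiring all templates would forbid the common pattern
where an extra template is added precisely to extend one terminus.
Interior columns are never touched; trimming is idempotent.

Target coverage divides the supported target residues inside the post-trim
span by the *full* target length, trimmed termini included. Using the
trimmed length as denominator would make the benchmark's 80% coverage
filter unfailable by construction.

Manual alignment edits are validated with the interactive-editor rules:
template sequences may have gaps moved or added anywhere but may only be
trimmed from the outside (the ungapped edit must be a contiguous substring
of the ungapped original); the target may be edited freely as long as only
amino-acid letters and `-` appear.

## PIR construction

A PIR entry set carries one `structureX` entry per template (with the
start/end author residues and chain that tie the alignment to the
coordinate file) and the target as a final `sequence` entry. Sequence
bodies are wrapped at 75 columns and terminated with `*`; line endings are
LF. The serializer is byte-stable and golden-file tested.

Template spans are resolved by matching the entry's residue content
(gaps removed, `.` matching any modified residue) against the chain's
observed residues; zero or multiple matches are errors, so a span is only
ever written when it is unambiguous. Each entry is then verified
position-by-position against the structure: letters must match observed
standard residues, `.` must sit on modified residues, and `-` is accepted
either as an alignment gap or as the rendering of a missing residue at
that polymer position (the walk consumes missing positions greedily, which
is order-safe because polymer order is fixed).

Ligand grafting follows the ending-residue rule: the selected ligand that
occurs last in the coordinate section becomes the template's new end
residue, and one column is appended for every polymer residue after the
old end and every HETATM record up to and including that ligand. The
target is padded with `-` and switched to `.` exactly at the columns of
*selected* ligands. Two readings of the rule are possible for unselected
HETATMs that precede the last selected one; we append them as template
columns with `-` in the target, which keeps the template entry faithful to
the coordinate file while requesting only the chosen ligands — the
narrower reading is documented here deliberately. With several templates,
each selected template receives its own appended column block, and all
other entries are gap-padded across it.

Job configurations default to 10 models per run with very-slow refinement,
the settings used for the automated benchmark; `none` and `fast` are the
alternative refinement levels. The HETATM/water read flags follow from the
selection (any non-water ligand sets `read_hetatm`, any water sets
`read_water`). The emitted modeling script is a template-filled stub for
inspection, never executed by this package.

## Structure-comparison scores

All scores pair residues by alignment-derived labels, never by raw author
numbering across different proteins, and default to CA atoms.

* **RMSD** comes from least-squares rigid superposition (Kabsch: SVD of
  the covariance matrix with the determinant correction that excludes
  reflections). Near-collinear point sets are rejected as ill-conditioned.
  The tests cross-check against an independent quaternion (Horn)
  closed-form implementation to 1e-6 Å.
* **TM-score** uses the standard length-normalized sum
  `1/L * sum 1/(1+(d_i/d0)^2)` with `d0 = 1.24 (L-15)^(1/3) - 1.8`, floored
  at 0.5 Å, normalized by the reference length. The maximization over
  superpositions is a fragment-seeded search: seed windows are superposed,
  then iteratively refined by re-fitting on the residues within a distance
  cutoff until the selection stabilizes; the best visited score is kept.
  For chains of at most 48 residues the seeds enumerate every contiguous
  window of every length; above that a ladder of window lengths
  (L, L/2, L/4, 7, 5, 3) with coarser strides is used. This is an
  approximation of the reference implementations' search; the tests hold
  it to an exhaustive refined-seed oracle on small pairs.
* **GDT-HA** averages, over the thresholds 0.5/1/2/4 Å, the maximal
  percentage of residues fitting under each threshold across the searched
  superpositions (each threshold drives its own refinement).
* **lDDT** is superposition-free: over all reference point pairs from
  different residues within a 15 Å inclusion radius, the fraction of
  pairwise distances preserved within 0.5/1/2/4 Å, averaged over the four
  tolerances. With `StructureModel` input all heavy atoms are used and
  same-residue pairs are excluded; with CA coordinate sets each point is a
  residue. No sequence-separation filter and no stereochemistry penalty
  are applied.
* **RMSD difference** subtracts the template-vs-target RMSD from the
  model-vs-target RMSD, a cheap correction for template-target
  conformational differences; negative values are meaningful.

Model sets whose members differ in length (different alignments trim
differently) are normalized by `longest_common_segment`, which restricts
every model to the longest contiguous run of labels present in all of
them, ties breaking to the earliest start.

## Benchmark protocol

A benchmark set is one (target, template) pair evaluated under five
alignment options. Three filters run in order:

1. **Bin consistency** — all five recomputed identities must fall in the
   same decade bin; realignment routinely moves borderline pairs across a
   boundary, which would make per-bin averages incomparable.
2. **Coverage** — at least 80% of the target modeled under *all five*
   options (boundary value included).
3. **Template-target RMSD outliers** — per bin, sets above the upper Tukey
   fence (Q3 + 1.5 IQR) are removed. The published protocol states that
   outliers were removed but not how; the one-sided Tukey fence is this
   package's choice (low RMSD is never suspect) and the multiplier is a
   parameter. The fence is computed once per invocation on the incoming
   distribution. Note that Tukey fences on a handful of values are blunt:
   with one or two sets per bin a gross outlier can survive; the filter is
   sharp from roughly four well-behaved sets per bin upward, which is why
   the synthetic benchmark defaults to `n_per_bin = 4`.

Top models are selected per aligner as the minimum of the supplied quality
scores (e.g. normalized statistical-potential Z-scores; the package never
computes them), with -1.0 or below flagged native-like. The self-template
remodel control builds a PIR in which the target's own structure is the
template — the pairing is 100% identity and the template entry still
renders the structure's missing/modified positions, so it exercises the
whole rendering/verification path under ideal modeling conditions.
Bookkeeping is the closed identity: total models = surviving sets x
alignment options x models per run.

## The synthetic generator

`generate_pair()` builds a target as a random sequence on an idealized
helical CA trace (2.3 Å radius, 100 degrees and 1.5 Å rise per residue,
giving the canonical ~3.8 Å consecutive-CA spacing) and derives the
template by mutating a sampled position subset to hit a requested
identity, adding isotropic Gaussian coordinate noise, deleting terminal
runs, recording missing runs (REMARK 465 plus absent ATOMs), marking MSE
modifications (MODRES plus in-chain HETATM) and appending single-atom
ligand HETATMs. The requested identity is interpreted over the true
alignment's both-non-gap columns, X-masked columns counting as mismatches;
specs whose masking makes the request unreachable are rejected rather than
silently adjusted. All randomness derives from the spec seed through R's
Mersenne-Twister with inversion sampling, so equal seeds give
byte-identical files.

`generate_benchmark()` scales this up: for each decade bin it draws sets
whose coordinate noise grows as identity falls (sigma from about 0.4 Å in
the 80s bin to about 2.3 Å in the 20s), emulates aligner disagreement by
planting short misalignments of varying width, synthesizes 10 quality
scores per aligner whose mean tracks identity, and plants labeled filter
failures: one low-coverage set, one bin-straddling set, and one
template-target RMSD outlier per bin. Synthetic "models" are the
template's coordinates over the aligned span relabeled to target numbering
with a small per-model perturbation.

What the generator deliberately does not emulate: real backbone geometry
and side chains, multi-chain assemblies, insertions/deletions beyond the
planted misalignments, correlated (domain-motion) deviations, and
multi-atom ligands. Passing tests therefore demonstrate the correctness of
the bookkeeping, rendering, filtering and scoring machinery under
controlled conditions — not modeling accuracy on real proteins, which
depends on the external programs this package does not run.

## Problem sizes and numerical choices

The shipped tests use 30-60 residue fixtures, 100 end-to-end PIR
constructions, 20-40 residue score toys against the exhaustive oracle,
20 noise seeds per sigma level for the degradation trends, and a
7-bin x 4-set benchmark with planted failures; these sizes were chosen so
the whole suite exercises every code path in a few minutes on one core.
Tie-breaks and tolerances worth knowing: identity rounding in the
generator resolves exact halves toward lower identity; top-model ties
break to the earlier model id; the longest-common-segment tie breaks to
the earliest start; rotation matrices are accepted as proper within 1e-6;
and the span matcher refuses ambiguous matches outright rather than
picking the first.

## Known limitations

* hhr parsing targets the summary-plus-alignment-blocks layout emitted by
  HHsearch; exotic header variants may need widening.
* The SEQRES-based missing-residue inference anchors exact matches
  greedily; heavily engineered constructs (tags absent from SEQRES,
  sequence conflicts) can defeat it, in which case REMARK 465 input is
  required.
* lDDT here implements the distance-preservation core without the
  stereochemistry checks of the reference tool.
* TM/GDT values above the exhaustive-seed regime (chains > 48 residues)
  are lower bounds from a heuristic seed ladder, as in the reference
  implementations, and can in principle undershoot the true optimum.
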