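# cmtools — comparative-modeling input preparation and benchmarking

`cmtools` is an R toolkit for the unglamorous but error-prone layer of
template-based protein structure prediction: turning a target sequence,
template structures and a target–template alignment into *correct* inputs
for a comparative-modeling engine, and measuring how good the resulting
models are.

It is aimed at structural bioinformaticians who drive MODELLER-style
engines from scripts or pipelines and need the surrounding plumbing to be
testable: parsing template PDB files without losing missing/modified
residue information, consuming BLAST/HHsearch reports, trimming and
validating alignments, writing PIR files (including ligand records), and
benchmarking models with the field's standard scores.

## What it computes

* **Annotated structure parsing** — PDB files become residue-level models
  in which every polymer position is `observed_standard`,
  `observed_modified` (MODRES / in-chain MSE-type HETATMs) or `missing`
  (REMARK 465, or inferred from SEQRES). The same chain renders as an
  `X`-masked sequence for alignment or as `-`/`.` for PIR output.
  Non-polymer HETATMs become an ordered ligand table.
* **Hit parsing** — BLAST XML (outfmt 5) and HHsearch `.hhr` reports are
  reduced to one uniform hit table: PDB id, chain, % identity, % query
  coverage, e-value and the pairwise alignment.
* **Alignment operations** — identity over both-non-gap columns
  (`X` never matches), lower-inclusive decade bins on [20, 90), terminal
  trimming to template-supported columns, coverage over the full target
  length, and validation of manual edits (templates: gaps anywhere, trims
  only from the outside; targets: any edit over amino-acid letters and
  `-`).
* **PIR construction** — MODELLER-dialect files with per-template start/end
  author residues resolved from and verified against the structures, and
  ligand grafting: selected HETATMs become `.` columns, the last selected
  ligand becomes the template's ending residue.
* **Structure comparison** — Kabsch superposition RMSD, TM-score
  (`d0 = 1.24 (L−15)^{1/3} − 1.8`, floored at 0.5 Å), GDT-HA
  (mean of the maximal fit fractions under 0.5/1/2/4 Å) and
  superposition-free lDDT (distance preservation within a 15 Å inclusion
  radius, 0.5/1/2/4 Å tolerances), plus model-set normalization to the
  longest common segment and the template-corrected RMSD difference.
* **Benchmark protocol** — per-set evaluation under five alignment
  options, three filters (bin consistency, ≥80% coverage for all five,
  per-bin Tukey-fence removal of template–target RMSD outliers),
  top-model selection from supplied quality scores (≤ −1.0 flagged
  native-like), per-bin score summaries and model-count accounting
  (sets × 5 options × 10 models per run).
* **Synthetic fixtures** — a deterministic generator of target/template
  PDB pairs, search reports and full benchmark collections with planted
  filter failures, so everything above is testable offline.

## Worked example

Build a synthetic 60-residue target and a noisy template at ~55% identity
with two missing residues, one selenomethionine and two ligands; prepare
the grafted PIR file; score the template against the target:

```r
library(cmtools)

spec <- fixture_spec(seed = 42, length = 60, target_identity_pct = 55,
                     coord_noise_sigma = 1.0,
                     missing_runs = list(c(20L, 2L)), modified_positions = 35L,
                     ligands = c("ADP", "MG"), terminal_deletions = c(2L, 2L))
pair <- generate_pair(spec)
tpl <- parse_pdb(pair$template_pdb, pdb_id = pair$template_id)
tpl
#> StructureModel 'tp000042': 1 chain(s), 56 polymer residue(s) (2 missing, 1 modified), 2 ligand record(s)

list_ligands(tpl)
#>   het_code chain resno icode coord_index is_water n_atoms
#> 1      ADP     A   159                 0    FALSE       1
#> 2       MG     A   160                 1    FALSE       1

compute_identity(pair$alignment$seqs[1], pair$alignment$seqs[2])  # 55.4
compute_coverage(pair$alignment)                                  # 90
assign_bin(55.4)                                                  # "[50,60)"

mods <- setNames(list(tpl), pair$template_id)
pir <- build_pir(trim_termini(pair$alignment), mods,
                 chains = setNames("A", pair$template_id))
pir <- graft_ligands(pir, mods,
                     data.frame(template = pair$template_id,
                                het_code = c("ADP", "MG"), coord_index = 0:1))
cat(write_pir(pir))
#> >P1;tp000042
#> structureX:tp000042.pdb:3:A:160:A::::
#> AVDWSPEDWFVWKNHIC--LRGTAIGPGEAMM.DRWNFCITRLNLLIAVWFEDMIH..*
#> >P1;tg000042
#> sequence:tg000042::::::::
#> AIDWTPEDCFVWPNHDCMCVRGNAILPGDDWMMDRWNTWQQRVNRQIGCATEDMIH..*
```

The template entry starts at author residue 3 (two N-terminal residues are
absent from the construct), renders the two missing residues as `--` and
the selenomethionine as `.`, and ends at residue 160 — the MG ion — with
the two grafted ligand columns (`..`) present in both entries.

```r
tgt <- parse_pdb(pair$target_pdb, pdb_id = pair$target_id)
score_set(as_coord_set(tpl, "A"), as_coord_set(tgt, "A"))
#>   rmsd    tm gdt_ha  lddt
#> 1  1.6 0.724   55.1 0.663
```

A miniature benchmark with planted filter failures:

```r
bench <- generate_benchmark(n_per_bin = 4, seed = 1)
res <- run_benchmark(bench, score_models = FALSE)
res$removed            # exactly the planted sets, by stage
res$accounting         # 28 sets x 5 aligners x 10 models = 1400
```

A thin command-line wrapper for both flows is installed at
`inst/scripts/cmtools-cli.R` (`fixtures` and `bench` subcommands).

## Documentation

The methods vignette (`vignettes/modeling-input-preparation.Rmd`) explains
the residue-status model, the identity/trimming/coverage conventions, the
PIR dialect and ligand-grafting rules, the score definitions and their
search strategy, the benchmark filters (including the Tukey-fence choice
for the outlier rule), and what the synthetic generator does and does not
emulate.
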