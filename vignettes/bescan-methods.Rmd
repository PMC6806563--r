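---
title: "Methods: strand-aware base-editor targetability in bescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-aware base-editor targetability in bescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bescan)
```

## The problem

Cytosine base editors (CBEs) are CRISPR-Cas/deaminase fusions that convert
C•G pairs to T•A within a short *editing window* of the protospacer,
without double-strand breaks. Two questions drive experimental design with
these enzymes:

* **create** — can a pathogenic C-to-T (or, equivalently, G-to-A on the
  opposite strand) SNV be installed at a given locus to model a disease?
* **correct** — can a pathogenic T-to-C (A-to-G) allele, which presents a
  C on one strand, be reverted back to T?

Both reduce to the same geometric question: is there at least one
protospacer placement such that (i) the target cytosine falls inside the
editor's editing window and (ii) the editor's PAM is present immediately
adjacent to the protospacer? `bescan` answers it for a configurable panel
of editors, classifies *bystander* cytosines (other Cs in the window, at
risk of co-editing) and *preferential* targets (the target C is the only C
in the window), and provides the accompanying amplicon-sequencing outcome
metrics.

## Coordinate model

All window positions are counted 5'→3' along the protospacer, position 1
at its 5'-most base. This single rule reproduces both conventions in use:

* for a **3'-PAM** (Cas9-family) editor, position 1 is the **PAM-distal**
  base;
* for a **5'-PAM** (Cpf1/Cas12a-family) editor, position 1 is the
  **PAM-proximal** base.

Internally every interval is 0-based half-open; genomic coordinates are
1-based inclusive on input (VCF/ClinVar dialects) and output, and the
free-sequence scanner reports 0-based half-open intervals over the input
string. Round-trips between the two are exact by construction and tested.

The enumeration itself slides the window rather than the genome: for each
window position $p \in [w_s, w_e]$ the protospacer is placed so the target
C sits at $p$, and the placement is kept iff the PAM (IUPAC-degenerate
match) sits immediately 3' or 5' of it. This visits exactly the placements
a naive full scan would keep, which is what the oracle-equivalence tests
assert against an independent brute-force enumerator that shares no code
with the production path.

## The editor panel

The bundled panel (`load_panel()`) holds 20 published CBEs in a
human-editable TSV (`inst/extdata/editor_panel.tsv`); the file, not the
code, is the single source of truth, and each row carries a citation
field naming the primary publication its geometry was transcribed from.
Geometries are per-editor: Cas9-family spacers are 20 nt (21 nt for the
SaCas9 variants), the Cas12a editor uses a 23 nt spacer with a 5' TTTV
PAM and an 8–13 window; narrowed-window (YE1/YE2/YEE/Target-AID) and
altered-PAM (VQR/EQR/VRER/NG) variants carry their published values.
Custom editors are first-class via `make_custom_editor()` and are accepted
anywhere a panel editor is.

Validation is strict at construction: `1 ≤ window_start ≤ window_end ≤
spacer_length`, PAM restricted to IUPAC codes, unique names within a
panel. Efficiency differences between editors are deliberately out of
scope — the model is geometry only, so a "targetable" verdict means *a
compatible placement exists*, not *editing will be efficient*.

## Decisions taken where the design was open

* **PAM matching is conservative.** An N (or any ambiguity code) in the
  *genome* never satisfies a PAM or protospacer position; such placements
  are rejected and tallied separately rather than optimistically matched.
* **Bystanders are target-strand cytosines only.** The deaminase acts on
  the displaced strand; a G inside the window (a C on the other strand) is
  not counted as a bystander.
* **A variant is "preferential" for an editor if ANY of its valid guides
  is bystander-free** (`preferential_rule = "any"`, switchable to
  `"all"`). The alternative reading — all guides bystander-free — is
  stricter but discards the practically relevant case where one clean
  guide exists among several.
* **All valid placements are reported**, not just one per editor; a
  `first_only` flag collapses to the terse single-guide view (smallest
  window position, ties to the leftmost protospacer start).
* **Correction mode edits the patient allele**: the pathogenic C (the alt
  allele) is substituted into the reference flank *before* guide search,
  since the sequence being edited in a correction experiment carries the
  mutation.
* **Significance filtering is an exact label match** ("pathogenic",
  case-insensitive). Compound labels such as "Pathogenic/Likely
  pathogenic" are excluded by default and can be admitted through
  `significance_labels`.
* **Duplicate rows are collapsed by (chrom, pos, ref, alt)** after the
  label filters, with a flag to disable; public variant tables often carry
  one row per assembly or per submission.
* **Reference mismatch is a hard error.** If the genome base at a
  variant's coordinate differs from the declared ref allele the pipeline
  stops; silent coordinate drift is the worst failure mode of this kind
  of tool.
* **Flank width** defaults to 30 nt each side (61 nt total context). The
  precondition `flank ≥ spacer_length + PAM length − 1` is checked against
  the selected panel and the flank is widened automatically (with a
  message) when an editor could otherwise reach beyond it.

## Quantification metrics

From SAM alignments over an amplicon (or the simplified pileup TSV used in
tests), the module computes:

* **indel frequency** = reads with ≥1 inserted/deleted nucleotide
  overlapping the region ÷ **mapped** reads;
* **substitution frequency** at a position = reads carrying the
  substituted base ÷ **total** reads.

The asymmetry between the two denominators is intentional and preserved
from the metric definitions this module implements; a `denominator`
argument switches the substitution metric to mapped reads for users who
prefer symmetry.

* **product purity** at a reference C = C→T reads ÷ (C→T + C→A + C→G)
  reads. With no edited reads the value is `NA` — an explicit undefined
  marker, never a silent 0. The alternative normalisation (C→T over all
  reads) is available via `mode = "of_all_reads"`.
* **normalisation to a reference editor** rescales per-editor values so
  the reference (BE3 by convention) reads 100%.
* **one-tailed Wilcoxon rank-sum test**: exact by enumeration of all
  $\binom{n_1+n_2}{n_1}$ rank assignments when the combined sample size is
  ≤ 20 without ties; normal approximation with tie and continuity
  correction otherwise. The exact path is validated against closed-form
  cases (e.g. $p = 1/20$ for $\{1,2,3\}$ vs $\{4,5,6\}$, one-sided) and
  the approximate path against `stats::wilcox.test` to $10^{-9}$.

## The synthetic-data generator and what it shows

All test inputs are generated in code with recorded ground truth:

* `generate_genome()` — i.i.d. random genomes at a requested GC content
  (default 0.5; the panel-statistics cohort uses 0.41, a realistic
  mammalian genome-wide GC).
* `plant_variants()` — SNVs of both edit classes planted at random
  eligible sites; the true targetable/preferential flags per editor come
  from the naive brute-force enumerator, never the production path.
* `generate_clinvar_fixture()` — a 1,000-row variant table mixing planted
  pathogenic SNVs with distractors (wrong significance, indel types,
  wrong assembly) in fixed proportions, with the planted composition
  recorded for exact-recovery checks.
* `simulate_reads()` — amplicon reads with planted editing rate 0.30,
  purity 0.90 and indel rate 0.05 at n = 10,000 reads (the package's
  standard recovery conditions); each read independently receives a 1-bp
  indel overlapping the edit site, or a C→T (probability purity) / C→A/G
  substitution.

These fixtures emulate the *combinatorics* of the problem — strand,
window, PAM, bystander configurations, class mixtures — not the biology of
real genomes: no repeat structure, no chromatin, no sequencing error
model, constant base quality, uniform base composition. Passing tests
therefore certify the geometry and the arithmetic, not editing efficiency
or behaviour on any particular human locus. Headline fractions computed on
synthetic cohorts (e.g. "~93% of planted SNVs targetable by ≥1 of 20
editors" at the sizes above) are properties of the simulation conditions,
not estimates for real variant databases, which additionally depend on the
database snapshot and genome build used.

## Problem sizes and numerics

The validation suite runs 1,000 oracle-equivalence cases (random 61-mers ×
random editor geometries), 500 strand-symmetry cases, 100
degenerate-limit cases, a 1,000-row filter-recovery table, a 300-variant
panel-statistics cohort over a 2×20 kb genome, and one 10,000-read
quantification recovery — sizes chosen so the whole suite completes in
about a minute on a laptop while keeping binomial standard errors small
(recovery assertions use 3 SE bands). All randomness flows from explicit
seeds; regeneration is byte-identical.

Degenerate inputs are handled explicitly: zero guide candidates is a valid
non-targetable verdict, empty filter input yields empty output with zero
step counts, truncated flanks at contig edges warn and record the
truncation, and undefined ratios (no mapped reads, no edited reads, zero
reference value) raise errors or `NA` markers rather than returning 0.

## Known limitations

* Geometry-only verdicts: no efficiency, context-preference (e.g. TC
  motif), chromatin or off-target modelling.
* SNVs only: indels and multi-allelic records are skipped on input.
* No liftover: coordinates are taken on the assembly the input declares.
* Adenine-editor windows are not modelled; T-to-C correction treats the
  mutant C as an ordinary cytosine target.
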