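# bescan

Strand-aware targetability prediction for CRISPR cytosine base editors.

Cytosine base editors (CBEs) convert C•G to T•A inside a short *editing
window* of the protospacer, provided a PAM sits adjacent to the
protospacer. `bescan` decides, for a panel of 20 published CBEs (or any
custom geometry), whether a given single-nucleotide variant can be
**created** (a pathogenic C-to-T / G-to-A change installed, to model
disease) or **corrected** (a pathogenic T-to-C / A-to-G allele — which
presents a C — reverted), and designs the gRNA spacers that do it.

For a target cytosine at protospacer position *p*, an editor with spacer
length *L*, window *[w_s, w_e]* and (IUPAC) PAM *P* yields a valid guide
placement iff *w_s ≤ p ≤ w_e* and *P* matches the sequence immediately 3'
(Cas9-family) or 5' (Cpf1-family) of the protospacer. Window positions
are counted 5'→3' from the protospacer's 5' end, so position 1 is
PAM-distal for 3'-PAM editors and PAM-proximal for 5'-PAM editors. Other
window cytosines on the target strand are *bystanders*; a placement with
none is *preferential*. The package also implements amplicon
deep-sequencing outcome metrics: indel frequency (indel reads / mapped
reads), substitution frequency (substituted reads / total reads), product
purity (C→T among C→N edits), reference-editor normalisation, and the
one-tailed Wilcoxon rank-sum test (exact for small samples).

It is aimed at genome engineers choosing an editor and guide for a locus,
and at bioinformaticians profiling editability across variant tables
(ClinVar-style TSV or VCF input).

## Worked example

Scan a sequence for editable cytosines/guanines with two panel editors:

```r
library(bescan)
panel <- load_panel()                      # bundled 20-editor panel
seq <- "GATTACAGATCCGATTTACGGATTAGGCTAAGGTTTACCGGATTACAGGA"
hits <- scan_sequence(seq, select_editors(panel, c("BE3", "hA3A-eBE-Y130F")))
head(hits[, c("target_index", "target_base", "editor", "strand",
              "window_pos", "spacer_seq", "pam_seq", "preferential")])
#>   target_index target_base         editor strand window_pos
#> 1           10           C            BE3      +          7
#> 2           10           C hA3A-eBE-Y130F      +          7
#> 3           11           C            BE3      +          8
#> 4           11           C hA3A-eBE-Y130F      +          8
#> 5           25           G            BE3      -          8
#> 6           25           G hA3A-eBE-Y130F      -          8
#>             spacer_seq pam_seq preferential
#> 1 ACAGATCCGATTTACGGATT     AGG        FALSE
#> 2 ACAGATCCGATTTACGGATT     AGG        FALSE
#> 3 ACAGATCCGATTTACGGATT     AGG        FALSE
#> 4 ACAGATCCGATTTACGGATT     AGG        FALSE
#> 5 CCTTAGCCTAATCCGTAAAT     CGG        FALSE
#> 6 CCTTAGCCTAATCCGTAAAT     CGG        FALSE
```

Row 1 reads: the C at 0-based position 10 sits at window position 7 of a
plus-strand BE3 protospacer whose PAM is AGG; `spacer_seq` is the 20-mer
one orders as the gRNA spacer. Rows 5–6 target a G — a cytosine on the
minus strand — so the spacer is the reverse-complement context.
`preferential = FALSE` because another window cytosine would be co-edited
(a bystander). The exact small-sample rank-sum test:

```r
rank_sum_one_tailed(c(1, 2, 3), c(4, 5, 6), "less")
#> [1] 0.05
```

The same engine runs from the shell (`exec/bescan`): `panel list`,
`search` (genome FASTA + variant table → per-candidate and per-variant
TSVs), `scan`, `quant` (SAM → metrics), `simulate`.

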