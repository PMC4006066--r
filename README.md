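# sxrna

Discovery of *trans*-acting three-way junctions between small RNAs and
mRNA stem-loop motifs.

Many RNA-binding proteins (RBPs) bind stem-loop motifs in mRNA — the
histone stem-loop (HSL) bound by SLBP, or the iron-response element
(IRE) bound by iron-regulatory proteins. A small non-coding RNA can
modulate such a motif in *trans*: rather than forming a contiguous
duplex, it can hybridize discontinuously to the two mRNA segments
flanking the stem-loop, splinting them together at the base of the stem.
The motif stem and the two trans helices then meet around a central
unpaired region — a three-way junction (3WJ) assembled from two
molecules. Depending on where the small RNA binds, it either
**induces**/strengthens the RBP motif (splinting the non-conserved
flanks) or **represses** it (hybridizing onto the conserved stem/loop
and ablating the structure).

This package is the computational screen for such interactions. Given
transcripts and a query set of small RNAs it:

1. finds stem-loop motif matches with a structured descriptor
   (built-in `hsl` / `ire`, or a YAML config) — `match_motif()`;
2. cofolds a ±25-base window around each motif (or the whole message)
   against each small RNA — `cofold()`, with a deterministic weighted
   base-pair-maximization reference backend (G:C = 3, A:U = 2, G:U = 1)
   and an optional external ViennaRNA `RNAcofold` backend;
3. parses the joint dot-bracket, verifies the motif stem is intact and
   the ncRNA splints both flanks, annotates the junction anchors
   (purple/blue/orange/green), measures junction segments (`mJ5`, `mJ3`,
   `nJ`), helices (`h5_pairs`, `h3_pairs`) and paired fractions, and
   classifies each candidate as `inducer`, `repressor` or `none` against
   configurable thresholds — `score_and_classify()`;
4. writes a deterministic TSV report — `scan_sxrna()`, `write_report()`.

A seeded fixture generator (`make_fixture_set()`) produces transcripts
with embedded motifs, designed splints with known junction geometry,
ablator negatives and dinucleotide-shuffled decoys, with ground truth —
the basis of the validation suite. See the methods vignette
(`vignettes/sxrna-methods.Rmd`) for the model, the anchor definitions,
threshold policy and the fixture design rationale.

## Worked example

A 30-nt transcript carrying one HSL (purine 5' flank, AA bulge, 16-base
stem-loop, 3' flank) and its designed splint:

```r
library(sxrna)

tx <- c(HIST_demo = "GAGAGAAAGGCUCUUUUCAGAGCCCACACC")
m  <- match_motif(builtin_descriptor("hsl"), tx[[1]], "HIST_demo")[[1]]
m
#> Motif 'hsl' on HIST_demo: span [9,24] stem5 [9,14] loop [15,18] stem3 [19,24] bulge {7,8}

sp <- make_splint(tx[[1]], m, splint_design(6, 6, gap = 2, gap_seq = "AA"),
                  id = "miR_demo")
cofold(tx[[1]], sp$seq)
#> GAGAGAAAGGCUCUUUUCAGAGCCCACACC&GGUGUGAAUCUCUC
#> ((((((..((((((....))))))((((((&))))))..)))))) (score 47.00)

cand <- scan_sxrna(tx, c(miR_demo = sp$seq), scan_config())
cand[, c("classification", "pass", "mJ5", "mJ3", "nJ",
         "h5_pairs", "h3_pairs", "ncrna_frac", "bulge_unpaired")]
#>   classification pass mJ5 mJ3 nJ h5_pairs h3_pairs ncrna_frac bulge_unpaired
#> 1        inducer TRUE   2   0  2        6        6  0.8571429           TRUE
```

The fold shows the three-way junction: the 16-base motif stem-loop in
the middle, the ncRNA's two arms pairing the flanks on either side of
it. The candidate is an inducer: both mRNA-side junctions are small
(`mJ5 = 2`, the AA bulge, left unpaired as SLBP binding requires;
`mJ3 = 0`, flush), the ncRNA-side junction is the designed 2-nt gap,
both trans helices have 6 pairs, and 86% of the ncRNA is hybridized.

The same pipeline is available from the shell:

```sh
inst/scripts/sxrna scan --fasta mrna.fa --ncrna mirs.fa \
    --motif hsl --window 25 --backend reference --out report.tsv
```

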