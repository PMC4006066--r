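---
title: "Detecting trans three-way junctions between small RNAs and mRNA stem-loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting trans three-way junctions between small RNAs and mRNA stem-loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sxrna)
```

## The model

Many RNA-binding proteins recognize stem-loop motifs in their target
mRNAs. The canonical example is the histone stem-loop (HSL), a conserved
16-base stem-loop at the 3' end of replication-dependent histone mRNAs
that is bound by the stem-loop binding protein (SLBP); the adenosines
immediately 5' of the stem must remain unpaired for productive binding.
A small non-coding RNA can modulate such a motif in *trans*: instead of
forming a contiguous duplex, the small RNA may hybridize discontinuously
to the two mRNA segments flanking the stem-loop, "splinting" them
together at the base of the stem. The resulting arrangement — the motif
stem plus the two trans helices meeting around a central unpaired region
— is a three-way junction (3WJ) formed from two molecules rather than in
*cis*. Such an interaction can stabilize the motif (an **inducer**,
reinforcing the RBP site); conversely, a small RNA complementary to the
conserved stem/loop itself destroys the motif (a **repressor**). This
package implements the discovery pipeline for these structural
interactions ("sxRNA"): motif search, cofolding of the motif region
against a query set of small RNAs, junction detection and scoring, and
inducer/repressor classification.

## Pipeline overview

For each transcript, `scan_sxrna()`:

1. finds motif matches with a structured descriptor (`match_motif()`);
2. extracts a sequence window of `window_flank` bases (default 25) on
   each side of the motif, clamped at the transcript ends — or the whole
   message in `mode = "whole"` (guarded by `max_whole_len`, default
   5000 nt, because folding cost grows cubically);
3. cofolds the window with each small RNA (`cofold()`);
4. parses the joint structure, checks that the motif stem is present and
   that the small RNA splints both flanks, annotates the junction
   anchors, applies the thresholds, and classifies
   (`score_and_classify()`);
5. emits one report row per (transcript, motif, ncRNA, mode), mapping
   all positions back to transcript coordinates.

All coordinates are 1-based and inclusive, the Bioconductor/GFF3
convention; every span is a closed interval `[start, end]`. Segment
lengths are measured in *unpaired bases between anchors*, e.g.
`mJ5 = purple5 - blue5 - 1` (see below).

## Motif descriptors

A descriptor is an ordered list of elements: sequence elements (IUPAC
codes), one `stem_open`/`stem_close` pair whose matched regions must be
reverse-complementary (Watson-Crick, plus G·U when `allow_wobble`, up to
`max_mismatch` mispairs), and optional 5' anchor elements flagged as
required-unpaired bulges. The built-in HSL descriptor is an AA bulge
anchor, a 6-bp stem, a 4-nt loop and the closing stem: a 16-base
stem-loop, the conserved HSL length. Its primary-sequence consensus is
deliberately not hard-coded beyond the adenosines: published HSL
consensus letters vary, and a user who wants a strict consensus can
supply one as a YAML descriptor config. The built-in IRE descriptor uses
the canonical CAGUGH loop over a 5-bp upper stem; that loop consensus
comes from the IRE literature rather than from a printed constant of the
discovery work this package re-implements. Matching tries every start
position and admissible length assignment, so overlapping and tandem
matches are all reported.

## The folding backend contract

The joint minimum-"energy" structure of an mRNA segment and one ncRNA is
produced behind a pluggable backend contract: any engine that returns a
two-strand dot-bracket (`&`-separated, one bracket family, nested)
satisfying the pair-table invariants can drive the detector, because the
junction algorithm only reads the pairing relation.

The bundled **reference backend** is a deterministic weighted
base-pair-maximization dynamic program (Nussinov-style) on the
concatenated sequence: pair weights G:C = 3, A:U = 2, G:U = 1; N never
pairs; intramolecular hairpin loops must span at least 3 unpaired bases;
no loop constraint across the strand break, so the molecules can
hybridize end-on. It is not a thermodynamic model — no stacking, loop
penalties, temperature or parameter files — and is chosen because it is
exactly testable: an exhaustive interval-enumeration oracle reproduces
its score on every random instance up to combined length 22 in the test
suite. Ties between co-optimal structures are resolved deterministically
in the traceback: each position pairs with the smallest partner that
achieves the optimum and is left unpaired only when no pairing does.
Preferring to *pair* keeps co-optimal helices flush against enclosing
stems (in particular, the bottom stem pair of a motif is kept rather
than traded for an equal-weight pairing into the loop), which the
downstream exact stem check relies on; preferring the smallest partner
keeps helices stem-proximal and reruns byte-identical.

The **external backend** shells out to ViennaRNA's `RNAcofold` and
reports its MFE (kcal/mol) as the score. It errors when the executable
is missing — never a silent fallback — so a scan is always attributable
to one engine. Candidate lists from a thermodynamic engine will differ
from the reference backend's; the junction definitions are unaffected.

## Junction anchors, segments and thresholds

Given a joint structure and a motif match, the detector applies three
criteria: (1) the motif structure is present — at least `min_stem_frac`
(default 1.0) of the stem pairs implied by the match are formed, and
(by default) no loop base pairs with the ncRNA; (2) the ncRNA binds
across the motif's base — an intermolecular pair within `max_reach`
(default 25, the window flank) on each side; (3) the interaction meets
the thresholds. The anchors follow the bookkeeping of the original
screen, named by the colors used there:

* **purple5/purple3** — bottom bases of the motif stem;
* **blue5/blue3** — first mRNA base paired to the ncRNA 5'/3' of the
  motif (nearest the motif base);
* **orange5/orange3** — last such bases (farthest from the motif);
* **green5/green3** — the ncRNA partners of the blue bases.

Segments between purple and blue anchors are the mRNA-side junction
regions (`mJ5`, `mJ3`); the segment between the green anchors is the
ncRNA-side junction (`nJ`); segments between blue and orange anchors are
the extents of the two trans helices, measured both as intermolecular
pair counts (`h5_pairs`, `h3_pairs`) and as mRNA spans, with interior
bulges tolerated but counted against the paired fraction.

Default thresholds are package policy: the source work states that
thresholds exist and what they bound (junction sizes per cis-3WJ
guidelines, hybridization quality per paired-base percentages) but not
their values. The defaults — at most 8 unpaired bases per junction
segment, at least 4 pairs per trans helix, flank paired fractions at
least 0.6, at least half the ncRNA paired, the full stem present, the
loop free of trans pairs — bound the same quantities cis-3WJ geometry
bounds, and every one is a `thresholds()` argument. Two design rules are
stricter than a naive reading: a repressor verdict requires *positive*
ablation evidence (at least `min_ablation_pairs = 3` intermolecular
pairs on the motif), because a motif can fail to fold for cis reasons
with no ncRNA involved; and candidates whose two helices engage the
ncRNA in an order inconsistent with antiparallel splinting are rejected
with reason `arm-order`. Relaxing any single threshold never demotes an
inducer (a monotonicity property asserted in the tests).

## The synthetic-fixture generator

`make_fixture_set()` produces the study conditions under which the
detector is validated: transcripts with one embedded motif, designed
splint ncRNAs with known junction geometry (arms of 4–10 bp, ncRNA gaps
of 0–6 nt, mismatch-free), ablator negatives (reverse complements of
loop + 3' stem) and dinucleotide-shuffled decoys of those ablators
(Altschul–Erickson shuffle, preserving length and dinucleotide counts).
The splint construction is: reverse complement of the bases immediately
3' of the motif, then the gap, then the reverse complement of the bases
immediately 5' of the bulge, so pairing the arms to their targets plus
the motif stem yields a valid nested structure whose annotation is
exactly `mJ5 =` bulge length, `mJ3 = 0` (the 3' helix is flush, one
concrete convention for truth values), `nJ =` gap, `h*_pairs =` arm
lengths.

Because the reference backend maximizes pair weight with no loop
penalties, a naively random fixture admits many equal-weight alternative
structures and the designed splint is frequently not what the fold
returns. The generator therefore *designs for dominance*:

* flanks are drawn from the purine alphabet {G, A} — purines cannot pair
  purines, so flanks are inert toward themselves, each other and the
  purine 5' stem arm — echoing the purine-rich context of the natural
  HSL;
* the 5' stem arm is purine with G at its base (strong bottom pair, and
  a strand that cannot pair the flanks or the bulge), making the 3' stem
  arm pyrimidine;
* degenerate loop positions draw from {A, C} with the base abutting the
  3' stem fixed to A, so the loop cannot tie with the top stem pair;
* the ncRNA gap uses bases that pair neither the bulge nor the flanks
  (in practice A);
* the flank base adjacent to the bulge is A and the first 3'-flank base
  is G, blocking the two boundary pair-swaps that would otherwise tie
  with the design;
* periodic stems (self-overlapping under shifts of 1–3) are rejected,
  since they admit equal-weight shifted registers;
* rejection sampling additionally forbids Watson–Crick complementarity
  runs of 4 or more bases between flanks, within a flank, or between a
  flank and the motif, and requires the assembled transcript to match
  the descriptor exactly once.

These choices make the designed structure the unique weight optimum up
to ties that the deterministic traceback resolves toward the design; the
residual failures are transcripts whose stems are A/U-weak enough that a
rearranged fold ties anyway, and the end-to-end recovery bound in the
acceptance suite (at least 90% classified as inducer) deliberately
leaves room for them. The fixtures
emulate the *geometry* of splinted junctions, not real sequence biology:
there is no miRNA seed structure, no expression, no conservation, and
the alphabet restrictions mean passing tests demonstrate correctness of
the detector and pipeline, not sensitivity on natural transcripts. With
a thermodynamic backend on natural sequences, both the candidate list
and the appropriate thresholds would differ.

The validated properties, each recomputed by `scripts/acceptance.R` and
asserted in `tests/testthat/test-acceptance.R`, are: exact recovery of
(`mJ5`, `mJ3`, `nJ`, `h5_pairs`, `h3_pairs`) on all designed structures;
end-to-end inducer recall of at least 90% on mismatch-free designs;
decoy inducer rate at most 5%; and — the structural signature emphasized
in the source work — the bulge adenosines unpaired in every detected
inducer structure.

## Numerical and degenerate-input choices

* Normalization (T→U, uppercase) is idempotent; N is accepted and never
  pairs.
* `parse_dotbracket` is strict: exactly one `&`, balanced brackets
  (errors carry positions), lengths must match; crossing pairings are
  unrepresentable in one bracket family and `render_dotbracket` refuses
  them.
* A single-pair trans helix is valid (`blue == orange`, span 1).
* A window clamped at a transcript end is silently clamped but flagged;
  bulge positions cut off by a `flank = 0` window count as unpaired.
* Report rows are sorted by (transcript, motif start, ncRNA, mode) and
  scans are byte-identical across reruns with the reference backend.
* Problem sizes in the validation suite — 200 random cofolds against the
  exhaustive oracle at combined length ≤ 22, 1000 random pair tables
  against the anchor oracle, 200 seeded splint designs — were chosen to
  exercise every code path at desk scale while the whole suite completes
  in minutes.

## Known limitations

* The reference backend's candidate lists are not comparable to a
  thermodynamic engine's; it exists for testability and method
  validation.
* Pseudoknotted ("kissing") topologies are out of scope: crossing
  intermolecular pairs cannot be represented.
* One stem per descriptor; multi-helix or pseudoknotted descriptors are
  rejected.
* Whether both mature arms and star species of a miRNA hairpin should be
  scanned is left to the user: records are scanned exactly as supplied.
* Whole-message and window scans are reported as independent rows; the
  package takes no stance on whether they must agree.
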