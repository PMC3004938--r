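---
title: "Detecting and classifying IS inversions from TIR configurations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying IS inversions from TIR configurations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirinv)
```

## The problem

Insertion sequences (IS) are the simplest autonomous bacterial DNA
transposons: a transposase gene bounded by terminal inverted repeats
(TIRs). Because the two TIRs of a single copy are near-identical sequences
in opposite orientation, they are themselves a substrate for ectopic
(non-allelic homologous) recombination, which inverts the intervening
sequence. An observed inversion at an IS locus, however, has more than one
possible cause: the element may also have excised and re-integrated at the
same target site in the opposite orientation.

The key to separating these mechanisms is an *asymmetry* between the TIRs.
For the IS5-family element modelled here, the two inward TIR reads (each
read 5'→3' from the element's outer edge toward its interior) are 23 bp
long and identical except for a single A/T difference at nucleotide
position (np) 17. When the element inverts, the fate of that diagnostic
position reveals the mechanism:

* **Full inversion (a/b)** — excision/re-integration, *or* TIR-TIR
  recombination whose conversion tract lies upstream of np 17 (np 1–16):
  the whole element flips, so the inward reads swap (left' = R,
  right' = L). The two causes cannot be told apart from sequence.
* **Internal inversion (c)** — a conversion tract downstream of the
  mismatch (np 18–23): the transposase gene flips but the diagnostic
  position does not, so the TIR configuration stays canonical (left' = L,
  right' = R).
* **Left-template conversion (d)** — the tract spans np 17 and the left
  TIR is the conversion template: both inward reads become L.
* **Right-template conversion (e)** — as (d) with the right TIR as
  template: both reads become R.

`classify_mechanism()` implements exactly this decision table, keyed on
the diagnostic position only. Full-string comparisons are reported in the
evidence trail, but a point mutation elsewhere in a TIR must not change a
mechanism call, so it does not.

Orientation itself is established upstream of the classifier, by
`call_presence_orientation()`, from the strand of the transposase ORF
relative to the flanking genomic anchor — deliberately *not* from the TIR
configuration, because outcome (c) inverts the gene while leaving the TIRs
canonical.

A fifth operator, precise **excision**, removes the element and leaves a
single target-site copy; it produces an `absent` call rather than a
mechanism class.

## The canonical element model

`element_spec()` captures the anatomy the detectors rely on. Defaults,
with units and why:

| parameter | default | meaning |
|---|---|---|
| `total_length` | 916 bp | span of the canonical element |
| `tir_length` | 23 bp | length of each terminal inverted repeat |
| `mismatch_np` | 17 | diagnostic A/T asymmetry, 1-based from the outer end |
| `minus35_np` | 5–10 | -35 box (TTGTCC) inside the left TIR |
| `minus10_np` | 28–33 | -10 box (TATAAT) just downstream of the left TIR |
| `orf_length` | 858 bp | transposase ORF, start through stop codon |

The -35/-10 geometry gives the canonical 17-bp sigma-70 spacer. Because
the -10 box sits downstream of the left TIR while the -35 box sits inside
it, an inversion that homogenises both TIRs to the left read (outcome d)
repositions functional promoter boxes ahead of the now-inverted gene — the
configuration the classifier is designed to recognise.

**Why 858 bp for the ORF.** The element leaves 870 bp between its TIRs,
but a top-strand reading frame opened at np 24 would place the -10 box
hexamer across a codon boundary such that np 30–32 read TAA — an in-frame
stop. No in-frame placement of an 870-bp ORF is compatible with the fixed
promoter boxes, so the generator opens the ORF immediately after the -10
box (np 34) and runs it to np 891: 286 codons, a valid start codon, random
sense codons, and a single in-frame stop at the end. Two filler positions
remain before the right TIR.

Two further sequence-level guards make annotation deterministic rather
than seed-dependent:

* a stop codon is planted in the spacer upstream of the ORF, in frame with
  it, so no upstream start codon can ever extend the longest ORF beyond
  the designed gene;
* the filler positions immediately inside each TIR are drawn
  *non-complementary* to their inverted-repeat partners ("boundary
  breakers"), so the repeat detector terminates exactly at the TIR
  boundary. Real TIRs are likewise delimited by divergent flanking
  sequence; without the breakers, a random filler base pairs with its
  partner one time in four and the detected repeat length would drift
  above the true value.

After assembly the generator verifies that the designed ORF is the unique
longest ORF on either strand and redraws the filler (deterministically
under the seed) in the rare case a random fill violates this.

## De novo TIR detection

`detect_tirs()` compares the element's prefix with the reverse complement
of its suffix and reports the largest length `k` in `[k_min, k_max]`
(defaults 10 and 50) at which the two inward reads differ at no more than
`d_max = 2` positions *and agree at position `k` itself*. The mismatch
budget accommodates the diagnostic asymmetry plus one point mutation. The
terminal-match condition is essential, not cosmetic: extending a
candidate repeat by one position adds at most one mismatch, so under a
pure mismatch budget the largest qualifying `k` would always overshoot
the true boundary by absorbing filler positions. Requiring the repeat to
end on a matching position (equivalently, trimming trailing mismatches)
pins the detected length to the repeat/flank boundary. With `d_max = 0`
the rule reduces to the longest exact terminal inverted repeat, which the
test suite checks against a brute-force scan over every `k`.

## Promoter scanning

`scan_promoters()` enumerates every (-35, -10) hexamer pair in the first
60 nt of the element with a spacer of 15–19 bp. The consensus notation
T\*T\*G\*ACA / T\*A\*TAAT\* marks the most conserved positions with an
asterisk; the scanner reads each asterisk as qualifying the position
*preceding* it, so the conserved sets are {1,2,3} for the -35 and {1,2,6}
for the -10. Conserved positions must match exactly; the remaining three
positions of each hexamer share a two-mismatch budget. This reading is the
one consistent with annotating TTGTCC as a -35 box: its two differences
from TTGACA fall on non-conserved positions 5 and 6 (read: 4 and 6 of the
hexamer), whereas the alternative reading (position following the
asterisk) would disqualify it. Hits are ranked by total matched consensus
positions (0–12), then closeness of the spacer to 17 bp, then position.
The scanner's output is checked against an exhaustive double loop over
all hexamer pairs on random sequence.

## Presence and orientation calling

Per strain, presence is decided by the fraction of non-gap characters over
the element's alignment columns: absent at ≤ 0.10, present at ≥ 0.50,
ambiguous in between. The thresholds are deliberately loose around the
edges because partially deleted or poorly determined copies should fall
into the `ambiguous` class rather than force a call either way. For
present strains the ungapped element region is extracted
(`extract_ungapped()` maintains an exact alignment-column ↔ ungapped
position map) and the longest ORF on either strand (minimum 300 bp, start
codons ATG/GTG/TTG, ties broken toward the top strand then leftmost)
gives the orientation relative to the reference copy.

## Event reconstruction

`reconstruct_events()` maps per-strain locus states (absent / canonical /
inverted) onto a rooted strain phylogeny by Sankoff parsimony. The default
cost model charges 1 for insertion, inversion (either direction) and
deletion, and 2 for a direct absent→inverted gain — equal to the
insertion-then-inversion route, so neither is favoured and the
deterministic tie-break (lower state index at every backtrace step)
resolves the ambiguity reproducibly. The number of co-optimal assignments
is reported alongside, so ambiguity is quantified rather than hidden. The
root state is fixed to `absent` by default — element gain is the derived
condition, matching the outgroup pattern at an insertion locus — and can
be freed or changed. Ambiguous leaves enter as state sets: an element
present but of undetermined orientation as {canonical, inverted}, a fully
undetermined strain as all three states. Setting the absent→inverted cost
to `Inf` provably forbids inversion without an ancestral insertion on the
same path.

## What the simulator emulates — and what it does not

`simulate_locus()` produces the study design the pipeline expects: ~20
strains on a birth-only phylogeny, one canonical insertion event on the
branch to a monophyletic clade (the element flanked by duplicated T(T/A)A
target sites), one inversion-process event on the branch to a nested
subclade, and Jukes–Cantor point mutations on every branch (probability
`mutation_rate × branch length` per site; default rate 0.005). Absence is
encoded as one contiguous gap block spanning the element plus the second
target-site copy, so alignments are exact by construction. The internal
breakpoint of operators (c)/(d)/(e) is fixed at np `mismatch_np + 1`; any
breakpoint between the mismatch and the TIR end yields the same observable
TIR configuration, since the inward reads are identical there. Excision
and re-integration is modelled as a whole-element reverse complement at
the same site with the same target-site duplication; whether reintegration
would regenerate different flanking repeats is left unmodelled, which is
also why outcomes (a) and (b) are reported as a single class.

With `protect_features = TRUE` (the default), mutations never hit the
diagnostic windows: both target-site copies and the first and last 60 bp
of the element, which contain the TIRs, promoter boxes, boundary breakers
and the ORF start/stop in either orientation. This keeps validation
focused on the logic of the detectors; `protect_features = FALSE` exposes
the diagnostics to mutation for realism runs.

What the simulator does *not* emulate: realistic bacterial base
composition or codon usage (filler is uniform random), indels other than
the event-level ones, rate heterogeneity, recombination between
*different* element copies (the pairwise-orientation rule is exposed as
the predictor `predict_pair_outcome()`, not simulated), solo-TIR
formation, and transposition-rate dynamics. Passing tests on simulated
data therefore demonstrate that the inference logic is correct under the
stated model, not that real alignments are free of the alignment errors,
partial deletions and annotation noise that the `ambiguous` class is
designed to absorb.

## Problem sizes used by the test suite

The suite validates each detector against an independent brute-force
oracle at sizes chosen to keep the default run fast while covering the
space: the exact-repeat rule on 60 random elements of 40–200 bp; the ORF
finder against exhaustive start/stop enumeration on 40 random sequences;
the promoter scanner against the exhaustive pair oracle on 1,000 random
200-mers; element-anatomy recovery on 100 generated canonical elements;
Sankoff parsimony against exhaustive enumeration over *all* rooted
topologies with 3–4 leaves × all 3^n leaf-state combinations, plus seeded
samples of 5- and 6-leaf topologies and state sets; and scenario recovery
end to end on 200 simulated loci at mutation rate 0.005 with protected
features (the headline accuracy property), plus exact 5/5 recovery at
rate 0.

## A worked example

```{r example}
spec <- element_spec()
element <- build_canonical_element(spec, seed = 1)

detect_tirs(element)
scan_promoters(element)[1, ]

inverted <- apply_inversion_operator(element, spec, "conversion_left_d")
classify_mechanism(detect_tirs(inverted), canonical_tirs(spec), "inverted")
```

```{r pipeline}
report <- run_pipeline(list(
  seed = 2026,
  simulate = list(n_loci = 22, inverted_loci = 2, n_strains = 12,
                  mutation_rate = 0)))
report
```

## Known limitations

* The classifier requires a canonical reference copy with exactly one TIR
  mismatch; elements whose asymmetry has been erased (or doubled) in the
  reference itself cannot be classified, by design.
* Orientation calling depends on finding an ORF ≥ 300 bp; heavily decayed
  transposase genes yield `ambiguous` calls and drop out of mechanism
  classification.
* Conversion-tract positions are resolved only to the three interval
  classes the diagnostic position supports; tract lengths are not
  inferred.
* The event model treats loci independently; linked loci on one replicon
  share a tree but not a likelihood.
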