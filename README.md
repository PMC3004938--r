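# tirinv

Detection and mechanistic classification of bacterial insertion-sequence
(IS) inversions caused by ectopic recombination between terminal inverted
repeats (TIRs).

## The problem

DNA transposons are bounded by TIRs — near-identical sequences in opposite
orientation at the element's two ends. Recombination between the TIRs of a
*single* IS copy inverts the element; but an inverted element can also
arise by excision and re-integration at the same target site in the
opposite orientation. `tirinv` is for microbial genomicists who have
multi-strain alignments of IS insertion loci (element plus flanking
genomic anchor) and want to (i) call per-strain element presence and
orientation, (ii) decide *which mechanism* produced each observed
inversion, and (iii) reconstruct the insertion/inversion history on the
strain phylogeny.

The mechanistic test exploits the asymmetry of the TIRs. Writing `L` and
`R` for the two inward TIR reads — 23 bp, identical except for a single
A/T difference at nucleotide position (np) 17 — the configuration of an
inverted element identifies its cause:

| left read | right read | class | mechanism |
|---|---|---|---|
| R | L | `full_inversion_ab` | excision/re-integration *or* recombination with a conversion tract upstream of np 17 (indistinguishable) |
| L | R | `internal_inversion_c` | conversion tract downstream of np 17: transposase gene flips, TIRs do not |
| L | L | `conversion_left_d` | tract spans np 17, left TIR as conversion template |
| R | R | `conversion_right_e` | tract spans np 17, right TIR as template |

Orientation itself is called from the transposase ORF strand relative to
the flanking anchors (not from TIR order, which outcome *c* leaves
canonical). Event histories are reconstructed by Sankoff parsimony over
states {absent, canonical, inverted} with unit costs for
insertion/inversion/deletion. A forward simulator generates
ground-truthed locus alignments (canonical insertion on a phylogeny,
inversion by each operator, precise excision, neutral point mutations)
for validation, and a σ70 promoter scanner annotates the −35/−10 boxes
whose repositioning makes inverted elements transcriptionally plausible.

## Worked example

```r
library(tirinv)

spec <- element_spec()                       # canonical element anatomy
element <- build_canonical_element(spec, seed = 1)

detect_tirs(element)
#> TIR pair (23 bp inward reads)
#>   left  : GACATTGTCCACGTCGAGCTACG
#>   right : GACATTGTCCACGTCGTGCTACG
#>   mismatches at np 17
```

The detector finds the 23-bp repeats de novo and catalogues the single
diagnostic mismatch at np 17. Apply the left-template conversion operator
and classify the result against the canonical reference:

```r
inverted <- apply_inversion_operator(element, spec, "conversion_left_d")
classify_mechanism(detect_tirs(inverted), canonical_tirs(spec), "inverted")
#> Mechanism call: conversion_left_d
#>   left TIR matches L, right TIR matches L at np 17
#>   - diagnostic np 17: observed left=A right=A (L carries A, R carries T)
#>   - left inward read equals canonical L, differs from canonical R (full string)
#>   - right inward read equals canonical L, differs from canonical R (full string)
```

Both TIRs of the inverted element now carry the left read — the signature
of TIR-TIR recombination with concomitant conversion of the right TIR.
The full pipeline (simulate → call → classify → reconstruct) over a
22-locus screen:

```r
report <- run_pipeline(list(
  seed = 2026,
  simulate = list(n_loci = 22, inverted_loci = 2, n_strains = 12,
                  mutation_rate = 0)))
report
#> IS inversion pipeline report
#>   loci screened          : 22
#>   loci with >=1 inverted : 2
#>   inverted-locus fraction: 2/22 = 9.1%
#>   inverted loci:
#>     locus01 (1 inverted strain)
#>     locus02 (1 inverted strain)
```

`summary.tsv`, `calls.tsv`, `mechanisms.tsv`, `events.tsv` and
`report.json` are written when `out_dir` is set. A thin command-line
wrapper is installed at `inst/scripts/tirinv`
(`tirinv simulate ...`, `tirinv pipeline --config ...`).

See `vignettes/is-inversion-methods.Rmd` for the model, the detector
design choices, and what the simulator does and does not emulate.

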