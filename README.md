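# argboxr

Information-theoretic modelling of the *Streptomyces coelicolor* ArgR
operator (the "ARG box").

ArgR is the master repressor of arginine and pyrimidine biosynthesis in
bacteria; in *S. coelicolor* it binds ~20-nt imperfect palindromic
operators that occur singly or as tandem pairs separated by 0–1 nt.
`argboxr` is for computational biologists studying this regulon (or any
palindromic prokaryotic operator): it ships a curated collection of 44
experimentally supported ARG boxes, builds a quantitative binding-site
model from the 37 well-conserved ones, and provides scoring, de-novo motif
discovery, genome scanning, site-architecture classification and gene
association around it — plus fully synthetic benchmark generators, so the
whole pipeline is testable offline.

## The model

For an alignment of *n* sites of width *L* with base frequencies
*f*(*b*, *l*), the package computes Schneider-style individual
information:

* weights  *Riw*(*b*, *l*) = 2 + log₂ *f*(*b*, *l*) − *e*(*n*)
* sequence score  *Ri*(*s*) = Σₗ *Riw*(*sₗ*, *l*)  (bits)
* conservation  *Rsequence* = Σₗ [2 − *H*(*l*) − *e*(*n*)]  (bits)

where *H*(*l*) is the column entropy and *e*(*n*) the exact small-sample
correction (enumerated, not approximated). Because the operator is a
palindrome bound by a symmetric ArgR oligomer, training boxes are counted
on both strands by default, giving a strand-symmetric matrix. Scanning
uses exact p-values from the dynamic-programming distribution of the
composition-aware log-odds score, combined with the operator-prediction
filter pair *p* < 10⁻⁵ and *Ri* > 10 bits.

## Worked example

```r
library(argboxr)

boxes <- arg_boxes()              # 44 curated boxes
model <- build_arg_model(boxes)   # trained on the 37-box subset
model
#> Individual-information model
#>   width L       : 20 nt
#>   sequences n   : 74 (both strands counted)
#>   e(n)          : 0.0296 bits/position
#>   Rsequence     : 10.06 bits
#>   consensus     : GTCTGCATGATCATGCAGAC (Ri = 21.00 bits)

ri_score(model, "CTTTGCATGGTCATGCGTAA")  # the strongest argG box
#> 17.37654
```

`Rsequence` (10.06 bits) is the average information an ArgR site carries;
the consensus scores 21.0 bits, and individual curated boxes range from
1.3 bits (the weak held-out *afsR* box) to 17.4 bits (*argG*). Computed
scores track the published per-box values with rank correlation 0.9997
(all 44 boxes within 0.19 bit).

Scanning a synthetic high-GC genome with planted sites:

```r
bg  <- generate_background(2e5, gc = 0.72, seed = 1)
pl  <- plant_sites(bg, model, n_sites = 10, ri_target = 14, seed = 2)
hits <- scan_sequence(pl$sequence, model)      # p < 1e-5 and Ri > 10
evaluate_scan(hits, pl$truth)$sensitivity
#> 1
assemble_sites(hits)$kind                      # single / tandem architectures
```

The `analysis/` directory holds numbered drivers that run the full
workflow (model building, box scoring, architecture classification, probe
discovery, scan benchmark) and write their tables under `results/`.

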