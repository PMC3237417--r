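# mirorigin

Genome-wide classification of plant miRNA genes by their mode of origin.

Plant miRNA genes are born continually — from inverted duplications of
their future target genes, from transposable elements (MITEs in
particular), from decaying pseudogenes, and from the tandem and segmental
duplications that also expand protein-coding families. `mirorigin`
implements that classification as a tested, reusable pipeline. Each miRNA
gene receives a *set* of origin-mode labels:

| label | rule (defaults) |
|-------|-----------------|
| TR | TE overlap covers >= 50% of the precursor |
| PR | pseudogene overlap covers >= 50% of the precursor |
| ID | precursor and its reverse complement both align to a cDNA with E < 0.05, identity > 0.8, mature inside the match |
| TD | miRNA pair < 15,000 bp apart, same family or precursor E < 1e-10 |
| SD | related miRNA pair inside the paired spans of a collinear anchor chain (protein anchors, E < 1e-10) |
| OT | none of the above |

On top of the labels, four *de novo* generation mechanisms are sub-typed:
**A** (two inverted copies of one non-MITE family, copy similarity > 80%),
**B** (one MITE family entirely covering the precursor and a predicted
target site, target passing the ID criteria), **C** (two adjacent
inverted pseudogenes of one parent, parent being a target), **D** (two
pseudogenes with paralogous parents), precedence A > C > D > B.

The package also provides: a Nussinov-style maximum base-pairing folder
with MIRcheck-style precursor validation (<= 4 mismatches, <= 2
consecutive, <= 2 asymmetric in the miRNA/miRNA* duplex); affine-gap
Smith-Waterman with Karlin-Altschul E-values (E = K·m·n·e^(−λS), K = 0.1,
λ = 1.037); protein family clustering with the alignable-length-dependent
similarity threshold I(L) = 0.01n + 4.8·L^(−0.32(1+exp(−L/1000))) (n = 6,
I = 30% for L >= 150 aa); a miRU-style complementarity target matcher; a
Monte Carlo gene-set intersection test (exact analog: hypergeometric
tail); a six-classifier cross-validated similarity readout; and a
synthetic genome generator that plants every mechanism with a truth
table.

## Worked example

Generate a synthetic genome with 10 planted miRNA genes per origin
category, classify it, and compare against the planted truth:

```r
library(mirorigin)

bundle <- generate_genome(synth_config(seed = 42), "bundle")
nrow(bundle$mirnas)          # 70 miRNA genes on a 400 kb chromosome
result <- classify_bundle(bundle)
head(result$calls, 4)
#   mirna_id labels mechanism
#   mirSD01a     SD      none
#   mirSD02a     SD      none
#     mirA01  TR;ID         A
#     mirA02  TR;ID         A
table(result$calls$mechanism)
#    A    B    C    D none
#   10   10   10   10   30
evaluate_recovery(result$calls, bundle$truth)[1:2]
# $origin_recovery     1
# $mechanism_recovery  1
```

All 40 mechanism plants are typed correctly and every origin label is
recovered: mechanism-A/B plants come out `TR;ID` (they sit in TEs *and*
match a target transcript — the multi-label structure is the point),
C/D plants come out `PR;ID`, tandem/segmental pairs `TD`/`SD`, and the
background hairpins `OT`.

The intersection test behaves like its hypergeometric oracle:

```r
monte_carlo_intersection(M = 10, m = 5, n = 5, N = 5,
                         reps = 100000, seed = 3)[c("expected",
                         "p_empirical", "p_analytic")]
# expected 2.5, p_empirical 0.0041, p_analytic 0.00397 (= 1/252)
```

And the headline species contrast recomputes from the published counts
(85/290 TE-related miRNA genes in rice vs 4/142 in Arabidopsis):

```r
chi_square_2x2(85, 205, 4, 138)
# statistic 40.90, p = 1.6e-10  (reported: P < 1e-3)
```

A full report (calls, synteny blocks, feature panel, count and
intersection matrices, de novo vs conserved comparison tables, manifest):

```r
run_pipeline(pipeline_config(seed = 1), "report")
```

or from the shell: `exec/mirorigin run --config cfg.yaml --out report`.

## Layout

* `R/`, `src/` — implementation (I/O, folding, alignment, classifier,
  synteny, features, statistics, pipeline; DP kernels in C++)
* `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles
* `vignettes/mirna-origin-methods.Rmd` — the model, every threshold and
  its provenance, what the synthetic world does and does not establish
* `exec/mirorigin` — command-line entry point
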