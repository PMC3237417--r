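---
title: "Methods: classifying miRNA gene origin modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying miRNA gene origin modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Plant miRNA genes arise repeatedly and recently, and several molecular
routes have been proposed for their birth: duplication of a future target
gene in inverted orientation (so that the locus transcribes a foldback
whose arms still base-pair with the target's mRNA), transposition of
miniature inverted-repeat transposable elements (MITEs, themselves
palindromic), decay of pseudogene pairs, and the ordinary tandem and
segmental duplication routes that also expand protein-coding families.
`mirorigin` implements a genome-wide classification of miRNA genes into
six origin-mode labels — TE-related (TR), pseudogene-related (PR),
inverted duplication (ID), tandem duplication (TD), segmental duplication
(SD) and other (OT) — sub-types four de novo generation mechanisms on top
of them, extracts a comparative feature panel, and tests relationships
between the label sets. Labels are a multi-label set: a locus sitting in a
MITE that also matches a target transcript is both TR and ID, and the
intersection structure of the sets is itself an analysis output.

## Origin rules and their thresholds

All thresholds live in `classify_config()`:

* **TR / PR** — the union of TE (pseudogene) overlaps must cover at least
  50% of the precursor. The source wording ("overlapped with TEs or with
  at least 50% coverage") admits an any-overlap reading; we implement the
  stricter >= 50% reading and expose `any_overlap = TRUE` as the switch.
  Coverage is a union across features, since repeat annotations are
  commonly fragmented.
* **ID** — both the forward precursor and its reverse complement must
  align locally to a cDNA (longest isoform per gene) with E < 0.05 and
  identity > 0.8, and the mature must lie inside a matched precursor
  region. Identity is computed over aligned columns (gap runs compressed
  to one column); the identity base is not stated in the source and this
  is our convention.
* **TD** — two miRNA genes on one chromosome, gap < 15,000 bp, and either
  the same family or precursor alignment E < 1e-10.
* **SD** — both members of a related miRNA pair (same family / E < 1e-10)
  must lie inside the paired spans of one collinear anchor chain. Whether
  the original analysis required the miRNAs to be anchors themselves or
  merely inside block spans is not stated; within-span is our reading.
* **Mechanisms** — A: two inverted-orientation copies of one non-MITE
  family overlap the precursor with copy similarity > 80%; B: one MITE
  family entirely covers the precursor and at least one predicted target
  site, with the target gene passing the ID criteria; C: two adjacent
  (gap <= 2 kb, a configurable convention — "adjacent" is not quantified
  in the source) inverted pseudogenes of one parent, the parent being a
  predicted target; D: two pseudogenes whose parents are paralogous.
  Ties resolve A > C > D > B, a declared arbitrary order.

## Folding and the MIRcheck-style filter

Precursors are folded by a Nussinov-style maximum base-pairing dynamic
program over {A:U, G:C, G:U} with a minimum loop of 3 nt, instead of a
thermodynamic folder. This is a deliberate fidelity gap: the downstream
criteria count pairings, not energies, and the maximum-pairing objective
is deterministic, dependency-free, and provably correct against an
enumeration oracle (tested on all-nested structures of sequences up to
14 nt). Traceback prefers closing pairs and outermost partners, which
favours long stacked helices among co-optimal structures.

The precursor filter mirrors MIRcheck: at most 4 mismatches and at most
2 consecutive mismatches in both the mature and the inferred miRNA*, and
at most 2 asymmetrically unpaired mature nucleotides. A "mismatch" is a
position unpaired or paired outside the partner span; the miRNA* is the
paired span of the mature with the canonical 2-nt 3' overhang (the
overhang positions are duplex geometry and are not counted as star
mismatches); "asymmetric" unpaired positions are the excess of unpaired
mature positions over unpaired star positions. Matures spanning the loop
fail with a reason rather than erroring — the source does not say how
multi-loop precursors were handled, so this is our convention. The fold
entry point accepts sequences down to 5 nt (the shortest that can hold a
pair over a 3-nt loop); precursor-scale length checks belong to callers.

## Alignment machinery

Local alignment is an affine-gap Smith-Waterman (match +1, mismatch -1,
gap open -2, gap extend -1; a length-L gap costs 2 + (L-1)) with a
deterministic traceback (diagonal > up > left). E-values use the
Karlin-Altschul form E = K m n exp(-lambda S) with declared constants
K = 0.1, lambda = 1.037, because the original searches inherit their
statistics from external tools without stating parameters; fixed declared
constants make every threshold reproducible. Copy similarity for
mechanism A is a global (Needleman-Wunsch) gap-compressed identity.

Protein family clustering uses the published two-part criterion —
similarity >= I(L), where I = 30% for alignable length L >= 150 aa and
I = 0.01 n + 4.8 L^(-0.32 (1 + exp(-L/1000))) (n = 6) below, and an
alignable region covering >= 80% of the longer protein. The printed form
of the formula is typographically broken in the source; our reading is
the one continuous with the 30% rule (I(150-) is about 0.303). Because a
+1/-1 scheme cannot extend local alignments below ~50% identity, family
clustering scores protein mismatches at -0.3 — mimicking the positive
expected score of a BLOSUM-style matrix — so that the similarity
thresholds, not the aligner, decide membership down to the 25-35% range
the criterion is designed to split. Families are single-linkage closures,
hence order-independent; tandem arrays are the transitive closure of
same-family pairs separated by fewer than 20 intervening genes.

Synteny chains are collinear anchor chains (protein pairs with E < 1e-10,
tandem-range pairs removed) found by sparse dynamic programming: strictly
increasing in one rank coordinate, strictly monotonic in the other, chain
score = sum of log(1 + anchor score) minus 1 per skipped gene rank, at
most 25 skipped ranks per step, at least 3 anchors per chain, and a
minimum chain score of 20 (the DAGchainer-style significance floor). The
floor matters: any permutation of 5 ranks contains a monotone triple
(Erdos-Szekeres), so structure alone cannot reject shuffled anchors;
with default weights the best spurious chain in a shuffle scores about
18.5, while four or more strong gap-free anchors clear 20. The exact
scoring of the original chaining tool is not restated in its methods;
these parameters reproduce planted blocks and reject shuffled anchors
(>= 95% of 1,000 permutations), which is the property the pipeline needs.

## Target matcher

The external target-prediction server is unversionable, so targets come
from a transparent complementarity scorer in the miRU lineage: per duplex
position, Watson-Crick 0, G:U 0.5, mismatch 1, penalties doubled at
mature positions 2-13, cutoff 4.0. The scan is ungapped; the gap term of
the scheme is documented but gapped sites are not searched (the synthetic
world only plants substitution-type divergence). Watson-Crick pairing at
mature positions 10-11 gives the cleaving-site pairing feature.

## The Monte Carlo intersection test

For two label sets of sizes m and n inside M genes with observed
intersection N, the test draws both subsets without replacement 100,000
times. The exact null is hypergeometric, and the suite requires the
empirical tail to track the analytic tail within three binomial standard
errors over a grid of set sizes. The source describes the empirical P in
one convoluted sentence; read closely it is the standard one-sided tail
with *strict* inequalities (ties at N excluded). The default mode uses
inclusive tails (P(sim >= N) for enrichment, P(sim <= N) for depletion),
which match the hypergeometric oracle exactly; `mode = "paper-literal"`
reproduces the strict-tail sentence as written. No multiple-testing
correction is applied across the pairwise matrix, matching the source.

## The classifier-suite similarity

Set similarity is read out as 5-fold stratified cross-validated accuracy
of six discriminative models, averaged. The six named families (naive
Bayes, kNN, decision tree, C4.5, SVM, random forest) are realised with
learners available offline: Gaussian naive Bayes, kNN (k = 5), binary
trees with gini and entropy splits, ridge-regularised logistic regression
(a linear margin classifier standing in for the linear SVM) and bagged
randomized trees (standing in for the random forest). Accuracy near 0.5
means the two sets are statistically indistinguishable on the feature
panel; the suite is calibrated on exchangeable sets (mean accuracy within
[0.40, 0.60] across 50 seeds) and saturates (>= 0.95) on a 10-sigma
separable pair.

## The synthetic world

`synth_config()` states the world: one chromosome (default 400 kb) of
i.i.d. uniform background — the simplest null that cannot fake homology —
with 10 planted miRNA genes per category, 60 background coding genes, a
25% repeat fraction (half MITEs), and 2% per-site substitution divergence
between planted duplicate copies. Planted foldbacks use 90-nt arms, a
6-nt spacer and a 21-nt mature on the 3' arm (arm lengths and spacers are
not stated for real loci in the source; these are declared defaults).
Non-MITE repeats are 800-1,200 bp; MITEs are ~170 bp with 12-bp terminal
inverted repeats and a palindromic core, matching the size contrast the
biology leans on. Mechanism plants follow the four schematics: A = two
inverted non-MITE copies whose arm also sits in a target transcript; B =
a MITE foldback plus an identical-family MITE inside a target transcript;
C = two inverted pseudogene copies of one parent; D = pseudogene copies
of two paralogous parents (4% cDNA / 5% protein divergence). Tandem pairs
sit 2-8 kb apart; segmental pairs sit inside two collinear 4-anchor gene
blocks placed at opposite chromosome ends so their anchor ranks clear the
tandem-range filter. Divergence in the repeat table is the percent of
substitutions actually applied, standing in for the source's
under-defined "divergence e-value". Tracks (siRNA, TATA promoters,
methylation, polymorphisms, expression, three cross-species catalogs
carrying the conserved matures) are planted with de novo/conserved
contrasts so the comparison tables have signal.

Every planted foldback is regenerated (bounded retries) until it passes
the MIRcheck filter; exhaustion raises an error naming the mechanism.
`mircheck_validate = FALSE` disables this, which is how the suite builds
mechanism-A plants with arm similarity below 80% to confirm they are
*not* typed A. `genome_length` is exact: planted content that does not
fit is an error, and the tail padding carries the background repeat
annotations, so background TEs can never contaminate planted loci (the
stated repeat fraction is therefore met only approximately).

What a green test does establish: the rules, thresholds, folding,
alignment, chaining and statistics compose correctly and recover planted
truth (>= 90% origin, >= 80% mechanism labels at 2% divergence). What it
does not establish: behaviour on real genomes — i.i.d. background has no
isochores or nested repeats, genes have single exons, divergence is
substitution-only (no indels), and the thermodynamic structure of real
precursors can differ from maximum-pairing structure.

## Numerical and degenerate-input choices

Internal genome coordinates are 0-based half-open with one conversion
point in the I/O layer (GFF3 and the repeat table are 1-based closed on
disk, BED is half-open); spans inside sequences are 1-based inclusive.
Overlap is strand-agnostic; strand matters only for sequence extraction
and inverted-orientation tests. Empty inputs (all-zero config, empty
tracks, empty anchor sets) yield empty outputs rather than errors;
feature rows with an empty group report P = NA. All randomness flows
from a single seed (R's RNG, including inside the compiled Monte Carlo
sampler), so a config hash plus seed pins every output byte.

## Known limitations

Maximum-pairing folding over-pairs relative to thermodynamic structure;
the E-value constants are declared, not fitted; the target scanner is
ungapped; conservation counting uses a <= 2-substitution exact-length
match rather than an alignment; and the six-classifier suite substitutes
two of the six named model families with closely related learners. Each
substitution is behind the module interface and is exercised by the same
contract tests an exact reimplementation would face.
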