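---
title: "Methods: structural variants from de novo assembly alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural variants from de novo assembly alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

asmsv discovers, genotypes and characterizes structural variants (SVs) and
novel sequence from pairwise alignments of de novo genome assemblies
against a reference. This vignette explains the models and procedures the
package implements, the assumptions behind them, the tunable parameters,
and what the synthetic-data generator does and does not emulate.

## Discovery from alignment blocks

The input is a LAST-dialect MAF: split alignments of assembly scaffolds
against the reference, two rows per block, reference first. Internally all
block coordinates are 0-based half-open on the forward strand; minus-strand
query coordinates are converted at parse time and the strand kept as a
flag. Variant records use the VCF convention (1-based anchored positions;
the first base of REF/ALT of any non-SNP record is the shared anchor base).

Each scaffold is traversed 5'→3'. Differences *within* one block become
SNPs (mismatch columns) and anchored indels (gap-column runs). Breakpoints
*between* adjacent blocks are classified from the reference-side and
query-side gaps:

| configuration | call |
|---|---|
| query gap only | insertion |
| reference gap only | deletion |
| gaps on both sides | simultaneous gap → block substitution (equal interiors) or length-asymmetric replacement |
| strand-flipped interior block, collinear same-strand flanks | inversion |
| reference chromosome change | inter-chromosomal translocation |
| non-collinear reference order | intra-chromosomal translocation |
| anything else | no solution |

Split aligners emit slightly overlapping block edges around repeats; a
query or reference overlap of up to `tol` (default 20 bp) is clamped,
larger overlaps give `no_solution` / `intra_translocation`. Events above
`max_gap` (default 50 kb, the upper end of the size range the method is
designed for) become `no_solution`.

Unaligned scaffold *ends* of at least 100 bp are "clipped" segments, and
scaffolds with no alignment at all are "nomadic" — both novel-sequence
candidates. Interior unaligned spans are insertion interiors and are
already accounted for by between-block calling; they are deliberately not
re-emitted as clipped sequence. Reference intervals not covered by an
individual's assembly are reported as intra- or inter-scaffold gaps
depending on whether the flanking covered intervals come from the same
scaffold. These definitions reconstruct the intended ones from context;
the original fine print was not available, so they are stated here
explicitly and enforced by the tests.

Translocation calls are reported in the per-individual variant table with
breakpoint and mate coordinates, but are not written as VCF REF/ALT
records: the package's VCF dialect is bi-allelic with full allele
sequences (never symbolic ALTs), and breakend notation is out of scope.

### Normalization

All indels and replacements are parsimony-trimmed and left-shifted to the
leftmost equivalent representation against the reference; complex
replacements are first re-anchored by align-gap-excise realignment (below)
in a ±20 bp reference context. Normalization is idempotent, and its
positions are property-tested against an exhaustive shifting oracle.
Population merging then collapses records with identical normalized
(chrom, pos, REF, ALT) — "exact breakpoint" semantics — into one
bi-allelic record listing the individuals it was assembled in; records
carried by at least 2 independent assemblies are flagged as double-hit
events, the default positive-training set for recalibration.

## Alignment kernels

Affine-gap global and local alignment (match +1, mismatch −2, gap open −4,
gap extension −1; a gap of length L scores `open + L·ext`) are implemented
in C++ with deterministic traceback (pair > deletion > insertion).
Similarity is summarized as *identity* (matches / alignment columns) and
*aligned ratio* (query bases in aligned columns / query length), the two
measures behind all 0.95 thresholds below.

The align-gap-excise realigner splits two windows into prefix + excised
middle + suffix, maximizing the sum of the global scores of the 5'
prefixes and 3' suffixes via prefix/suffix score matrices and a 2-D
suffix-maximum — the split-maximization core of the published
gap-excision approach, not its full five-matrix formulation, which is
sufficient for breakpoint placement at this scale. Ties push the split 3'
(identical windows give empty excisions at the window ends) and then
minimize the excision; the final left placement of the variant is the job
of left-shift normalization, which runs immediately afterwards. This
tie-break direction was chosen because both requirements — a deterministic
rule and empty excisions at the window end for identical windows — cannot
be met by leftmost splitting; leftmost placement is still guaranteed for
the emitted record via normalization.

## Genotyping model

Per variant, each individual contributes a 2-D observation
d = (r, a): the fractions of reads uniquely supporting the reference and
alternative allele among reads overlapping the locus (locus depth, not a
genome-wide average, is the denominator; depth 0 is missing). A
three-state Gaussian mixture over (RR, RA, AA) is fitted across the
population by EM:

* posterior: P(G_j | d) = w_j N(d | μ_j, Σ_j) / Σ_k w_k N(d | μ_k, Σ_k)
* objective: the standard mixture log-likelihood
  Σ_i log Σ_j w_j N(d_i | μ_j, Σ_j) for unrelated individuals
* initial weights (1/3, 1/3, 1/3); initial centers m · μ_expected with
  μ_expected = RR (1, 0.001), RA (0.5, 0.5), AA (0.001, 1) in (r, a)
  space. The scalar presentation of these centers elsewhere describes the
  a-intensity coordinate; a homozygous-reference individual has *high* r
  intensity, so the r coordinate mirrors it.
* linear constraints, enforced by projection at every M-step: a
  per-coordinate box |μ_j − m·μ_j,expected| ≤ 0.3, and the ordering
  μ_RR,a < μ_RA,a < μ_AA,a on the a-intensity coordinate. The exact form
  of the original constraints was not recoverable; this reconstruction is
  faithful to their stated purpose and is documented as such.
* covariances are diagonal by default (robust at small N; a full 2×2 is
  available), with a variance floor of 1e-4.
* convergence: log-likelihood change < 1e-6 or 200 iterations. A state
  that loses all responsibility mass keeps its initial center, with a
  warning.

The genotype is the posterior argmax (ties broken RR < RA < AA), with
Phred-scale quality GQ = −10·log10(1 − p_best) on normalized posteriors,
capped at 99. GQ is kept unrounded in the call tibble — the worked
1.76-for-uniform-posteriors example only makes sense unrounded — and
rounded to an integer at VCF emission.

The center scaling factor m is selected over {0.8, 0.9, 1.0, 1.1, 1.2}
(five rounds of training) by the rank-sum of (i) the constraint bias
Σ_j ‖μ̂_j − m·μ_j,expected‖₁ and (ii) the Mendelian error rate of the
resulting calls when trios are available; ties go to the m nearest 1.0,
then the smaller m. The Mendelian error rate is the fraction of
trio-complete loci whose child genotype is impossible under bi-allelic
transmission, validated against the exhaustive 27-case table.

## Quality recalibration

Nine technical features capture the three error sources (assembly error,
global misalignment, local alignment artifacts): local assembly gap ratio
(N fraction in ±500 bp of the scaffold), alternative-allele read depth,
neither-allele read depth, scaffold misalignment probability, scaffold
alignment score, local identity, position of the variant in the scaffold
(normalized to 0..1), and the proper / improper read-pair ratios. Any
subset may be used; features can also be supplied directly as a TSV, which
overrides the built-in operationalizations (the original feature
definitions were not published in full).

A Gaussian mixture is fitted per class (positive = trusted variants,
default the double-hit set; negative = known artifacts), with the
component count chosen by BIC over 1..8. Priors p01 = 0.6/0.4 and
p02 = 0.4/0.6 (known/novel) weight the class likelihoods into two-class
normalized probabilities

P_pos = p01·L_pos / (p01·L_pos + p02·L_neg),  P_neg = 1 − P_pos,

and the score is the base-10 log odds −lg(1 − P_pos) + lg(1 − P_neg),
clamped so it is always finite. Normalization is an interpretation: applied
to raw mixture densities the formula is undefined whenever a density
exceeds 1, while on normalized probabilities it is well-defined and
monotone in the Bayes factor.

The PASS threshold is chosen on the training ROC by Youden's J
(maximizing TPR − FPR). A threshold-free quantity (the AUC) cannot itself
pick a cutoff; J matches the stated intent of keeping most known positives
while minimizing included negatives. A stratified k-fold cross-validation
mode estimates the held-out error rate when no independent validation set
exists.

Loci with excess hetero- or homozygosity are filtered by the inbreeding
coefficient over the unrelated individuals (pedigree founders):
F = 1 − N_het / (2·p·q·N), removing F < −0.4 or F > 0.7 (strict
inequalities, as printed; the derivation of these constants is not
reproduced here — they are used as given). Monomorphic loci have
undefined F and are skipped by the filter.

## Ancestral state and type rectification

For each variant both alleles are built with 500 bp flanks and measured
against each outgroup genome by identity and aligned ratio of the best
local alignment (both thresholds strict >0.95; an aligned ratio below 0.3
counts as "does not align at all"). The rule table: NONE (no allele aligns
to any outgroup), NA (aligns but nothing passes), Common (both alleles
pass for all outgroups), Deletion (longer allele passes, shorter fails,
for ≥1 outgroup), Insertion (shorter passes, longer fails), Conflict
(outgroups disagree between Deletion and Insertion). The published
Deletion and Insertion rules are textually identical — an apparent
typesetting duplication — and are resolved here by the evolutionary
logic: if the *longer* allele matches the outgroup, the ancestral state
had the sequence and the derived event was its loss, i.e. a Deletion
event, and symmetrically; this resolution is consistent with the
rectification example below. Aligned ratio is measured on the allele
(query side).

A discovered insertion with ancestral state Deletion is rectified to a
deletion (the assembly allele is ancestral; the reference lineage lost
sequence), and symmetrically; the discovery-time category is kept in
`orig_category`. Applied to our simulations this reproduces the designated
event types exactly; on real data the operation reclassifies the fraction
of indels whose reference allele is the derived one.

The four great-ape outgroup genomes used in human work are a documented
preset: the package never downloads them; any outgroup FASTA set (or
per-variant orthologous windows) is accepted.

## Formation mechanism

Variants shorter than 50 bp are annotated UNSURE. Larger ones are tested
in a fixed precedence, first match wins: CCC (variant sequence exactly
identical to the equal-length sequence immediately 3' of the right
breakpoint — polymerase slippage), TEI (best local hit against a
mobile-element library record at identity ≥0.80 covering ≥0.80 of the
variant), VNTR (likewise against simple-repeat records), NAHR (reciprocal
local alignment of the 200-bp breakpoint flanks with identity >0.85 over
at least half the flank), NHR (microhomology of ≥2 bp, shorter than the
variant, between the variant sequence and a flank), else NA. The
precedence (most specific, exact test first; repeat identity before flank
homology) and the window/threshold choices are package decisions where the
original listed the tests without an order; all are configurable
arguments. The repeat library is a FASTA whose record names carry a class
tag (`#mobile_element` or `#simple_repeat`).

## Novel sequence

Insertion interiors longer than 100 bp that fail to align anywhere in the
reference at identity ≥0.95 and aligned ratio ≥0.95 are novel sequence
insertions anchored at their breakpoint ("not well aligned to the
reference" is operationalized by the same 0.95/0.95 pair used for
similarity to other genomes; the >100 bp rule is applied to the novel
interior, after anchor removal). Nomadic candidates (whole unaligned
scaffolds) are kept only when corroborated at 0.95/0.95 (inclusive) by at
least one other supplied genome; the rest — contamination, assembly error
— are discarded with a machine-readable reason. Kept sequences can be
linked to their closest known assembly by best local alignment identity
(weighted by query coverage so a trivial exact k-mer never wins), ties by
assembly name, floor 0.5.

## Synthetic data

The generator produces every input with known truth: a reference with
planted Alu-like (300 bp) and LINE-like (6 kb) element copies, diverged
tandem arrays and homologous segment pairs H–X–H'; variants planted with
mechanism signatures (element copies for TEI, X-deletions between
homologous flanks for NAHR, unit-count changes for VNTR, exact tandem
duplications for CCC, microhomology junctions for NHR, random interiors
for novel insertions); founder genotypes drawn at Hardy-Weinberg
frequencies (allele frequencies uniform on 0.2–0.8, redrawn until each
variant has a carrier) with Mendelian transmission to trio children;
error-free split alignments built jointly with the assembly sequences, so
blocks re-project exactly; read counts drawn multinomially at
Poisson-distributed depth (default mean 30, 2% of reads supporting
neither allele, 1% mismapped); outgroups carrying the designated ancestral
allele plus 2% background substitution divergence; and corroborated
nomadic plus uncorroborated contaminant scaffolds.

Two generator choices matter for interpreting the tests. First, planted
representations are constrained to be fixed points of normalization (the
base before each interior differs from the interior's last base, and
replacement interiors differ at both ends), so truth comparison is exact;
unit-count changes in tandem arrays are inherently ambiguous and are
planted in their left-normalized representation instead. Second,
orthologous outgroup windows are emitted per variant from the generator's
coordinate maps, because whole-genome outgroup alignment is outside the
package's scope.

What the simulation does *not* emulate: sequencing errors and assembler
mis-joins inside alignment blocks (alignments are error-free, so 100%
recovery demonstrates the bookkeeping, not robustness to noisy
alignments); collapsed diploid assemblies showing a mosaic of haplotypes
(carriers always expose the alternative allele); realistic repeat
landscapes (a handful of planted families rather than genome-wide
density); and orthology discovery. Passing tests therefore validate the
rules and models on inputs satisfying their assumptions, not performance
on real assemblies.

## Problem sizes and numerical choices

The study-scale checks use ~1,000 planted variants across all categories
on a two-chromosome reference of a few hundred kilobases with 8
individuals (2 trios + 2 unrelated); EM recovery uses 500 individuals;
concordance uses 40 variants × 80 individuals at depth 30; rule-accuracy
fixtures use 50 variants per mechanism class with one outgroup;
recalibration uses 300 + 300 simulated feature vectors with a held-out
half; the inbreeding check uses 1,000 Hardy-Weinberg loci of 20 unrelated
individuals. These sizes were chosen so each estimate's sampling noise is
well inside the asserted tolerance.

Numerical conventions collected in one place: alignment scoring as above;
EM tolerance 1e-6, 200 iterations, variance floor 1e-4; posterior
underflow returns a uniform posterior with a warning; GQ capped at 99; PL
capped at 255; recalibration probabilities clamped at 1 − 1e-10; mixture
component count 1..8 by BIC; ROC threshold by Youden's J; inbreeding
bounds −0.4/0.7 strict; minimum unaligned segment and novel-sequence
length 100 bp; mechanism minimum size 50 bp; merge tolerance for block
overlaps 20 bp; simultaneous-gap cap 50 kb.

## Known limitations

* Alignment production is accepted as input (MAF) or simulated; the exact
  split-alignment parameterization used upstream is not recoverable, so
  the package does not attempt to run an aligner.
* The multi-allelic genotype model and k-mer, alignment-free genotyping
  are explicitly out of scope (bi-allelic records only).
* Novelty and similarity checks run exact local alignment (O(nm)); they
  are meant for allele-versus-window and segment-versus-genome scales, not
  for whole-genome-versus-whole-genome search.
* The VCF reader targets this package's own dialect (plus anything
  structurally identical), not arbitrary VCF in the wild.
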