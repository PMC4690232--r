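# asmsv

Structural variant discovery, genotyping and characterization from
population-scale de novo assembly alignments.

Re-sequencing pipelines systematically miss complex structural variants
(SVs) and sequence absent from the reference genome. When de novo
assemblies are available instead, every variant — SNP to multi-kilobase
rearrangement — is encoded at nucleotide resolution in the
assembly-versus-reference alignment. `asmsv` turns such alignments
(LAST-dialect MAF) into an annotated population VCF, for
population-genetics and genome-biology work on cohorts of assemblies:

* **Discovery** — traverse each scaffold 5'→3'; differences within an
  alignment block become SNPs/indels, breakpoints between blocks become
  deletions, insertions, block substitutions, length-asymmetric
  replacements, inversions and translocations; unaligned scaffold
  sequence (clipped ends, nomadic scaffolds) and uncovered reference
  regions are accounted for; representations are left-shift normalized
  and merged across individuals into bi-allelic records, with double-hit
  events (identical breakpoints assembled in ≥2 individuals) flagged.
* **Genotyping** — per variant, each individual contributes
  d = (R intensity, A intensity), the fractions of reads uniquely
  supporting each allele. A linear-constrained three-state Gaussian
  mixture over (RR, RA, AA) is fitted by EM across the population,

      P(G_j | d) = w_j N(d | μ_j, Σ_j) / Σ_k w_k N(d | μ_k, Σ_k),

  with centers initialized at m·{(1, 0), (0.5, 0.5), (0, 1)} and m chosen
  over {0.8, …, 1.2} by constraint bias and trio Mendelian error.
  Genotype = posterior argmax; GQ = −10·log10(1 − p_best), capped at 99.
* **Quality recalibration** — positive/negative Bayesian Gaussian
  mixtures (BIC-selected components, 1..8) over nine technical features;
  score = −lg(1 − P_pos) + lg(1 − P_neg) on prior-weighted two-class
  probabilities; PASS threshold from the training ROC; plus the
  inbreeding-coefficient filter F = 1 − N_het/(2pqN), removing
  F < −0.4 or F > 0.7.
* **Characterization** — ancestral state per variant from outgroup
  genomes (identity and aligned ratio of both alleles with 500 bp flanks,
  0.95 thresholds → NONE/NA/Common/Deletion/Insertion/Conflict), type
  rectification, and formation mechanism (CCC, TEI, VNTR, NAHR, NHR;
  <50 bp → UNSURE) from breakpoint and repeat structure.
* **Novel sequence** — insertion alleles >100 bp absent from the
  reference, and nomadic scaffolds corroborated by other genomes, linked
  to their closest known assembly.
* **Synthetic data** — a deterministic generator producing every input
  with known ground truth (reference with repeat families, planted
  variants with mechanism signatures, trio populations, error-free split
  alignments, read counts, outgroups), so the whole pipeline is testable
  without downloads.

See the methods vignette (`vignettes/asmsv-methods.Rmd`) for the models,
assumptions, parameter choices and limitations.

## Worked example

```r
library(asmsv)

# simulate a small cohort: reference, assemblies, alignments, read counts
sim <- simulate_study(sim_config(seed = 1, scale = 0.3))

# discover and merge variants across the 8 individuals
disc <- discover_population(sim$blocks, sim$refdata$ref, sim$assemblies)
disc$records
#> # A tibble: 92 × 10
#>    chrom   pos id       ref    alt   category carriers ncarrier known double_hit
#>    <chr> <int> <chr>    <chr>  <chr> <chr>    <list>      <int> <lgl> <lgl>
#>  1 chr1   1700 var00001 GCGAG… G     deletion <chr>           6 FALSE TRUE
#>  2 chr1   4332 var00002 A      T     SNP      <chr>           6 FALSE TRUE
#>  3 chr1   5582 var00003 TAC    T     deletion <chr>           6 FALSE TRUE
#>  4 chr1  12088 var00004 T      TTTT… inserti… <chr>           8 FALSE TRUE
#>  ...

summarize_variants(disc$records)$by_type
#> # A tibble: 6 × 8
#>   category              n length min_length max_length individual_load sd_number
#> 1 SNP                  36     36          1          1           26.8      2.38
#> 2 block_substituti…     3    105         11         50            2.5      0.535
#> 3 deletion             23   7927          2       6000           15.5      1.85
#> 4 insertion            25   2140          4        300           17.4      2.07
#> 5 inversion             2    705        331        374            1.5      0.535
#> 6 length_asymmetri…     3     68         13         28            2.38     0.518
```

Each record is one bi-allelic site: `ncarrier` counts the assemblies the
variant was independently found in (`double_hit` marks the ≥2 cases used
as positive training evidence), and the summary shows per-type totals and
the mean per-individual load. Genotyping one variant across the cohort:

```r
ints <- compute_intensities(sim$intensity_counts)
fit <- fit_em(ints[ints$variant_id == "sim00004", ])
fit
#> Constrained 3-state Gaussian mixture genotype model
#>   n = 8 individuals, scaling factor m = 1.0, converged
#>   weights: RR 0.125  RA 0.625  AA 0.250

call_genotypes(ints[ints$variant_id == "sim00004", ], fit)[, c("sample", "gt", "gq")]
#> # A tibble: 8 × 3
#>   sample      gt       gq
#> 1 fam1_father RA     99
#> 2 fam1_mother RA     99
#> 3 fam2_father RR     46.3
#> ...
```

The fitted weights are the population genotype frequencies; `gq` is the
Phred-scale probability that the called genotype is wrong (capped at 99).
`tidy()`, `glance()` and `autoplot()` work on fitted genotype and
recalibration models, and `write_vcf()` emits the annotated call set.

A thin command-line front end over the same functions is installed at
`inst/scripts/asmsv` (subcommands `simulate`, `detect`, `genotype`,
`recal --cv`, `annotate`, `novel`, `report`).

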