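# racepop

Population structure, genetic diversity and race-diagnostic SNP markers for
germplasm panels.

`racepop` is built for collections structured into **ecological races** —
the motivating system is avocado (*Persea americana*), whose Mexican (M),
Guatemalan (G) and West Indian (WI) races and interracial hybrids (G×M,
G×WI) make up most commercial cultivars. From a biallelic SNP genotype
matrix and a table of race labels it computes:

* **Diversity** — per-locus and per-population MAF, observed heterozygosity
  *H*<sub>o</sub>, expected heterozygosity *H*<sub>e</sub> = 2*pq*, Nei's
  unbiased gene diversity (2*n*/(2*n*−1))·2*pq*, Shannon's information index
  *I* = −(*p* ln *p* + *q* ln *q*), and PIC = 1 − (*p*² + *q*²) − 2*p*²*q*².
* **Structure** — identity-by-state distances (1 − mean fraction of shared
  alleles), rooted ultrametric UPGMA trees with Newick export, classical
  PCoA with percent variance per axis, two-level AMOVA with Φ<sub>ST</sub> =
  σ²<sub>a</sub>/(σ²<sub>a</sub> + σ²<sub>b</sub>) and permutation p-values,
  supervised ancestry proportions **q** on the (M, G, WI) simplex by
  binomial-likelihood EM, and the Evanno ΔK = |L″(K)|/sd(L(K)) utility.
* **Race-diagnostic markers** — the three-step filter (zero missingness; an
  allele at frequency 1.00 in one pure race and 0.00 in the other two;
  carried by the expected hybrid classes, ≥⌈11/14·*n*⌉ of all hybrids for
  G-specific loci), KASP assay construction with the standard FAM
  (`GAAGGTGACCAAGTTCATGCT`) and VIC (`GAAGGTCGGAGTCAACGGATT`) tails and the
  target SNP at the 3′ terminus, and race classification of unknown
  accessions from a marker panel.
* **Simulation** — a Balding–Nichols multi-race generator with planted
  diagnostic loci, admixed or F1 hybrids, and full ground truth, including
  `mimic_paper_panel()`, the 21-accession reference design (2 M, 2 G, 3 WI,
  7 G×M, 7 G×WI).

I/O covers a minimal GT-only VCF v4.2, a dosage TSV dialect, panel TSVs,
bracketed-SNP context FASTA (`...ACGT[A/G]TTAA...`) and Newick. A pipeline
driver (`run_pipeline()`) and a CLI (`inst/exec/racepop`) compose the
stages deterministically under one seed.

## Worked example

```r
library(racepop)

sim <- mimic_paper_panel(divergence_F = 0.2, seed = 1, n_loci = 2000,
                         hybrid_mode = "f1", n_unknown = 2)
mk <- find_race_specific_loci(sim$gm, sim$panel)
mk
#>        locus_id race diagnostic_allele diagnostic_base hybrid_support
#> 1  ctg1:172:A:C    M               alt               C              7
#> 2  ctg1:264:G:A    G               ref               G             14
#> 3  ctg1:707:A:G   WI               alt               G              7
#> ...                                                   (9 loci in all)
```

Nine loci pass the three-step filter — exactly the nine the simulator
planted (three per race); `hybrid_support` counts the hybrid accessions
carrying the diagnostic allele (all 7 of the required class for M/WI loci,
all 14 hybrids for G loci). Classifying the two accessions whose labels
were withheld (`UNKNOWN`, simulated as true G×WI hybrids):

```r
classify_race(sim$gm, mk, sim$panel$sample_id[sim$panel$race_label == "UNKNOWN"])
#>   sample_id frac_M frac_G frac_WI detected call
#> 1 Unknown_1      0      1       1     G,WI GxWI
#> 2 Unknown_2      0      1       1     G,WI GxWI
```

Both carry every G-specific and every WI-specific diagnostic allele and no
M-specific one, so both are called Guatemalan × West Indian hybrids. The
structure side of the analysis:

```r
dm <- ibs_distance(sim$gm)
amova_two_level(dm, race_grouping(sim$panel, "k2"), n_perm = 999, seed = 7)
#> Two-level AMOVA (distance-based; samples as experimental unit)
#>              source df      SS   sigma2
#>   Among populations  1 0.30554 0.016095
#>  Within populations 19 2.60167 0.136930
#> Phi_ST = 0.1052 (10.52% among); p = 0.001 (999 permutations)

pcoa(dm, 3)
#> <pcoa_result> 23 samples, 3 axes (17.03, 10.57, 4.84% of variance)
```

About 10.5% of the molecular variance separates the WI-related accessions
(WI + G×WI) from the MG-related ones under this F1 panel, and no permuted
relabelling reached the observed Φ<sub>ST</sub> (p = 1/1000, the add-one
minimum). KASP assays for the discovered loci (contexts here are synthetic
random flanks):

```r
build_kasp_assays(mk[1:2, ], synthesize_contexts(sim$gm, mk$locus_id[1:2], seed = 2))[, c(1, 2, 3, 5)]
#>   assay_name target_locus race                                  fam_oligo
#> 1   PaMsSNP1 ctg1:172:A:C    M GAAGGTGACCAAGTTCATGCTGAGTAACCCGCGTGAGTAAGA
#> 2   PaGsSNP1 ctg1:264:G:A    G GAAGGTGACCAAGTTCATGCTGCGCATCCATCTGAAGGATTG
```

Each FAM oligo is the 21-base FAM tail plus 20 flanking bases plus the ref
allele as its 3′ terminus; the VIC oligo differs only at that final base.

## Documentation

See the methods vignette (`vignettes/racepop-methods.Rmd`) for the models,
conventions (AMOVA squared-distance convention, LD-prune fixpoint
semantics, EM details), the synthetic world's assumptions, and known
limitations.
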