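---
title: "Methods and design of racepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of racepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racepop)
```

## The problem

Crop germplasm collections are often structured into *ecological races* —
within-species lineages shaped by distinct climates, such as the Mexican (M),
Guatemalan (G) and West Indian (WI) races of avocado — with most commercial
cultivars being interracial hybrids (GxM, GxWI). Given a genome-wide
biallelic SNP genotype matrix over a panel of accessions and a table of race
labels, `racepop` answers three questions:

1. **Structure and diversity** — how do accessions cluster (UPGMA on
   identity-by-state distance, PCoA, supervised ancestry proportions, the
   Evanno delta-K heuristic), how much variation lies among versus within
   populations (AMOVA / $\Phi_{ST}$), and how diverse is each group
   ($MAF$, $H_o$, $H_e$, Nei's unbiased gene diversity, Shannon's $I$, PIC)?
2. **Race-diagnostic markers** — which loci are fixed for a private allele
   in one pure race, absent from the other two, and transmitted to the
   expected hybrids? These support KASP (Kompetitive allele-specific PCR)
   assays for cheap race typing.
3. **Classification** — given a small diagnostic marker panel, what race or
   hybrid combination is an unknown accession?

Because the genotype matrices that motivate this design are typically not
published, the package carries a first-class simulator whose output has
known ground truth, and all quantitative claims in the test suite are made
against that synthetic world.

## Genotype model and missing data

Genotypes are unphased, unordered pairs of alleles at strictly biallelic
loci, stored as alt-allele dosage (0/1/2) with `NA` an explicit missing
state. All statistics are phase-free, so 0/1 and 1/0 are identical. Missing
data is never imputed; every statistic documents its own rule (typically:
computed over typed samples only; pairwise-complete for correlations and
distances). The dosage view and the allele-pair call view are mutually
convertible without loss.

## The synthetic world

`simulate_panel()` draws, per locus, an ancestral alt frequency $p \sim
U(0.1, 0.9)$ (a discovery panel keeps reasonably common variants) and
per-race frequencies from the Balding–Nichols model, $p_r \sim
\mathrm{Beta}\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$, which has
mean $p$ and variance $F\,p(1-p)$; $F = 0$ degenerates to $p_r = p$
exactly. Pure-race individuals draw two allele copies binomially from their
race frequency. Hybrids come in two modes:

* **admixed** (default): each allele copy's source race is drawn from the
  individual's ancestry vector $q$, then the allele from that race's
  frequency — an admixed-gamete model;
* **f1**: one copy from each parent race, guaranteeing hybrids are
  heterozygous carriers of both parental diagnostic alleles, which is the
  regime the three-step marker filter presumes.

Race-diagnostic loci are *planted* by overwriting the race frequencies with
a fixed difference (frequency 1 of the diagnostic allele in the target
race, 0 elsewhere). Because the planted set is meant to be the complete
answer set for marker-recovery tests, the generator also re-draws
(deterministically under the seed) any unplanted locus whose realised
pure-race genotypes happen to form a perfect fixed difference — with only a
handful of pure accessions per race such accidents are otherwise common
enough to contaminate exact-recovery tests.

`mimic_paper_panel()` instantiates the reference design: 21 accessions
(2 M, 2 G, 3 WI, 7 GxM, 7 GxWI) named after the corresponding cultivars,
with each hybrid's dominant-parent fraction drawn from $U(0.51, 0.84)$ —
the M fraction for GxM and the WI fraction for GxWI, so every GxWI
accession is WI-dominant. Optionally, extra accessions that are truly GxWI
but labelled `UNKNOWN` emulate unknown-race selections.

What the generator does **not** emulate: linkage (loci are independent, so
LD pruning on simulated data only ever removes deliberately planted
duplicates or chance correlations), genotyping error (missingness only),
ascertainment structure beyond the frequency range, and any real genomic
context (KASP flanking sequences are random and are labelled synthetic). A
green test therefore establishes internal correctness and statistical
calibration under this model, not agreement with any published dataset.

## Diversity statistics

For a locus with alt frequency $p$ ($q = 1-p$) over $n$ typed samples:
$MAF = \min(p, q)$; $H_o$ = heterozygote fraction; $H_e = 2pq$; Nei's
unbiased gene diversity $= \frac{2n}{2n-1} 2pq$; Shannon's
$I = -(p\ln p + q\ln q)$ with $0\ln 0 = 0$ (natural log, the convention of
the classic popgen toolkits); $PIC = 1 - (p^2+q^2) - 2p^2q^2$ (the
two-allele specialisation of the Botstein 1980 formula). The source study
never published the exact formulas behind its distinct "He" and "Nei"
columns; these standard definitions at least reproduce the printed ordering
(Nei $\ge$ He), and no numeric agreement with its Table 2 is claimed.
Per-population summaries are unweighted means over the loci typed in at
least two samples of that population.

## Distance, tree, ordination

The IBS distance between two samples is one minus the mean per-locus
fraction of shared alleles over co-typed loci — equivalently mean
$|a-b|/2$ on dosages: identical genotypes 0, het versus hom 0.5, opposite
homozygotes 1. UPGMA is classical average linkage: merge heights are half
the merging distance, giving a rooted ultrametric tree; ties are broken by
the lexicographically smallest pair of cluster labels (a cluster labelled
by its smallest leaf) so results are reproducible to the bit. Newick export
goes through `ape`.

PCoA is classical metric scaling: Gower double-centering of $-d^2/2$,
eigendecomposition, coordinates scaled by the square roots of the retained
nonnegative eigenvalues. Negative eigenvalues (non-Euclidean input) are
excluded from the percent-variance denominator and reported, with no
Cailliez/Lingoes correction — users see the magnitude and can judge.
A genotype-covariance PCA (`genotype_pca()`) is provided for comparison,
since tools in this space are sometimes ambiguous about which they run.

## AMOVA

The two-level decomposition follows Excoffier: with $N$ samples in $G$
groups, $SS_{total} = \frac{1}{N}\sum_{i<j} d^2_{ij}$, $SS_{within} =
\sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij}$, mean squares from
$df = G-1$ and $N-G$ (samples, not haplotypes, are the experimental unit),
$\sigma^2_b = MS_w$, $\sigma^2_a = (MS_a - MS_w)/n_0$ with the standard
unequal-size coefficient, and $\Phi_{ST} = \sigma^2_a/(\sigma^2_a +
\sigma^2_b)$.

One convention matters and is easy to get wrong: for marker data the
*pairwise mismatch count is itself the squared molecular distance* — the
convention of the classical AMOVA programs. The IBS distance is
proportional to the mismatch count, so `amova_two_level()` uses the
supplied matrix as $d^2$ directly by default (`squared = TRUE`). Squaring
the IBS distance entrywise instead (`squared = FALSE` exists for genuinely
Euclidean inputs) roughly doubles $\Phi_{ST}$ on diverged panels and no
longer tracks $F_{ST}$: on simulated two-population panels at $F = 0.2$
the default convention concentrates near $\Phi_{ST} \approx 0.26$, the
entrywise-squared variant near $0.45$. $\Phi_{ST}$ is invariant to uniform
scaling of the input either way. Permutation p-values randomly relabel
samples with group sizes fixed and use the add-one estimator
$(1 + \#\{\Phi^{perm} \ge \Phi^{obs}\})/(1 + B)$, so $p = 0$ is impossible.

## LD pruning

Sliding-window greedy pruning over the input locus order (taken as genomic
order; the whole ordered list is treated as one sequence): within a window
of `window_size` surviving loci, pairs are scanned in order and one locus
of any pair with pairwise-complete dosage $r^2 >$ threshold is removed —
the one with the higher missing rate, ties broken against the later locus.
Windows advance by `step`, and full sweeps repeat until one removes
nothing. The fixpoint definition makes pruning idempotent and guarantees no
retained within-window pair exceeds the threshold; a single plink-style
sweep guarantees neither. Undefined correlations (zero variance, fewer than
two complete pairs) count as $r^2 = 0$. Defaults are window 50, step 5,
threshold 0.2. No implicit MAF filter is applied.

## Supervised ancestry and delta-K

Pure-race accessions define per-race reference allele frequencies, clamped
to $[10^{-3}, 1-10^{-3}]$ so fixed loci cannot produce infinite
log-likelihoods (the clamp only matters at fixed loci; estimates move by
$\ll 0.01$ under reasonable alternative clamps). For a sample with dosages
$g_\ell$ the model is binomial with mixture frequency $p_{mix}(\ell) =
\sum_r q_r p_r(\ell)$, maximised over the simplex by an EM whose latent
variable is each allele copy's source population. The log-likelihood is
non-decreasing by construction and asserted at every iteration; uniform
initialisation means identical references return the uniform (flat,
unidentifiable) solution. Iteration stops when $\max_r |\Delta q_r| <
10^{-9}$ or after 10,000 iterations. This supervised estimator replaces
Bayesian clustering deliberately: it is deterministic, fast, testable, and
the reference study's pure accessions make supervision natural.

`delta_k()` is a generic Evanno post-processor — $\Delta K =
|L''(K)|/\mathrm{sd}(L(K))$ over replicate log-likelihoods — usable on
external clustering output. To exercise it without MCMC,
`structure_like_likelihoods()` manufactures an L(K) table: samples are cut
into $K$ groups by UPGMA on the IBS matrix, group frequencies become $K$
reference sources, and replicates score the panel's total `estimate_q()`
log-likelihood on random locus subsets (the same subsets across $K$, so
values are comparable within a replicate).

## The three-step diagnostic filter

Over the non-`UNKNOWN` accessions: (1) keep loci with zero missing calls;
(2) for each race, keep loci where one allele is at frequency 1.00 in that
race's pure accessions — read as *all pure accessions homozygous for it* —
and at frequency 0.00 among the other two races' pure accessions; (3)
require the diagnostic allele *present*, interpreted as carried in at least
one copy (hybrids are expected heterozygous carriers), in all GxM
accessions for M-specific loci, all GxWI accessions for WI-specific loci,
and at least $\lceil \tfrac{11}{14} n_{hyb} \rceil$ of the combined hybrids
for G-specific loci — the proportional generalisation of the original
11-of-14 rule to arbitrary panels. A missing hybrid class degenerates that
race's step 3 to a warning-and-skip rather than an error, since steps 1–2
already carry the discriminating signal.

Classification scores, per sample and race, the fraction of that race's
markers carrying the diagnostic allele; a race is detected at fraction
$\ge$ `agreement` (default 1 — with a six-marker panel a single
disagreement should demote the call, not dilute it). Exactly one detection
plus sufficient diagnostic homozygosity gives a pure call; exactly two give
the hybrid call; anything else is `AMBIGUOUS`.

## KASP assay construction

Each assay couples two allele-specific oligos — the FAM-tailed
(`GAAGGTGACCAAGTTCATGCT`) oligo reading the ref allele and the VIC-tailed
(`GAAGGTCGGAGTCAACGGATT`) oligo reading the alt allele — built as tail +
the `oligo_len - 1` bases immediately 5' of the SNP + the allele base, so
the polymorphic base is the 3' terminus, plus a common reverse primer: the
reverse complement of `oligo_len` bases starting a fixed 10-base offset 3'
of the SNP. Design is purely positional; melting temperature, GC content
and off-target screening are out of scope, which is why real assay panels
are expected to lose some candidates (designing assays for every passing
locus and letting downstream QC drop some mirrors practice). The fixed
touchdown PCR profile travels with each assay as metadata. The dye-allele
pairing (FAM = ref) is this package's own convention; the source protocol
does not fix one.

## Pipeline

`run_pipeline()` composes the stages from one validated config with a
single global seed expanded per stage by fixed offsets, writing TSV/Newick
outputs and a JSON manifest with md5 checksums; identical config and
inputs give byte-identical outputs. The LD-pruned subset feeds only the
ancestry stage — the population-structure analysis is the one place the
modelled workflow prunes — while diversity, distance/tree, PCoA, AMOVA and
marker discovery consume the full matrix. This is not only fidelity but
necessity: same-race diagnostic loci are perfectly correlated, so pruning
first would delete the very loci the marker stage exists to find.

## Known limitations

* Loci are treated as independent everywhere; no linkage maps, no
  haplotype-aware $r^2$ (EM), no physical-distance windows.
* Diversity and AMOVA are biallelic-only; no rarefaction or allelic
  richness; no three-level AMOVA or pairwise $F_{ST}$ matrices.
* The supervised ancestry estimator cannot discover unlabelled structure;
  delta-K here post-processes likelihoods, it does not replace a full
  Bayesian clustering run.
* Genotype-level $\Phi_{ST}$ from IBS mismatch distances sits systematically
  above allele-level $F_{ST}$ on the same data (≈0.26 vs ≈0.20 at
  $F = 0.2$); comparisons across conventions should use one estimator
  throughout.
* KASP oligos are sequence-positional constructs with no thermodynamic
  validation.
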