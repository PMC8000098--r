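---
title: "Simulating cost-efficient genomic selection in a rabbit maternal line"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cost-efficient genomic selection in a rabbit maternal line}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`rabbitGS` is an in-silico laboratory for one question: when a rabbit
maternal line is selected for litter size, which combination of SNP-chip
densities across grand-parents, parents and candidate does gives the best
trade-off between genotyping cost, genotype-imputation accuracy and the
accuracy of genomic breeding values? The package simulates the whole chain —
founder genomes with linkage disequilibrium, a multi-generation breeding
programme, per-role genotyping and masking, pedigree-based imputation,
pedigree BLUP and single-step GBLUP evaluation — and reports the endpoints a
breeder cares about: imputation accuracy (IA), genotype yield, gEBV
accuracy, response to selection, the percentage of correctly selected
candidates, and euros spent on chips.

## The simulated system

**Trait.** Litter size at birth: heritability $h^2 = 0.113$, additive
variance $\sigma^2_a = 0.675$ in the base population, sex-limited
expression (only does have records). Phenotypes are Gaussian,
$y = \mu + \mathrm{TBV} + e$ with $e \sim N(0, \sigma^2_e)$ and
$\sigma^2_e = \sigma^2_a (1 - h^2)/h^2 \approx 5.2985$. A count model for
litter size is deliberately out of scope: the evaluation model is linear,
and only differences in breeding values matter, so $\mu$ is an arbitrary
constant (default 10 kits).

**Genome and trait architecture.** Twenty chromosomes, each 100 cM and
124.43 Mb, with a linear bp-to-cM map. Causal loci (QTNs) are drawn
uniformly from the segregating founder sites, the same number on every
chromosome: 44 per chromosome (880 in total) for the polygenic model,
5 per chromosome (100) for the sparse one. Effect magnitudes are
Gamma(shape 0.60, scale 0.80); signs are independent fair coin flips,
since a positive-valued Gamma would otherwise build a directional bias
into the founders. After sampling, all effects are rescaled by one
constant so that the variance of true breeding values over the founder
diploids equals 0.675 *exactly*; applying the scaling twice is a no-op,
which the tests assert.

**Breeding programme.** A foundation cohort is drawn from the founder
haplotype pool; five generations of random mating (138 does, 77 sires per
generation) precede twenty-one generations of truncation selection in
150-doe/150-male cohorts: the top 70 does and top 35 sires by pedigree-BLUP
EBV breed the next cohort. The last of those selections produces the
grand-parental generation of the genomic phase. In the two genomic
generations the *full* 150-doe cohort serves as dams (each contributing the
same number of kits, sexes exactly 1:1) and the 35 sires are picked by
single-step GBLUP on unmasked HD genotypes; the final mating produces the
candidate cohort of 1500 does and 1500 males. Generations are labelled so
the last three are the 26th–28th. Meiosis is a standard gene drop: Poisson
crossover counts with expectation length$_\mathrm{cM}$/100, uniform
positions, no interference, no mutation — so every allele of every
non-founder descends from a founder allele, a property the test suite
checks site by site.

Two structural decisions deserve a note, because the source material for
this design is ambiguous about them. First, the selection layer reads
"70 selected does" but the genotyping layer counts 150 genotyped dams with
1500 genotyped doe kits; these reconcile only if the full doe cohort
breeds in the genomic phase, which is what the package does. Second,
principal and surrogate sires (25 + 10) are not distinguished — all 35
selected males may sire, as the distinction has no computational
consequence here.

## Founder genomes

Founder haplotypes come from a forward Wright–Fisher burn-in over a fixed
set of candidate sites placed evenly on the physical map. Each tracked site
stands for its surrounding sequence window, so its per-generation mutation
probability is $\mu_{bp} \times L / n_\mathrm{sites}$; mutation flips
alleles symmetrically, the population starts monomorphic, and drift under
a two-epoch effective-size schedule (large ancestral, smaller recent
population, then one terminal expansion generation that samples the
requested number of haplotypes) shapes both the frequency spectrum and
linkage disequilibrium. Only segregating sites are retained, and the
generator raises an explicit shortfall error if a chromosome cannot supply
the HD panel plus its QTNs.

What this emulates: standing variation with realistic allele-frequency
spectra, LD that decays monotonically with genetic distance, and the high
relatedness of a closed nucleus. What it does not: sequence-level realism
(gene content, recombination hotspots, non-uniform maps), a calibrated
rabbit demographic history (the published coalescent option used for the
original experiment is not described numerically anywhere we could verify,
so any rabbit-specific $N_e$ trajectory remains an open calibration), and
the full 200,000-marker panel.

The `desk` preset is the package's routine scale: 1000 HD markers per
chromosome (MD and LD are the same 0.30 and 0.003 fractions of HD as at
full scale, so the 70% and 99.7% missing rates are preserved exactly), 600
founder haplotypes, 5000 tracked sites per chromosome, and a burn-in of
250 generations at $N_e = 250$ plus 100 at $N_e = 100$. Because a
forward-simulable $N_e$ is far below the effective size implied by a
coalescent founder step, the desk preset raises the per-bp mutation rate
to $10^{-8}$ so that the population-scaled diversity $4 N_e \mu L$ — and
with it the segregating-site supply per chromosome — stays adequate. This
is a scaling decision made from the diversity calculation, not a fitted
quantity. Cohort sizes are *not* scaled down: the candidate cohort is the
full 1500 + 1500, because the endpoint definitions (top 150 of 1500) are
tied to those counts.

## Genotyping strategies and cost model

The HD panel is sampled per chromosome from segregating non-QTN sites; MD
is a random nested subset of HD and LD of MD ("nested" is asserted as set
inclusion, exactly). Strategies S1–S7 and S3_A assign one platform (HD,
MD, LD or none) to each role — grand-dams, grand-sires, dams, sires,
candidate does — with grand-sires and sires always HD and candidate males
never genotyped. S3 genotypes a random half of the candidate does; S3_A is
identical (same random half, enforced by seeding the split from the
replicate stream, not the scenario) but additionally imputes the
non-genotyped half as whole genomes. Observed entries pass through
bit-exactly; there is no genotyping-error model.

Costs are flat per animal: platform price divided by 96 chips — EUR 100,
50 and 11 per HD, MD and LD animal — summed over the genotyped animals of
the last three generations. Chip-batching economics beyond the flat price
are out of scope.

## Imputation engine

The imputer is pedigree-based, in the spirit of long-range phasing plus
pedigree peeling, reduced to two primitives:

1. **Soft haplotypes.** Every genotyped animal carries two vectors of
   $P(\text{allele} = 1)$ over the HD grid; homozygous markers phase
   themselves, unknown positions hold the population frequency.
2. **Gamete-origin Viterbi.** For an animal with genotyped parents, a
   joint 4-state dynamic programme (sire haplotype × dam haplotype) runs
   over the animal's typed markers, scoring
   $|d - a_\mathrm{sire} - a_\mathrm{dam}|$ against the parental soft
   alleles with one switch penalty per parental-haplotype change
   (default 1). The chosen parental haplotypes simultaneously impute the
   animal's untyped markers and phase its own haplotype pair for the next
   generation; between typed markers the state switches at the cM
   midpoint.

The top reference generation has no genotyped parents, so its heterozygous
markers start unresolved. They are recovered by *progeny votes*: a
duo-processed offspring's Viterbi path says which parental haplotype it
inherited in each region, and wherever the transmitted allele is
determined (offspring homozygous, or the other parent's contribution
phased) that allele is a vote for the parent's haplotype at that marker.
After voting, the duo pass is repeated with the refined reference. This
replaces an explicit identity-by-state surrogate-window search with the
same information routed through the pedigree, and is the package's own
design.

Whole-genome imputation (S3_A's non-genotyped half) copies the imputed
genome of the animal's lowest-id genotyped full sib; non-genotyped full
sibs therefore carry *identical, duplicated* genomes. This mirrors how
whole-genome imputation behaves in this family structure — the imputer has
nothing but family information, and a sib's genome is its concrete guess —
and it matters for the results in two ways: a copied sib genome is a
single Mendelian draw rather than a conditional mean, so its per-individual
correlation with the truth is markedly lower than that of a typed-and-
imputed animal, and the duplicated rows entering G distort the genomic
relationships of that strategy. The smooth alternative (the parent-dosage
average, available as `impute_whole_genome()` and used as the fallback
when no full sib is genotyped) is a *better* predictor in correlation
terms, which is precisely why it would misrepresent this strategy: the
collapse of the whole-genome approach is a real property of copying
genomes within families, not of averaging them.

Fractional dosages feed the genomic relationship matrix; hard calls
(within `call_margin = 0.1` of an integer; whole-genome animals only where
both parents are homozygous) exist for the genotype-yield metric. IA is
the per-individual Pearson correlation between imputed and true dosage at
that individual's *untyped* markers only — typed markers never enter IA or
yield — averaged over individuals, with zero-variance individuals excluded
and counted. A declared parent contradicting its offspring at more than 1%
of shared typed markers (opposing homozygotes) is dropped from phasing
with a warning.

## Genetic evaluation

One animal model serves every analysis: $y = \mathbf{1}\mu + Za + e$, with
$a \sim N(0, A\sigma^2_a)$ for pedigree BLUP and $a \sim N(0, H\sigma^2_a)$
for single-step GBLUP, where

$$H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1} \end{pmatrix}.$$

$A^{-1}$ is assembled sparsely by Henderson's rules with
inbreeding-corrected Mendelian-sampling variances
($d_i = \tfrac12 - \tfrac14(F_s + F_d)$); inbreeding comes from the
tabular relationship recursion, and the tests cross-check both against an
independent recursive-kinship oracle and dense inversion. $G$ is the
VanRaden matrix on frequency-centred dosages (observed frequencies of the
genotyped set, the reference software's default, configurable), blended as
$0.95\,G_0 + 0.05\,A_{22}$ — the standard default, adopted because the
original analysis does not state its tuning. No further scaling of G to
A22 means is applied, which can shift accuracies by a small systematic
amount. Variance components are fixed at the simulation truth; nothing is
REML-estimated.

The mixed-model equations are solved by a sparse Cholesky factorisation
(`Matrix`), exact to factorisation accuracy; an iterative solver with a
convergence tolerance was considered and rejected as an unnecessary knob
at these problem sizes (a few thousand equations with one dense genotyped
block).

The evaluation data layout mirrors the study design: pedigree of the last
six generations (the 28th-generation males, never genotyped or
phenotyped, are dropped), doe records of the five ancestral generations,
candidate records excluded. Males of the two parental generations are
always in $G$; female ancestors' genotypes enter $G$ only in S1 and S2 —
in the low-density strategies they serve the imputation but are discarded
from $G$, as their error rate would otherwise contaminate the genomic
block. In S3 the non-genotyped candidate half is ranked by parent-average
EBV. QC before $G$ follows the reference defaults (MAF ≥ 0.05, call rates
≥ 0.90); in the pipeline it runs on the fractional dosage matrix, which is
complete after imputation, so the MAF filter does the work — running the
call-rate filter on the sparse whole-genome hard calls would empty S3_A's
marker set, contradicting how that strategy was actually analysed.

## Endpoints

Per scenario and replicate: mean IA and yield over the imputed candidates;
gEBV accuracy as $r(\mathrm{EBV}, \mathrm{TBV})$ over the 1500 candidate
does; response to selection as the mean TBV of the EBV-top-150 minus the
cohort mean (trait units, kits; no discounting); and the percentage of
correctly selected candidates as the overlap between the EBV-top-150 and
the TBV-top-150. "Correctly selected" has no published definition; the
overlap was chosen because it is the only reading with a natural chance
baseline — hypergeometric, 10% when selecting 150 of 1500 — against which
the reported twenty-something-percent values are meaningfully above
chance. Ties are broken by animal id everywhere, making every ranking
deterministic.

Within a replicate all strategies share the identical pedigree, TBVs and
phenotypes, so accuracy differences against the BLUP control are purely
method effects; the per-replicate difference distribution and the
fraction of replicates in which each strategy beats BLUP are part of the
summaries.

## Numerical and reproducibility choices

* One root seed; every stage (founders per chromosome, QTNs, effects,
  panels, each mating, each phenotype draw, the half-progeny split)
  derives its own stream by hashing a label into the root seed, so any
  stage can be reproduced in isolation and S3/S3_A share their split.
  Identical seed and configuration give bit-identical output, asserted in
  the tests.
* The within-programme BLUP selections use a five-generation pedigree
  window: the endpoint comparisons concern the final generations, and the
  window keeps the per-generation solves small. Whether the original
  stochastic engine used full or windowed history is unknown; this is a
  performance decision.
* Selection ties (identical EBVs, e.g. full-sib parent averages) are
  broken by lower animal id.
* Degenerate inputs fail loudly: zero founder TBV variance, chromosomes
  with too few segregating sites, all-markers-filtered QC, singular G
  (with advice to raise the blending weight), candidates with unknown
  parents in the parent-average path.

## Problem sizes used in the checks

The test suite exercises the full machinery on a miniature world (3
chromosomes, 120 HD markers each, 20-animal cohorts) and runs the
reduced-scale reproduction on the desk preset: 4 replicates of the 44-QTN
model for the imputation-accuracy ordering and the S1 / S3_A / BLUP
endpoint comparisons. The acceptance script uses 8 desk replicates of the
44-QTN model (plus 4 of the 5-QTN model for the pedigree-BLUP selection
endpoint). These sizes are the package's chosen working scale; full-scale
quantities that depend on the 200,000-marker panel and 36 replicates —
exact per-strategy IA to three decimals, the 2.53-kit twenty-generation
response — are outside what the reduced scale reproduces and are covered
by ordering and tolerance checks instead.

## Known limitations

* The founder generator approximates, rather than reproduces, a
  coalescent with rabbit demography; absolute LD levels differ from the
  original experiment, which mainly lowers the marker-QTN association
  component of gEBV accuracy relative to its relationship component.
* Marker panels are drawn uniformly from the segregating sites — there is
  no chip-style ascertainment towards common variants (a deliberate
  non-goal). This has a measurable consequence for the per-individual
  Pearson IA, which pools markers across the whole frequency spectrum: a
  large share of that correlation rewards merely tracking allele
  frequency, which even a copied family genome does well. Strategies
  whose information is purely familial (the whole-genome half of S3_A)
  therefore score higher on IA here than they would on an MAF-ascertained
  commercial chip, and the bottom end of the IA ordering compresses.
* The percentage-correctly-selected endpoint is tightly determined by the
  cohort-level accuracy and the litter structure: with candidates ranked
  by a family-level score (pedigree BLUP without candidate records), a
  cohort accuracy near 0.2 yields a top-150 overlap near 17%, and
  substantially higher overlap requires substantially higher accuracy.
  The package reports the overlap exactly as defined; it cannot be moved
  independently of the accuracy it derives from.
* Single-parity phenotypes; no repeated records, overlapping generations,
  culling on other traits, or litters-per-year economics.
* Additive genetics only — no dominance, epistasis or
  frequency-dependent effect coupling.
* The imputer is a pedigree tracker, not a population HMM; population-only
  imputation (unrelated reference panels) is out of scope.
* Genotyping errors and platform ascertainment by MAF are not modelled.
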