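---
title: "Clonal identity and agrobiodiversity analysis of microsatellite genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal identity and agrobiodiversity analysis of microsatellite genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmdiv)
```

## The problem

Date palms (*Phoenix dactylifera*) are dioecious trees propagated either
clonally, by transplanting basal offshoots, or sexually, by accidental or
deliberate seedlings. In a traditional oasis, farmers recognise *named
types* of palms, but a name does not guarantee genetic uniformity: a named
type may be a **true-to-type cultivar** (a single clonal line), an
**ethnovariety** (several clonal lines considered locally equivalent), or a
**local category** (genetically unrelated palms sharing a trait such as
fruit colour or season). Distinguishing these situations matters for how
agrobiodiversity is counted and conserved, and it can be done with a modest
panel of codominant markers: a set of nuclear microsatellites (SSRs)
genotyped as unordered diploid allele pairs, plus a haploid plastid
minisatellite whose repeat number defines the *chlorotype* (3 repeats =
occidental, 4 = oriental, 5 = *P. theophrasti*).

`palmdiv` implements the complete analysis chain for such data: pairwise
multilocus identity and clone-line detection tolerant of somatic mutation,
the named-type classification rule, duplicate removal, per-locus and
per-population diversity statistics, rarefied and private allelic richness,
Weir–Cockerham $F_{ST}$, distance trees, allele-dosage PCA, a Gibbs-sampling
admixture model with Evanno $\Delta K$ model selection, and chlorotype
assignment — together with a synthetic cohort generator that emulates the
oasis study design so every stage can be validated against a known truth.

## Identity and clone lines

For accessions $i, j$ the identity statistic is
$\mathrm{id}(i,j) = n_\mathrm{match} / n_\mathrm{compared}$, where a locus
is *compared* when both calls are non-missing and *matched* when the
unordered allele pairs are identical. A named type's **nuclear identity**
is the unweighted mean of $\mathrm{id}$ over all unordered pairs of its
accessions, as a percentage; its **chloroplastic identity** is the fraction
of comparable pairs with equal plastid allele. A set of exact clones scores
100/100 regardless of missing data, provided pairs remain comparable.

Clone lines are the connected components of the graph joining pairs with at
most $t$ mismatching compared loci (and at least $c$ compared loci). The
defaults are $t = 1$ and $c = 12$: a single-locus deviation is accepted as
a somatic mutation or genotyping error — clonally propagated lines do
accumulate such one-step changes — while two or more deviations break the
clonal hypothesis. Requiring 12 compared loci keeps pairs with heavy
missingness from being linked on a handful of loci. Line identifiers are
the lexicographically smallest member, so the partition does not depend on
input order. Deduplication keeps, per line, the member with the fewest
missing calls (ties broken by ID).

The classification rule mirrors the ethnobotanical definitions:

* $n = 1$ — *inconclusive* (no intra-type comparison possible);
* all accessions in one clone line — *true-to-type cultivar*;
* at least one multi-accession line spanning distinct gardens, plus at
  least one other genotype — *ethnovariety*;
* otherwise — *local category*.

A multi-accession line confined to a single garden is deliberately
discounted as evidence of clonal propagation (two neighbouring palms may
simply be a mother and its transplanted offshoot) and surfaces as a caveat
instead. Two kinds of labelling problems are flagged: an accession whose
clone line contains two or more members of a *different* named type (a
mislabelled offshoot of a widespread cultivar), and an accession unrelated
(identity < 50%) to every member of an otherwise uniform type (mean
pairwise identity of the others ≥ 90%), the signature of an informer
error. The consistency guard is ours: without it, every member of a
genuinely heterogeneous local category would be "an outlier".

```{r identity-example}
a1 <- matrix(1L, 4, 17); a2 <- matrix(2L, 4, 17)
a2[4, 9] <- 3L   # one somatic step in one member
tab <- genotype_table(
  meta = data.frame(accession = paste0("S", 1:4), named_type = "aghzal",
                    population = "oasis", garden = paste0("g", 1:4),
                    status = "named_type"),
  loci = data.frame(name = sprintf("L%02d", 1:17), kind = "nuclear"),
  a1 = a1, a2 = a2)
named_type_identity(tab, "aghzal")$nuc_identity   # 97.06
classify_named_type(tab, clone_partition(tab), "aghzal")$classification
```

## Diversity statistics

Per locus the package reports missing-data percentage, allele count,
polymorphic information content
$\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$, observed
heterozygosity $H_O$, Nei's unbiased gene diversity
$H_S = \frac{2n}{2n-1}\bigl(1 - \sum p^2\bigr)$ (the biased variant is a
flag), null-allele frequency under both the Brookfield-1 estimator
$(H_S - H_O)/(1 + H_S)$ and the Chakraborty estimator
$(H_S - H_O)/(H_S + H_O)$ (negatives clamped to zero and flagged), and a
Hardy–Weinberg test — a $\chi^2$ against HW expectations with
$k(k-1)/2$ degrees of freedom and no rare-allele pooling, or a Monte-Carlo
version permuting allele copies among genotypes with
$p = (1 + \#\{\chi^2_\mathrm{perm} \ge \chi^2_\mathrm{obs}\})/(B+1)$.

The inbreeding coefficient is the ratio of locus averages,
$F_{IS} = 1 - \overline{H_O}/\overline{H_S}$, with a 95% percentile
confidence interval from 1,000 bootstrap resamples of loci. A caveat
documented here rather than hidden: with as few as 17 loci the percentile
locus bootstrap undercovers slightly (≈ 86–88% empirical coverage of a
nominal 95% interval in our simulations); with 40 loci coverage is ≈ 96%.
The estimator itself is unbiased.

**Rarefaction.** Allelic richness comparisons across populations of unequal
size use hypergeometric rarefaction to a common haploid sample size $g$.
The exact form is
$A_g = \sum_a \bigl[1 - \binom{N - N_a}{g}/\binom{N}{g}\bigr]$, and private
allelic richness multiplies each allele's presence probability in the focal
population by its absence probability in every other population:
$P_g = \sum_a Q_a^{(f)} \prod_{j \ne f} (1 - Q_a^{(j)})$. The Monte-Carlo
mode (default 1,000 replicates, $g = 18$, the smallest haploid sample in
the study design) subsamples allele copies directly; the exact formulas are
its test oracle, and the two agree to < 0.1 allele in the suite. Richness
replicates are compared across populations with one-way ANOVA and Tukey HSD
letters (insert-and-absorb assignment). The letters inherit a caveat from
the practice they mirror: rarefaction replicates are resamples of one
dataset, not independent observations, so the grouping is descriptive.

## Population structure

The dosage matrix codes each (locus, allele) column 0/1/2 and imputes
missing calls with the column mean; PCA is a singular value decomposition
of the centred (optionally scaled) matrix, with component signs fixed by
making the largest-magnitude loading positive. Euclidean distances for
heatmaps/trees are computed on the raw (imputed, uncentred) dosage matrix;
Nei's 1972 distance $D = -\ln I$ pools the identity
$I = \sum_l \sum_a x_a y_a / \sqrt{\sum x^2 \sum y^2}$ across loci, with
$I = 0$ capped at $-\ln(10^{-12})$ and flagged. Neighbor-joining uses the
Saitou–Nei agglomeration (exact on additive matrices; negative branch
lengths clamped to zero and flagged), and branch support comes from
resampling **loci** with replacement — the resampling unit of the
tree-bootstrap convention for multilocus genotype data — with supports
reported as percentages on internal nodes; 80% is a display threshold only,
nothing is filtered.

$F_{ST}$ is the Weir–Cockerham (1984) variance-components estimator
$\theta$ for multiallelic codominant data, with per-locus components summed
and the multilocus value the ratio of sums
$\sum a / \sum (a + b + c)$. Fixed differences give $\theta = 1$ exactly; a
random split of one panmictic population stays within $\pm 0.02$ of zero at
$n = 200$.

## The admixture model

Individuals carry ancestry proportions $q_i$ on the $K$-simplex and each
cluster carries per-locus allele frequencies $p_{kl}$. The Gibbs sampler
augments the data with a latent cluster per allele copy (drawn
$\propto q_{ik} \, p_{kla}$), then applies conjugate Dirichlet updates to
$Q$ (prior $\alpha$) and $P$ (prior $\lambda = 1$). The symmetric ancestry
parameter $\alpha$ is itself updated by a Metropolis–Hastings random walk
with a uniform prior on $(0.001, 10)$ — the treatment that lets the
posterior sharpen on discrete populations; fixing $\alpha = 1$ adds two
prior pseudo-copies against 34 observed ones and visibly blurs $Q$. Under
the correlated-frequency F-model (a flag), $P$ is shrunk towards ancestral
frequencies $p_A$ with per-cluster drift $F_k \sim U(0.001, 0.5)$, both
updated by MH. Missing calls are skipped in the likelihood; the haploid
plastid locus is excluded by default. The model log-likelihood summary is
$\widehat{\ln P(D)} = \overline{L} - \mathrm{var}(L)/2$ over post-burn-in
iterations.

Replicate runs are aligned by greedy cluster matching against the
highest-likelihood run, and model selection reports both the
maximum-likelihood $K$ and the Evanno
$\Delta K = |L''(K)| \, / \, \mathrm{sd}(L(K))$, defined only for interior
$K$ with positive run-to-run standard deviation (zero sd is flagged, never
divided by). Desk-scale defaults (burn-in 1,000, 10,000 iterations, 5
runs) are deliberate: on cohorts of a few hundred accessions and ~17 SSRs
the sampler mixes in seconds, and the original long settings (100k burn-in,
1M steps, 10 runs) remain available as parameters.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults *are* the study
design being emulated:

* **Populations.** Per locus an ancestral frequency vector is drawn from a
  symmetric Dirichlet(1); each population draws its own vector from
  Dirichlet$(\theta \cdot p_\mathrm{anc})$ — the F-model analogue of
  correlated frequencies, with expected drift $\approx 1/(1+\theta)$
  against the ancestor and pairwise $F_{ST}$ near the mean drift of the two
  populations. The default oasis configuration uses $\theta = 16$ for the
  four *P. dactylifera* populations (pairwise $F_{ST} \approx 0.06$–0.08,
  the moderate east–west range), $\theta = 0.6$ for *P. theophrasti* and
  $\theta = 0.3$ for the *P. reclinata* outgroup (interspecies
  $F_{ST} \approx 0.3$).
* **Cohort layout.** 406 accessions: 109 named-type palms in 18 named types
  whose clone-line compositions are chosen to produce the three
  classification outcomes (e.g. single lines of 13 and 11 for the elite
  cultivars; a 7+1 type with a planted informer error; mixed-line types; a
  same-garden pair type; all-singleton categories), 18 + 22 accidental
  seedlings, 27 uncultivated desert palms, 121 + 98 western and eastern
  cultivated palms, 9 + 2 wild relatives.
* **Propagation.** Clone-line members are copies of a founder with
  independent stepwise somatic mutations (rate $\mu_{som} = 0.002$ per
  locus per propagation; one-repeat steps reflecting at the code bounds —
  the SSR stepwise-mutation convention). Seedlings are crosses between two
  distinct named-type parents (dioecy: selfing disallowed) with the plastid
  allele inherited from the mother. Genotyping error replaces allele calls
  at rate $\varepsilon = 0.002$ with a random domain allele; missing data
  is planted at 1.1%, the study's observed rate.
* **Chlorotypes.** Population-specific frequencies of the 3/4/5-repeat
  alleles (oasis ≈ 48/52 occidental/oriental, desert ≈ 74/26, western
  palms occidental-dominant, eastern oriental-dominant, *P. theophrasti*
  fixed for 5 repeats).

What the generator does **not** emulate: linkage, coalescent ancestry
within populations, selection, null alleles, allele-size homoplasy, and
realistic pedigree depth for seedlings (single-generation crosses only).
Passing tests therefore validate the estimators and the classification
logic under the design's assumptions, not the full messiness of real
genotyping campaigns.

## Numerical and design choices

* Identity means exclude pairs with fewer than $c$ compared loci (counted
  and reported) rather than let denominators of 1–2 loci dominate.
* Rarefaction uses `lchoose` differences for the exact hypergeometric
  probabilities, stable for any count layout; `g` is capped at the
  smallest haploid sample in the pipeline, which logs the reduction.
* NJ ties are resolved deterministically; negative branch lengths are
  clamped to zero with a flag rather than silently.
* Evanno's $\Delta K$ with zero run-to-run sd is reported as undefined
  with a warning and excluded from the argmax.
* Stage seeds in the pipeline derive from the global seed by a stable
  string hash of the stage name, so adding a stage never shifts another
  stage's stream; all randomness flows through R's RNG (the C++ sampler
  uses R's generator), making every result reproducible from one seed.
* Problem sizes in the validation suite are desk-scale by design: cohorts
  of 30–406 accessions, MCMC sweeps of 1,000 burn-in + 2,500–5,000
  iterations × 5 runs, 100-replicate tree bootstraps, 1,000-replicate
  rarefactions.

## Known limitations

* The chloroplastic identity of a named type is the fraction of comparable
  pairs with matching plastid allele; published tables computed from
  complete data are reproducible under this definition, but some published
  intermediate percentages suggest additional missing-data handling that is
  not documented anywhere we could verify, so no attempt is made to guess
  it.
* The classifier's garden rule needs garden metadata; accessions with
  missing garden IDs do not count towards "spanning distinct gardens".
* The locus-bootstrap $F_{IS}$ interval undercovers slightly at 17 loci
  (see above).
* Cervus-style fuzzy-matching thresholds for identity analysis are not
  modelled beyond the $t$/$c$ parameters.
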