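---
title: "Simulating breeding programs as cohort graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating breeding programs as cohort graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BreedSim)
```

## The model

BreedSim describes a breeding program as a directed graph. Nodes are
*cohorts* — named groups of individuals managed together (a year's calves, a
company's proven sires) — and edges are *breeding actions*: reproduction,
selection, aging/transfer, combining or splitting cohorts. A *repeat edge*
declares that the cycle it closes is carried out a stated number of times;
burn-in cycles are simply the first few repeats, run before measurement to
build up linkage disequilibrium and a pedigree. The graph, together with
trait, culling, founder-subpopulation and economy blocks, is a complete,
reproducible description of a program, serialized as versioned JSON
(`parseProgram()`, `serializeProgram()`, `validateProgram()`).

Simulation proceeds in three stages:

1. **Expansion** (`resolveRepeats()`): repeat edges are unrolled into serial
   copies of their cycle region, suffixed `_1`, `_2`, .... Several repeat
   edges may close the same cycle (aging of calves into the next year's
   cohort, selection of replacements, reproduction of the nucleus); their
   bodies are merged and unrolled together, and each repeat edge becomes a
   concrete action edge from its origin in copy *k* to its target in copy
   *k+1*. Nested cycles with different counts are resolved innermost-first.
2. **Scheduling** (`scheduleGeneration()`): each cohort's simulated time is
   the longest incoming path of generation times; cohorts referenced as
   training data for a breeding-value estimation count as dependencies. Ties
   are broken lexicographically so the order — and with it the random-number
   stream — is fully reproducible.
3. **Execution** (`runProgram()`): founder cohorts are drawn from per-marker
   allele frequencies, all other cohorts are produced by their incoming
   edges, and every cohort is snapshotted (pedigree, true genomic values,
   record means, EBVs, identity-by-descent inbreeding, QTL frequencies).

## Genetic machinery and its assumptions

**Founders and meiosis.** Founder haplotypes are independent Bernoulli draws
per marker — no linkage disequilibrium at creation; LD builds up during the
burn-in cycles, which is why the case study runs five of them before
measuring. Each founder haplotype carries a unique origin label. Meiosis is
a Haldane model: crossover counts per chromosome are Poisson with mean equal
to the chromosome length in Morgan, breakpoints uniform, no interference.
Gametes copy alleles *and* origin labels segment-wise, so kinship and
inbreeding can later be read off as the probability that sampled alleles
carry the same label (`kinshipInbreeding()`). There is no mutation model;
over the 25-cycle horizon of the case study its contribution would be
negligible.

**Traits.** A trait is parameterized by its phenotypic mean, genetic
standard deviation, heritability h², repeatability r ≥ h² and a QTL count.
All traits share one QTL position set (pleiotropy) with per-QTL effect
vectors drawn from a zero-mean multivariate normal whose correlation is the
requested genetic correlation matrix. Pleiotropy is the simplest mechanism
that keeps genetic correlations stable as selection moves allele
frequencies; the alternative (linked but distinct QTL) would erode them at a
rate depending on unmodelled map detail. Effects are rescaled per trait and
an intercept added so that under the founder frequencies the expected
genetic mean and variance hit their targets exactly
(var = Σ 2p(1−p)a²); the *realized* founder variance then scatters around
the target, and realized correlations drift under selection, as in any
stochastic simulation.

**Phenotypes.** A record is the true genomic value plus a
permanent-environment deviation (drawn once per individual, variance
(r − h²)·σ²ₚ) plus a transient residual (variance (1 − r)·σ²ₚ), both
following the residual correlation across traits recorded together. Records
accumulate as individuals pass through cohorts whose phenotyping class
grants them; the selection-usable phenotype is the running mean.

**Breeding-value estimation.** Evaluation is single-trait per trait, with
the index combining traits afterwards — the case study's index weights act
on already-standardized traits, so little is lost relative to a multi-trait
model, and the design effects of interest are not confounded with
estimation-model choices. Repeated records are collapsed to individual means
with effective residual variance ((1 − r)/n + (r − h²))·σ²ₚ; a full
repeatability-model MME would be the more general alternative. Variance
components are the true simulation parameters — no REML — which isolates
breeding-design effects from estimation noise. Pedigree BLUP builds the
A-inverse by Henderson's rules without inbreeding adjustment (exact while
parents are non-inbred, and the standard approximation in large
evaluations); the exact tabular A (`makeA()`) is kept for cross-checks.
Single-step GBLUP replaces the genotyped block using
H⁻¹ = A⁻¹ + [0, 0; 0, G_b⁻¹ − A₂₂⁻¹] with G from VanRaden's first method at
current observed allele frequencies and G_b = 0.95·G + 0.05·A₂₂. The
blending is not cosmetic: with observed frequencies G is exactly singular
(centring puts the ones vector in its null space), and w = 0.05 absorbs
that. Mixed-model equations are solved by sparse Cholesky; a singular
system raises an error suggesting a larger blend weight. The evaluation
pedigree is pruned to candidates, training cohorts and two ancestor
generations — EBV differences from the full pedigree are negligible at the
program's depth while the solve stays desk-scale.

**Selection and mating.** Candidates are ranked on the criterion (record
means, EBVs, or uniform random), combined by the named index; phenotype
indices treat traits without records as contributing zero, so young animals
compete on what is observable at their age. Ties break by individual id;
because dams are drawn in random order, this is equivalent to a random
tie-break but reproducible. Selected sires are used uniformly at random with
replacement (semen treated as unlimited); dams are used without replacement
until exhausted, then with replacement.

**Culling.** Age thresholds per housing class, applied automatically as
simulated time advances; individuals adopt the housing class of each cohort
they enter, so rules can address life stages (candidate bulls vs retired
sires). Dead individuals never mate or get selected but remain visible to
pedigree and breeding-value estimation. Haplotypes are released once an
individual is dead and no longer the parent of a living animal, which
bounds memory by the number of concurrently needed genomes.

## The dairy case study

`dairyScenario()` builds a dairy herd of 184 places in five age cohorts —
calf 44, heifer 40, cow-L1 36, cow-L2 34, cow-L3 30 (the split is this
package's documented assumption; only the total is fixed by the design) —
plus a simplified breeding company with one bull cohort (250) and one cow
cohort (2,000) per cycle. Five standardized traits (RZM, RZE, RZR, RZS,
RZKm; mean 100, genetic SD 12) follow the reference heritabilities,
repeatabilities, record-accumulation pattern and correlation matrix, with
index weights 45/15/10/7/3. Each cycle the company selects the top 25 bulls
by single-step GBLUP — only bulls genotyped, the two most recent company cow
cohorts as training — and farm replacements are chosen from the next-younger
cohort on the phenotype index. The cycle repeats 25 times: 5 burn-in plus 20
measured, with trait trajectories standardized to 100 at cycle 5. Company
cows are phenotyped at the cow-L3 record level, and cow-side selection is
index-on-phenotype; both are documented assumptions where the reference
design is silent. Scenario variants change exactly one lever each:
pedigree BLUP or single-step selection on the farm, top-50 instead of top-25
sires, or index weights 30/20/15/10/5.

The per-trait QTL count (1,000 at full fidelity, 200 in the reduced runs)
is an assumption of this package. Founder allele
frequencies are uniform(0.1, 0.9) per marker.

## Problem sizes and numerical choices

Full-fidelity settings (29 chromosomes, ~24 Morgan, 11,600 markers) are the
defaults, but the package's own studies run at reduced size, chosen once:
the acceptance analysis (`scripts/acceptance.R`) uses full cohort sizes with
a 1,450-marker panel, 200 QTL per trait and 5 replicates per scenario, and
the test suite uses the same panel with 3 replicates. Cohort sizes are
deliberately *not* scaled there: the cohort-scaling feature
(`applyScale()`, rounding half-up with a floor of one) is available to test
a program's conformity cheaply, but halving sire numbers roughly doubles
drift, so scaled runs overshoot inbreeding relative to the full design.
Reduced marker density mainly lowers the LD available to the genomic
evaluation; realized genetic gain runs some 10–20% below the full-density
result while directions, ratios between scenarios, accuracies and
inbreeding rates are preserved. Pairwise-kinship snapshots estimate over a
sample of individuals (default 30) and up to 1,000 marker positions;
inbreeding always uses all markers.

Determinism: one master seed; per-node child seeds are drawn from it up
front, so identical seeds give bit-identical results and error messages name
the offending node or edge. Degenerate inputs are handled explicitly:
zero-length chromosomes recombine never; monomorphic marker sets make G
undefined (error); selection requesting more individuals than are alive, or
reproduction from an empty parent set, fail with the edge named; founder
cohorts at cycle 1 are genuinely unrelated, so their genomic EBVs against
unrelated training data are uniformly zero and accuracy is undefined there.

## What the generator does and does not emulate

Synthetic founders reproduce allele-frequency spectra, Mendelian
inheritance, recombination and the consequent build-up of LD and pedigree
structure — the ingredients the compared breeding designs act on. They do
not reproduce real ascertainment of array markers, historical LD at
distances below the marker spacing, dominance or epistasis,
genotype-by-environment interaction, or trait-specific QTL architectures
(effects are Gaussian; a hook exists for other distributions). Passing
tests therefore demonstrate correct machinery and faithful relative
behaviour of designs, not calibrated absolute predictions for a particular
real population.

## Known limitations

Single-trait evaluation with true variance components; additive gene action
only; no optimum-contribution or mate-allocation schemes; longevity-style
traits whose phenotyping depends on survival are not modelled; the economy
module tracks and discounts costs but performs no optimization. Programs
exported from other graphical front-ends are not guaranteed to load: the
JSON dialect is this package's own, versioned `format_version: 1.0`.
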