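---
title: "Methods: four-way RIL QTL mapping under two planting densities"
author: "fourwayQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: four-way RIL QTL mapping under two planting densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourwayQTL)
```

# The population and the phenotype model

The package targets a four-way recombinant inbred line (FW-RIL)
population: four inbred founders are crossed pairwise, the two F1s are
intercrossed, and the double-cross progeny is advanced by single-seed
descent until lines are effectively homozygous. Each line's genome is a
mosaic of the four founder genomes, so a QTL carries up to four allelic
effects rather than the two of a biparental cross.

Phenotypes follow a split-block (split-plot) field design: planting
density is the main-plot factor with its own error stratum, lines are
sub-plots, with `r` replicates per cell and, for multi-environment data,
`e` environments. The generative model, which is also the ANOVA model read
forward, is

$$x_{eijr} = \mu + E_e + R_r + D_j + \sum_q \left[a_{i(q)} +
ad_{i(q),j}\right] + GE_{ei} + GDE_{eij} + \varepsilon_{eijr},$$

where $i(q)$ is the line's founder allele at QTL $q$, $a$ the additive
allele effects, $ad$ the allele-by-density interaction effects, and $GE$,
$GDE$, $\varepsilon$ independent mean-zero Gaussian components.

## Simulator: what it emulates and what it does not

`simulateFWRIL()` simulates the pedigree meiosis by meiosis. Crossovers
are a Poisson process at 1 per 100 cM with no interference (the Haldane
model); founder origin is tracked per haplotype; after the configurable
number of selfing generations (default 5, one per season of the emulated
programme) any residually heterozygous chromosome is fixed to one of its
two haplotypes chosen at random, so output lines are fully homozygous and
perfectly linked loci stay consistent. Founder SNP haplotypes are drawn
i.i.d. Bernoulli(0.5) per founder and marker, which keeps expected minor
allele frequencies far above the 0.05 filter floor. One master seed in
`designSpec()` (and the `seed` arguments of the genotype functions) makes
whole runs byte-reproducible; seeded calls restore the caller's RNG
state.

Default phenotype parameters were fixed once, before any testing, from
the published description of the emulated population: grand mean 14
nodes; environment margins (+1.0, +0.2, −1.2, −0.6, +0.6) and density
margins (±0.5) shrunk slightly from the real population's treatment
means; three QTL on separate chromosomes whose summed allelic variance
(~1.7 squared nodes) matches the published joint genotype variance; GE
and GDE variances (0.35 and 4.37) at the published joint estimates; and a
residual SD of 1.5 nodes. Under these defaults the simulated
environment-by-density means and SDs fall inside the spans tabulated for
the real population (means 11.77–16.68, SD 1.73–3.22), which the test
suite asserts.

The simulator does **not** emulate: real marker ascertainment or array
genotyping error, segregation distortion, residual heterozygosity in the
output, crossover interference, epistasis, or environment-by-density
fixed interactions. Passing tests therefore show that the analysis
machinery is correct under the stated model, not that real field data
satisfy that model.

# Phenotype analysis

`summarizeTrait()` summarizes line replicate means (the convention used
throughout: the replicate average is the line-level observation) with the
sample SD, adjusted Fisher–Pearson skewness and excess kurtosis — the
small-sample-adjusted forms for which a Gaussian scores 0. Constant
groups flag skewness/kurtosis as undefined rather than zero.

`splitBlockAnova()` uses closed-form cell-mean projections on balanced
data, so sums of squares and degrees of freedom are exactly additive;
unbalanced data are routed to sequential (type-I) least squares in model
order with a warning (the emulated field design is balanced, so this
path is a fallback). F tests respect the split-plot strata: density (and
environment-by-density) against the main-block error, genotype terms
against the residual. Sources with zero degrees of freedom lose their F
test with a warning.

`estimateVarComp()` is method-of-moments via expected mean squares —
auditable and sufficient to reproduce published single-environment
heritabilities exactly; REML was deliberately left out of scope.
Negative estimates are truncated at zero and logged in the result. One
structural caveat: the EMS convention treats the genotype-by-density
interaction as exchangeable across cells, whereas a QTL-driven
allele-by-density pattern is anti-symmetric across two densities (its
rows sum to zero). For such patterns the interaction appears under the
fixed-effect mean-square convention, inflating the exchangeable-model
component by roughly $d/(d-1)$; the recovery tests therefore validate
component estimation under the exchangeable model the estimator assumes.

`heritability()` implements the broad-sense line-mean formulas. For a
single environment $h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GD}/d +
\sigma^2/(dr))$; jointly $h^2 = \sigma^2_G / (\sigma^2_G +
\sigma^2_{GD}/d + \sigma^2_{GDE}/(de) + \sigma^2/(edr))$. The joint
formula contains no $\sigma^2_{GE}/e$ term; whether that stratum belongs
in the phenotypic variance of line means is a genuinely open modelling
choice, so the GE-inclusive variant is available behind
`includeGE = TRUE` while the plain form is the default.

# Response to density

`responseToDensity()` computes, per environment and on replicate means,

$$RD = x_{D2} - \frac{C_{D1D2}}{V_{D1}}\,(x_{D1} - \bar x_{D1}),$$

the conditional-variable form of "response to density": the high-density
phenotype with its linear regression on the low-density phenotype
removed, so that $\mathrm{cov}(RD, x_{D1}) = 0$ and $\overline{RD} =
\bar x_{D2}$ hold as algebraic identities. Sample ($n-1$) moments are
used; the choice cancels in the slope. Lines missing either density in
an environment are dropped for that environment (complete-case, counted
in the result). A degenerate $V_{D1}$ (below $10^{-12}$) returns
$RD = x_{D2}$ with a warning. Replicate means rather than per-replicate
values enter the computation, matching the averaging convention of the
summary tables.

# The four-founder genome scan

`inferFounderProbs()` runs a four-state forward–backward pass per
chromosome. Emissions at markers compare the line's observed biallelic
allele with each founder's allele (probability 1 on match, a floor of
0.001 on mismatch, uniform for missing data); founder-coded input yields
point-mass emissions. Transitions between adjacent evaluation points use
the selfed-RIL expansion $r^* = 2r/(1+2r)$ of the Haldane recombination
fraction of the gap, with an origin change landing uniformly on the
other three founders. $r^*$ is the two-way-RIL expansion; the exact
four-way process accumulates slightly more recombination, and the
simulator's Markov-chain oracle in the test suite quantifies that
approximation on synthetic data. Evaluation runs on the markers plus a
1-cM grid inclusive of chromosome ends.

`imScan()` is a regression (Haley–Knott-style) scan: at each grid
position the trait is regressed on the four founder posterior dosages;
$\mathrm{LOD} = (n/2)\log_{10}(RSS_0/RSS_1)$ against the intercept-only
model, $\mathrm{PVE} = 100\,(1 - RSS_1/RSS_0)$, and effects are reported
as deviations from the mean of the four estimates (sum-to-zero "Add"
convention). A full mixture-EM interval mapper was not used: for
near-homozygous RILs with dense posteriors the regression scan is
standard, fast and adequate. Degenerate positions (all lines one
founder) score LOD 0 and are flagged.

`icimScan()` adds a stage of stepwise cofactor selection on marker
founder dosages (entry p 0.001, removal p 0.002 — conservative defaults,
configurable) and rescans with the trait adjusted for selected cofactors
lying outside ±10 cM of the evaluation point, so a cofactor never
adjusts its own region. With no cofactor selected it reduces exactly to
`imScan()`.

`callQtl()` turns maximal runs of LOD ≥ 3 (the conventional threshold;
no permutation thresholds by design) into calls; the peak is the
leftmost maximum (deterministic tie-break), and the reported support is
the flanking-marker physical interval containing the peak, endpoints
inclusive as printed in the field's tables — not a LOD-drop interval.
`nameQtl()` merges calls whose marker intervals overlap (identity of
flanking markers available via `merge = "identical"`) into regions that
share a per-chromosome sequence number within each trait, with
cross-references when a region carries both the raw trait and the RD
trait.

# QTL effect decomposition across densities

`decomposeDensityEffects()` implements the moment decomposition of a
called QTL's phenotypes over allele classes and densities: grand mean,
allele effects $G_i$, density effects $D_j$, interactions $GD_{ij}$, and
the variance shares $\sigma^2_G = \sum_i f_i G_i^2$, $\sigma^2_D =
\frac1d \sum_j D_j^2$, $\sigma^2_{GD} = \sum_{ij} f_{ij} GD_{ij}^2$,
$\sigma^2_p$ = mean squared deviation, with $PVE_A$ and $PVE_{AD}$ the
percent shares of $\sigma^2_G$ and $\sigma^2_{GD}$. Frequencies are
observed class proportions (an equal-frequency override exists for
strict-formula checks). With two balanced densities $GD_{i,D2} =
-GD_{i,D1}$ exactly — the zero-sum consequence visible in the paired
interaction columns of this literature's tables. Lines are assigned to
allele classes by the posterior maximum when it reaches 0.7 (configurable);
excluded lines are counted. On balanced data the reconstruction
$\mu + G_i + D_j + GD_{ij} = \mu_{ij}$ is exact and
$PVE_A + PVE_{AD} \le 100$.

# Association stand-in and LD decay

The multi-locus mixed-model GWAS methods referenced in this literature
are cited, not specified, so they are not re-implemented. Instead
`markerScan()` is a clearly labelled single-marker regression scan with
the same reporting thresholds (MAF > 0.05, LOD ≥ 3, allele-substitution
effect, $r^2$ in percent) and a method label per record, so multi-method
support counting in the report module stays exercisable by running the
scan under different configurations. No kinship or structure correction
is applied: an FW-RIL has known, uniform kinship and no population
structure in the sense that motivates those corrections. `ldDecay()` bins
pairwise allele-indicator $r^2$ by physical distance and interpolates
the distance at which the mean first crosses a threshold (default 0.1);
it motivates the ±100 kb candidate windows.

# Report logic

Stability: a QTL region is "stable" under the default rule when at least
one support dimension (methods, densities, environments) is repeated;
the strict all-dimensions rule is available. The default was chosen
because the conjunction reading is not satisfied even by the published
stable sets in this literature. Candidate selection: stable, best PVE >
10 %, interval < 600 kb (linkage); ≥2 methods or multi-environment or
co-location, and $r^2$ > 10 % (association). Co-location places a QTN
inside a QTL's physical interval, endpoints inclusive. Windows extend
intervals by 100 kb each side, clamped at the first base. Coordinates
are handled as 1-based inclusive GRanges throughout, matching both
Bioconductor convention and the printed interval style. Gene
intersection stops at positional overlap with a BED/GFF3 annotation;
expression- and pathway-based filtering is out of scope.

# Numerical choices and problem sizes

* Balanced-path SS additivity is exact to square-root machine epsilon;
  the residual SS is clamped at zero.
* LOD values are clamped at zero; rank-deficient founder designs return
  NA for inestimable effects and flag the position.
* Ties at scan peaks break to the leftmost position; region sequence
  numbers order by physical start.
* The test suite runs at deliberately modest sizes chosen to keep the
  checks sharp but quick: founder-frequency checks at 2,000 lines,
  the two-locus Markov-chain comparison at 5,000 lines, scan power at
  100 seeds of 144 lines on one 100-cM chromosome with 26 markers, and
  false-positive control at 200 null scans; the whole suite completes in
  about a minute on one core.

# Known limitations

* The scan is regression-based; for strongly selected or distorted data
  a full likelihood mixture scan could differ.
* The $r^*$ transition understates four-way recombination accumulation
  slightly; posteriors between widely spaced markers are correspondingly
  a little overconfident.
* EMS variance components can be noisy in small designs and are
  truncated at zero rather than shrunk.
* The association module is a single-marker stand-in; its records carry
  a method label precisely so that downstream multi-method logic remains
  testable, not to emulate multi-locus estimators.
* The RD trait is defined for exactly one density increment; more than
  two densities are out of scope.
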