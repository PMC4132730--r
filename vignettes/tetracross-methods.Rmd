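---
title: "Quantifying meiotic crossovers and interference from pollen tetrads"
author: "tetracross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying meiotic crossovers and interference from pollen tetrads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetracross)
```

## The measurement problem

During meiosis, homologous chromosomes exchange segments through
crossovers (COs). In *Arabidopsis thaliana*, fluorescent-tagged lines
(FTLs) in a *qrt* background keep the four pollen grains of one meiosis
attached as a tetrad, and three linked fluorescent transgenes delimit two
adjacent genetic intervals (here called I2a and I2b). Scoring the presence
or absence of each colour in each of the four spores reveals every spore's
genotype at the three marker loci, so a single tetrad is a complete,
four-strand observation of one meiosis.

From a population of such tetrads one can estimate:

* **map distances** for each interval, via tetrad class frequencies;
* **crossover interference**, because having a CO in one interval should
  (in wild type) suppress COs in the adjacent interval;
* and, from cytology, **bivalent formation** at metaphase I — a chromosome
  pair needs at least one CO to appear as a bivalent, so CO-deficient
  genotypes show univalents.

tetracross implements this estimation chain together with a crossover
simulator, so every statistic can be validated end to end against known
ground truth without any external data.

## Tetrad classes and the Perkins estimator

For one interval, reduce each spore to its two-locus genotype. A tetrad is
a **parental ditype** (PD) if only the two parental genotypes appear (2:2),
a **non-parental ditype** (NPD) if only the two recombinant genotypes
appear, and a **tetratype** (TT) if all four genotypes appear. Which
genotypes count as parental is fixed by the declared phase of the line:
in coupling all three transgenes sit on one homolog; in repulsion the
middle marker sits on the opposite homolog. Any other multiset (for
example 3:1 segregation) is non-Mendelian scoring noise; such tetrads, and
tetrads with any unscorable spore, are excluded entirely and reported in
`nExcluded()` — partially scored tetrads would break the ditype logic, so
no partial scoring is attempted.

The map distance of an interval with $n = PD + TT + NPD$ scored tetrads is
estimated with the Perkins equation,

$$\hat d \;=\; 100\,\frac{TT/2 + 3\,NPD}{n}\ \text{cM},$$

which corrects for double COs through the NPD class. When $NPD = 0$ this
reduces to $50\,TT/n$; no further small-sample (Papazian) correction is
applied. The sampling variance comes from the multinomial delta method:
with $t = TT/n$, $q = NPD/n$,

$$\widehat{\operatorname{var}}(\hat d) \;=\;
\frac{100^2}{n}\Big[\tfrac14 t(1-t) + 9\,q(1-q) - 3\,t\,q\Big].$$

The test suite checks this variance against a multinomial parametric
bootstrap (agreement within 10% relative error at $n \ge 500$), and checks
the estimator's bias at 2, 5 and 10 cM against simulated truth.

Two genotypes are compared with a Z-test on the difference of distances,
$z = (\hat d_a - \hat d_b)/\sqrt{\hat v_a + \hat v_b}$, with a two-sided
normal p-value, and with `percentChange()` for effect size. All p-values
in the package are two-sided and reported raw (no multiple-testing
correction), matching how such experiments are conventionally reported.

## The interference ratio

Interference is quantified on the pair of adjacent intervals by
stratifying tetrads on one interval (the *conditioning* interval): tetrads
recombinant there (TT or NPD, pooled — the definition is "having
recombination", which does not distinguish the two) versus parental (PD)
tetrads. The Perkins distance of the *test* interval is computed inside
each stratum and the interference ratio is

$$IR \;=\; \frac{\hat d_{\text{with CO}}}{\hat d_{\text{without CO}}}.$$

$IR = 1$ when interference is absent (the strata are then statistically
identical), and $IR \to 0$ under strong positive interference. H0:
$IR = 1$ is equivalent to equality of the two stratified distances, so it
is tested with the same difference Z-statistic as genotype comparisons;
the difference parameterisation is preferred to a ratio-based test because
its normal approximation does not involve the denominator's curvature.
`irStandardError()` provides a first-order standard error for the ratio
itself, used for confidence intervals on reported IR values.

Because all of this depends only on the nine joint (I2a type, I2b type)
counts, `TetradClassCounts` — not the raw tetrad list — is the package's
sufficient statistic, and the finer 12-class A–L tetrad nomenclature of
the FTL literature is deliberately not the internal representation.

## The two-pathway crossover simulator

Plants and many other eukaryotes form COs through two pathways: class I
COs (ZMM-dependent, the majority) are subject to interference; class II
COs (MUS81-dependent, a minority in wild type) are not. The simulator
mirrors this architecture with two independent point processes on the
genetic map of one chromosome, superposed:

* **Class I**: a *stationary gamma-renewal process* with shape $\nu$ and
  mean count $\lambda_1$ per bivalent per meiosis. Inter-event distances
  are Gamma($\nu$, rate $\nu\lambda_1/L$); $\nu = 1$ recovers a Poisson
  process (no interference) and larger $\nu$ gives increasingly regular
  spacing (spacing CV $= 1/\sqrt{\nu}$), i.e. positive interference. The
  first event is drawn from the equilibrium (stationary residual)
  distribution so that the process has no edge effect at the chromosome
  start: for integer $\nu$ this is an exact equal-weight mixture of
  Gamma($j$, rate) for $j = 1..\nu$; for non-integer $\nu$ the closed-form
  equilibrium CDF is inverted on a 4096-point grid.
* **Class II**: a homogeneous Poisson process with mean count
  $\lambda_2$.

Each CO involves one of the two maternal and one of the two paternal
chromatids, chosen uniformly and independently (no chromatid
interference, no sister exchange) — the default assumption of tetrad
genetics. Spore genotypes are obtained by chromatid tracing: each spore's
DNA molecule starts on its own chromatid and jumps to the partner
chromatid at every CO involving the chromatid it currently rides. The
vectorised tracer is tested case by case against an independent
per-molecule implementation and against exhaustive enumeration of all 441
CO configurations with up to two COs per interval.

The obligate CO (every bivalent receives at least one CO, as enforced
biologically in wild type) is implemented by rejection: a bivalent that
drew no event is redrawn. This is exact conditioning on $\ge 1$ event and
provably leaves the event distribution conditional on $\ge 1$ event
unchanged, which the suite verifies by comparing rejection samples against
filtered unconditional samples.

`simulateMeiocytes()` applies the same event model independently to each
of `nChromPairs` chromosome pairs and reports a bivalent for every pair
with at least one CO, emulating metaphase-I spreads; with five pairs and
total intensity $\lambda$ per pair, mean bivalents are
$5(1 - e^{-\lambda})$ under Poisson placement, another closed form the
tests check.

### Units and calibration

Positions are in Morgans internally (cM only at reporting boundaries, to
avoid factor-100 bugs). Since map distance per gamete is half the expected
number of COs per bivalent, the position scale is genetically calibrated
exactly when $\lambda_1 + \lambda_2 = 2L$ for chromosome length $L$: a
marker interval of $d$ Morgans then has true Perkins distance $100d$ cM.
The defaults ($L = 1$ Morgan, $\lambda_1 = 2$, $\lambda_2 = 0$, $\nu = 1$,
markers at 0.425/0.475/0.525 giving two adjacent 5 cM intervals) describe
an interference-free null chromosome of realistic Arabidopsis genetic
length (~100 cM, ~2 COs per bivalent).

`presetConfig()` ships illustrative genotype-like settings: `wild_type`
($\nu = 7$, $\lambda_1 = 1.8$, $\lambda_2 = 0.2$, obligate CO — strong
interference with a ~10% class II share), `zmm` (class I cut to 10%, no
obligate CO), and `fancm_like`/`mhf_like` (class II released 8- and
5-fold, mimicking loss of a strong or weaker anti-CO factor). These
numerics are deliberately qualitative: no raw tetrad counts are available
in-text to fit $\nu$ or $\lambda$ to a particular experiment, so the
presets are for exploration and power studies, not inference about any
specific data set.

### What the generator does and does not emulate

It emulates per-tetrad fluorescence tables, joint class-count tables and
per-meiocyte bivalent counts under controllable interference, with exact
2:2 segregation. It does not emulate scoring noise (non-Mendelian
patterns, unscorable channels — the classifier's exclusion rules are
exercised with hand-built cases instead), chromatid interference,
chromosome-specific CO landscapes, DSB-to-CO resolution mechanics, or any
coupling between the two pathways. Passing tests therefore demonstrate
correctness of the estimation chain under the stated point-process model,
not robustness to every artefact of real pollen scoring.

## Cytology summaries

`bivalentSummary()` reports mean bivalents and the complementary mean
univalent pairs with the sample SD ($n-1$ denominator, the convention for
small cytology samples); inputs are validated against the chromosome
number. `fociSummary()` gives mean/SD/n for per-cell focus counts (e.g.
MLH1 foci, a class I CO proxy). Group comparisons reported only as
mean ± SD with n are handled by `welchTFromSummary()`, a Welch t-test
computed from the summaries with Welch–Satterthwaite degrees of freedom;
it reproduces `t.test()` on reconstructed raw samples to 1e-10. No test is
attached to bivalent means themselves — they are descriptive.

## Numerical and degenerate-input choices

* `perkinsDistance()` requires $n \ge 1$; a tiny negative delta-method
  variance from floating-point cancellation is clamped to 0.
* `distanceZTest()` refuses the degenerate case where both variances are
  zero; `interferenceRatio()` refuses an empty stratum and an IR with a
  zero denominator (both are "insufficient data", not numbers).
* `welchTFromSummary()` defines the all-zero-SD corner: p = 1 for equal
  means, p = 0 otherwise.
* Simulation is vectorised across meioses (padded event matrices and
  permutation composition), so 50,000 tetrads simulate in well under a
  second; all randomness flows from the single config seed, and seeded
  runs are byte-identical.
* Events exactly at a marker position belong to the downstream side
  (strict `<` comparison); this is a measure-zero tie-break under the
  continuous placement model.

## Problem sizes used for validation

The package's own calibration checks use: 50,000-tetrad simulations for
null-IR and small-distance recovery; 200 replicates of 2,000 tetrads per
true distance (2/5/10 cM) for estimator bias and a 5,000-draw multinomial
bootstrap for the variance cross-check; 1,000 simulated genotype pairs of
1,000 tetrads for the Z-test's type-I error; and 1,000 datasets of 2,000
tetrads for the IR test's type-I error, plus 200 datasets at $\nu = 10$
for its power direction. These sizes give Monte-Carlo error well below
each assertion's tolerance while keeping the suite fast.

## Known limitations

* IR and distance tests rely on normal approximations; with very short
  intervals or small strata (few TT tetrads in the with-CO stratum) the
  nominal level degrades — the calibration tests document the regime where
  it holds.
* The gamma-renewal model is a phenomenological interference model; it is
  standard and desk-computable, but it is not a mechanistic model of CO
  designation, and the simulator cannot fit $\nu$ to data.
* The Perkins estimator is exact through double COs; with three or more
  COs in one interval it is slightly biased (negligible below ~15 cM at
  realistic intensities).
* Repulsion phase is supported for classification, but the simulator's
  repulsion layout fixes the middle marker on the opposite homolog; other
  three-marker phase arrangements would need an explicit parental
  haplotype specification.
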