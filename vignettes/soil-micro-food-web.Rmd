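---
title: "Methods: soil micro-food-web analysis with microfoodweb"
author: "microfoodweb authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil micro-food-web analysis with microfoodweb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microfoodweb)
```

# Scope

The soil micro-food web — bacteria, fungi, and the nematodes that graze on
them and on each other — is routinely profiled with genus-level count
tables from amplicon sequencing or microscopy. `microfoodweb` implements
the standard analysis chain over such tables: alpha diversity, the
Ferris-framework nematode faunal indices, nematode metabolic footprints
with the functional-footprint rhombus, ternary partitioning of
decomposition energy channels, and thresholded Spearman co-occurrence
networks across kingdoms. A synthetic community generator with planted
structure makes every stage testable end to end without sequencing data.

All analyses start from a `CommunityExperiment` (a
`SummarizedExperiment` with a `counts` assay, taxa in rows, samples in
columns) and, for the nematode stages, a `NematodeTraits` database
mapping each genus to its trophic group (BF bacterivore, FF fungivore,
PP plant parasite, OP omnivore-predator), colonizer–persister (c-p)
class 1–5, and mean individual fresh weight in micrograms.

# Alpha diversity

Observed richness, Chao1, and Shannon diversity are computed per sample.
Chao1 uses the bias-corrected form
$S_{chao1} = S_{obs} + \frac{n_1(n_1-1)}{2(n_2+1)}$
with $n_1, n_2$ the singleton and doubleton counts; because singleton
counting is meaningless on transformed data, `chao1()` refuses
non-integer input (the table-level wrapper reports `NA` with a warning
instead, so a pipeline run on relative abundances still produces the
other indices). Shannon is the natural-log form
$H = -\sum p_i \ln p_i$; no base-2 option is offered by default. Indices
are computed on the table as given — no rarefaction is applied.

# Faunal indices

The faunal analysis weights nematode guilds (feeding letter pair × c-p
digit, e.g. Ba1, Fu2, Om4) into three components, using the canonical
published parameterisation of the framework (exposed and overridable via
`ferrisWeights()`):

* enrichment $e = 3.2\,\mathrm{Ba1} + 0.8\,\mathrm{Fu2}$
* basal $b = 0.8\,(\mathrm{Ba2} + \mathrm{Fu2})$
* structure $s = \sum_{cp \ge 3} w_{cp}\,\mathrm{(free\mbox{-}living\ guilds)}$,
  $w_3 = 1.8$, $w_4 = 3.2$, $w_5 = 5.0$, with bacterivore, fungivore,
  omnivore and carnivore guilds treated alike and plant parasites
  excluded throughout.

From these: EI $=100e/(e+b)$, SI $=100s/(s+b)$, BI $=100b/(e+s+b)$, and
the channel index CI $=100 \cdot 0.8\,\mathrm{Fu2} /
(3.2\,\mathrm{Ba1} + 0.8\,\mathrm{Fu2})$, which reads the enrichment
fauna as a fungal-versus-bacterial decomposition dial (CI near 100:
fungal channel; near 0: bacterial). Any index with a zero denominator is
*undefined* and reported `NA`, never 0 — a basal-only community
(BI = 100) and a community with no basal fauna (EI undefined) are
different ecological statements. Floating-point spill outside [0, 100]
is clamped so the range invariant is exact.

Maturity indices are abundance-weighted mean c-p classes: MI over
free-living taxa (cp-1 opportunists included by default;
`includeCp1 = FALSE` implements the tradition that starts at cp-2), PPI
over plant parasites, plus the PPI/MI disturbance ratio. Trophic
diversity TD is reciprocal Simpson dominance over the four trophic-group
proportions, $1/\sum p_g^2$ — the framework names TD without printing a
formula, so the definition used is stated here and in the function
documentation. The faunal profile assigns quadrants at the 50/50 lines
of the (SI, EI) plane with 50 counting as high: A (EI ≥ 50 > SI),
B (both ≥ 50), C (SI ≥ 50 > EI), D (both < 50).

The OP group is coded `Om` by default; an optional `op_subtype` trait
column marks carnivore genera `Ca`. The distinction never changes an
index value (both letters receive the same structural weights), only the
guild labels.

# Metabolic footprints

The carbon flux attributed to $N_t$ individuals of taxon $t$ with fresh
weight $W_t$ (µg) and c-p class $m_t$ is

$$\mathrm{NMF} = \sum_t N_t\left(0.1\,\frac{W_t}{m_t} + 0.273\,W_t^{0.75}\right),$$

respiration plus production with the standard coefficients. Footprints
are summed per trophic group (BFMF, FFMF, PPMF, OPMF; TNMF their total)
and into the enrichment footprint Fe (over Ba1 and Fu2, the fauna that
responds fastest to resource pulses) and structure footprint Fs (over
free-living cp 3–5, the higher trophic levels). Because the formula
needs absolute abundances, `groupFootprints()` refuses tables annotated
as relative unless forced — amplicon read counts are accepted as
abundance proxies only by the caller's explicit assertion
(`annotateNematodes(..., abundance = "absolute")`), since whether reads
can stand in for individuals is a study-design question the software
cannot decide.

The functional footprint draws a rhombus centred at (SI, EI) with
horizontal vertices SI ± 0.5 Fs/k and vertical vertices EI ± 0.5 Fe/k;
its area is $F_e F_s / (2k^2)$. The scaling constant $k$ is display
only; `autoFootprintK()` picks $k = \max(F_e, F_s)/50$ per dataset so
the largest diamond spans half the 0–100 plane, and every area report
carries its $k$.

# Energy-flow triangle

Channel fractions divide BFMF, FFMF and PPMF by their three-channel sum;
OPMF is excluded because the construction names only the three basal
channels (folding OP in proportionally is offered for sensitivity
analysis and provably leaves the simplex point unchanged). Fractions map
into the fixed equilateral triangle with base (0,0)–(100,0) and apex
(50, 86.6) by barycentric interpolation. Two conventions are deliberate:

* the apex uses the one-decimal 86.6 (not 86.6025…) so emitted
  coordinates match the frame as conventionally printed; round-trips use
  the same frame consistently, so inversion is still exact to numerical
  precision;
* the channel-to-vertex assignment (bacterial → lower left, fungal →
  lower right, plant → apex) is a documented, configurable option, not a
  fixed convention.

The seven-point reference frame (`referenceFrame()`) is the three
vertices, three side midpoints, and centroid.

# Co-occurrence networks

Tables from several kingdoms are joined on shared samples
(`bindKingdoms()`), prevalence-filtered (default: detected in at least 3
samples, boundary inclusive), and screened pairwise: Spearman's rho is
Pearson correlation of mid-ranks, and a pair is an edge iff
|rho| > 0.6 and p < 0.05 (both strict; both thresholds configurable).
Within- and between-kingdom pairs are all eligible. Constant taxa are
skipped with a message, never silently. Two p-value modes are offered:
`t_approx` (the rho-to-t transform; default, matching common tool
behaviour) and `exact_smalln` (the exact null distribution of the rank
statistic for n < 10 and a high-order approximation beyond, falling back
to the t approximation when ties make the exact distribution
unavailable). With 3 replicates per treatment an exact p < 0.05 is
unattainable for any non-perfect ranking, so published per-treatment
networks at that depth imply an approximate method — the reason
`t_approx` is the default. No multiple-testing correction is applied by
default (matching common practice for these descriptive networks); a
`p.adjust` method can be supplied.

Network summaries count only incident nodes and define average degree
as $2L/N$. Published network tables in this literature do not always
satisfy that identity (visualisation software computes degree on the
full node set, including isolates, or after other filtering); the
package documents and keeps the $2L/N$ definition rather than
reverse-engineering any particular tool.

Group-level signed associations (`groupAssociations()`) apply the same
machinery to six per-sample totals: bacteria, fungi, BF, FF, PP, OP.

# Synthetic community generator

`simulateCommunities()` emulates a replicated treatment design
(default 4 treatments × 3 replicates) with genus-level tables for three
kingdoms. Its construction:

* **Nematodes.** Taxa are assigned round-robin to the guilds of a
  per-treatment composition matrix; within-guild abundance weights are
  fixed Dirichlet-style draws, so the expected count of taxon $i$ in
  treatment $t$ is `librarySize` × (guild proportion × within-guild
  weight). The default schedule (`defaultGuildComposition()`) moves Fu2
  from 0.50 down to 0.10 and Ba1 from 0.05 up to 0.35 across the four
  treatments, i.e. closed-form CI of 71.4, 67.2, 62.5, 6.7 — a
  fungal-to-bacterial channel shift with CI above 60 except under the
  highest input, the canonical response to increasing nutrient
  addition. A matching trait table (guild-consistent c-p classes and
  trophic groups; log-normal fresh weights around group-typical
  magnitudes) is generated jointly, so end-to-end tests have no fixture
  dependence.
* **Bacteria and fungi.** Fixed log-normal base profiles (log-sd 1.25,
  a realistic rank-abundance steepness) with no systematic treatment
  effect by default.
* **Noise.** Counts are negative binomial with size parameter
  `dispersion` (default 5, mild biological overdispersion) around
  log-normally perturbed means (per-taxon log-sd `sampleNoiseSd`,
  default 0.6). All log-normal perturbations are mean-corrected
  ($e^{z - \sigma^2/2}$), so expected totals equal the configured
  library sizes.
* **Planted structure.** A latent factor lists taxa (any kingdom mix)
  and a `loading`, the target pairwise *rank* correlation of their
  latent abundances; it is converted to the Pearson correlation of the
  underlying normals by Greiner's relation
  $\rho_P = 2\sin(\pi\rho_S/6)$, so loading 1 yields identical ranks
  exactly. Factor sample scores are drawn once per simulation and
  shared across kingdoms, so cross-kingdom factors induce cross-kingdom
  association. Factor taxa swing with amplitude 1.5 log units
  (order-of-magnitude abundance changes, typical of strongly covarying
  genera). Count-level sampling noise attenuates the realised rank
  correlation of the *counts* toward the loading from below; validation
  experiments that need a stated correlation expressed in the counts
  should use a deep library and mild overdispersion (the package's own
  recovery tests use dispersion 25 and a 20,000-read library for this
  reason).
* **Reproducibility.** All randomness flows from one seed;
  `countNoise = FALSE` returns the latent means, and the noise-free
  expected matrices are always returned alongside the counts for
  closed-form checks.

`simulatePhosphorusGradient()` wraps the generator in the monotone
channel schedule, validates monotonicity (Fu2 non-increasing, Ba1
non-decreasing), and returns ground truth: closed-form per-treatment CI
and expected channel fractions computed from the noise-free tables.

What the generator does *not* emulate: compositional closure imposed by
sequencing depth, taxon-specific amplification bias, zero-inflation
beyond what the negative binomial produces, and phylogenetic
correlation among taxa. Passing tests therefore demonstrate that the
estimators recover planted structure under overdispersed count noise —
not that any particular field design has power against these additional
real-data artefacts.

# Validation design and problem sizes

The test suite checks every closed-form example by hand-frozen values,
and each estimator against an independent brute-force implementation:
diversity and faunal indices on 1,000 random communities (agreement to
1e-12), edge sets against an exhaustive pair-loop oracle on fifty 15 × 8
tables (exact set equality), rhombus areas against the shoelace formula,
and the barycentric round-trip on 1,000 simplex points (1e-9). Range and
monotonicity invariants run over 10,000 random communities.
Operating-characteristic checks use 200 simulations for planted-edge
recovery at n = 12 and 50 simulations of null tables at n = 10 for
type-I control, and the full gradient pipeline runs over 100 seeds of a
4 × 3 design with 15 nematode taxa; these sizes keep the suite fast
while leaving Monte-Carlo error well inside the asserted tolerances
(assertions use 3-standard-error bands).

# Known limitations

* Fresh weights in the packaged trait table are implementer-compiled
  reference values; footprints are only as good as the weight
  compilation, and users with their own compilation should load it with
  `readTraitTable()`.
* Spearman screening on compositional data can induce spurious negative
  correlations at low diversity; compositionality-aware methods are out
  of scope by design.
* The exact small-n p-value falls back to the t approximation in the
  presence of ties, which are common in sparse count tables.
* Treatment-level inference (ANOVA, multiple-comparison letters) is
  deliberately not provided; per-treatment means ± SE in the pipeline
  summary are descriptive.
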