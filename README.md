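# microfoodweb

Analysis of the **soil micro-food web** — bacteria, fungi, and nematodes —
from sample × genus count tables, for soil ecologists and
microbiome researchers who profile communities by amplicon sequencing or
microscopy and want the standard food-web condition indicators computed
reproducibly.

## What it computes

Given count tables for the three kingdoms and a nematode trait database
(trophic group, colonizer–persister class *cp* ∈ 1–5, fresh weight *W* in
µg per individual), the package derives:

* **Alpha diversity** per sample: observed richness S<sub>obs</sub>,
  Chao1 `S = Sobs + n1(n1−1)/(2(n2+1))`, and Shannon
  `H = −Σ pᵢ ln pᵢ`.
* **Faunal indices** of the Ferris framework from weighted guild
  components *e* = 3.2 Ba1 + 0.8 Fu2, *b* = 0.8 (Ba2 + Fu2),
  *s* = Σ w(cp) · (free-living cp 3–5 guilds):
  EI = 100 e/(e+b), SI = 100 s/(s+b), BI = 100 b/(e+s+b),
  CI = 100 · 0.8 Fu2 / (3.2 Ba1 + 0.8 Fu2), plus maturity indices
  MI/PPI (abundance-weighted mean c-p), PPI/MI, trophic diversity
  TD = 1/Σ p² and the A–D faunal-profile quadrant of (SI, EI).
* **Metabolic footprints**
  `NMF = Σ Nt (0.1 Wt/mt + 0.273 Wt^0.75)` per trophic group (BFMF,
  FFMF, PPMF, OPMF, TNMF), enrichment/structure footprints Fe and Fs,
  and the functional-footprint rhombus at (SI, EI) with area
  Fe·Fs/(2k²).
* **Energy-flow channels**: bacterial/fungal/plant channel fractions
  from (BFMF, FFMF, PPMF), mapped barycentrically into the fixed
  triangle with base (0,0)–(100,0) and apex (50, 86.6).
* **Co-occurrence networks**: all within- and cross-kingdom genus pairs
  with Spearman |rho| > 0.6 and p < 0.05 (thresholds configurable,
  t-approximation or exact small-n p-values), with signed summary
  statistics and GraphML export.
* **Synthetic communities** with a known phosphorus-gradient structure
  and planted correlations, for method validation
  (`simulateCommunities()`, `simulatePhosphorusGradient()`).

## Worked example

```r
library(microfoodweb)

sim <- simulateCommunities(simulationConfig(seed = 1))   # 4 treatments x 3 reps
nc  <- annotateNematodes(sim$nematodes, sim$traits, abundance = "absolute")

head(faunalIndices(nc), 4)
#>   sample_id   EI   SI   BI   CI   TD   MI PPI PPI_MI quadrant
#> 1      CK_1 49.5 56.6 30.4 71.5 3.65 2.42   3   1.24        C
#> 2      CK_2 53.5 56.9 28.8 73.0 2.86 2.41   3   1.24        B
#> 3      CK_3 54.7 54.0 29.6 64.4 3.46 2.34   3   1.28        B
#> 4     P60_1 50.3 50.8 32.8 70.1 3.33 2.33   3   1.29        B
```

CI above 60 says decomposition runs mainly through the fungal channel in
these low-phosphorus samples; MI ≈ 2.4 with PPI/MI ≈ 1.25 describes a
moderately disturbed, plant-parasite-balanced community, and the
quadrant column places each sample in the faunal profile (B: enriched
and structured; C: structured, resource-limited).

```r
fp <- groupFootprints(nc)
head(ternaryToCartesian(channelFractions(fp)), 4)
#>   sample_id f_bact f_fung f_plant    x    y
#> 1      CK_1  0.350  0.235   0.415 44.2 35.9
#> 2      CK_2  0.395  0.413   0.192 50.9 16.6
#> 3      CK_3  0.301  0.251   0.448 47.5 38.8
#> 4     P60_1  0.444  0.304   0.251 43.0 21.8

net <- spearmanEdges(prevalenceFilter(bindKingdoms(list(
  bacteria = sim$bacteria, fungi = sim$fungi, nematodes = sim$nematodes)), 3))
networkSummary(net)
#>   n_nodes total_links positive_links negative_links average_degree
#> 1     185         722            381            341       7.805405
```

The ternary coordinates place each sample inside the energy-flow
triangle (bacterial vertex lower left, fungal lower right, plant apex);
the network summary counts the signed co-occurrence links among all
genera that pass the correlation and significance thresholds. Across the
simulated gradient the mean channel index falls monotonically
(CK 69.6 → P60 61.5 → P120 55.9 → P180 6.5 here), recovering the
planted fungal-to-bacterial shift.

Real data enter through `readCommunityTable()` (TSV/CSV, either
orientation), `readBiomTable()` (BIOM), `readTraitTable()` /
`defaultTraits()`, and `runPipeline()` writes the complete results
bundle (diversity, indices, footprints, ternary coordinates, edges,
network statistics, per-treatment summaries) with a manifest that makes
reruns byte-identical.

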