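# herbnet

Quantifying spatial variability in plant–insect interactions from leaf
censuses, the way paleobotanists measure it.

Fossil leaf assemblages record insect herbivory as *damage types* (DTs) —
morphologically distinct feeding patterns, grouped into seven *functional
feeding groups* (FFGs: hole, margin, skeletonization, surface,
piercing-and-sucking, gall, mine) — scored on every leaf of a census.
`herbnet` implements the full quantitative toolkit for such censuses,
collected across a hierarchical design (forest → depositional environment →
quarry of ~400 leaves), for researchers comparing modern and fossil
herbivore communities:

* **Census data model and I/O** — long-format CSVs with validation; undamaged
  leaves are first-class so frequencies have per-leaf-censused denominators;
  quarries under the 300-leaf standard are filtered with an exclusion report.
* **Herbivory metrics** — damage frequency per selector (total, specialized,
  each FFG); DT diversity rarefied analytically to *n* = 300 leaves,
  `E[S] = Σ_d [1 − C(N−m_d, n)/C(N, n)]`; plant Shannon *H* and Pielou *J*;
  empirical-logit transforms.
* **Probabilistic DT co-occurrence** — exact leaf-level hypergeometric model:
  with DTs on `N1` and `N2` of `N` leaves, joint occupancy `J` is
  hypergeometric; pairs are positive (`P(J ≥ j_obs) < α`), negative
  (`P(J ≤ j_obs) < α`) or random, with effect size `(j_obs − N1·N2/N)/N`.
* **Bootstrap bipartite plant–DT networks** — quarries resampled to 300
  leaves without replacement (500×); connectance, binary NODF nestedness,
  partner diversity of plants, robustness of DTs to random plant removal
  (exact over all `P!` orders for `P ≤ 6`), and the H2′ specialization index
  `(H2max − H2)/(H2max − H2min)` under fixed marginals; DT degree profiles.
* **Community statistics** — Bray–Curtis, NMDS (Kruskal stress-1), ANOSIM
  with an exactly enumerated permutation null on small designs, Rosner
  (generalized ESD) outlier screening, Tukey–Kramer comparisons.
* **Synthetic study generator** — hierarchical Dirichlet composition,
  generalist/specialist host breadths, preservation bias, and a
  *Lymantria*-style outbreak scenario concentrated on a preferred host, so
  every stage is testable without field data.
* **Pipeline** — `run_pipeline()` orchestrates everything with per-stage
  CSVs and a JSON manifest; `outbreak_experiment()` runs paired
  outbreak/control simulations. A thin CLI lives at `inst/cli/herbnet.R`.

## Worked example

```r
library(herbnet)

cfg <- default_study_config(outbreak = TRUE, seed = 42)  # 3 forests, 28 quarries
cen <- generate_census(cfg)
cen
#> <leaf_census>
#>   leaves:   11200
#>   forests:  3
#>   quarries: 28
#>   DTs seen: 26 of 26 in catalog

flt <- filter_quarries(cen, 300)
mt  <- metrics_table(flt$census, n_std = 300)
aggregate(cbind(freq_total, div_total, plant_shannon) ~ forest, mt, mean)
#>   forest freq_total div_total plant_shannon
#> 1    TF1      0.781    25.303         2.199
#> 2    TF2      0.750    24.655         2.192
#> 3    WT1      0.730    24.668         2.374
```

Total damage frequency (~73–78% of leaves damaged) and rarefied DT
diversity (~25 DTs per 300 leaves) are similar across forests, while the
outbreak forest `TF1` runs slightly hot — the outbreak barely shows in
frequency. The network metrics are where it surfaces:

```r
v  <- aggregate_census(flt$census, "quarry")[["TF1/river/TF1_river_Q1"]]
bootstrap_networks(v, sample_size = 300, n_boot = 50, seed = 1)
#> <bootstrap_networks> quarry TF1/river/TF1_river_Q1 - 50 reps of 300 leaves ( 0 degenerate )
#>                    metric       mean          sd
#>               connectance  0.4528848 0.017019126
#>           nestedness_nodf 61.9844877 1.508259711
#>  partner_diversity_plants  1.9763123 0.069048158
#>            robustness_dts  0.8128536 0.005046269
#>                   h2prime  0.2981236 0.014674728
```

Here H2′ ≈ 0.30 against ≈ 0.25 for the same design without the outbreak:
concentrated feeding preference raises the specialization index even though
every other metric says the forest is generalized. Co-occurrence picks up
the biology at the leaf scale:

```r
cm <- cooccurrence_matrix(flt$census, forest = "TF1")
head(subset(cm$pairs, classification != "random",
            c(dt_a, dt_b, j_obs, expected, p_gt, classification)), 4)
#>    dt_a dt_b j_obs  expected          p_gt classification
#> 3  DT03 DT05   553 198.46925 2.447719e-202       positive
#> 5  DT03 DT07     5  20.66925  9.999987e-01       negative
#> 6  DT05 DT07    10  20.76225  9.988892e-01       negative
#> 12 DT03 DT13    83  68.00850  2.065658e-02       positive
```

The outbreak hole DTs (`DT03`, `DT05`) co-occur far above expectation
(553 shared leaves vs. 198 expected), while the specialized `DT07` avoids
them — its hosts are largely outside theirs.

`outbreak_experiment()` formalizes the detection claim: across paired
outbreak/control simulations, the target forest's mean bootstrap H2′
exceeds its control in essentially every seed while total damage frequency
shifts by only ~3 percentage points.

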