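# soilnetmf

Grazing reshapes grassland soils: it compacts them, shifts nutrient pools
and enzyme investment, and reorganises the bacterial and fungal
communities living in them. `soilnetmf` is an R package for the
computational side of such grazed-versus-ungrazed soil microbiome
studies. It takes OTU count tables, a soil-property/enzyme matrix and
treatment metadata and quantifies, per treatment:

* **microbial nutrient limitation** from ecoenzymatic stoichiometry:
  with `a = T(BG)`, `n = T(NAG) + T(LAP)`, `p = T(ACP)`, the vector
  `x = a/(a+p)`, `y = a/(a+n)` has length `sqrt(x^2 + y^2)` (carbon
  limitation) and angle `atan2(x, y)` in degrees (< 45 N-limited,
  > 45 P-limited);
* **soil multifunctionality** over 15 functions — after reflecting
  "bad-is-high" variables via `r(f) = -f + max(f)` and folding the
  vector angle to `-|x - 45|` — by three indices: entropy-weighted
  (`MF_i = sum_j w_j x'_ij` with information-entropy weights
  `w_j = (1 - E_j)/sum(1 - E)`), entropy-weighted over increasing
  numbers of functions, and threshold counting;
* **signed co-occurrence networks** (edges at `|r| > 0.8`,
  Benjamini-Hochberg `q < 0.01`) with every reported attribute: degree,
  connectance, clusters, modularity, centralizations, per-node
  closeness/transitivity/eigenvector centrality, per-sample subnetwork
  complexity, natural connectivity
  `ln(mean(exp(lambda_i)))` over adjacency eigenvalues, and
  Latora-efficiency vulnerability `max_i (E - E_i)/E`;
* **robustness and stability**: metric decline curves under random
  node/edge removal, and bootstrap distributions of average degree and
  natural connectivity after 50% node removal, compared by
  Kolmogorov-Smirnov and Kruskal-Wallis tests;
* **community assembly**: Levins niche breadth `B = 1/sum(p^2)` with
  Wilcoxon comparison, and PER-SIMPER / dispersal-niche continuum
  analysis (E-value distributions under occupancy-, richness- and
  both-fixed nulls);
* **driver-response dissection**: PC1 composites, an NMDS1 composition
  axis, and zero-/first-order Pearson correlation batteries.

A seeded synthetic-data generator (`synthetic_config()`,
`generate_otu_tables()`, `generate_soil_functions()`) emulates the
two-treatment design with planted co-abundance blocks and planted soil
effects, so every downstream stage is testable against ground truth.
`run_pipeline()` chains all stages and writes TSV/GraphML/JSON artifacts
plus a manifest of every seed and threshold.

## Worked example

```r
library(soilnetmf)

cfg    <- synthetic_config(n_per_group = 10, seed = 42)
soil   <- generate_soil_functions(cfg)
groups <- factor(rep(c("grazed", "ungrazed"), each = 10))

mf <- entropy_mf(prepare_functions(soil), groups = groups)
mean(mf$scores[groups == "grazed"])    # 0.427
mean(mf$scores[groups == "ungrazed"])  # 0.447

tabs  <- generate_otu_tables(cfg)
gt <- tabs$bacteria[, groups == "grazed"];   gt <- gt[rowSums(gt) > 0, ]
ut <- tabs$bacteria[, groups == "ungrazed"]; ut <- ut[rowSums(ut) > 0, ]
build_network(gt)
#> Co-occurrence network: 53 nodes, 151 edges (|r| > 0.8, q < 0.01)
build_network(ut)
#> Co-occurrence network: 25 nodes, 50 edges (|r| > 0.8, q < 0.01)

sg <- stability_bootstrap(build_network(gt), reps = 1000, seed = 1)
su <- stability_bootstrap(build_network(ut), reps = 1000, seed = 2)
compare_stability(sg, su, c("grazed", "ungrazed"))
#> average_degree: KS D = 0.619 (p = 0), Kruskal p = 1.17e-171; more stable: grazed
#> natural_connectivity: KS D = 0.722 (p = 0), Kruskal p = 6.85e-211; more stable: grazed

nb <- compare_breadth(gt, ut)
c(grazed = nb$mean_a, ungrazed = nb$mean_b, p = nb$p_value)
#> grazed 5.97, ungrazed 6.57, p = 1.1e-08
```

Read in order: the grazed soil scores lower on entropy-weighted
multifunctionality (0.427 vs 0.447 here; the decrease is detected far
more reliably by the threshold index — see the methods vignette); the
grazed bacterial network is larger and denser (53 nodes/151 edges vs
25/50) and keeps significantly higher average degree and natural
connectivity after half its nodes are removed (both stability tests:
grazed more stable); and grazed taxa occupy effectively fewer samples
(Levins breadth 5.97 vs 6.57, Wilcoxon p ≈ 1e-08) — a narrowed niche.

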