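---
title: "Methods: multifunctionality, co-occurrence networks and assembly under grazing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multifunctionality, co-occurrence networks and assembly under grazing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`soilnetmf` implements the computational core of a grazed-versus-ungrazed
grassland soil study: how long-term livestock grazing reshapes soil
multifunctionality, the microbial co-occurrence network, and the processes
assembling bacterial and fungal communities. This vignette documents the
models, the tunable parameters, and the design choices made where the
methods literature leaves the design open.

## The emulated study design

The package analyses a two-treatment design: grazed and ungrazed plots,
each with replicated topsoil samples, yielding (i) bacterial and fungal
OTU count tables, (ii) a samples x 15 soil-function matrix (available N,
P, K, Ca, Mg; pH; water content WC; bulk density BD; soil hardness SH;
the four extracellular enzyme activities BGC, NAG, LAP, ACP; microbial C
limitation; and the N/P-limitation vector angle), and (iii) treatment
metadata. Because the package is exercised end-to-end on synthetic data,
`synthetic_config()` + `generate_otu_tables()` + `generate_soil_functions()`
form a first-class, tested module whose defaults *are* the emulated study
conditions.

### The count model

Taxon abundances are log-normal: taxon $i$ has log-mean $\mu_i \sim
N(\log(\mathrm{depth}/T),\ \sigma_\mu^2)$ (default $\sigma_\mu = 1.2$,
giving a realistically skewed abundance distribution over $T$ taxa) and
per-sample residual $\sigma = 0.8$ on the log scale. Expected abundances
are closed to the sequencing depth (default 50,000) and counts drawn
Poisson, so tables are compositional counts. A planted co-abundance block
shares a latent factor within its treatment's samples:
$x_{ij} = \mu_i + \sigma(\sqrt{\rho}\, f_j + \sqrt{1-\rho}\,
\varepsilon_{ij})$, so pairwise correlations approach the target $\rho$.
Block taxa draw their $\mu_i$ from a moderately abundant stratum — the
planted modules emulate the abundant core taxa that co-occurrence
screening actually detects. The grazed community carries more and larger
blocks than the ungrazed one (bacteria: 12+10+8 vs 8+6 taxa at
$\rho = 0.99$; fungi: 8+6 vs 5), so the grazed network is denser — the
direction the study reports. Background taxa receive a per-taxon grazed
log-offset ($\sigma = 0.5$) producing compositional turnover between
treatments, and an occupancy restriction (each grazed background count
zeroed with probability 0.1) that narrows grazed niche breadth.

Two caveats the generator does *not* emulate: phylogenetic structure, and
compositional independence. On the latter: correlations are computed on
relative abundances, so closure induces real dependence when one taxon
dominates, and the skewed marginals make the normal-theory tail of
Pearson's $r$ anti-conservative at small $n$. The package's tests
therefore judge the "no planted structure" null against a
marginal-preserving permutation null rather than the $t$ null; after
Benjamini-Hochberg control at $q < 0.01$ the blockless network is empty
anyway.

### The soil-function effects

Treatment effects default to the study's printed values: SH x7.5,
ACa x2.9, AMg x2.9, BD x1.59, BGC x1.9, ACP x1.08, C-limitation x1.78,
WC x0.53, AP x0.27, pH +0.5 unit; the vector angle moves from a mean of
38 degrees (ungrazed, N-limited) to 45 degrees (grazed, crossing into
co-limitation). The remaining variables carry no planted effect.
Replicate noise is grouped by assay class, chosen once on field-realism
grounds: log-scale SD 0.3 for available-element assays, 0.25 for enzyme
activities, 0.4 for penetrometer hardness, 0.15 for water content, 0.1
for bulk density, 0.12 for the ratio-derived C-limitation index, absolute
SD 0.2 for pH and 4 degrees for the angle. Inverting the study's printed
p-values into noise levels was rejected: at $n = 3$ those p-values are
not literally attainable by the named tests, and the implied noise
pattern contradicts the study's own multifunctionality result.

C-limitation and the vector angle are generated directly with their
printed effects by default (`limitation = "direct"`); a
`limitation = "enzymes"` mode instead recomputes both columns from the
generated enzyme activities via `vector_limitation()`. Direct generation
is the default because the printed enzyme effects (BGC +90%, ACP +8%,
NAG/LAP unchanged) barely move the vector angle, so internal recomputation
cannot reproduce the printed limitation pattern.

## Enzyme-stoichiometry limitation vectors

With $a = T(\mathrm{BG})$, $n = T(\mathrm{NAG}) + T(\mathrm{LAP})$,
$p = T(\mathrm{ACP})$, the vector coordinates are $x = a/(a+p)$ and
$y = a/(a+n)$; vector length $\sqrt{x^2+y^2}$ indexes microbial carbon
limitation and the angle $\mathrm{atan2}(x, y)$ in degrees indexes the
N/P balance (below 45: N limitation; above 45: P limitation). $T$ is the
natural log by default (`trans = "ln"`, the standard option of the vector
method; activities must be positive) with a `raw` mode for worked
examples — whether the original analysis transformed activities is not
recoverable from the study, so both are exposed. The N pool sums NAG and
LAP after transform; the two-argument arctangent avoids division by zero
at $y = 0$.

Before multifunctionality scoring, "bad-is-high" functions are reflected
so that high always means good: $r(f) = -f + \max(f)$ for C limitation,
SH and BD (maximum maps to 0, order reversed), and the angle is folded
about co-limitation, $f(x) = -|x - 45|$ (both printed branches, meeting
at 0). `prepare_functions()` tracks reflection state and refuses to
reflect a column twice.

## Three multifunctionality indices

**Entropy-weighted (maximum number of functions).** Functions are min-max
normalised; sample shares $p_{ij} = x'_{ij}/\sum_i x'_{ij}$ give the
information entropy $E_j = -\frac{1}{\ln n}\sum_i p_{ij}\ln p_{ij}$,
divergence $d_j = 1 - E_j$, weights $w_j = d_j/\sum d$, and
$\mathrm{MF}_i = \sum_j w_j x'_{ij}$. The study cites its entropy index
to prior work without printing the formula; this standard
entropy-weighting scheme is the package's pinned interpretation, frozen
by longhand-arithmetic oracle tests. Constant functions get weight 0; an
all-constant matrix falls back to equal weights with a warning.

**Entropy-weighted (increasing number of functions).** For each subset
size $k = 1..J$ all $\binom{J}{k}$ subsets are enumerated when at most
`max_subsets_per_k` (default 500; enumeration at $J = 15, k \approx 7$
is infeasible), otherwise that many distinct subsets are drawn uniformly
under the seed. Per $k$ the per-sample mean score over subsets is
compared between treatments by Welch's t-test.

**Threshold counting.** Per function a reference maximum is computed
(default: the across-sample maximum; a top-5%-mean rule is offered) and a
sample's index at threshold $t$ is the count of functions at or above
$t\%$ of reference. The default grid is 10–90% in steps of 10.
Kruskal-Wallis compares treatments per threshold. Counts are
non-increasing in $t$ by construction.

A structural observation, established by the package's own recovery
analysis: the printed univariate effects pull a weighted-mean index in
both directions (five functions degrade under grazing after reflection,
five improve), so the entropy indices detect the grazed decrease only
weakly at $n = 10$ per group, whereas the threshold count detects it in
essentially every seed. The decrease direction is robust; its
detectability is index-dependent.

## Co-occurrence networks

Edges link taxa whose relative-abundance profiles correlate strictly
beyond $|r| > 0.8$ with Benjamini-Hochberg $q < 0.01$ (two-sided p from
the $t$ distribution, $n-2$ df). Design choices, documented loudly:

* Correlations use per-sample relative abundances with no further
  transform (pluggable via `transform`); compositional-aware inference
  (SparCC-style) is out of scope.
* One network per treatment, pooling that treatment's samples, mirroring
  the study's grazed/ungrazed network pair. At the field design's
  $n = 3$ per group, correlation inference is degenerate — $q < 0.01$ is
  unreachable — so synthetic recovery analyses raise the replication to
  $n = 10$.
* Zero-variance taxa are dropped before correlation (warning); isolated
  nodes are excluded from the network, which affects the node count.
* Whether the threshold applies to $|r|$ or positive $r$ only is not
  stated; $|r|$ is used (the study's networks contain negative links),
  and the sign is kept per edge for the positive/negative bookkeeping.

Topology metrics run on the unsigned 0/1 adjacency. Natural connectivity
is $\bar\lambda = \ln\left(\frac{1}{n}\sum_i e^{\lambda_i}\right)$ over
adjacency eigenvalues (log-mean-exp stabilised; 0 for an edgeless graph),
and vulnerability is Latora-efficiency based: with global efficiency
$E = \frac{1}{n(n-1)}\sum_{i\ne j} 1/d_{ij}$, disabling node $i$'s edges
(node retained) gives $E_i$ and the vulnerability is
$\max_i (E - E_i)/E$ — neither formula is cited by the study, so the
standard definitions are adopted. Communities come from greedy modularity
agglomeration (deterministic on these graphs); centralizations are
normalised to the star maximum; eigenvector centralities are computed by
a deterministic LAPACK eigendecomposition rather than a randomly-started
iterative solver, so repeated runs are bit-identical. Per-sample
subnetworks are induced subgraphs on the taxa present in each sample; the
five-attribute rows (nodes, edges, average degree, connectance, natural
connectivity) feed the "network complexity" PC1.

## Robustness and stability

`robustness_curve()` removes a fraction of nodes or edges uniformly at
random, independently per fraction (not cumulatively along one
trajectory — the independent convention was chosen; a cumulative one
would correlate points along the curve), with metrics on the reduced node
set and natural connectivity of an emptied graph defined as 0 for curve
continuity. Note the deliberate asymmetry with vulnerability: robustness
deletes nodes, vulnerability strips a node's edges but keeps $n$ fixed.
`stability_bootstrap()` repeats 50% node removal (default 1,000
replicates; the study's 100,000 is configurable) and
`compare_stability()` applies the two-sample Kolmogorov-Smirnov and
Kruskal-Wallis tests with mean ± normal-approximation 95% confidence
intervals — the interval method is unstated in the study, so the normal
approximation on the bootstrap mean is used. The higher-mean network is
labelled more stable.

## Niche breadth and the dispersal-niche continuum

Levins breadth is $B_i = 1/\sum_j p_{ij}^2$ on each taxon's sample
shares — the effective number of occupied samples. Breadth is computed
within each treatment's own samples (matching the grazed-versus-ungrazed
change framing) and compared by the Wilcoxon rank-sum test.

The PER-SIMPER analysis transforms the table to presence/absence,
computes the observed SIMPER profile (per-taxon share of between-group
Bray-Curtis dissimilarity, decomposed pair-by-pair, sorted), and compares
it to three nulls via `vegan::nullmodel`: `fix_taxa` ("r0", taxon
occupancy totals preserved — labelled dispersal-controlled), `fix_sites`
("c0", site richness totals preserved — labelled niche-controlled) and
`fix_both` (curveball swaps preserving both marginals). The
scheme-to-process labelling is an interpretation and is kept visible in
the output. Per permutation
$E = \log_{10} \sum_{\text{ranks}} (\mathrm{obs}_k - \mathrm{perm}_k)^2$
(an exactly invariant permutation yields $-\infty$). The summary index
standardises each scheme against the both-fixed null,
$\mathrm{DNCI} = \overline{d}_{\text{niche}} -
\overline{d}_{\text{dispersal}}$.

**Caveat.** The r0 and c0 nulls are structurally asymmetric: preserving
per-taxon occupancy keeps permuted profiles closer to the observed one
than preserving site richness does, so the DNCI carries a positive offset
even for matrices with no group structure, and the offset's interaction
with planted structure depends on occupancy density. Absolute DNCI values
should therefore be read comparatively — across communities, treatments
or taxon groups under the same dimensions — exactly as the study itself
compares E-value distributions qualitatively rather than quoting a
calibrated zero.

## Composite variables and correlation dissection

`composite_pc1()` z-scores the variables, takes the first principal axis,
normalises the scores to zero mean and unit SD (so duplicating the
variable set changes nothing) and fixes the sign so the score correlates
positively with the |loading|-weighted variable mean. The composition
axis is NMDS1 on Bray-Curtis dissimilarities (two axes, 16 seeded
restarts keeping minimal stress, metric principal coordinates as the
degenerate-case fallback), oriented positively against the most abundant
taxon's relative abundance. Ordination sign is arbitrary in the study;
these deterministic orientation rules exist purely for reproducibility.

Zero-order association is Pearson's $r$ with the $t$-based p-value;
first-order (single-control) partial correlation uses
$r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) /
\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}$ with $n-3$ df, verified against the
residual-regression route to $10^{-10}$. `association_battery()` runs
every driver-response pair with one partial per control; p-values are
unadjusted by default (the study reports raw correlations); a BH option
exists. At the field design's $n = 6$ the battery runs but is
low-powered; its correctness is formula-level, not inferential.

## Numerical conventions and degenerate inputs

$0\ln 0 = 0$ in entropies; $1/\infty = 0$ in efficiencies; strict
inequalities at both network thresholds; removal counts are
$\lfloor f \cdot \mathrm{count} \rfloor$ (with a $10^{-9}$ guard against
floating-point underflow of exact multiples); min-max of a constant
column is defined as 0 with entropy weight 0; the vector angle is clamped
to $[0, 90]$ and generated vector lengths to $[0, \sqrt{2}]$ (their
geometric ranges); ties in subset sampling are prevented by rejection on
sorted index keys. All randomness flows from one root seed through named
substreams (`substream_seed`), so every stage is independently
reproducible and two runs of `run_pipeline()` with the same configuration
are byte-identical.

## Problem sizes

The shipped tests and the acceptance analysis run at desk scale, chosen
as the package's own defaults: recovery analyses use 100 seeds at
$n = 10$ samples per treatment, 300 bacterial / 150 fungal taxa, 1,000
stability bootstrap replicates, up to 60–100 function subsets per $k$,
and 99–199 PER-SIMPER permutations; exhaustive graph oracles cover all
208 non-isomorphic graphs on up to six nodes. All are configurable
upward (the study-scale 100,000 bootstrap replicates are one argument
away).

## Known limitations

* Compositional closure is not modelled out of the correlation network;
  the transform is pluggable but the default is the naive one the study
  used.
* The entropy-MF formula, the DNCI scheme labelling, and the threshold
  reference rule are pinned interpretations of methods the study names
  but does not specify; each is isolated behind one function with oracle
  tests, so replacing an interpretation is local.
* The generator emulates effect directions and magnitudes, not soil
  chemistry: absolute baselines are round field-plausible values, and no
  spatial or temporal autocorrelation is modelled.
* Networks built from 3 samples per treatment are degenerate at the
  default thresholds; this mirrors the field design honestly rather than
  silently loosening thresholds.
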