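---
title: "Methods: seed-based network propagation for macrophage polarization drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-based network propagation for macrophage polarization drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarnet)
```

## The scientific question

Macrophages adopt a spectrum of activation states, conventionally anchored
by the pro-inflammatory M1 pole (IL-1, IL-6, TNF, iNOS-high) and the
tumor-promoting, alternatively activated M2 pole (arginase-1, mannose
receptor/MRC1, YM1, FIZZ1, VEGF-high). A small set of driver genes of the
M1-to-M2 transition can be established at the bench — by RT-PCR on sorted
tumor macrophages, expression profiling of wild-type versus knockout
bone-marrow-derived macrophages, and enzymatic assays. The question this
package operationalizes is: **given a curated driver list, which other genes
in the interactome are likely co-regulators of the transition?**

The working premise is guilt by association: genes that interact densely
with known drivers are themselves candidate drivers. polarnet turns that
premise into a reproducible computation — a random walk with restart over a
protein–protein interaction (PPI) network — and into a testable claim, via a
planted-module benchmark in which the "unknown" drivers are known by
construction.

## The propagation model

Let $G$ be a simple undirected PPI graph over gene symbols with positive
edge weights, $W$ its weighted adjacency and $D$ the diagonal matrix of
weighted degrees. We use the symmetric degree normalization

$$W' = D^{-1/2}\, W\, D^{-1/2},$$

whose spectral radius is at most 1. Curated drivers define a prior
(restart) vector $Y \ge 0$, normalized to $\sum_i Y_i = 1$. Scores evolve
by

$$F^{(t+1)} = \alpha\, W' F^{(t)} + (1-\alpha)\, Y, \qquad F^{(0)} = Y,$$

with mixing parameter $\alpha \in [0,1)$. Because
$\rho(\alpha W') \le \alpha < 1$ the map is a contraction, so the iteration
converges from any start to the unique fixed point

$$F = (1-\alpha)\,(I - \alpha W')^{-1} Y,$$

which `solve_closed_form()` computes directly by a dense solve and serves
as the independent oracle for the iterative `propagate()` in the test
suite. Genes are then ranked by $F$ and the induced subgraph on the top
$K$ genes — with drivers force-included — is the reported subnetwork,
annotated with per-gene expression changes.

Assumptions worth keeping in view: the network is treated as given and
unweighted evidence-wise (every retained interaction counts equally); M1
and M2 drivers are propagated jointly in one prior, with class labels kept
only for annotation, because the analysis produces a single map containing
both classes; and score differences are interpreted only ordinally (the
ranking), never as calibrated probabilities.

## Parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `alpha` | 0.5 | — | Balanced mixing between network smoothing and the prior, the common convention in propagation-based gene prioritization; exposed because no single value is canonical. |
| `tol` | 1e-6 | L1 change per iteration | Well below any score gap that affects the top-100 ranking on desk-scale networks; iteration count at convergence is recorded in the manifest. |
| `max_iter` | 1000 | iterations | Safety cap; convergence at `alpha = 0.5` typically needs ~15–40 iterations. |
| `k` | 100 | genes | The subnetwork reporting depth used throughout. |
| `force_include_seeds` | TRUE | — | The reported subnetwork should contain the known drivers by construction; substitutions are logged in the manifest. |
| `sig_threshold` | 0.05 | adjusted p | Flags, never filters: annotation marks significance but drops no node. |

Tie-breaking in the ranking is score (descending), then weighted degree
(descending), then symbol (ascending) — chosen purely for determinism, so
identical inputs yield byte-identical outputs.

## Input conventions and degenerate cases

Edge lists are tab-delimited with configurable symbol columns, so both
bare two-column files and BioGRID-style multi-column exports parse.
Self-loops are dropped and duplicate undirected records collapsed keeping
the maximum weight, because interaction databases contain redundant
records and the propagation operator assumes a simple graph. Symbols are
uppercased, and an editable alias fixture maps common/protein names to
official symbols (COX2→PTGS2, uPA→PLAU, VEGF→VEGFA, CD206/MMR→MRC1,
YM1→CHI3L3, FIZZ1→RETNLA, Mgl→CLEC10A, arginase→ARG1, …). Two entries
resolve presumed typographical variants seen in curation sources
(CHI3I3→CHI3L3, RENTLA→RETNLA); they are flagged in the fixture rather
than silently assumed, and IL1 is mapped to IL1B as the default
interpretation of an unsuffixed "IL1".

Disconnected graphs are allowed: components containing no seed receive
score exactly 0 (the iteration never moves mass into them), rather than
being removed. Isolated nodes produce all-zero rows of $W'$. Drivers
absent from the network are reported as unmapped, never silently dropped;
mapping zero drivers is an error, since the propagation is then undefined.

## The synthetic study

Real interactome snapshots and expression series are deliberately not
required; the generator produces inputs with the statistical structure the
method assumes, so that every stage is exercisable offline and the
recovery claim is checkable against ground truth.

* **Network**: preferential attachment (Barabási–Albert via
  `igraph::sample_pa`) with `n_nodes = 1000` and `attachment = 3`, giving
  the heavy-tailed degree distribution characteristic of PPI networks.
* **Planted module**: 30 nodes chosen uniformly; each missing
  within-module edge added independently with probability
  `within_p = 0.3`; 10 members revealed as drivers (split alternately
  M1/M2 so both classes are recoverable), 20 held out as ground truth.
  Edges are only ever added, never removed.
* **Expression**: a two-group WT vs. knockout design with
  `n_per_group = 5` replicates on the log2 scale; M2-classed module genes
  get a `+2` log2 mean shift in WT, M1-classed genes `-2`, background
  genes none, with i.i.d. Gaussian noise (`noise_sd = 0.5`). Effect and
  noise were fixed once at values typical of a strong microarray marker
  response (a 4-fold change against ~0.5 log2 residual spread); per-gene
  p-values come from equal-variance two-sample t-tests with
  Benjamini–Hochberg adjustment across the panel.

Each generator is a pure function of its parameters and `rng_seed`
(seeding is local and the caller's RNG stream is restored), so studies are
reproducible end to end.

What the generator does **not** emulate: probe-level array artifacts,
batch effects and their correction, correlated co-expression structure,
literature-bias in interaction coverage, or any coupling between a gene's
degree and its differential expression. Passing the recovery benchmark
therefore shows the method does what it claims **on networks whose modular
structure matches its premise** — it does not certify performance on a
particular interactome snapshot, where coverage bias and annotation error
dominate.

## The recovery benchmark

`recovery_experiment()` runs generate → plant → seed → propagate → rank →
score per replicate and reports held-out AUROC (tie-aware rank-sum form)
and precision@k, with seeds excluded from both ranking and positives —
they are inputs, not predictions, and counting them would inflate the
metrics. At the reference conditions (20 replicates), held-out AUROC is
≈ 0.99–1.0; with `within_p = 0` the module is indistinguishable from
background and AUROC sits at 0.5 within Monte-Carlo error; AUROC rises
monotonically across the density grid {0, 0.15, 0.3, 0.6, 1.0}. Those are
the problem sizes used throughout the tests and the acceptance script;
they run in seconds while leaving the conclusions unambiguous.

## Bench-quantification formulas

The quantification rules used alongside the network analysis have
executable homes:

* `relative_expression()` — expression relative to a housekeeping gene,
  $100 \times 2^{-\Delta Ct}$ with $\Delta Ct = Ct_\mathrm{gene} -
  Ct_\mathrm{ref}$. Methods sections sometimes print this formula without
  the minus sign; whether that is shorthand or a slip cannot be resolved
  from the text alone, so the default here is the standard negated form
  (lower Ct ⇒ more transcript, consistent with the reported marker
  directions) and `sign_convention = "as_printed"` preserves the literal
  positive-exponent reading.
* `tumor_volume()` — the caliper formula $0.5\,L\,W^2$ in mm³.
* `fit_standard_curve()` / `interpolate_concentration()` — ordinary
  least-squares calibration line (e.g. a Griess-assay nitrite curve from a
  0.25 mM serial dilution), with extrapolation beyond the calibrated range
  flagged. The conversion from raw arginase-assay absorbance to µmol urea
  is instrument-specific and is not hard-coded; supply a urea standard
  curve and then `arginase_units()` (µmol urea per minute) applies the
  unit definition.

## Expression annotation conventions

The differential-expression sign convention is log2fc = WT minus knockout,
so M2 markers (higher in WT) are positive and `direction` is `up_in_WT` /
`up_in_KO` by sign, `unmeasured` when no record matches. The annotation
never filters: the significance threshold only sets a flag. The "protein
or gene expression change" painted onto the map accepts any per-gene value
table; its provenance (array, proteomics, targeted assays) is the user's
to document.

## The iterative loop

When predicted candidates are validated at the bench, `iterate_seeds()`
merges them into the driver set (dedup by symbol, weights summed, evidence
unioned) and the pipeline re-runs; `analysis/05_iterate.R` demonstrates
the loop on the synthetic study, where adding recovered module members
pulls the remaining held-out members up the ranking.

## Known limitations

* The BioGRID release, species mapping and physical-interaction filtering
  behind any real network file are the user's responsibility; the package
  treats the edge list as given.
* Scores depend on degree structure; high-degree hubs accumulate mass from
  many seeds, which symmetric normalization tempers but does not remove.
* A single joint M1+M2 prior cannot say *which* pole a candidate serves;
  class attribution comes only from annotation.
* The closed-form solver is a dense oracle capped at 2000 nodes by design;
  production scoring is the sparse iteration.
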