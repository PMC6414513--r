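---
title: "Analyzing simultaneous DNA, RNA and protein synthesis by mass cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing simultaneous DNA, RNA and protein synthesis by mass cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trisyn)
```

Mass-cytometry panels can label all three biosynthetic arms at once: IdU is
incorporated into replicating DNA, bromouridine (BRU) into nascent RNA, and
puromycin into elongating peptides. `trisyn` implements the analysis stack
for such experiments, and — because real instruments are not available in a
test suite — ships a synthetic event generator whose ground-truth labels let
every stage be validated quantitatively.

## Event tables and transforms

Events are raw ion counts with a panel describing each channel's role:

```{r}
cc <- simulate_cell_cycle(cellcycle_spec(), n = 5000, seed = 1)
cc
head(cc$channels)
```

Analysis happens on the arcsinh scale with cofactor 5. The transform state is
tracked per channel, so accidentally double-transforming is an error:

```{r}
cct <- arcsinh_transform(cc, 5)
range(cct$values[, "IdU"])
```

S-phase cells are called by the raw-count rule "IdU > 10 counts":

```{r}
mean(idu_positive(cc))          # designed S fraction is 0.30
```

## Cell-cycle biosynthesis programs

The generator's truth labels expose the phase structure used everywhere
below. The designed program has high IdU in S, a transcription shutdown in
mitosis and a translation drop in late mitosis:

```{r}
tapply(asinh(channel_values(cc, "BRU") / 5), cc$labels$phase, median)
```

## The pipeline

`run_pipeline()` chains simulation (or ingestion), bead normalization,
debarcoding, transformation, gating, SPADE-style clustering, statistics,
Friedman–Rafsky testing and trajectory inference. Every stage derives its
own seed from the run seed and the stage name, and the manifest records the
full trace:

```{r}
cfg <- scenario_config("pbmc_timecourse", seed = 2, n_events = 800)
res <- run_pipeline(cfg, verbose = FALSE)
res$manifest
```

The PBMC scenario barcodes six stimulation time points into one pooled
acquisition; the shift table reports arcsinh-median differences relative to
the unstimulated control:

```{r}
sh <- res$stats$shifts
subset(sh, population == "CD4T" & channel == "BRU")
```

Transcription responds within the first hour and has returned toward
baseline by five hours, while translation (Puromycin) and CD69 surface
expression follow later — the temporal ordering the labeling strategy is
designed to resolve.

## Clustering

Clustering is SPADE-style: density-dependent downsampling protects rare
populations, average-linkage agglomeration builds a fixed number of nodes, a
minimum spanning tree summarizes their relations, and all events are
assigned to their nearest node. Downsampling keeps an event with probability
proportional to the inverse of its local-density *rank*, which preserves
rare populations without being sensitive to the absolute scale of the
density proxy:

```{r}
d <- make_scenario("marrow_hierarchy", seed = 3, n_events = 20000)
ev <- simulate_events(d)
lab <- ev$labels
ev <- subset_events(ev, !lab$bead & lab$viability == "live")
g <- spade_cluster(arcsinh_transform(ev, 5),
                   spade_params(scenario_config("marrow_hierarchy")$clustering$channels,
                                n_nodes = 60L, seed = 4))
g
```

## Population-equivalence testing

The Friedman–Rafsky test asks whether two point clouds are draws from the
same distribution: pool them, build the minimum spanning tree, and count
edges that cross between the samples. Too few crossings indicate separation.
The implementation subsamples S events per population N times and reports
the median p-value; for small graphs `fr_exact_null()` enumerates the exact
null distribution, which anchors the test suite:

```{r}
a <- matrix(rnorm(400), 200)
b <- matrix(rnorm(400, 1.5), 200)
fr_test(a, b, fr_params(S = 100, N = 11, seed = 5))$p_summary
fr_exact_null(cbind(1:5, 2:6), 3, 3)$p_leq(1)   # path graph, 3 vs 3
```

## Trajectory

For developmental continua the package computes a graph-ensemble pseudotime:
repeated random l-of-k nearest-neighbor subgraphs, shortest paths from a
start cell, and waypoint-based refinement. Channel trends along the axis are
rank-based sliding-window medians:

```{r}
bd <- experiment_design(scenario_panel("marrow_hierarchy"),
                        populations = list(b_continuum_spec(1)),
                        n_events = 1500, seed = 6)
bx <- simulate_events(bd)
bxt <- arcsinh_transform(bx, 5)
pt <- pseudotime(bxt, trajectory_params(
  c("CD34", "CD19", "CD10", "CD20", "IgM"), n_graphs = 5, n_waypoints = 50,
  start_rule = function(m) which.max(m[, 1L]), seed = 7))
cor(pt$pseudotime, bx$labels$tau, method = "spearman")
```

The recovered ordering tracks the true latent maturation time, and the
biosynthesis channels can then be read along the axis with
`channel_trends()` — e.g. the transcriptional burst of the plasmablast end
of the B-cell continuum appears after the IgM surface onset.

## Reproducibility

All randomness flows from user-supplied seeds; rerunning any pipeline with
the same config yields byte-identical outputs, and the manifest's config
hash plus per-stage seeds document a run completely.
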