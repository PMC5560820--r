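# ictonet

Simulation and analysis of **brain network ictogenicity**: how the
structure of a brain network shapes its propensity to generate
epileptiform spiking, and which nodes an *in silico* resection should
target.

The package is aimed at computational neuroscientists studying epilepsy
surgery models.  It implements:

* networks of **Wendling neural masses** (10 ODEs per node) and of
  **theta neurons** (the canonical/normal form of the
  saddle-node-on-invariant-circle bifurcation, SNIC), coupled through the
  adjacency matrix and driven by Gaussian noise, with a fast compiled
  Euler–Maruyama integrator and per-node reproducible noise streams;
* **BNI** (Brain Network Ictogenicity), the mean fraction of time nodes
  spend in spiking dynamics, with the sliding-window spike/epoch detector
  and coupling calibration to a reference `BNI_pre = 0.5`;
* **NI** (Node Ictogenicity), the relative BNI drop after virtual
  resection of each node, plus targeted and random progressive
  node-removal curves;
* generators for **random, scale-free, small-world and rich-club**
  topologies (directed and undirected) and a battery of node-importance
  measures (degree variants, eigenvector centrality, Jaccard-dissimilarity
  eigencentrality, dynamical importance, betweenness, closeness,
  clustering, local efficiency);
* **weighted Kendall** rank comparison of NI orderings and NI-vs-measure
  regression tables;
* **functional network inference** from multichannel recordings:
  median re-referencing, Butterworth filtering, 8 s segmentation, IAAFT
  surrogates, zero-lag Pearson correlation, Mann–Whitney U significance
  with Bonferroni–Holm correction, and the surrogate-corrected matrix
  `C = s (rho_o − rho_surr) / (1 − rho_surr)`;
* **weighted rich-club** profiles `phi(k) = phi_w(k) / phi_rand(k)`
  against degree- and weight-preserving null ensembles, richest-club
  membership and resected-fraction scoring;
* a synthetic iEEG-like recording generator with planted, epoch-dependent
  correlation structure, so the whole inference chain is testable without
  clinical data.

## The central quantities

For a network of `N` nodes each sitting a distance below the SNIC
bifurcation and driven by noise,

    BNI = (1/N) * sum_i (time node i spends in spiking dynamics) / (total time)

and, after calibrating the coupling so that `BNI_pre = 0.5`,

    NI_i = (BNI_pre − BNI_post_i) / BNI_pre

where `BNI_post_i` is recomputed after deleting node `i` with unchanged
parameters.  `NI_i = 1` means resecting node `i` abolishes spiking;
`NI_i = 0` means it makes no difference.

## Worked example

```r
library(ictonet)

# a directed Erdos-Renyi network, 15 nodes, mean in-degree 1.6
g <- generate_network("random", n = 15, mean_degree = 1.6,
                      directed = TRUE, seed = 5)

# calibrate the theta-model coupling to BNI = 0.5 at distance 1.2 from
# the bifurcation (starred noise sigma* = 5)
cal <- calibrate_coupling(g, "cm", distance = 1.2, sigma_star = 5,
                          seeds = 1:3, duration = 400)
cal
#> <icto_calibration> CM: coupling* = 0.875 -> BNI = 0.522 (target 0.50, distance 1.2)

# node ictogenicity under common random numbers
ni <- node_ictogenicity(g, "cm", cal$params, seeds = 1:3,
                        common_rng = TRUE, duration = 400)
round(ni$ni, 2)
#>  [1] 0.08 0.08 0.07 0.12 0.15 0.46 0.38 0.21 0.37 0.08 0.21 0.18 0.27 0.29 0.07
```

Nodes 6, 7 and 9 (the recurrent core of this network) carry the largest
NI -- removing any of them costs the network over a third of its spiking
time -- while removing a peripheral node (1, 2, 3, 10, 15) barely matters.
The same
ordering is recovered when the experiment is repeated at other distances
to the bifurcation — that robustness, quantified with a weighted Kendall
tau, is one of the package's headline analyses.

A full account of the models, the noise and detection conventions, and
the design decisions is in `vignettes/ictogenicity-framework.Rmd`.

## Command line

A thin CLI over the package functions is installed at
`inst/cli/ictonet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ictonet.R", package = "ictonet"))')" \
    gen-net --family rich_club --n 64 --club 10 --p1 0.7 --p2 0.2 --out net.tsv
```

Subcommands: `gen-net`, `simulate`, `bni`, `calibrate`, `ni`,
`removal-curve`, `compare-ranks`, `funcnet`, `richclub`, `synth`.

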