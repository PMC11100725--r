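# secom — single-cell super-enhancer contact and community analysis

`secom` analyzes multiplexed DNA-FISH (chromatin tracing) spot tables in
which the ~376 super-enhancers (SEs) of mouse embryonic stem cells are
localized in 3D in thousands of single nuclei (two alleles each, ~752 spots
per cell). It is aimed at labs doing ORCA-style sequential-hybridization
imaging and at anyone who wants to reanalyze FOF-CT-style spot tables
without touching raw images.

## What it computes

For each cell the package builds the all-vs-all Euclidean distance matrix
`D` over detected spots and derives:

- **Contacts** (radius 200 nm) and **communities** (radius 600 nm): the
  cluster size of a spot is the star count `1 + #{ j : D_ij < r }`.
  Per-SE mean cluster size is detection-normalized,
  `1 + mean(partners) / p_det(partners)`, and the 95th-percentile largest
  cluster per SE is reported alongside partner-count frequencies
  (0/1/2/3/4+).
- **Partner entropy**: with `p(e)` the normalized distribution of an SE's
  proximity partners across cells, `H = -Σ p(e) log₂ p(e)`; 0 bits means a
  fully specific partner set, `log₂(N)` a fully promiscuous one.
- **Cooperativity** of a hub triplet (A, B, C):
  `ratio = P(AB ∧ BC) / (P(AB) · P(BC))`, 1 under independence.
- **Odds ratios** from 2×2 contingency tables, `OR = ad / bc` (optional
  Haldane correction), used for transcription-burst coupling: per community
  size s, the odds of a nascent-transcription burst versus isolated alleles,
  plus co-bursting OR(θ) curves over burst-size thresholds.
- **Point-level registration**: mutual-nearest-unique pair matching, 3D
  second-order polynomial chromatic-aberration correction, geometric allele
  assignment (minimizing intra-chromosomal distance sums), detection
  efficiency and replicate localization error.
- **Per-SE genomic features** (bedGraph coverage, DamID LAD window scores,
  SPRITE speckle association, genomic tether metrics) and a **shallow
  neural network** (1 hidden layer × 10 logistic units, 100 replicate
  75/25 splits) regressing mean community size on those features, with
  subset ablation.
- A **synthetic-data generator**: the uniform-random nuclear null (exact
  inverse-CDF sphere sampling), a chromosome-territory model with optional
  landmark attractors, Bernoulli detection dropout, isotropic localization
  noise, and a log-odds-calibrated transcription-burst model.

## Worked example

```r
library(secom)
set.seed(42)

loci  <- synthetic_locus_table(376)            # synthetic SE master list
cells <- apply_detection_noise(
  simulate_territory_cells(loci, sim_config(n_cells = 100)),
  eff = 0.9, sigma = 60)
cells
#> <cell_table> 100 cells, 376 loci (0 dropped), 75200 spots (89.9% detected)

det <- detection_efficiency(cells)
sprintf("median both-allele detection: %.2f", det$overall_median)
#> "median both-allele detection: 0.81"        # ~0.9^2 per-spot dropout

cluster_size_profile(cells, 200, det)          # contact scale
#> <cluster_profile> radius 200 nm, 376 SEs; mean cluster size 1.311 (normalized: TRUE)
cluster_size_profile(cells, 600, det)          # community scale
#> <cluster_profile> radius 600 nm, 376 SEs; mean cluster size 3.869 (normalized: TRUE)

ev <- proximity_events(cells, 600,
                       se_subset = loci[linked_gene == "Nanog", se_id])
pd <- partner_distribution(ev, loci[name == "Nanog-0", se_id])
entropy(pd)
#> 1.58                                        # of log2(3) = 1.58 possible bits

cooperativity(ev, loci[name == "Nanog-1", se_id],
              loci[name == "Nanog-0", se_id],
              loci[name == "Nanog-2", se_id])$ratio
#> 1.02                                        # ~1: no cooperative nucleation simulated
```

Reading: at the contact scale spots are mostly alone (mean cluster size
1.31); at the community scale they sit in groups of ~4. Detection dropout
of 0.9 per spot gives the expected 0.81 both-allele rate, which the
profiles correct for. With community nucleation disabled the Nanog triplet
assembles independently (cooperativity ≈ 1).

A command-line front end covers the same pipeline
(`inst/cli/secom simulate|register|cluster|stats|express|predict|tracks`).

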