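# mscdiscord

Attributing gene-tree discordance to incomplete lineage sorting (ILS) and
hybridization under the multispecies coalescent.

## Who this is for

Phylogenomics of rapid radiations routinely finds that a large fraction of
the genome contradicts the species tree. Two processes produce that
pattern: ILS — ancestral polymorphism persisting across short internodes —
and gene flow, up to and including hybrid speciation. `mscdiscord` is for
researchers who want to (i) simulate genomes under a multispecies
coalescent (MSC) on a species *network* with a known hybrid edge, and
(ii) run the standard attribution toolkit on those genomes (or on their
own biallelic SNVs + window trees) with every estimator's behaviour
validated against conditions where the truth is known.

## What is inside

* **Simulator** — coalescent gene trees on a species tree in coalescent
  units (1 unit = 2N generations; discordance probability of an internal
  branch `tau` is `(2/3)·e^(−tau)`), with at most one hybrid edge: each
  locus follows the donor path with inheritance probability γ.
  Infinite-sites genotypes on synthetic coordinates; a separate
  admixed-panel generator with true ancestry tracts.
* **Window trees** — neighbour-joining on Jukes–Cantor distances per
  genomic window, parsimony-informative-site filter (≥ 10), topology
  tabulation.
* **Species tree** — quartet-concordance maximisation (exhaustive to
  8 taxa, greedy+NNI beyond) with per-branch quartet support
  `q1, q2, q3` (MSC expectation `q2 = q3 = (1/3)·e^(−tau)`), and
  consensus split networks at a frequency threshold.
* **Site patterns** — Patterson's D
  (`D = Σ(ABBA−BABA)/Σ(ABBA+BABA)`) with block-jackknife Z scores,
  f4-admixture ratios, the f-branch min-of-medians matrix, windowed
  F_d with the dynamic-donor denominator `p_D = max(p2, p3)`,
  Hudson's FST, heterozygosity windows.
* **γ estimation** — a site-pattern estimator of the hybrid inheritance
  probability,
  `γ̂ = (n_ABBA−n_BABA) / ((n_ABBA−n_BABA)+(n_BBAA−n_BABA))`,
  with block-bootstrap significance, triplet scans, individual-level
  estimates and a 500-replicate individual bootstrap.
* **Branch-length mixture** — per-triplet classification of discordance
  as ILS-only vs ILS+introgression by BIC between `Exp(λ)` and
  `π·Exp(λ) + (1−π)·(c + Exp(λ))`, with the ±10 ΔBIC decision band.
* **Local ancestry** — a two-source HMM for ancestry dosage (0–2),
  introgression sites at dosage > 1.5, top-1% tract windows,
  intersection with the top-5% F_d tail, and tree re-estimation from
  introgressed vs non-introgressed regions.
* **Pipeline** — `run_pipeline()` chains all stages on synthetic data
  and prints a structured report; a thin CLI
  (`inst/cli/mscdiscord-cli.R`) exposes each stage on files.

## Worked example

```r
library(mscdiscord)
# a radiation triplet with an ancestral hybrid edge (donor C, gamma = 0.3)
net <- species_network("(((A:1,B:1):0.5,C:1.5):4,O:5.5);", outgroup = "O",
                       hybrid = list(recipient = "B", donor = "C",
                                     time = 0.3, gamma = 0.3))
trees <- simulate_gene_trees(net, 2000, seed = 1)
trees
#> 2000 simulated gene trees, 4 lineages each; 610 donor-path loci
gm <- simulate_genotypes(trees, sites_per_locus = 20, mut_rate = 0.05,
                         seed = 2, locus_bp = 1000)
freqs <- polarize(gm)
patterson_d(freqs, "A", "B", "C", block_size = 5e4)
#> D statistic ((A,B),C): D = 0.5123, SE = 0.0393, Z = 13.05 [40 blocks, 23026 sites]
tabulate_topologies(trees)[1:3, ]
#>        topology count   freq rank
#> 1 (((A,B),C),O)   901 0.4505    1
#> 2 (((B,C),A),O)   738 0.3690    2
#> 3 (((A,C),B),O)   361 0.1805    3
```

The gene flow from C into B shows up three ways: roughly 30% of loci took
the donor path (610/2000), the topology grouping B with C is far more
common than its ILS mirror (0.369 vs 0.180), and D is strongly positive
(Z ≈ 13) where ILS alone predicts D ≈ 0.

The mixture classifier recovers known parameters from branch-length
samples directly:

```r
fit <- fit_mixture(c(rexp(700, 10), 1 + rexp(300, 10)), seed = 3)
fit
#> Triplet mixture (n = 1000): M1 lambda = 0.403 (BIC 189.1); M2 pi = 0.700, c = 1, lambda = 0.103 (BIC -1305.3)
#>   delta BIC (M2 - M1) = -1494.46 -> ILS+introgression
```

A full synthetic study — radiation with a balanced (γ = 0.5) hybrid node,
42 Mb genome, all attribution stages — runs in a couple of minutes:

```r
report <- run_pipeline(pipeline_config(seed = 42, gamma = 0.5))
report
#> gamma scan: 1 significant triplet(s); top: H = fm (parents as, sn), gamma = 0.491
#> mixture decisions (discordant classes): 0 ILS-only, 0 ILS+introgression, 70 indistinguishable
#> Fd top-5%: 154 windows; tracts: 42; intersection: 7
#> partitioned trees attach the focal clade differently: TRUE
#> median FST: between_group 0.563, within_group 0.343
```

The γ scan flags exactly the simulated hybrid clade with γ̂ near 0.5, and
the trees rebuilt from putatively introgressed regions attach that clade
to the donor lineage while the complement recovers the species tree. See
`vignette("discordance-attribution")` for the model, every estimator's
assumptions, and the power limits at desk scale.

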