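---
title: "Attributing gene-tree discordance to ILS and hybridization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing gene-tree discordance to ILS and hybridization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a rapid radiation, successive speciation events are separated by short
internal branches while ancestral populations remain large. Ancestral
polymorphism then persists across several splits, and individual loci
coalesce in orders that contradict the species tree: incomplete lineage
sorting (ILS). Gene flow — introgression after speciation, or outright
hybrid speciation — produces the same observable, a gene tree that
disagrees with the species tree. Attributing the observed discordance to
one cause or the other is the central task this package addresses: it
simulates genomes under a multispecies coalescent (MSC) on a species
network, and implements the statistics used in practice to separate the
two signals, so that each statistic can be validated against conditions
where the truth is known.

## The generative model

`species_network()` holds a rooted species tree with branch lengths in
**coalescent units** (one unit = 2N generations of the reference
population) and a relative effective population size per branch. Within a
branch carrying `k` lineages of size `N`, coalescences occur at rate
`choose(k, 2) / N`; the closed forms used throughout follow, e.g. a rooted
triplet whose internal branch has length `tau` yields a discordant gene
tree with probability `(2/3) exp(-tau)`.

At most one **hybrid edge** is supported, with hybrid-speciation
semantics: the recipient clade has two possible attachment points, and
each locus independently follows the donor path with probability `gamma`
(the inheritance probability), otherwise the major, species-tree path.
This matches a scenario in which a clade was founded by an ancestral
hybridization event; it is deliberately not a per-lineage migration model
(no locus is part-donor, part-major), and only one reticulation is
allowed. Removing the hybrid edge always leaves a tree, which the
constructor verifies.

`simulate_genotypes()` drops infinite-sites mutations on the simulated
genealogies: a candidate site becomes a variant with probability
`1 - exp(-mu * L)` (`L` the tree length), the mutation lands on a branch
with probability proportional to its length, and every tip below carries
the derived allele. With no back-mutation, polarisation against the
outgroup is exact, which makes the site-pattern oracles in the test suite
exact as well. Loci are tiled onto a synthetic coordinate system
(configurable locus length and inter-locus gap) so that all window
machinery runs on realistic coordinates. One simulated locus is one
non-recombining unit; recombination within a locus is not modelled.

`simulate_admixed_panel()` is the separate harness for local-ancestry
inference: two source panels at a chosen divergence (Balding–Nichols
frequencies, or fixed differences at `source_divergence = Inf`) and
admixed diploids whose haplotypes are tract mosaics with exponentially
distributed tract lengths (mean `1/(g * r)` bp), with the true tracts and
true dosages returned for scoring.

**What the generator does not emulate:** sequencing error and missing
data, within-locus recombination, selection, more than one reticulation,
variable mutation rate along the genome, and the repeat/low-quality
masking that shapes real window counts. Tests passing on these synthetic
genomes therefore validate the *statistical machinery* — estimator
algebra, calibration, power at known effect sizes — not robustness to
artefacts of real resequencing data.

## Window trees

Real pipelines infer one maximum-likelihood tree per genomic window; at
desk scale this package uses neighbour joining on Jukes–Cantor distances
instead (`infer_window_tree()`). The analyses downstream consume trees
only through their topologies and internal branch lengths, which NJ
recovers well at these divergences; the dialect difference (NJ/JC versus
ML under GTR+CAT) should be kept in mind when comparing branch lengths
across studies. Distances are computed between per-population consensus
sequences (majority allele by dosage; exact ties excluded for
determinism), with the window length in bp as the JC denominator — i.e.
positions without a variant record count as identical. Proportions at or
beyond the JC pole (0.75) are capped just below it, with a warning.

Windows with fewer than 10 parsimony-informative sites (two alleles each
carried by at least two populations) are not inferred and are flagged as
filtered; the threshold is configurable but 10 is the standard filter.
The tree is rooted on the outgroup, and `tabulate_topologies()`
canonicalises topologies (outgroup-rooted, children sorted, lengths
ignored) before ranking them.

## Quartet support and the species tree

`quartet_scores()` classifies, for every internal branch, all quartets
with one leaf from each of the four surrounding clades, in every gene
tree, into the species-tree arrangement (q1) and the two alternatives
(q2, q3). Under the MSC a branch of length `tau` expects
`q2 = q3 = (1/3) exp(-tau)`, which is the calibration used in the
acceptance tests. Counting is exact by default; above a configurable
per-branch quartet budget a seeded uniform sample of quartets is scored
instead. `infer_species_tree()` maximises total quartet concordance —
the criterion ASTRAL optimises — exhaustively over all unrooted
topologies up to 8 taxa, and by greedy taxon insertion with
nearest-neighbour-interchange refinement beyond; ties break
lexicographically on the canonical topology string, so results are
deterministic. The support attached to the returned tree is the raw
(q1, q2, q3) table; no attempt is made to reproduce ASTRAL's local
posterior probabilities, whose values would not be comparable anyway.

`consensus_splits()` keeps every bipartition whose gene-tree frequency
reaches the threshold (0.30 by default), *including mutually incompatible
ones* — consensus-network semantics. Lowering the threshold can only add
splits, which is the property that makes threshold sweeps interpretable.

## D statistics, f4 ratios and f-branch

All ABBA–BABA arithmetic is frequency-weighted (population mode):
`polarize()` converts dosages to derived-allele frequencies per
population, dropping sites where the outgroup is missing or polymorphic
and flipping sites where it is fixed for the alternate allele. For an
ordered trio `((P1, P2), P3)`,

```
ABBA = (1 - p1) p2 p3 (1 - p4),  BABA = p1 (1 - p2) p3 (1 - p4)
D = sum(ABBA - BABA) / sum(ABBA + BABA)
```

with the standard error from a delete-one block jackknife over contiguous
blocks and `Z = D / SE`. Two numerical rules matter: blocks must be at
least as long as the correlation length of the data (for synthetic
genomes, one locus), and a Z score is only reported with at least 20
blocks. `enumerate_trios()` orders every 3-subset by the reference
topology, so D is always computed with the species-tree sister pair as
(P1, P2).

`f4_ratio()` estimates the admixture fraction with the dynamic-donor
convention: the denominator repeats the numerator sum with
`pD = max(p2, p3)` substituted per site, approximating complete
replacement by the donor. `f_branch()` condenses all f4 ratios into one
value per (branch, donor): the minimum over recipient descendants of the
median over valid sisters — the heuristic that assigns signal to possibly
ancestral branches.

`fd_windows()` applies the same dynamic-donor normalisation within small
windows, where it remains bounded and stable. Windows with a non-positive
denominator *or a negative numerator* are reported as undefined rather
than zero; this is the standard Fd convention and it changes which
windows can enter the selected tail, so it is worth stating explicitly.
`top_fraction()` selects `ceiling(f * n_defined)` windows, breaking ties
by genomic order so reruns are identical.

## The gamma estimator

For a triplet (P1, H, P2) with polarised outgroup, write the
frequency-weighted rooted pattern sums `n_BBAA` (P1,H share), `n_ABBA`
(H,P2 share), `n_BABA` (P1,P2 share). Under ILS alone on topology
((P1,H),P2), `E[n_ABBA] = E[n_BABA]`; the sharing excesses over the
`n_BABA` baseline are proportional to the internal branch of whichever
parental tree a locus followed. If the two parental attachment points are
equally diverged, both excesses have the same constant of
proportionality, and expectations are linear in `gamma`:

```
gamma_hat = (n_ABBA - n_BABA) / ((n_ABBA - n_BABA) + (n_BBAA - n_BABA))
```

This estimator is a transparent stand-in derived from that linearity; it
is not a transcription of HyDe's invariant algebra. Its assumption is
also its failure mode: with unequal parental divergences the constants
differ and `gamma_hat` is biased toward the nearer parent. The property
tests verify exact swap symmetry (`gamma_hat -> 1 - gamma_hat` under
P1/P2 exchange), linearity of the expectation (regression slope within
[0.9, 1.1] across a gamma grid), and parameter recovery at equal
divergences.

Significance uses a site-block bootstrap of `gamma_hat` against the
nearer of {0, 1} (the no-hybridization values). Because the estimator is
a ratio, bootstrap replicates are heavy-tailed whenever a resample nearly
zeroes the denominator, so the spread is measured by half the central
68% percentile interval rather than a standard deviation. The triplet
scan tests every ordered triplet, corrects P values by Bonferroni, and
sorts significant hits by `|gamma - 0.5|` so balanced hybrid origins rank
first; extreme estimates near 0 or 1 mean "H is simply sister to one
parent" and are deliberately not significant. Individual-level estimates
replace the hybrid population by each individual in turn, and
`bootstrap_individuals()` (500 replicates by default) resamples
individuals to expose heterogeneity of introgression levels.

## The branch-length mixture classifier

For each species triplet, every gene tree restricted to the triplet
yields a topology class and the internal branch length C2. Under ILS the
discordant-class C2 is exponential from zero; loci that disagree because
of introgression (or that agree because of speciation) concentrate at a
positive offset. The two models are

* M1: `Exp(lambda)` — ILS only (`lambda` is the exponential *mean*);
* M2: `pi * Exp(lambda) + (1 - pi) * (c + Exp(lambda))` — a shared-scale
  shifted component at offset `c >= 0`.

The component families are a modelling choice justified by MSC theory
and validated purely by recovery tests (the decision rule itself does not
prescribe density families). M2 is fitted by EM with the offset profiled on a
data-quantile grid and refined numerically; 10 random starts, tolerance
1e-8 on the log-likelihood and at most 500 iterations per start, all
seed-controlled. Because `c` maximised jointly would run into the usual
boundary degeneracy (it drifts to the smallest shifted observation),
profiling is the numerically sane formulation.

Model choice is `BIC = k ln(n) - 2 logL` with k = 1 and 3, and the
decision applies the step rule to `delta = BIC_M2 - BIC_M1`: greater
than +10 means ILS-only, below -10 means ILS plus introgression, the band
between is indistinguishable. The rule is commonly quoted as a
"difference in delta BIC" without a fixed sign convention; defining delta as
BIC_M2 - BIC_M1 makes "greater than 10 prefers ILS alone" literally
true, and that is the convention implemented. The introgressed-locus
fraction of a class is `(1 - pi)` times its genomic frequency, zero by
convention when M1 is preferred.

Two power facts shape expectations at desk scale. First, since M2 nests
M1, `delta <= 2 ln(n)`, so an ILS-only call (`delta > 10`) is impossible
below n ≈ 150 observations per topology class — with a few hundred
window trees most classes land in the indistinguishable band, mirroring
how conservative the rule is on real data. Second, the offset of the
shifted component equals the relevant internal branch length; in a
radiation with 0.2-coalescent-unit internodes that offset is a fifth of
the ILS mean, so introgression calls require large classes even when the
signal is real. C2 is used in the input trees' own length units
(substitutions/site for NJ window trees); no unit conversion is
attempted, and `lambda`/`c` simply inherit that scale.

## Local ancestry

`infer_dosage()` is a deliberately simple two-source hidden Markov model:
each haplotype of an admixed diploid is a two-state chain whose switch
probability between adjacent markers at distance `d` bp is
`1 - exp(-g * r * d)` toward a stationary mix, and the diploid dosage
chain (states 0/1/2 donor haplotypes) is the exact convolution of two
independent haplotype chains. Emissions are genotype probabilities given
panel allele frequencies with a 0.5 pseudocount. The posterior mean
source-2 dosage is averaged over runs that differ only in `g`, mirroring
the practice of averaging several runs with different mixture-generation
settings. Protocols sometimes quote mixture-generation values in the
millions; such values are passed through as given rather than
reinterpreted, while synthetic tests use small, generation-scale `g`.

The post-processing rules are treated as normative: sites with dosage
strictly above 1.5 from either source are introgression sites; 10-kb
windows are scored by the sum of above-threshold dosages; the top 1% of
windows are putative tracts (an all-zero degenerate selection is flagged,
not suppressed); and the window-wise intersection with the top-5% Fd
selection gives the high-confidence candidate set. `partition_trees()`
then rebuilds NJ trees from variants inside versus outside the candidate
regions — the pipeline partitions on the *union* of the Fd and tract
selections so the complement is genuinely depleted of donor ancestry,
while the intersection is reported as the high-confidence set — and
reports whether the focal clade attaches differently.
`attachment_partners()` is used for that comparison because the focal
clade need not be monophyletic in the introgressed-region tree (it
typically nests inside the donor clade).

## Population summaries

`hudson_fst()` implements Hudson's estimator as a ratio of sums with the
finite-sample correction (the form recommended for sequence data);
negative estimates are retained, so identical sample frequencies give a
slightly negative value rather than exactly zero. A two-population
Weir–Cockerham variant is available behind `method = "wc"`.
`heterozygosity_windows()` counts dosage-1 calls per individual per
non-overlapping window and divides by the window length, treating
positions without a variant record as callable homozygous reference.

## The pipeline and its study conditions

`run_pipeline()` chains every stage on synthetic data. The default
configuration emulates the structure the attribution question assumes:
an outgroup six units deep; a basal in-group lineage; three in-group
clades created by rapid successive splits (internodes of 0.2 and 0.7
units; within-clade splits at 0.5); and one hybrid node — the `fm` clade
formed at age 1.0 from the `as` lineage (major parent) and the `sn`
lineage (donor) with `gamma = 0.5` and exactly equal parental
divergences. Two diploid individuals are sampled per in-group species,
one for the outgroup.

The synthetic genome is 600 loci of 70 kb (42 Mb) with 875 candidate
sites per locus (12.5/kb, a realistic SNV density) and mutation rate
0.02 per site per coalescent unit, giving roughly 260k variants. One
gene-fragment window spans each locus; the mixture stage keeps its 20-kb
window but strides one window per locus, so both schemes sample
independent genealogies; Fd uses 10-kb windows and heterozygosity 100-kb
windows. Analysis thresholds sit at their standard values (informative
sites ≥ 10, delta-BIC ±10, consensus 0.30, top 5% Fd, top 1% tracts,
dosage > 1.5, 500 bootstrap replicates, alpha 0.05). Resampling blocks
equal one locus — the smallest size respecting the correlation
structure, and hence the largest valid number of independent blocks at
this genome size. These sizes are the package's desk-scale study
conditions; they keep a full pipeline run to a couple of minutes while
leaving every stage with real statistical work to do.

One global seed fans out to per-stage seeds through a counter-based
multiplicative hash, so any stage can be reproduced independently, and
the report carries a manifest (configuration hash, seeds, package and R
versions). Stage failures halt the run naming the stage, with completed
stages preserved in the error condition.

At `gamma = 0.5` the two genome-wide arrangements of the hybrid clade are
nearly equally frequent, so which one the species-tree search returns is
effectively a coin toss — exactly the regime where the conflicted branch
shows `q1 ~ q2 ~ q3`. The attribution consequently rests on the gamma
scan (the only significant triplet has the hybrid clade in the middle
position), on the donor enrichment of the Fd and tract tails, and on the
partitioned trees: the introgressed-region tree attaches the hybrid
clade to the donor while the complement tree recovers the species-tree
position. With the hybrid edge removed (`gamma = 0`), the same pipeline
attributes all discordance to ILS: no significant gamma triplet, and at
most noise-level introgression weight in the mixture stage.

## Known limitations

* The gamma estimator assumes equal parental divergences; unequal
  divergences bias it toward the nearer parent (documented above, and
  visible in clade-level scans where the donor is an ancestral branch).
* The mixture classifier has essentially no power below ~150 trees per
  topology class, and its offset scale is tied to internode lengths;
  both limits are properties of the BIC rule, not of the implementation.
* NJ/JC branch lengths are not ML GTR+CAT branch lengths; C2 values are
  comparable within a run, not across methods.
* The HMM is a single-layer stand-in: it infers dosage from panel
  frequencies and a single recombination clock, without the two-layer
  structure of dedicated local-ancestry tools; only the post-processing
  rules are faithful.
* The simulator's locus = recombination-unit assumption makes
  block-resampling conservative and exact at the same time; real genomes
  need block sizes chosen against the actual correlation length.
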