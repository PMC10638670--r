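Package: mscdiscord
Title: Attributing Gene-Tree Discordance to Incomplete Lineage Sorting and
    Hybridization Under the Multispecies Coalescent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates gene trees and genotype matrices under a multispecies
    coalescent on a species network with a single hybrid edge, and implements
    the statistics used to attribute gene-tree discordance in rapid radiations
    to incomplete lineage sorting versus introgression: window-based
    neighbour-joining gene trees, quartet-support species-tree estimation and
    consensus split networks, Patterson's D with block-jackknife errors,
    f4-admixture ratios and the f-branch heuristic, windowed Fd scans, a
    site-pattern estimator of the hybrid inheritance probability gamma with
    individual-level bootstrap, an exponential-mixture classifier of triplet
    internal branch lengths (ILS-only versus ILS plus introgression by BIC),
    Hudson's FST, per-individual heterozygosity windows, and a two-source
    hidden Markov model for local-ancestry dosage with tract calling. An
    end-to-end pipeline reproduces the whole attribution analysis on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
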