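# Shared fixtures: small species networks and quick simulation wrappers.

# 3 species ((A,B),C) with internal branch tau, outgroup O.
triplet_net <- function(tau = 1, hybrid = NULL) {
  nwk <- sprintf("(((A:1,B:1):%g,C:%g):4,O:%g);", tau, 1 + tau, 5 + tau)
  species_network(nwk, outgroup = "O", hybrid = hybrid)
}

# 4 in-group taxa (((P1,P2),P3),O) with optional introgression pulse
# P3 -> P2 at a recent time.
quartet_net <- function(tau = 0.5, gamma = 0, pulse_time = 0.3) {
  hyb <- if (gamma > 0)
    list(recipient = "P2", donor = "P3", time = pulse_time, gamma = gamma)
  species_network(sprintf("(((P1:1,P2:1):%g,P3:%g):4,O:%g);",
                          tau, 1 + tau, 5 + tau),
                  outgroup = "O", hybrid = hyb)
}

# Hybrid triplet with exactly equal parental divergences: H attaches to P1 at
# age 0.5 on the major path and to P2 at age 0.5 on the donor path.
hyde_net <- function(gamma) {
  species_network("(((P1:0.5,H:0.5):0.5,P2:1.0):4,O:5.0);", outgroup = "O",
                  hybrid = list(recipient = "H", donor = "P2", time = 0.5,
                                gamma = gamma))
}

# Derived-allele frequency object built directly from a frequency matrix,
# for exact-arithmetic tests (positions 1 kb apart on one chromosome).
freqs_fixture <- function(freq, outgroup = "O") {
  if (!outgroup %in% colnames(freq)) {
    freq <- cbind(freq, 0)
    colnames(freq)[ncol(freq)] <- outgroup
  }
  structure(list(freq = freq, chrom = rep("chr1", nrow(freq)),
                 pos = (seq_len(nrow(freq)) - 1) * 1000,
                 outgroup = outgroup, n_dropped = 0L),
            class = "derived_freqs")
}

# Sister pair of the 3-taxon gene tree, read off the recorded coalescence
# times (1 = AB, 2 = AC, 3 = BC).
triplet_top <- function(tr, taxa = c("A", "B", "C")) {
  ct <- attr(tr, "coal_times")
  which.min(c(ct[taxa[1], taxa[2]], ct[taxa[1], taxa[3]],
              ct[taxa[2], taxa[3]]))
}

# Independent quartet-topology oracle: prune to the four tips and compare
# the unrooted topology against the three references with phangorn's RF
# distance. Deliberately avoids the package's four-point classification.
oracle_quartet <- function(tree, a, b, c, d) {
  sub <- ape::unroot(ape::keep.tip(tree, c(a, b, c, d)))
  refs <- lapply(c(sprintf("((%s,%s),(%s,%s));", a, b, c, d),
                   sprintf("((%s,%s),(%s,%s));", a, c, b, d),
                   sprintf("((%s,%s),(%s,%s));", a, d, b, c)),
                 function(t) ape::unroot(ape::read.tree(text = t)))
  hit <- which(vapply(refs, function(r)
    phangorn::RF.dist(sub, r, check.labels = TRUE) == 0, TRUE))
  if (length(hit) == 1) hit else NA_integer_
}
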