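# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute force, exhaustive enumeration and direct
# combinatorics only.

# Minimum change count by brute force over ALL internal-node assignments
# drawn from `alphabet`, on a rooted binary ape tree. Missing leaf states
# (NA) contribute no cost on their terminal edge.
brute_force_min_changes <- function(states, tree, alphabet) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  leaf <- states[tree$tip.label]
  grids <- expand.grid(rep(list(alphabet), nnode), stringsAsFactors = FALSE)
  best <- Inf
  for (i in seq_len(nrow(grids))) {
    assign <- as.character(grids[i, ])
    state_of <- function(node)
      if (node <= ntip) leaf[[node]] else assign[[node - ntip]]
    cost <- 0L
    for (e in seq_len(nrow(edge))) {
      sc <- state_of(edge[e, 2L])
      if (is.na(sc)) next
      if (state_of(edge[e, 1L]) != sc) cost <- cost + 1L
    }
    if (cost < best) best <- cost
  }
  best
}

# Exact distribution of the number of sites drawn >= 2 times when C uniform
# draws with replacement are made from V sites: full enumeration of the V^C
# equally likely outcome tuples.
enumerate_multihit_pmf <- function(V, C) {
  if (C == 0) return(c(`0` = 1))
  tuples <- expand.grid(rep(list(seq_len(V)), C))
  mh <- apply(tuples, 1L, function(r) sum(tabulate(r, V) >= 2L))
  table(mh) / nrow(tuples)
}

# A tiny fixed 4-leaf balanced tree used in several tests.
balanced4 <- function(bl = 0.1) {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  tr$edge.length <- rep(bl, nrow(tr$edge))
  tr
}

# Hand-built two-row alignment helper.
toy_alignment <- function(seqs, focal = names(seqs), gene_id = "toy",
                          strand = "unknown") {
  gene_alignment(gene_id, seqs, focal = focal, strand = strand)
}
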