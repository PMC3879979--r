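# --- tree bookkeeping -------------------------------------------------------

# Precompute postorder edge traversal, children, ancestor sets and branch ids
# for a rooted binary phylo tree. All node indices follow ape's convention
# (tips 1..ntip, root ntip+1).
tree_info <- function(tree) {
  validate_phylogeny(tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  root <- ntip + 1L
  children <- vector("list", ntip + nnode)
  for (i in seq_len(nrow(edge)))
    children[[edge[i, 1L]]] <- c(children[[edge[i, 1L]]], edge[i, 2L])
  parent <- integer(ntip + nnode)
  parent[edge[, 2L]] <- edge[, 1L]
  parent[root] <- NA_integer_
  # strict ancestors of each node (root-ward chain, excluding the node)
  anc <- vector("list", ntip + nnode)
  po_nodes <- unique(reorder(tree, "postorder")$edge[, 1L])  # internal, post-order
  for (n in rev(po_nodes)) {                                 # pre-order fill
    for (ch in children[[n]]) anc[[ch]] <- c(anc[[n]], n)
  }
  list(tree = tree, ntip = ntip, nnode = nnode, root = root,
       edge = edge, parent = parent, children = children, ancestors = anc,
       postorder_nodes = po_nodes, branch_id = branch_ids(tree))
}

# Are two edges (given by child node) on independent lineages, i.e. neither
# on the root-ward path of the other?
edges_independent <- function(info, child1, child2) {
  child1 != child2 &&
    !(child1 %in% info$ancestors[[child2]]) &&
    !(child2 %in% info$ancestors[[child1]])
}

# --- state coding -----------------------------------------------------------

# Integer-code a character matrix of residues: 1..20 for amino acids, NA for
# 'X', '-' or anything unrecognised.
encode_states <- function(m) {
  out <- matrix(match(m, AA_ALPHABET), nrow = nrow(m), dimnames = dimnames(m))
  out
}

# --- Fitch small parsimony --------------------------------------------------

# Vectorised Fitch over all columns of an integer state matrix
# (rows = tree tips in tip.label order, cols = sites; NA = missing).
# Missing tips carry the full-alphabet bitmask, i.e. are unconstrained.
# Returns the per-site minimum change count; NA for all-missing sites.
fitch_scores <- function(states, info) {
  full <- bitwShiftL(1L, length(AA_ALPHABET)) - 1L
  L <- ncol(states)
  nmask <- matrix(0L, nrow = info$ntip + info$nnode, ncol = L)
  for (t in seq_len(info$ntip)) {
    s <- states[t, ]
    nmask[t, ] <- ifelse(is.na(s), full, bitwShiftL(1L, s - 1L))
  }
  score <- integer(L)
  for (n in info$postorder_nodes) {
    ch <- info$children[[n]]
    m1 <- nmask[ch[1L], ]
    m2 <- nmask[ch[2L], ]
    inter <- bitwAnd(m1, m2)
    empty <- inter == 0L
    score <- score + empty
    nmask[n, ] <- ifelse(empty, bitwOr(m1, m2), inter)
  }
  all_missing <- colSums(!is.na(states)) == 0L
  score[all_missing] <- NA_integer_
  score
}

#' Minimum number of amino acid changes at one site (Fitch parsimony)
#'
#' Computes the small-parsimony minimum change count on a rooted binary tree
#' for one alignment column. Missing states (`X`, `-`, `NA`) leave the leaf
#' unconstrained.
#'
#' @param states Named character vector mapping every tip label to a residue,
#'   `"X"`, `"-"` or `NA`.
#' @param tree Rooted binary `phylo` covering `names(states)`.
#' @return Integer minimum change count, or `NA` if every state is missing.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitch_min_changes(c(A = "V", B = "I", C = "V", D = "I"), tr)  # 2
#' @export
fitch_min_changes <- function(states, tree) {
  info <- if (inherits(tree, "phylo")) tree_info(tree) else tree
  miss <- setdiff(info$tree$tip.label, names(states))
  if (length(miss))
    stop(sprintf("no state given for tip(s): %s", paste(miss, collapse = ", ")))
  m <- matrix(toupper(states[info$tree$tip.label]), ncol = 1L,
              dimnames = list(info$tree$tip.label, NULL))
  fitch_scores(encode_states(m), info)[1L]
}

#' Per-site minimum change counts for a whole gene
#'
#' Vectorised Fitch parsimony over every column of the focal rows of an
#' alignment (outgroups are never used for change counting).
#'
#' @param aln A [gene_alignment].
#' @param tree Rooted binary `phylo` covering the focal labels.
#' @return Integer vector, one minimum change count per column; `NA` marks
#'   columns where every focal state is missing.
#' @export
site_min_changes <- function(aln, tree) {
  info <- if (inherits(tree, "phylo")) tree_info(tree) else tree
  if (!setequal(info$tree$tip.label, aln$focal))
    stop("tree tips and focal labels must coincide for change counting")
  m <- alignment_matrix(aln)[aln$focal, , drop = FALSE]
  if (ncol(m) == 0L) return(integer(0))
  m <- m[info$tree$tip.label, , drop = FALSE]
  fitch_scores(encode_states(m), info)
}

# --- MPR enumeration --------------------------------------------------------

# Maximum number of distinct observed states before enumeration falls back
# to random sampling of internal assignments.
MPR_ENUM_GUARD <- 6L
MPR_SAMPLE_SIZE <- 50000L

#' Enumerate most-parsimonious reconstructions at a site
#'
#' Exhaustively enumerates internal-node state assignments over the observed
#' residues at the site, keeping every assignment that achieves the Fitch
#' minimum change count, and converts each into its list of change events
#' (branch, ancestral residue, derived residue). Restricting candidate
#' ancestral states to the residues observed at the site is sufficient to
#' recover all parsimony optima. If more than 6 distinct residues are
#' observed (impossible with 5 focal strains) the assignment space is
#' sampled with a warning instead of enumerated.
#'
#' @inheritParams fitch_min_changes
#' @param site Site index recorded in the result (0-based; purely a label).
#' @param root_state Optional residue used to break root-state ties: when
#'   given (e.g. a consensus outgroup residue), reconstructions whose root
#'   state differs are discarded unless that would discard all of them.
#' @return An object of class `site_reconstruction`: list with `site`,
#'   `min_changes`, `mprs` (list of data.frames with columns `branch`,
#'   `from`, `to`), `undefined` flag.
#' @export
enumerate_mprs <- function(states, tree, site = NA_integer_, root_state = NULL) {
  info <- if (inherits(tree, "phylo")) tree_info(tree) else tree
  states <- toupper(states[info$tree$tip.label])
  names(states) <- info$tree$tip.label
  obs <- states[states %in% AA_ALPHABET]
  if (length(obs) == 0L) {
    return(structure(list(site = site, min_changes = NA_integer_,
                          mprs = list(), undefined = TRUE),
                     class = "site_reconstruction"))
  }
  cand <- sort(unique(unname(obs)))
  nint <- info$nnode
  if (length(cand) > MPR_ENUM_GUARD) {
    warning(sprintf("site %s: %d distinct states; sampling %d internal assignments",
                    site, length(cand), MPR_SAMPLE_SIZE))
    assign <- matrix(sample(cand, MPR_SAMPLE_SIZE * nint, replace = TRUE),
                     ncol = nint)
    assign <- unique(assign)
  } else {
    assign <- as.matrix(expand.grid(rep(list(cand), nint),
                                    stringsAsFactors = FALSE))
  }
  ntip <- info$ntip
  # node state lookup per assignment row: tips fixed, internals from `assign`
  leaf_state <- ifelse(states %in% AA_ALPHABET, states, NA_character_)
  edge <- info$edge
  costs <- integer(nrow(assign))
  node_state_of <- function(row, node) {
    if (node <= ntip) leaf_state[[node]] else row[[node - ntip]]
  }
  for (i in seq_len(nrow(assign))) {
    row <- assign[i, ]
    cost <- 0L
    for (e in seq_len(nrow(edge))) {
      p <- edge[e, 1L]; ch <- edge[e, 2L]
      sc <- node_state_of(row, ch)
      if (is.na(sc)) next
      if (node_state_of(row, p) != sc) cost <- cost + 1L
    }
    costs[i] <- cost
  }
  k <- min(costs)
  best <- assign[costs == k, , drop = FALSE]
  if (!is.null(root_state) && root_state %in% cand) {
    pinned <- best[best[, info$root - ntip] == root_state, , drop = FALSE]
    if (nrow(pinned)) best <- pinned
  }
  mprs <- lapply(seq_len(nrow(best)), function(i) {
    row <- best[i, ]
    ev <- list()
    for (e in seq_len(nrow(edge))) {
      p <- edge[e, 1L]; ch <- edge[e, 2L]
      sc <- node_state_of(row, ch)
      if (is.na(sc)) next
      sp <- node_state_of(row, p)
      if (sp != sc)
        ev[[length(ev) + 1L]] <- data.frame(branch = info$branch_id[e],
                                            from = sp, to = sc,
                                            stringsAsFactors = FALSE)
    }
    if (length(ev)) do.call(rbind, ev) else
      data.frame(branch = character(), from = character(), to = character(),
                 stringsAsFactors = FALSE)
  })
  # distinct event lists only (different internal assignments can induce the
  # same event list when unconstrained leaves are involved)
  keys <- vapply(mprs, function(d) paste(d$branch, d$from, d$to, collapse = ";"),
                 character(1))
  mprs <- mprs[!duplicated(keys)]
  structure(list(site = site, min_changes = k, mprs = mprs, undefined = FALSE),
            class = "site_reconstruction")
}

#' @export
print.site_reconstruction <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("<site_reconstruction> site %s: undefined (all states missing)\n", x$site))
  } else {
    cat(sprintf("<site_reconstruction> site %s: %d change(s), %d MPR(s)\n",
                x$site, x$min_changes, length(x$mprs)))
  }
  invisible(x)
}

#' Map amino acid changes across all sites of a gene
#'
#' Runs Fitch parsimony on every kept column of the focal rows and
#' enumerates most-parsimonious reconstructions for the sites that changed.
#' Invariant sites get a single empty reconstruction.
#'
#' @inheritParams site_min_changes
#' @param enumerate_from Minimum change count from which MPRs are
#'   enumerated (default 1; use 2 to enumerate multihit sites only, which
#'   is all that parallel/convergent classification needs).
#' @return List of [enumerate_mprs()] `site_reconstruction` objects, one per
#'   column (0-based `site` indices).
#' @export
map_gene_changes <- function(aln, tree, enumerate_from = 1L) {
  info <- if (inherits(tree, "phylo")) tree_info(tree) else tree
  counts <- site_min_changes(aln, info)
  m <- alignment_matrix(aln)[aln$focal, , drop = FALSE]
  lapply(seq_along(counts), function(j) {
    k <- counts[j]
    if (is.na(k)) {
      structure(list(site = j - 1L, min_changes = NA_integer_, mprs = list(),
                     undefined = TRUE), class = "site_reconstruction")
    } else if (k < enumerate_from) {
      structure(list(site = j - 1L, min_changes = k,
                     mprs = if (k == 0L) list(data.frame(
                       branch = character(), from = character(),
                       to = character(), stringsAsFactors = FALSE)) else list(),
                     undefined = FALSE), class = "site_reconstruction")
    } else {
      enumerate_mprs(setNames(m[, j], rownames(m)), info, site = j - 1L)
    }
  })
}
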