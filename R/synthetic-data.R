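#' Configuration for the synthetic strand-labeled dataset generator
#'
#' The generator emulates the study design downstream stages expect: a set
#' of genes split between the leading and lagging strands, per-gene protein
#' alignments of a handful of closely related focal strains evolved on a
#' known rooted tree, a strand-dependent substitution-rate multiplier
#' (lagging genes evolve faster, mimicking their elevated nonsynonymous
#' rate), a configurable fraction of sites free to vary, and star-like
#' outgroup rows that add variability but never contribute focal-strain
#' changes.
#'
#' @param n_leading,n_lagging Gene counts per strand (`>= 0`).
#' @param gene_length Amino acids per gene (default 250, comfortably above
#'   the >200 core-gene filter).
#' @param tree Rooted binary focal-strain `phylo` with branch lengths in
#'   expected substitutions per site; default [default_strain_tree()]
#'   (5-leaf ladder, branch length 0.01).
#' @param rate_multiplier_lagging Branch-length multiplier for lagging
#'   genes (`>= 0`, default 2).
#' @param variable_fraction Fraction of sites eligible to vary, in `[0,1]`
#'   (default 0.5).
#' @param n_outgroups Number of outgroup rows (default 10).
#' @param outgroup_divergence Expected substitutions per site on each
#'   outgroup stem (default 0.3, the divergence of congeneric outgroup
#'   species sitting near the 70% identity retention threshold).
#' @param outgroup_gap_prob Per-site probability of a gap in each outgroup
#'   row (default 0: no gaps simulated).
#' @param seed RNG seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_leading = 200L, n_lagging = 30L,
                              gene_length = 250L,
                              tree = default_strain_tree(),
                              rate_multiplier_lagging = 2,
                              variable_fraction = 0.5,
                              n_outgroups = 10L,
                              outgroup_divergence = 0.3,
                              outgroup_gap_prob = 0,
                              seed = 1L) {
  stopifnot(n_leading >= 0, n_lagging >= 0, gene_length > 0,
            n_outgroups >= 0)
  validate_phylogeny(tree)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  if (!is.finite(rate_multiplier_lagging) || rate_multiplier_lagging < 0)
    stop("rate_multiplier_lagging must be finite and >= 0")
  if (!is.finite(variable_fraction) || variable_fraction < 0 || variable_fraction > 1)
    stop("variable_fraction must lie in [0, 1]")
  if (!is.finite(outgroup_divergence) || outgroup_divergence < 0)
    stop("outgroup_divergence must be finite and >= 0")
  if (outgroup_gap_prob < 0 || outgroup_gap_prob > 1)
    stop("outgroup_gap_prob must lie in [0, 1]")
  structure(list(n_leading = as.integer(n_leading),
                 n_lagging = as.integer(n_lagging),
                 gene_length = as.integer(gene_length), tree = tree,
                 rate_multiplier_lagging = rate_multiplier_lagging,
                 variable_fraction = variable_fraction,
                 n_outgroups = as.integer(n_outgroups),
                 outgroup_divergence = outgroup_divergence,
                 outgroup_gap_prob = outgroup_gap_prob,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Evolve an integer-coded sequence along one branch. Each eligible site
# receives a Poisson(b * m) number of substitution events (b = branch length
# in expected substitutions per site, m = strand rate multiplier); each
# event replaces the current residue with a uniformly chosen different one.
# Allowing multiple events per site per branch keeps event placement,
# conditional on the total count, exactly uniform-multinomial over eligible
# sites — the exchangeable world the conditional resampling null assumes.
# Returns the child sequence plus every event in order (site, from, to).
evolve_branch <- function(seq, eligible, b, m) {
  lam <- b * m
  child <- seq
  if (lam <= 0 || !length(eligible))
    return(list(seq = child, sites = integer(0),
                from = integer(0), to = integer(0)))
  k <- stats::rpois(length(eligible), lam)
  idx <- which(k > 0L)
  n_ev <- sum(k)
  sites <- integer(n_ev); from <- integer(n_ev); to <- integer(n_ev)
  pos <- 0L
  for (j in idx) {
    site <- eligible[j]
    cur <- child[site]
    for (e in seq_len(k[j])) {
      new <- 1L + (cur - 1L + sample.int(19L, 1L)) %% 20L  # uniform over the 19 others
      pos <- pos + 1L
      sites[pos] <- site; from[pos] <- cur; to[pos] <- new
      cur <- new
    }
    child[site] <- cur
  }
  list(seq = child, sites = sites, from = from, to = to)
}

#' Generate a synthetic strand-labeled dataset with known ground truth
#'
#' Every gene draws a uniform random root sequence, evolves it down the
#' focal tree (lagging genes with their branch lengths scaled by the rate
#' multiplier) and evolves each outgroup row independently from the root
#' (star-like, so outgroups never create focal-strain changes). All true
#' focal substitution events are recorded. The same config (including its
#' seed) reproduces the dataset exactly.
#'
#' @param config A [simulation_config()].
#' @return Object of class `strand_dataset`: list with `alignments` (list
#'   of [gene_alignment]), `strand_table` (data.frame `gene_id`, `strand`),
#'   `tree`, `truth` (data.frame `gene_id`, `site` 0-based, `branch`,
#'   `from`, `to`), `eligible` (per-gene 0-based indices of sites free to
#'   vary), `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  info <- tree_info(cfg$tree)
  # cladewise (preorder) edge ordering guarantees parents are evolved first
  tree <- reorder(cfg$tree, "cladewise")
  edge <- tree$edge
  bid <- branch_ids(tree)
  n_gene <- cfg$n_leading + cfg$n_lagging
  strands <- c(rep("leading", cfg$n_leading), rep("lagging", cfg$n_lagging))
  ids <- sprintf("gene%04d", seq_len(max(n_gene, 0L)))
  og_labels <- if (cfg$n_outgroups > 0L) sprintf("og%02d", seq_len(cfg$n_outgroups))
               else character(0)
  L <- cfg$gene_length
  n_eligible <- round(cfg$variable_fraction * L)
  alignments <- vector("list", n_gene)
  truth <- list()
  eligible_list <- vector("list", n_gene)
  local_seed(cfg$seed, {
    for (gi in seq_len(n_gene)) {
      m <- if (strands[gi] == "lagging") cfg$rate_multiplier_lagging else 1
      eligible <- if (n_eligible > 0L) sort(sample.int(L, n_eligible)) else integer(0)
      root_seq <- sample.int(20L, L, replace = TRUE)
      node_seq <- vector("list", info$ntip + info$nnode)
      node_seq[[info$root]] <- root_seq
      ev_rows <- list()
      for (e in seq_len(nrow(edge))) {
        par <- edge[e, 1L]; ch <- edge[e, 2L]
        res <- evolve_branch(node_seq[[par]], eligible, tree$edge.length[e], m)
        node_seq[[ch]] <- res$seq
        if (length(res$sites)) {
          ev_rows[[length(ev_rows) + 1L]] <- data.frame(
            gene_id = ids[gi], site = res$sites - 1L, branch = bid[e],
            from = AA_ALPHABET[res$from], to = AA_ALPHABET[res$to],
            stringsAsFactors = FALSE)
        }
      }
      rows <- vapply(seq_len(info$ntip), function(t)
        paste(AA_ALPHABET[node_seq[[t]]], collapse = ""), character(1))
      names(rows) <- cfg$tree$tip.label
      for (og in og_labels) {
        res <- evolve_branch(root_seq, eligible, cfg$outgroup_divergence, 1)
        og_chars <- AA_ALPHABET[res$seq]
        if (cfg$outgroup_gap_prob > 0) {
          gap <- stats::runif(L) < cfg$outgroup_gap_prob
          og_chars[gap] <- "-"
        }
        rows[[og]] <- paste(og_chars, collapse = "")
      }
      alignments[[gi]] <- gene_alignment(ids[gi], rows,
                                         focal = cfg$tree$tip.label,
                                         strand = strands[gi])
      eligible_list[[gi]] <- eligible - 1L
      if (length(ev_rows)) truth[[length(truth) + 1L]] <- do.call(rbind, ev_rows)
    }
  })
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), site = integer(), branch = character(),
               from = character(), to = character(), stringsAsFactors = FALSE)
  rownames(truth_df) <- NULL
  names(alignments) <- ids
  names(eligible_list) <- ids
  structure(list(
    alignments = alignments,
    strand_table = data.frame(gene_id = ids, strand = strands,
                              stringsAsFactors = FALSE),
    tree = cfg$tree, truth = truth_df, eligible = eligible_list,
    config = cfg), class = "strand_dataset")
}

#' @export
print.strand_dataset <- function(x, ...) {
  cat(sprintf("<strand_dataset> %d genes (%d leading, %d lagging), %d outgroup rows, %d true events\n",
              length(x$alignments), sum(x$strand_table$strand == "leading"),
              sum(x$strand_table$strand == "lagging"),
              x$config$n_outgroups, nrow(x$truth)))
  invisible(x)
}

#' Ground-truth per-gene change summary
#'
#' Computes, from the recorded true events and the alignments, the oracle
#' version of the per-gene summary used downstream: `V` (sites showing any
#' variant across all rows, observed-mode rule), `C` (true focal change
#' events), and the count of sites with two or more true focal events.
#'
#' @param dataset A [generate_dataset()] result.
#' @return Data.frame: `gene_id`, `strand`, `V`, `C`, `multihit_sites`.
#' @export
truth_summary <- function(dataset) {
  stopifnot(inherits(dataset, "strand_dataset"))
  rows <- lapply(seq_along(dataset$alignments), function(i) {
    aln <- dataset$alignments[[i]]
    ev <- dataset$truth[dataset$truth$gene_id == aln$gene_id, , drop = FALSE]
    site_hits <- table(ev$site)
    data.frame(gene_id = aln$gene_id, strand = aln$strand,
               V = sum(variable_sites(aln, "observed")),
               C = nrow(ev),
               multihit_sites = sum(site_hits >= 2L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a synthetic dataset as plain-text files
#'
#' Writes one FASTA per gene under `dir/alignments/`, the strand table as
#' TSV, the tree as newick and the truth table as JSON.
#'
#' @param dataset A `strand_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  aln_dir <- file.path(dir, "alignments")
  dir.create(aln_dir, recursive = TRUE, showWarnings = FALSE)
  for (aln in dataset$alignments)
    write_fasta_alignment(aln, file.path(aln_dir, paste0(aln$gene_id, ".fasta")))
  write_strand_table(dataset$strand_table, file.path(dir, "strand_table.tsv"))
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       dataframe = "rows")
  invisible(dir)
}

#' @rdname write_dataset
#' @param focal_labels Focal strain labels (default: the tree's tip labels).
#' @return `read_dataset()` returns a list with `alignments`,
#'   `strand_table`, `tree` (no truth: real datasets have none).
#' @export
read_dataset <- function(dir, focal_labels = NULL) {
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  if (is.null(focal_labels)) focal_labels <- tree$tip.label
  st <- read_strand_table(file.path(dir, "strand_table.tsv"))
  strand_of <- setNames(st$strand, st$gene_id)
  files <- list.files(file.path(dir, "alignments"), pattern = "\\.fasta$",
                      full.names = TRUE)
  alignments <- lapply(files, function(f) {
    id <- sub("\\.fasta$", "", basename(f))
    read_fasta_alignment(f, focal_labels, gene_id = id,
                         strand = if (!is.na(strand_of[id])) strand_of[[id]] else "unknown")
  })
  names(alignments) <- vapply(alignments, `[[`, character(1), "gene_id")
  list(alignments = alignments, strand_table = st, tree = tree)
}
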