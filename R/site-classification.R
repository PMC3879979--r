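#' Which alignment sites are variable?
#'
#' A site is *variable* in `observed` mode when more than one distinct
#' non-missing residue is seen across all rows (focal strains and
#' outgroups), or when any outgroup row carries a gap at the column. In
#' `all` mode every site is declared variable. In `interpolated` mode the
#' observed variable sites are augmented with a seeded random draw of
#' invariant sites until `ceiling(f * L)` sites are variable, sweeping the
#' space between the two definitions.
#'
#' @param aln A [gene_alignment] (gap columns in focal rows already removed).
#' @param mode `"observed"`, `"all"` or `"interpolated"`.
#' @param f Target variable fraction for `interpolated` mode; must lie in
#'   `[V/L, 1]` where `V` is the observed variable count.
#' @param seed Seed for the interpolated draw (local RNG; the global RNG
#'   state is untouched).
#' @return Logical vector, one flag per column.
#' @export
variable_sites <- function(aln, mode = c("observed", "all", "interpolated"),
                           f = NULL, seed = 1L) {
  mode <- match.arg(mode)
  L <- alignment_length(aln)
  if (mode == "all") return(rep(TRUE, L))
  m <- alignment_matrix(aln)
  og <- outgroup_labels(aln)
  obs <- vapply(seq_len(L), function(j) {
    col <- m[, j]
    res <- col[col %in% AA_ALPHABET]
    length(unique(res)) > 1L ||
      (length(og) > 0L && any(m[og, j] == "-"))
  }, logical(1))
  if (mode == "observed") return(obs)
  if (is.null(f)) stop("'f' is required in interpolated mode")
  V <- sum(obs)
  if (L == 0L) return(obs)
  if (f < V / L || f > 1)
    stop(sprintf("f = %.3f outside attainable range [%.3f, 1]", f, V / L))
  target <- ceiling(f * L)
  extra <- target - V
  if (extra > 0L) {
    pool <- which(!obs)
    add <- local_seed(seed, sample(pool, extra))
    obs[add] <- TRUE
  }
  obs
}

# Run `expr` under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Classify a site as parallel and/or convergent
#'
#' Within each most-parsimonious reconstruction, every pair of change events
#' on *independent* branches (neither branch root-ward of the other) with the
#' same derived residue is inspected: the pair is *parallel* when the
#' ancestral residues also agree and *convergent* when they differ. Under the
#' default `all_mprs` policy a flag is raised only if every MPR exhibits the
#' pattern (a conservative call: the pattern must be unambiguous); under
#' `any_mpr` one supporting MPR suffices.
#'
#' @param recon A `site_reconstruction` from [enumerate_mprs()] or
#'   [map_gene_changes()].
#' @param tree The tree used for the reconstruction.
#' @param policy `"all_mprs"` (default) or `"any_mpr"`.
#' @return A one-row data.frame: `site`, `variable` (NA here; filled by
#'   [summarize_genes()]), `n_changes`, `label`
#'   (`invariant`/`single_hit`/`multihit`), `parallel`, `convergent`.
#' @export
classify_site <- function(recon, tree, policy = c("all_mprs", "any_mpr")) {
  policy <- match.arg(policy)
  info <- if (inherits(tree, "phylo")) tree_info(tree) else tree
  k <- recon$min_changes
  if (recon$undefined || is.na(k)) {
    return(data.frame(site = recon$site, variable = NA, n_changes = NA_integer_,
                      label = NA_character_, parallel = FALSE, convergent = FALSE,
                      stringsAsFactors = FALSE))
  }
  label <- if (k == 0L) "invariant" else if (k == 1L) "single_hit" else "multihit"
  par_flag <- conv_flag <- FALSE
  if (k >= 2L && length(recon$mprs)) {
    child_of <- setNames(info$edge[, 2L], info$branch_id)
    per_mpr <- vapply(recon$mprs, function(ev) {
      p <- FALSE; cv <- FALSE
      n <- nrow(ev)
      if (n >= 2L) {
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
          if (ev$to[i] != ev$to[j]) next
          if (!edges_independent(info, child_of[[ev$branch[i]]],
                                 child_of[[ev$branch[j]]])) next
          if (ev$from[i] == ev$from[j]) p <- TRUE else cv <- TRUE
        }
      }
      c(p, cv)
    }, logical(2))
    if (policy == "all_mprs") {
      par_flag <- all(per_mpr[1L, ])
      conv_flag <- all(per_mpr[2L, ])
    } else {
      par_flag <- any(per_mpr[1L, ])
      conv_flag <- any(per_mpr[2L, ])
    }
  }
  data.frame(site = recon$site, variable = NA, n_changes = k, label = label,
             parallel = par_flag, convergent = conv_flag,
             stringsAsFactors = FALSE)
}

#' Per-gene change summary
#'
#' Combines variability, Fitch change counts and parallel/convergent
#' classification for one gene.
#'
#' @param aln A [gene_alignment] with focal rows free of gaps (apply
#'   [remove_gap_columns()] first).
#' @param tree Rooted binary `phylo` over the focal labels (or a
#'   precomputed internal tree info object).
#' @param variable_mode,f,seed Passed to [variable_sites()].
#' @param policy Passed to [classify_site()].
#' @param count_mode `"parsimony"` counts Fitch minimum changes;
#'   `"distinct"` counts distinct non-missing focal residues minus one (a
#'   naive convention some site lists use). Classification of
#'   parallel/convergent always uses parsimony reconstructions.
#' @return One-row data.frame with `gene_id`, `strand`, `L`, `V`, `C`,
#'   `multihit_sites`, `has_multihit`, `has_parallel`, `has_convergent`;
#'   the per-site table is attached as attribute `"sites"`.
#' @export
gene_change_summary <- function(aln, tree,
                                variable_mode = c("observed", "all", "interpolated"),
                                f = NULL, seed = 1L,
                                policy = c("all_mprs", "any_mpr"),
                                count_mode = c("parsimony", "distinct")) {
  variable_mode <- match.arg(variable_mode)
  policy <- match.arg(policy)
  count_mode <- match.arg(count_mode)
  info <- if (inherits(tree, "phylo")) tree_info(tree) else tree
  L <- alignment_length(aln)
  varflag <- variable_sites(aln, variable_mode, f = f, seed = seed)
  counts <- site_min_changes(aln, info)
  if (count_mode == "distinct") {
    m <- alignment_matrix(aln)[aln$focal, , drop = FALSE]
    counts <- vapply(seq_len(L), function(j) {
      res <- m[, j][m[, j] %in% AA_ALPHABET]
      if (!length(res)) NA_integer_ else length(unique(res)) - 1L
    }, integer(1))
  }
  multihit_idx <- which(!is.na(counts) & counts >= 2L)
  par_flag <- conv_flag <- logical(length(multihit_idx))
  if (length(multihit_idx)) {
    m <- alignment_matrix(aln)[aln$focal, , drop = FALSE]
    for (i in seq_along(multihit_idx)) {
      j <- multihit_idx[i]
      recon <- enumerate_mprs(setNames(m[, j], rownames(m)), info, site = j - 1L)
      cls <- classify_site(recon, info, policy = policy)
      par_flag[i] <- cls$parallel
      conv_flag[i] <- cls$convergent
    }
  }
  sites <- data.frame(
    site = seq_len(L) - 1L, variable = varflag, n_changes = counts,
    label = ifelse(is.na(counts), NA_character_,
                   ifelse(counts == 0L, "invariant",
                          ifelse(counts == 1L, "single_hit", "multihit"))),
    parallel = FALSE, convergent = FALSE, stringsAsFactors = FALSE)
  sites$parallel[multihit_idx] <- par_flag
  sites$convergent[multihit_idx] <- conv_flag
  out <- data.frame(
    gene_id = aln$gene_id, strand = aln$strand, L = L,
    V = sum(varflag), C = sum(counts, na.rm = TRUE),
    multihit_sites = length(multihit_idx),
    has_multihit = length(multihit_idx) > 0L,
    has_parallel = any(par_flag), has_convergent = any(conv_flag),
    stringsAsFactors = FALSE)
  attr(out, "sites") <- sites
  out
}

#' Summarize all genes and build the strand-by-parallel table
#'
#' @param alignments List of [gene_alignment] objects (focal rows gap-free).
#' @param tree Rooted binary `phylo` over the focal labels.
#' @param strand_table Optional data.frame (`gene_id`, `strand`) overriding
#'   the per-alignment strand labels. Every gene must resolve to
#'   `leading` or `lagging`.
#' @inheritParams gene_change_summary
#' @return Data.frame with one [gene_change_summary()] row per gene;
#'   attribute `"parallel_table"` holds the 2x2 strand-by-parallel count
#'   matrix (rows leading/lagging, columns parallel/no_parallel).
#' @export
summarize_genes <- function(alignments, tree, strand_table = NULL,
                            variable_mode = c("observed", "all", "interpolated"),
                            f = NULL, seed = 1L,
                            policy = c("all_mprs", "any_mpr"),
                            count_mode = c("parsimony", "distinct")) {
  variable_mode <- match.arg(variable_mode)
  policy <- match.arg(policy)
  count_mode <- match.arg(count_mode)
  info <- if (inherits(tree, "phylo")) tree_info(tree) else tree
  strand_of <- NULL
  if (!is.null(strand_table))
    strand_of <- setNames(strand_table$strand, strand_table$gene_id)
  rows <- lapply(alignments, function(aln) {
    if (!is.null(strand_of)) {
      if (is.na(strand_of[aln$gene_id]))
        stop(sprintf("gene '%s' missing from strand table", aln$gene_id))
      aln$strand <- strand_of[[aln$gene_id]]
    }
    if (!aln$strand %in% c("leading", "lagging"))
      stop(sprintf("gene '%s' has unknown strand label '%s'",
                   aln$gene_id, aln$strand))
    gene_change_summary(aln, info, variable_mode = variable_mode, f = f,
                        seed = seed, policy = policy, count_mode = count_mode)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "parallel_table") <- parallel_table(out)
  out
}

#' 2x2 strand-by-parallel contingency table
#'
#' @param summaries Data.frame from [summarize_genes()] (columns `strand`,
#'   `has_parallel`).
#' @return 2x2 integer matrix: rows `leading`/`lagging`, columns
#'   `parallel`/`no_parallel`.
#' @export
parallel_table <- function(summaries) {
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(c("leading", "lagging"),
                                c("parallel", "no_parallel")))
  for (st in c("leading", "lagging")) {
    sel <- summaries$strand == st
    tab[st, "parallel"] <- sum(sel & summaries$has_parallel)
    tab[st, "no_parallel"] <- sum(sel & !summaries$has_parallel)
  }
  tab
}
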