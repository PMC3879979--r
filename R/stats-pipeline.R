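#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the two-sided P-value by summing, over all tables with the
#' observed margins, the hypergeometric probabilities no larger than that
#' of the observed table (ties admitted within a relative tolerance of
#' 1e-7 — the convention standard statistical software uses). The
#' alternative doubled-one-tail convention
#' `min(1, 2 * min(P_lower, P_upper))` is also available.
#'
#' @param table 2x2 integer matrix (or vector `c(a, b, c, d)` read
#'   row-wise): rows are strands, columns are gene classes, e.g.
#'   `rbind(c(parallel_leading, rest_leading), c(parallel_lagging,
#'   rest_lagging))`.
#' @param convention `"minlike"` (default, sum of tables with smaller or
#'   equal probability) or `"doubled"` (twice the smaller tail).
#' @return Two-sided P-value. A zero margin yields `P = 1` (no information)
#'   with a message.
#' @examples
#' fisher_exact_two_tail(rbind(c(10, 293), c(3, 31)))  # 0.133
#' @export
fisher_exact_two_tail <- function(table, convention = c("minlike", "doubled")) {
  convention <- match.arg(convention)
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2L, byrow = TRUE)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0) || any(table != round(table)))
    stop("table entries must be non-negative integers")
  a <- table[1L, 1L]
  m <- sum(table[1L, ])   # row 1 margin
  n <- sum(table[2L, ])   # row 2 margin
  k <- sum(table[, 1L])   # column 1 margin
  if (m == 0 || n == 0 || k == 0 || sum(table[, 2L]) == 0) {
    message("degenerate 2x2 table (zero margin): P = 1 by convention")
    return(1)
  }
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  if (convention == "minlike") {
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else {
    lower <- sum(probs[support <= a])
    upper <- sum(probs[support >= a])
    p <- min(1, 2 * min(lower, upper))
  }
  min(1, p)
}

#' Run the full strand-balance analysis pipeline
#'
#' Orchestrates: data acquisition (synthetic generation or reading files) ->
#' ortholog filtering -> focal gap-column removal -> parsimony change
#' inference and site classification -> conditional resampling null (one
#' [null_distribution()] per requested variable-site mode) -> Fisher's
#' exact test on the strand-by-parallel table -> a deterministic report.
#'
#' @param config List with components:
#'   * `simulate`: a [simulation_config()] (synthetic mode), **or**
#'     `data`: list with `dir` (as written by [write_dataset()]) or the
#'     explicit paths `alignment_dir`, `strand_tsv`, `tree_newick`;
#'   * `filter`: optional list with `min_length` (default 200),
#'     `min_identity`, `min_coverage` (default 0.7); set to `FALSE` to skip;
#'   * `resample`: optional list with `n_replicates` (default 10000),
#'     `seed` (default 1), `modes` (subset of `"observed"`, `"all"`,
#'     default both) and `interp_f` (optional numeric vector of interpolated
#'     variable fractions);
#'   * `classify`: optional list with `policy` and `count_mode` (see
#'     [summarize_genes()]).
#' @return Object of class `pipeline_report`: list with `summaries`,
#'   `parallel_table`, `fisher_p`, `fisher_p_doubled`, `nulls` (named list
#'   of `multihit_null`), `filter_log`, `n_genes_in`, `n_genes_kept`,
#'   `config`.
#' @export
run_pipeline <- function(config) {
  if (!is.null(config$simulate)) {
    dataset <- generate_dataset(config$simulate)
    alignments <- dataset$alignments
    strand_table <- dataset$strand_table
    tree <- dataset$tree
  } else if (!is.null(config$data)) {
    d <- config$data
    if (!is.null(d$dir)) {
      ds <- read_dataset(d$dir)
    } else {
      tree <- ape::read.tree(d$tree_newick)
      st <- read_strand_table(d$strand_tsv)
      strand_of <- setNames(st$strand, st$gene_id)
      files <- list.files(d$alignment_dir, pattern = "\\.fa(sta)?$",
                          full.names = TRUE)
      alns <- lapply(files, function(f) {
        id <- sub("\\.fa(sta)?$", "", basename(f))
        read_fasta_alignment(f, tree$tip.label, gene_id = id,
                             strand = if (!is.na(strand_of[id])) strand_of[[id]] else "unknown")
      })
      names(alns) <- vapply(alns, `[[`, character(1), "gene_id")
      ds <- list(alignments = alns, strand_table = st, tree = tree)
    }
    alignments <- ds$alignments
    strand_table <- ds$strand_table
    tree <- ds$tree
  } else {
    stop("config must name either 'simulate' or 'data'")
  }
  n_in <- length(alignments)

  filter_log <- NULL
  if (!isFALSE(config$filter)) {
    f <- if (is.list(config$filter)) config$filter else list()
    fr <- ortholog_filter(alignments,
                          min_length = f$min_length %||% 200,
                          min_identity = f$min_identity %||% 0.7,
                          min_coverage = f$min_coverage %||% 0.7)
    alignments <- fr$kept
    filter_log <- fr$rejected
  }
  if (length(alignments) == 0L) stop("stage 'filter': no genes left")

  alignments <- lapply(alignments, remove_gap_columns)

  cl <- if (is.list(config$classify)) config$classify else list()
  rs <- if (is.list(config$resample)) config$resample else list()
  n_rep <- rs$n_replicates %||% 10000L
  seed <- rs$seed %||% 1L
  modes <- rs$modes %||% c("observed", "all")

  info <- tree_info(tree)
  nulls <- list()
  summaries <- NULL
  for (mode in modes) {
    smry <- summarize_genes(alignments, info, strand_table = strand_table,
                            variable_mode = mode, seed = seed,
                            policy = cl$policy %||% "all_mprs",
                            count_mode = cl$count_mode %||% "parsimony")
    if (mode == "observed" || is.null(summaries)) summaries <- smry
    nulls[[mode]] <- null_distribution(smry, n_replicates = n_rep, seed = seed,
                                       variable_mode = mode)
  }
  for (f_i in rs$interp_f %||% numeric(0)) {
    smry <- summarize_genes(alignments, info, strand_table = strand_table,
                            variable_mode = "interpolated", f = f_i, seed = seed,
                            policy = cl$policy %||% "all_mprs",
                            count_mode = cl$count_mode %||% "parsimony")
    nulls[[sprintf("interp_%.2f", f_i)]] <-
      null_distribution(smry, n_replicates = n_rep, seed = seed,
                        variable_mode = sprintf("interpolated(%.2f)", f_i))
  }

  tab <- attr(summaries, "parallel_table")
  structure(list(
    summaries = summaries, parallel_table = tab,
    fisher_p = fisher_exact_two_tail(tab),
    fisher_p_doubled = fisher_exact_two_tail(tab, convention = "doubled"),
    nulls = nulls, filter_log = filter_log,
    n_genes_in = n_in, n_genes_kept = length(alignments),
    config = config), class = "pipeline_report")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d/%d genes kept\n", x$n_genes_kept, x$n_genes_in))
  tab <- x$parallel_table
  cat(sprintf("  parallel-change genes: leading %d/%d, lagging %d/%d; Fisher two-sided P = %.2g\n",
              tab["leading", "parallel"], sum(tab["leading", ]),
              tab["lagging", "parallel"], sum(tab["lagging", ]),
              signif(x$fisher_p, 2)))
  for (nm in names(x$nulls)) {
    nl <- x$nulls[[nm]]
    cat(sprintf("  [%s] R_N obs %.3g (P = %.2g), R_G obs %.3g (P = %.2g)\n",
                nm, nl$r_n_obs, signif(nl$p_n, 2), nl$r_g_obs, signif(nl$p_g, 2)))
  }
  invisible(x)
}

#' Write a pipeline report to a run directory
#'
#' Emits `report.json` (tables, P-values, settings), `summaries.tsv`,
#' `null_rn_<mode>.tsv` / `null_rg_<mode>.tsv` with the raw replicate
#' values, and one null-histogram figure per mode (PDF).
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @param figures Whether to write histogram PDFs (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, figures = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$summaries, file.path(dir, "summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nulls_json <- lapply(report$nulls, function(nl)
    list(r_n_obs = nl$r_n_obs, r_g_obs = nl$r_g_obs, p_n = nl$p_n,
         p_g = nl$p_g, in_band_n = nl$in_band_n, in_band_g = nl$in_band_g,
         n_replicates = nl$n_replicates, seed = nl$seed))
  jsonlite::write_json(list(
    n_genes_in = report$n_genes_in, n_genes_kept = report$n_genes_kept,
    parallel_table = report$parallel_table,
    fisher_p = report$fisher_p, fisher_p_doubled = report$fisher_p_doubled,
    nulls = nulls_json,
    package_version = as.character(utils::packageVersion("strandbalance"))),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(report$nulls)) {
    nl <- report$nulls[[nm]]
    utils::write.table(data.frame(r_n = nl$r_n_null),
                       file.path(dir, sprintf("null_rn_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(r_g = nl$r_g_null),
                       file.path(dir, sprintf("null_rg_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (figures) {
      grDevices::pdf(file.path(dir, sprintf("null_%s.pdf", nm)), width = 8, height = 4)
      plot(nl)
      grDevices::dev.off()
    }
  }
  invisible(dir)
}
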