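#' One conditional resampling replicate for a gene
#'
#' Draws `C` sites uniformly with replacement from the gene's `V` variable
#' sites — the conditional null in which the observed number of amino acid
#' changes is kept but their placement is random — and reports how many
#' sites were drawn at least twice.
#'
#' Uses the current RNG state; seed management belongs to the caller (see
#' [null_distribution()] for the reproducible aggregate).
#'
#' @param V Number of variable sites (`>= 1` when `C >= 1`).
#' @param C Number of changes to place (`>= 0`).
#' @return List with `multihit_drawn` (count of sites drawn `>= 2` times)
#'   and `any_multihit` (flag).
#' @examples
#' set.seed(1); draw_gene_replicate(V = 3, C = 3)
#' @export
draw_gene_replicate <- function(V, C) {
  stopifnot(length(V) == 1L, length(C) == 1L, C >= 0)
  if (C == 0) return(list(multihit_drawn = 0L, any_multihit = FALSE))
  if (V < 1) stop("a gene with changes (C >= 1) must have V >= 1 variable sites")
  hits <- tabulate(sample.int(V, C, replace = TRUE), nbins = V)
  mh <- sum(hits >= 2L)
  list(multihit_drawn = mh, any_multihit = mh >= 1L)
}

#' Expected number of multiply-drawn sites
#'
#' Closed-form mean of `multihit_drawn` under `C` uniform draws with
#' replacement from `V` sites:
#' `V * (1 - (1-1/V)^C - (C/V) * (1-1/V)^(C-1))`.
#'
#' @inheritParams draw_gene_replicate
#' @return Expected multihit-site count (0 when `C < 2` or `V = 0`).
#' @export
expected_multihit <- function(V, C) {
  ifelse(C < 2 | V < 1, 0,
         V * (1 - (1 - 1 / V)^C - (C / V) * (1 - 1 / V)^(C - 1)))
}

# Deterministic per-gene stream seed: a simple string hash of the gene id
# folded into the master seed, so replicate draws do not depend on gene
# order. Kept below 2^31.
gene_stream_seed <- function(seed, gene_id) {
  h <- 0
  for (k in utf8ToInt(gene_id)) h <- (h * 131 + k) %% 1073741789
  as.integer((seed %% 1048573) * 1021 + h) %% 2147483647L
}

# All replicates for one gene at once: nrep draws of C sites from V,
# returning the per-replicate multihit-site counts.
gene_replicates_vec <- function(V, C, nrep) {
  if (C == 0L) return(integer(nrep))
  draws <- sample.int(V, C * nrep, replace = TRUE)
  rep_idx <- rep(seq_len(nrep) - 1L, each = C)
  tab <- tabulate(draws + V * rep_idx, nbins = V * nrep)
  as.integer(colSums(matrix(tab >= 2L, nrow = V)))
}

#' Null distribution of the lagging:leading multihit ratios
#'
#' Implements the conditional resampling null: per replicate, every gene's
#' observed change count `C` is scattered uniformly with replacement over
#' its `V` variable sites; sites drawn more than once are the replicate's
#' "multihit" sites. Aggregating by strand gives
#' `R_N` = (total multiply-drawn sites, lagging) / (same, leading) and
#' `R_G` = (lagging genes with any multiply-drawn site) / (same, leading).
#' The observed counterparts use the genes' actual multihit-site counts.
#' Two-tail P-values come from [two_tail_p()].
#'
#' Zero denominators: a ratio with numerator > 0 is `+Inf` (sorting above
#' every finite replicate); `0/0` is defined as 1 (neutral), so all
#' replicates are retained without pseudocounts.
#'
#' Genes with `C >= 1` but `V = 0` (possible only through reversion-only
#' multihit sites or exotic variability definitions) are excluded with a
#' warning.
#'
#' @param summaries Data.frame with columns `gene_id`, `strand`
#'   (`leading`/`lagging`), `V`, `C`, `multihit_sites`, `has_multihit`
#'   (as from [summarize_genes()]).
#' @param n_replicates Number of replicates (default 10000).
#' @param seed Master seed; per-gene streams are derived from it so results
#'   do not depend on gene order.
#' @param variable_mode Free-text tag recorded in the result.
#' @return Object of class `multihit_null`: list with `r_n_null`,
#'   `r_g_null`, `r_n_obs`, `r_g_obs`, `p_n`, `p_g`, `in_band_n`,
#'   `in_band_g` (central-90% checks), `n_replicates`, `seed`,
#'   `variable_mode`, `excluded_genes`.
#' @export
null_distribution <- function(summaries, n_replicates = 10000L, seed = 1L,
                              variable_mode = "observed") {
  stopifnot(n_replicates >= 1L)
  need <- c("gene_id", "strand", "V", "C", "multihit_sites")
  miss <- setdiff(need, names(summaries))
  if (length(miss))
    stop(sprintf("summaries missing column(s): %s", paste(miss, collapse = ", ")))
  if (!all(summaries$strand %in% c("leading", "lagging")))
    stop("strand labels must be 'leading' or 'lagging'")
  bad <- summaries$C >= 1 & summaries$V < 1
  excluded <- summaries$gene_id[bad]
  if (any(bad)) {
    warning(sprintf("excluding %d gene(s) with C >= 1 but V = 0: %s",
                    sum(bad), paste(excluded, collapse = ", ")))
    summaries <- summaries[!bad, , drop = FALSE]
  }
  lag <- summaries$strand == "lagging"
  mh_n <- matrix(0L, nrow = n_replicates, ncol = 2L)  # cols: leading, lagging
  mh_g <- matrix(0L, nrow = n_replicates, ncol = 2L)
  for (i in seq_len(nrow(summaries))) {
    g <- summaries[i, ]
    if (g$C == 0) next
    col <- if (lag[i]) 2L else 1L
    counts <- local_seed(gene_stream_seed(seed, g$gene_id),
                         gene_replicates_vec(g$V, g$C, n_replicates))
    mh_n[, col] <- mh_n[, col] + counts
    mh_g[, col] <- mh_g[, col] + (counts >= 1L)
  }
  ratio <- function(num, den) ifelse(den > 0, num / den, ifelse(num > 0, Inf, 1))
  r_n_null <- ratio(mh_n[, 2L], mh_n[, 1L])
  r_g_null <- ratio(mh_g[, 2L], mh_g[, 1L])
  obs_n <- c(sum(summaries$multihit_sites[!lag]), sum(summaries$multihit_sites[lag]))
  obs_g <- c(sum(summaries$multihit_sites[!lag] > 0), sum(summaries$multihit_sites[lag] > 0))
  r_n_obs <- ratio(obs_n[2L], obs_n[1L])
  r_g_obs <- ratio(obs_g[2L], obs_g[1L])
  structure(list(
    r_n_null = r_n_null, r_g_null = r_g_null,
    r_n_obs = r_n_obs, r_g_obs = r_g_obs,
    p_n = two_tail_p(r_n_obs, r_n_null),
    p_g = two_tail_p(r_g_obs, r_g_null),
    in_band_n = central_band_check(r_n_obs, r_n_null),
    in_band_g = central_band_check(r_g_obs, r_g_null),
    n_replicates = n_replicates, seed = seed, variable_mode = variable_mode,
    excluded_genes = excluded), class = "multihit_null")
}

#' @export
print.multihit_null <- function(x, ...) {
  cat(sprintf("<multihit_null> %d replicates (seed %s, variable sites: %s)\n",
              x$n_replicates, x$seed, x$variable_mode))
  cat(sprintf("  R_N observed %.4g, null median %.4g, two-tail P = %.4g%s\n",
              x$r_n_obs, stats::median(x$r_n_null), x$p_n,
              if (x$in_band_n) " (inside central 90%)" else ""))
  cat(sprintf("  R_G observed %.4g, null median %.4g, two-tail P = %.4g%s\n",
              x$r_g_obs, stats::median(x$r_g_null), x$p_g,
              if (x$in_band_g) " (inside central 90%)" else ""))
  invisible(x)
}

#' Histogram of the resampling null with the observed ratio
#'
#' Draws the null distributions of `R_N` and `R_G` with an arrow marking
#' each observed value.
#'
#' @param x A `multihit_null`.
#' @param which `"both"`, `"R_N"` or `"R_G"`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.multihit_null <- function(x, which = c("both", "R_N", "R_G"), ...) {
  which <- match.arg(which)
  panels <- if (which == "both") c("R_N", "R_G") else which
  if (length(panels) == 2L) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  for (p in panels) {
    vals <- if (p == "R_N") x$r_n_null else x$r_g_null
    obs <- if (p == "R_N") x$r_n_obs else x$r_g_obs
    pp <- if (p == "R_N") x$p_n else x$p_g
    fin <- vals[is.finite(vals)]
    h <- graphics::hist(fin, breaks = 30,
                        main = sprintf("%s (P = %.2g)", p, pp),
                        xlab = sprintf("%s (lagging : leading)", p), ...)
    if (is.finite(obs)) {
      graphics::arrows(obs, max(h$counts) * 0.5, obs, 0, length = 0.1,
                       col = "red", lwd = 2)
    }
  }
  invisible(x)
}

#' Two-tail empirical P-value
#'
#' `p = min(1, 2 * min(#\{null >= obs\}, #\{null <= obs\}) / n)`, with ties
#' counted in both tails. When the smaller tail count is zero the add-one
#' convention `2 * 1 / (n + 1)` is reported instead of an exact zero.
#'
#' @param observed Observed statistic.
#' @param null_values Non-empty numeric vector of null replicates (`Inf`
#'   allowed).
#' @return P-value in `(0, 1]`.
#' @export
two_tail_p <- function(observed, null_values) {
  n <- length(null_values)
  stopifnot(n >= 1L)
  k <- min(sum(null_values >= observed), sum(null_values <= observed))
  if (k == 0L) return(2 / (n + 1))
  min(1, 2 * k / n)
}

#' Is the observed value inside the central band of the null?
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of null replicates.
#' @param level Central coverage (default 0.90).
#' @return `TRUE` iff `observed` lies within the
#'   `[(1-level)/2, 1-(1-level)/2]` empirical quantiles (inverse-ECDF
#'   quantiles, so infinite replicates are handled).
#' @export
central_band_check <- function(observed, null_values, level = 0.90) {
  stopifnot(level > 0, level < 1)
  a <- (1 - level) / 2
  qs <- stats::quantile(null_values, probs = c(a, 1 - a), type = 1, names = FALSE)
  observed >= qs[1L] && observed <= qs[2L]
}
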