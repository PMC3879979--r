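#' Equilibrium probability of lagging-strand encoding
#'
#' Under mutation-selection balance, inversion mutations move a gene from
#' the leading to the lagging strand at rate `u` per gene per generation and
#' back at rate `v`, while lagging encoding carries a selective disadvantage
#' `s`. The influx-outflux balance `(1-q)u = q(v+s)` gives the equilibrium
#' lagging-encoding probability `q = u/(u+v+s)`; when `u = v` this is
#' `1/(2 + s/u)`. `q` decreases as `s` grows, matching the depletion of
#' highly expressed and essential genes from the lagging strand.
#'
#' @param u Leading-to-lagging inversion mutation rate (`>= 0`).
#' @param v Lagging-to-leading rate (`>= 0`).
#' @param s Selective disadvantage of lagging encoding, `0 <= s < 1`
#'   (derived under weak selection, `s << 1`).
#' @return Equilibrium probability `u/(u+v+s)`.
#' @examples
#' equilibrium_q(1e-4, 1e-4, 2e-4)  # u = v, s/u = 2  ->  0.25
#' @export
equilibrium_q <- function(u, v, s) {
  check_balance_params(u, v, s)
  if (any(u + v + s == 0))
    stop("equilibrium undefined when u = v = s = 0")
  u / (u + v + s)
}

check_balance_params <- function(u, v, s, q0 = NULL) {
  vals <- c(u, v, s)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("u, v and s must be finite and non-negative")
  if (any(s >= 1)) stop("s must be < 1")
  if (!is.null(q0) && (any(!is.finite(q0)) || any(q0 < 0) || any(q0 > 1)))
    stop("q0 must lie in [0, 1]")
  invisible(TRUE)
}

# One generation of the deterministic dynamics: inversion mutation moves
# probability mass between strands, then purifying selection removes lagging
# lineages at rate s (a purged lineage reappears leading-encoded). The fixed
# point u(1-s) / (u(1-s) + v + s(1-v)) approaches u/(u+v+s) as the
# per-generation rates become small.
balance_step <- function(q, u, v, s) {
  (q * (1 - v) + (1 - q) * u) * (1 - s)
}

#' Iterate the deterministic strand-orientation dynamics
#'
#' Runs the discrete-generation mutation-then-selection map from `q0` until
#' the per-generation change falls below `tolerance` or `max_generations` is
#' reached. For small `u`, `v`, `s` the fixed point agrees with the analytic
#' equilibrium [equilibrium_q()] to first order.
#'
#' @inheritParams equilibrium_q
#' @param q0 Initial lagging-encoding probability.
#' @param max_generations Iteration cap (default 1e7).
#' @param tolerance Convergence threshold on `|q'' - q|` (default 1e-12).
#' @param record_every Store the trajectory every this many generations
#'   (default 1000; generation 0 and the final state are always stored).
#' @return Object of class `balance_trajectory`: list with `q_t` (recorded
#'   values), `generations` (their generation indices), `q_final`,
#'   `converged`, `generations_run`, `params`, `analytic` (the
#'   [equilibrium_q()] value, or `NA` if undefined).
#' @examples
#' tr <- iterate_deterministic(1e-4, 1e-4, 1e-4, q0 = 0.9)
#' abs(tr$q_final - 1/3) / (1/3)  # well under 1%
#' @export
iterate_deterministic <- function(u, v, s, q0 = 0.5,
                                  max_generations = 1e7, tolerance = 1e-12,
                                  record_every = 1000L) {
  check_balance_params(u, v, s, q0)
  stopifnot(max_generations >= 1, tolerance > 0)
  q <- q0
  rec_q <- q0
  rec_g <- 0
  converged <- FALSE
  gen <- 0
  while (gen < max_generations) {
    gen <- gen + 1
    q2 <- balance_step(q, u, v, s)
    if (gen %% record_every == 0) {
      rec_q <- c(rec_q, q2)
      rec_g <- c(rec_g, gen)
    }
    if (abs(q2 - q) < tolerance) {
      q <- q2
      converged <- TRUE
      break
    }
    q <- q2
  }
  if (rec_g[length(rec_g)] != gen) {
    rec_q <- c(rec_q, q)
    rec_g <- c(rec_g, gen)
  }
  analytic <- if (u + v + s > 0) u / (u + v + s) else NA_real_
  structure(list(q_t = rec_q, generations = rec_g, q_final = q,
                 converged = converged, generations_run = gen,
                 params = list(u = u, v = v, s = s, q0 = q0),
                 analytic = analytic, kind = "deterministic"),
            class = "balance_trajectory")
}

#' Wright-Fisher-style stochastic check of the balance
#'
#' Tracks `n_genes` independent two-state gene lineages. Each generation a
#' leading gene becomes lagging with probability `u` and a lagging gene
#' leading with probability `v` (binomial sampling); purifying selection
#' then purges each lagging lineage with probability `s`, the purged genes
#' reappearing leading-encoded. The per-gene stationary probability equals
#' the fixed point of [iterate_deterministic()], so the long-run
#' time-average of the lagging fraction matches the deterministic value.
#'
#' @inheritParams iterate_deterministic
#' @param n_genes Number of gene lineages (`>= 1`).
#' @param generations Number of generations to simulate.
#' @param seed RNG seed (local; the global RNG state is untouched).
#' @return A `balance_trajectory` with `q_t` = lagging fraction at every
#'   generation (length `generations + 1`, starting at `q0`).
#' @export
simulate_wright_fisher <- function(u, v, s, q0 = 0.5, n_genes = 10000L,
                                   generations = 1000L, seed = 1L) {
  check_balance_params(u, v, s, q0)
  stopifnot(n_genes >= 1, generations >= 0)
  q_t <- numeric(generations + 1L)
  local_seed(seed, {
    n_lag <- stats::rbinom(1L, n_genes, q0)
    q_t[1L] <- n_lag / n_genes
    for (g in seq_len(generations)) {
      gains <- stats::rbinom(1L, n_genes - n_lag, u)
      losses <- stats::rbinom(1L, n_lag, v)
      n_lag <- n_lag + gains - losses
      n_lag <- n_lag - stats::rbinom(1L, n_lag, s)
      q_t[g + 1L] <- n_lag / n_genes
    }
  })
  analytic <- if (u + v + s > 0) u / (u + v + s) else NA_real_
  structure(list(q_t = q_t, generations = 0:generations,
                 q_final = q_t[length(q_t)], converged = NA,
                 generations_run = generations,
                 params = list(u = u, v = v, s = s, q0 = q0,
                               n_genes = n_genes, seed = seed),
                 analytic = analytic, kind = "wright_fisher"),
            class = "balance_trajectory")
}

#' @export
print.balance_trajectory <- function(x, ...) {
  p <- x$params
  cat(sprintf("<balance_trajectory> %s: u=%g v=%g s=%g q0=%g\n",
              x$kind, p$u, p$v, p$s, p$q0))
  cat(sprintf("  final q = %.6g after %d generation(s)%s\n", x$q_final,
              x$generations_run,
              if (isTRUE(x$converged)) " (converged)"
              else if (isFALSE(x$converged)) " (not converged)" else ""))
  if (!is.na(x$analytic))
    cat(sprintf("  analytic equilibrium u/(u+v+s) = %.6g\n", x$analytic))
  invisible(x)
}

#' @export
plot.balance_trajectory <- function(x, ...) {
  graphics::plot(x$generations, x$q_t, type = "l", xlab = "generation",
                 ylab = "lagging-encoding probability q", ylim = c(0, 1), ...)
  if (!is.na(x$analytic))
    graphics::abline(h = x$analytic, lty = 2, col = "red")
  invisible(x)
}
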