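# Skyline reconstruction of Nef(t) from genealogies.
#
# Inference is conditional on a genealogy (the simulator's true tree or a
# UPGMA estimate), the defining conditional-likelihood computation of the
# Bayesian skyline: the (k lineages, interval duration) decomposition of an
# ultrametric tree is the sufficient statistic for a piecewise-constant
# Nef(t), and a Metropolis-Hastings sampler explores group sizes and
# per-group Nef.  Joint tree+parameter inference over tree space is out of
# scope.

#' Molecular clock configuration
#'
#' @param mu substitution rate per site per year (default 3.02e-7, a
#'   non-coding control-region rate).
#' @param generation_years years per generation (default 25).
#' @return object of class `"clock_config"`.
#' @export
clock_config <- function(mu = 3.02e-7, generation_years = 25) {
  stopifnot(mu > 0, generation_years > 0)
  structure(list(mu = mu, generation_years = generation_years),
            class = "clock_config")
}

#' Estimate an ultrametric genealogy by UPGMA on corrected distances
#'
#' Pairwise distances are corrected with the F84 model (the closed-form
#' distance for transition/transversion-biased substitution, the distance
#' analogue of HKY), then clustered by average linkage.  Node heights in
#' expected substitutions/site are converted to generations through
#' `mu * generation_years`.
#'
#' @param aln character alignment matrix (n >= 3).
#' @param clock a [clock_config()].
#' @return an ultrametric `phylo` with branch lengths in generations;
#'   attribute `"degenerate"` is `TRUE` when the alignment is invariant.
#' @export
estimate_genealogy <- function(aln, clock = clock_config()) {
  if (nrow(aln) < 3) stop("need at least 3 sequences", call. = FALSE)
  dna <- ape::as.DNAbin(tolower(aln))
  d <- ape::dist.dna(dna, model = "F84", pairwise.deletion = TRUE)
  dm <- as.matrix(d)
  if (any(!is.finite(dm))) {
    bad <- which(!is.finite(dm), arr.ind = TRUE)[1, ]
    stop(sprintf("saturated distance between %s and %s: correction undefined",
                 rownames(dm)[bad[1]], colnames(dm)[bad[2]]), call. = FALSE)
  }
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  tr <- ape::as.phylo(hc)  # heights halved: ultrametric tip-to-node distances
  tr$edge.length <- tr$edge.length / (clock$mu * clock$generation_years)
  attr(tr, "degenerate") <- max(dm) == 0
  tr
}

#' Coalescent-interval decomposition of an ultrametric genealogy
#'
#' Intervals between successive coalescent heights, oldest event last.  With
#' all tips at the present every interval ends in a coalescence; simultaneous
#' coalescences (as in balanced UPGMA trees) produce zero-length intervals.
#'
#' @param tree ultrametric `phylo` with branch lengths in generations.
#' @param tol relative tolerance for the ultrametricity check.
#' @return data frame of class `"coalescent_intervals"` with columns `k`
#'   (lineage count during the interval), `dt` (duration), `t0`, `t1`
#'   (interval bounds in generations before present) and `coalescent` flag;
#'   attributes `n` (tips) and `event_times`.
#' @export
coalescent_intervals <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (!ape::is.ultrametric(tree, tol = tol, option = 2) &&
      max(ape::node.depth.edgelength(tree)) > 0) {
    stop("tree is not ultrametric within tolerance", call. = FALSE)
  }
  heights <- sort(unname(ape::branching.times(tree)))
  stopifnot(length(heights) == n - 1)
  t0 <- c(0, heights[-(n - 1)])
  out <- data.frame(k = n:2, dt = heights - t0, t0 = t0, t1 = heights,
                    coalescent = TRUE)
  structure(out, class = c("coalescent_intervals", "data.frame"),
            n = n, event_times = heights)
}

#' Classic (deterministic) skyline estimate
#'
#' The Pybus-Rambaut construction: each inter-coalescent interval with `k`
#' lineages and duration `dt` yields `N = k (k - 1) dt / 2` in generations, a
#' method-of-moments inversion of the coalescent rate.  Zero-length intervals
#' give `N = 0` with a warning.
#'
#' @param intervals a [coalescent_intervals()] data frame.
#' @return the same data frame with an added `N` column.
#' @export
classic_skyline <- function(intervals) {
  N <- intervals$k * (intervals$k - 1) * intervals$dt / 2
  if (any(intervals$dt == 0)) {
    warning("zero-length coalescent interval(s): N estimated as 0")
  }
  intervals$N <- N
  intervals
}

# Normalise input to a list of interval data frames.
as_interval_sets <- function(intervals) {
  if (inherits(intervals, "coalescent_intervals")) return(list(intervals))
  stopifnot(is.list(intervals), length(intervals) >= 1)
  intervals
}

pooled_event_times <- function(sets) {
  sort(unlist(lapply(sets, attr, "event_times")))
}

#' Piecewise-constant coalescent log-likelihood
#'
#' Log-likelihood of per-group Nef values for one or more independent
#' genealogies, given epoch boundaries placed at pooled coalescent events:
#' each interval with `k` lineages spending time `dt` in an epoch of size `N`
#' contributes `-k (k - 1) dt / (2 N)`, and each coalescence contributes
#' `-log N` of its epoch.
#'
#' @param intervals a [coalescent_intervals()] object or a list of them.
#' @param group_sizes integer coalescent-event counts per group (summing to
#'   the pooled number of events).
#' @param sizes Nef per group (> 0).
#' @return log-likelihood (scalar).
#' @export
coalescent_loglik <- function(intervals, group_sizes, sizes) {
  sets <- as_interval_sets(intervals)
  ev <- pooled_event_times(sets)
  stopifnot(sum(group_sizes) == length(ev), all(group_sizes >= 1),
            length(sizes) == length(group_sizes), all(sizes > 0))
  bounds <- ev[cumsum(group_sizes)]
  m <- length(sizes)
  lo <- c(0, bounds[-m])
  hi <- bounds
  hi[m] <- Inf
  ll <- 0
  for (s in sets) {
    kk <- s$k * (s$k - 1) / 2
    for (j in seq_len(m)) {
      ov <- pmax(0, pmin(s$t1, hi[j]) - pmax(s$t0, lo[j]))
      ll <- ll - sum(kk * ov) / sizes[j]
    }
    epoch <- pmin(findInterval(s$t1[s$coalescent], bounds,
                               left.open = TRUE) + 1L, m)
    ll <- ll - sum(log(sizes[epoch]))
  }
  ll
}

skyline_log_prior <- function(sizes, bounds) {
  # scale-invariant (1/N, bounded to keep it proper) on the first group;
  # smoothing by Exponential(mean = previous group's Nef) on each subsequent
  # group, all restricted to the same bounds
  if (any(sizes < bounds[1] | sizes > bounds[2])) return(-Inf)
  lp <- -log(sizes[1])
  if (length(sizes) > 1) {
    for (j in 2:length(sizes)) {
      lp <- lp - log(sizes[j - 1]) - sizes[j] / sizes[j - 1]
    }
  }
  lp
}

#' Bayesian skyline MCMC on coalescent intervals
#'
#' Metropolis-Hastings sampling of a piecewise-constant Nef trajectory with
#' `m` groups of consecutive coalescent events.  Moves are multiplicative
#' scale proposals on a random group's Nef and single-event swaps between
#' adjacent groups (symmetric).  The prior is scale-invariant (1/N) on the
#' first group's Nef with each later group exponentially smoothed around its
#' predecessor.
#'
#' @inheritParams coalescent_loglik
#' @param m number of groups (1 <= m <= number of pooled events).
#' @param iterations total MCMC iterations (default 200000).
#' @param thin sampling interval (default 100).
#' @param burn_in fraction of iterations discarded (default 0.1).
#' @param seed optional integer seed.
#' @param prop_scale half-width of the log-scale proposal (> 0).
#' @param bounds lower and upper Nef bounds making the scale-invariant prior
#'   proper (default very wide; they act as numerical guards under a real
#'   likelihood).
#' @param flat_likelihood sample the prior only (for sampler validation).
#' @return object of class `"skyline_mcmc"`: thinned post-burn-in draws of
#'   `N` (draws x m), `group_sizes`, log-posterior `lp`, pooled
#'   `event_times`, acceptance rate and per-group ESS diagnostics.
#' @export
mcmc_skyline <- function(intervals, m = 5, iterations = 200000, thin = 100,
                         burn_in = 0.1, seed = NULL, prop_scale = 0.7,
                         bounds = c(1e-3, 1e9), flat_likelihood = FALSE) {
  if (prop_scale <= 0) stop("prop_scale must be positive", call. = FALSE)
  if (iterations < thin) stop("iterations must be >= thin", call. = FALSE)
  sets <- as_interval_sets(intervals)
  ev <- pooled_event_times(sets)
  ne <- length(ev)
  if (m > ne) stop("m must be <= number of coalescent events", call. = FALSE)
  m <- as.integer(m)

  # flattened interval arrays across genealogies: same math as
  # coalescent_loglik (asserted in the tests), one vector op per epoch
  f_t0 <- unlist(lapply(sets, `[[`, "t0"))
  f_t1 <- unlist(lapply(sets, `[[`, "t1"))
  f_kk <- unlist(lapply(sets, function(s) s$k * (s$k - 1) / 2))
  loglik <- function(gs, Ns) {
    if (flat_likelihood) return(0)
    b <- ev[cumsum(gs)]
    mm <- length(Ns)
    lo <- c(0, b[-mm])
    hi <- b
    hi[mm] <- Inf
    ll <- -sum(log(Ns[pmin(findInterval(ev, b, left.open = TRUE) + 1L, mm)]))
    for (j in seq_len(mm)) {
      ov <- pmax(0, pmin(f_t1, hi[j]) - pmax(f_t0, lo[j]))
      ll <- ll - sum(f_kk * ov) / Ns[j]
    }
    ll
  }
  with_seed(seed, {
    gs <- rep(ne %/% m, m)
    gs[seq_len(ne %% m)] <- gs[seq_len(ne %% m)] + 1L
    total_rate_time <- sum(vapply(sets, function(s)
      sum(s$k * (s$k - 1) / 2 * s$dt), 0))
    Ns <- rep(min(max(total_rate_time / ne, bounds[1]), bounds[2]), m)
    lp <- loglik(gs, Ns) + skyline_log_prior(Ns, bounds)

    keep <- floor(iterations / thin)
    first_kept <- ceiling(burn_in * keep) + 1L
    N_out <- matrix(NA_real_, keep, m)
    gs_out <- matrix(NA_integer_, keep, m)
    lp_out <- numeric(keep)
    acc <- 0L
    for (it in seq_len(iterations)) {
      u_move <- stats::runif(1)
      if (u_move < 0.1) {
        # scale every group by a common factor: mixes the overall level,
        # which single-group moves traverse slowly under the smoothing prior
        fac <- exp(stats::runif(1, -prop_scale, prop_scale))
        Ns2 <- Ns * fac
        lp2 <- if (any(Ns2 < bounds[1] | Ns2 > bounds[2])) -Inf else
          loglik(gs, Ns2) + skyline_log_prior(Ns2, bounds)
        if (log(stats::runif(1)) < lp2 - lp + m * log(fac)) {
          Ns <- Ns2; lp <- lp2; acc <- acc + 1L
        }
      } else if (m > 1 && u_move < 0.3) {
        j <- sample.int(m - 1L, 1L)
        dir <- sample(c(-1L, 1L), 1L)
        gs2 <- gs
        gs2[j] <- gs2[j] + dir
        gs2[j + 1L] <- gs2[j + 1L] - dir
        if (all(gs2 >= 1L)) {
          lp2 <- loglik(gs2, Ns) + skyline_log_prior(Ns, bounds)
          if (log(stats::runif(1)) < lp2 - lp) {
            gs <- gs2; lp <- lp2; acc <- acc + 1L
          }
        }
      } else {
        j <- sample.int(m, 1L)
        Ns2 <- Ns
        fac <- exp(stats::runif(1, -prop_scale, prop_scale))
        Ns2[j] <- Ns2[j] * fac
        lp2 <- if (Ns2[j] < bounds[1] || Ns2[j] > bounds[2]) -Inf else
          loglik(gs, Ns2) + skyline_log_prior(Ns2, bounds)
        # Hastings: multiplicative proposal has log-ratio log(fac)
        if (log(stats::runif(1)) < lp2 - lp + log(fac)) {
          Ns <- Ns2; lp <- lp2; acc <- acc + 1L
        }
      }
      if (it %% thin == 0L) {
        i <- it %/% thin
        N_out[i, ] <- Ns
        gs_out[i, ] <- gs
        lp_out[i] <- lp
      }
    }
    sel <- first_kept:keep
    ess_per_group <- apply(log(N_out[sel, , drop = FALSE]), 2, ess)
    if (min(ess_per_group) < 50) {
      warning(sprintf("low effective sample size (min ESS = %.0f); ",
                      min(ess_per_group)),
              "consider more iterations")
    }
    structure(list(N = N_out[sel, , drop = FALSE],
                   group_sizes = gs_out[sel, , drop = FALSE],
                   lp = lp_out[sel],
                   event_times = ev, n_events = ne, m = m,
                   accept_rate = acc / iterations, ess = ess_per_group),
              class = "skyline_mcmc")
  })
}

#' @export
print.skyline_mcmc <- function(x, ...) {
  cat(sprintf("Skyline MCMC: %d draws, %d groups over %d coalescent events\n",
              nrow(x$N), x$m, x$n_events))
  cat(sprintf("  acceptance %.2f; min ESS %.0f\n", x$accept_rate, min(x$ess)))
  invisible(x)
}

# Piecewise Nef value of one draw at times t (generations bp).
draw_values_at <- function(ev, gs, Ns, t) {
  bounds <- ev[cumsum(gs)]
  idx <- pmin(findInterval(t, bounds, left.open = TRUE) + 1L, length(Ns))
  Ns[idx]
}

#' Posterior skyline trajectory on a time grid
#'
#' Evaluates every posterior draw's piecewise-constant Nef(t) on a grid and
#' summarises per gridpoint by the posterior median and 95% HPD interval.
#' Times are reported both in generations and in years before present
#' (generations x `generation_years`).
#'
#' @param chain a [mcmc_skyline()] result.
#' @param clock a [clock_config()].
#' @param grid time grid in generations before present (default: 101 points
#'   from 0 to the oldest pooled coalescence); points beyond the root are
#'   truncated with a warning.
#' @param prob HPD mass (default 0.95).
#' @return data frame of class `"skyline_trajectory"`: `time_gen`,
#'   `time_ybp`, `median`, `hpd_low`, `hpd_high`; attribute `"ess"`.
#' @export
skyline_trajectory <- function(chain, clock = clock_config(), grid = NULL,
                               prob = 0.95) {
  stopifnot(inherits(chain, "skyline_mcmc"))
  if (!nrow(chain$N)) stop("empty chain", call. = FALSE)
  root <- max(chain$event_times)
  if (is.null(grid)) {
    grid <- seq(0, root, length.out = 101)
  } else if (any(grid > root + 1e-9)) {
    warning("grid truncated at the root height")
    grid <- grid[grid <= root + 1e-9]
  }
  grid <- sort(grid)
  vals <- vapply(seq_len(nrow(chain$N)), function(i) {
    draw_values_at(chain$event_times, chain$group_sizes[i, ], chain$N[i, ],
                   grid)
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  med <- apply(vals, 1, stats::median)
  hpd <- apply(vals, 1, hpd_interval, prob = prob)
  out <- data.frame(time_gen = grid,
                    time_ybp = grid * clock$generation_years,
                    median = med, hpd_low = hpd[1, ], hpd_high = hpd[2, ])
  structure(out, class = c("skyline_trajectory", "data.frame"),
            ess = chain$ess)
}

#' Skyline robustness to subsampling
#'
#' Re-runs the whole genealogy -> intervals -> MCMC -> trajectory pipeline on
#' random subsets of the alignment, the standard check that sample size does
#' not drive the reconstruction.
#'
#' @param aln alignment matrix.
#' @param sizes subsample sizes (values < 3 are skipped with a warning;
#'   values equal to `nrow(aln)` use the full data).
#' @param clock a [clock_config()].
#' @param m,iterations,thin passed to [mcmc_skyline()].
#' @param seed optional master seed.
#' @param grid common time grid in generations (default from the full-data
#'   run).
#' @return named list of `"skyline_trajectory"` objects, one per size.
#' @export
subsample_robustness <- function(aln, sizes, clock = clock_config(), m = 5,
                                 iterations = 20000, thin = 20, seed = NULL,
                                 grid = NULL) {
  out <- list()
  for (s in sizes) {
    if (s < 3) {
      warning("subsample size ", s, " < 3 skipped")
      next
    }
    s <- min(s, nrow(aln))
    sub_seed <- if (is.null(seed)) NULL else stable_seed(seed, paste0("sub", s))
    idx <- with_seed(sub_seed, sample.int(nrow(aln), s))
    tr <- estimate_genealogy(aln[idx, , drop = FALSE], clock)
    ints <- coalescent_intervals(tr)
    ch <- mcmc_skyline(ints, m = min(m, s - 1), iterations = iterations,
                       thin = thin,
                       seed = if (is.null(sub_seed)) NULL else sub_seed + 1L)
    g <- grid
    if (!is.null(g)) g <- g[g <= max(ch$event_times)]
    out[[as.character(s)]] <- skyline_trajectory(ch, clock, grid = g)
  }
  out
}
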