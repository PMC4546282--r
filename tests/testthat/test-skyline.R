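test_that("UPGMA genealogy estimation handles identical and degenerate input", {
  ref <- control_region_reference(200)
  alt <- setdiff(c("A", "C", "G", "T"), ref$seq[3])[1]
  aln <- make_aln(ref$seq, list(
    a = c(), b = c(),
    c = stats::setNames(rep(alt, 1), "3")))
  # make c clearly distinct at several sites
  for (i in 4:12) aln["c", i] <- setdiff(c("A", "C", "G", "T"), ref$seq[i])[1]
  tr <- estimate_genealogy(aln, clock_config(mu = 1e-5))
  h <- ape::branching.times(tr)
  expect_equal(min(h), 0)  # the identical pair coalesces at height zero
  mrca_ab <- ape::getMRCA(tr, c("a", "b"))
  expect_equal(unname(h[as.character(mrca_ab)]), 0)

  same <- make_aln(ref$seq, list(a = c(), b = c(), c = c()))
  tr0 <- estimate_genealogy(same, clock_config())
  expect_true(attr(tr0, "degenerate"))
  expect_equal(sum(tr0$edge.length), 0)
})

test_that("true topologies are recovered from long-branch alignments", {
  cfg <- sim_config(mu = 2e-5, seq_length = 1122, kappa = 4,
                    gamma_shape = Inf)
  ok <- 0
  for (r in 1:50) {
    tr <- respace_tree(simulate_genealogy(demographic_model(10), 8,
                                          seed = 5000 + r), 60)
    aln <- evolve_sequences(tr, cfg, seed = 6000 + r)
    est <- estimate_genealogy(aln, clock_config(mu = 2e-5))
    if (ape::dist.topo(ape::unroot(tr), ape::unroot(est)) == 0) ok <- ok + 1
  }
  expect_gte(ok / 50, 0.9)
})

test_that("coalescent intervals decompose ultrametric trees", {
  two <- ape::read.tree(text = "(a:100,b:100);")
  ints <- coalescent_intervals(two)
  expect_equal(ints$k, 2)
  expect_equal(ints$dt, 100)
  expect_true(all(ints$coalescent))

  bal <- ape::read.tree(text = "((a:10,b:10):15,(c:10,d:10):15);")
  ib <- coalescent_intervals(bal)
  expect_equal(ib$k, c(4, 3, 2))
  expect_equal(ib$dt, c(10, 0, 15))

  for (n in c(5, 17, 40)) {
    tr <- simulate_genealogy(demographic_model(500), n, seed = n)
    ints_n <- coalescent_intervals(tr)
    expect_equal(nrow(ints_n), n - 1)
    expect_equal(sum(ints_n$coalescent), n - 1)
  }

  bad <- ape::read.tree(text = "(a:5,(b:1,c:9):2);")
  expect_error(coalescent_intervals(bad), "ultrametric")
})

test_that("the classic skyline inverts the coalescent rate per interval", {
  ints <- coalescent_intervals(ape::read.tree(text = "(a:100,b:100);"))
  expect_equal(classic_skyline(ints)$N, 100)

  fake <- data.frame(k = 10, dt = 2, t0 = 0, t1 = 2, coalescent = TRUE)
  class(fake) <- c("coalescent_intervals", "data.frame")
  attr(fake, "event_times") <- 2
  expect_equal(classic_skyline(fake)$N, 90)

  set.seed(55)
  est <- replicate(100, {
    ints_r <- coalescent_intervals(simulate_genealogy(demographic_model(1000),
                                                      30))
    sum(ints_r$k * (ints_r$k - 1) * ints_r$dt / 2) / nrow(ints_r)
  })
  expect_lt(abs(mean(est) - 1000) / 1000, 0.25)
})

test_that("the coalescent log-likelihood equals an independent hand coding", {
  set.seed(66)
  sets <- lapply(1:3, function(i)
    coalescent_intervals(simulate_genealogy(
      demographic_model(c(800, 200), 40), 12)))
  ne <- length(mesodemog:::pooled_event_times(sets))
  for (m in c(1, 3, 5)) {
    gs <- rep(ne %/% m, m)
    gs[seq_len(ne %% m)] <- gs[seq_len(ne %% m)] + 1
    Ns <- stats::runif(m, 100, 2000)
    expect_equal(coalescent_loglik(sets, gs, Ns),
                 bf_coalescent_loglik(sets, gs, Ns), tolerance = 1e-10)
    # single-tree route too (11 events from 12 tips)
    gs1 <- c(11 - (m - 1), rep(1, m - 1))
    expect_equal(coalescent_loglik(sets[[1]], gs1, Ns),
                 bf_coalescent_loglik(sets[1], gs1, Ns), tolerance = 1e-10)
  }
})

test_that("the MCMC internal likelihood matches the exported one", {
  set.seed(67)
  ints <- coalescent_intervals(simulate_genealogy(demographic_model(500), 15))
  ch <- suppressWarnings(mcmc_skyline(ints, m = 3, iterations = 2000,
                                      thin = 10, burn_in = 0, seed = 68))
  i <- nrow(ch$N)
  lp_expected <- coalescent_loglik(ints, ch$group_sizes[i, ], ch$N[i, ]) +
    mesodemog:::skyline_log_prior(ch$N[i, ], c(1e-3, 1e9))
  expect_equal(ch$lp[i], lp_expected, tolerance = 1e-9)
})

test_that("a single-interval posterior matches its analytic form", {
  # n = 2, one interval of length T, prior 1/N: the posterior of X = 1/N is
  # Exponential(rate T); the sampler must reproduce it
  T_len <- 500
  tr <- ape::read.tree(text = sprintf("(a:%d,b:%d);", T_len, T_len))
  ch <- mcmc_skyline(coalescent_intervals(tr), m = 1, iterations = 200000,
                     thin = 200, seed = 5)
  expect_gt(stats::ks.test(1 / ch$N[, 1], "pexp", T_len)$p.value, 0.01)
})

test_that("the m=1 posterior ties to the analytic MLE", {
  # with an inverse-gamma posterior, E[1/N] = n_events / sum(k(k-1)dt/2),
  # i.e. the harmonic posterior mean equals the MLE
  set.seed(77)
  ints <- coalescent_intervals(simulate_genealogy(demographic_model(2000), 30))
  mle <- sum(ints$k * (ints$k - 1) * ints$dt / 2) / nrow(ints)
  ch <- mcmc_skyline(ints, m = 1, iterations = 60000, thin = 30, seed = 78)
  expect_lt(abs(1 / mean(1 / ch$N[, 1]) - mle) / mle, 0.1)
})

test_that("a flat likelihood recovers the prior (sampler validation)", {
  tr <- ape::read.tree(text = "((a:100,b:100):100,c:200);")
  ch <- mcmc_skyline(coalescent_intervals(tr), m = 2, iterations = 400000,
                     thin = 400, bounds = c(10, 1e4),
                     flat_likelihood = TRUE, seed = 3)
  set.seed(4)
  acc1 <- acc2 <- numeric(0)
  while (length(acc1) < 20000) {
    n1 <- exp(stats::runif(40000, log(10), log(1e4)))
    n2 <- stats::rexp(40000, 1 / n1)
    keep <- n2 >= 10 & n2 <= 1e4
    acc1 <- c(acc1, n1[keep])
    acc2 <- c(acc2, n2[keep])
  }
  expect_gt(stats::ks.test(ch$N[, 1], acc1)$p.value, 0.01)
  expect_gt(stats::ks.test(ch$N[, 2], acc2)$p.value, 0.01)
})

test_that("trajectories summarise draws with medians, HPDs and unit conversion", {
  fake <- structure(list(
    N = matrix(c(100, 300), 2, 1), group_sizes = matrix(1L, 2, 1),
    lp = c(0, 0), event_times = 50, n_events = 1L, m = 1L,
    accept_rate = 1, ess = 2), class = "skyline_mcmc")
  traj <- skyline_trajectory(fake, clock_config(), grid = c(0, 25, 50))
  expect_equal(traj$median, rep(200, 3))
  expect_equal(traj$hpd_low, rep(100, 3))
  expect_equal(traj$hpd_high, rep(300, 3))
  expect_equal(traj$time_ybp, traj$time_gen * 25)

  const <- structure(list(
    N = matrix(150, 5, 1), group_sizes = matrix(1L, 5, 1), lp = rep(0, 5),
    event_times = 50, n_events = 1L, m = 1L, accept_rate = 1, ess = 5),
    class = "skyline_mcmc")
  tc <- skyline_trajectory(const, grid = c(0, 50))
  expect_equal(tc$hpd_high - tc$hpd_low, c(0, 0))
  expect_warning(skyline_trajectory(const, grid = c(0, 500)), "truncated")
})

test_that("growth histories are detected as growth in the posterior median", {
  detected <- 0
  for (r in 1:20) {
    tr <- simulate_genealogy(demographic_model(c(5000, 500), 200), 30,
                             seed = 300 + r)
    ch <- suppressWarnings(
      mcmc_skyline(coalescent_intervals(tr), m = 3, iterations = 20000,
                   thin = 20, seed = r))
    traj <- skyline_trajectory(ch)
    if (traj$median[1] > traj$median[nrow(traj)]) detected <- detected + 1
  }
  expect_gte(detected / 20, 0.8)
})

test_that("classic and finest-grained Bayesian skylines are rank-correlated", {
  rho <- vapply(1:3, function(r) {
    tr <- simulate_genealogy(demographic_model(c(4000, 1000, 300), c(40, 150)),
                             30, seed = 10 + r)
    ints <- coalescent_intervals(tr)
    cs <- suppressWarnings(classic_skyline(ints))
    ch <- suppressWarnings(mcmc_skyline(ints, m = nrow(ints),
                                        iterations = 60000, thin = 30,
                                        seed = 20 + r))
    stats::cor(cs$N, apply(ch$N, 2, stats::median), method = "spearman")
  }, 0)
  expect_gt(stats::median(rho), 0.7)
})

test_that("subsampling leaves the reconstruction qualitatively unchanged", {
  cfg <- sim_config(mu = 2e-5, seq_length = 600, gamma_shape = Inf)
  tr <- simulate_genealogy(demographic_model(200), 40, seed = 90)
  aln <- evolve_sequences(tr, cfg, seed = 91)
  clock <- clock_config(mu = 2e-5)
  expect_warning(
    out <- subsample_robustness(aln, c(2, 10, 20, 40), clock = clock, m = 3,
                                iterations = 15000, thin = 15, seed = 92),
    "skipped")
  expect_identical(names(out), c("10", "20", "40"))
  # skip t = 0: duplicate haplotypes put zero-height coalescences at the tip
  # end of UPGMA genealogies, an artifact that grows with sample size
  common <- seq(25, 100, by = 25)
  meds <- vapply(out[c("20", "40")], function(tt)
    stats::approx(tt$time_gen, tt$median, xout = common, rule = 2)$y,
    numeric(length(common)))
  expect_true(all(apply(meds, 1, function(v) max(v) / min(v) < 10)))
})
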