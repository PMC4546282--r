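# Independent oracles and small fixture builders used across the suite.
# These deliberately take different computational routes from the package
# implementations they check.

# mean pairwise differences by direct string comparison over all pairs
bf_theta <- function(aln) {
  n <- nrow(aln)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- toupper(aln[i, ])
      b <- toupper(aln[j, ])
      ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      tot <- tot + sum(a[ok] != b[ok])
    }
  }
  tot / choose(n, 2)
}

# per-site average heterozygosity route to nucleotide diversity (complete data)
bf_pi_sitewise <- function(aln) {
  n <- nrow(aln)
  h <- apply(aln, 2, function(col) {
    counts <- table(col)
    (1 - sum((counts / n)^2)) * n / (n - 1)
  })
  mean(h)
}

# Tajima's D constants written out independently
bf_tajimas_d <- function(S, theta, n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n * n + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  (theta - S / a1) /
    sqrt((c1 / a1) * S + (c2 / (a1 * a1 + a2)) * S * (S - 1))
}

# Ewens K-distribution via polynomial expansion of the rising factorial:
# coefficients of x(x+1)...(x+n-1) are |s(n, k)|
bf_ewens_probs <- function(n, theta) {
  coef <- 1
  for (i in 0:(n - 1)) {
    coef <- c(0, coef) + c(coef * i, 0)  # multiply polynomial by (x + i)
  }
  stirling <- coef[-1]  # k = 1..n
  p <- stirling * theta^seq_len(n) / prod(theta + 0:(n - 1))
  p / sum(p)
}

# Variance components through an explicit Euclidean embedding (coordinates
# route instead of the pairwise-sum route).  The AMOVA input holds squared
# distances, so the embedding uses their square roots, which for difference
# counts is an exact Euclidean representation.
embed_coords <- function(d2) {
  n <- nrow(d2)
  fit <- stats::cmdscale(stats::as.dist(sqrt(d2)), k = n - 1, eig = TRUE)
  fit$points
}

ss_centroid <- function(x) {
  x <- as.matrix(x)
  sum(sweep(x, 2, colMeans(x))^2)
}

bf_phist_components <- function(d, pop) {
  x <- embed_coords(d)
  pop <- as.factor(pop)
  N <- length(pop)
  P <- nlevels(pop)
  np <- tabulate(pop)
  ss_t <- ss_centroid(x)
  ss_wp <- sum(vapply(levels(pop), function(l)
    ss_centroid(x[pop == l, , drop = FALSE]), 0))
  sigma_w <- ss_wp / (N - P)
  nprime <- (N - sum(np^2) / N) / (P - 1)
  sigma_a <- ((ss_t - ss_wp) / (P - 1) - sigma_w) / nprime
  list(sigma_a = sigma_a, sigma_w = sigma_w,
       phist = sigma_a / (sigma_a + sigma_w))
}

bf_amova_components <- function(d, pop, grp_of_pop) {
  x <- embed_coords(d)
  pop <- as.character(pop)
  grp <- grp_of_pop[pop]
  N <- length(pop)
  pops <- unique(pop)
  groups <- unique(grp)
  P <- length(pops)
  G <- length(groups)
  ss_t <- ss_centroid(x)
  ss_wp <- sum(vapply(pops, function(p)
    ss_centroid(x[pop == p, , drop = FALSE]), 0))
  ss_wg <- sum(vapply(groups, function(g)
    ss_centroid(x[grp == g, , drop = FALSE]), 0))
  np <- vapply(pops, function(p) sum(pop == p), 0)
  ng <- vapply(groups, function(g) sum(grp == g), 0)
  sum_np2_by_g <- vapply(groups, function(g)
    sum(np[grp_of_pop[pops] == g]^2), 0)
  n1 <- (N - sum(sum_np2_by_g / ng)) / (P - G)
  n2 <- (sum(sum_np2_by_g / ng) - sum(np^2) / N) / (G - 1)
  n3 <- (N - sum(ng^2) / N) / (G - 1)
  sigma_c <- ss_wp / (N - P)
  sigma_b <- ((ss_wg - ss_wp) / (P - G) - sigma_c) / n1
  sigma_a <- ((ss_t - ss_wg) / (G - 1) - sigma_c - n2 * sigma_b) / n3
  list(sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c,
       F_CT = sigma_a / (sigma_a + sigma_b + sigma_c))
}

# piecewise-coalescent log-likelihood by explicit epoch-by-epoch walking
bf_coalescent_loglik <- function(sets, group_sizes, sizes) {
  ev <- sort(unlist(lapply(sets, attr, "event_times")))
  bounds <- ev[cumsum(group_sizes)]
  nef_at_time <- function(t) {
    j <- 1
    while (j < length(sizes) && t > bounds[j]) j <- j + 1
    sizes[j]
  }
  breaks <- c(0, bounds, Inf)
  ll <- 0
  for (s in sets) {
    for (r in seq_len(nrow(s))) {
      t0 <- s$t0[r]; t1 <- s$t1[r]
      rate <- s$k[r] * (s$k[r] - 1) / 2
      for (j in seq_len(length(breaks) - 1)) {
        lo <- max(t0, breaks[j]); hi <- min(t1, breaks[j + 1])
        if (hi > lo) ll <- ll - rate * (hi - lo) / sizes[min(j, length(sizes))]
      }
      if (s$coalescent[r]) ll <- ll - log(nef_at_time(t1))
    }
  }
  ll
}

# rebuild a tree's node heights evenly spaced (long internal branches)
respace_tree <- function(tr, step) {
  n <- length(tr$tip.label)
  h <- ape::branching.times(tr)
  hnew <- stats::setNames(step * rank(h, ties.method = "first"), names(h))
  hh <- c(stats::setNames(numeric(n), seq_len(n)), hnew)
  tr$edge.length <- hh[as.character(tr$edge[, 1])] -
    hh[as.character(tr$edge[, 2])]
  tr
}

# tiny alignment with named rows from a reference plus listed substitutions
make_aln <- function(ref_seq, subs_per_sample) {
  out <- t(vapply(subs_per_sample, function(subs) {
    s <- ref_seq
    if (length(subs)) s[as.integer(names(subs))] <- subs
    s
  }, character(length(ref_seq))))
  rownames(out) <- names(subs_per_sample)
  out
}

# manual variant profile (bypasses call_variants)
manual_profile <- function(pos, allele, region = "HVRI") {
  out <- data.frame(pos = pos, allele = allele,
                    region = rep(region, length.out = length(pos)),
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_profile", "data.frame")
  out
}

# growth-then-decline truth shared by the recovery tests: staircase rise to a
# peak ending ~2500 ybp (100 generations) then stepwise decline to the present
growth_decline_model <- function() {
  demographic_model(
    c(5000, 9000, 16000, 25000, 14000, 6000, 2500, 1000, 400),
    c(30, 60, 90, 110, 200, 300, 400, 520),
    label = "growth 13000 ybp, decline from ~2500 ybp")
}

# inversion time of a trajectory via the package's own rule
inversion_time <- function(traj, window = 7) {
  s <- igr_series(resample_to_generations(traj))
  inv <- detect_inversion(s, window = window)
  pn <- inv[inv$direction == "positive->negative", , drop = FALSE]
  if (nrow(pn)) pn$time_ybp else NA_real_
}
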