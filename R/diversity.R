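# Within-population diversity estimators and neutrality tests.
#
# Conventions follow the classic control-region literature: theta is the mean
# number of pairwise differences between sequences (not Watterson's
# estimator, which appears only inside Tajima's D as S/a1); missing data are
# handled by pairwise deletion.

is_called <- function(x) {
  out <- x %in% DNA_BASES
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

# Pairwise difference counts and jointly-called site counts between all rows.
pairwise_differences <- function(aln) {
  aln <- toupper(aln)
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  sites <- matrix(ncol(aln), n, n, dimnames = dimnames(d))
  called <- is_called(aln)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- called[i, ] & called[j, ]
      d[i, j] <- d[j, i] <- sum(aln[i, ok] != aln[j, ok])
      sites[i, j] <- sites[j, i] <- sum(ok)
    }
  }
  list(diff = d, sites = sites)
}

#' Number of segregating (polymorphic) sites
#'
#' Sites with at least two observed unambiguous states; missing/ambiguous
#' bases are ignored per site.
#'
#' @param aln character alignment matrix (samples x sites).
#' @return integer count.
#' @export
segregating_sites <- function(aln) {
  aln <- toupper(aln)
  sum(apply(aln, 2, function(col) {
    length(unique(col[is_called(col)])) >= 2
  }))
}

#' Mean number of pairwise differences (theta)
#'
#' `theta = sum_{i<j} d_ij / C(n,2)` where `d_ij` counts differing,
#' jointly-called sites under pairwise deletion.
#'
#' @inheritParams segregating_sites
#' @return numeric.
#' @export
mean_pairwise_differences <- function(aln) {
  n <- nrow(aln)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  pd <- pairwise_differences(aln)
  sum(pd$diff[upper.tri(pd$diff)]) / choose(n, 2)
}

#' Haplotype (gene) diversity with its standard deviation
#'
#' `H = n/(n-1) * (1 - sum p_i^2)`, with the sampling standard deviation from
#' Nei's (1987, eq. 8.12) variance formula for gene diversity.
#'
#' @param counts vector of haplotype counts (any order).
#' @return list with `H` and `sd`.
#' @examples
#' haplotype_diversity(c(3, 2, 1))  # H = 6/5 * (1 - 14/36)
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  H <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(H = H, sd = sqrt(max(v, 0)))
}

#' Per-site nucleotide diversity with its standard deviation
#'
#' `pi` is the mean over sequence pairs of the proportion of differing,
#' jointly-called sites (so `pi * L = theta` on complete data).  The standard
#' deviation is from Tajima's (1983) total variance of the estimator,
#' `V(pi) = (n+1) pi / (3 (n-1) L) + 2 (n^2+n+3) pi^2 / (9 n (n-1))`.
#'
#' @inheritParams segregating_sites
#' @return list with `pi` and `sd`.
#' @export
nucleotide_diversity <- function(aln) {
  n <- nrow(aln)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  pd <- pairwise_differences(aln)
  up <- upper.tri(pd$diff)
  usable <- pd$sites[up]
  if (all(usable == 0)) stop("no jointly-called sites", call. = FALSE)
  pi <- mean(pd$diff[up][usable > 0] / usable[usable > 0])
  L <- mean(usable[usable > 0])
  v <- (n + 1) * pi / (3 * (n - 1) * L) +
    2 * (n^2 + n + 3) * pi^2 / (9 * n * (n - 1))
  list(pi = pi, sd = sqrt(max(v, 0)))
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' `D = (theta - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' constants `a1 = sum 1/i`, `a2 = sum 1/i^2` (i = 1..n-1),
#' `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2 + a2)`.
#'
#' @param S number of segregating sites.
#' @param theta mean number of pairwise differences.
#' @param n sample size (>= 4).
#' @return `D`, or `NA` with attribute `"reason"` when `S = 0` (undefined).
#' @export
tajimas_d <- function(S, theta, n) {
  if (n < 4) stop("Tajima's D needs n >= 4", call. = FALSE)
  if (S == 0) {
    return(structure(NA_real_, reason = "no segregating sites"))
  }
  k <- tajima_constants(n)
  (theta - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

# log of unsigned Stirling numbers of the first kind |s(n, k)| for k = 1..n,
# by the recursion |s(n+1,k)| = n |s(n,k)| + |s(n,k-1)| in log space.
log_stirling_first <- function(n) {
  ls <- -Inf + numeric(n)
  ls[1] <- 0  # |s(1,1)| = 1
  if (n == 1) return(ls)
  for (m in 1:(n - 1)) {
    new <- numeric(n) - Inf
    for (k in seq_len(m + 1)) {
      terms <- c(if (k <= m) log(m) + ls[k],
                 if (k > 1) ls[k - 1])
      new[k] <- logsumexp(terms)
    }
    ls <- new
  }
  ls
}

#' Ewens distribution of the number of alleles
#'
#' Log-probabilities `Pr(K = k | theta, n)` under the Ewens sampling formula,
#' `|s(n,k)| theta^k / theta_(n)` with `theta_(n)` the rising factorial.
#'
#' @param n sample size.
#' @param theta scaled diversity parameter (> 0).
#' @return numeric vector of length `n`: log Pr(K = k) for k = 1..n.
#' @export
ewens_log_probs <- function(n, theta) {
  stopifnot(n >= 1, theta > 0)
  ls <- log_stirling_first(n)
  k <- seq_len(n)
  ls + k * log(theta) - sum(log(theta + 0:(n - 1)))
}

#' Fu's FS neutrality statistic
#'
#' `FS = ln(S' / (1 - S'))` where `S' = Pr(K >= k_obs | theta, n)` under the
#' Ewens sampling distribution, with theta plugged in as the mean number of
#' pairwise differences (Fu 1997; Arlequin practice).  Star-like genealogies
#' (an excess of haplotypes for the observed theta) give strongly negative
#' FS.
#'
#' @param n sample size.
#' @param k observed number of distinct haplotypes.
#' @param theta mean pairwise differences (> 0).
#' @return `FS`; `+/-Inf` sentinel with a warning when `S'` underflows to 1
#'   or 0.
#' @export
fus_fs <- function(n, k, theta) {
  stopifnot(n >= 2, k >= 1, k <= n)
  if (theta <= 0) stop("Fu's FS needs theta > 0", call. = FALSE)
  lp <- ewens_log_probs(n, theta)
  ls_ge <- logsumexp(lp[k:n])       # log S'
  ls_lt <- if (k > 1) logsumexp(lp[seq_len(k - 1)]) else -Inf  # log(1 - S')
  if (ls_lt == -Inf) {
    warning("S' = 1 to machine precision; returning +Inf")
    return(Inf)
  }
  if (ls_ge == -Inf) {
    warning("S' = 0 to machine precision; returning -Inf")
    return(-Inf)
  }
  ls_ge - ls_lt
}

#' Diversity summary for one population
#'
#' Computes the standard control-region summary row: sample size, haplotype
#' count `k`, segregating sites `S`, haplotype diversity `H +- sd`,
#' nucleotide diversity `pi +- sd`, mean pairwise differences `theta`,
#' Tajima's `D` and Fu's `FS`.
#'
#' @param aln alignment matrix for one population (n >= 2 rows).
#' @param profiles optional pre-computed profiles (for haplotype identity);
#'   computed from `aln` if missing.
#' @inheritParams call_variants
#' @return one-row data frame.
#' @export
diversity_summary <- function(aln, profiles = NULL,
                              reference = control_region_reference(ncol(aln))) {
  n <- nrow(aln)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  if (is.null(profiles)) profiles <- profile_alignment(aln, reference)
  hap <- collapse_haplotypes(profiles, "full")
  counts <- table(hap)
  k <- length(counts)
  S <- segregating_sites(aln)
  theta <- mean_pairwise_differences(aln)
  H <- haplotype_diversity(as.numeric(counts))
  P <- nucleotide_diversity(aln)
  D <- if (S > 0 && n >= 4) tajimas_d(S, theta, n) else NA_real_
  FS <- if (theta > 0) fus_fs(n, k, theta) else NA_real_
  data.frame(n = n, k = k, S = S, H = H$H, H_sd = H$sd,
             pi = P$pi, pi_sd = P$sd, theta = theta,
             D = as.numeric(D), FS = FS)
}

#' Per-population diversity table
#'
#' One [diversity_summary()] row per population, in the shape of the classic
#' per-population diversity tables of control-region studies.
#'
#' @param aln full alignment.
#' @param populations named sample -> population vector.
#' @inheritParams call_variants
#' @return data frame with a `population` column.
#' @export
diversity_table <- function(aln, populations,
                            reference = control_region_reference(ncol(aln))) {
  pops <- unique(populations[rownames(aln)])
  rows <- lapply(pops, function(p) {
    ids <- intersect(rownames(aln), names(populations)[populations == p])
    sub <- aln[ids, , drop = FALSE]
    cbind(population = p, diversity_summary(sub, reference = reference))
  })
  do.call(rbind, rows)
}
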