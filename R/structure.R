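# Between-population structure: Phi-st, AMOVA, Mantel, MDS, shared haplotypes.
#
# "Fst" throughout this module is the haplotype-distance-based Phi-st of the
# AMOVA framework (Excoffier, Smouse & Quattro 1992; the Arlequin
# convention), NOT an allele-frequency Fst: variance components are computed
# from squared molecular distances between haplotypes.

#' Pairwise-difference distance matrix for a set of sequences
#'
#' @param aln character alignment matrix.
#' @return symmetric matrix of pairwise difference counts (pairwise
#'   deletion).
#' @export
difference_matrix <- function(aln) {
  pairwise_differences(aln)$diff
}

# Two-level AMOVA variance components from a squared-distance decomposition.
# d: full distance matrix; pop: factor of population labels.
phist_components <- function(d, pop) {
  pop <- as.factor(pop)
  N <- length(pop)
  P <- nlevels(pop)
  d2 <- d  # entries are already squared molecular distances
  ss_total <- sum(d2[upper.tri(d2)]) / N
  np <- tabulate(pop)
  ss_wp <- 0
  for (l in seq_len(P)) {
    idx <- which(as.integer(pop) == l)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_wp <- ss_wp + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_ap <- ss_total - ss_wp
  sigma_w <- ss_wp / (N - P)
  nprime <- (N - sum(np^2) / N) / (P - 1)
  sigma_a <- (ss_ap / (P - 1) - sigma_w) / nprime
  list(sigma_a = sigma_a, sigma_w = sigma_w,
       phist = sigma_a / (sigma_a + sigma_w))
}

#' Pairwise Phi-st between two populations
#'
#' Two-level AMOVA on the matrix of pairwise sequence differences (difference
#' counts are the squared Euclidean distances of site-indicator vectors, so
#' they enter the sums of squares directly, as in Arlequin); Phi-st is
#' the among-population fraction of molecular variance.  Significance is by
#' permutation of individuals among the two populations, with the
#' `(b + 1) / (m + 1)` correction.  Negative estimates (possible when the
#' within-population variance exceeds the total) are reported as computed and
#' flagged.
#'
#' @param alnA,alnB alignment matrices of the two populations (each n >= 2).
#' @param n_perm number of permutations (>= 1).
#' @param seed optional integer seed.
#' @return list with `phist`, `p_value`, `negative` flag and the variance
#'   components.
#' @export
pairwise_phist <- function(alnA, alnB, n_perm = 1000, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  stopifnot(nrow(alnA) >= 2, nrow(alnB) >= 2, ncol(alnA) == ncol(alnB))
  d <- difference_matrix(rbind(alnA, alnB))
  pop <- rep(c("A", "B"), c(nrow(alnA), nrow(alnB)))
  obs <- phist_components(d, pop)
  if (!is.finite(obs$phist)) {
    warning("no molecular variation at all: Phi-st undefined")
    return(list(phist = NaN, p_value = NA_real_, negative = NA,
                sigma_a = obs$sigma_a, sigma_w = obs$sigma_w))
  }
  b <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      phist_components(d, sample(pop))$phist >= obs$phist
    }, NA))
  })
  list(phist = obs$phist, p_value = (b + 1) / (n_perm + 1),
       negative = obs$phist < 0,
       sigma_a = obs$sigma_a, sigma_w = obs$sigma_w)
}

#' Matrix of pairwise Phi-st (and p-values) across populations
#'
#' @param aln full alignment.
#' @param populations named sample -> population vector.
#' @param n_perm permutations per pair.
#' @param seed optional master seed; pair seeds are derived stably.
#' @return list of two symmetric matrices, `phist` and `p_value`.
#' @export
phist_matrix <- function(aln, populations, n_perm = 1000, seed = NULL) {
  pops <- unique(populations[rownames(aln)])
  k <- length(pops)
  phist <- p <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ai <- aln[intersect(rownames(aln),
                          names(populations)[populations == pops[i]]), ,
                drop = FALSE]
      aj <- aln[intersect(rownames(aln),
                          names(populations)[populations == pops[j]]), ,
                drop = FALSE]
      s <- if (is.null(seed)) NULL else
        stable_seed(seed, paste(pops[i], pops[j]))
      r <- pairwise_phist(ai, aj, n_perm, s)
      phist[i, j] <- phist[j, i] <- r$phist
      p[i, j] <- p[j, i] <- r$p_value
    }
  }
  list(phist = phist, p_value = p)
}

#' Corrected average pairwise difference between two populations
#'
#' `d_xy - (d_x + d_y) / 2`: the mean between-population difference corrected
#' for within-population diversity (net nucleotide divergence in difference
#' units).
#'
#' @inheritParams pairwise_phist
#' @return numeric.
#' @export
corrected_pairwise_diff <- function(alnA, alnB) {
  stopifnot(nrow(alnA) >= 2, nrow(alnB) >= 2)
  d <- difference_matrix(rbind(alnA, alnB))
  na <- nrow(alnA)
  nb <- nrow(alnB)
  ia <- seq_len(na)
  ib <- na + seq_len(nb)
  dxy <- mean(d[ia, ib])
  dx <- sum(d[ia, ia][upper.tri(d[ia, ia])]) / choose(na, 2)
  dy <- sum(d[ib, ib][upper.tri(d[ib, ib])]) / choose(nb, 2)
  dxy - (dx + dy) / 2
}

# Three-level sums of squares and variance components
# (Excoffier-Smouse-Quattro decomposition from squared distances).
amova_components <- function(d, pop, grp_of_pop) {
  pop <- as.character(pop)
  grp <- grp_of_pop[pop]
  N <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  G <- length(unique(grp))
  d2 <- d  # entries are already squared molecular distances
  ss_block <- function(idx) {
    if (length(idx) < 2) return(0)
    sub <- d2[idx, idx]
    sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_t <- ss_block(seq_len(N))
  ss_wp <- sum(vapply(pops, function(p) ss_block(which(pop == p)), 0))
  groups <- unique(grp)
  ss_wg <- sum(vapply(groups, function(g) ss_block(which(grp == g)), 0))
  ssd_ap_wg <- ss_wg - ss_wp
  ssd_ag <- ss_t - ss_wg

  np <- vapply(pops, function(p) sum(pop == p), 0)
  ng <- vapply(groups, function(g) sum(grp == g), 0)
  sum_np2_by_g <- vapply(groups, function(g) {
    sum(vapply(pops[grp_of_pop[pops] == g],
               function(p) sum(pop == p)^2, 0))
  }, 0)
  n1 <- (N - sum(sum_np2_by_g / ng)) / (P - G)
  n2 <- (sum(sum_np2_by_g / ng) - sum(np^2) / N) / (G - 1)
  n3 <- (N - sum(ng^2) / N) / (G - 1)

  sigma_c <- ss_wp / (N - P)
  sigma_b <- (ssd_ap_wg / (P - G) - sigma_c) / n1
  sigma_a <- (ssd_ag / (G - 1) - sigma_c - n2 * sigma_b) / n3
  tot <- sigma_a + sigma_b + sigma_c
  list(sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c,
       F_CT = sigma_a / tot, F_SC = sigma_b / (sigma_b + sigma_c),
       F_ST = (sigma_a + sigma_b) / tot,
       ss = c(among_groups = ssd_ag, among_pops_within = ssd_ap_wg,
              within_pops = ss_wp),
       df = c(G - 1, P - G, N - P))
}

#' Hierarchical AMOVA with permutation tests
#'
#' Three-level analysis of molecular variance from squared pairwise
#' distances: among groups (`F_CT`), among populations within groups
#' (`F_SC`), within populations (`F_ST`).  Permutation null distributions
#' follow the standard schemes: whole populations permuted among groups for
#' `F_CT`; individuals permuted among populations within their group for
#' `F_SC`; individuals permuted among all populations for `F_ST`.  P-values
#' use `(b + 1) / (m + 1)`.
#'
#' @param d matrix of squared molecular distances over all individuals;
#'   pairwise difference counts from [difference_matrix()] are exactly that.
#' @param populations population label per individual (in matrix order).
#' @param groups named population -> group vector (>= 2 groups).
#' @param n_perm permutations (default 1000).
#' @param seed optional integer seed.
#' @return object of class `"amova_result"`.
#' @export
amova <- function(d, populations, groups, n_perm = 1000, seed = NULL) {
  populations <- as.character(populations)
  pops <- unique(populations)
  if (!all(pops %in% names(groups))) {
    stop("every population needs a group assignment", call. = FALSE)
  }
  groups <- groups[pops]
  if (length(unique(groups)) < 2) {
    stop("degenerate design: need at least 2 groups", call. = FALSE)
  }
  if (any(table(groups) == length(pops))) {
    stop("degenerate design: one group contains all populations",
         call. = FALSE)
  }
  if (length(pops) == length(unique(groups))) {
    stop("degenerate design: every group holds a single population, so the ",
         "among-populations-within-groups level vanishes", call. = FALSE)
  }
  obs <- amova_components(d, populations, groups)
  with_seed(seed, {
    b_ct <- b_sc <- b_st <- 0L
    for (r in seq_len(n_perm)) {
      # F_CT: permute whole populations among groups
      g_perm <- stats::setNames(sample(unname(groups)), names(groups))
      p_ct <- amova_components(d, populations, g_perm)
      if (is.finite(p_ct$F_CT) && p_ct$F_CT >= obs$F_CT) b_ct <- b_ct + 1L
      # F_SC: permute individuals among populations within groups
      pop_sc <- populations
      for (g in unique(groups)) {
        idx <- which(groups[populations] == g)
        pop_sc[idx] <- sample(populations[idx])
      }
      p_sc <- amova_components(d, pop_sc, groups)
      if (is.finite(p_sc$F_SC) && p_sc$F_SC >= obs$F_SC) b_sc <- b_sc + 1L
      # F_ST: permute individuals among all populations
      p_st <- amova_components(d, sample(populations), groups)
      if (is.finite(p_st$F_ST) && p_st$F_ST >= obs$F_ST) b_st <- b_st + 1L
    }
    structure(c(obs, list(
      p_CT = (b_ct + 1) / (n_perm + 1),
      p_SC = (b_sc + 1) / (n_perm + 1),
      p_ST = (b_st + 1) / (n_perm + 1),
      n_perm = n_perm)), class = "amova_result")
  })
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (Phi-statistics from squared molecular distances)\n")
  comp <- data.frame(
    source = c("Among groups", "Among populations within groups",
               "Within populations"),
    df = x$df,
    sigma2 = c(x$sigma_a, x$sigma_b, x$sigma_c))
  print(comp, row.names = FALSE)
  cat(sprintf("F_CT = %.4f (p = %.4f); F_SC = %.4f (p = %.4f); F_ST = %.4f (p = %.4f)\n",
              x$F_CT, x$p_CT, x$F_SC, x$p_SC, x$F_ST, x$p_ST))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the off-diagonal upper triangles; significance by
#' jointly permuting the rows and columns of the second matrix.  For `n <= 7`
#' an exhaustive enumeration over all `n!` permutations is available.
#'
#' @param dA,dB symmetric distance matrices with identical labels/order.
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed optional integer seed.
#' @param exhaustive enumerate all permutations instead of sampling.
#' @return list with `r`, `p_value`, `method`.
#' @export
mantel_test <- function(dA, dB, n_perm = 10000, seed = NULL,
                        exhaustive = FALSE) {
  stopifnot(all(dim(dA) == dim(dB)))
  n <- nrow(dA)
  if (n < 3) stop("need at least 3 labels", call. = FALSE)
  up <- upper.tri(dA)
  a <- dA[up]
  if (stats::sd(a) == 0 || stats::sd(dB[up]) == 0) {
    stop("constant distance matrix: correlation undefined", call. = FALSE)
  }
  r_for <- function(perm) stats::cor(a, dB[perm, perm][up])
  obs <- r_for(seq_len(n))
  if (exhaustive) {
    if (n > 7) stop("exhaustive enumeration limited to n <= 7", call. = FALSE)
    perms <- all_permutations(n)
    rs <- vapply(perms, r_for, 0)
    p <- mean(rs >= obs - 1e-12)
  } else {
    b <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        r_for(sample.int(n)) >= obs - 1e-12
      }, NA))
    })
    p <- (b + 1) / (n_perm + 1)
  }
  list(r = obs, p_value = p,
       method = if (exhaustive) "exhaustive" else "monte-carlo")
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (s in sub) {
    for (pos in 0:(n - 1L)) {
      i <- i + 1L
      out[[i]] <- append(s, n, after = pos)
    }
  }
  out
}

#' Great-circle distance matrix from coordinates
#'
#' Haversine distances in kilometres, for use against genetic distances in a
#' Mantel test.
#'
#' @param lat,lon numeric vectors (decimal degrees).
#' @param labels names for the matrix.
#' @return symmetric matrix of distances in km.
#' @export
geographic_distance_matrix <- function(lat, lon, labels = NULL) {
  n <- length(lat)
  stopifnot(length(lon) == n)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <-
        geosphere::distHaversine(c(lon[i], lat[i]), c(lon[j], lat[j])) / 1000
    }
  }
  m
}

#' Classical (metric) multidimensional scaling of a distance matrix
#'
#' Principal-coordinates analysis: double-centred Gram matrix, top
#' eigenpairs.  Negative eigenvalues are dropped and their mass reported in
#' the goodness of fit.
#'
#' @param d symmetric distance matrix.
#' @param dims number of dimensions (default 2; must be <= n - 1).
#' @return object of class `"mds_solution"`: list with `points` (centred
#'   coordinates), `eigenvalues`, `gof` (share of positive eigenvalue mass
#'   captured), `negative_mass`.
#' @export
mds_scaling <- function(d, dims = 2) {
  n <- nrow(d)
  if (n < 3) stop("need at least 3 labels", call. = FALSE)
  if (dims > n - 1) stop("dims must be <= n - 1", call. = FALSE)
  fit <- stats::cmdscale(stats::as.dist(d), k = dims, eig = TRUE)
  pts <- fit$points
  pts <- sweep(pts, 2, colMeans(pts))
  pos <- fit$eig[fit$eig > 1e-12]
  structure(list(points = pts, eigenvalues = fit$eig,
                 gof = sum(pos[seq_len(min(dims, length(pos)))]) / sum(pos),
                 negative_mass = sum(abs(fit$eig[fit$eig < 0])) /
                   sum(abs(fit$eig)),
                 method = "classical metric scaling (principal coordinates)"),
            class = "mds_solution")
}

#' Correlation of MDS centroid distance with diversity
#'
#' Euclidean distance of each population from the centroid of the MDS
#' configuration, correlated (Pearson) with haplotype diversity: peripheral
#' populations with low diversity give strongly negative `r`.
#'
#' @param mds an `"mds_solution"`.
#' @param H named vector of haplotype diversity per population (same labels).
#' @return list with `r`, `p_value`, `centroid_distance`.
#' @export
centroid_diversity_correlation <- function(mds, H) {
  pts <- mds$points
  if (nrow(pts) < 3) stop("need at least 3 populations", call. = FALSE)
  H <- H[rownames(pts)]
  if (anyNA(H)) stop("H missing for some populations", call. = FALSE)
  cd <- sqrt(rowSums(pts^2))  # coordinates are centred
  if (stats::sd(H) == 0 || stats::sd(cd) == 0) {
    stop("correlation undefined: constant input", call. = FALSE)
  }
  ct <- stats::cor.test(cd, H)
  list(r = unname(ct$estimate), p_value = ct$p.value, centroid_distance = cd)
}

#' Shared-haplotype count matrix
#'
#' Entry (i, j) is the number of distinct haplotypes present in both
#' populations (typically HVRI haplotypes from [collapse_haplotypes()]).
#'
#' @param sets named list of haplotype-id vectors per population.
#' @return symmetric integer matrix; the diagonal holds each population's own
#'   haplotype count.
#' @export
shared_haplotype_matrix <- function(sets) {
  k <- length(sets)
  m <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      m[i, j] <- length(intersect(unique(sets[[i]]), unique(sets[[j]])))
    }
  }
  m
}
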