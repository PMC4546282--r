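#' Piecewise-constant demographic model
#'
#' A history of the effective number of breeding females, Nef, expressed as a
#' piecewise-constant function of time in generations before present.  Epoch 1
#' covers `[0, change_times[1])`, epoch 2 `[change_times[1], change_times[2])`
#' and so on; `Nef(t)` is right-continuous in time-before-present.  Nef is the
#' haploid effective count of maternal lineages, so with k extant lineages the
#' coalescent hazard is `k (k - 1) / (2 Nef)` per generation.
#'
#' @param sizes positive Nef values, one per epoch (most recent first).
#' @param change_times strictly increasing epoch boundaries in generations
#'   before present; one fewer than `sizes`.
#' @param label free-text label carried through outputs.
#' @return an object of class `"demographic_model"`.
#' @examples
#' # tenfold growth 520 generations (13,000 years / 25) before present
#' demographic_model(c(5000, 500), 520, label = "post-glacial growth")
#' @export
demographic_model <- function(sizes, change_times = numeric(0), label = "") {
  sizes <- as.numeric(sizes)
  change_times <- as.numeric(change_times)
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    stop("all Nef sizes must be positive and finite", call. = FALSE)
  }
  if (length(sizes) != length(change_times) + 1L) {
    stop("need length(sizes) == length(change_times) + 1", call. = FALSE)
  }
  if (length(change_times) &&
      (any(change_times <= 0) || any(diff(change_times) <= 0))) {
    stop("change_times must be positive and strictly increasing", call. = FALSE)
  }
  structure(list(sizes = sizes, change_times = change_times, label = label),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model", if (nzchar(x$label)) sQuote(x$label) else "",
      "\n  epochs (generations bp): ",
      paste(c(0, x$change_times), "-", c(x$change_times, Inf),
            ": Nef=", signif(x$sizes, 4), collapse = "; "),
      "\n", sep = "")
  invisible(x)
}

#' Evaluate Nef(t)
#'
#' @param model a [demographic_model()].
#' @param t times in generations before present.
#' @return Nef at each `t`.
#' @export
nef_at <- function(model, t) {
  stopifnot(inherits(model, "demographic_model"))
  idx <- findInterval(t, model$change_times) + 1L
  model$sizes[idx]
}

#' Simulation configuration for control-region sequence evolution
#'
#' Defaults emulate a full human mtDNA control region: 1122 sites, a
#' non-coding-region substitution rate of 3.02e-7 per site per year, 25-year
#' generations, and HKY+Gamma site evolution with strong transition bias and
#' pronounced rate heterogeneity (4 discrete categories).
#'
#' @param seq_length number of sites.
#' @param mu substitution rate per site per year.
#' @param generation_years years per generation.
#' @param kappa HKY transition/transversion rate ratio.
#' @param gamma_shape shape of the discrete-gamma rate heterogeneity
#'   (4 categories, median rates); `Inf` disables heterogeneity.
#' @param base_freqs stationary base frequencies in A, C, G, T order.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(seq_length = 1122L,
                       mu = 3.02e-7,
                       generation_years = 25,
                       kappa = 20,
                       gamma_shape = 0.26,
                       base_freqs = c(A = 0.31, C = 0.33, G = 0.13, T = 0.23)) {
  stopifnot(seq_length >= 1, mu > 0, generation_years > 0, kappa > 0,
            gamma_shape > 0)
  assert_prob_vector(base_freqs)
  structure(list(seq_length = as.integer(seq_length), mu = mu,
                 generation_years = generation_years, kappa = kappa,
                 gamma_shape = gamma_shape,
                 base_freqs = stats::setNames(as.numeric(base_freqs), DNA_BASES)),
            class = "sim_config")
}

DNA_BASES <- c("A", "C", "G", "T")

# Draw the waiting time to the next coalescence for k lineages starting at
# time t0 (generations bp) under a piecewise-constant model, by inverse-CDF
# time rescaling across epochs: spend Exp(1) hazard at rate k(k-1)/(2 Nef).
coal_waiting_time <- function(model, t0, k) {
  e <- stats::rexp(1)
  rate_const <- k * (k - 1) / 2
  t <- t0
  bounds <- c(model$change_times, Inf)
  repeat {
    i <- findInterval(t, model$change_times) + 1L
    rate <- rate_const / model$sizes[i]
    need <- e / rate
    if (t + need <= bounds[i]) return(t + need)
    e <- e - (bounds[i] - t) * rate
    t <- bounds[i]
  }
}

# Assemble an ape "phylo" from per-lineage newick fragments.
merge_newick <- function(s1, h1, s2, h2, h) {
  sprintf("(%s:%.12g,%s:%.12g)", s1, h - h1, s2, h - h2)
}

#' Simulate a coalescent genealogy under variable population size
#'
#' Standard (Kingman) coalescent with time rescaling through the epochs of a
#' piecewise-constant Nef history.  All tips are sampled at the present; the
#' returned tree is rooted, binary and ultrametric with branch lengths in
#' generations.
#'
#' @param model a [demographic_model()].
#' @param n number of tips (>= 2).
#' @param seed optional integer seed (the caller's RNG stream is preserved).
#' @param tip_labels optional character vector of tip names.
#' @return an `ape::phylo` tree.
#' @examples
#' tr <- simulate_genealogy(demographic_model(1000), n = 8, seed = 1)
#' ape::is.ultrametric(tr)
#' @export
simulate_genealogy <- function(model, n, seed = NULL, tip_labels = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  if (n < 2) stop("need at least 2 tips to coalesce", call. = FALSE)
  n <- as.integer(n)
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n))
  stopifnot(length(tip_labels) == n)
  with_seed(seed, {
    frag <- as.list(tip_labels)
    height <- numeric(n)
    t <- 0
    for (k in n:2) {
      t <- coal_waiting_time(model, t, k)
      pair <- sample.int(length(frag), 2L)
      merged <- merge_newick(frag[[pair[1]]], height[pair[1]],
                             frag[[pair[2]]], height[pair[2]], t)
      frag <- c(frag[-pair], list(merged))
      height <- c(height[-pair], t)
    }
    ape::read.tree(text = paste0(frag[[1]], ";"))
  })
}

#' Simulate a structured coalescent genealogy across demes
#'
#' Lineages coalesce only within demes and migrate between demes at the
#' backward (lineage-tracing) rates of `mig`.  Each deme has its own
#' piecewise-constant Nef history.  Waiting times use competing exponentials
#' with rates held constant between epoch boundaries.
#'
#' @param models list of [demographic_model()] objects, one per deme.
#' @param mig square matrix of per-generation backward migration rates;
#'   the diagonal is ignored.
#' @param n_per_deme integer tip counts per deme.
#' @param seed optional integer seed.
#' @param max_events cap on total events before declaring non-coalescence
#'   (guards against disconnected migration graphs).
#' @return an `ape::phylo` with attribute `"demes"`: a named vector giving
#'   each tip's deme of sampling.
#' @export
simulate_structured_genealogy <- function(models, mig, n_per_deme, seed = NULL,
                                          max_events = 1e6) {
  ndeme <- length(models)
  if (ndeme < 2) stop("need at least 2 demes", call. = FALSE)
  stopifnot(is.matrix(mig), nrow(mig) == ndeme, ncol(mig) == ndeme,
            length(n_per_deme) == ndeme)
  mig <- as.matrix(mig)
  diag(mig) <- 0
  if (any(mig < 0)) stop("migration rates must be nonnegative", call. = FALSE)
  for (m in models) stopifnot(inherits(m, "demographic_model"))

  tips <- unlist(lapply(seq_len(ndeme), function(d)
    paste0("d", d, "_s", seq_len(n_per_deme[d]))))
  demes_of_tip <- stats::setNames(rep(seq_len(ndeme), n_per_deme), tips)

  with_seed(seed, {
    frag <- as.list(tips)
    height <- numeric(length(tips))
    deme <- rep(seq_len(ndeme), n_per_deme)
    t <- 0
    events <- 0L
    all_bounds <- sort(unique(unlist(lapply(models, `[[`, "change_times"))))
    while (length(frag) > 1L) {
      kd <- tabulate(deme, nbins = ndeme)
      nef <- vapply(seq_len(ndeme), function(d) nef_at(models[[d]], t), 0)
      coal_rates <- kd * (kd - 1) / (2 * nef)
      mig_out <- rowSums(mig)[deme]              # per-lineage emigration rate
      total <- sum(coal_rates) + sum(mig_out)
      nb <- all_bounds[all_bounds > t][1]
      if (total <= 0) {
        if (is.na(nb)) {
          stop("lineages cannot reach a common ancestor: migration graph ",
               "leaves demes disconnected", call. = FALSE)
        }
        t <- nb
        next
      }
      w <- stats::rexp(1, total)
      if (!is.na(nb) && t + w > nb) {
        t <- nb
        next
      }
      t <- t + w
      events <- events + 1L
      if (events > max_events) {
        stop("event cap exceeded before common ancestry; migration matrix ",
             "too weakly connected", call. = FALSE)
      }
      u <- stats::runif(1, 0, total)
      if (u < sum(coal_rates)) {
        d <- sample.int(ndeme, 1L, prob = coal_rates)
        idx <- which(deme == d)
        pair <- idx[sample.int(length(idx), 2L)]
        merged <- merge_newick(frag[[pair[1]]], height[pair[1]],
                               frag[[pair[2]]], height[pair[2]], t)
        keep <- setdiff(seq_along(frag), pair)
        frag <- c(frag[keep], list(merged))
        height <- c(height[keep], t)
        deme <- c(deme[keep], d)
      } else {
        l <- sample.int(length(frag), 1L, prob = mig_out)
        deme[l] <- sample.int(ndeme, 1L, prob = mig[deme[l], ])
      }
    }
    tr <- ape::read.tree(text = paste0(frag[[1]], ";"))
    attr(tr, "demes") <- demes_of_tip[tr$tip.label]
    tr
  })
}

# HKY85 machinery ------------------------------------------------------------

# Rate matrix scaled to one expected substitution per unit time.
hky_rate_matrix <- function(kappa, base_freqs) {
  p <- as.numeric(base_freqs)
  Q <- matrix(rep(p, each = 4), 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  transitions <- rbind(c(1, 3), c(3, 1), c(2, 4), c(4, 2))  # A<->G, C<->T
  Q[transitions] <- Q[transitions] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q / sum(-diag(Q) * p)
}

# Exact HKY transition probabilities P(t) = expm(Q t), via the symmetric
# similarity transform available for any reversible rate matrix.
hky_transition_probs <- function(Q, base_freqs, t) {
  p <- as.numeric(base_freqs)
  sq <- sqrt(p)
  S <- diag(sq) %*% Q %*% diag(1 / sq)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  P <- diag(1 / sq) %*% e$vectors %*% diag(exp(e$values * t)) %*%
    t(e$vectors) %*% diag(sq)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Median rates of the 4-category discrete gamma, normalised to mean 1.
discrete_gamma_rates <- function(shape, ncat = 4L) {
  if (!is.finite(shape)) return(rep(1, ncat))
  r <- stats::qgamma((2 * seq_len(ncat) - 1) / (2 * ncat),
                     shape = shape, rate = shape)
  r / mean(r)
}

#' Evolve sequences along a genealogy under HKY+Gamma
#'
#' Sites evolve independently under the HKY85 substitution model with
#' 4-category discrete-gamma rate heterogeneity (median category rates).
#' States are propagated from the root using exact HKY transition
#' probabilities per branch, so multiple hits are handled without
#' approximation.  Branch lengths in generations are converted to expected
#' substitutions per site through `mu * generation_years`.
#'
#' @param tree genealogy (`phylo`) with branch lengths in generations.
#' @param cfg a [sim_config()].
#' @param root_seq optional root sequence (character vector of A/C/G/T of
#'   length `cfg$seq_length`); drawn from `cfg$base_freqs` if missing.
#' @param motif optional data frame with columns `pos` (1-based simulator
#'   coordinate) and `allele`; applied to the root before evolving, which
#'   plants a haplogroup-defining motif at the ancestor.
#' @param seed optional integer seed.
#' @return character matrix (tips x sites) of bases, with attributes
#'   `"root_seq"` and `"rate_category"`.
#' @export
evolve_sequences <- function(tree, cfg, root_seq = NULL, motif = NULL,
                             seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(cfg, "sim_config"))
  L <- cfg$seq_length
  with_seed(seed, {
    if (is.null(root_seq)) {
      root_seq <- sample(DNA_BASES, L, replace = TRUE, prob = cfg$base_freqs)
    }
    root_seq <- toupper(root_seq)
    stopifnot(length(root_seq) == L, all(root_seq %in% DNA_BASES))
    if (!is.null(motif)) {
      if (any(motif$pos < 1 | motif$pos > L)) {
        stop("motif position outside the simulated sequence", call. = FALSE)
      }
      root_seq[motif$pos] <- toupper(as.character(motif$allele))
    }
    rates <- discrete_gamma_rates(cfg$gamma_shape)
    cat_of_site <- sample.int(length(rates), L, replace = TRUE)
    Q <- hky_rate_matrix(cfg$kappa, cfg$base_freqs)
    scale <- cfg$mu * cfg$generation_years  # generations -> expected subs/site

    tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
    ntip <- length(tree$tip.label)
    nnode <- tree$Nnode
    states <- matrix(NA_integer_, ntip + nnode, L)
    root <- ntip + 1L
    states[root, ] <- match(root_seq, DNA_BASES)
    for (i in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[i, 1]
      child <- tree$edge[i, 2]
      b <- tree$edge.length[i] * scale
      kid <- states[parent, ]
      if (b > 0) {
        for (cc in seq_along(rates)) {
          sites <- which(cat_of_site == cc)
          if (!length(sites)) next
          P <- hky_transition_probs(Q, cfg$base_freqs, b * rates[cc])
          cum <- t(apply(P, 1, cumsum))
          u <- stats::runif(length(sites))
          kid[sites] <- rowSums(u > cum[states[parent, sites], , drop = FALSE]) + 1L
        }
      }
      states[child, ] <- kid
    }
    out <- matrix(DNA_BASES[states[seq_len(ntip), ]], ntip, L,
                  dimnames = list(tree$tip.label, NULL))
    attr(out, "root_seq") <- root_seq
    attr(out, "rate_category") <- cat_of_site
    out
  })
}

#' Generate a complete synthetic study fixture
#'
#' Builds an mtDNA-control-region-like dataset for a multi-population study
#' design: per population a haplogroup mixture, a demographic history, and a
#' sample size.  Within each population, samples are allocated to haplogroups
#' by multinomial draw; each haplogroup cluster descends from a genealogy
#' simulated under the population's Nef history, with the haplogroup's
#' diagnostic motif planted at the cluster root.  All coordinates follow the
#' simulator's concatenated control-region layout (see
#' [control_region_reference()]).
#'
#' @param scenario a list with elements
#'   * `populations`: list of per-population lists with fields `name`, `n`,
#'     `mixture` (named haplogroup proportions summing to 1), `model`
#'     (a [demographic_model()]), and optionally `region`, `language`,
#'     `lat`, `lon`;
#'   * `motifs`: a motif table as returned by [read_motif_table()] or
#'     [default_motif_table()] (positions in reference coordinates);
#'   * `cfg`: optional [sim_config()].
#' @param seed master integer seed; per-population child seeds are derived by
#'   stable hashing of the population name.
#' @param out_dir optional directory; when given, writes `alignment.fasta`
#'   (70-column wrap), `metadata.tsv`, `genealogies.nwk` (branch lengths in
#'   generations) and `truth.json` (true mixtures, histories and labels).
#' @return invisibly, a list with `alignment`, `metadata`, `trees`,
#'   `truth`, and the `reference` used.
#' @export
make_study_fixture <- function(scenario, seed, out_dir = NULL) {
  cfg <- scenario$cfg %||% sim_config()
  ref <- control_region_reference(cfg$seq_length)
  motifs <- scenario$motifs %||% default_motif_table(ref)
  pops <- scenario$populations
  stopifnot(length(pops) >= 1)

  aln <- NULL
  meta <- NULL
  trees <- list()
  truth <- list(populations = list())
  for (pop in pops) {
    if (abs(sum(pop$mixture) - 1) > 1e-8) {
      stop(sprintf("haplogroup mixture for population %s does not sum to 1",
                   pop$name), call. = FALSE)
    }
    pseed <- stable_seed(seed, pop$name)
    hgs <- names(pop$mixture)
    counts <- with_seed(pseed, {
      as.vector(stats::rmultinom(1, pop$n, pop$mixture))
    })
    labels <- rep(hgs, counts)
    pop_aln <- matrix(NA_character_, 0, cfg$seq_length)
    sample_ids <- character(0)
    sample_hg <- character(0)
    for (j in seq_along(hgs)) {
      nh <- counts[j]
      if (nh == 0) next
      hg <- hgs[j]
      ids <- sprintf("%s_%s_%02d", pop$name, gsub("[^A-Za-z0-9]", "", hg),
                     seq_len(nh))
      motif_sim <- motif_to_sim_coords(motifs[[hg]], ref)
      hseed <- stable_seed(pseed, hg)
      if (nh == 1) {
        s <- ref$seq
        s[motif_sim$pos] <- motif_sim$allele
        seqs <- matrix(s, 1, cfg$seq_length, dimnames = list(ids, NULL))
      } else {
        tr <- simulate_genealogy(pop$model, nh, seed = hseed, tip_labels = ids)
        trees[[paste(pop$name, hg, sep = ":")]] <- tr
        seqs <- evolve_sequences(tr, cfg, root_seq = ref$seq,
                                 motif = motif_sim,
                                 seed = stable_seed(hseed, "seq"))
      }
      pop_aln <- rbind(pop_aln, seqs)
      sample_ids <- c(sample_ids, ids)
      sample_hg <- c(sample_hg, rep(hg, nh))
    }
    rownames(pop_aln) <- sample_ids
    aln <- rbind(aln, pop_aln)
    meta <- rbind(meta, data.frame(
      sample = sample_ids, population = pop$name,
      region = pop$region %||% "NA", language = pop$language %||% "NA",
      lat = pop$lat %||% NA_real_, lon = pop$lon %||% NA_real_,
      stringsAsFactors = FALSE))
    truth$populations[[pop$name]] <- list(
      n = pop$n, mixture = as.list(pop$mixture),
      realised_counts = stats::setNames(as.list(counts), hgs),
      model = list(sizes = pop$model$sizes,
                   change_times = pop$model$change_times),
      haplogroup = stats::setNames(as.list(sample_hg), sample_ids))
  }
  truth$seed <- seed
  truth$config <- unclass(cfg)

  out <- list(alignment = aln, metadata = meta, trees = trees, truth = truth,
              reference = ref)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(aln, file.path(out_dir, "alignment.fasta"))
    utils::write.table(meta, file.path(out_dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (length(trees)) {
      ape::write.tree(do.call(c, unname(trees)),
                      file.path(out_dir, "genealogies.nwk"))
    }
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

#' Write an alignment as wrapped FASTA
#'
#' @param aln character matrix (samples x sites).
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(aln, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    s <- paste(aln[i, ], collapse = "")
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
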