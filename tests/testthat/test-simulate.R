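test_that("demographic model validates its epochs and evaluates Nef(t)", {
  m <- demographic_model(c(1000, 100), 50)
  expect_equal(nef_at(m, c(0, 49.9, 50, 200)), c(1000, 1000, 100, 100))
  expect_error(demographic_model(c(0, 10), 5), "positive")
  expect_error(demographic_model(c(1, 2, 3), c(10, 5)), "increasing")
  expect_error(demographic_model(1000, 10), "change_times")
})

test_that("2-tip TMRCA under constant Nef is exponential with mean Nef", {
  N <- 500
  m <- demographic_model(N)
  set.seed(101)
  tm <- replicate(2000, max(ape::branching.times(simulate_genealogy(m, 2))))
  expect_lt(abs(mean(tm) - N) / N, 0.05)
  expect_gt(stats::ks.test(tm, "pexp", 1 / N)$p.value, 0.01)
})

test_that("near-infinite Nef still yields a valid ultrametric 2-tip tree", {
  tr <- simulate_genealogy(demographic_model(1e12), 2, seed = 1)
  expect_true(ape::is.ultrametric(tr))
  expect_identical(tr$Nnode, 1L)
  expect_gt(max(ape::branching.times(tr)), 1e9)
})

test_that("two-epoch mean TMRCA lies between the constant-size means", {
  set.seed(202)
  tmrca <- function(model) {
    mean(replicate(4000,
      max(ape::branching.times(simulate_genealogy(model, 10)))))
  }
  mid <- tmrca(demographic_model(c(1000, 100), 50))
  lo <- tmrca(demographic_model(100))
  hi <- tmrca(demographic_model(1000))
  expect_gt(mid, lo)
  expect_lt(mid, hi)
})

test_that("genealogy simulation is deterministic given a seed and rejects n < 2", {
  m <- demographic_model(800)
  t1 <- simulate_genealogy(m, 12, seed = 7)
  t2 <- simulate_genealogy(m, 12, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_error(simulate_genealogy(m, 1), "2 tips")
})

test_that("structured coalescent labels demes and errors without connectivity", {
  m <- demographic_model(100)
  tr <- simulate_structured_genealogy(list(m, m),
                                      matrix(c(0, 0.1, 0.1, 0), 2),
                                      c(4, 5), seed = 3)
  demes <- attr(tr, "demes")
  expect_identical(length(tr$tip.label), 9L)
  expect_equal(as.integer(table(demes)), c(4L, 5L))
  expect_true(ape::is.ultrametric(tr))
  expect_error(
    simulate_structured_genealogy(list(m, m), matrix(0, 2, 2), c(3, 3),
                                  seed = 4),
    "disconnected|common ancestor")
})

test_that("strong migration removes population structure (Phi-st near 0)", {
  cfg <- sim_config(mu = 4e-6, seq_length = 400, gamma_shape = Inf)
  phist_rep <- function(mrate, r) {
    mm <- matrix(c(0, mrate, mrate, 0), 2)
    tr <- simulate_structured_genealogy(
      list(demographic_model(50), demographic_model(50)), mm, c(8, 8),
      seed = 17000 * r + round(1e4 * mrate))
    aln <- evolve_sequences(tr, cfg, seed = 31000 * r + round(1e4 * mrate) + 1)
    demes <- attr(tr, "demes")
    mesodemog:::phist_components(difference_matrix(aln),
                                 demes[rownames(aln)])$phist
  }
  high_mig <- vapply(1:100, function(r) phist_rep(10, r), 0)
  expect_lt(abs(mean(high_mig)), 0.02)
  by_rate <- vapply(c(1, 0.1, 0.01), function(mr)
    mean(vapply(1:100, function(r) phist_rep(mr, r), 0)), 0)
  expect_true(all(diff(by_rate) > 0))  # Phi-st grows as migration falls
})

test_that("zero substitution rate reproduces the root sequence at every tip", {
  ref <- control_region_reference()
  tr <- simulate_genealogy(demographic_model(500), 6, seed = 5)
  aln <- evolve_sequences(tr, sim_config(mu = 1e-30), root_seq = ref$seq,
                          seed = 6)
  expect_true(all(aln == matrix(ref$seq, 6, length(ref$seq), byrow = TRUE)))
})

test_that("extreme transition bias produces only transitions", {
  cfg <- sim_config(mu = 2e-5, seq_length = 500, kappa = 1e9,
                    gamma_shape = Inf)
  tr <- simulate_genealogy(demographic_model(200), 6, seed = 1)
  root <- control_region_reference(500)$seq
  aln <- evolve_sequences(tr, cfg, root_seq = root, seed = 2)
  diffs <- which(aln != matrix(root, nrow(aln), 500, byrow = TRUE),
                 arr.ind = TRUE)
  expect_gt(nrow(diffs), 50)  # enough changes for the check to have teeth
  pur <- c("A", "G")
  pyr <- c("C", "T")
  is_transition <- mapply(function(i, j) {
    (root[j] %in% pur && aln[i, j] %in% pur) ||
      (root[j] %in% pyr && aln[i, j] %in% pyr)
  }, diffs[, 1], diffs[, 2])
  expect_true(all(is_transition))
})

test_that("planted motifs are carried by essentially all tips at low rate", {
  ref <- control_region_reference()
  motif <- mesodemog:::motif_to_sim_coords(default_motif_table()$A2, ref)
  cfg <- sim_config()  # default control-region rate: mu*t per site << 1e-3
  carried <- 0
  total <- 0
  for (r in 1:10) {
    tr <- simulate_genealogy(demographic_model(300), 20, seed = 7000 + r)
    aln <- evolve_sequences(tr, cfg, root_seq = ref$seq, motif = motif,
                            seed = 7100 + r)
    has_all <- apply(aln[, motif$pos, drop = FALSE], 1,
                     function(x) all(x == motif$allele))
    carried <- carried + sum(has_all)
    total <- total + length(has_all)
  }
  expect_gte(carried / total, 0.99)
  expect_error(
    evolve_sequences(tr, cfg, root_seq = ref$seq,
                     motif = data.frame(pos = 99999, allele = "T")),
    "position")
})

test_that("tip base composition stays at the stationary frequencies", {
  cfg <- sim_config()
  tr <- ape::read.tree(text = "(a:1000000,b:1000000);")
  aln <- evolve_sequences(tr, cfg, seed = 11)
  freqs <- table(factor(aln[1, ], levels = c("A", "C", "G", "T"))) / ncol(aln)
  se <- sqrt(cfg$base_freqs * (1 - cfg$base_freqs) / ncol(aln))
  expect_true(all(abs(freqs - cfg$base_freqs) <= 3 * se))
})

test_that("sequence evolution is byte-deterministic given seed and config", {
  tr <- simulate_genealogy(demographic_model(400), 10, seed = 21)
  cfg <- sim_config(mu = 1e-5, seq_length = 300)
  a1 <- evolve_sequences(tr, cfg, seed = 22)
  a2 <- evolve_sequences(tr, cfg, seed = 22)
  expect_identical(a1, a2)
})

test_that("HKY transition probabilities match a brute-force matrix exponential", {
  p <- c(0.31, 0.33, 0.13, 0.23)
  Q <- mesodemog:::hky_rate_matrix(20, p)
  for (t in c(0.01, 0.2, 1.5)) {
    P <- mesodemog:::hky_transition_probs(Q, p, t)
    # series expansion oracle
    Pser <- diag(4)
    term <- diag(4)
    for (k in 1:60) {
      term <- term %*% (Q * t) / k
      Pser <- Pser + term
    }
    expect_equal(unname(P), unname(Pser), tolerance = 1e-10)
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
  }
  # stationarity: pi Q = 0 and pi P = pi
  expect_equal(as.numeric(p %*% Q), rep(0, 4), tolerance = 1e-12)
})

test_that("study fixtures honour the requested design and are reproducible", {
  pops <- list(
    list(name = "PopA", n = 30,
         mixture = c(A2 = 0.5, B2 = 0.3, C1 = 0.2),
         model = demographic_model(300), region = "West", language = "L1",
         lat = 20, lon = -103),
    list(name = "PopB", n = 20,
         mixture = c(A2 = 0.6, D1 = 0.4),
         model = demographic_model(300), region = "Maya", language = "L2",
         lat = 19, lon = -89))
  scen <- list(populations = pops, cfg = sim_config(seq_length = 300))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- make_study_fixture(scen, seed = 42, out_dir = d1)
  fx2 <- make_study_fixture(scen, seed = 42, out_dir = d2)
  expect_identical(nrow(fx1$alignment), 50L)
  expect_identical(fx1$metadata$population, rep(c("PopA", "PopB"), c(30, 20)))
  for (f in c("alignment.fasta", "metadata.tsv", "genealogies.nwk",
              "truth.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  expect_error(
    make_study_fixture(list(populations = list(list(
      name = "X", n = 5, mixture = c(A2 = 0.7), model = demographic_model(10)
    ))), seed = 1),
    "sum to 1")
})

test_that("single-sample populations yield sequences without a genealogy", {
  scen <- list(populations = list(list(
    name = "Solo", n = 1, mixture = c(A2 = 1),
    model = demographic_model(100))), cfg = sim_config(seq_length = 200))
  fx <- make_study_fixture(scen, seed = 9)
  expect_identical(nrow(fx$alignment), 1L)
  expect_length(fx$trees, 0)
})

test_that("fixture haplogroup counts follow the requested mixture", {
  # column mixtures shaped like an eight-population founding-lineage table
  mixes <- list(
    Maya_qr = c(A2 = .649, B2 = .162, C1 = .149, D1 = .040),
    Maya_y = c(A2 = .655, B2 = .125, B4b1 = .025, C1 = .125, D1 = .070),
    Maya_c = c(A2 = .703, B2 = .054, C1 = .189, D1 = .054),
    Tzotzil = c(A2 = .414, B2 = .241, C1 = .253, D4h3a = .092),
    Tojolabal = c(A2 = .257, B2 = .581, D1 = .162),
    Mazateco = c(A2 = .537, B2 = .341, C1 = .024, D4h3a = .098),
    Purepecha = c(A2 = .831, B2 = .015, C1 = .108, D1 = .046),
    Huichol = c(A2 = .255, B2 = .275, C1 = .470))
  ns <- c(74, 40, 37, 87, 74, 41, 65, 102)
  pops <- lapply(seq_along(mixes), function(i) {
    mx <- mixes[[i]] / sum(mixes[[i]])
    list(name = names(mixes)[i], n = ns[i], mixture = mx,
         model = demographic_model(200))
  })
  fx <- make_study_fixture(list(populations = pops,
                                cfg = sim_config(seq_length = 200)),
                           seed = 77)
  for (i in seq_along(pops)) {
    truth <- fx$truth$populations[[pops[[i]]$name]]
    counts <- unlist(truth$realised_counts)
    expect_identical(sum(counts), as.integer(ns[i]))
    gof <- suppressWarnings(
      stats::chisq.test(counts, p = pops[[i]]$mixture))
    expect_gt(gof$p.value, 0.001)
  }
})
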