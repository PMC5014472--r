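test_that("identical seeds give byte-identical FASTA output", {
  cfg <- small_sim_config(41, n_sites = 40)
  s1 <- simulate_alignment(cfg)
  s2 <- simulate_alignment(cfg)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_codon_alignment(s1$alignment, f1)
  write_codon_alignment(s2$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$truth, s2$truth)
  # a different seed changes the draw
  cfg2 <- small_sim_config(42, n_sites = 40)
  s3 <- simulate_alignment(cfg2)
  expect_false(identical(s1$alignment$codons, s3$alignment$codons))
})

test_that("zero branch lengths copy the root sequence to every tip", {
  tree <- parse_tree(text = "((a1:0,a2:0):0,(b1:0,b2:0):0);")
  scheme <- assign_partitions(tree, c("a1", "a2"), c("b1", "b2"))
  cfg <- simulation_config(
    tree, scheme,
    partition_omegas = list(
      EGV1 = omega_distribution(0.2, 1, p1 = 0.8, p2 = 0.2),
      EGV2 = omega_distribution(0.3, 1, p1 = 0.6, p2 = 0.4),
      CONNECTING = omega_distribution(0.05, 1, p1 = 0.75, p2 = 0.25)),
    exch = test_exch(), pos_freqs = test_pos_freqs(), n_sites = 50, seed = 5)
  sim <- simulate_alignment(cfg)
  seqs <- apply(sim$alignment$codons, 1, paste, collapse = "")
  expect_length(unique(seqs), 1)
  code <- genetic_code()
  expect_identical(unname(sim$alignment$codons[1, ]),
                   code$codons[sim$truth$root_states])
})

test_that("no stop codons are ever produced", {
  sim <- simulate_alignment(small_sim_config(43, n_sites = 100))
  code <- genetic_code()
  expect_false(any(sim$alignment$codons %in% code$stops))
})

test_that("category draws match the partition mixture weights", {
  cfg <- small_sim_config(44, n_a = 6, n_b = 6, n_sites = 400)
  sim <- simulate_alignment(cfg)
  et <- egvselect:::edges_with_labels(sim$tree, sim$scheme)
  for (lab in c("EGV1", "EGV2")) {
    cols <- which(et$edges$label == lab)
    draws <- sim$truth$categories[, cols]
    w <- cfg$partition_omegas[[lab]]$weights
    freq <- tabulate(draws, nbins = 3) / length(draws)
    se <- sqrt(w * (1 - w) / length(draws))
    expect_true(all(abs(freq - w) <= pmax(4 * se, 1e-3)))
  }
})

test_that("a long branch renders the child distribution stationary", {
  # single very long branch: child codon frequencies match pi (chi-square GOF)
  tree <- parse_tree(text = "(a1:0.01,a2:0.01,(b1:0.01,b2:100):0.01);")
  scheme <- assign_partitions(tree, c("a1", "a2"), c("b1", "b2"))
  pf <- test_pos_freqs()
  cfg <- simulation_config(
    tree, scheme,
    partition_omegas = list(
      EGV1 = omega_distribution(0.2, 1, p1 = 0.8, p2 = 0.2),
      EGV2 = omega_distribution(0.3, 1, p1 = 0.6, p2 = 0.4),
      CONNECTING = omega_distribution(0.05, 1, p1 = 0.75, p2 = 0.25)),
    exch = test_exch(), pos_freqs = pf, n_sites = 6000, seed = 46)
  sim <- simulate_alignment(cfg)
  pi <- cf3x4_frequencies(pf)
  obs <- table(factor(sim$alignment$codons["b2", ], levels = names(pi)))
  gof <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = pi))
  expect_gt(gof$p.value, 0.01)
})

test_that("simulator and likelihood agree on which parameters generated the data", {
  sim <- simulate_alignment(small_sim_config(47, n_a = 5, n_b = 5,
                                             n_sites = 400))
  truth <- params_from_mixtures(
    list(EGV1 = omega_distribution(0.2, 1, p1 = 0.8, p2 = 0.2),
         EGV2 = omega_distribution(0.3, 1, p1 = 0.6, p2 = 0.4),
         CONNECTING = omega_distribution(0.05, 1, p1 = 0.75, p2 = 0.25)),
    test_exch(), test_pos_freqs())
  ll_true <- total_log_likelihood(sim$alignment, sim$tree, sim$scheme, truth)
  set.seed(48)
  worse <- 0
  for (r in 1:5) {
    pert <- params_from_mixtures(
      list(EGV1 = omega_distribution(runif(1), 1 + rexp(1), p1 = runif(1, 0, 0.6),
                                     p2 = 0.2),
           EGV2 = omega_distribution(runif(1), 1 + rexp(1), p1 = runif(1, 0, 0.6),
                                     p2 = 0.2),
           CONNECTING = omega_distribution(runif(1), 1 + rexp(1),
                                           p1 = runif(1, 0, 0.6), p2 = 0.2)),
      test_exch(), test_pos_freqs())
    if (total_log_likelihood(sim$alignment, sim$tree, sim$scheme, pert) <
        ll_true) worse <- worse + 1
  }
  expect_gte(worse, 4)
})

test_that("simulation config validation catches bad inputs", {
  tree <- quartet_tree()
  scheme <- quartet_scheme(tree)
  om <- list(EGV1 = omega_distribution(0.2, 1, p1 = 0.8, p2 = 0.2),
             EGV2 = omega_distribution(0.3, 1, p1 = 0.6, p2 = 0.4),
             CONNECTING = omega_distribution(0.05, 1, p1 = 0.75, p2 = 0.25))
  expect_error(simulation_config(tree, scheme, om, test_exch(),
                                 test_pos_freqs(), n_sites = 0, seed = 1),
               "n_sites")
  expect_error(simulation_config(tree, scheme, om[-1], test_exch(),
                                 test_pos_freqs(), n_sites = 10, seed = 1),
               "partition")
  expect_error(simulation_config(tree, scheme, om, test_exch(),
                                 test_pos_freqs(), n_sites = 10),
               "seed")
})
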