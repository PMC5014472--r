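test_that("zero-length star tree gives log pi for a constant column", {
  tree <- parse_tree(text = "(x1:0,x2:0,x3:0);")
  et <- egvselect:::edge_table(tree)
  scheme <- structure(list(
    assignment = data.frame(id = et$edges$id, label = "P1"),
    labels = "P1", roles = NULL), class = "partition_scheme")
  pf <- test_pos_freqs()
  params <- model_parameters(
    exch = test_exch(), pos_freqs = pf,
    groups = list(P1 = list(classes = c("w1", "w2"), omega1 = 0.3, p1 = 0.5)))
  aln <- codon_alignment(c(x1 = "AAA", x2 = "AAA", x3 = "AAA"))
  pi <- cf3x4_frequencies(pf)
  expect_equal(site_log_likelihood(aln, tree, scheme, params),
               log(unname(pi["AAA"])), tolerance = 1e-12)
})

test_that("pruning equals brute-force marginalisation on the quartet", {
  tree <- quartet_tree()
  scheme <- quartet_scheme(tree)
  params <- quartet_params()
  cols <- list(c(a1 = "ATG", a2 = "ATG", b1 = "ATG", b2 = "CTG"),
               c(a1 = "AAA", a2 = "AAC", b1 = "GAA", b2 = "AAA"),
               c(a1 = "TTT", a2 = "TTC", b1 = "TTA", b2 = "CTT"))
  for (col in cols) {
    aln <- codon_alignment(col)
    pruned <- site_log_likelihood(aln, tree, scheme, params)
    brute <- brute_force_site_loglik(tree, scheme, quartet_mixtures(),
                                     test_exch(), test_pos_freqs(), col)
    expect_equal(pruned, brute, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to the rooting used for pruning", {
  sim <- simulate_alignment(small_sim_config(5, n_sites = 30))
  params <- params_from_mixtures(
    list(EGV1 = omega_distribution(0.2, 1.5, p1 = 0.6, p2 = 0.3),
         EGV2 = omega_distribution(0.4, 2, p1 = 0.3, p2 = 0.4),
         CONNECTING = omega_distribution(0.1, 1.2, p1 = 0.5, p2 = 0.3)),
    test_exch(), test_pos_freqs())
  ll0 <- total_log_likelihood(sim$alignment, sim$tree, sim$scheme, params)
  for (tip in c("a1", "b2")) {
    rerooted <- ape::root(sim$tree, outgroup = tip, resolve.root = TRUE)
    ll <- total_log_likelihood(sim$alignment, rerooted, sim$scheme, params)
    expect_equal(ll, ll0, tolerance = 1e-10)
  }
})

test_that("duplicating a column adds exactly its site log-likelihood", {
  tree <- quartet_tree()
  scheme <- quartet_scheme(tree)
  params <- quartet_params()
  aln1 <- codon_alignment(c(a1 = "ATGAAA", a2 = "ATGAAC",
                            b1 = "ATGCAA", b2 = "CTGAAA"))
  aln2 <- codon_alignment(c(a1 = "ATGAAAAAA", a2 = "ATGAACAAC",
                            b1 = "ATGCAACAA", b2 = "CTGAAAAAA"))
  ll1 <- site_log_likelihood(aln1, tree, scheme, params)
  ll2 <- total_log_likelihood(aln2, tree, scheme, params)
  expect_equal(ll2, sum(ll1) + ll1[2], tolerance = 1e-9)
  # total equals the sum of per-site values
  expect_equal(total_log_likelihood(aln1, tree, scheme, params), sum(ll1),
               tolerance = 1e-9)
})

test_that("pattern compression does not change per-site values", {
  sim <- simulate_alignment(small_sim_config(6, n_sites = 60))
  params <- params_from_mixtures(
    list(EGV1 = omega_distribution(0.2, 1, p1 = 0.8, p2 = 0.2),
         EGV2 = omega_distribution(0.3, 1, p1 = 0.6, p2 = 0.4),
         CONNECTING = omega_distribution(0.05, 1, p1 = 0.75, p2 = 0.25)),
    test_exch(), test_pos_freqs())
  ll <- site_log_likelihood(sim$alignment, sim$tree, sim$scheme, params)
  # recompute each duplicated pattern column in isolation
  keys <- apply(sim$alignment$codons, 2, paste, collapse = "|")
  dup <- which(duplicated(keys))[1]
  skip_if(is.na(dup), "no duplicated pattern in this simulation")
  orig <- match(keys[dup], keys)
  expect_identical(ll[dup], ll[orig])
})

test_that("gaps and ambiguity codes act as partial missing data", {
  tree <- quartet_tree()
  scheme <- quartet_scheme(tree)
  params <- quartet_params()
  base <- codon_alignment(c(a1 = "ATG", a2 = "ATG", b1 = "ATG", b2 = "CTG"))
  ll_base <- site_log_likelihood(base, tree, scheme, params)
  # fully missing codon marginalises over all states: likelihood rises
  gapped <- codon_alignment(c(a1 = "ATG", a2 = "---", b1 = "ATG", b2 = "CTG"))
  ll_gap <- site_log_likelihood(gapped, tree, scheme, params)
  expect_gt(ll_gap, ll_base)
  # ambiguity restricted to the true state set: likelihood between the two
  amb <- codon_alignment(c(a1 = "ATG", a2 = "ATR", b1 = "ATG", b2 = "CTG"))
  ll_amb <- site_log_likelihood(amb, tree, scheme, params)
  expect_gt(ll_amb, ll_base - 1e-12)
  expect_lt(ll_amb, ll_gap)
  # the ambiguous-likelihood is the sum over compatible completions
  lA <- site_log_likelihood(codon_alignment(
    c(a1 = "ATG", a2 = "ATA", b1 = "ATG", b2 = "CTG")), tree, scheme, params)
  expect_equal(exp(ll_amb), exp(ll_base) + exp(lA), tolerance = 1e-12)
})

test_that("stop codons and tip mismatches produce instructive errors", {
  tree <- quartet_tree()
  scheme <- quartet_scheme(tree)
  params <- quartet_params()
  expect_error(codon_alignment(c(a1 = "TAA", a2 = "ATG", b1 = "ATG",
                                 b2 = "CTG")), "screening")
  aln <- codon_alignment(c(a1 = "ATG", a2 = "ATG", b1 = "ATG", zz = "CTG"))
  expect_error(total_log_likelihood(aln, tree, scheme, params), "zz")
  aln2 <- codon_alignment(c(a1 = "ATG", a2 = "ATG", b1 = "ATG"))
  expect_error(total_log_likelihood(aln2, tree, scheme, params), "b2")
})
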