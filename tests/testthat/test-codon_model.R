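test_that("universal genetic code has 61 sense codons indexed lexicographically", {
  gc <- genetic_code()
  expect_length(gc$codons, 61)
  expect_setequal(gc$stops, c("TAA", "TAG", "TGA"))
  expect_identical(gc$codons[1], "AAA")
  expect_identical(gc$codons[61], "TTT")
  expect_identical(gc$codons, sort(gc$codons))
  expect_identical(unname(gc$index[gc$codons]), 1:61)
})

test_that("CF3x4 reduces to uniform under uniform positional frequencies", {
  pf <- positional_frequencies(matrix(0.25, 3, 4))
  expect_equal(unname(cf3x4_frequencies(pf)), rep(1 / 61, 61), tolerance = 1e-14)
})

test_that("CF3x4 zeroes codons whose first position has frequency zero", {
  pf <- positional_frequencies(rbind(c(0.4, 0.3, 0.3, 0), rep(0.25, 4),
                                     rep(0.25, 4)))
  pi <- cf3x4_frequencies(pf)
  startsT <- startsWith(names(pi), "T")
  expect_true(all(pi[startsT] == 0))
  expect_true(all(pi[!startsT] > 0))
  expect_equal(sum(pi), 1)
})

test_that("CF3x4 matches explicit enumeration over 64 codons minus stops", {
  pf <- positional_frequencies(rbind(c(.4, .3, .2, .1), rep(.25, 4),
                                     c(.1, .2, .3, .4)))
  # direct enumeration, independent of the implementation's index machinery
  nucs <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(nucs, nucs, paste0), nucs, paste0))
  prod64 <- vapply(all64, function(cd) {
    p <- strsplit(cd, "")[[1]]
    pf[1, p[1]] * pf[2, p[2]] * pf[3, p[3]]
  }, numeric(1))
  sense <- setdiff(sort(all64), c("TAA", "TAG", "TGA"))
  expected <- prod64[sense] / sum(prod64[sense])
  expect_equal(cf3x4_frequencies(pf), expected, tolerance = 1e-14)
})

test_that("degenerate positional frequencies are rejected", {
  pf <- matrix(c(1, 0, 0, 0,
                 0, 0, 0, 1,
                 1, 0, 0, 0), 3, 4, byrow = TRUE)
  # ATA is a sense codon, so this combination is fine
  expect_silent(cf3x4_frequencies(positional_frequencies(pf)))
  # T's only possible products are the stops TAA/TGA-like patterns
  pf2 <- matrix(c(0, 0, 0, 1,    # pos1: T
                  1, 0, 0, 0,    # pos2: A
                  1, 0, 0, 0), 3, 4, byrow = TRUE)  # pos3: A -> TAA only
  expect_error(cf3x4_frequencies(positional_frequencies(pf2)), "unusable")
  expect_error(positional_frequencies(matrix(0.3, 3, 4)), "sum to 1")
})

test_that("rate matrix forbids multi-nucleotide steps and is a generator", {
  pf <- test_pos_freqs()
  pi <- cf3x4_frequencies(pf)
  Q <- build_rate_matrix(test_exch(), pi, pf, omega = 0.5)
  expect_equal(Q["AAA", "ACC"], 0)
  expect_equal(Q["AAA", "CCA"], 0)
  expect_true(Q["AAA", "AAC"] > 0)
  expect_lt(max(abs(rowSums(Q))), 1e-10)
})

test_that("rate matrix satisfies detailed balance for random parameters", {
  set.seed(11)
  for (rep in 1:5) {
    pf <- positional_frequencies(t(replicate(3, {
      x <- runif(4, 0.1, 1); x / sum(x)
    })))
    pi <- cf3x4_frequencies(pf)
    ex <- rexp(5) + 0.1
    Q <- build_rate_matrix(ex, pi, pf, omega = runif(1, 0, 3))
    flux <- pi * Q
    expect_lt(max(abs(flux - t(flux))), 1e-14)
  }
})

test_that("neutral scaling gives mean rate 1 and is shared across omegas", {
  pf <- test_pos_freqs()
  pi <- cf3x4_frequencies(pf)
  Q1 <- build_rate_matrix(test_exch(), pi, pf, omega = 1)
  expect_equal(-sum(pi * diag(Q1)), 1, tolerance = 1e-12)
  # a shared constant means omega = 0.5 halves only nonsynonymous flux,
  # so its mean rate sits strictly between 0.5 and 1
  Qh <- build_rate_matrix(test_exch(), pi, pf, omega = 0.5)
  r <- -sum(pi * diag(Qh))
  expect_gt(r, 0.5); expect_lt(r, 1)
})

test_that("transition matrix is stochastic, identity at t = 0, pi at large t", {
  pf <- test_pos_freqs()
  pi <- cf3x4_frequencies(pf)
  Q <- build_rate_matrix(test_exch(), pi, pf, omega = 0.7)
  expect_equal(transition_matrix(Q, 0, pi), diag(61) + 0 * Q,
               ignore_attr = TRUE, tolerance = 1e-12)
  P <- transition_matrix(Q, 0.37, pi)
  expect_true(all(P >= 0))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  Pinf <- transition_matrix(Q, 1000, pi)
  expect_lt(max(abs(sweep(Pinf, 2, pi))), 1e-6)
  expect_error(transition_matrix(Q, -0.1, pi), "non-negative")
})

test_that("symmetric-transform exponential agrees with Matrix::expm", {
  skip_if_not_installed("Matrix")
  pf <- test_pos_freqs()
  pi <- cf3x4_frequencies(pf)
  Q <- build_rate_matrix(test_exch(), pi, pf, omega = 0.4)
  t <- 0.21
  ours <- transition_matrix(Q, t, pi)
  ref <- as.matrix(Matrix::expm(Q * t))
  expect_equal(ours, ref, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("branch mixture matrix is the convex combination of its categories", {
  pf <- test_pos_freqs()
  pi <- cf3x4_frequencies(pf)
  t <- 0.3
  # p1 = 1 collapses to the omega1 matrix alone
  d1 <- omega_distribution(0.2, 3, p1 = 1, p2 = 0)
  P1 <- branch_mixture_matrix(d1, test_exch(), pf, t)
  Q02 <- build_rate_matrix(test_exch(), pi, pf, 0.2)
  expect_equal(P1, transition_matrix(Q02, t, pi), tolerance = 1e-12)
  # omega1 = omega3 = 1 is neutral regardless of the weights
  dn <- omega_distribution(1, 1, p1 = 0.3, p2 = 0.3)
  Pn <- branch_mixture_matrix(dn, test_exch(), pf, t)
  Q1 <- build_rate_matrix(test_exch(), pi, pf, 1)
  expect_equal(Pn, transition_matrix(Q1, t, pi), tolerance = 1e-12)
  # general mixture: stochastic, entries within the component envelope
  d <- omega_distribution(0.1, 2.5, p1 = 0.5, p2 = 0.2)
  P <- branch_mixture_matrix(d, test_exch(), pf, t)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  comps <- lapply(c(0.1, 1, 2.5), function(w)
    transition_matrix(build_rate_matrix(test_exch(), pi, pf, w), t, pi))
  lo <- pmin(comps[[1]], comps[[2]], comps[[3]])
  hi <- pmax(comps[[1]], comps[[2]], comps[[3]])
  expect_true(all(P >= lo - 1e-12 & P <= hi + 1e-12))
  # all category matrices share the stationary distribution
  expect_lt(max(abs(pi %*% P - pi)), 1e-9)
})

test_that("omega distribution invariants are enforced", {
  expect_error(omega_distribution(1.2, 2, p1 = 0.5), "omega1")
  expect_error(omega_distribution(0.5, 0.8, p1 = 0.5), "omega3")
  expect_error(omega_distribution(0.5, 2, p1 = 0.7, p2 = 0.5), "exceed 1")
  d <- omega_distribution(0.5, 2, p1 = 0.6, p2 = 0.4)
  expect_equal(sum(d$weights), 1)
})
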