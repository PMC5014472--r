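# Independent oracles. The brute-force site likelihood marginalises the
# internal-node states by explicit enumeration, using mixture matrices
# built through the R-level branch_mixture_matrix() path — it never touches
# the pruning code.

brute_force_site_loglik <- function(tree, scheme, mixtures, exch, pos_freqs,
                                    tip_codons) {
  code <- genetic_code()
  pi <- cf3x4_frequencies(pos_freqs, code)
  et <- egvselect:::edges_with_labels(tree, scheme)
  tr <- et$tree
  ed <- et$edges
  Ps <- lapply(seq_len(nrow(ed)), function(k)
    branch_mixture_matrix(mixtures[[ed$label[k]]], exch, pos_freqs,
                          ed$length[k], code))
  ntip <- length(tr$tip.label)
  nint <- tr$Nnode
  tip_state <- match(tip_codons[tr$tip.label], code$codons)
  stopifnot(!anyNA(tip_state))
  # enumerate all joint internal-state assignments, vectorised over the grid
  grid <- as.matrix(expand.grid(rep(list(seq_along(code$codons)), nint)))
  root <- ntip + 1L
  state_col <- function(node) {
    if (node <= ntip) rep(tip_state[node], nrow(grid)) else grid[, node - ntip]
  }
  vals <- pi[state_col(root)]
  for (k in seq_len(nrow(ed))) {
    vals <- vals * Ps[[k]][cbind(state_col(ed$parent[k]), state_col(ed$child[k]))]
  }
  log(sum(vals))
}

# omega mixtures matching quartet_params()
quartet_mixtures <- function() {
  list(EGV1 = omega_distribution(0.3, 1, p1 = 0.6, p2 = 0.4),
       EGV2 = omega_distribution(0.2, 2, p1 = 0.5, p2 = 0.3),
       CONNECTING = omega_distribution(0.5, 1, p1 = 0, p2 = 1))
}

# Random tree with ntip tips (>= 3), random scheme assigning every branch
# to one of `k` partitions by bipartition id, random parameters. Used by
# the pruning-oracle battery. Returns everything needed for both routes.
random_oracle_case <- function(ntip, seed) {
  set.seed(seed)
  tree <- ape::rtree(ntip, rooted = FALSE,
                     tip.label = paste0("t", seq_len(ntip)),
                     br = function(n) stats::runif(n, 0.02, 0.6))
  et <- egvselect:::edge_table(tree)
  labels <- paste0("P", seq_len(3))
  lab <- sample(labels, nrow(et$edges), replace = TRUE)
  # every label must be used at least once
  lab[seq_len(3)] <- labels
  scheme <- structure(list(
    assignment = data.frame(id = et$edges$id, label = lab,
                            stringsAsFactors = FALSE),
    labels = labels, roles = NULL), class = "partition_scheme")
  rand_simplex <- function() { x <- stats::runif(3); x / sum(x) }
  mixtures <- lapply(labels, function(l) {
    w <- rand_simplex()
    omega_distribution(stats::runif(1), 1 + stats::rexp(1), p1 = w[1], p2 = w[2])
  })
  names(mixtures) <- labels
  pf <- positional_frequencies(t(replicate(3, rand_simplex4())))
  exch <- stats::rexp(5) + 0.2
  code <- genetic_code()
  # draw the tip column from the model itself (root from pi, then each
  # branch under its mixture matrix, built through the R-level route) so
  # the pattern has non-negligible probability; independently-uniform tips
  # can have likelihoods near 1e-40 where double precision dominates both
  # computation routes
  pi <- cf3x4_frequencies(pf, code)
  et2 <- egvselect:::edge_table(tree)
  Ps <- lapply(seq_len(nrow(et2$edges)), function(k) {
    l2 <- lab[match(et2$edges$id[k], et$edges$id)]
    branch_mixture_matrix(mixtures[[l2]], exch, pf, et2$edges$length[k], code)
  })
  ntot <- ntip + tree$Nnode
  states <- integer(ntot)
  root <- et2$edges$parent[nrow(et2$edges)]
  states[root] <- sample.int(61, 1, prob = pi)
  for (k in rev(seq_len(nrow(et2$edges)))) {
    pa <- et2$edges$parent[k]; ch <- et2$edges$child[k]
    states[ch] <- sample.int(61, 1, prob = Ps[[k]][states[pa], ])
  }
  tip_codons <- stats::setNames(code$codons[states[seq_len(ntip)]],
                                tree$tip.label)
  list(tree = tree, scheme = scheme, mixtures = mixtures, pos_freqs = pf,
       exch = exch, tip_codons = tip_codons)
}

rand_simplex4 <- function() { x <- stats::runif(4, 0.1, 1); x / sum(x) }

# model_parameters equivalent to a named list of omega_distributions
params_from_mixtures <- function(mixtures, exch, pos_freqs) {
  groups <- lapply(mixtures, function(m) {
    list(classes = c("w1", "w2", "w3"), omega1 = m$omega[1],
         omega3 = m$omega[3], p1 = m$weights[1], p2 = m$weights[2])
  })
  model_parameters(exch = exch, pos_freqs = pos_freqs, groups = groups)
}
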