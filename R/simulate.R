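#' Generative simulator with the branch-site mixture structure
#'
#' The simulator draws data from exactly the process the likelihood
#' assumes: the root codon comes from the CF3x4 equilibrium, and for every
#' site and branch an omega category is drawn i.i.d. from the branch's
#' partition mixture before the child state evolves under that category's
#' transition matrix. The per-site per-branch category draws are returned
#' as the simulation truth. Only sense codons are ever produced.
#'
#' Draw order is fixed (sites outer, branches in preorder) so a seed fully
#' determines the output.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param tree A `phylo` tree (see [simulate_two_clade_tree()] to sample
#'   one).
#' @param scheme A `partition_scheme` labelling the branches.
#' @param partition_omegas Named list of [omega_distribution()], one per
#'   partition label.
#' @param exch Five nucleotide exchangeabilities.
#' @param pos_freqs 3x4 positional frequency matrix.
#' @param n_sites Number of codon sites (>= 1).
#' @param seed Mandatory integer seed.
#' @export
simulation_config <- function(tree, scheme, partition_omegas, exch,
                              pos_freqs, n_sites, seed) {
  stopifnot(inherits(scheme, "partition_scheme"))
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory for simulation")
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (!setequal(names(partition_omegas), scheme$labels)) {
    stop("partition_omegas must name every partition label exactly once")
  }
  lapply(partition_omegas, function(d) stopifnot(inherits(d, "omega_distribution")))
  structure(list(tree = tree, scheme = scheme,
                 partition_omegas = partition_omegas,
                 exch = validate_exchangeabilities(exch),
                 pos_freqs = positional_frequencies(pos_freqs),
                 n_sites = as.integer(n_sites), seed = as.integer(seed)),
            class = "simulation_config")
}

#' Sample a two-clade tree joined by a single connecting branch
#'
#' Random topologies within each clade (exponential branch lengths, in
#' expected substitutions per codon site) joined root-to-root so that the
#' unrooted tree has exactly one branch separating the clades.
#'
#' @param n_a,n_b Tip counts of the two clades (tips named `a1..`, `b1..`).
#' @param mean_length Mean within-clade branch length.
#' @param connecting_length Length of the clade-separating branch.
#' @param seed Integer seed.
#' @return A `phylo` tree.
#' @export
simulate_two_clade_tree <- function(n_a, n_b, mean_length = 0.05,
                                    connecting_length = 0.8, seed = 1) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  subtree_newick <- function(n, prefix) {
    tr <- ape::rtree(n, rooted = TRUE, tip.label = paste0(prefix, seq_len(n)),
                     br = function(k) stats::rexp(k, 1 / mean_length))
    sub(";$", "", ape::write.tree(tr))
  }
  nwk <- sprintf("(%s:%g,%s:%g);",
                 subtree_newick(n_a, "a"), connecting_length / 2,
                 subtree_newick(n_b, "b"), connecting_length / 2)
  parse_tree(text = nwk)
}

#' Default desk-scale simulation scenario
#'
#' Mirrors the shape of a two-clade endogenous-element study: 15 + 14 taxa,
#' 350 codons, shallow within-clade divergence with a long connecting
#' branch, a strongly purifying foreground mixture (omega1 = 0.2,
#' p1 = 0.8) on clade A, and transition-biased exchangeabilities with
#' mildly AT-rich positional frequencies.
#'
#' @param seed Integer seed.
#' @param n_sites Number of codon sites.
#' @param fg_omega1,fg_p1 Foreground purifying parameters (clade A).
#' @export
default_simulation_config <- function(seed, n_sites = 350,
                                      fg_omega1 = 0.2, fg_p1 = 0.8) {
  tree <- simulate_two_clade_tree(15, 14, mean_length = 0.05,
                                  connecting_length = 0.8, seed = seed)
  scheme <- assign_partitions(tree, paste0("a", 1:15), paste0("b", 1:14))
  pf <- positional_frequencies(rbind(c(0.30, 0.20, 0.25, 0.25),
                                     c(0.30, 0.20, 0.20, 0.30),
                                     c(0.25, 0.20, 0.20, 0.35)))
  simulation_config(
    tree, scheme,
    partition_omegas = list(
      EGV1 = omega_distribution(fg_omega1, omega3 = 1, p1 = fg_p1,
                                p2 = 1 - fg_p1),
      EGV2 = omega_distribution(0.3, omega3 = 1, p1 = 0.6, p2 = 0.4),
      CONNECTING = omega_distribution(0.05, omega3 = 1, p1 = 0.75, p2 = 0.25)),
    exch = c(AC = 1, AG = 4, AT = 1, CG = 1, CT = 4),
    pos_freqs = pf, n_sites = n_sites, seed = seed)
}

#' Simulate a codon alignment under the partitioned branch-site model
#'
#' @param config A [simulation_config()].
#' @return List with `alignment` (a `codon_alignment`), `truth` (per-site
#'   per-branch omega category matrix and root codon states), `tree`, and
#'   `scheme`.
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed %% .Machine$integer.max)
  code <- universal_code()
  et <- edges_with_labels(config$tree, config$scheme)
  tr <- et$tree
  ntip <- length(tr$tip.label)
  nedge <- nrow(et$edges)
  pi <- cf3x4_frequencies(config$pos_freqs, code)

  # per-branch, per-category transition matrices from the compiled core
  labels <- et$edges$label
  glabels <- config$scheme$labels
  gidx <- match(labels, glabels)
  omegas <- lapply(config$partition_omegas[glabels], `[[`, "omega")
  weights <- lapply(config$partition_omegas[glabels], `[[`, "weights")
  Pcat <- cpp_category_matrices(et$edges$length, gidx, omegas,
                                unname(config$exch), unname(pi),
                                config$pos_freqs, code$codon_nuc,
                                as.integer(factor(code$aa)))

  # preorder = reverse postorder: parents are visited before children
  preorder <- rev(seq_len(nedge))
  root <- tr$edge[nrow(tr$edge), 1]
  nstate <- length(code$codons)

  states <- matrix(0L, nrow = ntip + tr$Nnode, ncol = config$n_sites)
  categories <- matrix(0L, nrow = config$n_sites, ncol = nedge)
  root_states <- integer(config$n_sites)

  for (s in seq_len(config$n_sites)) {
    root_states[s] <- sample.int(nstate, 1, prob = pi)
    states[root, s] <- root_states[s]
    for (k in preorder) {
      pa <- et$edges$parent[k]; ch <- et$edges$child[k]
      w <- weights[[gidx[k]]]
      cat_k <- sample.int(length(w), 1, prob = w)
      categories[s, k] <- cat_k
      P <- Pcat[[k]][[cat_k]]
      states[ch, s] <- sample.int(nstate, 1, prob = P[states[pa, s], ])
    }
  }

  seqs <- vapply(seq_len(ntip), function(i)
    paste(code$codons[states[i, ]], collapse = ""), character(1))
  names(seqs) <- tr$tip.label
  aln <- codon_alignment(seqs, code = code)
  colnames(categories) <- et$edges$id
  list(alignment = aln,
       truth = list(categories = categories, root_states = root_states),
       tree = tr, scheme = config$scheme, config = config)
}
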