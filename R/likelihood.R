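#' Partitioned random-effects likelihood
#'
#' Likelihood of an in-frame codon alignment under the partitioned
#' branch-site mixture model: each branch uses its partition's
#' weight-averaged mixture transition matrix, sites are independent, and
#' the tree is traversed by Felsenstein pruning (compiled core). The model
#' is reversible, so the arbitrary pruning root does not affect the value.
#'
#' @name likelihood_and_tests
NULL

#' Model parameters for the partitioned codon mixture model
#'
#' @param exch Five nucleotide exchangeabilities (AC, AG, AT, CG, CT).
#' @param pos_freqs 3x4 positional frequency matrix.
#' @param groups Named list of parameter groups; each element is a list with
#'   `classes` (subset of `c("w1", "w2", "w3")`, `"w2"` always present) and
#'   the selection parameters it needs: `omega1`, `p1` when `"w1"` is
#'   active; `omega3`, `p2` when `"w3"` is active.
#' @param partition_group Named character vector mapping partition labels to
#'   group names; identity if omitted. Several partitions may share one
#'   group (merged foreground).
#' @param lengths Optional named branch-length vector (names = branch ids)
#'   overriding the tree's lengths.
#' @return A `model_parameters` object.
#' @export
model_parameters <- function(exch, pos_freqs, groups, partition_group = NULL,
                             lengths = NULL) {
  exch <- validate_exchangeabilities(exch)
  pos_freqs <- positional_frequencies(pos_freqs)
  if (is.null(names(groups)) || anyDuplicated(names(groups))) {
    stop("groups must be a uniquely named list")
  }
  groups <- lapply(groups, validate_group)
  structure(list(exch = exch, pos_freqs = pos_freqs, groups = groups,
                 partition_group = partition_group, lengths = lengths),
            class = "model_parameters")
}

validate_group <- function(g) {
  if (is.null(g$classes)) g$classes <- c("w1", "w2", "w3")
  if (!all(g$classes %in% c("w1", "w2", "w3"))) stop("unknown omega class")
  if (!"w2" %in% g$classes) stop("the neutral class w2 (omega = 1) is always present")
  if ("w1" %in% g$classes) {
    if (is.null(g$omega1) || is.null(g$p1)) stop("class w1 needs omega1 and p1")
    if (g$omega1 < 0 || g$omega1 > 1) stop("omega1 must lie in [0, 1]")
    if (g$p1 < 0 || g$p1 > 1) stop("p1 must lie in [0, 1]")
  } else {
    g$omega1 <- NULL; g$p1 <- 0
  }
  if ("w3" %in% g$classes) {
    if (is.null(g$omega3) || is.null(g$p2)) stop("class w3 needs omega3 and p2")
    if (g$omega3 < 1) stop("omega3 must be >= 1")
    if (g$p2 < 0) stop("p2 must be non-negative")
  } else {
    g$omega3 <- NULL
    g$p2 <- 1 - g$p1   # all remaining weight is neutral
  }
  if (g$p1 + g$p2 > 1 + 1e-12) stop("p1 + p2 must not exceed 1")
  g
}

# omega values and weights actually entering the mixture for one group
group_mixture <- function(g) {
  omega <- numeric(0); w <- numeric(0)
  if ("w1" %in% g$classes) { omega <- c(omega, g$omega1); w <- c(w, g$p1) }
  omega <- c(omega, 1)
  w2 <- if ("w3" %in% g$classes) g$p2 else 1 - g$p1
  w <- c(w, w2)
  if ("w3" %in% g$classes) {
    omega <- c(omega, g$omega3); w <- c(w, max(0, 1 - g$p1 - g$p2))
  }
  list(omega = omega, weights = w / sum(w))
}

# Static per-dataset structures reused across likelihood evaluations.
likelihood_plan <- function(aln, tree, scheme) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(scheme, "partition_scheme"))
  et <- edges_with_labels(tree, scheme)
  tr <- et$tree  # unrooted, postorder
  miss_tree <- setdiff(aln$taxa, tr$tip.label)
  if (length(miss_tree) > 0L) {
    stop("tip in alignment but not in tree: ", miss_tree[1])
  }
  miss_aln <- setdiff(tr$tip.label, aln$taxa)
  if (length(miss_aln) > 0L) {
    stop("tip in tree but not in alignment: ", miss_aln[1])
  }
  pat <- compress_patterns(aln)
  # reorder tip slices to the tree's tip numbering
  ord <- match(tr$tip.label, aln$taxa)
  tc <- tip_conditionals(aln, pat)[, , ord, drop = FALSE]
  code <- aln$code
  list(tree = tr, edges = et$edges, patterns = pat, tipcond = tc,
       n_node_total = length(tr$tip.label) + tr$Nnode,
       root = tr$edge[nrow(tr$edge), 1],
       codon_nuc = code$codon_nuc,
       aa_idx = as.integer(factor(code$aa)),
       code = code)
}

# Evaluate the total and per-pattern log-likelihood for given parameters.
eval_loglik <- function(plan, params) {
  stopifnot(inherits(params, "model_parameters"))
  labels <- plan$edges$label
  pg <- params$partition_group
  if (is.null(pg)) pg <- stats::setNames(names(params$groups), names(params$groups))
  gname <- unname(pg[labels])
  if (anyNA(gname)) {
    stop("no parameter group for partition label(s): ",
         paste(unique(labels[is.na(gname)]), collapse = ", "))
  }
  gidx <- match(gname, names(params$groups))
  mix <- lapply(params$groups, group_mixture)
  lens <- plan$edges$length
  if (!is.null(params$lengths)) {
    m <- match(plan$edges$id, names(params$lengths))
    lens[!is.na(m)] <- params$lengths[m[!is.na(m)]]
  }
  pi <- cf3x4_frequencies(params$pos_freqs, plan$code)
  cpp_partitioned_loglik(
    plan$tipcond, plan$patterns$counts,
    cbind(plan$edges$parent, plan$edges$child), lens, gidx,
    plan$n_node_total, plan$root,
    lapply(mix, `[[`, "omega"), lapply(mix, `[[`, "weights"),
    unname(params$exch), unname(pi), params$pos_freqs,
    plan$codon_nuc, plan$aa_idx)
}

#' Per-site log-likelihoods
#'
#' @param aln A `codon_alignment`.
#' @param tree A `phylo` tree whose tips match the alignment.
#' @param scheme A `partition_scheme` labelling every branch.
#' @param params A [model_parameters()] object.
#' @return Numeric vector, one log-probability per codon site (pattern
#'   compression is internal and does not change the values).
#' @export
site_log_likelihood <- function(aln, tree, scheme, params) {
  plan <- likelihood_plan(aln, tree, scheme)
  out <- eval_loglik(plan, params)
  out$pattern_loglik[plan$patterns$site_to_pattern]
}

#' Total log-likelihood of the alignment
#'
#' @inheritParams site_log_likelihood
#' @export
total_log_likelihood <- function(aln, tree, scheme, params) {
  plan <- likelihood_plan(aln, tree, scheme)
  eval_loglik(plan, params)$loglik
}
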