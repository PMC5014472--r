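#' Trees, stable branch identifiers, and branch partitions
#'
#' Branches are identified by the tip bipartition they induce on the
#' unrooted tree: the identifier is the comma-joined sorted tip set of the
#' smaller side (ties broken lexicographically). This makes partition
#' labels invariant under re-rooting and tip reordering.
#'
#' @name partitioned_phylogeny
NULL

#' Parse a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that validates bracket structure
#' (reporting the character position of the first imbalance), requires
#' branch lengths, and rejects negative lengths.
#'
#' @param text Newick string, or `NULL` if `file` is given.
#' @param file Path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
parse_tree <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply Newick text or a file path")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed Newick: unmatched ')' at position ", i)
    }
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' (string ends at position ",
         length(chars), ")")
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick: ape could not parse the string")
  if (anyDuplicated(tr$tip.label)) stop("tip names must be unique")
  if (is.null(tr$edge.length)) stop("tree must have branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  tr
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Branch-length precision.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

# Collapse a degree-2 root so both rooted parses of the same unrooted tree
# yield identical edge tables.
unrooted_form <- function(tree) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tree
}

# Edge table with stable bipartition identifiers. Tipsets are computed by
# postorder accumulation below each edge's child node.
edge_table <- function(tree) {
  tree <- unrooted_form(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  below <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2]; pa <- tree$edge[k, 1]
    below[[pa]] <- c(below[[pa]], below[[ch]])
  }
  all_tips <- sort(tree$tip.label)
  ids <- character(nrow(tree$edge))
  small <- vector("list", nrow(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    side <- sort(below[[tree$edge[k, 2]]])
    other <- setdiff(all_tips, side)
    pick <- if (length(side) < length(other)) side
            else if (length(side) > length(other)) other
            else if (paste(side, collapse = ",") <= paste(other, collapse = ",")) side
            else other
    small[[k]] <- pick
    ids[k] <- paste(pick, collapse = ",")
  }
  list(tree = tree,
       edges = data.frame(parent = tree$edge[, 1], child = tree$edge[, 2],
                          length = tree$edge.length, id = ids,
                          stringsAsFactors = FALSE),
       below = below)
}

#' Assign the three-way branch partition from two clades
#'
#' Splits the branches of an unrooted tree into the subtree of `clade_a`,
#' the subtree of `clade_b`, and the single connecting branch separating
#' them. The two clades must be disjoint, jointly cover all tips, and each
#' be separable by removing one branch (monophyletic in the unrooted
#' sense).
#'
#' @param tree A `phylo` object.
#' @param clade_a,clade_b Character vectors of tip names.
#' @param labels Length-3 labels for (clade A, clade B, connecting branch).
#' @return A `partition_scheme`: data frame of branch id -> label plus the
#'   label set. Attach test roles with [set_partition_roles()].
#' @export
assign_partitions <- function(tree, clade_a, clade_b,
                              labels = c("EGV1", "EGV2", "CONNECTING")) {
  stopifnot(length(labels) == 3L, !anyDuplicated(labels))
  et <- edge_table(tree)
  all_tips <- sort(et$tree$tip.label)
  clade_a <- sort(unique(clade_a)); clade_b <- sort(unique(clade_b))
  if (length(intersect(clade_a, clade_b)) > 0L) {
    stop("clades overlap: ", paste(intersect(clade_a, clade_b), collapse = ", "))
  }
  missing_tips <- setdiff(c(clade_a, clade_b), all_tips)
  if (length(missing_tips) > 0L) {
    stop("clade tips not in tree: ", paste(missing_tips, collapse = ", "))
  }
  uncovered <- setdiff(all_tips, c(clade_a, clade_b))
  if (length(uncovered) > 0L) {
    stop("clades must cover all tips; uncovered: ",
         paste(uncovered, collapse = ", "))
  }
  if (length(clade_a) < 2L || length(clade_b) < 2L) {
    stop("each clade needs at least two tips so its partition is non-empty")
  }

  side_sets <- lapply(seq_len(nrow(et$edges)),
                      function(k) sort(et$below[[et$edges$child[k]]]))
  classify <- function(S) {
    if (setequal(S, clade_a) || setequal(S, clade_b)) return(labels[3])
    if (all(S %in% clade_a) || all(clade_b %in% S)) return(labels[1])
    if (all(S %in% clade_b) || all(clade_a %in% S)) return(labels[2])
    NA_character_
  }
  lab <- vapply(side_sets, classify, character(1))
  if (anyNA(lab)) {
    bad <- side_sets[[which(is.na(lab))[1]]]
    stop("clades are not monophyletic on this tree; offending branch splits off tips: ",
         paste(intersect(bad, clade_a), collapse = ","), " | ",
         paste(intersect(bad, clade_b), collapse = ","))
  }
  n_conn <- sum(lab == labels[3])
  if (n_conn != 1L) {
    stop("expected exactly one connecting branch, found ", n_conn,
         " (are both clades non-trivial and monophyletic?)")
  }
  scheme <- structure(
    list(assignment = data.frame(id = et$edges$id, label = lab,
                                 stringsAsFactors = FALSE),
         labels = labels, roles = NULL),
    class = "partition_scheme"
  )
  scheme
}

#' Assign foreground/background roles to partitions
#'
#' Multiple partitions may share the `FG` role (a merged foreground); they
#' then share a single selection-parameter set in the tests.
#'
#' @param scheme A `partition_scheme`.
#' @param roles Named character vector, names = partition labels, values in
#'   `FG`, `BG1`, `BG2`.
#' @export
set_partition_roles <- function(scheme, roles) {
  stopifnot(inherits(scheme, "partition_scheme"))
  if (!all(names(roles) %in% scheme$labels)) {
    stop("unknown partition label in roles: ",
         paste(setdiff(names(roles), scheme$labels), collapse = ", "))
  }
  if (!all(scheme$labels %in% names(roles))) {
    stop("every partition needs a role; missing: ",
         paste(setdiff(scheme$labels, names(roles)), collapse = ", "))
  }
  if (!all(roles %in% c("FG", "BG1", "BG2"))) {
    stop("roles must be FG, BG1 or BG2")
  }
  if (!any(roles == "FG")) stop("at least one partition must be foreground (FG)")
  scheme$roles <- roles
  scheme
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat("Branch partition scheme:\n")
  print(table(x$assignment$label))
  if (!is.null(x$roles)) {
    cat("roles:", paste(names(x$roles), x$roles, sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Read / write a branch-partition table
#'
#' Tab-separated with columns `bipartition_smaller_side_tips` (comma-joined
#' sorted tip names of the branch's smaller side) and `label`.
#'
#' @param file Path.
#' @param labels Optional label set; inferred from the table if omitted.
#' @export
read_partition_tsv <- function(file, labels = NULL) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("bipartition_smaller_side_tips", "label")
  if (!all(need %in% names(d))) {
    stop("partition table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(labels)) labels <- unique(d$label)
  structure(
    list(assignment = data.frame(id = d$bipartition_smaller_side_tips,
                                 label = d$label, stringsAsFactors = FALSE),
         labels = labels, roles = NULL),
    class = "partition_scheme"
  )
}

#' @rdname read_partition_tsv
#' @param scheme A `partition_scheme`.
#' @export
write_partition_tsv <- function(scheme, file) {
  stopifnot(inherits(scheme, "partition_scheme"))
  d <- data.frame(bipartition_smaller_side_tips = scheme$assignment$id,
                  label = scheme$assignment$label)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# Join a scheme onto a tree's edge table; every branch must get a label.
edges_with_labels <- function(tree, scheme) {
  et <- edge_table(tree)
  m <- match(et$edges$id, scheme$assignment$id)
  if (anyNA(m)) {
    stop("scheme does not label branch(es): ",
         paste(utils::head(et$edges$id[is.na(m)], 3), collapse = " ; "))
  }
  et$edges$label <- scheme$assignment$label[m]
  et
}
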