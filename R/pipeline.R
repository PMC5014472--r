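#' Pipeline driver: screen, filter, fit, test
#'
#' Chains the stages the analysis needs end to end: read inputs, optionally
#' screen candidate sequences and drop non-intact ones (premature stops,
#' frameshifts, externally supplied recombination flags), then run the
#' requested selection tests and write JSON + TSV reports with a provenance
#' block. The same stages are available individually as exported functions;
#' `run_pipeline()` only composes them.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Recognised fields: `seed`; `alignment` (FASTA), `tree` (Newick);
#'   either `partitions` (TSV path) or `clades` (list with `a`, `b` tip
#'   vectors and optional `labels`); `roles` (named list label -> role);
#'   `tests` (subset of `"purifying"`, `"positive"`); `exclude` (tip names
#'   to drop before fitting, e.g. recombination-flagged copies);
#'   `out_dir`; `control` (optimizer settings for [fit_model()]).
#' @return Invisibly, the list of `selection_test` results.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (field in c("alignment", "tree", "out_dir")) {
    if (is.null(cfg[[field]])) stop("config is missing required field: ", field)
  }
  seed <- as.integer(cfg$seed %||% 1L)
  for (f in c(cfg$alignment, cfg$tree, cfg$partitions)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  aln <- read_codon_alignment(cfg$alignment)
  tree <- parse_tree(file = cfg$tree)

  if (!is.null(cfg$exclude) && length(cfg$exclude) > 0L) {
    keep <- setdiff(aln$taxa, cfg$exclude)
    seqs <- apply(aln$codons[keep, , drop = FALSE], 1, paste, collapse = "")
    aln <- codon_alignment(stats::setNames(seqs, keep))
    tree <- ape::drop.tip(tree, intersect(tree$tip.label, cfg$exclude))
  }

  scheme <- if (!is.null(cfg$partitions)) {
    read_partition_tsv(cfg$partitions)
  } else if (!is.null(cfg$clades)) {
    labels <- unlist(cfg$clades$labels %||% c("EGV1", "EGV2", "CONNECTING"))
    assign_partitions(tree, unlist(cfg$clades$a), unlist(cfg$clades$b),
                      labels = labels)
  } else {
    stop("config needs either `partitions` (TSV) or `clades`")
  }
  roles <- unlist(cfg$roles %||% stop("config needs `roles`"))
  scheme <- set_partition_roles(scheme, roles)

  tests <- cfg$tests %||% "purifying"
  control <- cfg$control %||% list()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  for (tname in tests) {
    fun <- switch(tname, purifying = purifying_selection_test,
                  positive = positive_selection_test,
                  stop("unknown test: ", tname))
    results[[tname]] <- fun(aln, tree, scheme, seed = seed, control = control)
  }

  atomically <- function(path, writer) {
    tmp <- paste0(path, ".tmp")
    writer(tmp)
    file.rename(tmp, path)
  }
  atomically(file.path(cfg$out_dir, "selection_tests.json"),
             function(p) write_test_report(results, json_file = p))
  atomically(file.path(cfg$out_dir, "selection_tests.tsv"),
             function(p) write_test_report(results, tsv_file = p))
  atomically(file.path(cfg$out_dir, "provenance.yaml"), function(p) {
    yaml::write_yaml(list(
      config = cfg, seed = seed,
      config_hash = config_hash(cfg),
      package = as.character(utils::packageVersion("egvselect")),
      r_version = R.version.string), p)
  })
  invisible(results)
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Screen a FASTA of candidate sequences
#'
#' Runs the nucleotide-level screens (nonanucleotide, stem-loop) and, when
#' references are given, the ORF intactness check; protein FASTA inputs are
#' scanned for RCR motifs. Absence of a feature is a result, not an error.
#'
#' @param nuc_fasta,protein_fasta Optional FASTA paths.
#' @param reference Optional in-frame reference ORF (string) for the
#'   intactness check of each nucleotide sequence.
#' @param circular Treat nucleotide sequences as circular.
#' @param min_stem,max_loop,max_mismatch Hairpin parameters.
#' @param motifs Protein motif patterns.
#' @param tsv_file,json_file Optional report paths.
#' @return Data frame, one row per sequence per check.
#' @export
screen_sequences <- function(nuc_fasta = NULL, protein_fasta = NULL,
                             reference = NULL, circular = FALSE,
                             min_stem = 5, max_loop = 15, max_mismatch = 1,
                             motifs = default_rcr_motifs(),
                             tsv_file = NULL, json_file = NULL) {
  rows <- list()
  if (!is.null(nuc_fasta)) {
    if (!file.exists(nuc_fasta)) stop("input file not found: ", nuc_fasta)
    ss <- Biostrings::readBStringSet(nuc_fasta)
    for (i in seq_along(ss)) {
      s <- as.character(ss[[i]]); nm <- names(ss)[i]
      hits <- find_nonanucleotide(s, circular = circular)
      rows[[length(rows) + 1L]] <- data.frame(
        id = nm, check = "nonanucleotide",
        result = if (nrow(hits) > 0L)
          paste(sprintf("%d%s", hits$position, hits$strand), collapse = ",")
        else "absent", stringsAsFactors = FALSE)
      hp <- "absent"
      for (k in which(hits$strand == "+")) {
        call <- find_stem_loop(s, hits$position[k], min_stem = min_stem,
                               max_loop = max_loop, max_mismatch = max_mismatch)
        if (!is.null(call)) {
          hp <- sprintf("stem=%d;mismatches=%d;gc=%.2f;loop=%d-%d",
                        call$stem_length, call$mismatches, call$gc_fraction,
                        call$loop_start, call$loop_end)
          break
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = nm, check = "hairpin", result = hp, stringsAsFactors = FALSE)
      if (!is.null(reference)) {
        v <- check_orf_intactness(s, reference)
        rows[[length(rows) + 1L]] <- data.frame(
          id = nm, check = "orf_intactness",
          result = paste0(v$status,
                          if (!is.na(v$stop_codon))
                            paste0(";stop_codon=", v$stop_codon) else "",
                          if (!is.na(v$frameshift_column))
                            paste0(";frameshift_col=", v$frameshift_column) else ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(protein_fasta)) {
    if (!file.exists(protein_fasta)) stop("input file not found: ", protein_fasta)
    ss <- Biostrings::readBStringSet(protein_fasta)
    for (i in seq_along(ss)) {
      hits <- detect_rcr_motifs(as.character(ss[[i]]), motifs)
      rows[[length(rows) + 1L]] <- data.frame(
        id = names(ss)[i], check = "rcr_motifs",
        result = if (nrow(hits) > 0L)
          paste(sprintf("%s:%d", hits$motif, hits$position), collapse = ",")
        else "absent", stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(id = character(0), check = character(0), result = character(0))
  if (!is.null(tsv_file)) {
    utils::write.table(report, tsv_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_file)) {
    jsonlite::write_json(report, json_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}
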