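#' Screening of candidate endogenous geminiviral sequences
#'
#' Detectors for the hallmarks used to characterise endogenous geminiviral
#' elements: the virion-strand replication-origin nonanucleotide
#' (TAATATTAC) and its GC-rich stem-loop, ORF intactness relative to a
#' reference (premature stops, frameshifts), rolling-circle-replication
#' (RCR) and dNTP-binding motifs in Rep protein sequences, and a
#' conservative count of genetically distinct repeat copies.
#'
#' All reported coordinates are 1-based inclusive.
#'
#' @name egv_screening
NULL

NONANUCLEOTIDE <- "TAATATTAC"

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

find_fixed <- function(text, pattern) {
  m <- gregexpr(pattern, text, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Locate the replication-origin nonanucleotide
#'
#' Finds every occurrence of the conserved nonanucleotide (default
#' `TAATATTAC`) and, optionally, of its reverse complement. On circular
#' sequences matches may span the origin (scanned by doubling the sequence
#' minus one base and deduplicating wrapped hits).
#'
#' @param seq Nucleotide string.
#' @param both_strands Also search the reverse complement.
#' @param circular Treat the sequence as circular.
#' @param motif Motif to search (default the canonical nonanucleotide).
#' @return Data frame with `position` (1-based, forward strand) and
#'   `strand`.
#' @export
find_nonanucleotide <- function(seq, both_strands = TRUE, circular = FALSE,
                                motif = NONANUCLEOTIDE) {
  seq <- toupper(seq)
  L <- nchar(seq)
  n <- nchar(motif)
  scan_text <- if (circular && L >= 2L) {
    paste0(seq, substr(seq, 1, min(n - 1L, L - 1L)))
  } else {
    seq
  }
  hits <- data.frame(position = integer(0), strand = character(0),
                     stringsAsFactors = FALSE)
  fwd <- find_fixed(scan_text, motif)
  fwd <- unique(ifelse(fwd > L, fwd - L, fwd))
  fwd <- fwd[fwd <= L]
  if (length(fwd) > 0L) {
    hits <- rbind(hits, data.frame(position = fwd, strand = "+",
                                   stringsAsFactors = FALSE))
  }
  if (both_strands && !identical(motif, revcomp(motif))) {
    rc <- find_fixed(scan_text, revcomp(motif))
    rc <- unique(ifelse(rc > L, rc - L, rc))
    rc <- rc[rc <= L]
    if (length(rc) > 0L) {
      hits <- rbind(hits, data.frame(position = rc, strand = "-",
                                     stringsAsFactors = FALSE))
    }
  }
  hits[order(hits$position, hits$strand), , drop = FALSE]
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

# lexicographic comparison of equal-length numeric keys
compare_lex <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] > b[k]) return(1L)
    if (a[k] < b[k]) return(-1L)
  }
  0L
}

#' Find the stem-loop around a nonanucleotide anchor
#'
#' Searches all loop intervals of length at most `max_loop` that contain
#' the anchored nonanucleotide and extends an inverted-repeat stem outward
#' from each, tolerating at most `max_mismatch` mismatched pairs (a stem
#' never ends on a mismatch). The call with the most *matched* stem pairs
#' wins; ties prefer fewer mismatches, then the shorter loop. Ranking by
#' matched pairs rather than raw stem length stops a tolerated mismatch
#' from outranking a perfect stem.
#'
#' @param seq Nucleotide string.
#' @param anchor_pos 1-based start of the nonanucleotide hit.
#' @param min_stem Minimum stem length to report (default 5).
#' @param max_loop Maximum loop length (default 15).
#' @param max_mismatch Maximum mismatched stem pairs (default 1).
#' @param motif_length Length of the anchored motif (default 9).
#' @return A `hairpin_call` list (`loop_start`, `loop_end`, `stem_length`,
#'   `mismatches`, `gc_fraction`, `strand`) or `NULL` if no qualifying stem
#'   exists.
#' @export
find_stem_loop <- function(seq, anchor_pos, min_stem = 5, max_loop = 15,
                           max_mismatch = 1, motif_length = nchar(NONANUCLEOTIDE)) {
  seq <- toupper(seq)
  L <- nchar(seq)
  a1 <- anchor_pos; a2 <- anchor_pos + motif_length - 1L
  if (a1 < 1L || a2 > L) stop("anchor does not lie within the sequence")
  if (max_loop < motif_length) return(NULL)
  ch <- strsplit(seq, "")[[1]]
  best <- NULL
  best_key <- NULL
  for (i in seq.int(max(1L, a2 - max_loop + 1L), a1)) {
    for (j in seq.int(a2, min(L, i + max_loop - 1L))) {
      # extend stem outward from loop [i, j]
      s <- 0L; mm <- 0L; s_best <- 0L; mm_best <- 0L
      repeat {
        li <- i - s - 1L; ri <- j + s + 1L
        if (li < 1L || ri > L) break
        match_pair <- !is.na(comp_base[ch[li]]) &&
          identical(unname(comp_base[ch[li]]), ch[ri])
        if (match_pair) {
          s <- s + 1L
          s_best <- s; mm_best <- mm
        } else {
          mm <- mm + 1L
          if (mm > max_mismatch) break
          s <- s + 1L   # provisional; only kept if a later pair matches
        }
      }
      if (s_best >= min_stem) {
        cand <- list(loop_start = i, loop_end = j, stem_length = s_best,
                     mismatches = mm_best)
        cand_key <- c(s_best - mm_best, -mm_best, -(j - i))
        if (is.null(best) || compare_lex(cand_key, best_key) > 0) {
          best <- cand
          best_key <- cand_key
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  arm_left <- ch[seq.int(best$loop_start - best$stem_length, best$loop_start - 1L)]
  arm_right <- ch[seq.int(best$loop_end + 1L, best$loop_end + best$stem_length)]
  arms <- c(arm_left, arm_right)
  best$gc_fraction <- mean(arms %in% c("G", "C"))
  best$strand <- "+"
  class(best) <- "hairpin_call"
  best
}

#' Check ORF intactness against an in-frame reference
#'
#' Works on a pairwise alignment of the observed sequence to an in-frame
#' reference ORF (supplied aligned, or computed with a global affine-gap
#' aligner). A gap run whose length is not divisible by 3 is a frameshift
#' (terminal overhangs are ignored); a stop codon aligned to any reference
#' codon before the last is a premature stop.
#'
#' @param observed,reference Nucleotide strings; aligned (same length, `-`
#'   gaps) when `aligned = TRUE`, raw otherwise.
#' @param aligned Are the two strings already aligned?
#' @param code A [genetic_code()].
#' @return List with `status` (`intact`, `premature_stop`, `frameshift`, or
#'   `both`), `stop_codon` (codon index or `NA`), `frameshift_column`
#'   (alignment column or `NA`).
#' @export
check_orf_intactness <- function(observed, reference, aligned = FALSE,
                                 code = universal_code()) {
  observed <- toupper(observed); reference <- toupper(reference)
  ref_plain <- gsub("-", "", reference)
  if (nchar(ref_plain) %% 3 != 0) stop("reference ORF is not in frame")
  ref_codons <- substring(ref_plain, seq(1, nchar(ref_plain) - 2, 3),
                          seq(3, nchar(ref_plain), 3))
  if (any(ref_codons[-length(ref_codons)] %in% code$stops)) {
    stop("reference ORF contains an internal stop codon")
  }
  if (!aligned) {
    pa <- Biostrings::pairwiseAlignment(observed, ref_plain, type = "global",
                                        gapOpening = 10, gapExtension = 0.5)
    observed <- as.character(Biostrings::alignedPattern(pa))
    reference <- as.character(Biostrings::alignedSubject(pa))
  }
  if (nchar(observed) != nchar(reference)) {
    stop("aligned sequences must have equal length")
  }
  obs <- strsplit(observed, "")[[1]]
  ref <- strsplit(reference, "")[[1]]
  ncol_aln <- length(obs)

  # frameshifts: gap runs (either sequence) with length %% 3 != 0,
  # ignoring runs touching the alignment ends (terminal overhangs)
  frameshift_col <- NA_integer_
  for (v in list(obs, ref)) {
    r <- rle(v == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gaps <- which(r$values)
    for (g in gaps) {
      if (starts[g] == 1L || ends[g] == ncol_aln) next
      if (r$lengths[g] %% 3L != 0L) {
        if (is.na(frameshift_col) || starts[g] < frameshift_col) {
          frameshift_col <- starts[g]
        }
      }
    }
  }

  # premature stops: reference codon positions carrying a full observed codon
  ref_posidx <- cumsum(ref != "-")          # reference coordinate per column
  stop_codon <- NA_integer_
  n_ref_codons <- length(ref_codons)
  for (cd in seq_len(n_ref_codons - 1L)) {
    cols <- which(ref != "-" & ref_posidx >= 3L * cd - 2L & ref_posidx <= 3L * cd)
    trip <- obs[cols]
    if (length(trip) == 3L && !any(trip == "-") &&
        paste(trip, collapse = "") %in% code$stops) {
      stop_codon <- cd
      break
    }
  }

  status <- if (!is.na(stop_codon) && !is.na(frameshift_col)) "both"
            else if (!is.na(stop_codon)) "premature_stop"
            else if (!is.na(frameshift_col)) "frameshift"
            else "intact"
  list(status = status, stop_codon = stop_codon,
       frameshift_column = frameshift_col)
}

#' Default RCR / dNTP-binding motif patterns
#'
#' Canonical HUH-endonuclease and geminivirus Rep patterns; fully
#' overridable because motif definitions vary across the literature.
#'
#' @export
default_rcr_motifs <- function() {
  c("RCR-I" = "[FY]LTY",
    "RCR-II" = "H.H",
    "RCR-III" = "Y..[KR]",
    "dNTP-binding" = "G.{4}GK[TS]")
}

#' Scan a Rep protein sequence for RCR motifs
#'
#' @param protein Amino-acid string (20-letter alphabet plus `X`).
#' @param motifs Named character vector of regular expressions
#'   ([default_rcr_motifs()]).
#' @return Data frame with `motif`, `position` (1-based protein
#'   coordinates), `match`.
#' @export
detect_rcr_motifs <- function(protein, motifs = default_rcr_motifs()) {
  protein <- toupper(protein)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", protein)) {
    stop("protein sequence contains invalid residues")
  }
  if (is.null(names(motifs)) || anyDuplicated(names(motifs))) {
    stop("motif patterns must be uniquely named")
  }
  for (nm in names(motifs)) {
    ok <- tryCatch({ grepl(motifs[[nm]], "A", perl = TRUE); TRUE },
                   condition = function(c) FALSE)
    if (!ok) stop("invalid motif pattern '", nm, "': ", motifs[[nm]])
  }
  out <- list()
  for (nm in names(motifs)) {
    m <- gregexpr(motifs[[nm]], protein, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    out[[nm]] <- data.frame(
      motif = nm, position = as.integer(m),
      match = substring(protein, m, m + len - 1L),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(motif = character(0), position = integer(0),
                      match = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$position, res$motif), , drop = FALSE]
}

# bitmask of compatible bases per symbol (A=1, C=2, G=4, T=8), internal
# gap = 16, wildcard = everything
symbol_masks <- function() {
  iupac <- Biostrings::IUPAC_CODE_MAP
  base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  masks <- vapply(iupac, function(s) {
    sum(base_bit[strsplit(s, "")[[1]]])
  }, integer(1))
  c(masks, "-" = 16L, "?" = 31L, "." = 31L)
}

#' Count distinct haplotypes among aligned repeat copies
#'
#' Two counts: the naive number of distinct strings (exact match, gaps
#' significant), and a conservative lower bound on the number of
#' genetically distinct copies — the size of a largest set of sequences
#' that are *pairwise definitely different*, i.e. conflict at at least one
#' column after treating N/IUPAC ambiguity codes and terminal gap runs as
#' wildcards. The bound is a maximum clique of the conflict graph,
#' computed exactly up to `exact_limit` sequences and greedily beyond.
#'
#' @param seqs Named or unnamed character vector of equal-length aligned
#'   sequences.
#' @param exact_limit Maximum number of sequences for the exact clique
#'   search (default 30).
#' @return List with `naive`, `lower_bound`, and `grouping` (a heuristic
#'   assignment of sequences to mutually compatible classes).
#' @export
count_distinct_haplotypes <- function(seqs, exact_limit = 30L) {
  seqs <- toupper(seqs)
  n <- length(seqs)
  if (n == 0L) stop("no sequences supplied")
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences must be aligned to equal length")
  }
  naive <- length(unique(seqs))
  masks <- symbol_masks()
  L <- nchar(seqs[1])
  M <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    ch <- strsplit(seqs[i], "")[[1]]
    if (any(!ch %in% names(masks))) {
      stop("invalid symbol in sequence ", i, ": ",
           ch[which(!ch %in% names(masks))[1]])
    }
    m <- unname(masks[ch])
    # terminal gap runs are wildcards (missing sequence, not indels)
    nong <- which(ch != "-")
    if (length(nong) > 0L) {
      if (nong[1] > 1L) m[seq_len(nong[1] - 1L)] <- 31L
      if (nong[length(nong)] < L) m[seq.int(nong[length(nong)] + 1L, L)] <- 31L
    } else {
      m[] <- 31L
    }
    M[i, ] <- m
  }
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      conflict[i, j] <- conflict[j, i] <- any(bitwAnd(M[i, ], M[j, ]) == 0L)
    }
  }
  lb <- if (n == 1L) 1L else if (n <= exact_limit) {
    g <- igraph::graph_from_adjacency_matrix(conflict, mode = "undirected")
    as.integer(igraph::clique_num(g))
  } else {
    greedy_clique(conflict)
  }
  lb <- max(lb, 1L)

  # heuristic grouping into mutually compatible classes
  classes <- integer(n)
  reps <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (all(!conflict[i, reps[[k]]])) {
        classes[i] <- k; reps[[k]] <- c(reps[[k]], i); placed <- TRUE; break
      }
    }
    if (!placed) { reps[[length(reps) + 1L]] <- i; classes[i] <- length(reps) }
  }
  names(classes) <- names(seqs)
  list(naive = naive, lower_bound = lb, grouping = classes)
}

greedy_clique <- function(conflict) {
  n <- nrow(conflict)
  ord <- order(rowSums(conflict), decreasing = TRUE)
  chosen <- integer(0)
  for (i in ord) {
    if (all(conflict[i, chosen])) chosen <- c(chosen, i)
  }
  length(chosen)
}
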