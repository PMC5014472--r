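#' Screening fixtures with a planted-feature manifest
#'
#' Generates random sequences carrying exactly the screening features they
#' are documented to carry, so the screening detectors can be validated
#' against the manifest. Backgrounds are rejection-sampled: a fixture
#' without a planted nonanucleotide contains none on either strand, a
#' planted anchor without a planted hairpin has no qualifying stem around
#' it (checked with an exhaustive inverted-repeat scan written
#' independently of the detector), and protein backgrounds match none of
#' the motif patterns.
#'
#' @name screening_fixtures
NULL

rand_dna <- function(n, p = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Exhaustive anchored stem scan used only for fixture rejection. Written
# directly from the definition (all loop intervals, all pairings) and kept
# independent of the detector so the manifest stays a genuine oracle.
naive_best_stem <- function(seq, anchor_pos, min_stem, max_loop, max_mismatch,
                            motif_length = nchar(NONANUCLEOTIDE)) {
  ch <- strsplit(toupper(seq), "")[[1]]
  L <- length(ch)
  a1 <- anchor_pos; a2 <- anchor_pos + motif_length - 1L
  lo <- max(1L, a2 - max_loop + 1L)
  if (lo > a1) return(NULL)
  best <- NULL
  for (i in lo:a1) {
    for (j in a2:min(L, i + max_loop - 1L)) {
      s <- 0L; mm <- 0L; s_best <- 0L; mm_best <- 0L
      repeat {
        li <- i - s - 1L; ri <- j + s + 1L
        if (li < 1L || ri > L) break
        pair_ok <- ch[li] %in% names(comp_base) &&
          identical(unname(comp_base[ch[li]]), ch[ri])
        if (!pair_ok) {
          mm <- mm + 1L
          if (mm > max_mismatch) break
        }
        s <- s + 1L
        if (pair_ok) { s_best <- s; mm_best <- mm }
      }
      if (s_best >= min_stem) {
        key <- c(s_best - mm_best, -mm_best, -(j - i))
        if (is.null(best) || compare_lex(key, best$key) > 0) {
          best <- list(stem = s_best, mm = mm_best, key = key)
        }
      }
    }
  }
  best
}

plant_nuc_fixture <- function(len, want_nona, want_hairpin, stem_len, loop_len,
                              min_stem, max_loop, max_mismatch, max_tries = 500L) {
  motif <- NONANUCLEOTIDE
  nm <- nchar(motif)
  for (try in seq_len(max_tries)) {
    if (!want_nona) {
      s <- rand_dna(len)
      if (nrow(find_nonanucleotide(s)) == 0L) {
        return(list(seq = s, nona_pos = NA_integer_, stem = NA_integer_))
      }
      next
    }
    if (want_hairpin) {
      extra <- loop_len - nm                  # loop bases beyond the motif
      lead <- sample.int(extra + 1L, 1L) - 1L # motif offset inside the loop
      arm <- paste(sample(c("G", "C"), stem_len, replace = TRUE),
                   collapse = "")
      loop <- paste0(rand_dna(lead), motif, rand_dna(extra - lead))
      hp <- paste0(arm, loop, revcomp(arm))
      pos0 <- sample.int(max(1L, len - nchar(hp) - 20L), 1L) + 10L
      s <- paste0(rand_dna(pos0 - 1L), hp,
                  rand_dna(max(0L, len - pos0 + 1L - nchar(hp))))
      nona_pos <- pos0 + stem_len + lead
    } else {
      nona_pos <- sample.int(len - nm - 20L, 1L) + 10L
      s <- paste0(rand_dna(nona_pos - 1L), motif,
                  rand_dna(len - nona_pos + 1L - nm))
    }
    # reject accidental extra motif hits (checked by plain string search,
    # not the detector)
    ext <- s
    n_fwd <- length(find_fixed(ext, motif))
    n_rev <- length(find_fixed(ext, revcomp(motif)))
    if (n_fwd != 1L || n_rev != 0L) next
    if (regexpr(motif, s, fixed = TRUE) != nona_pos) next
    best <- naive_best_stem(s, nona_pos, min_stem, max_loop, max_mismatch)
    if (want_hairpin) {
      if (is.null(best) || best$stem != stem_len || best$mm != 0L) next
      return(list(seq = s, nona_pos = nona_pos, stem = stem_len))
    }
    if (!is.null(best)) next
    return(list(seq = s, nona_pos = nona_pos, stem = NA_integer_))
  }
  stop("fixture rejection sampling did not converge; relax the constraints")
}

random_sense_codons <- function(n, code = universal_code()) {
  code$codons[sample.int(length(code$codons), n, replace = TRUE)]
}

plant_orf_fixture <- function(n_codons, stop_at, frameshift_len, code) {
  if (!is.na(frameshift_len) && frameshift_len %% 3L == 0L) {
    stop("a frameshift indel length divisible by 3 is not a frameshift")
  }
  ref_codons <- c(random_sense_codons(n_codons - 1L, code), "TAG")
  ref <- paste(ref_codons, collapse = "")
  obs <- ref
  if (!is.na(stop_at)) {
    stopifnot(stop_at >= 1L, stop_at < n_codons)
    substr(obs, 3L * stop_at - 2L, 3L * stop_at) <- sample(code$stops, 1L)
  }
  fs_col <- NA_integer_
  ref_aln <- ref; obs_aln <- obs
  if (!is.na(frameshift_len)) {
    # delete frameshift_len bases from the observed copy, keeping the
    # planted stop codon (if any) intact; supply the alignment explicitly
    avoid <- if (is.na(stop_at)) integer(0) else seq.int(3L * stop_at - 2L, 3L * stop_at)
    ok <- setdiff(seq.int(4L, nchar(ref) - 3L - frameshift_len), avoid)
    ok <- ok[vapply(ok, function(p) !any(seq.int(p, p + frameshift_len - 1L) %in% avoid),
                    logical(1))]
    if (length(ok) == 0L) stop("ORF too short to place the frameshift")
    p <- ok[sample.int(length(ok), 1L)]
    gap <- paste(rep("-", frameshift_len), collapse = "")
    obs_aln <- paste0(substr(obs, 1L, p - 1L), gap,
                      substr(obs, p + frameshift_len, nchar(obs)))
    fs_col <- p
  }
  list(observed = obs_aln, reference = ref_aln, stop_codon = stop_at,
       frameshift_column = fs_col)
}

plant_protein_fixture <- function(len, motif_names, motifs, max_tries = 500L) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  instance <- function(nm) {
    switch(nm,
           "RCR-I" = paste0(sample(c("F", "Y"), 1), "LTY"),
           "RCR-II" = paste0("H", sample(setdiff(aas, "H"), 1), "H"),
           "RCR-III" = paste0("Y", paste(sample(setdiff(aas, c("K", "R", "Y")), 2,
                                                replace = TRUE), collapse = ""),
                              sample(c("K", "R"), 1)),
           "dNTP-binding" = paste0("G", paste(sample(setdiff(aas, c("G", "K")), 4,
                                                     replace = TRUE), collapse = ""),
                                   "GK", sample(c("T", "S"), 1)),
           stop("no planted instance defined for motif ", nm))
  }
  for (try in seq_len(max_tries)) {
    bg <- paste(sample(aas, len, replace = TRUE), collapse = "")
    seqs <- vapply(motif_names, instance, character(1))
    pos <- sort(sample.int(len - 12L, length(motif_names)))
    if (length(pos) > 1L && any(diff(pos) < 12L)) next
    s <- bg
    for (k in seq_along(pos)) {
      substr(s, pos[k], pos[k] + nchar(seqs[k]) - 1L) <- seqs[k]
    }
    hits <- detect_rcr_motifs(s, motifs)
    want <- data.frame(motif = motif_names, position = as.integer(pos),
                       stringsAsFactors = FALSE)
    want <- want[order(want$position, want$motif), , drop = FALSE]
    if (nrow(hits) == nrow(want) &&
        all(hits$motif == want$motif) && all(hits$position == want$position)) {
      return(list(seq = s,
                  motifs = paste(sprintf("%s:%d", want$motif, want$position),
                                 collapse = ",")))
    }
  }
  stop("protein fixture rejection sampling did not converge")
}

#' Generate a battery of screening fixtures
#'
#' Each fixture is one of three kinds: `nuc` (nonanucleotide / hairpin),
#' `orf` (premature stop / frameshift against a reference), or `protein`
#' (RCR motifs). Which features a fixture carries is drawn at random; the
#' manifest records the ground truth. [screen_fixture_battery()] recomputes
#' the same table with the detectors.
#'
#' @param n Number of fixtures.
#' @param seed Integer seed.
#' @param nuc_length,orf_codons,protein_length Sequence sizes.
#' @param min_stem,max_loop,max_mismatch Hairpin-detection parameters used
#'   both for rejection sampling and later screening.
#' @param motifs Motif patterns ([default_rcr_motifs()]).
#' @return List with `fixtures` (list of per-fixture inputs) and `manifest`
#'   (data frame of planted features).
#' @export
generate_screening_fixtures <- function(n, seed, nuc_length = 150L,
                                        orf_codons = 40L, protein_length = 80L,
                                        min_stem = 5L, max_loop = 15L,
                                        max_mismatch = 1L,
                                        motifs = default_rcr_motifs()) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code <- universal_code()
  fixtures <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    kind <- sample(c("nuc", "orf", "protein"), 1L)
    id <- sprintf("fx%04d", i)
    if (kind == "nuc") {
      want_nona <- stats::runif(1) < 0.7
      want_hp <- want_nona && stats::runif(1) < 0.5
      stem <- if (want_hp) sample(seq.int(min_stem, 9L), 1L) else NA_integer_
      loop <- if (want_hp) sample(seq.int(nchar(NONANUCLEOTIDE), max_loop), 1L)
              else NA_integer_
      fx <- plant_nuc_fixture(nuc_length, want_nona, want_hp, stem, loop,
                              min_stem, max_loop, max_mismatch)
      fixtures[[i]] <- list(id = id, kind = "nuc", seq = fx$seq)
      rows[[i]] <- data.frame(id = id, kind = "nuc",
                              nonanucleotide_pos = fx$nona_pos,
                              hairpin_stem = fx$stem,
                              status = NA_character_, stop_codon = NA_integer_,
                              frameshift_column = NA_integer_,
                              motifs = NA_character_, stringsAsFactors = FALSE)
    } else if (kind == "orf") {
      stop_at <- if (stats::runif(1) < 0.5)
        sample.int(orf_codons - 2L, 1L) + 1L else NA_integer_
      fs <- if (stats::runif(1) < 0.5)
        sample(c(1L, 2L, 4L), 1L) else NA_integer_
      fx <- plant_orf_fixture(orf_codons, stop_at, fs, code)
      status <- if (!is.na(stop_at) && !is.na(fx$frameshift_column)) "both"
                else if (!is.na(stop_at)) "premature_stop"
                else if (!is.na(fx$frameshift_column)) "frameshift"
                else "intact"
      fixtures[[i]] <- list(id = id, kind = "orf", observed = fx$observed,
                            reference = fx$reference)
      rows[[i]] <- data.frame(id = id, kind = "orf",
                              nonanucleotide_pos = NA_integer_,
                              hairpin_stem = NA_integer_,
                              status = status, stop_codon = fx$stop_codon,
                              frameshift_column = fx$frameshift_column,
                              motifs = NA_character_, stringsAsFactors = FALSE)
    } else {
      k <- sample.int(length(motifs), 1L)
      picked <- sort(sample(names(motifs), k))
      fx <- plant_protein_fixture(protein_length, picked, motifs)
      fixtures[[i]] <- list(id = id, kind = "protein", seq = fx$seq)
      rows[[i]] <- data.frame(id = id, kind = "protein",
                              nonanucleotide_pos = NA_integer_,
                              hairpin_stem = NA_integer_,
                              status = NA_character_, stop_codon = NA_integer_,
                              frameshift_column = NA_integer_,
                              motifs = fx$motifs, stringsAsFactors = FALSE)
    }
  }
  list(fixtures = fixtures, manifest = do.call(rbind, rows),
       params = list(min_stem = min_stem, max_loop = max_loop,
                     max_mismatch = max_mismatch, motifs = motifs))
}

#' Screen a fixture battery and tabulate the detected features
#'
#' Runs the screening detectors over fixtures from
#' [generate_screening_fixtures()] and returns a table of identical shape
#' to the manifest, for direct comparison.
#'
#' @param battery Output of [generate_screening_fixtures()].
#' @return Data frame shaped like `battery$manifest`.
#' @export
screen_fixture_battery <- function(battery) {
  pars <- battery$params
  rows <- lapply(battery$fixtures, function(fx) {
    row <- data.frame(id = fx$id, kind = fx$kind,
                      nonanucleotide_pos = NA_integer_,
                      hairpin_stem = NA_integer_,
                      status = NA_character_, stop_codon = NA_integer_,
                      frameshift_column = NA_integer_,
                      motifs = NA_character_, stringsAsFactors = FALSE)
    if (fx$kind == "nuc") {
      hits <- find_nonanucleotide(fx$seq)
      if (nrow(hits) > 0L) {
        row$nonanucleotide_pos <- hits$position[1]
        call <- find_stem_loop(fx$seq, hits$position[1],
                               min_stem = pars$min_stem,
                               max_loop = pars$max_loop,
                               max_mismatch = pars$max_mismatch)
        if (!is.null(call)) row$hairpin_stem <- call$stem_length
      }
    } else if (fx$kind == "orf") {
      v <- check_orf_intactness(fx$observed, fx$reference, aligned = TRUE)
      row$status <- v$status
      row$stop_codon <- v$stop_codon
      row$frameshift_column <- v$frameshift_column
    } else {
      hits <- detect_rcr_motifs(fx$seq, pars$motifs)
      if (nrow(hits) > 0L) {
        row$motifs <- paste(sprintf("%s:%d", hits$motif, hits$position),
                            collapse = ",")
      }
    }
    row
  })
  do.call(rbind, rows)
}
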