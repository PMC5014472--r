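test_that("nonanucleotide search finds direct, absent and wrapped matches", {
  hits <- find_nonanucleotide("ACGTAATATTACGGA", both_strands = FALSE)
  expect_equal(hits$position, 4)
  expect_equal(hits$strand, "+")
  # the near-palindromic motif also occurs as a reverse-complement overlap
  both <- find_nonanucleotide("ACGTAATATTACGGA")
  expect_equal(both$position, c(3, 4))
  expect_equal(both$strand, c("-", "+"))
  expect_equal(nrow(find_nonanucleotide("AAAA")), 0)
  # circular match spanning the origin
  circ <- find_nonanucleotide("ATTACGGGGTAAT", circular = TRUE,
                              both_strands = FALSE)
  expect_equal(circ$position, 10)
  expect_equal(circ$strand, "+")
  # the same sequence linear: no hit
  expect_equal(nrow(find_nonanucleotide("ATTACGGGGTAAT", circular = FALSE,
                                        both_strands = FALSE)), 0)
})

test_that("hits on a sequence and its reverse complement mirror each other", {
  set.seed(61)
  for (r in 1:5) {
    s <- paste0(paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                      collapse = ""),
                "TAATATTAC",
                paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                      collapse = ""))
    rc <- egvselect:::revcomp(s)
    h_fwd <- find_nonanucleotide(s)
    h_rc <- find_nonanucleotide(rc)
    L <- nchar(s)
    # every + hit at p maps to a - hit at L - p - 7 on the complement
    for (k in seq_len(nrow(h_fwd))) {
      mapped <- L - h_fwd$position[k] - 7
      other <- h_rc[h_rc$position == mapped, ]
      expect_equal(nrow(other), 1)
      expect_true(other$strand != h_fwd$strand[k])
    }
  }
})

test_that("a planted perfect GC stem around the loop is called exactly", {
  arm <- "GGCCGGGC"
  loop <- "AATAATATTACAA"   # 13 nt containing the nonanucleotide
  # flanks chosen non-complementary so the stem cannot extend past the arms
  s <- paste0("AAAAAAAAAA", arm, loop, egvselect:::revcomp(arm), "CCCCCCCCCC")
  anchor <- find_nonanucleotide(s, both_strands = FALSE)$position[1]
  call <- find_stem_loop(s, anchor)
  expect_equal(call$stem_length, 8)
  expect_equal(call$mismatches, 0)
  expect_equal(call$gc_fraction, 1.0)
  expect_equal(call$loop_end - call$loop_start + 1, 13)
})

test_that("no qualifying stem returns NULL", {
  s <- paste0(strrep("A", 30), "TAATATTAC", strrep("A", 30))
  expect_null(find_stem_loop(s, 31))
})

test_that("ORF intactness classifies stops, frameshifts and intact ORFs", {
  ref <- "ATGAAATGGTAG"
  expect_equal(check_orf_intactness("ATGAAATGGTAG", ref)$status, "intact")
  v <- check_orf_intactness("ATGTAATGGTAG", ref)
  expect_equal(v$status, "premature_stop")
  expect_equal(v$stop_codon, 2)
  # 1-nt deletion relative to the reference (alignment supplied)
  v2 <- check_orf_intactness("ATGAA-TGGTAG", ref, aligned = TRUE)
  expect_equal(v2$status, "frameshift")
  expect_equal(v2$frameshift_column, 6)
  # 3-nt deletion keeps the frame
  v3 <- check_orf_intactness("ATG---TGGTAG", ref, aligned = TRUE)
  expect_equal(v3$status, "intact")
  # both offences at once
  v4 <- check_orf_intactness("ATGTAAT-GTAG", ref, aligned = TRUE)
  expect_equal(v4$status, "both")
  expect_error(check_orf_intactness("ATGAAA", "ATGAA"), "frame")
  expect_error(check_orf_intactness("ATGAAA", "ATGTAATAG"), "internal stop")
})

test_that("an unaligned 1-nt deletion is aligned and flagged", {
  ref <- paste0("ATG", "AAACCCGGGTTTAGAAGACAT", "TGA")
  obs <- paste0("ATG", "AAACCCGGGTTAGAAGACAT", "TGA")  # one T dropped
  v <- check_orf_intactness(obs, ref)
  expect_equal(v$status, "frameshift")
})

test_that("RCR motif scan hits planted motifs and nothing in poly-alanine", {
  pep <- paste0("AAAAAAAAAA", "FLTY", "AAAAAAAA", "HDH", "AAAAAAAA",
                "YQPK", "AAAAAAAA", "GMWERGKT", "AAAA")
  hits <- detect_rcr_motifs(pep)
  expect_setequal(hits$motif, c("RCR-I", "RCR-II", "RCR-III", "dNTP-binding"))
  expect_equal(hits$position[hits$motif == "RCR-I"], 11)
  expect_equal(hits$position[hits$motif == "RCR-II"], 23)
  expect_equal(hits$position[hits$motif == "RCR-III"], 34)
  expect_equal(hits$position[hits$motif == "dNTP-binding"], 46)
  expect_equal(nrow(detect_rcr_motifs(strrep("A", 50))), 0)
  expect_error(detect_rcr_motifs("ALXT*"), NA)  # stop/X symbols tolerated
  expect_error(detect_rcr_motifs("AL1T"), "invalid residues")
  expect_error(detect_rcr_motifs("AAAA", motifs = c(bad = "[")), "invalid motif")
})

test_that("haplotype counting: naive count, conservative bound, wildcards", {
  expect_equal(count_distinct_haplotypes(c("ACGT", "ACGT", "ACGT"))[1:2],
               list(naive = 1L, lower_bound = 1L))
  expect_equal(count_distinct_haplotypes(c("ACGT", "ACGA", "ACGT"))[1:2],
               list(naive = 2L, lower_bound = 2L))
  # N is compatible with both others, which conflict with each other
  out <- count_distinct_haplotypes(c("ACNT", "ACGT", "ACTT"))
  expect_equal(out$naive, 3L)
  expect_equal(out$lower_bound, 2L)
  expect_error(count_distinct_haplotypes(c("ACGT", "ACG")), "equal length")
})

test_that("terminal gaps are wildcards but internal gaps are differences", {
  out <- count_distinct_haplotypes(c("--GTACGT", "ACGTACGT"))
  expect_equal(out$lower_bound, 1L)
  out2 <- count_distinct_haplotypes(c("AC-TACGT", "ACGTACGT"))
  expect_equal(out2$lower_bound, 2L)
})

test_that("conservative bound never exceeds the naive count (property)", {
  set.seed(62)
  for (r in 1:20) {
    n <- sample(3:12, 1)
    L <- 30
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      x <- base
      k <- sample(0:3, 1)
      if (k > 0) {
        idx <- sample(L, k)
        x[idx] <- sample(c("A", "C", "G", "T", "N"), k, replace = TRUE)
      }
      paste(x, collapse = "")
    }, character(1))
    out <- count_distinct_haplotypes(seqs)
    expect_lte(out$lower_bound, out$naive)
    # members of one grouping class never conflict, so the number of
    # classes is itself an upper bound certificate for compatibility
    expect_gte(length(unique(out$grouping)), out$lower_bound)
  }
})

test_that("brute-force maximum conflicting set matches the clique bound", {
  set.seed(63)
  for (r in 1:10) {
    n <- sample(3:7, 1)
    L <- 8
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "N"), L, replace = TRUE), collapse = ""),
      character(1))
    out <- count_distinct_haplotypes(seqs)
    # brute force over all subsets
    masks <- egvselect:::symbol_masks()
    M <- t(vapply(seqs, function(s)
      unname(masks[strsplit(s, "")[[1]]]), integer(L)))
    conflict <- function(i, j) any(bitwAnd(M[i, ], M[j, ]) == 0L)
    best <- 1L
    for (sz in n:2) {
      combos <- utils::combn(n, sz)
      for (c_i in seq_len(ncol(combos))) {
        set <- combos[, c_i]
        pairs <- utils::combn(set, 2)
        if (all(vapply(seq_len(ncol(pairs)), function(p)
          conflict(pairs[1, p], pairs[2, p]), logical(1)))) {
          best <- sz
          break
        }
      }
      if (best == sz) break
    }
    expect_equal(out$lower_bound, best)
  }
})
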