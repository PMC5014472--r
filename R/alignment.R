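#' In-frame codon alignments
#'
#' A `codon_alignment` stores the aligned coding sequences as a taxa x sites
#' matrix of codon strings plus, for the likelihood machinery, the set of
#' compatible sense-codon states per cell (gaps and IUPAC ambiguity codes
#' contribute partial likelihood 1 over all compatible states). An
#' unambiguous in-frame stop codon is rejected with a pointer to the
#' screening filter.
#'
#' @param sequences Named character vector of aligned nucleotide sequences,
#'   equal lengths divisible by 3.
#' @param code A [genetic_code()].
#' @return A `codon_alignment` object.
#' @export
codon_alignment <- function(sequences, code = universal_code()) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must have unique names")
  }
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stop("aligned sequences must have equal length")
  if (lens[1] %% 3 != 0) stop("alignment length must be divisible by 3 (in-frame)")
  nsite <- lens[1] %/% 3
  codons <- matrix("", nrow = length(sequences), ncol = nsite,
                   dimnames = list(names(sequences), NULL))
  for (i in seq_along(sequences)) {
    codons[i, ] <- substring(sequences[i], 3 * seq_len(nsite) - 2, 3 * seq_len(nsite))
  }
  stop_hits <- which(matrix(codons %in% code$stops, nrow = nrow(codons)),
                     arr.ind = TRUE)
  if (nrow(stop_hits) > 0L) {
    stop("in-frame stop codon in sequence '",
         rownames(codons)[stop_hits[1, 1]], "' at codon ", stop_hits[1, 2],
         "; run the screening filter (check_orf_intactness) and remove ",
         "non-intact sequences before fitting")
  }
  structure(list(codons = codons, taxa = names(sequences), n_sites = nsite,
                 code = code),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", length(x$taxa), "taxa x", x$n_sites, "codons\n")
  invisible(x)
}

#' Read an in-frame codon alignment from FASTA
#'
#' @param file FASTA path.
#' @param code A [genetic_code()].
#' @export
read_codon_alignment <- function(file, code = universal_code()) {
  ss <- Biostrings::readBStringSet(file)
  codon_alignment(stats::setNames(as.character(ss), names(ss)), code = code)
}

#' Write a codon alignment to FASTA
#'
#' @param aln A `codon_alignment`.
#' @param file Output path.
#' @export
write_codon_alignment <- function(aln, file) {
  stopifnot(inherits(aln, "codon_alignment"))
  seqs <- apply(aln$codons, 1, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(seqs, aln$taxa)), file)
  invisible(file)
}

# Site-pattern compression: unique columns of codon strings with counts.
# Fully-missing columns (every cell compatible with all states) are kept;
# they contribute log(1) per category and are harmless.
compress_patterns <- function(aln) {
  keys <- apply(aln$codons, 2, paste, collapse = "\r")
  first <- !duplicated(keys)
  counts <- as.numeric(table(keys)[keys[first]])
  list(columns = which(first), counts = counts,
       site_to_pattern = match(keys, keys[first]))
}

# Tip conditional likelihoods: 61 x npat x ntaxa array of 0/1 indicators.
tip_conditionals <- function(aln, patterns = compress_patterns(aln)) {
  code <- aln$code
  nstate <- length(code$codons)
  npat <- length(patterns$columns)
  ntax <- length(aln$taxa)
  arr <- array(0, dim = c(nstate, npat, ntax))
  # cache state sets per distinct codon string
  uniq <- unique(as.vector(aln$codons[, patterns$columns, drop = FALSE]))
  sets <- codon_state_sets(uniq, code)
  names(sets) <- uniq
  for (i in seq_len(ntax)) {
    for (j in seq_len(npat)) {
      arr[sets[[aln$codons[i, patterns$columns[j]]]], j, i] <- 1
    }
  }
  arr
}
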