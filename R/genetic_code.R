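#' Genetic-code machinery for codon models
#'
#' A genetic code object fixes the mapping from codons to amino acids, the
#' stop-codon set, and — crucially for the rate-matrix code — a stable index
#' over the sense codons. The index is lexicographic with nucleotide order
#' `A < C < G < T`, so for the universal code sense codon 1 is `AAA` and
#' sense codon 61 is `TTT`.
#'
#' @param table Named character vector mapping all 64 codons to one-letter
#'   amino acids, with `"*"` for stop codons. Defaults to the universal
#'   (standard) code.
#' @return An object of class `genetic_code` with components:
#'   \describe{
#'     \item{codons}{character(61), sense codons in lexicographic order}
#'     \item{stops}{character, the stop codons}
#'     \item{aa}{character(61), amino acid per sense codon}
#'     \item{codon_nuc}{61 x 3 integer matrix of nucleotide indices (A=1,
#'       C=2, G=3, T=4) per codon position}
#'     \item{index}{named integer vector codon -> 1..61}
#'   }
#' @examples
#' gc <- genetic_code()
#' length(gc$codons)   # 61
#' gc$stops            # TAA TAG TGA
#' @export
genetic_code <- function(table = NULL) {
  if (is.null(table)) {
    table <- Biostrings::GENETIC_CODE
  }
  if (length(table) != 64L || is.null(names(table))) {
    stop("genetic code table must be a named vector with 64 codon entries")
  }
  nucs <- c("A", "C", "G", "T")
  all_codons <- sort(names(table))  # lexicographic, A < C < G < T
  aa_all <- table[all_codons]
  stops <- all_codons[aa_all == "*"]
  codons <- all_codons[aa_all != "*"]
  if (length(codons) < 2L) stop("degenerate genetic code: fewer than 2 sense codons")
  mat <- t(vapply(strsplit(codons, ""), function(x) match(x, nucs), integer(3)))
  idx <- seq_along(codons)
  names(idx) <- codons
  structure(
    list(codons = codons, stops = stops, aa = unname(aa_all[codons]),
         codon_nuc = mat, index = idx),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", length(x$codons), "sense codons, stops:",
      paste(x$stops, collapse = " "), "\n")
  invisible(x)
}

# Cached universal code; rebuilt lazily (cheap, but called in inner loops).
.egv_env <- new.env(parent = emptyenv())

universal_code <- function() {
  if (is.null(.egv_env$ucode)) .egv_env$ucode <- genetic_code()
  .egv_env$ucode
}

# Map codon strings (possibly with IUPAC ambiguity or gaps) to the set of
# compatible sense-codon indices. "---"/"NNN" etc. -> all 61. A codon that
# resolves only to stop codons is an error: stop codons in-frame are data
# the screening stage should have removed.
codon_state_sets <- function(codon_strings, code = universal_code()) {
  iupac <- Biostrings::IUPAC_CODE_MAP
  iupac <- c(iupac, "-" = "ACGT", "." = "ACGT", "?" = "ACGT")
  lapply(codon_strings, function(cd) {
    cd <- toupper(cd)
    parts <- strsplit(cd, "")[[1]]
    if (length(parts) != 3L) stop("codon string must have length 3: ", cd)
    if (any(!parts %in% names(iupac))) {
      stop("invalid nucleotide symbol in codon: ", cd)
    }
    opts <- lapply(parts, function(p) strsplit(iupac[[p]], "")[[1]])
    combos <- expand.grid(opts, stringsAsFactors = FALSE)
    cods <- paste0(combos[[1]], combos[[2]], combos[[3]])
    hit <- unname(code$index[cods[cods %in% code$codons]])
    if (length(hit) == 0L) {
      stop("codon '", cd, "' resolves only to stop codons; ",
           "run the screening filter (check_orf_intactness) before fitting")
    }
    sort(hit)
  })
}
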