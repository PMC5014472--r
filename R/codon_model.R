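#' Codon-substitution model: CF3x4 frequencies, MG94xREV rates, mixtures
#'
#' The rate matrix follows the MG94 convention crossed with a general
#' time-reversible (GTR) nucleotide model: a single-nucleotide change
#' `a -> b` at codon position `p` has rate
#' `r(a,b) * f[p, b] * (omega if nonsynonymous else 1)`,
#' where `r` is the symmetric nucleotide exchangeability (GT fixed at 1) and
#' `f` is the 3x4 positional nucleotide frequency matrix. Equilibrium codon
#' frequencies are the CF3x4 form: positional products renormalised over
#' sense codons after stop exclusion. Matrices are scaled so the neutral
#' (`omega = 1`) process has mean rate 1 substitution per codon site per
#' unit branch length; the same constant is applied to every omega category
#' so branch lengths are comparable across selection regimes.
#'
#' @name codon_model
NULL

nuc_names <- c("A", "C", "G", "T")
exch_names <- c("AC", "AG", "AT", "CG", "CT")

#' Positional nucleotide frequencies
#'
#' @param f 3x4 numeric matrix, rows = codon positions, columns = A, C, G, T;
#'   each row must sum to 1.
#' @return Validated matrix with dimnames set.
#' @export
positional_frequencies <- function(f) {
  f <- as.matrix(f)
  if (!all(dim(f) == c(3L, 4L))) stop("positional frequencies must be 3x4")
  if (any(f < 0)) stop("positional frequencies must be non-negative")
  if (any(abs(rowSums(f) - 1) > 1e-8)) {
    stop("each row of the positional frequency matrix must sum to 1")
  }
  dimnames(f) <- list(paste0("pos", 1:3), nuc_names)
  f
}

#' Empirical positional frequencies of a codon alignment
#'
#' Observed nucleotide proportions at each codon position, the plug-in
#' input for [cf3x4_frequencies()]. Gaps and ambiguity codes are ignored.
#'
#' @param aln A `codon_alignment` (see [read_codon_alignment()]).
#' @return 3x4 positional frequency matrix.
#' @export
empirical_positional_frequencies <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  chars <- strsplit(as.character(t(aln$codons)), "")  # per codon, 3 chars
  m <- matrix(0, 3, 4, dimnames = list(paste0("pos", 1:3), nuc_names))
  flat <- unlist(chars)
  pos <- rep_len(1:3, length(flat))
  keep <- flat %in% nuc_names
  tab <- table(factor(pos[keep], 1:3), factor(flat[keep], nuc_names))
  m[] <- as.numeric(tab)
  sw <- rowSums(m)
  if (any(sw == 0)) stop("a codon position has no unambiguous nucleotides")
  positional_frequencies(m / sw)
}

#' CF3x4 equilibrium codon frequencies
#'
#' Products of positional nucleotide frequencies over the sense codons,
#' renormalised after excluding stop codons. With uniform positional
#' frequencies this reduces to the uniform distribution over the 61 sense
#' codons.
#'
#' @param pos_freqs 3x4 positional frequency matrix
#'   ([positional_frequencies()]).
#' @param code A [genetic_code()].
#' @return Named numeric vector of length 61 summing to 1.
#' @examples
#' pf <- positional_frequencies(matrix(0.25, 3, 4))
#' pi <- cf3x4_frequencies(pf)
#' all.equal(unname(pi), rep(1/61, 61))
#' @export
cf3x4_frequencies <- function(pos_freqs, code = universal_code()) {
  f <- positional_frequencies(pos_freqs)
  cn <- code$codon_nuc
  pi <- f[1, cn[, 1]] * f[2, cn[, 2]] * f[3, cn[, 3]]
  s <- sum(pi)
  if (s <= 0) {
    stop("unusable positional frequencies: every sense codon has product 0")
  }
  pi <- pi / s
  names(pi) <- code$codons
  pi
}

#' Omega mixture distribution for one branch partition
#'
#' Three dN/dS categories: `omega1 <= 1` (purifying), `omega2 = 1` fixed
#' (neutral), `omega3 >= 1` (positive), with mixture weights `p1`, `p2`,
#' and `1 - p1 - p2`.
#'
#' @param omega1 Purifying rate ratio in `[0, 1]`.
#' @param omega3 Positive rate ratio `>= 1`.
#' @param p1,p2 Weights of the purifying and neutral categories.
#' @return An `omega_distribution` object.
#' @export
omega_distribution <- function(omega1, omega3 = 1, p1, p2 = 1 - p1) {
  if (omega1 < 0 || omega1 > 1) stop("omega1 must lie in [0, 1]")
  if (omega3 < 1) stop("omega3 must be >= 1")
  if (p1 < 0 || p2 < 0) stop("mixture weights must be non-negative")
  if (p1 + p2 > 1 + 1e-12) stop("p1 + p2 must not exceed 1")
  structure(
    list(omega = c(omega1, 1, omega3),
         weights = c(p1, p2, max(0, 1 - p1 - p2))),
    class = "omega_distribution"
  )
}

#' @export
print.omega_distribution <- function(x, ...) {
  cat(sprintf("omega mixture: w1=%.4g (p=%.3f)  w2=1 (p=%.3f)  w3=%.4g (p=%.3f)\n",
              x$omega[1], x$weights[1], x$weights[2], x$omega[3], x$weights[3]))
  invisible(x)
}

# The neutral-rate normalising constant: expected rate of the omega = 1
# matrix under pi. Shared across categories.
neutral_rate_constant <- function(ex, pi, pos_freqs, code = universal_code()) {
  Q1 <- rate_matrix_unscaled(ex, pi, pos_freqs, omega = 1, code = code)
  -sum(pi * diag(Q1))
}

validate_exchangeabilities <- function(ex) {
  ex <- as.numeric(ex)
  if (length(ex) != 5L) stop("need 5 exchangeabilities (AC, AG, AT, CG, CT); GT is fixed at 1")
  if (any(ex <= 0)) stop("exchangeabilities must be positive")
  names(ex) <- exch_names
  ex
}

# Symmetric 4x4 exchangeability matrix with GT = 1.
exch_matrix <- function(ex) {
  ex <- validate_exchangeabilities(ex)
  r <- matrix(0, 4, 4, dimnames = list(nuc_names, nuc_names))
  r["A", "C"] <- ex["AC"]; r["A", "G"] <- ex["AG"]; r["A", "T"] <- ex["AT"]
  r["C", "G"] <- ex["CG"]; r["C", "T"] <- ex["CT"]; r["G", "T"] <- 1
  r + t(r)
}

rate_matrix_unscaled <- function(ex, pi, pos_freqs, omega, code) {
  n <- length(code$codons)
  r <- exch_matrix(ex)
  f <- positional_frequencies(pos_freqs)
  cn <- code$codon_nuc
  Q <- matrix(0, n, n, dimnames = list(code$codons, code$codons))
  for (p in 1:3) {
    same_other <- outer(cn[, -p, drop = FALSE][, 1], cn[, -p, drop = FALSE][, 1], "==") &
      outer(cn[, -p, drop = FALSE][, 2], cn[, -p, drop = FALSE][, 2], "==")
    diff_here <- outer(cn[, p], cn[, p], "!=")
    hit <- which(same_other & diff_here, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    a <- cn[hit[, 1], p]; b <- cn[hit[, 2], p]
    rate <- r[cbind(a, b)] * f[cbind(p, b)]
    nonsyn <- code$aa[hit[, 1]] != code$aa[hit[, 2]]
    rate[nonsyn] <- rate[nonsyn] * omega
    Q[hit] <- rate
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Build the scaled MG94xREV codon rate matrix
#'
#' @param ex Five nucleotide exchangeabilities (AC, AG, AT, CG, CT); GT = 1.
#' @param pi Equilibrium codon frequencies ([cf3x4_frequencies()]); must be
#'   consistent with `pos_freqs`.
#' @param pos_freqs 3x4 positional frequency matrix supplying the MG94
#'   target-nucleotide factor.
#' @param omega Nonsynonymous/synonymous rate ratio, `>= 0`.
#' @param code A [genetic_code()].
#' @param scale_constant Optional precomputed neutral-rate constant; pass it
#'   when building several categories so all share one scaling.
#' @return 61x61 generator matrix (rows sum to 0).
#' @export
build_rate_matrix <- function(ex, pi, pos_freqs, omega, code = universal_code(),
                              scale_constant = NULL) {
  if (omega < 0) stop("omega must be non-negative")
  if (is.null(scale_constant)) {
    scale_constant <- neutral_rate_constant(ex, pi, pos_freqs, code)
  }
  Q <- rate_matrix_unscaled(ex, pi, pos_freqs, omega, code)
  Q / scale_constant
}

#' Transition probability matrix exp(Qt)
#'
#' Computed through the symmetric similarity transform available for
#' reversible generators: `S = D^{1/2} Q D^{-1/2}` with `D = diag(pi)` is
#' symmetric, so `exp(Qt) = D^{-1/2} V exp(Lambda t) V' D^{1/2}` from one
#' symmetric eigendecomposition. Numerical dust below 0 is clamped and rows
#' renormalised.
#'
#' @param Q Generator matrix from [build_rate_matrix()].
#' @param t Branch length `>= 0` (expected substitutions per codon site at
#'   the neutral rate).
#' @param pi Stationary distribution of `Q`; recovered from the generator
#'   if omitted.
#' @return Stochastic matrix of the same dimension as `Q`.
#' @export
transition_matrix <- function(Q, t, pi = NULL) {
  if (t < 0) stop("branch length t must be non-negative")
  if (is.null(pi)) pi <- stationary_from_generator(Q)
  eg <- reversible_eigen(Q, pi)
  P <- transition_from_eigen(eg, t)
  dimnames(P) <- dimnames(Q)
  P
}

# pi q_ij = pi_j q_ji  =>  pi_i proportional to the detailed-balance weights;
# recover pi from one off-diagonal pair per state via the first row chain.
stationary_from_generator <- function(Q) {
  # For a reversible generator, pi solves pi Q = 0; use the null space.
  d <- eigen(t(Q))
  k <- which.min(abs(d$values))
  v <- Re(d$vectors[, k])
  v <- abs(v)
  v / sum(v)
}

reversible_eigen <- function(Q, pi) {
  if (any(pi <= 0)) stop("stationary distribution must be strictly positive for the symmetric transform")
  s <- sqrt(pi)
  S <- (s * Q) %*% diag(1 / s)          # rows scaled by sqrt(pi)
  S <- (S + t(S)) / 2                   # symmetrise residual asymmetry
  eg <- eigen(S, symmetric = TRUE)
  list(values = eg$values, vectors = eg$vectors, sqrt_pi = s)
}

transition_from_eigen <- function(eg, t) {
  V <- eg$vectors
  E <- V %*% (exp(eg$values * t) * t(V))
  P <- (1 / eg$sqrt_pi) * E %*% diag(eg$sqrt_pi)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Per-branch mixture transition matrix
#'
#' Under branch-site random-effects independence each site draws its omega
#' category independently on each branch, so the branch's effective
#' transition matrix is the weight-averaged mixture of the three category
#' matrices.
#'
#' @param dist An [omega_distribution()].
#' @param ex,pos_freqs Shared nucleotide exchangeabilities and positional
#'   frequencies.
#' @param t Branch length.
#' @param code A [genetic_code()].
#' @return 61x61 stochastic matrix.
#' @export
branch_mixture_matrix <- function(dist, ex, pos_freqs, t, code = universal_code()) {
  stopifnot(inherits(dist, "omega_distribution"))
  pi <- cf3x4_frequencies(pos_freqs, code)
  sc <- neutral_rate_constant(ex, pi, pos_freqs, code)
  P <- matrix(0, length(pi), length(pi), dimnames = list(code$codons, code$codons))
  for (k in 1:3) {
    if (dist$weights[k] == 0) next
    Qk <- build_rate_matrix(ex, pi, pos_freqs, dist$omega[k], code, scale_constant = sc)
    P <- P + dist$weights[k] * transition_matrix(Qk, t, pi)
  }
  P
}
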