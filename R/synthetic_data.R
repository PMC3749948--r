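# Synthetic alignment generators: each produces data with exactly the
# statistical structure one pipeline stage assumes, so every stage can
# be validated without external downloads.

#' Fully conserved alignment
#'
#' M copies of one fixed sequence (the seed only picks the sequence).
#' Downstream, with a positive pseudocount, the Pearson matrix of this
#' alignment has exactly three distinct eigenvalues: one large
#' non-degenerate eigenvalue with an extended eigenvector, an (L-1)-fold
#' degenerate small eigenvalue whose eigenspace admits a basis localized
#' on pairs of sites with opposite-sign components, and the eigenvalue 1
#' with multiplicity (q-2)L.
#'
#' @param L Number of positions (>= 2).
#' @param q Alphabet size (states 1..q of the standard alphabet).
#' @param M Number of (identical) sequences.
#' @param seed Integer seed used only to draw the conserved sequence.
#' @param sequence Optional explicit conserved sequence (integer states
#'   in 1..q, length L); overrides \code{seed}.
#' @return An [encoded_msa()] object.
#' @export
conserved_msa <- function(L, q = 21L, M = 10L, seed = 1L, sequence = NULL) {
  stopifnot(L >= 2, M >= 1, q >= 3)
  if (is.null(sequence)) {
    set.seed(seed)
    seq1 <- sample.int(q, L, replace = TRUE)
  } else {
    stopifnot(length(sequence) == L, all(sequence >= 1), all(sequence <= q))
    seq1 <- as.integer(sequence)
  }
  encoded_msa(matrix(seq1, nrow = M, ncol = L, byrow = TRUE),
              alphabet = hp_alphabet()[seq_len(q)])
}

#' Independent-site (profile) alignment
#'
#' Samples each column i.i.d. from a per-site frequency profile: the
#' null model in which all covariance vanishes, all eigenvalues tend to
#' one and all patterns (hence couplings) vanish with growing M.
#'
#' @param profile L x q matrix of per-site state frequencies, rows
#'   summing to one.
#' @param M Number of sequences.
#' @param seed Integer seed.
#' @return An [encoded_msa()] object.
#' @export
independent_msa <- function(profile, M, seed) {
  profile <- as.matrix(profile)
  if (any(profile < 0) || any(abs(rowSums(profile) - 1) > 1e-8)) {
    stop("profile rows must be nonnegative and sum to 1")
  }
  L <- nrow(profile); q <- ncol(profile)
  set.seed(seed)
  d <- vapply(seq_len(L), function(i)
    sample.int(q, M, replace = TRUE, prob = profile[i, ]), integer(M))
  encoded_msa(d, alphabet = hp_alphabet()[seq_len(q)])
}

#' Uniformly random alignment
#'
#' Convenience wrapper around [independent_msa()] with the uniform
#' profile; useful as a featureless null.
#'
#' @param L,q,M Dimensions.
#' @param seed Integer seed.
#' @return An [encoded_msa()] object.
#' @export
random_msa <- function(L, q, M, seed) {
  independent_msa(matrix(1 / q, L, q), M, seed)
}

#' Two-site planted pattern
#'
#' The elementary covariation motif: a pattern with exactly two nonzero
#' components, \eqn{\xi_i(a) = c} and \eqn{\xi_j(b) = \pm c}.  With
#' opposite signs and repulsive character it enforces an XOR-type
#' constraint favoring the joint presence or joint absence of the two
#' states; with equal signs it merely biases their co-occurrence count.
#'
#' @param L,q Dimensions.
#' @param i,a First site and state.
#' @param j,b Second site and state.
#' @param c Component magnitude (default 1).
#' @param equal_sign If TRUE both components are +c; default FALSE
#'   (opposite signs).
#' @param sign Pattern character, "repulsive" (default) or "attractive".
#' @return An \code{hp_pattern}.
#' @export
two_site_pattern <- function(L, q, i, a, j, b, c = 1,
                             equal_sign = FALSE,
                             sign = c("repulsive", "attractive")) {
  sign <- match.arg(sign)
  stopifnot(i != j, i >= 1, j <= L, a >= 1, a <= q, b >= 1, b <= q)
  xi <- matrix(0, L, q)
  xi[i, a] <- c
  xi[j, b] <- if (equal_sign) c else -c
  structure(list(xi = xi, sign = sign, eigenvalue = NA_real_,
                 omega = NA_real_, loglik_contribution = NA_real_,
                 ipr = ipr(xi), delta = coupling_contribution(xi),
                 mode = NA_integer_),
            class = "hp_pattern")
}

#' Alignment sampled from a planted low-rank Hopfield-Potts model
#'
#' Builds the coupling model of the given patterns (plus optional
#' fields), samples M sequences with the Gibbs sampler, and returns both
#' the alignment and the ground-truth model for recovery tests.
#'
#' @param L,q Dimensions.
#' @param patterns List of \code{hp_pattern} objects (e.g. from
#'   [two_site_pattern()]); may be empty for a pure profile model.
#' @param h Optional L x q field matrix (default zero: uniform profile).
#' @param M Number of sequences to sample.
#' @param seed Integer seed.
#' @param burn_in,thin Gibbs sampler settings.
#' @return List with \code{msa} (an [encoded_msa()]) and \code{model}
#'   (the ground-truth \code{hp_model}).
#' @export
planted_pattern_family <- function(L, q, patterns, h = NULL, M, seed,
                                   burn_in = 1000L, thin = 10L) {
  model <- if (length(patterns) == 0L) {
    coupling_model(matrix(0, L * q, L * q), h, L = L, q = q, rank = 0L)
  } else {
    m <- build_couplings(patterns)
    if (m$L != L || m$q != q) stop("pattern dimensions do not match L, q")
    if (!is.null(h)) m$h <- h
    m
  }
  msa <- gibbs_sample(model, n_sequences = M, seed = seed,
                      burn_in = burn_in, thin = thin)
  list(msa = msa, model = model)
}
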