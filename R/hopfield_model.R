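# The generative Hopfield-Potts model: log-scores, low-rank couplings,
# fields, exact enumeration for tiny systems, Gibbs sampling.
#
# Couplings are stored as a dense symmetric Lq x Lq matrix in site-major
# blocks; diagonal (i = i) blocks are zero, and within every block the
# q-th row and column are zero (the gauge that sets all parameters
# involving the last alphabet state to zero).

#' Log-score of a sequence under one pattern
#'
#' \eqn{S = (\sum_i \xi_i(a_i))^2}.  The square makes the score a
#' covariation statistic: for a two-site pattern with opposite-sign
#' components it behaves as an XOR of the two favored residues (score 1
#' when exactly one is present, 0 when both or neither are), while
#' equal-sign components score 4 when both are present.
#'
#' @param seq Integer vector of states in 1..q, length L.
#' @param pattern An \code{hp_pattern} or an L x q component matrix.
#' @return Nonnegative scalar, invariant under a global sign flip of
#'   the pattern.
#' @export
log_score <- function(seq, pattern) {
  xi <- if (inherits(pattern, "hp_pattern")) pattern$xi else pattern
  if (length(seq) != nrow(xi)) {
    stop("sequence length ", length(seq), " does not match pattern length ",
         nrow(xi))
  }
  if (any(seq < 1L) || any(seq > ncol(xi))) stop("sequence states out of range")
  sum(xi[cbind(seq_len(nrow(xi)), seq)])^2
}

#' Construct a coupling model
#'
#' @param e Dense symmetric Lq x Lq coupling matrix (site-major blocks,
#'   zero diagonal blocks, gauge rows/columns zero).
#' @param h L x q field matrix with \code{h[, q] = 0}, or NULL.
#' @param L,q Dimensions.
#' @param rank Number of patterns behind \code{e}.
#' @return Object of class \code{hp_model}.
#' @export
coupling_model <- function(e, h = NULL, L, q, rank = NA_integer_) {
  if (!isTRUE(all.equal(dim(e), c(L * q, L * q)))) {
    stop("e must be an Lq x Lq matrix")
  }
  if (is.null(h)) h <- matrix(0, nrow = L, ncol = q)
  stopifnot(nrow(h) == L, ncol(h) == q)
  structure(list(e = e, h = h, L = L, q = q, rank = rank),
            class = "hp_model")
}

#' @export
print.hp_model <- function(x, ...) {
  cat(sprintf("Hopfield-Potts model: L = %d, q = %d, coupling rank %s\n",
              x$L, x$q, ifelse(is.na(x$rank), "unknown", x$rank)))
  invisible(x)
}

# rows of the site-major block of position i
.site_idx <- function(i, q) (i - 1L) * q + seq_len(q)

#' Low-rank couplings from a pattern set
#'
#' \deqn{e_{ij}(a,b) = \sum_{\mu\,attr} \xi^\mu_i(a)\xi^\mu_j(b)
#'   - \sum_{\nu\,rep} \xi^\nu_i(a)\xi^\nu_j(b), \qquad i \ne j.}
#' With all \eqn{(q-1)L} patterns included this reproduces the mean-field
#' DCA couplings \eqn{-(C^{-1})_{ij}(a,b)} (the signed prefactors
#' \eqn{\pm\omega^2(\lambda) = 1 - 1/\lambda} resum the inverse of the
#' Pearson matrix, up to the block-diagonal part which is not part of the
#' couplings).  The result is invariant under the choice of orthonormal
#' basis within degenerate eigen-subspaces.
#'
#' @param patset An \code{hp_patternset}, or a list of \code{hp_pattern}
#'   objects.
#' @return An \code{hp_model} with fields set to zero.
#' @export
build_couplings <- function(patset) {
  patterns <- if (inherits(patset, "hp_patternset")) patset$patterns else patset
  if (length(patterns) == 0L) stop("cannot infer dimensions from an empty pattern list; use coupling_model() directly")
  dims <- vapply(patterns, function(p) dim(p$xi), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all patterns must share the same L and q")
  }
  L <- dims[1, 1]; q <- dims[2, 1]
  Xi <- t(vapply(patterns, function(p) as.vector(t(p$xi)), numeric(L * q)))
  sgn <- ifelse(vapply(patterns, `[[`, character(1), "sign") == "attractive", 1, -1)
  e <- crossprod(Xi, sgn * Xi)
  for (i in seq_len(L)) {
    idx <- .site_idx(i, q)
    e[idx, idx] <- 0
  }
  e <- (e + t(e)) / 2
  coupling_model(e, h = NULL, L = L, q = q, rank = length(patterns))
}

#' Fields from single-site frequencies and couplings
#'
#' Mean-field/independent-site closure in the last-state gauge:
#' \deqn{h_i(a) = \ln\frac{f_i(a)}{f_i(q)} - \sum_{j \ne i} \sum_b e_{ij}(a,b) f_j(b)}
#' for a = 1..q-1 and \eqn{h_i(q) = 0}.  With zero couplings these are
#' exactly the PSSM fields of the independent-site model.
#'
#' @param freqs An \code{hp_freqs} object.
#' @param model An \code{hp_model} (couplings; fields are overwritten).
#' @return The model with fields filled in.
#' @export
fit_fields <- function(freqs, model) {
  stopifnot(inherits(freqs, "hp_freqs"), inherits(model, "hp_model"))
  L <- model$L; q <- model$q
  if (freqs$L != L || freqs$q != q) stop("dimension mismatch between freqs and model")
  if (any(freqs$f1 <= 0)) {
    stop("zero single-site frequencies; use a positive pseudocount_fraction")
  }
  fvec <- as.vector(t(freqs$f1))                # site-major, full q states
  mean_field <- matrix(model$e %*% fvec, nrow = L, ncol = q, byrow = TRUE)
  h <- log(freqs$f1 / freqs$f1[, q]) - mean_field
  h[, q] <- 0                                   # exact by gauge, enforce bitwise
  model$h <- h
  model
}

#' Exact distribution of a small model
#'
#' Enumerates all q^L sequences of
#' \eqn{P(a) \propto \exp(\sum_{i<j} e_{ij}(a_i,a_j) + \sum_i h_i(a_i))}
#' and returns the normalization, all probabilities and the one- and
#' two-site marginals.  Guarded to \eqn{q^L \le 10^6}; larger state
#' spaces must use [gibbs_sample()].
#'
#' @param model An \code{hp_model}.
#' @return List with \code{configs} (q^L x L integer matrix), \code{P},
#'   \code{logZ}, \code{f1} (L x q), \code{f2} (Lq x Lq, site-major,
#'   diagonal blocks diag(f1)).
#' @export
enumerate_distribution <- function(model) {
  L <- model$L; q <- model$q
  if (q^L > 1e6) {
    stop("state space q^L = ", q^L, " exceeds the enumeration guard (1e6); ",
         "use gibbs_sample() instead")
  }
  configs <- as.matrix(expand.grid(rep(list(seq_len(q)), L)))
  colnames(configs) <- NULL
  storage.mode(configs) <- "integer"
  n <- nrow(configs)
  # energy = sum_i h + sum_{i<j} e
  E <- numeric(n)
  for (i in seq_len(L)) {
    E <- E + model$h[i, configs[, i]]
  }
  for (i in seq_len(L - 1L)) {
    ri <- (i - 1L) * q
    for (j in (i + 1L):L) {
      rj <- (j - 1L) * q
      E <- E + model$e[cbind(ri + configs[, i], rj + configs[, j])]
    }
  }
  Emax <- max(E)
  w <- exp(E - Emax)
  Z <- sum(w)
  P <- w / Z
  f1 <- matrix(0, L, q)
  for (i in seq_len(L)) {
    f1[i, ] <- vapply(seq_len(q), function(a) sum(P[configs[, i] == a]),
                      numeric(1))
  }
  f2 <- matrix(0, L * q, L * q)
  for (i in seq_len(L)) {
    idx_i <- .site_idx(i, q)
    f2[idx_i, idx_i] <- diag(f1[i, ], nrow = q)
    if (i < L) {
      for (j in (i + 1L):L) {
        idx_j <- .site_idx(j, q)
        blk <- matrix(0, q, q)
        for (a in seq_len(q)) {
          sel <- configs[, i] == a
          if (any(sel)) {
            blk[a, ] <- vapply(seq_len(q), function(b)
              sum(P[sel & configs[, j] == b]), numeric(1))
          }
        }
        f2[idx_i, idx_j] <- blk
        f2[idx_j, idx_i] <- t(blk)
      }
    }
  }
  list(configs = configs, P = P, logZ = log(Z) + Emax, f1 = f1, f2 = f2)
}

#' Sample an alignment from the model by Gibbs sampling
#'
#' Single-site heat-bath updates in fixed site order 1..L.  One chain is
#' run for \code{burn_in} sweeps, then a sequence is emitted every
#' \code{thin} sweeps until \code{n_sequences} have been collected.
#' Deterministic for a fixed seed.
#'
#' @param model An \code{hp_model}.
#' @param n_sequences Number of sequences to emit.
#' @param seed Integer seed.
#' @param burn_in Burn-in sweeps (default 1000).
#' @param thin Sweeps between emitted sequences (default 10).
#' @return An [encoded_msa()] object (alphabet truncated to the model's
#'   q states).
#' @export
gibbs_sample <- function(model, n_sequences, seed, burn_in = 1000L, thin = 10L) {
  stopifnot(inherits(model, "hp_model"), n_sequences >= 1)
  set.seed(seed)
  start <- sample.int(model$q, model$L, replace = TRUE)
  out <- gibbs_sample_cpp(model$e, t(model$h), model$L, model$q,
                          as.integer(n_sequences), as.integer(burn_in),
                          as.integer(thin), as.integer(start))
  encoded_msa(out, alphabet = hp_alphabet()[seq_len(model$q)])
}

#' Interaction log-likelihood ratio of a p-pattern model
#'
#' \eqn{\sum_{k\,selected} s(\lambda_k) / \sum_k s(\lambda_k)}: the
#' fraction of the maximal interaction log-likelihood captured by the p
#' most likely patterns.  Zero at p = 0, one at full rank,
#' non-decreasing in p.
#'
#' @param spectrum An \code{hp_spectrum}.
#' @param p Number of patterns.
#' @return Value in \[0, 1\].
#' @export
interaction_likelihood_ratio <- function(spectrum, p) {
  stopifnot(inherits(spectrum, "hp_spectrum"))
  n <- length(spectrum$eigvals)
  if (p < 0 || p > n) stop("p must be in 0..", n)
  if (p == 0) return(0)
  s <- likelihood_contribution(spectrum$eigvals)
  total <- sum(s)
  if (total == 0) return(1)
  ord <- order(-s, spectrum$eigvals, seq_len(n))
  sum(s[ord[seq_len(p)]]) / total
}

#' Serialize a model to a plain-text file
#'
#' Block format: a header line \code{model L q rank}, then \code{h i a
#' value} lines for all nonzero fields and \code{e i j a b value} lines
#' for all nonzero couplings with i < j; 1-based indices, full
#' \code{\%.17g} precision for bit-exact round-trips.
#'
#' @param model An \code{hp_model}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "hp_model"))
  L <- model$L; q <- model$q
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("model %d %d %d", L, q,
                     ifelse(is.na(model$rank), -1L, model$rank)), con)
  nz <- which(model$h != 0, arr.ind = TRUE)
  if (nrow(nz)) {
    writeLines(sprintf("h %d %d %.17g", nz[, 1], nz[, 2],
                       model$h[nz]), con)
  }
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      blk <- model$e[.site_idx(i, q), .site_idx(j, q), drop = FALSE]
      nz <- which(blk != 0, arr.ind = TRUE)
      if (nrow(nz)) {
        writeLines(sprintf("e %d %d %d %d %.17g", i, j, nz[, 1], nz[, 2],
                           blk[nz]), con)
      }
    }
  }
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path Input path.
#' @return An \code{hp_model}.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1], "model ")) {
    stop("not a model file: ", path)
  }
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]][-1])
  L <- hdr[1]; q <- hdr[2]; rank <- if (hdr[3] < 0) NA_integer_ else hdr[3]
  e <- matrix(0, L * q, L * q)
  h <- matrix(0, L, q)
  for (line in lines[-1]) {
    tok <- strsplit(line, " ", fixed = TRUE)[[1]]
    if (tok[1] == "h") {
      h[as.integer(tok[2]), as.integer(tok[3])] <- as.numeric(tok[4])
    } else if (tok[1] == "e") {
      i <- as.integer(tok[2]); j <- as.integer(tok[3])
      a <- as.integer(tok[4]); b <- as.integer(tok[5])
      v <- as.numeric(tok[6])
      e[(i - 1L) * q + a, (j - 1L) * q + b] <- v
      e[(j - 1L) * q + b, (i - 1L) * q + a] <- v
    } else {
      stop("unrecognized model line: ", line)
    }
  }
  coupling_model(e, h, L = L, q = q, rank = rank)
}
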