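# Sequence reweighting, regularized frequencies, covariance and Pearson
# correlation matrix.
#
# Throughout, the "reduced" representation keeps only states 1..q-1 at
# each site (the last alphabet state is dropped, never the gap, which is
# state 1).  Reduced site-major indexing: entry (i, a) of an L x (q-1)
# array sits at row (i-1)(q-1) + a of the corresponding matrix.

#' Similarity-based sequence weights
#'
#' Each sequence is down-weighted by the number of alignment members
#' closer than a Hamming-distance fraction \code{theta} of the length:
#' \eqn{w_b = 1 / |\{b' : d(a^b, a^{b'}) < \theta L\}|}, with every
#' sequence always counting its exact duplicates (and itself), so that
#' \code{theta = 0} reduces to duplicate removal.  Gaps count as an
#' ordinary 21st state in the distance.  The sum
#' \eqn{M_{eff} = \sum_b w_b} is the effective number of independent
#' sequences.
#'
#' @param msa An [encoded_msa()] object.
#' @param theta Distance fraction in \[0, 1); default 0.2, the standard
#'   mean-field DCA value.
#' @return Object of class \code{hp_weights}: list with \code{w},
#'   \code{theta}, \code{M_eff}.
#' @export
compute_weights <- function(msa, theta = 0.2) {
  stopifnot(inherits(msa, "encoded_msa"))
  if (theta < 0 || theta >= 1) stop("theta must be in [0, 1)")
  d <- msa$data
  M <- nrow(d); L <- ncol(d)
  key <- apply(d, 1L, paste0, collapse = ",")
  uk <- unique(key)
  cls <- match(key, uk)            # class of each sequence
  mult <- tabulate(cls, nbins = length(uk))
  U <- d[match(uk, key), , drop = FALSE]
  nu <- nrow(U)
  cutoff <- theta * L
  # neighbour count per unique class: exact duplicates always count;
  # distinct classes count when their Hamming distance is < theta*L
  neigh <- mult
  if (cutoff > 0 && nu > 1L) {
    q <- msa$q
    chunk <- max(1L, floor(2^22 / nu))
    for (start in seq(1L, nu, by = chunk)) {
      idx <- start:min(start + chunk - 1L, nu)
      # matches[u, v] = number of agreeing positions between U[idx[u],] and U[v,]
      matches <- matrix(0, nrow = length(idx), ncol = nu)
      for (a in seq_len(q)) {
        A <- U[idx, , drop = FALSE] == a
        if (!any(A)) next
        matches <- matches + tcrossprod(A * 1, (U == a) * 1)
      }
      dist <- L - matches
      within <- dist < cutoff
      # exclude same-class pairs (already counted via mult)
      within[cbind(seq_along(idx), idx)] <- FALSE
      neigh[idx] <- neigh[idx] + as.vector(within %*% mult)
    }
  }
  w <- 1 / neigh[cls]
  structure(list(w = w, theta = theta, M_eff = sum(w)), class = "hp_weights")
}

#' Pseudocount-regularized frequency counts
#'
#' Weighted single-site and pair frequencies mixed with a uniform
#' pseudocount.  With total pseudocount mass
#' \eqn{\Lambda = \frac{pc}{1-pc} M_{eff}} (so that
#' \code{pseudocount_fraction} = 0.5 means half counts, half uniform
#' prior, independently of the alignment depth):
#' \deqn{f_i(A) = \frac{\Lambda/q + \sum_b w_b \delta(a_i^b, A)}{\Lambda + M_{eff}}}
#' \deqn{f_{ij}(A,B) = \frac{\Lambda/q^2 + \sum_b w_b \delta(a_i^b,A)\delta(a_j^b,B)}{\Lambda + M_{eff}}, \quad i \ne j}
#' and \eqn{f_{ii}(A,B) = f_i(A)\delta(A,B)} for consistency.
#'
#' @param msa An [encoded_msa()] object.
#' @param weights An \code{hp_weights} object, or NULL for unit weights.
#' @param pseudocount_fraction Relative pseudocount weight in \[0, 1);
#'   default 0.5, the standard mean-field DCA value.
#' @return Object of class \code{hp_freqs}: list with \code{f1} (L x q
#'   matrix), \code{f2} (Lq x Lq matrix in site-major blocks, diagonal
#'   blocks equal to \code{diag(f1[i, ])}), \code{pseudocount_fraction},
#'   \code{M_eff}, \code{L}, \code{q}.
#' @export
compute_frequencies <- function(msa, weights = NULL, pseudocount_fraction = 0.5) {
  stopifnot(inherits(msa, "encoded_msa"))
  pc <- pseudocount_fraction
  if (pc < 0 || pc >= 1) stop("pseudocount_fraction must be in [0, 1)")
  d <- msa$data
  M <- nrow(d); L <- ncol(d); q <- msa$q
  w <- if (is.null(weights)) rep(1, M) else weights$w
  if (length(w) != M) stop("weights length does not match alignment depth")
  M_eff <- sum(w)
  Lambda <- pc / (1 - pc) * M_eff
  denom <- Lambda + M_eff
  # sparse indicator matrix: M rows, L*q columns, site-major:
  # row b has a 1 in column (i-1)*q + a_i^b for every position i
  cols <- sweep(d, 2L, (seq_len(L) - 1L) * q, `+`)
  X <- Matrix::sparseMatrix(i = rep(seq_len(M), times = L),
                            j = as.vector(cols),
                            x = 1, dims = c(M, L * q))
  f1vec <- (Lambda / q + as.vector(Matrix::crossprod(X, w))) / denom
  f1 <- matrix(f1vec, nrow = L, ncol = q, byrow = TRUE)
  f2 <- as.matrix(Matrix::crossprod(X, X * w))
  f2 <- (Lambda / q^2 + f2) / denom
  # enforce the i = j consistency blocks
  for (i in seq_len(L)) {
    idx <- (i - 1L) * q + seq_len(q)
    f2[idx, idx] <- diag(f1[i, ], nrow = q)
  }
  structure(list(f1 = f1, f2 = f2, pseudocount_fraction = pc,
                 M_eff = M_eff, L = L, q = q),
            class = "hp_freqs")
}

# stacked reduced single-site frequencies, length (q-1)*L
.reduced_f1_vec <- function(freqs) {
  as.vector(t(freqs$f1[, -freqs$q, drop = FALSE]))
}

# indices of reduced states within the full Lq site-major layout
.reduced_index <- function(L, q) {
  as.vector(vapply(seq_len(L), function(i) (i - 1L) * q + seq_len(q - 1L),
                   integer(q - 1L)))
}

#' Covariance matrix in the reduced representation
#'
#' \eqn{C_{ij}(a,b) = f_{ij}(a,b) - f_i(a) f_j(b)} for reduced states
#' \eqn{a, b \in 1..q-1} (last alphabet state dropped), returned as a
#' symmetric \eqn{(q-1)L \times (q-1)L} matrix in site-major blocks.
#'
#' @param freqs An \code{hp_freqs} object.
#' @return Numeric matrix with attributes \code{L} and \code{q}.
#' @export
compute_covariance <- function(freqs) {
  stopifnot(inherits(freqs, "hp_freqs"))
  L <- freqs$L; q <- freqs$q
  keep <- .reduced_index(L, q)
  fv <- .reduced_f1_vec(freqs)
  C <- freqs$f2[keep, keep, drop = FALSE] - tcrossprod(fv)
  C <- (C + t(C)) / 2
  attr(C, "L") <- L
  attr(C, "q") <- q
  C
}

#' Pearson correlation matrix and its spectrum
#'
#' Whiten the covariance matrix by the symmetric square roots of its
#' per-site diagonal blocks: \eqn{\Gamma_{ij} = D_i^{-1/2} C_{ij} D_j^{-1/2}}
#' with \eqn{D_i = C_{ii}}, so each diagonal block of \eqn{\Gamma} is the
#' identity, and compute the full symmetric eigendecomposition with
#' eigenvalues in decreasing order.  The mean eigenvalue equals 1 (the
#' trace of \eqn{\Gamma} is its dimension).
#'
#' @param C Reduced covariance matrix from [compute_covariance()].
#' @return Object of class \code{hp_spectrum}: list with \code{Gamma},
#'   \code{eigvals}, \code{eigvecs} (columns), per-site lists
#'   \code{D_sqrt} and \code{D_sqrt_inv}, and \code{L}, \code{q}.
#' @export
compute_pearson <- function(C) {
  L <- attr(C, "L"); q <- attr(C, "q")
  if (is.null(L) || is.null(q)) stop("C must come from compute_covariance()")
  r <- q - 1L
  D_sqrt <- vector("list", L)
  D_sqrt_inv <- vector("list", L)
  for (i in seq_len(L)) {
    idx <- (i - 1L) * r + seq_len(r)
    ei <- eigen(C[idx, idx, drop = FALSE], symmetric = TRUE)
    if (any(ei$values < 1e-12)) {
      stop("single-site covariance block at position ", i,
           " is numerically singular (min eigenvalue ",
           format(min(ei$values)), "); use a positive pseudocount_fraction")
    }
    D_sqrt[[i]] <- ei$vectors %*% (sqrt(ei$values) * t(ei$vectors))
    D_sqrt_inv[[i]] <- ei$vectors %*% ((1 / sqrt(ei$values)) * t(ei$vectors))
  }
  Dinv <- matrix(0, r * L, r * L)
  for (i in seq_len(L)) {
    idx <- (i - 1L) * r + seq_len(r)
    Dinv[idx, idx] <- D_sqrt_inv[[i]]
  }
  Gamma <- Dinv %*% C %*% Dinv
  Gamma <- (Gamma + t(Gamma)) / 2
  ev <- eigen(Gamma, symmetric = TRUE)   # decreasing eigenvalue order
  structure(list(Gamma = Gamma, eigvals = ev$values, eigvecs = ev$vectors,
                 D_sqrt = D_sqrt, D_sqrt_inv = D_sqrt_inv, L = L, q = q),
            class = "hp_spectrum")
}

#' @export
print.hp_spectrum <- function(x, ...) {
  cat(sprintf("Pearson spectrum: L = %d, q = %d, %d modes; lambda in [%.4g, %.4g], mean %.6f\n",
              x$L, x$q, length(x$eigvals), min(x$eigvals), max(x$eigvals),
              mean(x$eigvals)))
  invisible(x)
}

#' Write the eigenvalue spectrum as CSV
#' @param spectrum An \code{hp_spectrum} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(k = seq_along(spectrum$eigvals),
                              lambda = spectrum$eigvals),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write per-sequence weights as CSV
#' @param msa An [encoded_msa()] object.
#' @param weights An \code{hp_weights} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_weights_csv <- function(msa, weights, path) {
  utils::write.csv(data.frame(label = msa$labels, w = weights$w),
                   path, row.names = FALSE)
  invisible(path)
}
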