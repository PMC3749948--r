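# Hopfield-Potts patterns from eigenmodes of the Pearson matrix:
# construction, likelihood-based selection, localization diagnostics.

#' Per-pattern log-likelihood contribution
#'
#' The contribution of the eigenmode with eigenvalue \eqn{\lambda} to the
#' model log-likelihood, per unit of \eqn{M_{eff}}:
#' \deqn{s(\lambda) = (\lambda - 1 - \ln\lambda) / 2.}
#' It vanishes at \eqn{\lambda = 1}, decreases on (0, 1) and increases on
#' (1, Inf): both the largest and the smallest eigenvalues contribute
#' strongly, eigenvalues near one contribute little.  The overall
#' \eqn{M_{eff}} factor is common to all modes and irrelevant for ranking
#' or likelihood ratios, so it is omitted.
#'
#' @param lambda Positive eigenvalue(s).
#' @return Nonnegative value(s) of s.
#' @export
likelihood_contribution <- function(lambda) {
  if (any(lambda <= 0)) stop("lambda must be positive")
  (lambda - 1 - log(lambda)) / 2
}

#' Pattern prefactor
#'
#' \eqn{\omega(\lambda) = \sqrt{|1 - 1/\lambda|}}; zero at
#' \eqn{\lambda = 1}, below 1 for attractive modes (\eqn{\lambda > 1}),
#' unbounded as \eqn{\lambda \to 0}.
#'
#' @param lambda Positive eigenvalue(s).
#' @return Prefactor value(s).
#' @export
pattern_prefactor <- function(lambda) {
  if (any(lambda <= 0)) stop("lambda must be positive")
  sqrt(abs(1 - 1 / lambda))
}

#' Build the Hopfield-Potts pattern of one eigenmode
#'
#' The pattern of mode k is \eqn{\xi_i(a) = \omega(\lambda_k)
#' (D_i^{-1/2} v_k)_i(a)} on the reduced states a = 1..q-1, extended with
#' \eqn{\xi_i(q) = 0} (gauge).  Modes with \eqn{\lambda > 1} give
#' attractive patterns, \eqn{\lambda < 1} repulsive ones.
#'
#' @param spectrum An \code{hp_spectrum} from [compute_pearson()].
#' @param k Mode index (1 = largest eigenvalue).
#' @return Object of class \code{hp_pattern}: list with \code{xi} (L x q
#'   matrix), \code{sign} ("attractive"/"repulsive"), \code{eigenvalue},
#'   \code{omega}, \code{loglik_contribution}, \code{ipr}, \code{delta},
#'   \code{mode}.
#' @export
pattern_from_mode <- function(spectrum, k) {
  stopifnot(inherits(spectrum, "hp_spectrum"))
  n <- length(spectrum$eigvals)
  if (k < 1 || k > n) stop("mode index k must be in 1..", n)
  L <- spectrum$L; q <- spectrum$q; r <- q - 1L
  lam <- spectrum$eigvals[k]
  om <- pattern_prefactor(lam)
  v <- spectrum$eigvecs[, k]
  xi <- matrix(0, nrow = L, ncol = q)
  for (i in seq_len(L)) {
    idx <- (i - 1L) * r + seq_len(r)
    xi[i, seq_len(r)] <- om * as.vector(spectrum$D_sqrt_inv[[i]] %*% v[idx])
  }
  pat <- structure(list(xi = xi, sign = if (lam > 1) "attractive" else "repulsive",
                        eigenvalue = lam, omega = om,
                        loglik_contribution = likelihood_contribution(lam),
                        ipr = NA_real_, delta = NA_real_, mode = k),
                   class = "hp_pattern")
  if (any(xi != 0)) {
    pat$ipr <- ipr(pat)
    pat$delta <- coupling_contribution(pat)
  } else {
    pat$delta <- 0
  }
  pat
}

#' Inverse participation ratio of a pattern
#'
#' \eqn{IPR = \sum_{i,a} \xi_i(a)^4 / (\sum_{i,a} \xi_i(a)^2)^2}: equals
#' 1 for a pattern concentrated on a single component and 1/N for a
#' pattern uniformly spread over N components.  Scale-invariant.
#'
#' @param pattern An \code{hp_pattern}, or a numeric matrix/vector of
#'   components.
#' @return IPR in (0, 1].
#' @export
ipr <- function(pattern) {
  x <- if (inherits(pattern, "hp_pattern")) pattern$xi else pattern
  s2 <- sum(x^2)
  if (s2 == 0) stop("IPR is undefined for an all-zero pattern")
  sum(x^4) / s2^2
}

#' Typical coupling contribution of a pattern
#'
#' The couplings generated by one pattern are the pairwise outer products
#' \eqn{\xi_i(a)\xi_j(b)}.  Their typical magnitude over the pattern's
#' effectively occupied site pairs is
#' \deqn{\Delta = \sqrt{\sum_{i \ne j} \sum_{a,b} (\xi_i(a)\xi_j(b))^2 / (N_{eff}(N_{eff}-1))}}
#' with \eqn{N_{eff} = 1/IPR} the effective number of components.
#' Homogeneous of degree 2 in the pattern scale; zero for the null
#' pattern.  Localized patterns of large norm give few, large
#' contributions.
#'
#' @param pattern An \code{hp_pattern} or numeric L x q matrix.
#' @return Nonnegative scalar.
#' @export
coupling_contribution <- function(pattern) {
  x <- if (inherits(pattern, "hp_pattern")) pattern$xi else pattern
  if (all(x == 0)) return(0)
  site_sq <- rowSums(x^2)                       # sum_a xi_i(a)^2 per site
  total <- sum(site_sq)^2 - sum(site_sq^2)      # sum_{i != j} of products
  n_eff <- 1 / ipr(x)
  n_pair_eff <- n_eff * max(n_eff - 1, .Machine$double.eps)
  sqrt(total / n_pair_eff)
}

#' Select the p most likely patterns
#'
#' Ranks all eigenmodes by their likelihood contribution \eqn{s(\lambda)}
#' and keeps the top p (ties broken toward the smaller eigenvalue, then
#' the smaller mode index).  Reports the eigenvalue thresholds
#' \code{x_minus} < 1 < \code{x_plus} bracketing inclusion and the counts
#' of attractive (p_plus) and repulsive (p_minus) selected patterns.
#' Numerically degenerate eigenvalue groups (gap < 1e-9) make individual
#' patterns basis-dependent (couplings are not affected); a warning lists
#' them when some but not all members of a group are selected.
#'
#' @param spectrum An \code{hp_spectrum}.
#' @param p Number of patterns, 0..(q-1)L.
#' @return Object of class \code{hp_patternset}: list with
#'   \code{patterns}, \code{p_plus}, \code{p_minus}, \code{x_minus},
#'   \code{x_plus}, \code{modes}, \code{spectrum_eigvals}.
#' @export
select_patterns <- function(spectrum, p) {
  stopifnot(inherits(spectrum, "hp_spectrum"))
  n <- length(spectrum$eigvals)
  if (p < 0 || p > n) stop("p must be in 0..", n)
  lam <- spectrum$eigvals
  s <- likelihood_contribution(lam)
  ord <- order(-s, lam, seq_len(n))
  sel <- ord[seq_len(p)]
  if (p > 0 && p < n) {
    # warn when a numerically degenerate group straddles the cut
    near <- which(abs(lam - lam[sel[p]]) < 1e-9)
    if (length(near) > 1L && !all(near %in% sel)) {
      warning("eigenvalue group {", paste(near, collapse = ","),
              "} is numerically degenerate across the selection cut; ",
              "per-pattern outputs within it are basis-dependent")
    }
  }
  patterns <- lapply(sel, function(k) pattern_from_mode(spectrum, k))
  lam_sel <- lam[sel]
  structure(list(patterns = patterns,
                 p_plus = sum(lam_sel > 1),
                 p_minus = sum(lam_sel < 1),
                 x_plus = if (any(lam_sel > 1)) min(lam_sel[lam_sel > 1]) else Inf,
                 x_minus = if (any(lam_sel < 1)) max(lam_sel[lam_sel < 1]) else 0,
                 modes = sel, spectrum_eigvals = lam),
            class = "hp_patternset")
}

#' @export
print.hp_patternset <- function(x, ...) {
  cat(sprintf("Hopfield-Potts pattern set: p = %d (%d attractive, %d repulsive); thresholds x- = %.4g, x+ = %.4g\n",
              length(x$patterns), x$p_plus, x$p_minus, x$x_minus, x$x_plus))
  invisible(x)
}

#' Select patterns by target likelihood fraction
#'
#' Chooses the smallest p such that the selected patterns capture at
#' least \code{fraction} of the total interaction log-likelihood
#' \eqn{\sum_k s(\lambda_k)}.  A fraction around 0.9 typically retains
#' contact-prediction performance while discarding most modes.
#'
#' @param spectrum An \code{hp_spectrum}.
#' @param fraction Target in \[0, 1\].
#' @return An \code{hp_patternset}.
#' @export
select_patterns_by_fraction <- function(spectrum, fraction) {
  stopifnot(inherits(spectrum, "hp_spectrum"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  s <- likelihood_contribution(spectrum$eigvals)
  n <- length(s)
  ord <- order(-s, spectrum$eigvals, seq_len(n))
  cum <- cumsum(s[ord])
  total <- sum(s)
  p <- if (total == 0) 0L else which(cum >= fraction * total - 1e-15)[1]
  if (is.na(p)) p <- n
  select_patterns(spectrum, p)
}

#' Summary table of a pattern set
#'
#' @param patset An \code{hp_patternset}.
#' @return data.frame with one row per pattern: mode k, lambda, sign,
#'   s(lambda), omega, IPR, Delta.
#' @export
pattern_summary <- function(patset) {
  stopifnot(inherits(patset, "hp_patternset"))
  do.call(rbind, lapply(patset$patterns, function(p) {
    data.frame(k = p$mode, lambda = p$eigenvalue, sign = p$sign,
               s = p$loglik_contribution, omega = p$omega,
               ipr = p$ipr, delta = p$delta)
  }))
}

#' Write one pattern as TSV (position, state symbol, component)
#' @param pattern An \code{hp_pattern}.
#' @param path Output path.
#' @param alphabet Symbol vector (default [hp_alphabet()]).
#' @return Invisibly, \code{path}.
#' @export
write_pattern_tsv <- function(pattern, path, alphabet = hp_alphabet()) {
  xi <- pattern$xi
  df <- data.frame(position = rep(seq_len(nrow(xi)), times = ncol(xi)),
                   state = rep(alphabet[seq_len(ncol(xi))], each = nrow(xi)),
                   xi = as.vector(xi))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
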