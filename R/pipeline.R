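# End-to-end convenience wrapper used by the command-line interface and
# by recovery tests.

#' Run the full Hopfield-Potts pipeline on an alignment
#'
#' Reweighting, regularized frequencies, covariance, Pearson spectrum,
#' pattern selection, low-rank couplings, fields, contact scores and the
#' ranked prediction list, in one call.
#'
#' @param msa An [encoded_msa()] object.
#' @param theta Reweighting distance fraction (default 0.2), or NULL
#'   for unit weights (appropriate for alignments known to be sampled
#'   i.i.d., e.g. synthetic families).
#' @param pseudocount_fraction Pseudocount weight (default 0.5).
#' @param p Number of patterns; exactly one of \code{p} and
#'   \code{loglik_fraction} must be given.
#' @param loglik_fraction Target interaction-likelihood fraction for
#'   pattern selection.
#' @param min_separation Minimum |i - j| for ranked pairs (default 5).
#' @return List with \code{weights}, \code{freqs}, \code{spectrum},
#'   \code{patterns} (an \code{hp_patternset}), \code{model},
#'   \code{scores}, \code{predictions}, \code{likelihood_ratio}.
#' @export
hp_pipeline <- function(msa, theta = 0.2, pseudocount_fraction = 0.5,
                        p = NULL, loglik_fraction = NULL,
                        min_separation = 5L) {
  if (is.null(p) == is.null(loglik_fraction)) {
    stop("give exactly one of p and loglik_fraction")
  }
  weights <- if (is.null(theta)) {
    structure(list(w = rep(1, nrow(msa$data)), theta = NA_real_,
                   M_eff = nrow(msa$data)), class = "hp_weights")
  } else {
    compute_weights(msa, theta = theta)
  }
  freqs <- compute_frequencies(msa, weights,
                               pseudocount_fraction = pseudocount_fraction)
  spectrum <- compute_pearson(compute_covariance(freqs))
  patset <- if (!is.null(p)) select_patterns(spectrum, p)
            else select_patterns_by_fraction(spectrum, loglik_fraction)
  if (length(patset$patterns) == 0L) {
    model <- coupling_model(matrix(0, msa$q * ncol(msa$data), msa$q * ncol(msa$data)),
                            L = ncol(msa$data), q = msa$q, rank = 0L)
  } else {
    model <- build_couplings(patset)
  }
  model <- fit_fields(freqs, model)
  scores <- apc(frobenius_scores(model))
  predictions <- rank_pairs(scores, min_separation = min_separation)
  list(weights = weights, freqs = freqs, spectrum = spectrum,
       patterns = patset, model = model, scores = scores,
       predictions = predictions,
       likelihood_ratio = interaction_likelihood_ratio(spectrum,
                                                       length(patset$patterns)))
}
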