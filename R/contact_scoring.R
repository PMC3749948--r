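# Contact scores from coupling blocks: zero-sum gauge, Frobenius norm,
# average product correction, ranked predictions.

#' Zero-sum (Ising) gauge of one coupling block
#'
#' Double-centering \eqn{\tilde e(a,b) = e(a,b) - e(\cdot,b) - e(a,\cdot)
#' + e(\cdot,\cdot)}, where the dot averages uniformly over all q states
#' including the gap.  All row and column means of the result are zero;
#' this is the gauge minimizing the Frobenius norm of the block, and it
#' removes any additive single-position term.  Idempotent.
#'
#' @param block Square q x q coupling block.
#' @return Double-centered block.
#' @export
zero_sum_gauge <- function(block) {
  block <- as.matrix(block)
  if (nrow(block) != ncol(block)) stop("coupling block must be square")
  rm <- rowMeans(block)
  cm <- colMeans(block)
  block - outer(rm, rep(1, ncol(block))) -
    outer(rep(1, nrow(block)), cm) + mean(block)
}

#' Frobenius-norm contact scores
#'
#' \eqn{F_{ij} = \sqrt{\sum_{a,b} \tilde e_{ij}(a,b)^2}} over the
#' zero-sum-gauge coupling blocks; \eqn{F_{ii} = 0} by convention.
#' Invariant under adding any single-position function to the couplings.
#'
#' @param model An \code{hp_model}.
#' @return Object of class \code{hp_scores}: list with \code{F} (L x L),
#'   \code{F_apc} (NULL until [apc()] is applied), \code{L}.
#' @export
frobenius_scores <- function(model) {
  stopifnot(inherits(model, "hp_model"))
  L <- model$L; q <- model$q
  F <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    idx_i <- (i - 1L) * q + seq_len(q)
    for (j in (i + 1L):L) {
      idx_j <- (j - 1L) * q + seq_len(q)
      blk <- zero_sum_gauge(model$e[idx_i, idx_j, drop = FALSE])
      F[i, j] <- F[j, i] <- sqrt(sum(blk^2))
    }
  }
  structure(list(F = F, F_apc = NULL, L = L), class = "hp_scores")
}

#' Average product correction
#'
#' \eqn{F^{APC}_{ij} = F_{ij} - F_{i\cdot} F_{\cdot j} / F_{\cdot\cdot}},
#' where \eqn{F_{i\cdot}} is the mean of row i over \eqn{j \ne i} and
#' \eqn{F_{\cdot\cdot}} the mean over all off-diagonal entries.  The
#' correction removes the separable (conservation/phylogeny-driven)
#' component of the score; a rank-one score matrix with constant factor
#' maps to exactly zero.
#'
#' @param scores An \code{hp_scores} from [frobenius_scores()], or a
#'   plain symmetric L x L matrix.
#' @return The \code{hp_scores} object with \code{F_apc} filled in.
#' @export
apc <- function(scores) {
  if (!inherits(scores, "hp_scores")) {
    scores <- structure(list(F = as.matrix(scores), F_apc = NULL,
                             L = nrow(as.matrix(scores))),
                        class = "hp_scores")
  }
  F <- scores$F
  L <- nrow(F)
  if (L < 3L) stop("APC needs at least 3 positions")
  row_mean <- rowSums(F) / (L - 1)     # diagonal is zero by convention
  total_mean <- sum(F) / (L * (L - 1))
  if (total_mean == 0) {
    warning("all contact scores are zero; APC returns zeros")
    scores$F_apc <- F
    return(scores)
  }
  Fapc <- F - outer(row_mean, row_mean) / total_mean
  diag(Fapc) <- 0
  scores$F_apc <- Fapc
  scores
}

#' Ranked contact predictions
#'
#' Pairs (i, j), i < j, with \eqn{|i - j| \ge} \code{min_separation},
#' sorted by decreasing APC-corrected score; ties broken by (i, j)
#' lexicographic order.
#'
#' @param scores An \code{hp_scores} with \code{F_apc} filled (APC is
#'   applied on the fly if missing).
#' @param min_separation Minimum |i - j| (default 5, excluding trivial
#'   short-range pairs).
#' @return data.frame with columns rank, i, j, F, F_apc.
#' @export
rank_pairs <- function(scores, min_separation = 5L) {
  stopifnot(inherits(scores, "hp_scores"))
  if (min_separation < 0) stop("min_separation must be >= 0")
  if (is.null(scores$F_apc)) scores <- apc(scores)
  L <- scores$L
  pairs <- which(upper.tri(scores$F), arr.ind = TRUE)
  keep <- (pairs[, 2] - pairs[, 1]) >= min_separation
  pairs <- pairs[keep, , drop = FALSE]
  df <- data.frame(i = pairs[, 1], j = pairs[, 2],
                   F = scores$F[pairs],
                   F_apc = scores$F_apc[pairs])
  df <- df[order(-df$F_apc, df$i, df$j), , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Write ranked predictions as TSV
#' @param predictions data.frame from [rank_pairs()].
#' @param path Output path.
#' @param top Keep only the top N rows (default all).
#' @return Invisibly, \code{path}.
#' @export
write_predictions_tsv <- function(predictions, path, top = Inf) {
  if (is.finite(top)) predictions <- utils::head(predictions, top)
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
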