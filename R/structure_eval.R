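# Evaluation of predicted contacts against a 3D structure: minimal
# heavy-atom distance maps and true-positive-rate curves.

#' Minimal inter-residue distance map from a structure
#'
#' Reads ATOM records of one chain, keeps the highest-occupancy altLoc
#' per atom, drops hydrogens, and computes for every pair of mapped
#' alignment columns the minimum over all heavy-atom pairs of the
#' Euclidean distance.  The alignment-column-to-residue mapping must be
#' supplied explicitly as a table.
#'
#' @param pdb_file Path to a PDB file (first model of multi-model files).
#' @param chain Chain identifier.
#' @param mapping data.frame with columns \code{column} (1-based
#'   alignment column) and \code{resno} (residue number in the chain);
#'   an optional \code{ins} column holds insertion codes.
#' @param contact_cutoff Contact cutoff in Angstrom (default 8).
#' @return Object of class \code{hp_dmap}: list with \code{d} (symmetric
#'   distance matrix over mapped columns), \code{columns} (the mapped
#'   alignment columns, in order), \code{contact_cutoff}.
#' @export
distance_map <- function(pdb_file, chain, mapping, contact_cutoff = 8.0) {
  if (!all(c("column", "resno") %in% names(mapping))) {
    stop("mapping must have columns 'column' and 'resno'")
  }
  # rm.alt=FALSE: keep all altLoc records, we pick by occupancy below
  pdb <- suppressWarnings(bio3d::read.pdb(pdb_file, multi = FALSE,
                                          rm.alt = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' not found in ", pdb_file)
  # drop hydrogens; elesy may be missing, fall back on atom-name heuristics
  is_h <- !is.na(at$elesy) & toupper(trimws(at$elesy)) == "H"
  is_h <- is_h | grepl("^[0-9]*H", trimws(at$elety))
  at <- at[!is_h, , drop = FALSE]
  # altLoc: keep the highest-occupancy alternative per (resno, ins, elety)
  alt <- !is.na(at$alt) & at$alt != ""
  if (any(alt)) {
    key <- paste(at$resno, at$insert, at$elety, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      if (length(ix) == 1L) return(ix)
      ix[which.max(ifelse(is.na(at$o[ix]), 0, at$o[ix]))]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  ins <- if ("ins" %in% names(mapping)) as.character(mapping$ins) else
    rep("", nrow(mapping))
  ins[is.na(ins)] <- ""
  at_ins <- as.character(at$insert)
  at_ins[is.na(at_ins)] <- ""
  coords <- vector("list", nrow(mapping))
  missing <- character(0)
  for (r in seq_len(nrow(mapping))) {
    sel <- at$resno == mapping$resno[r] & at_ins == ins[r]
    if (!any(sel)) {
      missing <- c(missing, paste0(mapping$resno[r], ins[r]))
    } else {
      coords[[r]] <- cbind(at$x[sel], at$y[sel], at$z[sel])
    }
  }
  if (length(missing)) {
    stop("residues not found in chain '", chain, "': ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(mapping)
  d <- matrix(0, n, n)
  for (r in seq_len(n - 1L)) {
    for (s in (r + 1L):n) {
      A <- coords[[r]]; B <- coords[[s]]
      # all-pairs squared distances between the two residues' atoms
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
      d[r, s] <- d[s, r] <- sqrt(max(0, min(d2)))
    }
  }
  structure(list(d = d, columns = as.integer(mapping$column),
                 contact_cutoff = contact_cutoff),
            class = "hp_dmap")
}

#' True-positive rate curve of ranked contact predictions
#'
#' A predicted pair counts as a true positive when the minimal heavy-atom
#' distance of the mapped residues is strictly below \code{cutoff}.
#' Pairs with an unmapped endpoint are skipped and do not consume a
#' rank.  TP(n) is the fraction of true positives among the first n
#' scored pairs.
#'
#' @param predictions data.frame from [rank_pairs()] (columns i, j, in
#'   rank order).
#' @param dmap An \code{hp_dmap} from [distance_map()].
#' @param cutoff Contact cutoff in Angstrom (default the map's cutoff).
#' @param min_separation Optional additional |i - j| filter (default 0:
#'   assume predictions were already filtered).
#' @return data.frame with columns n, i, j, distance, contact, tp_rate.
#' @export
tp_rate_curve <- function(predictions, dmap, cutoff = dmap$contact_cutoff,
                          min_separation = 0L) {
  stopifnot(inherits(dmap, "hp_dmap"))
  if (nrow(predictions) == 0L) stop("empty prediction list")
  keep <- abs(predictions$j - predictions$i) >= min_separation
  predictions <- predictions[keep, , drop = FALSE]
  ri <- match(predictions$i, dmap$columns)
  rj <- match(predictions$j, dmap$columns)
  mapped <- !is.na(ri) & !is.na(rj)
  predictions <- predictions[mapped, , drop = FALSE]
  if (nrow(predictions) == 0L) stop("no prediction pair is mapped to the structure")
  dist <- dmap$d[cbind(ri[mapped], rj[mapped])]
  contact <- dist < cutoff
  data.frame(n = seq_len(nrow(predictions)),
             i = predictions$i, j = predictions$j,
             distance = dist, contact = contact,
             tp_rate = cumsum(contact) / seq_along(contact))
}
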