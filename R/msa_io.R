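# Alignment input/output and integer encoding over the 21-letter alphabet.

#' The fixed 21-letter alphabet
#'
#' State 1 is the gap \code{'-'}; states 2..21 are the 20 standard amino
#' acids in alphabetical order (A, C, D, ..., Y).  The gap deliberately
#' occupies the first state so that the reduced representation used for
#' the covariance matrix (which drops the *last* state) never discards
#' the gap: gap symbols carry genuine signal, e.g. in patterns reflecting
#' alignment-boundary gap stretches.
#'
#' @return Character vector of length 21.
#' @export
hp_alphabet <- function() {
  c("-", "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Lookup table: ASCII character -> state in 1..21.  Built once at load.
.encode_table <- local({
  tab <- rep.int(1L, 256L)  # default: gap state (covers '.', unknowns)
  aa <- hp_alphabet()
  for (s in seq_along(aa)) {
    tab[utf8ToInt(aa[s]) + 1L] <- s
  }
  tab
})

#' Encode a character as an alphabet state
#'
#' Total on single ASCII characters: upper-case amino-acid letters map to
#' states 2..21; gap characters (\code{'-'}, \code{'.'}) map to state 1;
#' ambiguous or unknown residues (X, B, Z, U, O and anything else) also
#' map to the gap state, keeping the alphabet at q = 21 as in mean-field
#' DCA.  Lower-case letters denote insert states in Stockholm alignments
#' and are mapped to the gap state.
#'
#' @param c Character vector of single characters.
#' @return Integer vector of states in 1..21.
#' @export
#' @examples
#' encode_symbol(c("-", "A", "X", "a"))
encode_symbol <- function(c) {
  code <- vapply(as.character(c), function(ch) {
    if (nchar(ch) == 0L) return(1L)
    utf8ToInt(substr(ch, 1L, 1L))
  }, integer(1))
  code[code > 255L | code < 0L] <- utf8ToInt(".")
  # lower-case amino-acid letters are insert states -> gap
  lower <- code >= utf8ToInt("a") & code <= utf8ToInt("z")
  code[lower] <- utf8ToInt(".")
  unname(.encode_table[code + 1L])
}

#' Construct an encoded alignment
#'
#' @param data Integer matrix, M sequences (rows) by L positions
#'   (columns), entries in 1..q.
#' @param labels Optional per-sequence identifiers.
#' @param alphabet Ordered symbol vector mapping states to characters;
#'   defaults to [hp_alphabet()].
#' @return An object of class \code{encoded_msa} with fields
#'   \code{data}, \code{labels}, \code{alphabet}, \code{q}.
#' @export
encoded_msa <- function(data, labels = NULL, alphabet = hp_alphabet()) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  q <- length(alphabet)
  if (anyDuplicated(alphabet)) stop("alphabet symbols must be distinct")
  if (!"-" %in% alphabet) stop("alphabet must contain the gap symbol '-'")
  if (nrow(data) < 1L || ncol(data) < 2L) {
    stop("alignment must have M >= 1 sequences and L >= 2 positions")
  }
  if (anyNA(data) || any(data < 1L) || any(data > q)) {
    stop("alignment entries must be integers in [1, ", q, "]")
  }
  if (is.null(labels)) labels <- paste0("seq", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) {
    stop("labels must have one entry per sequence")
  }
  structure(list(data = data, labels = as.character(labels),
                 alphabet = alphabet, q = q),
            class = "encoded_msa")
}

#' @export
print.encoded_msa <- function(x, ...) {
  cat(sprintf("Encoded MSA: M = %d sequences, L = %d positions, q = %d states\n",
              nrow(x$data), ncol(x$data), x$q))
  invisible(x)
}

#' @export
dim.encoded_msa <- function(x) dim(x$data)

#' Read a multiple-sequence alignment
#'
#' Reads a FASTA or Stockholm 1.0 alignment and encodes it over the
#' 21-letter alphabet.  \code{'.'} characters and lower-case insert
#' states map to the gap state; unknown or ambiguous residues (X, B, Z,
#' U, O, ...) also map to the gap state, and their count is reported in
#' a message.
#'
#' @param path Path to the alignment file.
#' @param format Either \code{"fasta"} or \code{"stockholm"}.
#' @return An [encoded_msa()] object.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty alignment file: ", path)
  seqs <- if (format == "fasta") {
    aln <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                    error = function(e) stop("could not parse fasta file '",
                                             path, "': ", conditionMessage(e),
                                             call. = FALSE))
    stats::setNames(as.character(aln), names(aln))
  } else {
    # parsed by hand: AAMultipleAlignment readers upper-case residues,
    # which would lose the lower-case insert-state convention
    .read_stockholm(path)
  }
  if (length(seqs) == 0L) stop("empty alignment file: ", path)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences have unequal lengths: ",
         paste(unique(lens), collapse = ", "))
  }
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  enc <- matrix(encode_symbol(chars), nrow = nrow(chars))
  # count residues mapped to gap that were not gap-like in the input
  gaplike <- chars %in% c("-", ".") |
    (chars >= "a" & chars <= "z")
  n_unknown <- sum(enc == 1L & !gaplike)
  msa <- encoded_msa(enc, labels = names(seqs))
  message(sprintf("read %d sequences x %d positions (%d unknown/ambiguous residues mapped to gap)",
                  nrow(enc), ncol(enc), n_unknown))
  msa
}

# Minimal Stockholm 1.0 reader preserving residue case.  Sequence lines
# are "name sequence"; "#" annotation, blank lines and the trailing "//"
# are skipped; multi-block files are concatenated per name.
.read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^# STOCKHOLM", lines[1])) {
    stop("could not parse stockholm file '", path,
         "': missing '# STOCKHOLM' header", call. = FALSE)
  }
  keep <- !grepl("^\\s*(#|//|$)", lines)
  out <- list()
  for (line in lines[keep]) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) != 2L) {
      stop("could not parse stockholm file '", path,
           "': malformed sequence line '", line, "'", call. = FALSE)
    }
    out[[tok[1]]] <- paste0(out[[tok[1]]], tok[2])
  }
  unlist(out)
}

#' Write an alignment as FASTA
#'
#' @param msa An [encoded_msa()] object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_alignment <- function(msa, path) {
  stopifnot(inherits(msa, "encoded_msa"))
  chars <- matrix(msa$alphabet[msa$data], nrow = nrow(msa$data))
  seqs <- apply(chars, 1L, paste0, collapse = "")
  writeLines(paste0(">", msa$labels, "\n", seqs), path)
  invisible(path)
}

#' Write the encoded integer matrix as TSV
#'
#' Long format with 1-based sequence index, position and state, plus the
#' symbol, one row per alignment cell.
#'
#' @param msa An [encoded_msa()] object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_encoded_tsv <- function(msa, path) {
  stopifnot(inherits(msa, "encoded_msa"))
  d <- msa$data
  df <- data.frame(sequence = rep(seq_len(nrow(d)), times = ncol(d)),
                   position = rep(seq_len(ncol(d)), each = nrow(d)),
                   state = as.vector(d),
                   symbol = msa$alphabet[as.vector(d)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
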