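# Shared fixture builders; everything is generated in code.

# absolute cosine similarity between two flattened component arrays
abs_cosine <- function(x, y) {
  x <- as.vector(x); y <- as.vector(y)
  abs(sum(x * y)) / sqrt(sum(x^2) * sum(y^2))
}

# unit-weight hp_weights for an alignment sampled i.i.d.
unit_weights <- function(msa) {
  structure(list(w = rep(1, nrow(msa$data)), theta = NA_real_,
                 M_eff = nrow(msa$data)), class = "hp_weights")
}

write_fasta_lines <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unlist(seqs)), path)
  path
}

# one ATOM record in fixed-width PDB format
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, alt = " ", elem = "C") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resn, chain, resno, x, y, z, occ, 0, elem)
}

# 3-residue synthetic structure: residues 1 and 2 are close through a
# side-chain atom, residue 3 is far from both
write_toy_pdb <- function(path) {
  writeLines(c(
    pdb_atom_line(1, " CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, " CA", "ALA", "A", 2, 3, 4, 0),
    pdb_atom_line(3, " CB", "ALA", "A", 2, 1, 1, 0),
    pdb_atom_line(4, " CA", "SER", "A", 3, 30, 0, 0),
    "END"), path)
  path
}

# brute-force frequency oracle: loops over the definition directly
oracle_frequencies <- function(msa, w, pc) {
  d <- msa$data; M <- nrow(d); L <- ncol(d); q <- msa$q
  M_eff <- sum(w)
  Lambda <- pc / (1 - pc) * M_eff
  f1 <- matrix(0, L, q)
  for (i in seq_len(L)) for (a in seq_len(q)) {
    f1[i, a] <- (Lambda / q + sum(w * (d[, i] == a))) / (Lambda + M_eff)
  }
  f2 <- array(0, c(L, L, q, q))
  for (i in seq_len(L)) for (j in seq_len(L)) for (a in seq_len(q)) for (b in seq_len(q)) {
    f2[i, j, a, b] <- if (i == j) {
      if (a == b) f1[i, a] else 0
    } else {
      (Lambda / q^2 + sum(w * (d[, i] == a) * (d[, j] == b))) / (Lambda + M_eff)
    }
  }
  list(f1 = f1, f2 = f2)
}
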