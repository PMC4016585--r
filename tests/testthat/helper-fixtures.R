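# Fixtures are generated in code at test time: tiny PDB files, alignments
# and small graphs.

# Write a minimal PDB file.  `residues` is a list; each element is a list
# with resn, resno, chain and `atoms`, a data.frame with columns
# name, x, y, z (optionally alt, occ, elem).
write_test_pdb <- function(residues, path = tempfile(fileext = ".pdb"),
                           models = 1L, shift = function(m) c(0, 0, 0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(models)) {
    if (models > 1L) writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    dx <- shift(m)
    for (r in residues) {
      at <- r$atoms
      for (i in seq_len(nrow(at))) {
        serial <- serial + 1L
        alt <- if (!is.null(at$alt)) at$alt[i] else " "
        occ <- if (!is.null(at$occ)) at$occ[i] else 1.00
        elem <- if (!is.null(at$elem)) at$elem[i] else
          substr(gsub("[0-9]", "", at$name[i]), 1, 1)
        writeLines(sprintf(
          "ATOM  %5d  %-3s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, at$name[i], alt, r$resn, r$chain %||% "A", r$resno,
          at$x[i] + dx[1], at$y[i] + dx[2], at$z[i] + dx[3], occ, 0.0,
          elem), con)
      }
    }
    if (models > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small protein-like residue: backbone N/CA/C/O plus one side-chain atom
# at an offset from CA.
test_residue <- function(resn, resno, ca = c(0, 0, 0), sc_offset = c(1.5, 0, 0),
                         chain = "A", sidechain = TRUE) {
  atoms <- data.frame(
    name = c("N", "CA", "C", "O"),
    x = ca[1] + c(-1.3, 0, 1.3, 2.0),
    y = ca[2] + c(0.2, 0, 0.2, 1.0),
    z = ca[3] + c(0, 0, 0, 0))
  if (sidechain)
    atoms <- rbind(atoms, data.frame(name = "CB", x = ca[1] + sc_offset[1],
                                     y = ca[2] + sc_offset[2],
                                     z = ca[3] + sc_offset[3]))
  list(resn = resn, resno = resno, chain = chain, atoms = atoms)
}

# Four (or more) homologous single-model structures with `nres` residues,
# slightly jittered, all sharing the same residue numbering.
make_homolog_set <- function(n_struct = 4L, nres = 5L, seed = 42L) {
  set.seed(seed)
  paths <- character(n_struct)
  for (s in seq_len(n_struct)) {
    residues <- lapply(seq_len(nres), function(i)
      test_residue("ALA", i, ca = c(3.8 * i + rnorm(1, 0, 0.2),
                                    rnorm(1, 0, 0.2), rnorm(1, 0, 0.2))))
    paths[s] <- write_test_pdb(residues)
  }
  paths
}

write_test_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  path
}

# Two disconnected cliques of size `size` with unit edge weights.
two_clique_adjacency <- function(size = 5L) {
  k <- 2L * size
  A <- matrix(0, k, k)
  A[seq_len(size), seq_len(size)] <- 1
  A[(size + 1):k, (size + 1):k] <- 1
  diag(A) <- 0
  rownames(A) <- colnames(A) <- sprintf("n%02d", seq_len(k))
  A
}

# All set partitions of seq_len(n) as membership vectors (Bell number
# growth: keep n small).
all_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  smaller <- all_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    for (g in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, g)
  }
  out
}

# Random connected-ish weighted graph for oracle comparisons.
random_weighted_adjacency <- function(n, p_edge = 0.5, seed = 1L) {
  set.seed(seed)
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  on <- up[runif(length(up)) < p_edge]
  A[on] <- runif(length(on), 0.1, 1)
  A <- A + t(A)
  rownames(A) <- colnames(A) <- sprintf("n%02d", seq_len(n))
  A
}
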