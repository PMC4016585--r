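#' Read a structural ensemble from PDB files
#'
#' Parses PDB files with [bio3d::read.pdb()] into a list of structure
#' records.  In `"homologs"` mode each path contributes one structure (its
#' first model); in `"trajectory"` mode a single multi-model PDB is read
#' and every `MODEL` becomes one record.  Hydrogens and waters are
#' discarded; alternate locations are resolved to the highest occupancy.
#'
#' Structures are consumed already superposed (e.g. the output of a
#' flexible structure aligner such as MATT): no superposition is performed
#' here.
#'
#' @param paths character vector of PDB file paths (length 1 in trajectory
#'   mode).
#' @param mode `"homologs"` or `"trajectory"`.
#' @return A list of records, each a list with `id` and `residues`; every
#'   residue is a list with `label`, `atoms` (heavy-atom coordinate matrix,
#'   one row per atom, in Angstrom) and `sidechain` (side-chain heavy
#'   atoms; the CA atom stands in for glycine, whose side chain is empty,
#'   so contact maps have no holes at glycines).
#' @export
read_structures <- function(paths, mode = c("homologs", "trajectory")) {
  mode <- match.arg(mode)
  if (length(paths) == 0L) stop("no structures found")
  if (mode == "trajectory") {
    if (length(paths) != 1L)
      stop("trajectory mode expects a single multi-model PDB file")
    pdb <- bio3d::read.pdb(paths, multi = TRUE, verbose = FALSE)
    nmod <- nrow(pdb$xyz)
    if (is.null(nmod) || nmod < 1L) stop("no models found in ", paths)
    base <- basename(paths)
    lapply(seq_len(nmod), function(m) {
      structure_record(pdb, sprintf("%s#%d", base, m), model = m)
    })
  } else {
    lapply(paths, function(p) {
      pdb <- bio3d::read.pdb(p, verbose = FALSE)
      structure_record(pdb, basename(p), model = 1L)
    })
  }
}

backbone_atoms <- c("N", "CA", "C", "O", "OXT")
water_resids <- c("HOH", "WAT", "DOD", "H2O")

# Build one structure record from a bio3d pdb object and a model index.
structure_record <- function(pdb, id, model = 1L) {
  atom <- pdb$atom
  xyz <- if (!is.null(nrow(pdb$xyz)) && nrow(pdb$xyz) > 1L) {
    matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  } else cbind(atom$x, atom$y, atom$z)
  keep <- atom$type == "ATOM" &
    !(atom$resid %in% water_resids) &
    !grepl("^[0-9]*H", atom$elety) &
    !(!is.na(atom$elesy) & atom$elesy == "H")
  if (!any(keep)) stop("no protein residues in ", id)
  atom <- atom[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]
  if (anyNA(xyz) || !all(is.finite(xyz)))
    stop("non-finite coordinates in ", id)
  # altloc: within each (chain, residue, atom name), keep highest occupancy
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
  best <- unlist(lapply(split(seq_along(key), key),
                        function(ix) ix[which.max(occ[ix])]),
                 use.names = FALSE)
  best <- sort(best)
  atom <- atom[best, , drop = FALSE]
  xyz <- xyz[best, , drop = FALSE]
  rkey <- paste(atom$chain, atom$resno, atom$insert, sep = "|")
  ridx <- split(seq_along(rkey), factor(rkey, levels = unique(rkey)))
  residues <- lapply(seq_along(ridx), function(i) {
    ix <- ridx[[i]]
    a <- xyz[ix, , drop = FALSE]
    sc <- a[!(atom$elety[ix] %in% backbone_atoms), , drop = FALSE]
    if (nrow(sc) == 0L)
      sc <- a[atom$elety[ix] == "CA", , drop = FALSE]
    if (nrow(sc) == 0L) sc <- a
    list(label = sprintf("%s%s%s", atom$resid[ix[1L]], atom$resno[ix[1L]],
                         ifelse(is.na(atom$chain[ix[1L]]) |
                                  atom$chain[ix[1L]] == "", "",
                                paste0(".", atom$chain[ix[1L]]))),
         resid = atom$resid[ix[1L]],
         atoms = a, sidechain = sc)
  })
  list(id = id, residues = residues)
}

#' Map structures through a multiple alignment
#'
#' Reads an aligned FASTA (gaps `-`) whose sequences correspond 1:1, in
#' order, to the residue sequences of the structure records, and returns
#' the per-column residue indices.  A column is usable as a landmark only
#' when no structure has a gap in it.
#'
#' @param fasta path to the aligned FASTA file, or a `bio3d` `fasta`
#'   object.
#' @param records list of structure records from [read_structures()].
#' @return An `alignment_map`: list with `columns`, an
#'   `n_columns x n_structures` integer matrix of residue indices with
#'   `NA` at gaps.
#' @export
alignment_map <- function(fasta, records) {
  aln <- if (is.character(fasta)) bio3d::read.fasta(fasta) else fasta
  ali <- aln$ali
  if (nrow(ali) != length(records))
    stop("alignment has ", nrow(ali), " sequences but ", length(records),
         " structures were read")
  cols <- matrix(NA_integer_, ncol(ali), nrow(ali))
  for (s in seq_len(nrow(ali))) {
    nongap <- which(!(ali[s, ] %in% c("-", ".")))
    nres <- length(records[[s]]$residues)
    if (length(nongap) != nres)
      stop(sprintf(
        "sequence %d has %d aligned residues but structure '%s' has %d",
        s, length(nongap), records[[s]]$id, nres))
    cols[nongap, s] <- seq_len(nres)
  }
  structure(list(columns = cols, ids = rownames(ali)),
            class = "alignment_map")
}

# Identity mapping for trajectory snapshots (shared topology).
identity_map <- function(records) {
  nres <- vapply(records, function(r) length(r$residues), 0L)
  if (length(unique(nres)) != 1L)
    stop("trajectory models disagree on residue count; an alignment is required")
  structure(list(columns = matrix(rep(seq_len(nres[1L]), length(records)),
                                  nres[1L], length(records)),
                 ids = vapply(records, `[[`, "", "id")),
            class = "alignment_map")
}

#' Landmark coordinates of a structural ensemble
#'
#' A landmark is the centroid (arithmetic mean of *all* heavy-atom
#' coordinates) of a residue that is homologously present — no gap in any
#' structure — in a column of the multiple alignment.  Gapped columns are
#' excluded entirely.
#'
#' @param records list of structure records from [read_structures()].
#' @param map an [alignment_map()]; `NULL` uses the identity mapping
#'   (trajectory mode: all models share the topology).
#' @return A [coord_ensemble()] with one row per structure, `dims = 3`, and
#'   one landmark per fully occupied alignment column.  Landmark ids derive
#'   from the residue labels of the first structure.
#' @export
compute_landmarks <- function(records, map = NULL) {
  if (length(records) < 4L)
    stop("at least 4 structures are required (correlation undefined below)")
  map <- map %||% identity_map(records)
  cols <- map$columns
  keep <- which(rowSums(is.na(cols)) == 0L)
  if (length(keep) == 0L)
    stop("no alignment column is occupied in every structure")
  n <- length(records)
  values <- matrix(NA_real_, n, length(keep) * 3L)
  for (s in seq_len(n)) {
    res <- records[[s]]$residues
    cent <- t(vapply(cols[keep, s], function(ri)
      colMeans(res[[ri]]$atoms), numeric(3L)))
    values[s, ] <- as.vector(t(cent))
  }
  labels <- vapply(cols[keep, 1L], function(ri)
    records[[1L]]$residues[[ri]]$label, "")
  coord_ensemble(values, make.unique(labels, sep = "#"), dims = 3L)
}

#' Consensus contact map of a structural ensemble
#'
#' Within one structure, two residues are in contact iff the minimum
#' distance over all pairs of their side-chain heavy atoms is at most
#' `cutoff` (4.5 Angstrom by default; the boundary counts as contact).
#' Across the ensemble, a pair is in consensus contact iff the
#' within-structure contact holds in at least a fraction `consensus` of the
#' structures considered.
#'
#' @inheritParams compute_landmarks
#' @param cutoff contact distance threshold in Angstrom.
#' @param consensus required fraction of structures, in `(0, 1]`.
#' @param structures indices of the records to use (default all; molecular
#'   dynamics pipelines typically use the first snapshot only, since the
#'   frames share a topology).
#' @return A `contact_map`: list with `contacts` (symmetric logical matrix
#'   with `FALSE` diagonal, rows/cols in landmark order), `cutoff` and
#'   `consensus`.
#' @export
compute_contacts <- function(records, map = NULL, cutoff = 4.5,
                             consensus = 0.5, structures = NULL) {
  if (consensus <= 0 || consensus > 1) stop("'consensus' must lie in (0, 1]")
  map <- map %||% identity_map(records)
  cols <- map$columns
  keep <- which(rowSums(is.na(cols)) == 0L)
  k <- length(keep)
  if (k == 0L) stop("no alignment column is occupied in every structure")
  structures <- structures %||% seq_along(records)
  count <- matrix(0L, k, k)
  for (s in structures) {
    res <- records[[s]]$residues
    sc <- lapply(cols[keep, s], function(ri) res[[ri]]$sidechain)
    sq <- lapply(sc, function(a) rowSums(a^2))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      d2 <- min(outer(sq[[i]], sq[[j]], "+") - 2 * tcrossprod(sc[[i]], sc[[j]]))
      if (sqrt(max(d2, 0)) <= cutoff) {
        count[i, j] <- count[i, j] + 1L
        count[j, i] <- count[j, i] + 1L
      }
    }
  }
  contacts <- count / length(structures) >= consensus
  diag(contacts) <- FALSE
  structure(list(contacts = contacts, cutoff = cutoff,
                 consensus = consensus),
            class = "contact_map")
}

#' Write a contact map as TSV
#'
#' One row per unordered landmark pair with columns `i`, `j` and `contact`
#' (0/1).
#'
#' @param cm a `contact_map`.
#' @param landmark_ids landmark labels for the rows/columns.
#' @param path output file.
#' @export
write_contact_tsv <- function(cm, landmark_ids, path) {
  stopifnot(inherits(cm, "contact_map"))
  idx <- which(upper.tri(cm$contacts), arr.ind = TRUE)
  df <- data.frame(i = landmark_ids[idx[, 1L]], j = landmark_ids[idx[, 2L]],
                   contact = as.integer(cm$contacts[idx]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
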