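test_that("PDB reading extracts heavy-atom residues", {
  path <- write_test_pdb(list(
    test_residue("ALA", 1, ca = c(0, 0, 0)),
    test_residue("GLY", 2, ca = c(3.8, 0, 0), sidechain = FALSE),
    test_residue("SER", 3, ca = c(7.6, 0, 0))))
  rec <- read_structures(path, mode = "homologs")
  expect_length(rec, 1L)
  expect_length(rec[[1]]$residues, 3L)
  # glycine: CA stands in as the side chain
  gly <- rec[[1]]$residues[[2]]
  expect_equal(nrow(gly$sidechain), 1L)
  expect_equal(unname(gly$sidechain[1, ]), c(3.8, 0, 0))
})

test_that("multi-model PDBs become one record per model in trajectory mode", {
  path <- write_test_pdb(list(test_residue("ALA", 1), test_residue("VAL", 2,
                                                                   ca = c(3.8, 0, 0))),
                         models = 3, shift = function(m) c(0.1 * m, 0, 0))
  recs <- read_structures(path, mode = "trajectory")
  expect_length(recs, 3L)
  # models are shifted copies: same residue count, different coordinates
  expect_length(recs[[1]]$residues, 2L)
  expect_false(isTRUE(all.equal(recs[[1]]$residues[[1]]$atoms,
                                recs[[2]]$residues[[1]]$atoms)))
})

test_that("hydrogens are discarded and water-only files error", {
  res <- test_residue("ALA", 1)
  res$atoms <- rbind(res$atoms,
                     data.frame(name = "HB1", x = 1.6, y = 0.1, z = 0))
  path <- write_test_pdb(list(res))
  rec <- read_structures(path, mode = "homologs")
  expect_equal(nrow(rec[[1]]$residues[[1]]$atoms), 5L)  # no HB1
  wat <- list(resn = "HOH", resno = 1, chain = "A",
              atoms = data.frame(name = "O", x = 0, y = 0, z = 0))
  expect_error(read_structures(write_test_pdb(list(wat)), "homologs"),
               "no protein residues")
})

test_that("landmarks are heavy-atom centroids of ungapped columns", {
  paths <- make_homolog_set(4, nres = 3)
  recs <- read_structures(paths, mode = "homologs")
  ens <- compute_landmarks(recs)
  expect_s3_class(ens, "coord_ensemble")
  expect_equal(ens$n_obs, 4L)
  expect_equal(ens$dims, 3L)
  expect_length(ens$landmark_ids, 3L)
  # centroid oracle: mean of all heavy atoms of the residue
  expect_equal(unname(ens$values[1, 1:3]),
               unname(colMeans(recs[[1]]$residues[[1]]$atoms)))
  expect_error(compute_landmarks(recs[1:3]), "at least 4")
})

test_that("gapped alignment columns are excluded from the landmarks", {
  paths <- make_homolog_set(4, nres = 3)
  recs <- read_structures(paths, mode = "homologs")
  # structure 4 misses the middle column
  recs[[4]]$residues <- recs[[4]]$residues[c(1, 3)]
  fasta <- write_test_fasta(list(s1 = "AAA", s2 = "AAA", s3 = "AAA",
                                 s4 = "A-A"))
  map <- alignment_map(fasta, recs)
  expect_equal(dim(map$columns), c(3L, 4L))
  ens <- compute_landmarks(recs, map)
  expect_length(ens$landmark_ids, 2L)
  # mismatched residue counts are an error
  bad <- write_test_fasta(list(s1 = "AAA", s2 = "AAA", s3 = "AAA",
                               s4 = "AAA"))
  expect_error(alignment_map(bad, recs), "aligned residues")
})

test_that("landmark count is invariant to structure input order", {
  paths <- make_homolog_set(5, nres = 4)
  e1 <- compute_landmarks(read_structures(paths, "homologs"))
  e2 <- compute_landmarks(read_structures(rev(paths), "homologs"))
  expect_equal(length(e1$landmark_ids), length(e2$landmark_ids))
})

test_that("contacts use minimum side-chain distance with an inclusive cutoff", {
  # two residues whose closest side-chain atoms sit exactly 4.5 A apart,
  # and a third one far away
  r1 <- test_residue("ALA", 1, ca = c(0, 0, 0), sc_offset = c(1.0, 0, 0))
  r2 <- test_residue("ALA", 2, ca = c(4.5, 0, 0), sc_offset = c(1.0, 0, 0))
  r3 <- test_residue("ALA", 3, ca = c(40, 0, 0))
  # side chains at x = 1.0 and x = 5.5: distance exactly 4.5
  paths <- vapply(1:4, function(i) write_test_pdb(list(r1, r2, r3)), "")
  recs <- read_structures(paths, "homologs")
  cm <- compute_contacts(recs, cutoff = 4.5)
  expect_true(cm$contacts[1, 2])
  expect_true(isSymmetric(cm$contacts))
  expect_false(any(diag(cm$contacts)))
  expect_false(cm$contacts[1, 3])
  # at 4.6 A separation the same pair is out of contact
  r2b <- test_residue("ALA", 2, ca = c(4.6, 0, 0), sc_offset = c(1.0, 0, 0))
  paths_b <- vapply(1:4, function(i) write_test_pdb(list(r1, r2b, r3)), "")
  cmb <- compute_contacts(read_structures(paths_b, "homologs"), cutoff = 4.5)
  expect_false(cmb$contacts[1, 2])
  # cutoff monotonicity: contacts(4.5) subset of contacts(6.0)
  cm6 <- compute_contacts(recs, cutoff = 6.0)
  expect_true(all(cm6$contacts[cm$contacts]))
})

test_that("consensus fraction gates ensemble contacts", {
  near <- list(test_residue("ALA", 1, ca = c(0, 0, 0)),
               test_residue("ALA", 2, ca = c(3.0, 0, 0)))
  far <- list(test_residue("ALA", 1, ca = c(0, 0, 0)),
              test_residue("ALA", 2, ca = c(30, 0, 0)))
  # contact present in 2 of 4 structures
  paths <- c(write_test_pdb(near), write_test_pdb(near),
             write_test_pdb(far), write_test_pdb(far))
  recs <- read_structures(paths, "homologs")
  expect_true(compute_contacts(recs, consensus = 0.5)$contacts[1, 2])
  # 1 of 4 < 0.5: no consensus contact
  paths1 <- c(write_test_pdb(near), write_test_pdb(far),
              write_test_pdb(far), write_test_pdb(far))
  recs1 <- read_structures(paths1, "homologs")
  expect_false(compute_contacts(recs1, consensus = 0.5)$contacts[1, 2])
})
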