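test_that("Kabsch alignment recovers exact superpositions", {
  set.seed(11)
  P <- matrix(stats::rnorm(12), 4, 3)
  fit <- kabsch_align(P, P)
  expect_lt(fit$rmsd, 1e-12)
  expect_lt(max(abs(fit$rotation - diag(3))), 1e-9)
  R <- random_rotation(); tt <- c(1, -2, 3)
  Q <- sweep(P %*% t(R), 2, tt, "+")
  expect_lt(kabsch_align(P, Q)$rmsd, 1e-6)
})

test_that("Kabsch agrees with the quaternion oracle on random instances", {
  set.seed(12)
  for (i in 1:50) {
    P <- matrix(stats::rnorm(12, sd = 3), 4, 3)
    Q <- matrix(stats::rnorm(12, sd = 3), 4, 3)
    expect_lt(abs(kabsch_align(P, Q)$rmsd - quaternion_rmsd(P, Q)), 1e-6)
  }
})

test_that("degenerate (collinear) input is flagged but still aligned", {
  P <- cbind(0:3, 0, 0)
  fit <- kabsch_align(P, P)
  expect_true(fit$degenerate)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("correspondence enumeration equals the brute-force oracle", {
  set.seed(13)
  for (trial in 1:200) {
    np <- sample(3:5, 1)
    nf <- sample(3:8, 1)
    pcls <- sample(FEATURE_CLASSES[1:3], np, replace = TRUE)
    fcls <- sample(FEATURE_CLASSES[1:3], nf, replace = TRUE)
    ph <- make_ph(pcls, matrix(stats::runif(np * 3, 0, 6), np))
    feats <- make_feats(fcls, matrix(stats::runif(nf * 3, 0, 6), nf))
    got <- enumerate_correspondences(ph, feats)
    want <- brute_force_correspondences(ph, feats)
    expect_identical(assignment_set(got), assignment_set(want))
  }
})

test_that("correspondence preconditions and trivial cases", {
  ph2 <- make_ph(c("Aromatic", "Aromatic"), matrix(0:5, 2, 3))
  expect_error(enumerate_correspondences(ph2, make_feats("Aromatic",
                                                         matrix(0, 1, 3))),
               "too small")
  # a class absent from the molecule -> no assignments
  ph <- make_ph(c("Aromatic", "Hydrophobic", "PositiveIon"),
                matrix(c(0, 0, 0, 3, 0, 0, 0, 3, 0), 3, byrow = TRUE))
  feats <- make_feats(c("Aromatic", "Hydrophobic"),
                      matrix(c(0, 0, 0, 3, 0, 0), 2, byrow = TRUE))
  expect_length(enumerate_correspondences(ph, feats), 0L)
})

test_that("a molecule matches a pharmacophore built from its own features", {
  xyz <- matrix(c(0, 0, 0, 3, 0, 0, 0, 4, 0, 2, 2, 2), 4, byrow = TRUE)
  cls <- c("Aromatic", "HydrogenAcceptor", "Hydrophobic", "NegativeIon")
  ph <- make_ph(cls, xyz)
  mol <- molecule_record("self", list(xyz), list(make_feats(cls, xyz)))
  asg <- enumerate_correspondences(ph, extract_ligand_features(mol, 1L))
  expect_true(any(vapply(asg, function(a) all(a == 1:4), logical(1))))
  m <- match_conformer(ph, mol, 1L)
  expect_lt(m$rmsd, 1e-9)
})

test_that("matching respects the 1 Angstrom tolerance boundary", {
  # square in the xy plane with alternating out-of-plane displacements:
  # zero net translation and torque, so no rigid motion can absorb the
  # per-point displacement and post-alignment residuals equal it exactly
  sq <- matrix(c(1.5, 1.5, 0, -1.5, 1.5, 0, -1.5, -1.5, 0, 1.5, -1.5, 0),
               4, byrow = TRUE)
  cls <- c("Aromatic", "HydrogenAcceptor", "Hydrophobic", "NegativeIon")
  ph <- make_ph(cls, sq, radius = 1)
  bend <- cbind(0, 0, c(1, -1, 1, -1))
  near <- sq + 0.99 * bend
  mol_near <- molecule_record("near", list(near), list(make_feats(cls, near)))
  expect_false(is.null(match_conformer(ph, mol_near, 1L)))
  far <- sq + 1.01 * bend
  mol_far <- molecule_record("far", list(far), list(make_feats(cls, far)))
  expect_null(match_conformer(ph, mol_far, 1L))
})

test_that("congruent same-class triangles match with zero rmsd", {
  xyz <- matrix(c(0, 0, 0, 3, 0, 0, 1.5, 2.6, 0), 3, byrow = TRUE)
  ph <- make_ph(rep("Hydrophobic", 3), xyz)
  R <- random_rotation()
  moved <- sweep(xyz %*% t(R), 2, c(10, -5, 2), "+")
  mol <- molecule_record("tri", list(moved),
                         list(make_feats(rep("Hydrophobic", 3), moved)))
  m <- match_conformer(ph, mol, 1L)
  expect_false(is.null(m))
  expect_lt(m$rmsd, 1e-6)
})

test_that("matching is invariant under rigid motion of the conformer", {
  set.seed(14)
  xyz <- matrix(stats::runif(12, 0, 5), 4)
  cls <- c("Aromatic", "Aromatic", "Hydrophobic", "PositiveIon")
  ph <- make_ph(cls, xyz)
  jit <- xyz + matrix(stats::runif(12, -0.3, 0.3), 4)
  for (i in 1:10) {
    R <- random_rotation(); tt <- stats::runif(3, -20, 20)
    moved <- sweep(jit %*% t(R), 2, tt, "+")
    mol <- molecule_record("m", list(moved), list(make_feats(cls, moved)))
    m <- match_conformer(ph, mol, 1L)
    expect_false(is.null(m))
    if (i == 1L) rmsd0 <- m$rmsd
    expect_lt(abs(m$rmsd - rmsd0), 1e-6)
  }
})

test_that("enlarging tolerance radii never destroys a match", {
  set.seed(15)
  for (trial in 1:20) {
    xyz <- matrix(stats::runif(9, 0, 5), 3)
    cls <- sample(FEATURE_CLASSES, 3, replace = TRUE)
    jit <- xyz + matrix(stats::runif(9, -0.5, 0.5), 3)
    mol <- molecule_record("m", list(jit), list(make_feats(cls, jit)))
    matched_small <- !is.null(match_conformer(make_ph(cls, xyz, radius = 1),
                                              mol, 1L))
    matched_big <- !is.null(match_conformer(make_ph(cls, xyz, radius = 2),
                                            mol, 1L))
    if (matched_small) expect_true(matched_big)
  }
})

test_that("screening returns one conformer per molecule and applies exclusion", {
  xyz <- matrix(c(0, 0, 0, 3, 0, 0, 0, 4, 0), 3, byrow = TRUE)
  cls <- c("Aromatic", "HydrogenAcceptor", "Hydrophobic")
  ph <- make_ph(cls, xyz)
  # two matching conformers -> one hit
  mol2 <- molecule_record("two", list(xyz, xyz + 0.1),
                          list(make_feats(cls, xyz),
                               make_feats(cls, xyz + 0.1)))
  hits <- screen(ph, list(mol2))
  expect_length(hits, 1L)
  expect_lt(hits[[1]]$rmsd, 1e-9)  # the better-fitting conformer is kept
  # receptor atom 0.5 A from an aligned molecule atom -> excluded
  rec <- protein_structure(data.frame(element = "C", x = 0.5, y = 0, z = 0,
                                      atom_type = 1L))
  expect_length(screen(ph, list(mol2), receptor = rec, clash_dist = 1.5), 0L)
  # far receptor does not interfere
  rec2 <- protein_structure(data.frame(element = "C", x = 50, y = 0, z = 0,
                                       atom_type = 1L))
  expect_length(screen(ph, list(mol2), receptor = rec2), 1L)
  expect_length(screen(ph, list()), 0L)
})
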