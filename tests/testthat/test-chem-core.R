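test_that("feature classes are fixed, ordered, and bijective with indices", {
  expect_length(FEATURE_CLASSES, 6L)
  expect_identical(FEATURE_CLASSES[1], "Aromatic")
  expect_identical(FEATURE_CLASSES[6], "PositiveIon")
  expect_identical(feature_class_index(FEATURE_CLASSES), 0:5)
  expect_error(feature_class_index("Banana"), "unknown feature class")
})

test_that("pharm_point validates radius and latent length", {
  expect_error(pharm_point("Aromatic", c(0, 0, 0), radius = 0), "radius")
  expect_error(pharm_point("Aromatic", c(0, 0, 0), latent = 1:5), "latent")
  p <- pharm_point("Aromatic", c(1, 2, 3), latent = rep(0.1, 32))
  expect_length(p$latent, 32L)
})

test_that("pharmacophore rejects duplicate (class, position) points", {
  p1 <- pharm_point("Aromatic", c(0, 0, 0))
  p2 <- pharm_point("Aromatic", c(0, 0, 0))
  expect_error(pharmacophore(list(p1, p2)), "duplicate")
  expect_silent(pharmacophore(list(p1, pharm_point("Hydrophobic", c(0, 0, 0)))))
})

test_that("read_protein parses toy PDBs, filters HETATM, errors when empty", {
  atoms <- data.frame(resname = "GLY", atomname = "CA", element = "C",
                      x = c(0, 3.8, 7.6), y = 0, z = 0)
  st <- read_protein(write_toy_pdb(atoms))
  expect_s3_class(st, "protein_structure")
  expect_equal(nrow(st$atoms), 3L)

  atoms2 <- rbind(atoms,
                  data.frame(resname = "LIG", atomname = "C1", element = "C",
                             x = 10, y = 0, z = 0))
  atoms2$type <- c("ATOM", "ATOM", "ATOM", "HETATM")
  st2 <- read_protein(write_toy_pdb(atoms2), receptor_only = TRUE)
  expect_equal(nrow(st2$atoms), 3L)
  st3 <- read_protein(write_toy_pdb(atoms2), receptor_only = FALSE)
  expect_equal(nrow(st3$atoms), 4L)

  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_protein(empty), "zero heavy atoms|unreadable")
})

test_that("atom typing follows the 14-type convention", {
  atoms <- data.frame(
    resname = c("PHE", "PHE", "LYS", "ASP", "GLY", "ZN", "CA"),
    atomname = c("CG", "CD1", "NZ", "OD1", "N", "ZN", "CA"),
    element = c("C", "C", "N", "O", "N", "ZN", "CA"),
    x = seq(0, 30, by = 5), y = 0, z = 0,
    type = c(rep("ATOM", 5), "HETATM", "HETATM"),
    resno = c(1, 1, 2, 3, 4, 5, 6))
  st <- read_protein(write_toy_pdb(atoms), receptor_only = TRUE)
  ty <- st$atoms$atom_type
  names(ty) <- st$atoms$atomname
  expect_equal(unname(ty[c("CG", "CD1")]), c(3L, 3L))   # aromatic hydrophobe
  expect_equal(unname(ty["NZ"]), 7L)                    # nitrogen donor
  expect_equal(unname(ty["OD1"]), 8L)                   # oxygen acceptor
  expect_equal(unname(ty["N"]), 7L)                     # backbone amide N
  expect_equal(unname(ty["ZN"]), 13L)
  expect_equal(unname(ty["CA"])[1], 12L)                # calcium ion
  # idempotent
  expect_identical(assign_atom_types(st)$atoms$atom_type, st$atoms$atom_type)
})

test_that("untyped carbons split hydrophobe / non-hydrophobe by bonded heteroatom", {
  # benzene-like carbon with only C neighbours -> aliphatic hydrophobe
  # fallback (no residue template, not marked aromatic)
  atoms <- data.frame(resname = "UNK", atomname = c("C1", "C2", "O1"),
                      element = c("C", "C", "O"),
                      x = c(0, 10, 11.4), y = 0, z = 0)
  st <- suppressWarnings(read_protein(write_toy_pdb(atoms)))
  ty <- st$atoms$atom_type
  expect_equal(ty[1], 1L)  # isolated carbon: hydrophobe
  expect_equal(ty[2], 2L)  # carbon 1.4 A from an oxygen: non-hydrophobe
})

test_that("unknown elements fall to type 14 with a warning", {
  atoms <- data.frame(resname = "UNK", atomname = "X1", element = "XX",
                      x = 0, y = 0, z = 0)
  expect_warning(st <- read_protein(write_toy_pdb(atoms)), "generic type 14")
  expect_equal(st$atoms$atom_type, 14L)
})

test_that("complementary groups: charged residues, donors, acceptors, rings", {
  lys <- data.frame(resname = "LYS",
                    atomname = c("CB", "CG", "CD", "CE", "NZ"),
                    element = c("C", "C", "C", "C", "N"),
                    x = c(0, 1.5, 3, 4.5, 6), y = 0, z = 0, resno = 1)
  asp <- data.frame(resname = "ASP", atomname = c("CG", "OD1", "OD2"),
                    element = c("C", "O", "O"),
                    x = c(0, 1.1, -1.1), y = 20, z = 0, resno = 2)
  st <- read_protein(write_toy_pdb(rbind(lys, asp)))
  gr <- find_complementary_groups(st)
  # lysine amine anchors ligand negative ions
  neg <- gr[gr$complements == "NegativeIon", ]
  expect_equal(nrow(neg), 1L)
  expect_equal(as.numeric(neg[1, c("x", "y", "z")]), c(6, 0, 0))
  # aspartate carboxylate anchors ligand positive ions, at the O centroid
  pos <- gr[gr$complements == "PositiveIon", ]
  expect_equal(nrow(pos), 1L)
  expect_equal(as.numeric(pos[1, c("x", "y", "z")]), c(0, 20, 0))
  # a glycine-only chain has no aromatic anchors
  gly <- data.frame(resname = "GLY", atomname = c("N", "CA", "C", "O"),
                    element = c("N", "C", "C", "O"),
                    x = c(0, 1.5, 3, 4.2), y = 0, z = 0, resno = 1)
  gr2 <- find_complementary_groups(read_protein(write_toy_pdb(gly)))
  expect_equal(sum(gr2$complements == "Aromatic"), 0L)
  # but it does have backbone donor and acceptor anchors
  expect_gte(sum(gr2$complements == "HydrogenAcceptor"), 1L)
  expect_gte(sum(gr2$complements == "HydrogenDonor"), 1L)
})

test_that("phenylalanine ring is detected as one aromatic centroid", {
  ang <- (0:5) * pi / 3
  phe <- data.frame(resname = "PHE",
                    atomname = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                    element = "C",
                    x = 5 + 1.39 * cos(ang), y = 1.39 * sin(ang), z = 2,
                    resno = 1)
  gr <- find_complementary_groups(read_protein(write_toy_pdb(phe)))
  ar <- gr[gr$complements == "Aromatic", ]
  expect_equal(nrow(ar), 1L)
  expect_equal(as.numeric(ar[1, c("x", "y", "z")]), c(5, 0, 2),
               tolerance = 1e-6)
})

test_that("group finding is covariant under rigid transforms", {
  set.seed(42)
  w <- make_pocket(seed = 5)
  st <- w$structure
  gr <- find_complementary_groups(st)
  R <- random_rotation(); tt <- c(3, -7, 11)
  st2 <- st
  xyz2 <- sweep(protein_coords(st) %*% t(R), 2, tt, "+")
  st2$atoms$x <- xyz2[, 1]; st2$atoms$y <- xyz2[, 2]; st2$atoms$z <- xyz2[, 3]
  gr2 <- find_complementary_groups(st2)
  expect_equal(nrow(gr), nrow(gr2))
  a1 <- sweep(as.matrix(gr[, c("x", "y", "z")]) %*% t(R), 2, tt, "+")
  a2 <- as.matrix(gr2[, c("x", "y", "z")])
  # same complements in the same order (construction order is stable)
  expect_identical(gr$complements, gr2$complements)
  expect_lt(max(abs(a1 - a2)), 1e-6)
})

test_that("pharmacophore JSON round-trips exactly", {
  ph <- make_ph(c("Aromatic", "HydrogenAcceptor", "NegativeIon"),
                matrix(c(0.123456, 1, 2, 3.5, -2.25, 0.75, 10, 11, 12),
                       3, byrow = TRUE))
  ph$points[[2]]$radius <- 1.5
  ph$points[[3]]$latent <- seq(0, 1, length.out = 32)
  f <- tempfile(fileext = ".json")
  write_pharmacophore(ph, f)
  ph2 <- read_pharmacophore(f)
  expect_identical(pharm_classes(ph2), pharm_classes(ph))
  expect_lt(max(abs(pharm_positions(ph2) - pharm_positions(ph))), 1e-6)
  expect_equal(vapply(ph2$points, function(p) p$radius, numeric(1)),
               c(1, 1.5, 1))
  expect_equal(ph2$points[[3]]$latent, ph$points[[3]]$latent)
})

test_that("pharmacophore JSON errors and defaults", {
  f <- tempfile(fileext = ".json")
  writeLines('{"points":[{"name":"Banana","x":0,"y":0,"z":0}]}', f)
  expect_error(read_pharmacophore(f), "unknown feature class")
  writeLines('{"points":[{"name":"Aromatic","x":0,"y":0}]}', f)
  expect_error(read_pharmacophore(f), "coordinates")
  # missing radius defaults to the 1 Angstrom screening tolerance
  writeLines('{"points":[{"name":"Aromatic","x":1,"y":2,"z":3}]}', f)
  expect_equal(read_pharmacophore(f)$points[[1]]$radius, 1.0)
})
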