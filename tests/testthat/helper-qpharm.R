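# shared fixtures and independent oracles

# write a minimal PDB file from atom tuples and return its path
write_toy_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  # atoms: data.frame with resname, atomname, element, x, y, z,
  # optional type ("ATOM"/"HETATM"), resno
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    rec <- if (is.null(a$type) || is.na(a$type)) "ATOM" else a$type
    resno <- if (is.null(a$resno) || is.na(a$resno)) i else a$resno
    lines[i] <- sprintf(
      "%-6s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      rec, i, a$atomname, a$resname, resno, a$x, a$y, a$z, a$element)
  }
  writeLines(c(lines, "END"), path)
  path
}

# uniform random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# independent quaternion (Horn) superposition oracle: optimal RMSD of Q
# onto P via the eigen-decomposition of the 4x4 key matrix
quaternion_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  M <- t(Q0) %*% P0
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  n <- nrow(P)
  msd <- (sum(P0^2) + sum(Q0^2) - 2 * lmax) / n
  sqrt(max(msd, 0))
}

# brute-force correspondence oracle: every injective class-respecting map
# filtered by the pairwise predicate
brute_force_correspondences <- function(ph, feats) {
  np <- length(ph$points)
  pxyz <- pharm_positions(ph)
  pcls <- pharm_classes(ph)
  radii <- vapply(ph$points, function(p) p$radius, numeric(1))
  fxyz <- as.matrix(feats[, c("x", "y", "z")])
  cand <- lapply(seq_len(np), function(i) which(feats$cls == pcls[i]))
  grids <- do.call(expand.grid, cand)
  out <- list()
  for (r in seq_len(nrow(grids))) {
    a <- as.integer(grids[r, ])
    if (anyDuplicated(a)) next
    ok <- TRUE
    for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
      dp <- sqrt(sum((pxyz[i, ] - pxyz[j, ])^2))
      df <- sqrt(sum((fxyz[a[i], ] - fxyz[a[j], ])^2))
      if (abs(dp - df) > radii[i] + radii[j]) { ok <- FALSE; break }
      if (!ok) break
    }
    if (ok) out[[length(out) + 1L]] <- a
  }
  out
}

# canonical string form of an assignment list, for set comparison
assignment_set <- function(asg) sort(vapply(asg, paste, character(1),
                                            collapse = ","))

# small pharmacophore from a class/position table
make_ph <- function(cls, xyz, radius = 1) {
  pharmacophore(lapply(seq_along(cls), function(i) {
    pharm_point(cls[i], xyz[i, ], radius = radius)
  }))
}

# feature table from class vector + coordinate matrix
make_feats <- function(cls, xyz) {
  data.frame(cls = cls, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

extdata <- function(f) system.file("extdata", f, package = "qpharm")
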