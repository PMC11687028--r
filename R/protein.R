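#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records with bio3d, drops hydrogens, optionally drops
#' HETATM records (ligands, waters), and assigns the 14 integer atom types
#' via [assign_atom_types()].
#'
#' @param path PDB file path.
#' @param receptor_only If `TRUE` (default) HETATM records are excluded,
#'   except common metal ions (ZN, CA, MG, MN, FE), which are part of the
#'   receptor for typing purposes.
#' @return A typed [protein_structure()].
#' @export
read_protein <- function(path, receptor_only = TRUE) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unreadable PDB file: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1, 1), at$elesy)))
  keep <- elem != "H" & elem != "D"
  if (receptor_only) {
    ion_res <- c("ZN", "CA", "MG", "MN", "FE", "NA", "K")
    keep <- keep & (at$type == "ATOM" |
                      (at$type == "HETATM" & at$resid %in% ion_res))
  }
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0L) stop("zero heavy atoms")
  atoms <- data.frame(
    element = elem,
    x = at$x, y = at$y, z = at$z,
    resname = toupper(trimws(at$resid)),
    resid = paste0(at$chain, at$resno),
    atomname = toupper(trimws(at$elety)),
    stringsAsFactors = FALSE
  )
  assign_atom_types(protein_structure(atoms, id = basename(path)))
}

# residue-template atom types for standard amino acids; backbone entries
# (N, CA, C, O, OXT) are shared.  Values follow the 14-type convention in
# N_ATOM_TYPES.
.backbone_types <- c(N = 7L, CA = 2L, C = 2L, O = 8L, OXT = 8L)

.sidechain_types <- list(
  ALA = c(CB = 1L),
  ARG = c(CB = 1L, CG = 1L, CD = 2L, NE = 7L, CZ = 2L, NH1 = 7L, NH2 = 7L),
  ASN = c(CB = 1L, CG = 2L, OD1 = 8L, ND2 = 7L),
  ASP = c(CB = 1L, CG = 2L, OD1 = 8L, OD2 = 8L),
  CYS = c(CB = 2L, SG = 10L),
  GLN = c(CB = 1L, CG = 1L, CD = 2L, OE1 = 8L, NE2 = 7L),
  GLU = c(CB = 1L, CG = 1L, CD = 2L, OE1 = 8L, OE2 = 8L),
  GLY = c(),
  HIS = c(CB = 1L, CG = 4L, ND1 = 6L, CD2 = 4L, CE1 = 4L, NE2 = 7L),
  ILE = c(CB = 1L, CG1 = 1L, CG2 = 1L, CD1 = 1L, CD = 1L),
  LEU = c(CB = 1L, CG = 1L, CD1 = 1L, CD2 = 1L),
  LYS = c(CB = 1L, CG = 1L, CD = 1L, CE = 2L, NZ = 7L),
  MET = c(CB = 1L, CG = 2L, SD = 10L, CE = 2L),
  PHE = c(CB = 1L, CG = 3L, CD1 = 3L, CD2 = 3L, CE1 = 3L, CE2 = 3L, CZ = 3L),
  PRO = c(CB = 1L, CG = 1L, CD = 2L),
  SER = c(CB = 2L, OG = 9L),
  THR = c(CB = 2L, OG1 = 9L, CG2 = 1L),
  TRP = c(CB = 1L, CG = 3L, CD1 = 4L, CD2 = 3L, NE1 = 7L, CE2 = 4L,
          CE3 = 3L, CZ2 = 3L, CZ3 = 3L, CH2 = 3L),
  TYR = c(CB = 1L, CG = 3L, CD1 = 3L, CD2 = 3L, CE1 = 3L, CE2 = 3L,
          CZ = 4L, OH = 9L),
  VAL = c(CB = 1L, CG1 = 1L, CG2 = 1L)
)

# element fallback when no residue template applies
.element_fallback <- function(element) {
  switch(element,
         C = 1L, N = 6L, O = 8L, S = 10L, P = 11L,
         F = 5L, CL = 5L, BR = 5L, I = 5L,
         CA = 12L, ZN = 13L,
         MG = 14L, MN = 14L, FE = 14L, B = 14L, NA. = 14L,
         NA_integer_)
}

#' Assign integer atom types to protein heavy atoms
#'
#' Each heavy atom gets exactly one type in 1..14. Standard amino-acid
#' atoms are typed from residue templates (carbons split aromatic vs
#' aliphatic and hydrophobe vs heteroatom-bonded; N/O split by donor /
#' acceptor role); metals and other elements fall back to element rules.
#' Untyped carbons are split hydrophobe / non-hydrophobe by a bonded-to-
#' heteroatom distance test (< 1.75 Angstrom to N/O/S/P). Unknown elements
#' map to type 14 (generic metal bucket) with a warning. Idempotent.
#'
#' @param structure A [protein_structure()].
#' @return The structure with `atom_type` filled in.
#' @export
assign_atom_types <- function(structure) {
  stopifnot(inherits(structure, "protein_structure"))
  at <- structure$atoms
  n <- nrow(at)
  type <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    rn <- at$resname[i]
    an <- at$atomname[i]
    if (!is.na(.backbone_types[an]) && rn %in% names(.sidechain_types)) {
      type[i] <- .backbone_types[[an]]
    } else if (rn %in% names(.sidechain_types)) {
      tmpl <- .sidechain_types[[rn]]
      if (an %in% names(tmpl)) type[i] <- tmpl[[an]]
    }
    if (is.na(type[i]) && at$element[i] %in% c("ZN", "CA", "MG", "MN", "FE")) {
      type[i] <- .element_fallback(at$element[i])
    }
  }
  # element fallback for atoms no template covered
  miss <- which(is.na(type))
  if (length(miss)) {
    xyz <- as.matrix(at[, c("x", "y", "z")])
    hetero <- at$element %in% c("N", "O", "S", "P")
    for (i in miss) {
      el <- at$element[i]
      t0 <- .element_fallback(el)
      if (is.na(t0)) {
        warning("unknown element '", el, "' mapped to generic type 14")
        t0 <- 14L
      }
      if (el == "C") {
        # hydrophobe unless bonded to a heteroatom
        d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
        bonded_het <- any(hetero & d > 1e-6 & d < 1.75)
        arom <- isTRUE(at$aromatic[i])
        t0 <- if (arom) (if (bonded_het) 4L else 3L)
              else (if (bonded_het) 2L else 1L)
      }
      type[i] <- t0
    }
  }
  structure$atoms$atom_type <- type
  structure
}

#' Find complementary functional groups on a protein
#'
#' Returns the protein-side anchors that ligand features interact with:
#' aromatic ring centroids (anchoring ligand `Aromatic` features), hydrogen
#' donors (anchoring `HydrogenAcceptor`), acceptors (anchoring
#' `HydrogenDonor`), hydrophobic carbon cluster centroids (anchoring
#' `Hydrophobic`), positively charged groups (anchoring `NegativeIon`) and
#' negatively charged groups (anchoring `PositiveIon`).
#'
#' Donor / acceptor groups are single typed atoms (types 7/9 donate, types
#' 6/8/9 accept). Aromatic and hydrophobic groups are distance-connected
#' clusters of aromatic (3/4) resp. hydrophobic-carbon (1) atoms, anchored
#' at the cluster centroid; aromatic clusters require at least 5 atoms
#' (a ring). Charged groups come from residue templates: LYS NZ and the
#' ARG guanidinium centroid are positive, ASP/GLU carboxylate-oxygen
#' centroids negative.
#'
#' @param structure A typed [protein_structure()].
#' @param bond_dist Distance (Angstrom) under which two atoms count as
#'   bonded for cluster building; default 1.8.
#' @return data.frame with columns `complements` (ligand feature class the
#'   anchor attracts), `x`, `y`, `z` (anchor) and `source_atoms` (list
#'   column of atom indices).
#' @export
find_complementary_groups <- function(structure, bond_dist = 1.8) {
  stopifnot(inherits(structure, "protein_structure"))
  at <- structure$atoms
  if (any(is.na(at$atom_type))) structure <- assign_atom_types(structure)
  at <- structure$atoms
  xyz <- protein_coords(structure)
  out <- list()
  add <- function(cls, anchor, idx) {
    out[[length(out) + 1L]] <<- data.frame(
      complements = cls, x = anchor[1], y = anchor[2], z = anchor[3],
      source_atoms = I(list(as.integer(idx))), stringsAsFactors = FALSE)
  }
  centroid <- function(idx) colMeans(xyz[idx, , drop = FALSE])

  cluster_idx <- function(idx) {
    # split atom indices into distance-connected clusters
    if (length(idx) == 0L) return(list())
    if (length(idx) == 1L) return(list(idx))
    d <- cross_dist(xyz[idx, , drop = FALSE], xyz[idx, , drop = FALSE])
    adj <- d < bond_dist & upper.tri(d)
    ed <- which(adj, arr.ind = TRUE)
    g <- igraph::graph_from_edgelist(cbind(ed[, 1], ed[, 2]), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    lapply(split(seq_along(idx), comp), function(j) idx[j])
  }

  # charged-group membership excludes an atom from the neutral donor /
  # acceptor lists: ionic anchors are ionic only
  charged <- logical(nrow(at))
  for (idx in split(seq_len(nrow(at)), at$resid)) {
    rn <- at$resname[idx[1]]
    an <- at$atomname[idx]
    if (rn == "LYS") charged[idx[an == "NZ"]] <- TRUE
    if (rn == "ARG") charged[idx[an %in% c("NE", "NH1", "NH2")]] <- TRUE
    if (rn == "ASP") charged[idx[an %in% c("OD1", "OD2")]] <- TRUE
    if (rn == "GLU") charged[idx[an %in% c("OE1", "OE2")]] <- TRUE
  }

  # aromatic rings
  for (cl in cluster_idx(which(at$atom_type %in% c(3L, 4L)))) {
    if (length(cl) >= 5L) add("Aromatic", centroid(cl), cl)
  }
  # donors anchor ligand acceptors; acceptors anchor ligand donors
  for (i in which(at$atom_type %in% c(7L, 9L) & !charged)) {
    add("HydrogenAcceptor", xyz[i, ], i)
  }
  for (i in which(at$atom_type %in% c(6L, 8L, 9L) & !charged)) {
    add("HydrogenDonor", xyz[i, ], i)
  }
  # hydrophobic clusters (aliphatic hydrophobe carbons)
  for (cl in cluster_idx(which(at$atom_type == 1L))) {
    add("Hydrophobic", centroid(cl), cl)
  }
  # charged groups from residue templates
  res <- split(seq_len(nrow(at)), at$resid)
  for (idx in res) {
    rn <- at$resname[idx[1]]
    an <- at$atomname[idx]
    if (rn == "LYS" && "NZ" %in% an) {
      i <- idx[an == "NZ"]
      add("NegativeIon", xyz[i, ], i)
    } else if (rn == "ARG" && any(c("NE", "NH1", "NH2") %in% an)) {
      i <- idx[an %in% c("NE", "NH1", "NH2", "CZ")]
      add("NegativeIon", centroid(i), i)
    } else if (rn == "ASP" && any(c("OD1", "OD2") %in% an)) {
      i <- idx[an %in% c("OD1", "OD2")]
      add("PositiveIon", centroid(i), i)
    } else if (rn == "GLU" && any(c("OE1", "OE2") %in% an)) {
      i <- idx[an %in% c("OE1", "OE2")]
      add("PositiveIon", centroid(i), i)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(complements = character(0), x = numeric(0),
                      y = numeric(0), z = numeric(0),
                      source_atoms = I(list())))
  }
  do.call(rbind, out)
}
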