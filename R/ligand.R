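# MDL atom-block charge codes -> formal charge
.mdl_charge <- function(code) {
  c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2,
    `7` = -3)[as.character(code)]
}

#' Read a molecule library from an SDF file
#'
#' Reads a (possibly multi-conformer) SDF with ChemmineR. Consecutive
#' records with the same title are grouped into one molecule with several
#' conformers. An optional `label` data field ("active" / "decoy") sets
#' the screening label. Feature points are computed per conformer with
#' [extract_ligand_features()].
#'
#' @param path SDF file path.
#' @param compute_features Compute typed feature points per conformer
#'   (default `TRUE`).
#' @return List of [molecule_record()] objects.
#' @export
read_molecule_library <- function(path, compute_features = TRUE) {
  sdfs <- ChemmineR::read.SDFset(path)
  ids <- vapply(seq_along(sdfs), function(i) {
    h <- ChemmineR::header(sdfs[[i]])
    if (length(h) >= 1 && nzchar(h[[1]])) h[[1]] else paste0("mol", i)
  }, character(1))
  groups <- split(seq_along(sdfs), factor(ids, levels = unique(ids)))
  lapply(names(groups), function(id) {
    idx <- groups[[id]]
    confs <- list(); feats <- list(); label <- "unknown"; elements <- NULL
    for (i in idx) {
      sdf <- sdfs[[i]]
      ab <- ChemmineR::atomblock(sdf)
      elem <- toupper(sub("_.*$", "", rownames(ab)))
      heavy <- elem != "H"
      xyz <- unname(ab[, 1:3, drop = FALSE])[heavy, , drop = FALSE]
      confs[[length(confs) + 1L]] <- xyz
      if (is.null(elements)) elements <- elem[heavy]
      feats[[length(feats) + 1L]] <-
        if (compute_features) .mol_features(sdf) else
          data.frame(cls = character(0), x = numeric(0), y = numeric(0),
                     z = numeric(0))
      db <- ChemmineR::datablock(sdf)
      if ("label" %in% names(db)) label <- db[["label"]]
    }
    molecule_record(id, confs, feats, label = label, elements = elements)
  })
}

# internal: molecular-graph context for one SDF record
.mol_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- toupper(sub("_.*$", "", rownames(ab)))
  xyz <- unname(ab[, 1:3, drop = FALSE])
  # atom-block layout from ChemmineR: C1-C3 coords, C5 mass diff, C6 charge
  charge <- unname(.mdl_charge(ab[, "C6"]))
  n <- length(elem)
  nb <- vector("list", n)
  order <- list()
  if (nrow(bb)) {
    for (k in seq_len(nrow(bb))) {
      a <- bb[k, 1]; b <- bb[k, 2]; o <- bb[k, 3]
      nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
      order[[paste(min(a, b), max(a, b))]] <- o
    }
  }
  rings <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE,
                                     inner = TRUE),
                    error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
  ring_idx <- lapply(rings$RINGS, function(r) as.integer(sub("^.*_", "", r)))
  arom_flag <- as.logical(unlist(rings$AROMATIC))
  arom_rings <- if (length(ring_idx) && length(arom_flag)) {
    ring_idx[which(arom_flag)]
  } else list()
  aromatic_atom <- rep(FALSE, n)
  for (r in arom_rings) aromatic_atom[r] <- TRUE
  nH <- vapply(seq_len(n), function(i) sum(elem[nb[[i]]] == "H"), integer(1))
  list(elem = elem, xyz = xyz, charge = charge, nb = nb, order = order,
       arom_rings = arom_rings, aromatic_atom = aromatic_atom, nH = nH)
}

# internal: typed feature points for one SDF record (one conformer)
.mol_features <- function(sdf) {
  g <- .mol_graph(sdf)
  feats <- list()
  add <- function(cls, pos) {
    feats[[length(feats) + 1L]] <<- data.frame(
      cls = cls, x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
  }
  bond_order <- function(a, b) {
    o <- g$order[[paste(min(a, b), max(a, b))]]
    if (is.null(o)) 0L else o
  }
  heavy_nb <- function(i) g$nb[[i]][g$elem[g$nb[[i]]] != "H"]

  # aromatic: one feature per aromatic ring, at the ring centroid
  for (r in g$arom_rings) {
    add("Aromatic", colMeans(g$xyz[r, , drop = FALSE]))
  }

  # charged groups: negatives grouped by shared central atom (carboxylate,
  # phosphate, sulfonate oxygens), positives at the charged atom
  neg <- which(g$charge < 0 & g$elem %in% c("O", "S", "N"))
  used <- rep(FALSE, length(g$elem))
  for (i in neg) {
    if (used[i]) next
    ctr <- heavy_nb(i)
    grp <- i
    if (length(ctr)) {
      # sibling oxygens on the same central atom (incl. =O partners)
      sib <- heavy_nb(ctr[1])
      sib <- sib[g$elem[sib] == "O" & sib != i]
      sib <- sib[vapply(sib, function(s)
        g$charge[s] < 0 || bond_order(ctr[1], s) == 2, logical(1))]
      grp <- c(i, sib)
    }
    used[grp] <- TRUE
    add("NegativeIon", colMeans(g$xyz[grp, , drop = FALSE]))
  }
  for (i in which(g$charge > 0 & g$elem == "N")) {
    add("PositiveIon", g$xyz[i, ])
  }

  # hydrogen donors: N/O with attached hydrogen, not negatively charged
  for (i in which(g$elem %in% c("N", "O"))) {
    if (g$nH[i] >= 1L && g$charge[i] <= 0) add("HydrogenDonor", g$xyz[i, ])
  }
  # hydrogen acceptors: any O not positively charged; N with a free lone
  # pair (aromatic N without H, or sp3/sp2 N with < 3 heavy neighbours and
  # no positive charge, excluding amide-type N bonded to a carbonyl C)
  for (i in which(g$elem == "O")) {
    add("HydrogenAcceptor", g$xyz[i, ])
  }
  for (i in which(g$elem == "N")) {
    if (g$charge[i] > 0) next
    hn <- heavy_nb(i)
    amide <- any(vapply(hn, function(c) {
      g$elem[c] == "C" && any(vapply(heavy_nb(c), function(o)
        g$elem[o] == "O" && bond_order(c, o) == 2, logical(1)))
    }, logical(1)))
    if (g$aromatic_atom[i] && g$nH[i] == 0L && length(hn) <= 2L) {
      add("HydrogenAcceptor", g$xyz[i, ])
    } else if (!g$aromatic_atom[i] && !amide &&
               length(hn) + g$nH[i] <= 3L) {
      add("HydrogenAcceptor", g$xyz[i, ])
    }
  }

  # hydrophobic: bond-connected clusters of apolar carbons (no double bond
  # to a heteroatom; aromatic carbons and CHn carbons count)
  apolar <- vapply(seq_along(g$elem), function(i) {
    if (g$elem[i] != "C") return(FALSE)
    hn <- heavy_nb(i)
    dbl_het <- any(vapply(hn, function(j)
      g$elem[j] %in% c("O", "N", "S") && bond_order(i, j) >= 2, logical(1)))
    !dbl_het && (g$aromatic_atom[i] || g$nH[i] >= 1L ||
                   all(g$elem[hn] == "C"))
  }, logical(1))
  if (any(apolar)) {
    idx <- which(apolar)
    g2 <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    pos <- match(seq_along(g$elem), idx)
    el <- list()
    for (i in idx) for (j in g$nb[[i]]) {
      if (j > i && !is.na(pos[j]) && apolar[j]) {
        el[[length(el) + 1L]] <- c(pos[i], pos[j])
      }
    }
    if (length(el)) g2 <- igraph::add_edges(g2, unlist(el))
    memb <- igraph::components(g2)$membership
    for (cl in split(idx, memb)) {
      add("Hydrophobic", colMeans(g$xyz[cl, , drop = FALSE]))
    }
  }

  if (length(feats) == 0L) {
    return(data.frame(cls = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0)))
  }
  do.call(rbind, feats)
}

#' Extract typed feature points from a molecule conformer
#'
#' Deterministic rule-based typing on the molecular graph: aromatic
#' features at aromatic-ring centroids; negative/positive ion features at
#' charged-group centroids; donor/acceptor features at matched N/O atoms;
#' hydrophobic features at centroids of bond-connected apolar-carbon
#' clusters. See the package vignette for the full rule table.
#'
#' @param mol A [molecule_record()] created by [read_molecule_library()]
#'   (features precomputed), or a `ChemmineR::SDFset` element.
#' @param conformer_index 1-based conformer index.
#' @return data.frame with columns `cls`, `x`, `y`, `z`.
#' @export
extract_ligand_features <- function(mol, conformer_index = 1L) {
  if (inherits(mol, "molecule_record")) {
    if (conformer_index < 1L || conformer_index > length(mol$conformers)) {
      stop("invalid conformer index")
    }
    return(mol$feature_points[[conformer_index]])
  }
  if (methods::is(mol, "SDF")) return(.mol_features(mol))
  if (methods::is(mol, "SDFset")) return(.mol_features(mol[[conformer_index]]))
  stop("unsupported molecule object")
}

#' Feature points of a molecule conformer as a matrix + classes
#' @noRd
.feature_xyz <- function(fp) {
  list(cls = fp$cls, xyz = as.matrix(fp[, c("x", "y", "z")]))
}
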