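#' Pharmacophore feature classes
#'
#' The six interaction chemotypes used throughout the package, in fixed
#' order. Indexing is 0-based to match the class-index convention used in
#' model outputs (`Aromatic` = 0 ... `PositiveIon` = 5).
#'
#' @format Character vector of length 6.
#' @export
FEATURE_CLASSES <- c(
  "Aromatic", "HydrogenAcceptor", "HydrogenDonor",
  "Hydrophobic", "NegativeIon", "PositiveIon"
)

#' Number of protein atom types
#'
#' Protein heavy atoms are featurized into 14 integer types following the
#' smina/gnina atom-typing convention: aliphatic carbon (hydrophobe /
#' non-hydrophobe = 1/2), aromatic carbon (3/4), halogens (5), nitrogen
#' acceptor (6), nitrogen donor (7), oxygen acceptor (8), oxygen
#' donor/donor-acceptor (9), sulfur (10), phosphorus (11), calcium (12),
#' zinc (13) and generic metal (14).
#'
#' @export
N_ATOM_TYPES <- 14L

#' Validate / look up a feature class
#'
#' @param cls Character scalar, one of [FEATURE_CLASSES].
#' @return The 0-based class index (integer).
#' @export
feature_class_index <- function(cls) {
  i <- match(cls, FEATURE_CLASSES)
  if (any(is.na(i))) {
    stop("unknown feature class: ", paste(cls[is.na(i)], collapse = ", "))
  }
  i - 1L
}

#' Construct a pharmacophore point
#'
#' A single typed interaction point: a feature class, a 3D position in
#' Angstroms, a tolerance radius (default 1 Angstrom, the radius used for
#' screening) and an optional 32-length latent embedding of the local
#' protein environment.
#'
#' @param cls Feature class name (one of [FEATURE_CLASSES]).
#' @param position Numeric length-3 vector, Angstroms.
#' @param radius Tolerance radius in Angstroms (> 0), default 1.
#' @param latent Optional numeric vector of length 32.
#' @return Object of class `pharm_point`.
#' @export
pharm_point <- function(cls, position, radius = 1.0, latent = NULL) {
  feature_class_index(cls)
  position <- as.numeric(position)
  stopifnot(length(position) == 3L, all(is.finite(position)))
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    stop("radius must be a positive scalar")
  }
  if (!is.null(latent)) {
    latent <- as.numeric(latent)
    if (length(latent) != 32L) stop("latent must have length 32")
  }
  structure(list(cls = cls, position = position, radius = radius,
                 latent = latent),
            class = "pharm_point")
}

#' Construct a pharmacophore
#'
#' An ordered set of typed 3D points used as a virtual-screening query.
#' Screening requires at least 3 points; smaller objects may exist while a
#' pharmacophore is being assembled.
#'
#' @param points List of [pharm_point()] objects.
#' @param name Text label.
#' @return Object of class `pharmacophore`.
#' @export
pharmacophore <- function(points = list(), name = "pharmacophore") {
  stopifnot(is.list(points))
  for (p in points) {
    if (!inherits(p, "pharm_point")) stop("points must be pharm_point objects")
  }
  key <- vapply(points, function(p) {
    paste(p$cls, paste(sprintf("%.6f", p$position), collapse = ","))
  }, character(1))
  if (anyDuplicated(key)) stop("duplicate (class, position) point")
  structure(list(points = points, name = name), class = "pharmacophore")
}

#' @export
print.pharmacophore <- function(x, ...) {
  cat(sprintf("<pharmacophore '%s': %d points>\n", x$name, length(x$points)))
  for (p in x$points) {
    cat(sprintf("  %-16s (%7.3f, %7.3f, %7.3f) r=%.2f%s\n", p$cls,
                p$position[1], p$position[2], p$position[3], p$radius,
                if (is.null(p$latent)) "" else " +latent"))
  }
  invisible(x)
}

#' @export
length.pharmacophore <- function(x) length(x$points)

#' Matrix of pharmacophore point positions
#' @param ph A `pharmacophore`.
#' @return n x 3 numeric matrix.
#' @export
pharm_positions <- function(ph) {
  if (length(ph$points) == 0L) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, lapply(ph$points, function(p) p$position))
}

#' Feature classes of a pharmacophore's points
#' @param ph A `pharmacophore`.
#' @return Character vector.
#' @export
pharm_classes <- function(ph) {
  vapply(ph$points, function(p) p$cls, character(1))
}

#' Construct a protein structure
#'
#' Heavy-atom representation of a receptor: one row per atom with element,
#' coordinates, residue bookkeeping and (after [assign_atom_types()]) an
#' integer atom type 1-14.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `resname`, `resid`, `atomname`, `atom_type`.
#' @param id Text identifier.
#' @return Object of class `protein_structure`.
#' @export
protein_structure <- function(atoms, id = "protein") {
  stopifnot(is.data.frame(atoms),
            all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  for (col in c("resname", "atomname")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- ""
  }
  if (is.null(atoms$resid)) atoms$resid <- seq_len(nrow(atoms))
  if (is.null(atoms$atom_type)) atoms$atom_type <- NA_integer_
  structure(list(atoms = atoms, id = id), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure '%s': %d heavy atoms, %s>\n", x$id,
              nrow(x$atoms),
              if (all(is.na(x$atoms$atom_type))) "untyped" else "typed"))
  invisible(x)
}

#' Atom coordinates of a protein structure
#' @param structure A `protein_structure`.
#' @return n x 3 numeric matrix.
#' @export
protein_coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Construct a molecule record
#'
#' A small molecule with one or more conformers (each an atom-coordinate
#' matrix over the same atoms), per-conformer typed feature points, and a
#' screening label.
#'
#' @param mol_id Text identifier.
#' @param conformers List of n_atoms x 3 coordinate matrices.
#' @param feature_points Per conformer, a data.frame with columns `cls`,
#'   `x`, `y`, `z` (the typed interaction points of that conformer).
#' @param label One of "active", "decoy", "unknown".
#' @param elements Optional character vector of atom elements (shared by
#'   all conformers).
#' @return Object of class `molecule_record`.
#' @export
molecule_record <- function(mol_id, conformers, feature_points,
                            label = "unknown", elements = NULL) {
  label <- match.arg(label, c("active", "decoy", "unknown"))
  stopifnot(is.list(conformers), length(conformers) >= 1L,
            is.list(feature_points),
            length(feature_points) == length(conformers))
  n_at <- nrow(conformers[[1]])
  for (cf in conformers) {
    stopifnot(is.matrix(cf), ncol(cf) == 3L, nrow(cf) == n_at)
  }
  for (fp in feature_points) {
    stopifnot(is.data.frame(fp), all(c("cls", "x", "y", "z") %in% names(fp)))
    if (nrow(fp)) feature_class_index(fp$cls)
  }
  structure(list(mol_id = mol_id, conformers = conformers,
                 feature_points = feature_points, label = label,
                 elements = elements),
            class = "molecule_record")
}

#' Interaction distance thresholds
#'
#' Distance band (min, max) in Angstroms between a ligand-side feature and
#' its complementary protein-side group, per feature class. The defaults
#' are the screening-convention thresholds: Aromatic (1.5, 7), HydrogenAcceptor
#' (1, 4), HydrogenDonor (1, 4), Hydrophobic (1.5, 5), NegativeIon (1.5, 5),
#' PositiveIon (1.5, 5).
#'
#' @param min_dist,max_dist Named numeric vectors over [FEATURE_CLASSES];
#'   omit for the defaults.
#' @return data.frame with columns `cls`, `min_dist`, `max_dist`.
#' @export
interaction_thresholds <- function(min_dist = NULL, max_dist = NULL) {
  df <- data.frame(
    cls = FEATURE_CLASSES,
    min_dist = c(1.5, 1, 1, 1.5, 1.5, 1.5),
    max_dist = c(7, 4, 4, 5, 5, 5),
    stringsAsFactors = FALSE
  )
  if (!is.null(min_dist)) df$min_dist[match(names(min_dist), df$cls)] <- min_dist
  if (!is.null(max_dist)) df$max_dist[match(names(max_dist), df$cls)] <- max_dist
  if (any(df$min_dist >= df$max_dist)) stop("min_dist must be < max_dist")
  df
}

# internal: run expr with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# internal: pairwise Euclidean distances between rows of two matrices
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * (A %*% t(B))
  sqrt(pmax(d2, 0))
}
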