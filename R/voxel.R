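# voxel grid geometry: cubic volume of edge 9.5 A at 0.5 A resolution,
# endpoint-inclusive -> 20 voxel centres per side, 14 atom-type channels.
VOXEL_DIM <- 20L
VOXEL_RES <- 0.5
VOXEL_EDGE <- 9.5

# van-der-Waals radii (Angstrom) for the splat kernel, by element
.vdw_radius <- function(element) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
         F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
         CA = 1.97, ZN = 1.39, MG = 1.73, MN = 1.61, FE = 1.52)[element]
  ifelse(is.na(r), 1.6, r)
}

#' Voxelize protein context around a query point
#'
#' Splats each heavy atom's density onto its atom-type channel of a
#' 14-channel cubic grid (edge 9.5 Angstrom, 0.5 Angstrom resolution, 20
#' voxel centres per side) centred on `center`. The kernel is a truncated
#' Gaussian: `exp(-r^2 / (2 sigma^2))` with `sigma = vdW/2`, cut off at
#' `1.5 * vdW`. Atoms outside the cube contribute nothing. Deterministic.
#'
#' @param structure A typed [protein_structure()].
#' @param center Numeric length-3, Angstrom.
#' @return Object of class `voxel_tensor`: list with `values` (array
#'   `20 x 20 x 20 x 14`, spatial x/y/z then channel) and `center`.
#' @export
voxelize <- function(structure, center) {
  stopifnot(inherits(structure, "protein_structure"), length(center) == 3L)
  at <- structure$atoms
  if (any(is.na(at$atom_type))) stop("structure must be typed")
  vals <- array(0, dim = c(VOXEL_DIM, VOXEL_DIM, VOXEL_DIM, N_ATOM_TYPES))
  axis <- center_axis(center)
  lo <- vapply(axis, min, numeric(1)) ; hi <- vapply(axis, max, numeric(1))
  for (i in seq_len(nrow(at))) {
    pos <- c(at$x[i], at$y[i], at$z[i])
    rad <- .vdw_radius(at$element[i])
    cut <- 1.5 * rad
    if (any(pos < lo - cut) || any(pos > hi + cut)) next
    rng <- lapply(1:3, function(k) {
      which(abs(axis[[k]] - pos[k]) <= cut)
    })
    if (any(vapply(rng, length, integer(1)) == 0L)) next
    dx <- axis[[1]][rng[[1]]] - pos[1]
    dy <- axis[[2]][rng[[2]]] - pos[2]
    dz <- axis[[3]][rng[[3]]] - pos[3]
    d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
    dens <- exp(-d2 / (2 * (rad / 2)^2))
    dens[d2 > cut^2] <- 0
    ch <- at$atom_type[i]
    cur <- vals[rng[[1]], rng[[2]], rng[[3]], ch]
    # element order of the extraction matches dens regardless of dropped
    # dimensions
    vals[rng[[1]], rng[[2]], rng[[3]], ch] <- cur + as.vector(dens)
  }
  structure(list(values = vals, center = as.numeric(center)),
            class = "voxel_tensor")
}

# voxel-centre coordinates along each axis for a cube centred at `center`
center_axis <- function(center) {
  half <- VOXEL_EDGE / 2
  lapply(1:3, function(k) center[k] - half + VOXEL_RES * (0:(VOXEL_DIM - 1L)))
}

# flatten a voxel tensor to the layout the CNN expects
# (spatial x-fastest within each channel block)
voxel_flat <- function(vt) as.numeric(vt$values)

# sparse representation (index/value pairs) for compact dataset storage
voxel_sparse <- function(vt) {
  v <- as.numeric(vt$values)
  idx <- which(v > 1e-8)
  list(idx = idx, val = v[idx])
}

# densify a list of sparse voxel samples into an n x (14*8000) matrix
voxel_batch <- function(sparse_list) {
  n <- length(sparse_list)
  X <- matrix(0, n, VOXEL_DIM^3 * N_ATOM_TYPES)
  for (i in seq_len(n)) {
    s <- sparse_list[[i]]
    X[i, s$idx] <- s$val
  }
  X
}
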