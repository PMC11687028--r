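# ---- dense CNN score fields and candidate feature extraction -------------

#' Evaluate the CNN on a 0.5-Angstrom lattice over a box
#'
#' Grids the box at 0.5 Angstrom, voxelizes the protein context around
#' every lattice point and applies the CNN, storing the six class scores
#' and the 32-length latent per point.
#'
#' @param structure A typed [protein_structure()].
#' @param box List with `min` and `max` length-3 corners (Angstrom), or a
#'   length-6 vector `(x0, y0, z0, x1, y1, z1)`.
#' @param model A `qpharm_cnn`.
#' @param chunk Lattice points per forward chunk.
#' @return Object of class `score_field`: list with `points` (n x 3),
#'   `scores` (n x 6), `latent` (n x 32), `box`, `dims`.
#' @export
score_grid <- function(structure, box, model, chunk = 64L) {
  box <- as_box(box)
  ax <- lapply(1:3, function(k) {
    if (box$max[k] < box$min[k]) stop("empty box")
    seq(box$min[k], box$max[k], by = 0.5)
  })
  dims <- vapply(ax, length, integer(1))
  grid <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                                KEEP.OUT.ATTRS = FALSE))
  n <- nrow(grid)
  vox <- vector("list", n)
  for (i in seq_len(n)) vox[[i]] <- voxel_sparse(voxelize(structure, grid[i, ]))
  pred <- cnn_predict(model, vox, chunk = chunk)
  structure(list(points = grid, scores = pred$scores, latent = pred$latent,
                 box = box, dims = dims),
            class = "score_field")
}

as_box <- function(box) {
  if (is.list(box) && !is.null(box$min)) {
    list(min = as.numeric(box$min), max = as.numeric(box$max))
  } else {
    b <- as.numeric(box)
    stopifnot(length(b) == 6L)
    list(min = b[1:3], max = b[4:6])
  }
}

#' Build a score field from explicit values
#'
#' Assembles a `score_field` from a lattice and per-point scores; used to
#' exercise the downstream extraction operators without a trained model.
#'
#' @param points n x 3 lattice coordinates (0.5 Angstrom spacing).
#' @param scores n x 6 class scores in `[0, 1]`.
#' @param latent Optional n x 32 matrix (zeros when omitted).
#' @param box,dims Optional geometry (derived from `points` when omitted).
#' @return A `score_field`.
#' @export
score_field <- function(points, scores, latent = NULL, box = NULL,
                        dims = NULL) {
  points <- as.matrix(points)
  scores <- as.matrix(scores)
  stopifnot(nrow(points) == nrow(scores), ncol(scores) == 6L,
            all(scores >= 0 & scores <= 1))
  if (is.null(latent)) latent <- matrix(0, nrow(points), 32L)
  if (is.null(box)) box <- list(min = apply(points, 2, min),
                                max = apply(points, 2, max))
  if (is.null(dims)) {
    dims <- vapply(1:3, function(k) length(unique(points[, k])), integer(1))
  }
  colnames(scores) <- FEATURE_CLASSES
  structure(list(points = points, scores = scores, latent = latent,
                 box = box, dims = dims),
            class = "score_field")
}

#' Connected components of super-threshold lattice points
#'
#' 26-neighbour connectivity on the 0.5-Angstrom lattice, restricted to
#' points whose score for `cls` exceeds `threshold`. Components are
#' disjoint and exhaustive.
#'
#' @param field A `score_field`.
#' @param cls Feature class name.
#' @param threshold Score threshold in (0, 1); default 0.5.
#' @return List of components: each a list with `cls`, `members` (row
#'   indices into the field), `scores`.
#' @export
connected_components <- function(field, cls, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  k <- feature_class_index(cls) + 1L
  sel <- which(field$scores[, k] > threshold)
  if (length(sel) == 0L) return(list())
  pts <- field$points[sel, , drop = FALSE]
  # neighbours: lattice points within one step (0.5 A) along each axis
  d <- cross_dist(pts, pts)
  adj <- d < 0.5 * sqrt(3) + 1e-6 & upper.tri(d)
  ed <- which(adj, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(sel), directed = FALSE)
  if (nrow(ed)) g <- igraph::add_edges(g, t(ed))
  memb <- igraph::components(g)$membership
  lapply(split(seq_along(sel), memb), function(i) {
    list(cls = cls, members = sel[i], scores = field$scores[sel[i], k])
  })
}

#' Anchor top component points to complementary groups
#'
#' For every (complementary group of class c, connected component of class
#' c) pair, selects the single highest-score member point whose distance
#' to the group anchor lies within the class's interaction band; the
#' number of protein groups near a component thus determines how many
#' points it contributes. Duplicate lattice points are collapsed. Ties in
#' score break toward the lowest lattice index (deterministic).
#'
#' @param field The `score_field` the components came from.
#' @param components List of components ([connected_components()]).
#' @param groups Complementary groups ([find_complementary_groups()]).
#' @param thresholds Interaction band table ([interaction_thresholds()]).
#' @return data.frame with `cls`, `x`, `y`, `z`, `score`, `point` (field
#'   row index) and the latent rows as attribute `latent`.
#' @export
anchor_top_points <- function(field, components, groups,
                              thresholds = interaction_thresholds()) {
  picked <- list()
  for (comp in components) {
    cls <- comp$cls
    band <- thresholds[thresholds$cls == cls, ]
    ganchors <- groups[groups$complements == cls, , drop = FALSE]
    if (nrow(ganchors) == 0L) next
    mpts <- field$points[comp$members, , drop = FALSE]
    for (gi in seq_len(nrow(ganchors))) {
      a <- as.numeric(ganchors[gi, c("x", "y", "z")])
      dist <- sqrt(rowSums(sweep(mpts, 2, a)^2))
      ok <- dist >= band$min_dist & dist <= band$max_dist
      if (!any(ok)) next
      cand <- which(ok)
      best <- cand[order(-comp$scores[cand], comp$members[cand])][1]
      picked[[length(picked) + 1L]] <-
        data.frame(cls = cls, x = mpts[best, 1], y = mpts[best, 2],
                   z = mpts[best, 3], score = comp$scores[best],
                   point = comp$members[best], stringsAsFactors = FALSE)
    }
  }
  if (length(picked) == 0L) {
    out <- data.frame(cls = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), score = numeric(0), point = integer(0))
    attr(out, "latent") <- matrix(0, 0, 32L)
    return(out)
  }
  out <- do.call(rbind, picked)
  dup <- duplicated(paste(out$cls, out$point))
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "latent") <- field$latent[out$point, , drop = FALSE]
  out
}

#' Merge nearby same-class points by centroid-linkage clustering
#'
#' Iteratively merges the closest pair of clusters whose centroids lie
#' within `merge_dist`, until no pair of cluster centroids is closer than
#' `merge_dist`. Each cluster becomes one pharmacophore point at the
#' member centroid, with the member-latent mean as its latent.
#'
#' @param points data.frame with `cls`, `x`, `y`, `z` (one class only, or
#'   mixed: clustering is done per class).
#' @param merge_dist Merge threshold in Angstrom (default 1.5).
#' @param latent Optional per-point latent matrix (rows match `points`);
#'   taken from `attr(points, "latent")` when present.
#' @return List of [pharm_point()]s.
#' @export
cluster_points <- function(points, merge_dist = 1.5, latent = NULL) {
  if (is.null(latent)) latent <- attr(points, "latent")
  if (is.null(latent)) latent <- matrix(0, nrow(points), 32L)
  out <- list()
  for (cls in unique(points$cls)) {
    sel <- which(points$cls == cls)
    xyz <- as.matrix(points[sel, c("x", "y", "z")])
    clusters <- lapply(seq_along(sel), function(i) sel[i])
    cent <- xyz
    repeat {
      if (length(clusters) < 2L) break
      d <- cross_dist(cent, cent)
      diag(d) <- Inf
      m <- which(d == min(d), arr.ind = TRUE)[1, ]
      if (d[m[1], m[2]] >= merge_dist) break
      i <- min(m); j <- max(m)
      clusters[[i]] <- c(clusters[[i]], clusters[[j]])
      clusters[[j]] <- NULL
      cent <- do.call(rbind, lapply(clusters, function(ix) {
        colMeans(as.matrix(points[ix, c("x", "y", "z"), drop = FALSE]))
      }))
    }
    for (ci in seq_along(clusters)) {
      ix <- clusters[[ci]]
      lat <- colMeans(latent[ix, , drop = FALSE])
      out[[length(out) + 1L]] <-
        pharm_point(cls, cent[ci, ], latent = lat)
    }
  }
  out
}

#' Predict candidate pharmacophore features for a binding site
#'
#' The full extraction pipeline: dense CNN score field over the box, per
#' class 26-connected components above threshold, top in-band point per
#' (complementary group, component) pair, centroid-linkage merging. Every
#' output point carries its latent embedding.
#'
#' @inheritParams score_grid
#' @param threshold Component score threshold (default 0.5).
#' @param merge_dist Cluster merge distance, Angstrom (default 1.5).
#' @param thresholds Interaction bands ([interaction_thresholds()]).
#' @param groups Optional precomputed complementary groups.
#' @return List of [pharm_point()]s.
#' @export
predict_features <- function(structure, box, model, threshold = 0.5,
                             merge_dist = 1.5,
                             thresholds = interaction_thresholds(),
                             groups = NULL) {
  if (is.null(groups)) groups <- find_complementary_groups(structure)
  if (nrow(groups) == 0L) return(list())
  field <- score_grid(structure, box, model)
  out <- list()
  for (cls in FEATURE_CLASSES) {
    comps <- connected_components(field, cls, threshold)
    if (length(comps) == 0L) next
    top <- anchor_top_points(field, comps, groups, thresholds)
    if (nrow(top) == 0L) next
    out <- c(out, cluster_points(top, merge_dist))
  }
  out
}

#' Persist / load a score field as TSV
#'
#' Writes `x, y, z` and the six class scores as a TSV, with the latent
#' matrix in a companion `<path>.latent.tsv` file.
#'
#' @param field A `score_field`.
#' @param path Output TSV path.
#' @return `path` invisibly; `read_score_field(path)` restores the field.
#' @export
write_score_field <- function(field, path) {
  df <- data.frame(field$points, field$scores, check.names = FALSE)
  names(df)[1:3] <- c("x", "y", "z")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(field$latent, paste0(path, ".latent.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_score_field
#' @export
read_score_field <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  lat_path <- paste0(path, ".latent.tsv")
  lat <- if (file.exists(lat_path)) {
    as.matrix(utils::read.table(lat_path, sep = "\t"))
  } else NULL
  if (!is.null(lat)) dimnames(lat) <- NULL
  score_field(as.matrix(df[, 1:3]), as.matrix(df[, 4:9]), latent = lat)
}

# ---- adversarial mining --------------------------------------------------

#' Mine adversarial negatives from a score field
#'
#' Applies the physical-plausibility rules to positive predictions
#' (score > `positive_threshold`): a lattice point positive for class c is
#' mined as an all-negative training sample when it is (a) closer than the
#' class's minimum interaction distance to any protein heavy atom, or (b)
#' farther than the class's maximum interaction distance from every
#' complementary group of class c.
#'
#' @param field A `score_field`.
#' @param structure The typed [protein_structure()].
#' @param groups Complementary groups ([find_complementary_groups()]).
#' @param thresholds Interaction bands ([interaction_thresholds()]).
#' @param positive_threshold Score above which a prediction counts as
#'   positive (default 0.5).
#' @return data.frame with `x`, `y`, `z`, `cls` (the violated class) and
#'   `reason` ("too_close" / "no_partner"); labels are implicitly all
#'   zero.
#' @export
mine_from_field <- function(field, structure, groups,
                            thresholds = interaction_thresholds(),
                            positive_threshold = 0.5) {
  axyz <- protein_coords(structure)
  out <- list()
  for (cls in FEATURE_CLASSES) {
    k <- feature_class_index(cls) + 1L
    band <- thresholds[thresholds$cls == cls, ]
    pos <- which(field$scores[, k] > positive_threshold)
    if (length(pos) == 0L) next
    pts <- field$points[pos, , drop = FALSE]
    dmin_atom <- apply(cross_dist(pts, axyz), 1, min)
    ganchors <- groups[groups$complements == cls, , drop = FALSE]
    if (nrow(ganchors) > 0L) {
      gxyz <- as.matrix(ganchors[, c("x", "y", "z")])
      dmin_grp <- apply(cross_dist(pts, gxyz), 1, min)
    } else {
      dmin_grp <- rep(Inf, nrow(pts))
    }
    too_close <- dmin_atom < band$min_dist
    no_partner <- dmin_grp > band$max_dist
    sel <- which(too_close | no_partner)
    if (length(sel)) {
      out[[length(out) + 1L]] <- data.frame(
        x = pts[sel, 1], y = pts[sel, 2], z = pts[sel, 3], cls = cls,
        reason = ifelse(too_close[sel], "too_close", "no_partner"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      cls = character(0), reason = character(0)))
  }
  do.call(rbind, out)
}

#' Mine adversarial negative training samples for a binding site
#'
#' Grids the box at 0.5 Angstrom, evaluates the CNN, applies
#' [mine_from_field()], and returns voxelized all-negative training
#' samples ready for [train_cnn()].
#'
#' @inheritParams score_grid
#' @param thresholds Interaction bands.
#' @param positive_threshold Positive-prediction score threshold.
#' @return List of training samples (`vox`, `labels` = all zeros, `meta`).
#' @export
mine_adversarial <- function(structure, box, model,
                             thresholds = interaction_thresholds(),
                             positive_threshold = 0.5) {
  groups <- find_complementary_groups(structure)
  field <- score_grid(structure, box, model)
  mined <- mine_from_field(field, structure, groups, thresholds,
                           positive_threshold)
  pts <- unique(mined[, c("x", "y", "z")])
  lapply(seq_len(nrow(pts)), function(i) {
    list(vox = voxel_sparse(voxelize(structure, as.numeric(pts[i, ]))),
         labels = numeric(6),
         meta = list(origin = "adversarial_negative",
                     point = as.numeric(pts[i, ])))
  })
}
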