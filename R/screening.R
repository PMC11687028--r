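#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares optimal proper rotation and translation mapping `Q` onto
#' `P`, via SVD of the cross-covariance with determinant correction so the
#' rotation is always proper. Degenerate (collinear / coincident) inputs
#' are flagged but still aligned.
#'
#' @param P,Q n x 3 matrices of paired points (n >= 3).
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`,
#'   and `degenerate` flag. The aligned copy of `Q` is
#'   `Q %*% t(rotation) + translation` (rowwise).
#' @export
kabsch_align <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3L, ncol(Q) == 3L, nrow(P) == nrow(Q), nrow(P) >= 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(Q0) %*% P0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  Qr <- Q0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((Qr - P0)^2)))
  translation <- cp - as.numeric(R %*% cq)
  list(rotation = R, translation = translation, rmsd = rmsd,
       degenerate = degenerate)
}

#' Enumerate class-respecting point correspondences
#'
#' All injective assignments of pharmacophore points to same-class molecule
#' feature points that survive pairwise distance pruning: for every pair of
#' pharmacophore points (i, j), the intra-molecule distance of their images
#' must agree with the intra-pharmacophore distance within the summed
#' tolerance radii, `|d_ph(i,j) - d_feat(a(i), a(j))| <= r_i + r_j`.
#' Backtracking with incremental pruning; equivalent to brute-force
#' enumeration filtered by the same predicate.
#'
#' @param ph A [pharmacophore()] with >= 3 points.
#' @param feats data.frame of molecule feature points (`cls`, `x`, `y`, `z`).
#' @return List of integer vectors; entry k of an assignment is the row of
#'   `feats` matched to pharmacophore point k.
#' @export
enumerate_correspondences <- function(ph, feats) {
  if (length(ph$points) < 3L) stop("pharmacophore too small")
  np <- length(ph$points)
  if (nrow(feats) == 0L) return(list())
  pxyz <- pharm_positions(ph)
  pcls <- pharm_classes(ph)
  radii <- vapply(ph$points, function(p) p$radius, numeric(1))
  fxyz <- as.matrix(feats[, c("x", "y", "z")])
  pd <- cross_dist(pxyz, pxyz)
  fd <- cross_dist(fxyz, fxyz)
  cand <- lapply(seq_len(np), function(i) which(feats$cls == pcls[i]))
  if (any(vapply(cand, length, integer(1)) == 0L)) return(list())
  out <- list()
  assign <- integer(np)
  used <- rep(FALSE, nrow(feats))
  recurse <- function(i) {
    if (i > np) {
      out[[length(out) + 1L]] <<- assign
      return(invisible(NULL))
    }
    for (a in cand[[i]]) {
      if (used[a]) next
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        if (abs(pd[i, j] - fd[a, assign[j]]) > radii[i] + radii[j]) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        assign[i] <<- a
        used[a] <<- TRUE
        recurse(i + 1L)
        used[a] <<- FALSE
      }
    }
  }
  recurse(1L)
  out
}

#' Match one conformer against a pharmacophore
#'
#' Enumerates surviving correspondences, rigidly aligns the matched
#' molecule feature points onto the pharmacophore points (Kabsch), and
#' accepts an assignment if every post-alignment residual is within that
#' pharmacophore point's tolerance radius. Returns the accepted match with
#' the smallest RMSD, or `NULL`.
#'
#' @param ph A [pharmacophore()] (>= 3 points).
#' @param mol A [molecule_record()].
#' @param conformer_index 1-based conformer index.
#' @return List with `mol_id`, `conformer_index`, `assignment`, `rmsd`,
#'   `rotation`, `translation`, or `NULL` when no assignment is accepted.
#' @export
match_conformer <- function(ph, mol, conformer_index = 1L) {
  feats <- extract_ligand_features(mol, conformer_index)
  asg <- enumerate_correspondences(ph, feats)
  if (length(asg) == 0L) return(NULL)
  pxyz <- pharm_positions(ph)
  radii <- vapply(ph$points, function(p) p$radius, numeric(1))
  fxyz <- as.matrix(feats[, c("x", "y", "z")])
  best <- NULL
  for (a in asg) {
    fit <- kabsch_align(pxyz, fxyz[a, , drop = FALSE])
    aligned <- fxyz[a, , drop = FALSE] %*% t(fit$rotation)
    aligned <- sweep(aligned, 2, fit$translation, "+")
    resid <- sqrt(rowSums((aligned - pxyz)^2))
    if (all(resid <= radii + 1e-9)) {
      if (is.null(best) || fit$rmsd < best$rmsd) {
        best <- list(mol_id = mol$mol_id, conformer_index = conformer_index,
                     assignment = a, rmsd = fit$rmsd,
                     rotation = fit$rotation, translation = fit$translation)
      }
      if (fit$rmsd < 1e-12) break
    }
  }
  best
}

#' Screen a molecule library with a pharmacophore
#'
#' Evaluates every conformer of every molecule, applies receptor exclusion
#' (a match is dropped when any aligned heavy atom comes within
#' `clash_dist` of a receptor heavy atom), and keeps at most one match per
#' molecule (the lowest-RMSD accepted conformer).
#'
#' @param ph A [pharmacophore()] (>= 3 points).
#' @param library List of [molecule_record()] objects.
#' @param receptor Optional typed [protein_structure()] for exclusion.
#' @param clash_dist Heavy-atom clash distance in Angstrom (default 1.5).
#' @return List of match records (see [match_conformer()]).
#' @export
screen <- function(ph, library, receptor = NULL, clash_dist = 1.5) {
  if (length(ph$points) < 3L) stop("pharmacophore too small")
  rxyz <- if (!is.null(receptor)) protein_coords(receptor) else NULL
  hits <- list()
  for (mol in library) {
    best <- NULL
    for (ci in seq_along(mol$conformers)) {
      m <- match_conformer(ph, mol, ci)
      if (is.null(m)) next
      if (!is.null(rxyz)) {
        atoms <- mol$conformers[[ci]] %*% t(m$rotation)
        atoms <- sweep(atoms, 2, m$translation, "+")
        if (min(cross_dist(atoms, rxyz)) < clash_dist) next
      }
      if (is.null(best) || m$rmsd < best$rmsd) best <- m
    }
    if (!is.null(best)) hits[[length(hits) + 1L]] <- best
  }
  hits
}

#' Confusion counts from screening hits
#'
#' @param hits List of match records from [screen()].
#' @param library The screened library (labelled molecule records).
#' @return List with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(hits, library) {
  hit_ids <- vapply(hits, function(h) h$mol_id, character(1))
  labels <- vapply(library, function(m) m$label, character(1))
  ids <- vapply(library, function(m) m$mol_id, character(1))
  returned <- ids %in% hit_ids
  list(TP = sum(returned & labels == "active"),
       FP = sum(returned & labels == "decoy"),
       TN = sum(!returned & labels == "decoy"),
       FN = sum(!returned & labels == "active"))
}

#' Virtual-screening evaluation metrics
#'
#' Computes hit rate, precision, recall, F1, enrichment factor and the
#' Guner-Henry score from a confusion table:
#' \deqn{HR = (TP+FP)/N, \quad P = TP/(TP+FP), \quad R = TP/(TP+FN)}
#' \deqn{F1 = 2PR/(P+R), \quad EF = P / ((TP+FN)/N)}
#' \deqn{GH = \frac{TP(3(TP+FN)+TP+FP)}{4(TP+FN)(TP+FP)}
#'            \left[1 - \frac{FP}{TN+FN}\right]}
#' Empty-denominator conventions: `P = 0` when nothing is returned, `R = 0`
#' when there are no actives, `F1 = 0` when `P + R = 0`, `EF = 0` when the
#' library holds no actives, `GH = 0` when its yield term is undefined.
#'
#' @param counts List with `TP`, `FP`, `TN`, `FN` (all non-negative, not
#'   all zero).
#' @return List with `HR`, `P`, `R`, `F1`, `EF`, `GH` and the four counts.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  N <- TP + FP + TN + FN
  if (N == 0) stop("all-zero confusion counts")
  HR <- (TP + FP) / N
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  EF <- if (TP + FN > 0) P / ((TP + FN) / N) else 0
  GH <- if (TP + FN > 0 && TP + FP > 0 && TN + FN > 0) {
    (TP * (3 * (TP + FN) + TP + FP) / (4 * (TP + FN) * (TP + FP))) *
      (1 - FP / (TN + FN))
  } else 0
  list(HR = HR, P = P, R = R, F1 = F1, EF = EF, GH = GH,
       TP = TP, FP = FP, TN = TN, FN = FN)
}

#' F1 score of a pharmacophore on a labelled library
#'
#' Convenience wrapper: screen, count, return F1. This is the reward used
#' by the reinforcement-learning environment.
#'
#' @inheritParams screen
#' @return F1 score in `[0, 1]`.
#' @export
screen_f1 <- function(ph, library, receptor = NULL, clash_dist = 1.5) {
  counts <- confusion_counts(screen(ph, library, receptor, clash_dist),
                             library)
  compute_metrics(counts)$F1
}
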