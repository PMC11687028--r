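#' Leakage-free fold assignment by ligand similarity
#'
#' Single-linkage clusters ligands whose pairwise Tanimoto similarity
#' exceeds `cutoff` (default 0.9) and assigns whole clusters to folds,
#' greedily balancing fold sizes (largest cluster first into the smallest
#' fold). No pair with similarity above the cutoff ever straddles folds.
#'
#' @param ligands A `ChemmineR::SDFset` (atom-pair Tanimoto similarities
#'   are computed) or a precomputed symmetric similarity matrix.
#' @param cutoff Similarity threshold (default 0.9).
#' @param n_folds Number of folds (default 3).
#' @return Integer vector of fold assignments (1..n_folds), one per
#'   ligand.
#' @export
fold_split <- function(ligands, cutoff = 0.9, n_folds = 3L) {
  sim <- if (is.matrix(ligands)) {
    ligands
  } else {
    ap <- ChemmineR::sdf2ap(ligands)
    n <- length(ChemmineR::cid(ap))
    m <- diag(1, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- ChemmineR::cmp.similarity(ap[i], ap[j])
    }
    m
  }
  n <- nrow(sim)
  adj <- sim > cutoff
  diag(adj) <- FALSE
  ed <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(ed)) g <- igraph::add_edges(g, t(ed))
  memb <- igraph::components(g)$membership
  clusters <- split(seq_len(n), memb)
  if (n_folds > length(clusters)) {
    stop("n_folds exceeds the number of similarity clusters")
  }
  sizes <- vapply(clusters, length, integer(1))
  fold_of <- integer(n)
  load <- integer(n_folds)
  for (ci in order(-sizes)) {
    f <- which.min(load)
    fold_of[clusters[[ci]]] <- f
    load[f] <- load[f] + sizes[ci]
  }
  fold_of
}
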