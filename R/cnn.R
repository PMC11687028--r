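# ---- im2col 3D convolution machinery -------------------------------------
#
# Layers operate on flattened batches: X is (n, inC * D^3) with spatial
# position fastest (x, then y, then z) inside each channel block.  A
# convolution is a gather into patch matrix M of shape (n * npos, 27*inC)
# followed by one BLAS multiply with the (27*inC, outC) kernel matrix.

conv_meta <- function(D, inC, outC, stride, pad, kernel = 3L) {
  Do <- (D + 2L * pad - kernel) %/% stride + 1L
  npos <- Do^3
  ksz <- kernel^3
  opos <- expand.grid(ox = 0:(Do - 1L), oy = 0:(Do - 1L), oz = 0:(Do - 1L))
  off <- expand.grid(dx = 0:(kernel - 1L), dy = 0:(kernel - 1L),
                     dz = 0:(kernel - 1L))
  # source column in the unpadded input for each (position, patch element);
  # 0 marks zero padding
  IDX <- matrix(0L, npos, ksz * inC)
  for (ch in seq_len(inC)) {
    chbase <- (ch - 1L) * D^3
    for (k in seq_len(ksz)) {
      sx <- opos$ox * stride + off$dx[k] + 1L - pad
      sy <- opos$oy * stride + off$dy[k] + 1L - pad
      sz <- opos$oz * stride + off$dz[k] + 1L - pad
      ok <- sx >= 1L & sx <= D & sy >= 1L & sy <= D & sz >= 1L & sz <= D
      v <- integer(npos)
      v[ok] <- chbase + sx[ok] + (sy[ok] - 1L) * D + (sz[ok] - 1L) * D^2
      IDX[, (ch - 1L) * ksz + k] <- v
    }
  }
  list(D = D, Do = Do, inC = inC, outC = outC, stride = stride, pad = pad,
       kernel = kernel, npos = npos, IDX = IDX, Fin = inC * D^3)
}

conv_fwd <- function(X, W, b, meta) {
  n <- nrow(X)
  M <- .im2col(X, meta$IDX)
  Y <- M %*% W
  Y <- sweep(Y, 2, b, "+")
  dim(Y) <- c(n, meta$npos * meta$outC)
  list(Y = Y, M = M)
}

conv_bwd <- function(dY, M, W, meta, n, need_dx = TRUE) {
  dim(dY) <- c(n * meta$npos, meta$outC)
  dW <- crossprod(M, dY)
  db <- colSums(dY)
  dX <- NULL
  if (need_dx) {
    dM <- dY %*% t(W)
    dX <- .col2im(dM, meta$IDX, meta$Fin)
  }
  list(dW = dW, db = db, dX = dX)
}

# ---- CNN definition ------------------------------------------------------

#' Initialize the multilabel voxel CNN
#'
#' A 2x2x2 stride-2 patch embedding (14 -> 8 channels) followed by two
#' 3x3x3 convolution blocks (8 -> 16 -> 32 channels, the first with
#' stride 2) over the 20^3 voxel grid, a flattening dense layer,
#' a 32-unit penultimate dense layer whose activations are the latent
#' embedding, and a 6-unit sigmoid head (multilabel, one confidence per
#' feature class). He-style initialization, seeded.
#'
#' @param seed Integer RNG seed (default 0).
#' @param widths Integer vector of the three convolution widths.
#' @param dense_width Width of the post-flatten dense layer.
#' @return Object of class `qpharm_cnn` (weights + layer metadata).
#' @export
cnn_init <- function(seed = 0L, widths = c(8L, 16L, 32L), dense_width = 64L) {
  meta1 <- conv_meta(VOXEL_DIM, N_ATOM_TYPES, widths[1], 2L, 0L, kernel = 2L)
  meta2 <- conv_meta(meta1$Do, widths[1], widths[2], 2L, 1L)
  meta3 <- conv_meta(meta2$Do, widths[2], widths[3], 1L, 1L)
  # the dense head reads only the central 3x3x3 block of the last
  # feature map: interaction bands end well inside the cube, and cropping
  # keeps far-context clutter out of the classification pathway
  Do3 <- meta3$Do
  ctr <- ((Do3 - 3L) %/% 2L) + 1:3
  pos <- as.matrix(expand.grid(ctr, ctr, ctr))
  lin <- pos[, 1] + (pos[, 2] - 1L) * Do3 + (pos[, 3] - 1L) * Do3^2
  crop_idx <- as.integer(outer(lin, (seq_len(widths[3]) - 1L) * Do3^3, "+"))
  flat <- length(crop_idx)
  with_seed(seed, {
    he <- function(nin, nout) {
      matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
    }
    W <- list(
      W1 = he(8L * N_ATOM_TYPES, widths[1]),  b1 = numeric(widths[1]),
      W2 = he(27L * widths[1], widths[2]),    b2 = numeric(widths[2]),
      W3 = he(27L * widths[2], widths[3]),    b3 = numeric(widths[3]),
      Wd = he(flat, dense_width),             bd = numeric(dense_width),
      Wl = he(dense_width, 32L),              bl = numeric(32L),
      Wo = he(32L, 6L),                       bo = numeric(6L)
    )
    structure(list(params = W, meta = list(meta1, meta2, meta3),
                   crop_idx = crop_idx, flat = flat, widths = widths,
                   dense_width = dense_width),
              class = "qpharm_cnn")
  })
}

# forward over a flattened batch; returns scores, latents and (optionally)
# the intermediates needed for the backward pass
cnn_fwd_batch <- function(model, X, keep = FALSE) {
  p <- model$params
  m <- model$meta
  n <- nrow(X)
  c1 <- conv_fwd(X, p$W1, p$b1, m[[1]]); A1 <- pmax(c1$Y, 0)
  c2 <- conv_fwd(A1, p$W2, p$b2, m[[2]]); A2 <- pmax(c2$Y, 0)
  c3 <- conv_fwd(A2, p$W3, p$b3, m[[3]]); A3 <- pmax(c3$Y, 0)
  A3c <- A3[, model$crop_idx, drop = FALSE]
  Zd <- sweep(A3c %*% p$Wd, 2, p$bd, "+"); Ad <- pmax(Zd, 0)
  Zl <- sweep(Ad %*% p$Wl, 2, p$bl, "+"); Al <- pmax(Zl, 0)
  Zo <- sweep(Al %*% p$Wo, 2, p$bo, "+")
  scores <- 1 / (1 + exp(-Zo))
  out <- list(scores = scores, latent = Al, logits = Zo)
  if (keep) out$cache <- list(X = X, c1 = c1, A1 = A1, c2 = c2, A2 = A2,
                              c3 = c3, A3 = A3, A3c = A3c, Zd = Zd,
                              Ad = Ad, Zl = Zl, n = n)
  out
}

# gradient of the masked, positively-weighted multilabel BCE loss for
# one batch; posw is the per-class weight on positive terms
cnn_bwd_batch <- function(model, fw, Y, mask, posw = rep(1, 6)) {
  p <- model$params
  m <- model$meta
  cc <- fw$cache
  n <- cc$n
  S <- fw$scores
  dZo <- S * (1 - Y) - sweep(Y * (1 - S), 2, posw, "*")
  dZo <- sweep(dZo, 2, mask, "*") / (n * max(sum(mask), 1))
  g <- list()
  g$Wo <- crossprod(fw$latent, dZo); g$bo <- colSums(dZo)
  dAl <- dZo %*% t(p$Wo); dZl <- dAl * (cc$Zl > 0)
  g$Wl <- crossprod(cc$Ad, dZl); g$bl <- colSums(dZl)
  dAd <- dZl %*% t(p$Wl); dZd <- dAd * (cc$Zd > 0)
  g$Wd <- crossprod(cc$A3c, dZd); g$bd <- colSums(dZd)
  dA3 <- matrix(0, n, ncol(cc$A3))
  dA3[, model$crop_idx] <- dZd %*% t(p$Wd)
  dY3 <- dA3 * (cc$c3$Y > 0)
  b3 <- conv_bwd(dY3, cc$c3$M, p$W3, m[[3]], n, TRUE)
  g$W3 <- b3$dW; g$b3 <- b3$db
  dY2 <- b3$dX * (cc$c2$Y > 0)
  b2 <- conv_bwd(dY2, cc$c2$M, p$W2, m[[2]], n, TRUE)
  g$W2 <- b2$dW; g$b2 <- b2$db
  dY1 <- b2$dX * (cc$c1$Y > 0)
  b1 <- conv_bwd(dY1, cc$c1$M, p$W1, m[[1]], n, FALSE)
  g$W1 <- b1$dW; g$b1 <- b1$db
  g
}

#' Apply the CNN to one voxel tensor
#'
#' Deterministic given the weights: per-class sigmoid confidences (a
#' multilabel head, not a softmax) plus the 32-length latent embedding
#' from the penultimate hidden layer.
#'
#' @param grid A `voxel_tensor` from [voxelize()], or a flattened numeric
#'   vector of length `14 * 8000`.
#' @param model A `qpharm_cnn`.
#' @return List with `scores` (named length-6, in `[0,1]`) and `latent`
#'   (length 32).
#' @export
cnn_forward <- function(grid, model) {
  x <- if (inherits(grid, "voxel_tensor")) voxel_flat(grid) else as.numeric(grid)
  if (length(x) != VOXEL_DIM^3 * N_ATOM_TYPES) stop("grid shape mismatch")
  fw <- cnn_fwd_batch(model, matrix(x, nrow = 1))
  list(scores = stats::setNames(as.numeric(fw$scores), FEATURE_CLASSES),
       latent = as.numeric(fw$latent))
}

#' Apply the CNN to many samples at once
#'
#' @param model A `qpharm_cnn`.
#' @param samples List of sparse voxel samples (from the dataset
#'   generator) or an already-densified matrix.
#' @param chunk Samples per forward chunk (memory control).
#' @return List with `scores` (n x 6) and `latent` (n x 32) matrices.
#' @export
cnn_predict <- function(model, samples, chunk = 64L) {
  from_matrix <- is.matrix(samples)
  n <- if (from_matrix) nrow(samples) else length(samples)
  scores <- matrix(NA_real_, n, 6L)
  latent <- matrix(NA_real_, n, 32L)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    # densify one chunk at a time: the full dense batch would not fit in
    # memory for lattice-sized sample lists
    X <- if (from_matrix) samples[i:j, , drop = FALSE]
         else voxel_batch(samples[i:j])
    fw <- cnn_fwd_batch(model, X)
    scores[i:j, ] <- fw$scores
    latent[i:j, ] <- fw$latent
    i <- j + 1L
  }
  colnames(scores) <- FEATURE_CLASSES
  list(scores = scores, latent = latent)
}

# Adam optimizer state/update over a named list of parameter arrays
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the multilabel voxel CNN
#'
#' Minimizes per-class binary cross-entropy (multi-hot labels decompose
#' per class) with Adam. Classes that have no positive example in the
#' training samples are skipped with a warning. Defaults follow the
#' full-scale recipe (256 epochs, batch 256, learning rate 1e-5); all are
#' overridable for desk-scale runs. When a held-out set is supplied the
#' checkpoint with the best mean per-class ROC-AUC is returned.
#'
#' @param samples List of training samples, each `list(vox = list(idx,
#'   val), labels = numeric(6))`.
#' @param model A `qpharm_cnn` to start from, or `NULL` to initialize.
#' @param epochs,batch,lr Optimization controls.
#' @param holdout Optional list of samples for checkpoint selection.
#' @param pos_weight Per-class weight on positive terms of the loss:
#'   a numeric vector of length 6, `"balanced"` (negative/positive count
#'   ratio per class, capped at 10; the default — the synthetic datasets
#'   are strongly imbalanced), or `NULL` for unweighted.
#' @param seed RNG seed for shuffling (default 0).
#' @param chunk Samples per gradient sub-chunk (memory control).
#' @param verbose Print per-epoch loss.
#' @return The trained `qpharm_cnn`, with a `history` element (per-epoch
#'   mean training loss) attached.
#' @export
train_cnn <- function(samples, model = NULL, epochs = 256L, batch = 256L,
                      lr = 1e-5, holdout = NULL, pos_weight = "balanced",
                      seed = 0L, chunk = 32L, verbose = FALSE) {
  if (length(samples) == 0L) stop("empty sample list")
  if (is.null(model)) model <- cnn_init(seed = seed)
  Y <- do.call(rbind, lapply(samples, function(s) s$labels))
  mask <- as.numeric(colSums(Y) > 0)
  if (any(mask == 0)) {
    warning("classes without positives skipped: ",
            paste(FEATURE_CLASSES[mask == 0], collapse = ", "))
  }
  posw <- if (is.null(pos_weight)) {
    rep(1, 6)
  } else if (identical(pos_weight, "balanced")) {
    pmin(10, colSums(Y == 0) / pmax(colSums(Y), 1))
  } else {
    stopifnot(length(pos_weight) == 6L)
    as.numeric(pos_weight)
  }
  vox <- lapply(samples, function(s) s$vox)
  n <- length(samples)
  state <- adam_init(model$params)
  history <- numeric(epochs)
  best <- list(auc = -Inf, params = model$params)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = batch)) {
        bi <- ord[start:min(start + batch - 1L, n)]
        grads <- NULL
        bl <- 0
        for (cs in seq(1L, length(bi), by = chunk)) {
          ci <- bi[cs:min(cs + chunk - 1L, length(bi))]
          X <- voxel_batch(vox[ci])
          Yb <- Y[ci, , drop = FALSE]
          fw <- cnn_fwd_batch(model, X, keep = TRUE)
          z <- fw$logits
          base <- log1p(exp(-abs(z))) + pmax(z, 0)
          lmat <- (1 - Yb) * base + sweep(Yb * (base - z), 2, posw, "*")
          bl <- bl + sum(sweep(lmat, 2, mask, "*")) /
            (length(bi) * max(sum(mask), 1))
          g <- cnn_bwd_batch(model, fw, Yb, mask, posw)
          w <- length(ci) / length(bi)
          if (is.null(grads)) {
            grads <- lapply(g, function(x) x * w)
          } else {
            for (k in names(g)) grads[[k]] <- grads[[k]] + g[[k]] * w
          }
        }
        upd <- adam_step(model$params, grads, state, lr)
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + bl
        nb <- nb + 1L
      }
      history[ep] <- ep_loss / nb
      if (!is.null(holdout)) {
        auc <- mean(cnn_auc(model, holdout), na.rm = TRUE)
        if (auc > best$auc) best <- list(auc = auc, params = model$params)
      }
      if (verbose) message(sprintf("epoch %d loss %.4f", ep, history[ep]))
    }
  })
  if (!is.null(holdout)) model$params <- best$params
  model$history <- history
  model
}

#' Per-class ROC-AUC of the CNN on a labelled sample set
#'
#' One-vs-rest ROC-AUC per feature class; `NA` for classes whose labels
#' are constant in the set.
#'
#' @param model A `qpharm_cnn`.
#' @param samples Labelled samples (as in [train_cnn()]).
#' @return Named numeric vector over [FEATURE_CLASSES].
#' @export
cnn_auc <- function(model, samples) {
  Y <- do.call(rbind, lapply(samples, function(s) s$labels))
  pred <- cnn_predict(model, lapply(samples, function(s) s$vox))$scores
  vapply(seq_len(6L), function(k) {
    y <- Y[, k]
    if (length(unique(y)) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(y, pred[, k], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1)) |> stats::setNames(FEATURE_CLASSES)
}
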