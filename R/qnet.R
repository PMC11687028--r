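# ---- geometric Q-network -------------------------------------------------
#
# Heterogeneous message-passing network over protein-pharmacophore graphs.
# Node hidden states are SE(3)-invariant scalar channels; geometry enters
# through (a) radial Gaussian embeddings of edge lengths and (b) norms of
# spherical-harmonic-weighted message aggregates of order l = 1 and l = 2.
# Because every geometric quantity reaching the scalar pathway is an
# invariant (distances; Euclidean norms of quantities that rotate under an
# orthogonal representation), the scalar output is exactly invariant to
# global rotations and translations, and node order cannot affect the
# result (aggregation is by mean).

#' Q-network configuration
#'
#' @param ns Scalar channels per layer (default 32).
#' @param nv Higher-order channels per spherical-harmonic order (l = 1 and
#'   l = 2; default 8).
#' @param k Message-passing layers (default 6).
#' @param n_radial Radial Gaussian basis size (default 16).
#' @param cutoff_ff,cutoff_fp Radial basis cutoffs per edge type,
#'   matching the graph distance thresholds (defaults 12 / 11).
#' @return List of class `qnet_config` (l_max is fixed at 2).
#' @export
qnet_config <- function(ns = 32L, nv = 8L, k = 6L, n_radial = 16L,
                        cutoff_ff = 12, cutoff_fp = 11) {
  stopifnot(ns > 0, nv > 0, k > 0, n_radial > 1)
  structure(list(ns = ns, nv = nv, k = k, n_radial = n_radial,
                 cutoff_ff = cutoff_ff, cutoff_fp = cutoff_fp, l_max = 2L),
            class = "qnet_config")
}

#' Initialize Q-network parameters
#'
#' Separate embedding weights per node type (feature latents, protein
#' one-hot atom types), separate message weights per edge type
#' (feature-feature, protein-to-feature, feature-to-protein) per layer, a
#' shared node-update transform per layer, and a dense head producing the
#' scalar Q-value.
#'
#' @param cfg A [qnet_config()].
#' @param seed Integer seed (default 0).
#' @return List of class `qnet_params`.
#' @export
qnet_init <- function(cfg = qnet_config(), seed = 0L) {
  ns <- cfg$ns; nv <- cfg$nv
  msg_in <- cfg$n_radial + 2L * ns
  msg_out <- ns + 2L * nv
  with_seed(seed, {
    he <- function(nin, nout) {
      matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
    }
    p <- list(Wf = he(32L, ns), bf = numeric(ns),
              Wp = he(N_ATOM_TYPES, ns), bp = numeric(ns))
    for (l in seq_len(cfg$k)) {
      for (et in c("ff", "fp", "pf")) {
        p[[paste0("W1_", l, "_", et)]] <- he(msg_in, msg_out)
        p[[paste0("b1_", l, "_", et)]] <- numeric(msg_out)
      }
      p[[paste0("Wu_", l)]] <- he(2L * ns + 2L * nv, ns)
      p[[paste0("bu_", l)]] <- numeric(ns)
    }
    p$Wh <- he(ns, ns); p$bh <- numeric(ns)
    p$wo <- he(ns, 1L); p$bo <- 0
    structure(list(params = p, cfg = cfg), class = "qnet_params")
  })
}

# radial Gaussian basis: centres evenly spaced on [0, cutoff], width =
# spacing
.rbf <- function(d, cutoff, n) {
  mu <- seq(0, cutoff, length.out = n)
  w <- mu[2] - mu[1]
  exp(-outer(d, mu, "-")^2 / (2 * w^2))
}

# real spherical harmonics of the unit vector rows of U (unnormalized
# consistently; each order transforms under an orthogonal representation,
# so channel norms are rotation invariant)
.sh1 <- function(U) U
.sh2 <- function(U) {
  x <- U[, 1]; y <- U[, 2]; z <- U[, 3]
  s3 <- sqrt(3)
  cbind(s3 * x * y, s3 * y * z, (3 * z^2 - 1) / 2, s3 * x * z,
        s3 / 2 * (x^2 - y^2))
}

# edge geometry for one graph: directed edges grouped by type, with
# per-type mean-aggregation matrices (computed once at graph construction)
graph_geometry <- function(graph) {
  nf <- length(graph$ids)
  np <- nrow(graph$pxyz)
  n <- nf + np
  xyz <- rbind(graph$fxyz, graph$pxyz)
  et <- list()
  if (nrow(graph$eff)) {
    e <- rbind(graph$eff, graph$eff[, 2:1, drop = FALSE])
    et$ff <- list(src = e[, 1], tgt = e[, 2], which = "ff")
  }
  if (!is.null(graph$efp) && nrow(graph$efp)) {
    fi <- graph$efp[, 1]; pj <- graph$efp[, 2] + nf
    et$fp <- list(src = pj, tgt = fi, which = "fp")  # protein -> feature
    et$pf <- list(src = fi, tgt = pj, which = "pf")  # feature -> protein
  }
  for (nm in names(et)) {
    e <- et[[nm]]
    v <- xyz[e$src, , drop = FALSE] - xyz[e$tgt, , drop = FALSE]
    d <- sqrt(rowSums(v^2))
    u <- v / pmax(d, 1e-9)
    et[[nm]]$d <- d
    et[[nm]]$Y1 <- .sh1(u)
    et[[nm]]$Y2 <- .sh2(u)
    # dense mean-aggregation operator: AGG[t, e] = 1/deg(t)
    deg <- tabulate(e$tgt, nbins = n)
    AGG <- matrix(0, n, length(e$tgt))
    AGG[cbind(e$tgt, seq_along(e$tgt))] <- 1 / pmax(deg[e$tgt], 1)
    et[[nm]]$AGG <- AGG
  }
  list(types = et, nf = nf, np = np, n = n)
}

.qnet_edges <- function(graph, cfg) {
  ed <- if (!is.null(graph$geo)) graph$geo else graph_geometry(graph)
  for (nm in names(ed$types)) {
    cut <- if (nm == "ff") cfg$cutoff_ff else cfg$cutoff_fp
    ed$types[[nm]]$rbf <- .rbf(ed$types[[nm]]$d, cut, cfg$n_radial)
  }
  ed
}

# forward pass; keep = TRUE retains intermediates for the backward pass
qnet_fwd <- function(model, graph, keep = FALSE) {
  cfg <- model$cfg; p <- model$params
  ns <- cfg$ns; nv <- cfg$nv
  ed <- .qnet_edges(graph, cfg)
  n <- ed$n; nf <- ed$nf
  H0f <- sweep(graph$latent %*% p$Wf, 2, p$bf, "+")
  Hp0 <- if (ed$np > 0L) {
    onehot <- matrix(0, ed$np, N_ATOM_TYPES)
    onehot[cbind(seq_len(ed$np), graph$ptype)] <- 1
    sweep(onehot %*% p$Wp, 2, p$bp, "+")
  } else matrix(0, 0, ns)
  H <- pmax(rbind(H0f, Hp0), 0)
  Z0 <- rbind(H0f, Hp0)
  layers <- list()
  for (l in seq_len(cfg$k)) {
    S <- matrix(0, n, ns)
    N1 <- matrix(0, n, nv); N2 <- matrix(0, n, nv)
    V1 <- array(0, c(n, nv, 3)); V2 <- array(0, c(n, nv, 5))
    lt <- list()
    for (nm in names(ed$types)) {
      e <- ed$types[[nm]]
      E <- cbind(e$rbf, H[e$src, , drop = FALSE], H[e$tgt, , drop = FALSE])
      Z1 <- sweep(E %*% p[[paste0("W1_", l, "_", nm)]], 2,
                  p[[paste0("b1_", l, "_", nm)]], "+")
      M <- pmax(Z1, 0)
      Ms <- M[, seq_len(ns), drop = FALSE]
      Mv1 <- M[, ns + seq_len(nv), drop = FALSE]
      Mv2 <- M[, ns + nv + seq_len(nv), drop = FALSE]
      S <- S + e$AGG %*% Ms
      for (c3 in 1:3) {
        V1[, , c3] <- V1[, , c3] + e$AGG %*% (Mv1 * e$Y1[, c3])
      }
      for (c5 in 1:5) {
        V2[, , c5] <- V2[, , c5] + e$AGG %*% (Mv2 * e$Y2[, c5])
      }
      lt[[nm]] <- list(E = E, Z1 = Z1, M = M)
    }
    eps2 <- 1e-8
    N1 <- sqrt(V1[, , 1]^2 + V1[, , 2]^2 + V1[, , 3]^2 + eps2)
    N2 <- sqrt(V2[, , 1]^2 + V2[, , 2]^2 + V2[, , 3]^2 + V2[, , 4]^2 +
                 V2[, , 5]^2 + eps2)
    dim(N1) <- c(n, nv); dim(N2) <- c(n, nv)
    inp <- cbind(H, S, N1, N2)
    Zu <- sweep(inp %*% p[[paste0("Wu_", l)]], 2, p[[paste0("bu_", l)]], "+")
    Hn <- H + pmax(Zu, 0)
    layers[[l]] <- list(H = H, S = S, V1 = V1, V2 = V2, N1 = N1, N2 = N2,
                        inp = inp, Zu = Zu, types = lt)
    H <- Hn
  }
  g <- colMeans(H)
  Zh <- as.numeric(g %*% p$Wh) + p$bh
  Ah <- pmax(Zh, 0)
  q <- sum(Ah * p$wo) + p$bo
  out <- list(q = q)
  if (keep) out$cache <- list(ed = ed, Z0 = Z0, layers = layers, Hfinal = H,
                              g = g, Zh = Zh, Ah = Ah, graph = graph)
  out
}

# rowsum with guaranteed n rows (groups may be missing)
rowsum_pad <- function(x, group, n) {
  out <- matrix(0, n, ncol(x))
  rs <- rowsum(x, group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# backward pass: gradients of q w.r.t. all parameters
qnet_bwd <- function(model, cache) {
  cfg <- model$cfg; p <- model$params
  ns <- cfg$ns; nv <- cfg$nv
  ed <- cache$ed; n <- ed$n
  g <- list()
  dAh <- as.numeric(p$wo)
  g$wo <- matrix(cache$Ah, ncol = 1); g$bo <- 1
  dZh <- dAh * (cache$Zh > 0)
  g$Wh <- outer(cache$g, dZh); g$bh <- dZh
  dg <- as.numeric(p$Wh %*% dZh)
  dH <- matrix(rep(dg / n, each = n), n, ns)
  for (l in rev(seq_len(cfg$k))) {
    ly <- cache$layers[[l]]
    Wu <- p[[paste0("Wu_", l)]]
    dZu <- (dH * (ly$Zu > 0))
    g[[paste0("Wu_", l)]] <- crossprod(ly$inp, dZu)
    g[[paste0("bu_", l)]] <- colSums(dZu)
    dinp <- dZu %*% t(Wu)
    dH_res <- dH  # residual path
    dHl <- dH_res + dinp[, seq_len(ns), drop = FALSE]
    dS <- dinp[, ns + seq_len(ns), drop = FALSE]
    dN1 <- dinp[, 2 * ns + seq_len(nv), drop = FALSE]
    dN2 <- dinp[, 2 * ns + nv + seq_len(nv), drop = FALSE]
    dV1 <- array(0, c(n, nv, 3)); dV2 <- array(0, c(n, nv, 5))
    for (c3 in 1:3) dV1[, , c3] <- dN1 * ly$V1[, , c3] / ly$N1
    for (c5 in 1:5) dV2[, , c5] <- dN2 * ly$V2[, , c5] / ly$N2
    for (nm in names(ed$types)) {
      e <- ed$types[[nm]]
      lt <- ly$types[[nm]]
      tAGG <- t(e$AGG)
      dM <- matrix(0, nrow(lt$M), ns + 2L * nv)
      dM[, seq_len(ns)] <- tAGG %*% dS
      dmv1 <- matrix(0, nrow(lt$M), nv)
      for (c3 in 1:3) {
        s <- dV1[, , c3]; dim(s) <- c(n, nv)
        dmv1 <- dmv1 + (tAGG %*% s) * e$Y1[, c3]
      }
      dM[, ns + seq_len(nv)] <- dmv1
      dmv2 <- matrix(0, nrow(lt$M), nv)
      for (c5 in 1:5) {
        s <- dV2[, , c5]; dim(s) <- c(n, nv)
        dmv2 <- dmv2 + (tAGG %*% s) * e$Y2[, c5]
      }
      dM[, ns + nv + seq_len(nv)] <- dmv2
      dZ1 <- dM * (lt$Z1 > 0)
      W1 <- p[[paste0("W1_", l, "_", nm)]]
      g[[paste0("W1_", l, "_", nm)]] <- crossprod(lt$E, dZ1)
      g[[paste0("b1_", l, "_", nm)]] <- colSums(dZ1)
      dE <- dZ1 %*% t(W1)
      dHsrc <- dE[, cfg$n_radial + seq_len(ns), drop = FALSE]
      dHtgt <- dE[, cfg$n_radial + ns + seq_len(ns), drop = FALSE]
      dHl <- dHl + rowsum_pad(dHsrc, e$src, n) + rowsum_pad(dHtgt, e$tgt, n)
    }
    dH <- dHl
  }
  dZ0 <- dH * (cache$Z0 > 0)
  nf <- ed$nf
  dZf <- dZ0[seq_len(nf), , drop = FALSE]
  g$Wf <- crossprod(cache$graph$latent, dZf); g$bf <- colSums(dZf)
  if (ed$np > 0L) {
    dZp <- dZ0[nf + seq_len(ed$np), , drop = FALSE]
    onehot <- matrix(0, ed$np, N_ATOM_TYPES)
    onehot[cbind(seq_len(ed$np), cache$graph$ptype)] <- 1
    g$Wp <- crossprod(onehot, dZp); g$bp <- colSums(dZp)
  } else {
    g$Wp <- p$Wp * 0; g$bp <- p$bp * 0
  }
  # parameters untouched by this graph (absent edge types) get zero grads
  for (k in names(p)) if (is.null(g[[k]])) g[[k]] <- p[[k]] * 0
  g
}

#' Q-value of a protein-pharmacophore graph
#'
#' Scalar expected-return estimate. Invariant to global rotations and
#' translations of the graph and to node order, by construction.
#'
#' @param graph A `pharm_graph` (non-empty).
#' @param model A `qnet_params`.
#' @return Numeric scalar.
#' @export
q_value <- function(graph, model) {
  stopifnot(inherits(model, "qnet_params"), length(graph$ids) >= 1L)
  qnet_fwd(model, graph)$q
}

#' Q-values of several graphs
#'
#' Elementwise equal to [q_value()] on each graph.
#'
#' @param graphs List of `pharm_graph`s.
#' @param model A `qnet_params`.
#' @return Numeric vector.
#' @export
batch_q <- function(graphs, model) {
  vapply(graphs, function(g) q_value(g, model), numeric(1))
}
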