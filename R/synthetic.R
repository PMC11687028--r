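# Synthetic fixtures: toy pockets built from pseudo-residue motifs, planted
# feature sets with a unique F1-optimal subset, labelled point-set molecule
# libraries, and voxel datasets.  Everything is deterministic under `seed`.

# class -> protein-side motif kind that anchors it
.motif_kind <- c(Aromatic = "ring", HydrogenAcceptor = "amine_donor",
                 HydrogenDonor = "carbonyl_acceptor", Hydrophobic = "greasy",
                 NegativeIon = "ammonium", PositiveIon = "carboxylate")

# orthonormal basis completing unit vector u
.frame <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# atoms (data.frame rows) of one motif anchored at `anchor`, opening toward
# direction `u` (unit, pointing at the pocket interior); `resid` tags the
# motif so charged groups are detected per instance
.motif_atoms <- function(kind, anchor, u, resid, azimuth = 0) {
  fr <- .frame(u)
  e1 <- cos(azimuth) * fr$e1 + sin(azimuth) * fr$e2
  e2 <- -sin(azimuth) * fr$e1 + cos(azimuth) * fr$e2
  row <- function(el, p, ty, rn, an) {
    data.frame(element = el, x = p[1], y = p[2], z = p[3], atom_type = ty,
               resname = rn, resid = resid, atomname = an,
               stringsAsFactors = FALSE)
  }
  # back atoms sit straight behind the anchor along the axis: every motif
  # then determines its interaction axis from its own geometry, so the
  # axis-localized feature-existence rule is learnable from the voxels
  back <- function(d) anchor - d * u
  switch(kind,
    amine_donor = rbind(
      row("N", anchor, 7L, "AMN", "N1"),
      row("C", back(1.47), 2L, "AMN", "C1")),
    carbonyl_acceptor = rbind(
      row("O", anchor, 8L, "CRB", "O1"),
      row("C", back(1.23), 2L, "CRB", "C1")),
    ring = {
      # stem carbon behind the centroid disambiguates the normal's sign
      ang <- (0:5) * pi / 3
      rbind(
        do.call(rbind, lapply(seq_along(ang), function(k) {
          p <- anchor + 1.39 * (cos(ang[k]) * e1 + sin(ang[k]) * e2)
          row("C", p, 3L, "ARO", paste0("C", k))
        })),
        row("C", back(1.5), 2L, "ARO", "CB"))
    },
    greasy = {
      # three-carbon face toward the pocket plus one carbon behind: the
      # exposed-face direction is the axis
      ang <- c(0, 2, 4) * pi / 3
      rbind(
        do.call(rbind, lapply(seq_along(ang), function(k) {
          p <- anchor + 0.88 * (cos(ang[k]) * e1 + sin(ang[k]) * e2)
          row("C", p, 1L, "GRS", paste0("C", k))
        })),
        row("C", back(1.2), 1L, "GRS", "C4"))
    },
    ammonium = rbind(
      row("N", anchor, 7L, "LYS", "NZ"),
      row("C", back(1.49), 2L, "LYS", "CE"),
      row("C", back(2.6), 2L, "LYS", "CD")),
    carboxylate = rbind(
      row("O", anchor + 1.10 * e1, 8L, "ASP", "OD1"),
      row("O", anchor - 1.10 * e1, 8L, "ASP", "OD2"),
      row("C", anchor - 1.00 * u, 2L, "ASP", "CG")),
    stop("unknown motif kind: ", kind))
}

# ligand feature classes each motif supports, with the motif's preferred
# interaction distance (Angstrom, inside the class band). The charged
# motifs support two classes at the same distance — an ammonium is both a
# salt-bridge partner for ligand negative ions and a donor for ligand
# acceptors — which is the class-overlap phenomenon multilabel training
# handles.
.motif_roles <- function(kind) {
  switch(kind,
    amine_donor = data.frame(cls = "HydrogenAcceptor", dstar = 2.5),
    carbonyl_acceptor = data.frame(cls = "HydrogenDonor", dstar = 2.5),
    ring = data.frame(cls = "Aromatic", dstar = 3.5),
    greasy = data.frame(cls = "Hydrophobic", dstar = 3.25),
    ammonium = data.frame(cls = c("NegativeIon", "HydrogenAcceptor"),
                          dstar = 2.9),
    carboxylate = data.frame(cls = c("PositiveIon", "HydrogenDonor"),
                             dstar = 2.9))
}

# ground-truth feature-existence rule: a feature of class `cls` exists at
# query point q iff some group with a role for `cls` has
# |dist(q, anchor) - dstar| <= 0.3 and angle(q - anchor, axis) <= 8.6
# degrees. The window is small enough in every direction (corner within
# ~0.7 Angstrom of its centre at the largest dstar) that planted truth is
# recoverable to 1 Angstrom even when the learned score surface is flat
# across the window and smeared by half a lattice step.
.role_labels <- function(roles, q) {
  labels <- numeric(6)
  for (r in roles) {
    v <- q - r$anchor
    d <- sqrt(sum(v^2))
    if (d < 1e-6) next
    cosang <- sum(v * r$axis) / d
    for (j in seq_len(nrow(r$tab))) {
      if (abs(d - r$tab$dstar[j]) <= 0.3 && cosang >= cos(0.15)) {
        labels[feature_class_index(r$tab$cls[j]) + 1L] <- 1
      }
    }
  }
  labels
}

#' Generate a synthetic binding pocket
#'
#' Builds a pseudo-protein pocket: typed pseudo-residue motifs (aromatic
#' ring, amine donor, carbonyl acceptor, hydrophobic cluster, ammonium,
#' carboxylate) arranged on a spherical shell around the origin with their
#' interaction faces pointing inward, plus inert filler atoms for voxel
#' context. Deterministic under `seed`; every requested group is
#' re-detected by [find_complementary_groups()].
#'
#' @param seed Integer seed.
#' @param n_groups Named integer vector: number of groups per ligand
#'   feature class the pocket should anchor (names from
#'   [FEATURE_CLASSES]). Default one of each.
#' @param radius Shell radius in Angstrom (default 6.5).
#' @param n_filler Number of inert filler atoms (default 30).
#' @return List with `structure` (typed [protein_structure()]) and
#'   `groups` (data.frame `complements`, `x`, `y`, `z` of planted anchors,
#'   ground truth for round-trip tests).
#' @export
make_pocket <- function(seed = 0L,
                        n_groups = stats::setNames(rep(1L, 6), FEATURE_CLASSES),
                        radius = 6.5, n_filler = 30L) {
  stopifnot(all(names(n_groups) %in% FEATURE_CLASSES), all(n_groups >= 0L))
  with_seed(seed, {
    total <- sum(n_groups)
    # anchor directions with minimum angular separation (rejection)
    dirs <- list()
    tries <- 0L
    while (length(dirs) < total && tries < 20000L) {
      tries <- tries + 1L
      v <- stats::rnorm(3)
      v <- v / sqrt(sum(v^2))
      if (v[3] > 0.55) next  # leave the pocket mouth open
      ok <- all(vapply(dirs, function(d) sum(d * v) < cos(40 * pi / 180),
                       logical(1)))
      if (ok) dirs[[length(dirs) + 1L]] <- v
    }
    if (length(dirs) < total) stop("could not place pocket groups")
    classes <- rep(names(n_groups), times = n_groups)
    atoms <- list(); ganchors <- list()
    for (g in seq_len(total)) {
      cls <- classes[g]
      kind <- .motif_kind[[cls]]
      anchor <- radius * dirs[[g]]
      u <- -dirs[[g]]
      az <- stats::runif(1, 0, 2 * pi)
      atoms[[g]] <- .motif_atoms(kind, anchor, u, resid = paste0("G", g),
                                 azimuth = az)
      ganchors[[g]] <- data.frame(complements = cls, x = anchor[1],
                                  y = anchor[2], z = anchor[3],
                                  kind = kind, ax = u[1], ay = u[2],
                                  az = u[3], stringsAsFactors = FALSE)
    }
    # inert filler (aliphatic non-hydrophobe carbons anchor nothing)
    fill <- list()
    nf <- 0L; tries <- 0L
    gdir <- do.call(rbind, dirs)
    while (nf < n_filler && tries < 20000L) {
      tries <- tries + 1L
      v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
      if (v[3] > 0.55) next
      if (total > 0L && max(gdir %*% v) > cos(18 * pi / 180)) next
      nf <- nf + 1L
      p <- v * radius * stats::runif(1, 1.02, 1.25)
      fill[[nf]] <- data.frame(element = "C", x = p[1], y = p[2], z = p[3],
                               atom_type = 2L, resname = "FIL",
                               resid = paste0("F", nf), atomname = "C1",
                               stringsAsFactors = FALSE)
    }
    structure_df <- do.call(rbind, c(atoms, fill))
    groups <- do.call(rbind, ganchors)
    # hydrophobic anchors live at the cluster centroid, not the placement
    # point: report the centroid as ground truth
    for (g in which(groups$complements == "Hydrophobic")) {
      sub <- atoms[[g]]
      groups[g, c("x", "y", "z")] <- colMeans(sub[, c("x", "y", "z")])
    }
    list(structure = protein_structure(structure_df,
                                       id = sprintf("synthetic-pocket-%d", seed)),
         groups = groups)
  })
}

#' Plant candidate pharmacophore features in a synthetic pocket
#'
#' Places one candidate feature per pocket group, at the class's preferred
#' anchor distance (band centre +/- 0.3 Angstrom) along the inward
#' direction, and designates a random subset of size 3-5 as the optimal
#' pharmacophore.
#'
#' @param pocket Output of [make_pocket()].
#' @param n_features Number of features to plant (<= number of groups).
#' @param opt_size Size of the optimal subset (3, 4 or 5); `NULL` samples
#'   one.
#' @param seed Integer seed.
#' @return List with `planted` (data.frame `cls`, `x`, `y`, `z`,
#'   `group`) and `optimal_subset` (integer indices into `planted`).
#' @export
plant_features <- function(pocket, n_features = nrow(pocket$groups),
                           opt_size = NULL, seed = 0L) {
  gr <- pocket$groups
  if (n_features > nrow(gr)) stop("not enough pocket groups")
  with_seed(seed + 17L, {
    pick <- sample.int(nrow(gr), n_features)
    rows <- lapply(pick, function(g) {
      anchor <- as.numeric(gr[g, c("x", "y", "z")])
      u <- as.numeric(gr[g, c("ax", "ay", "az")])
      tab <- .motif_roles(gr$kind[g])
      d <- tab$dstar[tab$cls == gr$complements[g]] +
        stats::runif(1, -0.15, 0.15)
      p <- anchor + d * u
      data.frame(cls = gr$complements[g], x = p[1], y = p[2], z = p[3],
                 group = g, stringsAsFactors = FALSE)
    })
    planted <- do.call(rbind, rows)
    if (is.null(opt_size)) {
      opt_size <- sample(3:min(5L, n_features), 1)
    }
    stopifnot(opt_size >= 3L, opt_size <= min(5L, n_features))
    optimal <- sort(sample.int(n_features, opt_size))
    list(planted = planted, optimal_subset = optimal)
  })
}

# point-set "molecule": the synthetic library carries typed feature points
# directly (atoms = the feature positions), isolating matching and RL logic
# from chemistry
.point_molecule <- function(id, fp, label) {
  xyz <- as.matrix(fp[, c("x", "y", "z")])
  rownames(xyz) <- NULL
  molecule_record(id, list(xyz), list(fp), label = label)
}

# random rigid motion applied to a feature-point data.frame
.rigid_jumble <- function(fp) {
  th <- stats::runif(3, 0, 2 * pi)
  Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0,
                 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0,
                 -sin(th[2]), 0, cos(th[2])), 3, byrow = TRUE)
  R <- Rz %*% Ry
  t <- stats::runif(3, -20, 20)
  xyz <- as.matrix(fp[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  fp[, c("x", "y", "z")] <- xyz
  fp
}

# uniform point in a ball of radius r
.ball <- function(r) {
  repeat {
    v <- stats::runif(3, -r, r)
    if (sum(v^2) <= r^2) return(v)
  }
}

#' Build a labelled synthetic screening library
#'
#' Actives contain feature points congruent (within `jitter`) to the
#' optimal planted subset plus distractor features; decoys are copies with
#' one optimal point displaced far outside the tolerance radius. The
#' construction is verified by actually screening: the optimal subset must
#' retrieve every active and no decoy, and every other planted subset of
#' size 3-5 must score F1 at most `gap`. Failing draws are rejected and
#' regenerated (bounded retries).
#'
#' @param planted,optimal_subset Output of [plant_features()].
#' @param n_actives,n_decoys Library composition (defaults 8 / 48).
#' @param jitter Per-point placement noise for actives, Angstrom (< 1, the
#'   tolerance radius); default 0.3.
#' @param n_distractor Extra random far-away features per molecule.
#' @param gap Maximum allowed F1 for non-optimal subsets (default 0.6).
#' @param seed Integer seed.
#' @param max_tries Regeneration attempts before giving up.
#' @return List of [molecule_record()]; attribute `verified` = TRUE.
#' @export
make_library <- function(planted, optimal_subset, n_actives = 8L,
                         n_decoys = 48L, jitter = 0.3, n_distractor = 2L,
                         gap = 0.6, seed = 0L, max_tries = 10L) {
  stopifnot(jitter < 1)
  opt <- planted[optimal_subset, , drop = FALSE]
  k <- nrow(opt)
  pxyz <- as.matrix(planted[, c("x", "y", "z")])

  gen_one <- function(base, displace_idx = NULL) {
    fp <- base
    xyz <- as.matrix(fp[, c("x", "y", "z")])
    for (i in seq_len(nrow(xyz))) xyz[i, ] <- xyz[i, ] + .ball(jitter)
    if (!is.null(displace_idx)) {
      v <- stats::rnorm(3); v <- 5 * v / sqrt(sum(v^2))
      xyz[displace_idx, ] <- xyz[displace_idx, ] + v
    }
    fp[, c("x", "y", "z")] <- xyz
    # distractors: random class, far from every planted feature
    for (j in seq_len(n_distractor)) {
      repeat {
        cls <- sample(FEATURE_CLASSES, 1)
        pos <- colMeans(xyz) + .ball(12)
        dmin <- min(sqrt(rowSums(sweep(pxyz, 2, pos)^2)))
        if (dmin > 3.5) break
      }
      fp <- rbind(fp[, c("cls", "x", "y", "z")],
                  data.frame(cls = cls, x = pos[1], y = pos[2], z = pos[3]))
    }
    .rigid_jumble(fp[, c("cls", "x", "y", "z")])
  }

  subset_ph <- function(idx) {
    pharmacophore(lapply(idx, function(i) {
      pharm_point(planted$cls[i], as.numeric(planted[i, c("x", "y", "z")]))
    }), name = paste(idx, collapse = "+"))
  }
  ph_opt <- subset_ph(optimal_subset)

  build <- function() {
    lib <- list()
    for (i in seq_len(n_actives)) {
      lib[[length(lib) + 1L]] <-
        .point_molecule(sprintf("active%03d", i), gen_one(opt), "active")
    }
    for (i in seq_len(n_decoys)) {
      # a displaced vertex can still form a congruent point set (rotation
      # about the axis through the remaining points): reject decoy draws
      # that the optimal pharmacophore still matches
      for (try in 1:25) {
        mol <- .point_molecule(sprintf("decoy%03d", i),
                               gen_one(opt, displace_idx = 1L + (i - 1L) %% k),
                               "decoy")
        if (is.null(match_conformer(ph_opt, mol))) break
        mol <- NULL
      }
      if (is.null(mol)) stop("could not generate a non-matching decoy")
      lib[[length(lib) + 1L]] <- mol
    }
    lib
  }

  verify <- function(lib) {
    if (n_actives == 0L) {
      warning("no actives: library verification skipped")
      return(TRUE)
    }
    cts <- confusion_counts(screen(subset_ph(optimal_subset), lib), lib)
    if (cts$TP != n_actives || cts$FP != 0L) return(FALSE)
    n <- nrow(planted)
    for (sz in 3:min(5L, n)) {
      for (idx in utils::combn(n, sz, simplify = FALSE)) {
        if (length(idx) == k && all(idx == optimal_subset)) next
        if (screen_f1(subset_ph(idx), lib) > gap) return(FALSE)
      }
    }
    TRUE
  }

  for (try in seq_len(max_tries)) {
    lib <- with_seed(seed + 1000L * (try - 1L) + 31L, build())
    if (verify(lib)) {
      attr(lib, "verified") <- TRUE
      return(lib)
    }
  }
  stop("library verification failed after ", max_tries, " attempts")
}

#' Generate a complete synthetic world
#'
#' Pocket + planted candidate features + verified labelled library: the
#' optimal subset screens at F1 = 1 and every other planted subset of
#' size 3-5 at F1 <= `gap`, so the reinforcement-learning signal is
#' unambiguous.
#'
#' @param seed Integer seed.
#' @param opt_size Optimal subset size (3-5) or `NULL` to sample.
#' @param n_features Number of planted candidate features.
#' @param n_filler Inert pocket filler atoms (see [make_pocket()]).
#' @param ... Passed to [make_library()].
#' @return List with `pocket`, `structure`, `groups`, `planted`,
#'   `optimal_subset`, `library`, `seed`.
#' @export
make_world <- function(seed = 0L, opt_size = 3L, n_features = 6L,
                       n_filler = 30L, ...) {
  ngr <- stats::setNames(rep(1L, 6), FEATURE_CLASSES)
  if (n_features > 6L) {
    extra <- n_features - 6L
    ngr[seq_len(extra)] <- ngr[seq_len(extra)] + 1L
  }
  pocket <- make_pocket(seed, n_groups = ngr, n_filler = n_filler)
  pf <- plant_features(pocket, n_features = n_features, opt_size = opt_size,
                       seed = seed)
  library <- make_library(pf$planted, pf$optimal_subset, seed = seed, ...)
  list(pocket = pocket, structure = pocket$structure, groups = pocket$groups,
       planted = pf$planted, optimal_subset = pf$optimal_subset,
       library = library, seed = seed)
}

#' Generate a synthetic voxel training dataset
#'
#' Samples query points inside synthetic pockets (the same pocket family
#' the extraction pipeline runs on) and labels them with the localized
#' feature-existence rule: a feature of class c exists where some group
#' supporting c sits at its preferred distance (within 0.5 Angstrom) and
#' the query lies on the group's interaction axis (within 20 degrees).
#' Positives are drawn on-axis inside the existence window; negatives are
#' drawn on-axis at wrong distances, off-axis at the right distance, and
#' uniformly in the pocket interior (labels always follow the rule, so
#' accidental positives are labelled correctly). Points facing the
#' charged motifs are multi-labelled by construction (an ammonium
#' supports both NegativeIon and HydrogenAcceptor features). Balanced and
#' deterministic under `seed`.
#'
#' @param n_per_class Positive samples per class.
#' @param seed Integer seed.
#' @param neg_frac Structured negatives per class as a fraction of
#'   `n_per_class` (default 1).
#' @param random_frac Uniform interior samples as a fraction of
#'   `n_per_class` (default 0.5).
#' @param n_pockets Number of distinct pockets sampled from (default
#'   scales with `n_per_class`).
#' @param pockets Optional list of [make_pocket()] outputs to include in
#'   the sampled pocket set, e.g. the binding sites the model will later
#'   be applied to (the desk-scale analogue of mining training points
#'   from the inference binding sites).
#' @param focus Sampling multiplicity of each supplied pocket relative
#'   to a generated one (default 25).
#' @return List of samples `list(vox = list(idx, val), labels =
#'   numeric(6), meta = list(...))`.
#' @export
make_voxel_dataset <- function(n_per_class = 200L, seed = 0L,
                               neg_frac = 1.0, random_frac = 0.5,
                               n_pockets = NULL, pockets = NULL,
                               focus = 25L) {
  stopifnot(n_per_class >= 1L)
  # one pocket per positive sample per class: pocket contexts then cannot
  # be memorized, and the network is forced to learn the local motif
  # geometry (with a handful of shared pockets, fresh-pocket scores at
  # true feature points collapse to zero while held-out same-pocket AUC
  # stays high)
  if (is.null(n_pockets)) n_pockets <- n_per_class
  wrap <- function(pk, weight) {
    roles <- lapply(seq_len(nrow(pk$groups)), function(g) {
      list(anchor = as.numeric(pk$groups[g, c("x", "y", "z")]),
           axis = as.numeric(pk$groups[g, c("ax", "ay", "az")]),
           kind = pk$groups$kind[g],
           tab = .motif_roles(pk$groups$kind[g]))
    })
    list(structure = pk$structure, roles = roles, weight = weight)
  }
  user <- lapply(pockets, wrap, weight = as.integer(focus))
  pockets <- c(user, lapply(seq_len(n_pockets), function(i) {
    wrap(make_pocket(seed = seed * 97L + i, n_filler = 12L), 1L)
  }))

  sample_at <- function(pk, q, type) {
    list(vox = voxel_sparse(voxelize(pk$structure, q)),
         labels = .role_labels(pk$roles, q),
         meta = list(point = q, type = type))
  }
  perp_jitter <- function(axis, amount) {
    fr <- .frame(axis)
    phi <- stats::runif(1, 0, 2 * pi)
    amount * (cos(phi) * fr$e1 + sin(phi) * fr$e2)
  }

  with_seed(seed + 5L, {
    samples <- list()
    for (cls in FEATURE_CLASSES) {
      # groups supporting this class, across pockets
      supp <- list()
      for (pi in seq_along(pockets)) {
        for (r in pockets[[pi]]$roles) {
          if (cls %in% r$tab$cls) {
            entry <- list(pi = pi, r = r,
                          dstar = r$tab$dstar[r$tab$cls == cls])
            for (rep in seq_len(pockets[[pi]]$weight)) {
              supp[[length(supp) + 1L]] <- entry
            }
          }
        }
      }
      for (i in seq_len(n_per_class)) {
        s <- supp[[1L + (i - 1L) %% length(supp)]]
        d <- s$dstar + stats::runif(1, -0.22, 0.22)
        q <- s$r$anchor + d * s$r$axis +
          perp_jitter(s$r$axis, stats::runif(1, 0, 0.3))
        samples[[length(samples) + 1L]] <-
          sample_at(pockets[[s$pi]], q, "positive")
      }
      # negatives sandwich the existence boundary from just outside, so
      # the learned score surface decays where the truth window ends
      n_neg <- round(neg_frac * n_per_class)
      for (i in seq_len(n_neg)) {
        s <- supp[[1L + (i - 1L) %% length(supp)]]
        q <- switch((i %% 3L) + 1L,
          s$r$anchor + (s$dstar + stats::runif(1, 0.4, 2.5)) * s$r$axis,
          s$r$anchor + max(0.7, s$dstar - stats::runif(1, 0.4, 2.0)) *
            s$r$axis,
          s$r$anchor + (s$dstar + stats::runif(1, -0.22, 0.22)) *
            s$r$axis + perp_jitter(s$r$axis, stats::runif(1, 0.65, 1.8)))
        samples[[length(samples) + 1L]] <-
          sample_at(pockets[[s$pi]], q, "negative")
      }
    }
    n_rand <- round(random_frac * n_per_class) * 6L
    draw <- rep(seq_along(pockets),
                times = vapply(pockets, `[[`, integer(1), "weight"))
    for (i in seq_len(n_rand)) {
      pi <- draw[1L + (i - 1L) %% length(draw)]
      q <- .ball(5.5)
      samples[[length(samples) + 1L]] <- sample_at(pockets[[pi]], q,
                                                   "random")
    }
    samples[sample.int(length(samples))]
  })
}
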