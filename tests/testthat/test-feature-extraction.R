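fake_field <- function(pts, cls_scores) {
  # cls_scores: named list class -> numeric vector over pts
  sc <- matrix(0, nrow(pts), 6)
  for (cls in names(cls_scores)) {
    sc[, feature_class_index(cls) + 1L] <- cls_scores[[cls]]
  }
  score_field(pts, sc)
}

test_that("connected components honour 26-connectivity and thresholds", {
  # 1D chain of lattice points with a 2-step sub-threshold gap
  pts <- cbind(seq(0, 3, by = 0.5), 0, 0)
  s <- c(0.9, 0.8, 0.2, 0.3, 0.7, 0.9, 0.8)
  f <- fake_field(pts, list(Aromatic = s))
  comps <- connected_components(f, "Aromatic", 0.5)
  expect_length(comps, 2L)
  expect_setequal(lengths(lapply(comps, `[[`, "members")), c(2L, 3L))
  # single super-threshold point
  f1 <- fake_field(matrix(c(0, 0, 0), 1), list(Hydrophobic = 0.9))
  expect_length(connected_components(f1, "Hydrophobic", 0.5), 1L)
  expect_length(connected_components(f1, "Aromatic", 0.5), 0L)
  # diagonal neighbours (26-connectivity) join
  pts2 <- rbind(c(0, 0, 0), c(0.5, 0.5, 0.5))
  f2 <- fake_field(pts2, list(Aromatic = c(0.9, 0.9)))
  expect_length(connected_components(f2, "Aromatic", 0.5), 1L)
  expect_error(connected_components(f1, "Aromatic", 0))
})

test_that("anchoring picks the top in-band point per (group, component)", {
  # donor at origin; acceptor component along +x
  st <- protein_structure(data.frame(element = "N", x = 0, y = 0, z = 0,
                                     atom_type = 7L))
  groups <- find_complementary_groups(st)
  pts <- cbind(seq(1.5, 3.0, by = 0.5), 0, 0)
  sc <- c(0.6, 0.95, 0.8, 0.7)
  f <- fake_field(pts, list(HydrogenAcceptor = sc))
  comps <- connected_components(f, "HydrogenAcceptor", 0.5)
  expect_length(comps, 1L)
  top <- anchor_top_points(f, comps, groups)
  expect_equal(nrow(top), 1L)
  expect_equal(top$x, 2.0)   # the component's maximum-score member
  # two donor groups near one component -> up to two points (the second
  # donor's in-band window selects a different top member)
  st2 <- protein_structure(data.frame(element = "N", x = c(0, 6.5),
                                      y = 0, z = 0, atom_type = 7L))
  groups2 <- find_complementary_groups(st2)
  top2 <- anchor_top_points(f, comps, groups2)
  expect_equal(nrow(top2), 2L)
  expect_setequal(top2$x, c(2.0, 2.5))
  # a component entirely out of band contributes nothing
  far <- fake_field(cbind(seq(5, 6, by = 0.5), 0, 0),
                    list(HydrogenAcceptor = c(0.9, 0.9, 0.9)))
  cf <- connected_components(far, "HydrogenAcceptor", 0.5)
  expect_equal(nrow(anchor_top_points(far, cf, groups)), 0L)
})

test_that("equal scores break ties toward the lowest lattice index", {
  st <- protein_structure(data.frame(element = "N", x = 0, y = 0, z = 0,
                                     atom_type = 7L))
  groups <- find_complementary_groups(st)
  pts <- cbind(c(2, 2.5), 0, 0)
  f <- fake_field(pts, list(HydrogenAcceptor = c(0.8, 0.8)))
  comps <- connected_components(f, "HydrogenAcceptor", 0.5)
  top <- anchor_top_points(f, comps, groups)
  expect_equal(top$point, 1L)
})

test_that("centroid merging: near pairs fuse at the midpoint, far pairs stay", {
  pts <- data.frame(cls = "Aromatic", x = c(0, 1), y = 0, z = 0)
  out <- cluster_points(pts, merge_dist = 1.5)
  expect_length(out, 1L)
  expect_equal(out[[1]]$position, c(0.5, 0, 0))
  pts2 <- data.frame(cls = "Aromatic", x = c(0, 2), y = 0, z = 0)
  out2 <- cluster_points(pts2, merge_dist = 1.5)
  expect_length(out2, 2L)
  # single point maps to itself
  out3 <- cluster_points(data.frame(cls = "Hydrophobic", x = 1, y = 2, z = 3))
  expect_equal(out3[[1]]$position, c(1, 2, 3))
})

test_that("no two merged outputs of one class are closer than merge_dist", {
  set.seed(41)
  for (trial in 1:20) {
    n <- sample(3:12, 1)
    pts <- data.frame(cls = "Hydrophobic",
                      x = stats::runif(n, 0, 6), y = stats::runif(n, 0, 6),
                      z = 0)
    out <- cluster_points(pts, merge_dist = 1.5)
    if (length(out) > 1L) {
      xyz <- do.call(rbind, lapply(out, function(p) p$position))
      d <- as.matrix(stats::dist(xyz))
      diag(d) <- Inf
      expect_gte(min(d), 1.5)
    }
  }
})

test_that("merged cluster latents are member means", {
  pts <- data.frame(cls = "Aromatic", x = c(0, 1), y = 0, z = 0)
  lat <- rbind(rep(1, 32), rep(3, 32))
  out <- cluster_points(pts, merge_dist = 1.5, latent = lat)
  expect_equal(out[[1]]$latent, rep(2, 32))
})

test_that("score_grid covers exactly the requested box, deterministically", {
  st <- protein_structure(data.frame(element = "N", x = 0, y = 0, z = 0,
                                     atom_type = 7L))
  model <- cnn_init(seed = 1L, widths = c(2L, 3L, 4L), dense_width = 8L)
  f <- score_grid(st, c(1, 0, 0, 2, 0.5, 0), model)
  expect_equal(nrow(f$points), 3L * 2L * 1L)
  expect_true(all(f$points[, 1] >= 1 & f$points[, 1] <= 2))
  f2 <- score_grid(st, c(1, 0, 0, 2, 0.5, 0), model)
  expect_identical(f$scores, f2$scores)
  # 1-point box
  f3 <- score_grid(st, c(0, 0, 0, 0, 0, 0), model)
  expect_equal(nrow(f3$points), 1L)
  expect_error(score_grid(st, c(1, 0, 0, 0, 0, 0), model), "empty box")
})

test_that("every anchored output lies within its class band of some group", {
  set.seed(43)
  w <- make_pocket(seed = 12, n_filler = 8L)
  groups <- find_complementary_groups(w$structure)
  th <- interaction_thresholds()
  # random dense field over the pocket interior
  ax <- seq(-4, 4, by = 0.5)
  pts <- as.matrix(expand.grid(ax, ax, 0))
  sc <- matrix(stats::runif(nrow(pts) * 6), ncol = 6)
  f <- score_field(pts, sc)
  for (cls in FEATURE_CLASSES) {
    comps <- connected_components(f, cls, 0.5)
    top <- anchor_top_points(f, comps, groups)
    if (nrow(top) == 0L) next
    band <- th[th$cls == cls, ]
    ga <- groups[groups$complements == cls, c("x", "y", "z")]
    for (i in seq_len(nrow(top))) {
      d <- sqrt(rowSums(sweep(as.matrix(ga), 2,
                              as.numeric(top[i, c("x", "y", "z")]))^2))
      expect_true(any(d >= band$min_dist & d <= band$max_dist))
    }
  }
})

test_that("score fields round-trip through TSV with latents", {
  set.seed(44)
  pts <- as.matrix(expand.grid(seq(0, 1, 0.5), 0, 0))
  sc <- matrix(stats::runif(nrow(pts) * 6), ncol = 6)
  lat <- matrix(stats::rnorm(nrow(pts) * 32), ncol = 32)
  f <- score_field(pts, sc, latent = lat)
  p <- tempfile(fileext = ".tsv")
  write_score_field(f, p)
  f2 <- read_score_field(p)
  expect_equal(f2$points, f$points, ignore_attr = TRUE)
  expect_equal(unname(f2$scores), unname(f$scores), tolerance = 1e-9)
  expect_equal(f2$latent, f$latent, tolerance = 1e-9)
})

test_that("a pocket with no complementary groups yields no features", {
  st <- protein_structure(data.frame(element = "C", x = c(0, 5), y = 0, z = 0,
                                     atom_type = 2L))
  model <- cnn_init(seed = 1L, widths = c(2L, 3L, 4L), dense_width = 8L)
  expect_length(predict_features(st, c(-1, -1, -1, 1, 1, 1), model), 0L)
})
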