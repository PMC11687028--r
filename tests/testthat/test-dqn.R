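test_that("the exploration schedule matches its closed form and bounds", {
  cfg <- dqn_config()
  expect_equal(epsilon(0, cfg), 0.836)
  expect_equal(epsilon(1e9, cfg), 0.017, tolerance = 1e-9)
  expect_equal(epsilon(11967, cfg), 0.017 + (0.836 - 0.017) * exp(-1))
  ts <- seq(0, 5e4, by = 500)
  es <- epsilon(ts, cfg)
  expect_true(all(diff(es) < 0))                    # strictly decreasing
  expect_true(all(es >= 0.017 & es <= 0.836))
})

test_that("stage presets set horizon and exploration conventions", {
  lig <- dqn_preset("ligand")
  expect_equal(lig$T_max, 10L)
  expect_equal(lig$eps_o, 0.836)
  cnn <- dqn_preset("cnn")
  expect_equal(cnn$T_max, 5L)
  expect_equal(cnn$eps_o, 0.5)
  expect_equal(dqn_preset("cnn", gamma = 0.5)$gamma, 0.5)
})

test_that("epsilon-greedy selection is uniform at eps = 1 and greedy at 0", {
  env <- local({
    st <- protein_structure(data.frame(element = "C", x = 0, y = 0, z = -3,
                                       atom_type = 2L))
    feats <- data.frame(cls = FEATURE_CLASSES[1:4],
                        x = c(0, 2, 4, 6), y = 0, z = 0)
    attr(feats, "latent") <- matrix(seq_len(4 * 32) / 128, 4, 32)
    pharm_env(feats, st, reward_fn = function(ids) 0)
  })
  model <- qnet_init(qnet_config(ns = 4L, nv = 2L, k = 1L, n_radial = 4L),
                     seed = 2L)
  props <- proposals(env, env_reset(env))
  set.seed(51)
  counts <- table(replicate(4000, select_action(props, model, eps = 1)$index))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
  # eps = 0: always the argmax
  qs <- batch_q(props, model)
  for (i in 1:5) {
    expect_equal(select_action(props, model, eps = 0)$index,
                 which.max(qs))
  }
})

test_that("Q ties break toward the lowest canonical graph key", {
  env <- local({
    # the only atom is far outside delta_fp: every single-feature graph is
    # then identical up to translation -> exactly tied Q values
    st <- protein_structure(data.frame(element = "C", x = 0, y = 0, z = -50,
                                       atom_type = 2L))
    feats <- data.frame(cls = rep("Aromatic", 3), x = c(0, 2, 4), y = 0, z = 0)
    attr(feats, "latent") <- matrix(0, 3, 32)
    pharm_env(feats, st, reward_fn = function(ids) 0)
  })
  model <- qnet_init(qnet_config(ns = 4L, nv = 2L, k = 1L, n_radial = 4L),
                     seed = 3L)
  props <- proposals(env, env_reset(env))
  expect_equal(diff(range(batch_q(props, model))), 0)
  props <- props[c(3, 2, 1)]
  sel <- select_action(props, model, eps = 0)
  expect_identical(sel$graph$key, "0001")
})

test_that("TD targets follow the bootstrap rule", {
  qs <- c(0.1, 0.6)
  fake <- list(reward = 0.2, terminal = FALSE,
               next_proposals = list("a", "b"))
  qi <- 0L
  q_fn <- function(g) { qi <<- qi + 1L; qs[qi] }
  expect_equal(td_target(fake, NULL, gamma = 0.5, q_fn = q_fn), 0.5)
  expect_equal(td_target(list(reward = 0.7, terminal = TRUE), NULL, 0.9), 0.7)
  qi <- 0L
  expect_equal(td_target(fake, NULL, gamma = 0, q_fn = q_fn), 0.2)
})

test_that("soft updates blend parameters linearly", {
  cfg <- qnet_config(ns = 4L, nv = 2L, k = 1L, n_radial = 4L)
  a <- qnet_init(cfg, seed = 1L)
  b <- qnet_init(cfg, seed = 2L)
  same <- soft_update(a, b, tau = 1)
  expect_equal(same$params$Wf, a$params$Wf)
  copy <- soft_update(a, b, tau = 0)
  expect_equal(copy$params$Wf, b$params$Wf)
  mix <- soft_update(a, b, tau = 0.686)
  expect_equal(mix$params$Wf, 0.686 * a$params$Wf + 0.314 * b$params$Wf)
  bad <- b
  bad$params$Wf <- bad$params$Wf[, 1:2]
  expect_error(soft_update(a, bad, 0.5), "shape mismatch")
})

test_that("replay memory is FIFO-bounded", {
  mem <- replay_memory(5L)
  for (i in 1:8) replay_push(mem, list(id = i))
  expect_equal(replay_size(mem), 5L)
  ids <- vapply(mem$buf, `[[`, numeric(1), "id")
  expect_equal(ids, 4:8)   # first 3 evicted
  set.seed(52)
  s <- replay_sample(mem, 3L)
  expect_length(s, 3L)
})

test_that("simulated episodes respect the horizon and termination rules", {
  st <- protein_structure(data.frame(element = "C", x = 0, y = 0, z = -3,
                                     atom_type = 2L))
  feats <- data.frame(cls = FEATURE_CLASSES[1:5],
                      x = c(0, 2, 4, 6, 8), y = 0, z = 0)
  attr(feats, "latent") <- matrix(stats::rnorm(5 * 32, sd = 0.2), 5, 32)
  env1 <- pharm_env(feats, st, reward_fn = function(ids) 0.4, T_max = 1L)
  model <- qnet_init(qnet_config(ns = 4L, nv = 2L, k = 1L, n_radial = 4L),
                     seed = 4L)
  set.seed(53)
  tr <- simulate_episode(env1, model, eps = 1)
  expect_length(tr, 1L)
  expect_false(is.null(tr[[1]]$chosen))
  # longer horizon: first transition never terminal, length <= T_max
  env5 <- pharm_env(feats, st, reward_fn = function(ids) 0.4, T_max = 5L)
  for (i in 1:5) {
    tr <- simulate_episode(env5, model, eps = 1)
    expect_false(tr[[1]]$terminal)
    expect_lte(length(tr), 5L)
    # the recorded flags mark exactly the final transition
    flags <- vapply(tr, `[[`, logical(1), "terminal")
    if (any(flags)) expect_identical(which(flags), length(tr))
  }
})

test_that("training is deterministic under the seed and loss shrinks", {
  st <- protein_structure(data.frame(element = "C", x = c(0, 4), y = 0,
                                     z = -3, atom_type = 2L))
  feats <- data.frame(cls = FEATURE_CLASSES[1:4],
                      x = c(0, 2, 4, 6), y = 0, z = 0)
  attr(feats, "latent") <- matrix(stats::rnorm(4 * 32, sd = 0.3), 4, 32)
  mkenv <- function() pharm_env(feats, st, T_max = 4L,
                                reward_fn = function(ids) {
                                  if (setequal(ids, 1:3)) 1 else 0.1
                                })
  qcfg <- qnet_config(ns = 4L, nv = 2L, k = 1L, n_radial = 4L)
  cfg <- dqn_config(episodes = 8L, batch = 8L, alpha = 50, lr = 0.01,
                    seed = 7L)
  r1 <- dqn_train(mkenv(), cfg, qcfg)
  r2 <- dqn_train(mkenv(), cfg, qcfg)
  expect_identical(r1$model$params, r2$model$params)
  expect_identical(r1$log$return, r2$log$return)
})

test_that("regression loss on a fixed minibatch decreases over 50 steps", {
  st <- protein_structure(data.frame(element = "C", x = 0, y = 0, z = -3,
                                     atom_type = 2L))
  feats <- data.frame(cls = FEATURE_CLASSES[1:4],
                      x = c(0, 2, 4, 6), y = 0, z = 0)
  attr(feats, "latent") <- matrix(stats::rnorm(4 * 32, sd = 0.3), 4, 32)
  env <- pharm_env(feats, st, T_max = 4L, reward_fn = function(ids) {
    if (setequal(ids, 1:3)) 1 else 0.1
  })
  model <- qnet_init(qnet_config(ns = 4L, nv = 2L, k = 1L, n_radial = 4L),
                     seed = 8L)
  set.seed(54)
  batch <- unlist(lapply(1:3, function(i) {
    simulate_episode(env, model, eps = 1)
  }), recursive = FALSE)
  ys <- vapply(batch, td_target, numeric(1), target_model = model,
               gamma = 0.8636)
  loss_of <- function(m) {
    mean(vapply(seq_along(batch), function(i) {
      (q_value(batch[[i]]$chosen, m) - ys[i])^2
    }, numeric(1)))
  }
  l0 <- loss_of(model)
  opt <- qpharm:::adam_init(model$params)
  for (step in 1:50) {
    grads <- lapply(model$params, function(p) p * 0)
    for (i in seq_along(batch)) {
      fw <- qpharm:::qnet_fwd(model, batch[[i]]$chosen, keep = TRUE)
      gr <- qpharm:::qnet_bwd(model, fw$cache)
      sc <- 2 * (fw$q - ys[i]) / length(batch)
      for (k in names(gr)) grads[[k]] <- grads[[k]] + gr[[k]] * sc
    }
    upd <- qpharm:::adam_step(model$params, grads, opt, 0.01)
    model$params <- upd$params
    opt <- upd$state
  }
  expect_lt(loss_of(model), l0)
})

test_that("greedy generation masks the stop action below min_size", {
  st <- protein_structure(data.frame(element = "C", x = 0, y = 0, z = -3,
                                     atom_type = 2L))
  feats <- data.frame(cls = FEATURE_CLASSES[1:5],
                      x = c(0, 2, 4, 6, 8), y = 0, z = 0)
  attr(feats, "latent") <- matrix(stats::rnorm(5 * 32, sd = 0.3), 5, 32)
  # reward prefers stopping as early as possible: a stop-preferring Q
  env <- pharm_env(feats, st, T_max = 8L,
                   reward_fn = function(ids) 1 / length(ids))
  model <- qnet_init(qnet_config(ns = 4L, nv = 2L, k = 1L, n_radial = 4L),
                     seed = 5L)
  ph4 <- generate_pharmacophore(model, env, min_size = 4L)[[1]]
  expect_gte(length(ph4$points), 4L)
  ph3 <- generate_pharmacophore(model, env, min_size = 3L)[[1]]
  expect_gte(length(ph3$points), 3L)
  # an ensemble yields one pharmacophore per model
  ens <- generate_pharmacophore(list(model, model), env, min_size = 3L)
  expect_length(ens, 2L)
})
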