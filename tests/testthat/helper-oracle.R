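# exhaustive search over all episode trajectories of a deterministic
# environment: the optimal discounted return from the empty state
optimal_return <- function(env, gamma) {
  memo <- new.env(parent = emptyenv())
  rec <- function(state) {
    if (state$done || state$t >= env$T_max) return(0)
    key <- paste(if (is.null(state$graph)) "" else state$graph$key,
                 state$t, sep = "@")
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    for (g in proposals(env, state)) {
      st <- env_step(env, state, g)
      v <- st$reward + if (st$done) 0 else gamma * rec(st$state)
      if (v > best) best <- v
    }
    memo[[key]] <- best
    best
  }
  rec(env_reset(env))
}

# discounted return of the greedy policy of a trained model
greedy_return <- function(env, model, gamma) {
  state <- env_reset(env)
  ret <- 0
  disc <- 1
  while (!state$done && state$t < env$T_max) {
    props <- proposals(env, state)
    qs <- batch_q(props, model)
    best <- which(qs == max(qs))
    if (length(best) > 1L) {
      keys <- vapply(props[best], function(g) g$key, character(1))
      best <- best[order(keys)[1]]
    }
    st <- env_step(env, state, props[[best[1]]])
    ret <- ret + disc * st$reward
    disc <- disc * gamma
    state <- st$state
  }
  ret
}

# environment factory for the enumerable toy MDP: 6 features, a unique
# best triple with reward shaping toward it
toy_mdp_env <- function(best = c(2L, 4L, 5L), T_max = 5L) {
  st <- protein_structure(data.frame(
    element = "C", x = c(0, 6), y = 0, z = -3, atom_type = 2L))
  feats <- data.frame(cls = FEATURE_CLASSES,
                      x = c(0, 1.5, 3, 4.5, 6, 7.5), y = 0, z = 0)
  attr(feats, "latent") <- with_seed(1L, matrix(stats::rnorm(6 * 32,
                                                             sd = 0.4),
                                                6, 32))
  reward_fn <- function(ids) {
    if (setequal(ids, best)) return(1.0)
    if (length(ids) == 3L && length(intersect(ids, best)) == 2L) return(0.3)
    0.05
  }
  pharm_env(feats, st, reward_fn = reward_fn, T_max = T_max)
}

# train a desk-scale agent on one synthetic world and report whether the
# greedy rollout recovers the planted optimal subset
recover_world <- function(wseed, episodes = 150L) {
  w <- make_world(seed = wseed, n_filler = 6L)
  feats <- w$planted[, c("cls", "x", "y", "z")]
  attr(feats, "latent") <- with_seed(wseed + 7L,
                                     matrix(stats::rnorm(6 * 32, sd = 0.5),
                                            ncol = 32))
  env <- pharm_env(feats, w$structure, w$library, T_max = 5L)
  qcfg <- qnet_config(ns = 8L, nv = 2L, k = 2L, n_radial = 6L)
  cfg <- dqn_config(episodes = episodes, batch = 16L, alpha = 150,
                    eps_o = 1.0, eps_T = 0.05, lr = 0.004, seed = wseed)
  res <- dqn_train(env, cfg, qcfg)
  ph <- generate_pharmacophore(res$model, env, min_size = 3L)[[1]]
  got <- as.integer(strsplit(ph$name, "-")[[1]])
  setequal(got, w$optimal_subset)
}

with_seed <- qpharm:::with_seed
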