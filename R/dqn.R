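# ---- deep Q-learning: replay, epsilon-greedy, soft target updates --------

#' DQN hyperparameter configuration
#'
#' Defaults are the sweep-selected values used as fixed constants:
#' discount gamma = 0.8636, epsilon schedule (start 0.836, final 0.017,
#' decay 11967), batch 50, replay capacity 1893, target update every C = 2
#' episodes with importance tau = 0.686, learning rate 0.00012, episode
#' budget 16752 and horizon T = 10 (ligand-derived candidates; 5 is the
#' convention for CNN-derived ones). All overridable; desk-scale runs use
#' far fewer episodes.
#'
#' @param gamma,eps_o,eps_T,alpha,batch,C,tau,T_max,episodes,lr,memory
#'   See description.
#' @param seed Master seed for all training randomness.
#' @return List of class `dqn_config`.
#' @export
dqn_config <- function(gamma = 0.8636, eps_o = 0.836, eps_T = 0.017,
                       alpha = 11967, batch = 50L, C = 2L, tau = 0.686,
                       T_max = 10L, episodes = 16752L, lr = 0.00012,
                       memory = 1893L, seed = 0L) {
  stopifnot(gamma >= 0, gamma <= 1, eps_T <= eps_o)
  structure(list(gamma = gamma, eps_o = eps_o, eps_T = eps_T, alpha = alpha,
                 batch = batch, C = C, tau = tau, T_max = T_max,
                 episodes = episodes, lr = lr, memory = memory, seed = seed),
            class = "dqn_config")
}

#' Training-stage presets
#'
#' Two conventional stages: `"ligand"` — pretraining on ligand-derived
#' candidate features (the full defaults, horizon T = 10); `"cnn"` —
#' fine-tuning on CNN-derived candidates, with less exploration
#' (`eps_o = 0.5`) and horizon T = 5.
#'
#' @param stage `"ligand"` or `"cnn"`.
#' @param ... Overrides passed to [dqn_config()].
#' @return A [dqn_config()].
#' @export
dqn_preset <- function(stage = c("ligand", "cnn"), ...) {
  stage <- match.arg(stage)
  if (stage == "ligand") {
    dqn_config(T_max = 10L, ...)
  } else {
    dqn_config(eps_o = 0.5, T_max = 5L, ...)
  }
}

#' Exploration schedule
#'
#' Exponential decay `eps_T + (eps_o - eps_T) * exp(-t / alpha)`: 0.836 at
#' t = 0, approaching 0.017 as t grows, with the default constants.
#'
#' @param t Step count (>= 0).
#' @param cfg A [dqn_config()] (or any list with `eps_o`, `eps_T`,
#'   `alpha`).
#' @return Epsilon value(s).
#' @export
epsilon <- function(t, cfg = dqn_config()) {
  stopifnot(all(t >= 0))
  cfg$eps_T + (cfg$eps_o - cfg$eps_T) * exp(-t / cfg$alpha)
}

#' Epsilon-greedy action selection
#'
#' With probability `eps` a uniform proposal; otherwise the argmax of the
#' Q-values. Ties in Q break toward the lowest canonical graph key, so
#' selection is deterministic given the RNG state.
#'
#' @param props List of proposal `pharm_graph`s (non-empty).
#' @param model A `qnet_params`.
#' @param eps Exploration probability.
#' @return List with `graph` (chosen) and `index`.
#' @export
select_action <- function(props, model, eps) {
  if (length(props) == 0L) stop("empty proposal set")
  if (stats::runif(1) < eps) {
    i <- sample.int(length(props), 1L)
  } else {
    qs <- batch_q(props, model)
    best <- which(qs == max(qs))
    if (length(best) > 1L) {
      keys <- vapply(props[best], function(g) g$key, character(1))
      best <- best[order(keys)[1]]
    }
    i <- best[1]
  }
  list(graph = props[[i]], index = i)
}

#' Temporal-difference target
#'
#' `y = r` for terminal transitions, else `y = r + gamma * max Q(G';
#' target)` over the next proposal set, evaluated under the target
#' network.
#'
#' @param transition List with `reward`, `terminal`, `next_proposals`.
#' @param target_model Target-network `qnet_params`.
#' @param gamma Discount factor.
#' @param q_fn Optional function(graph) overriding the Q evaluation
#'   (used for memoised target evaluation).
#' @return Numeric scalar.
#' @export
td_target <- function(transition, target_model, gamma, q_fn = NULL) {
  if (transition$terminal) return(transition$reward)
  stopifnot(length(transition$next_proposals) > 0L)
  qs <- if (is.null(q_fn)) {
    batch_q(transition$next_proposals, target_model)
  } else {
    vapply(transition$next_proposals, q_fn, numeric(1))
  }
  transition$reward + gamma * max(qs)
}

#' Soft target-network update
#'
#' `theta_target <- tau * theta_target + (1 - tau) * theta`: `tau` is the
#' importance kept on the target parameters.
#'
#' @param target_model,model `qnet_params` with identical shapes.
#' @param tau Blend factor in `[0, 1]`.
#' @return Updated target `qnet_params`.
#' @export
soft_update <- function(target_model, model, tau) {
  for (k in names(model$params)) {
    if (!identical(dim(target_model$params[[k]]), dim(model$params[[k]])) ||
        length(target_model$params[[k]]) != length(model$params[[k]])) {
      stop("parameter shape mismatch: ", k)
    }
    target_model$params[[k]] <- tau * target_model$params[[k]] +
      (1 - tau) * model$params[[k]]
  }
  target_model
}

#' FIFO replay memory
#'
#' Bounded buffer of transitions; once `capacity` is reached the oldest
#' entry is evicted first.
#'
#' @param capacity Maximum number of stored transitions (default 1893).
#' @return Object of class `replay_memory`.
#' @export
replay_memory <- function(capacity = 1893L) {
  e <- new.env(parent = emptyenv())
  e$buf <- vector("list", 0L)
  e$capacity <- as.integer(capacity)
  class(e) <- "replay_memory"
  e
}

#' @rdname replay_memory
#' @param mem A `replay_memory`.
#' @param transition Transition record to append.
#' @export
replay_push <- function(mem, transition) {
  mem$buf[[length(mem$buf) + 1L]] <- transition
  if (length(mem$buf) > mem$capacity) mem$buf <- mem$buf[-1L]
  invisible(mem)
}

#' @rdname replay_memory
#' @export
replay_size <- function(mem) length(mem$buf)

#' @rdname replay_memory
#' @param n Sample size.
#' @export
replay_sample <- function(mem, n) {
  mem$buf[sample.int(length(mem$buf), min(n, length(mem$buf)))]
}

#' Simulate one episode
#'
#' Starts from the empty graph and follows the epsilon-greedy policy,
#' recording for every step the chosen graph, its reward, the next
#' proposal set and the terminal flag. At most `T_max` transitions; the
#' first step can never be terminal (the empty graph is not
#' re-selectable).
#'
#' @param env A `pharm_env`.
#' @param model A `qnet_params`.
#' @param eps Exploration probability (scalar, or function of the global
#'   step).
#' @param t0 Global step offset for a step-dependent `eps`.
#' @return List of transitions: `chosen`, `reward`, `next_proposals`,
#'   `terminal`.
#' @export
simulate_episode <- function(env, model, eps, t0 = 0L) {
  state <- env_reset(env)
  out <- list()
  while (!state$done && state$t < env$T_max) {
    props <- proposals(env, state)
    e <- if (is.function(eps)) eps(t0 + state$t) else eps
    act <- select_action(props, model, e)
    st <- env_step(env, state, act$graph)
    nxt_props <- if (st$done) list() else proposals(env, st$state)
    out[[length(out) + 1L]] <- list(chosen = act$graph, reward = st$reward,
                                    next_proposals = nxt_props,
                                    terminal = st$done)
    state <- st$state
  }
  out
}

#' Train the Q-network by deep Q-learning
#'
#' Per episode: simulate with the decaying epsilon-greedy policy, push
#' transitions into replay memory, and after every environment step sample
#' a minibatch and regress `Q(chosen)` toward the TD target (squared
#' error) with Adam; the target network is blended toward the online
#' network every `C` episodes. Target-network Q-values over proposal sets
#' are memoised per (environment, subset, target version). All randomness
#' derives from `cfg$seed`; identical seeds give identical trajectories.
#'
#' @param envs A `pharm_env` or list of them (one is drawn per episode).
#' @param cfg A [dqn_config()].
#' @param qcfg A [qnet_config()] for the network.
#' @param model Optional warm-start `qnet_params`.
#' @param verbose Print progress every 25 episodes.
#' @return List: `model`, `target`, `log` (per-episode data.frame with
#'   `episode`, `eps`, `return`, `loss`).
#' @export
dqn_train <- function(envs, cfg = dqn_config(), qcfg = qnet_config(),
                      model = NULL, verbose = FALSE) {
  if (inherits(envs, "pharm_env")) envs <- list(envs)
  stopifnot(length(envs) >= 1L)
  if (is.null(model)) model <- qnet_init(qcfg, seed = cfg$seed)
  target <- model
  mem <- replay_memory(cfg$memory)
  opt <- adam_init(model$params)
  tversion <- 0L
  tcache <- new.env(parent = emptyenv())
  gstep <- 0L
  log <- vector("list", cfg$episodes)

  target_q <- function(ei, g) {
    key <- paste0(ei, "|", tversion, "|", g$key)
    v <- tcache[[key]]
    if (is.null(v)) {
      v <- q_value(g, target)
      tcache[[key]] <- v
    }
    v
  }

  with_seed(cfg$seed + 101L, {
    for (ep in seq_len(cfg$episodes)) {
      ei <- if (length(envs) == 1L) 1L else sample.int(length(envs), 1L)
      env <- envs[[ei]]
      state <- env_reset(env)
      ep_ret <- 0
      ep_loss <- 0; nupd <- 0L
      while (!state$done && state$t < env$T_max) {
        props <- proposals(env, state)
        act <- select_action(props, model, epsilon(gstep, cfg))
        st <- env_step(env, state, act$graph)
        nxt <- if (st$done) list() else proposals(env, st$state)
        replay_push(mem, list(env_index = ei, chosen = act$graph,
                              reward = st$reward, next_proposals = nxt,
                              terminal = st$done))
        ep_ret <- ep_ret + st$reward
        state <- st$state
        gstep <- gstep + 1L
        if (replay_size(mem) >= min(cfg$batch, 8L)) {
          batch <- replay_sample(mem, cfg$batch)
          # transitions sharing (environment, chosen graph) have identical
          # TD targets under a fixed target network: group them and weight
          # one gradient evaluation by the multiplicity
          keys <- vapply(batch, function(tr) {
            paste0(tr$env_index, "|", tr$chosen$key, "|", tr$terminal)
          }, character(1))
          grads <- NULL
          bl <- 0
          for (grp in split(seq_along(batch), keys)) {
            tr <- batch[[grp[1]]]
            w <- length(grp)
            y <- td_target(tr, target, cfg$gamma,
                           q_fn = function(g) target_q(tr$env_index, g))
            fw <- qnet_fwd(model, tr$chosen, keep = TRUE)
            diff <- fw$q - y
            bl <- bl + w * diff^2
            gr <- qnet_bwd(model, fw$cache)
            sc <- 2 * diff * w / length(batch)
            if (is.null(grads)) {
              grads <- lapply(gr, function(x) x * sc)
            } else {
              for (k in names(gr)) grads[[k]] <- grads[[k]] + gr[[k]] * sc
            }
          }
          if (!all(vapply(grads, function(x) all(is.finite(x)), logical(1)))) {
            stop("divergence: non-finite gradients at episode ", ep)
          }
          upd <- adam_step(model$params, grads, opt, cfg$lr)
          model$params <- upd$params
          opt <- upd$state
          ep_loss <- ep_loss + bl / length(batch)
          nupd <- nupd + 1L
        }
      }
      if (ep %% cfg$C == 0L) {
        target <- soft_update(target, model, cfg$tau)
        tversion <- tversion + 1L
      }
      log[[ep]] <- data.frame(episode = ep, eps = epsilon(gstep, cfg),
                              return = ep_ret,
                              loss = if (nupd) ep_loss / nupd else NA_real_)
      if (verbose && ep %% 25L == 0L) {
        message(sprintf("episode %d eps %.3f return %.3f loss %.4f",
                        ep, epsilon(gstep, cfg), ep_ret,
                        if (nupd) ep_loss / nupd else NA))
      }
    }
  })
  list(model = model, target = target, log = do.call(rbind, log))
}

#' Greedy pharmacophore generation
#'
#' Rolls out the greedy (epsilon = 0) policy of one or more trained
#' models; the stop action (re-selecting the current graph) is masked
#' until the graph has at least `min_size` features. One pharmacophore is
#' returned per model.
#'
#' @param models A `qnet_params` or list of them (an ensemble).
#' @param env A `pharm_env` over the candidate features.
#' @param min_size Minimum number of features (>= 3, default 3).
#' @return List of [pharmacophore()]s (one per model).
#' @export
generate_pharmacophore <- function(models, env, min_size = 3L) {
  stopifnot(min_size >= 3L)
  if (inherits(models, "qnet_params")) models <- list(models)
  lapply(models, function(model) {
    state <- env_reset(env)
    repeat {
      cur_n <- if (is.null(state$graph)) 0L else length(state$graph$ids)
      props <- proposals(env, state, allow_stop = cur_n >= min_size)
      if (length(props) == 0L) {
        stop("candidate features insufficient to reach min_size")
      }
      qs <- batch_q(props, model)
      best <- which(qs == max(qs))
      if (length(best) > 1L) {
        keys <- vapply(props[best], function(g) g$key, character(1))
        best <- best[order(keys)[1]]
      }
      g <- props[[best[1]]]
      st <- env_step(env, state, g)
      state <- st$state
      if (st$done) return(graph_pharmacophore(g))
      if (state$t >= env$T_max) return(graph_pharmacophore(state$graph))
    }
  })
}
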