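# ---- MDP environment: protein-pharmacophore graphs, F1 rewards ----------

#' Build a heterogeneous protein-pharmacophore graph
#'
#' The MDP state: feature nodes (32-d latent features) connected pairwise
#' within `delta_ff`, protein nodes (atoms within `delta_fp` of any
#' feature, one-hot atom type) connected to features within `delta_fp`.
#' No protein-protein edges. Recomputed from the feature subset, so the
#' graph is order-free and idempotent.
#'
#' @param pool Candidate feature pool: data.frame `cls`, `x`, `y`, `z`
#'   with attribute (or list element) `latent` (n x 32).
#' @param ids Integer indices of the features in the graph (non-empty).
#' @param structure A typed [protein_structure()].
#' @param delta_ff Feature-feature edge threshold, Angstrom (default 12).
#' @param delta_fp Feature-protein edge threshold, Angstrom (default 11).
#' @return Object of class `pharm_graph`.
#' @export
build_graph <- function(pool, ids, structure, delta_ff = 12, delta_fp = 11) {
  if (length(ids) == 0L) stop("empty feature subset")
  ids <- sort(as.integer(ids))
  feat <- pool$features[ids, , drop = FALSE]
  lat <- pool$latent[ids, , drop = FALSE]
  fxyz <- as.matrix(feat[, c("x", "y", "z")])
  nf <- length(ids)
  eff <- matrix(integer(0), 0, 2)
  if (nf > 1L) {
    d <- cross_dist(fxyz, fxyz)
    pair <- which(d <= delta_ff & upper.tri(d), arr.ind = TRUE)
    eff <- unname(pair)
  }
  axyz <- protein_coords(structure)
  dpf <- cross_dist(fxyz, axyz)
  keep <- which(apply(dpf, 2, min) <= delta_fp)
  pxyz <- axyz[keep, , drop = FALSE]
  ptype <- structure$atoms$atom_type[keep]
  efp <- which(dpf[, keep, drop = FALSE] <= delta_fp, arr.ind = TRUE)
  efp <- unname(efp)  # (feature index, local protein index)
  g <- structure(list(ids = ids, cls = feat$cls, fxyz = fxyz, latent = lat,
                      pxyz = pxyz, ptype = ptype, eff = eff, efp = efp,
                      delta_ff = delta_ff, delta_fp = delta_fp,
                      key = paste(sprintf("%04d", ids), collapse = "-")),
                 class = "pharm_graph")
  g$geo <- graph_geometry(g)
  g
}

#' @export
print.pharm_graph <- function(x, ...) {
  cat(sprintf("<pharm_graph [%s]: %d features, %d protein atoms, %d ff + %d fp edges>\n",
              x$key, length(x$ids), nrow(x$pxyz), nrow(x$eff), nrow(x$efp)))
  invisible(x)
}

#' Pharmacophore carried by a graph
#' @param graph A `pharm_graph`.
#' @param name Optional name.
#' @return A [pharmacophore()] (radius 1 points with latents).
#' @export
graph_pharmacophore <- function(graph, name = graph$key) {
  pharmacophore(lapply(seq_along(graph$ids), function(i) {
    pharm_point(graph$cls[i], graph$fxyz[i, ], latent = graph$latent[i, ])
  }), name = name)
}

#' Create a pharmacophore-assembly environment
#'
#' Wraps a candidate feature pool, a receptor structure and a labelled
#' screening library into the episodic MDP: states are protein-
#' pharmacophore graphs, actions choose the next graph from the proposal
#' set, the reward of a chosen graph with at least 3 features is its F1
#' score on the library (0 below 3 features), and an episode terminates
#' when the current graph is re-selected or after `T_max` steps. Rewards
#' are memoised per feature subset; the cache never changes a value
#' (recomputation is bit-identical).
#'
#' @param features Candidate features: data.frame `cls`, `x`, `y`, `z`
#'   (with optional `latent` attribute, n x 32) or a list of
#'   [pharm_point()]s.
#' @param structure Typed [protein_structure()].
#' @param library Labelled list of [molecule_record()]s, or `NULL` when a
#'   custom `reward_fn` is supplied.
#' @param delta_ff,delta_fp Graph distance thresholds (defaults 12 / 11).
#' @param T_max Maximum steps per episode (default 10; 5 is the
#'   convention for CNN-derived candidates).
#' @param reward_fn Optional `function(ids)` returning the reward of the
#'   feature subset; defaults to screening F1.
#' @param use_cache Memoise rewards by subset key (default TRUE).
#' @return Object of class `pharm_env`.
#' @export
pharm_env <- function(features, structure, library = NULL, delta_ff = 12,
                      delta_fp = 11, T_max = 10L, reward_fn = NULL,
                      use_cache = TRUE) {
  if (is.list(features) && !is.data.frame(features)) {
    lat <- do.call(rbind, lapply(features, function(p) {
      if (is.null(p$latent)) numeric(32) else p$latent
    }))
    features <- data.frame(
      cls = vapply(features, function(p) p$cls, character(1)),
      x = vapply(features, function(p) p$position[1], numeric(1)),
      y = vapply(features, function(p) p$position[2], numeric(1)),
      z = vapply(features, function(p) p$position[3], numeric(1)),
      stringsAsFactors = FALSE)
    attr(features, "latent") <- lat
  }
  lat <- attr(features, "latent")
  if (is.null(lat)) lat <- matrix(0, nrow(features), 32L)
  pool <- list(features = features[, c("cls", "x", "y", "z")], latent = lat)
  if (is.null(reward_fn)) {
    if (is.null(library)) stop("need a library or a reward_fn")
    reward_fn <- function(ids) {
      ph <- pharmacophore(lapply(ids, function(i) {
        pharm_point(pool$features$cls[i],
                    as.numeric(pool$features[i, c("x", "y", "z")]))
      }))
      screen_f1(ph, library)
    }
  }
  env <- list(pool = pool, structure = structure, library = library,
              delta_ff = delta_ff, delta_fp = delta_fp, T_max = T_max,
              reward_fn = reward_fn, use_cache = use_cache,
              cache = new.env(parent = emptyenv()))
  class(env) <- "pharm_env"
  env
}

#' Reward of a feature subset (memoised)
#' @param env A `pharm_env`.
#' @param ids Feature indices (>= 3 for a screenable pharmacophore).
#' @return Reward in `[0, 1]`.
#' @export
env_reward <- function(env, ids) {
  if (length(ids) < 3L) return(0)
  key <- paste(sort(ids), collapse = "-")
  if (env$use_cache && !is.null(env$cache[[key]])) return(env$cache[[key]])
  r <- env$reward_fn(sort(ids))
  if (env$use_cache) env$cache[[key]] <- r
  r
}

#' Initial state of an episode
#' @param env A `pharm_env`.
#' @return State list: `graph` (`NULL` = empty), `available`, `t`, `done`.
#' @export
env_reset <- function(env) {
  list(graph = NULL, available = seq_len(nrow(env$pool$features)), t = 0L,
       done = FALSE)
}

#' Proposal set for a state
#'
#' One proposal per available feature within `delta_ff` of any current
#' feature node (for the empty state: every candidate), plus the current
#' graph itself when it already has at least 3 feature nodes.
#'
#' @param env A `pharm_env`.
#' @param state An environment state.
#' @param allow_stop Include the current graph when eligible (default
#'   TRUE; inference masks it below a minimum size).
#' @return List of `pharm_graph`s.
#' @export
proposals <- function(env, state, allow_stop = TRUE) {
  if (state$done) stop("episode is done")
  cur <- state$graph
  out <- list()
  if (is.null(cur)) {
    for (id in state$available) {
      out[[length(out) + 1L]] <- build_graph(env$pool, id, env$structure,
                                             env$delta_ff, env$delta_fp)
    }
    return(out)
  }
  fxyz <- cur$fxyz
  for (id in state$available) {
    p <- as.numeric(env$pool$features[id, c("x", "y", "z")])
    d <- sqrt(rowSums(sweep(fxyz, 2, p)^2))
    if (min(d) <= env$delta_ff) {
      out[[length(out) + 1L]] <- build_graph(env$pool, c(cur$ids, id),
                                             env$structure, env$delta_ff,
                                             env$delta_fp)
    }
  }
  if (allow_stop && length(cur$ids) >= 3L) out[[length(out) + 1L]] <- cur
  out
}

#' Environment transition
#'
#' Applies a chosen proposal: the reward is 0 when the chosen graph has
#' fewer than 3 feature nodes and its screening F1 otherwise; the episode
#' ends when the current graph was re-selected or the step budget is
#' exhausted.
#'
#' @param env A `pharm_env`.
#' @param state Current state.
#' @param action A `pharm_graph` from [proposals()].
#' @return List with `state` (next state), `reward`, `done`.
#' @export
env_step <- function(env, state, action) {
  stopifnot(inherits(action, "pharm_graph"))
  cur <- state$graph
  cur_key <- if (is.null(cur)) "" else cur$key
  reselected <- identical(action$key, cur_key)
  legal <- if (reselected) {
    length(cur$ids) >= 3L
  } else if (is.null(cur)) {
    length(action$ids) == 1L && action$ids %in% state$available
  } else {
    added <- setdiff(action$ids, cur$ids)
    length(added) == 1L && added %in% state$available &&
      setequal(setdiff(action$ids, added), cur$ids) &&
      min(sqrt(rowSums(sweep(cur$fxyz, 2,
        as.numeric(env$pool$features[added, c("x", "y", "z")]))^2))) <=
        env$delta_ff
  }
  if (!legal) stop("action not in proposal set")
  t2 <- state$t + 1L
  done <- reselected || t2 >= env$T_max
  reward <- env_reward(env, action$ids)
  nxt <- list(graph = action,
              available = setdiff(state$available, action$ids),
              t = t2, done = done)
  list(state = nxt, reward = reward, done = done)
}
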