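#' @title Attractor analysis
#' @description Attractor detection for synchronous Boolean networks:
#'   exhaustive enumeration of the free-node hypercube (exact basin weights,
#'   small networks) and a stochastic sampling procedure (noisy time courses
#'   followed by deterministic descent of every visited state) that scales to
#'   large networks. Attractors are reported in canonical form: the cycle
#'   rotation starting at the lexicographically smallest state.
#' @name attractors
NULL

state_keys <- function(M) {
  do.call(paste0, lapply(seq_len(ncol(M)), function(j) M[, j]))
}

# nodes that are neither inputs nor hard-clamped (the sampled/enumerated axes)
free_nodes <- function(model, clamps) {
  hard <- names(clamps)[vapply(clamps, function(cl) cl$level >= 1, logical(1))]
  setdiff(setdiff(model$nodes, model$inputs), hard)
}

check_binary_env <- function(model, env) {
  env <- check_env(model, env)
  if (!all(env %in% c(0, 1))) {
    stop("deterministic descent requires binary input levels", call. = FALSE)
  }
  env
}

check_binary_clamps <- function(model, clamps) {
  clamps <- check_clamps(model, clamps)
  lv <- vapply(clamps, `[[`, numeric(1), "level")
  if (length(lv) > 0 && !all(lv %in% c(0, 1))) {
    stop("deterministic descent requires clamp levels of exactly 0 or 1",
         call. = FALSE)
  }
  clamps[lv >= 1]
}

# template state: inputs at env values, hard clamps at forced values, rest 0
base_state <- function(model, env, clamps) {
  st <- stats::setNames(integer(length(model$nodes)), model$nodes)
  st[names(env)] <- as.integer(env)
  for (nd in names(clamps)) {
    st[nd] <- if (clamps[[nd]]$mode == "on") 1L else 0L
  }
  st
}

canonical_cycle <- function(states) {
  k <- nrow(states)
  if (k == 1) return(states)
  keys <- state_keys(states)
  start <- which.min(match(keys, sort(keys)))
  states[c(seq(start, k), if (start > 1) seq_len(start - 1L)), , drop = FALSE]
}

attractor_key <- function(states) {
  paste(state_keys(states), collapse = "|")
}

new_attractor <- function(states, basin = NA_real_) {
  states <- canonical_cycle(states)
  structure(list(states = states, length = nrow(states), basin = basin,
                 key = attractor_key(states)),
            class = "bn_attractor")
}

#' @export
print.bn_attractor <- function(x, ...) {
  kind <- if (x$length == 1) "fixed point" else sprintf("%d-cycle", x$length)
  cat(sprintf("<bn_attractor> %s, basin %.4g\n", kind, x$basin))
  print(x$states)
  invisible(x)
}

#' Deterministic descent to an attractor
#'
#' Iterates noise-free synchronous steps from `state` until a state repeats,
#' returning the attractor (in canonical form) and the number of pre-cycle
#' steps.
#'
#' @param model A `boolean_model`.
#' @param state Starting 0/1 state vector.
#' @param env Named binary input levels.
#' @param clamps Binary-level [clamp_policy()] (levels exactly 0 or 1).
#' @param max_steps Step cap; exceeding it signals an implementation bug
#'   (the state space of n nodes cannot exceed 2^n).
#' @return A list with `attractor` (a `bn_attractor`) and `transient`
#'   (integer).
#' @export
descend_to_attractor <- function(model, state, env = NULL, clamps = NULL,
                                 max_steps = 1e6) {
  stopifnot(inherits(model, "boolean_model"))
  env <- check_binary_env(model, env)
  clamps <- check_binary_clamps(model, clamps)
  state <- check_state(model, state)
  M <- matrix(state, nrow = 1, dimnames = list(NULL, model$nodes))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  path <- matrix(0L, nrow = 64L, ncol = length(model$nodes),
                 dimnames = list(NULL, model$nodes))
  t <- 0L
  repeat {
    key <- state_keys(M)
    hit <- seen[[key]]
    if (!is.null(hit)) {
      cycle <- path[seq(hit, t), , drop = FALSE]
      return(list(attractor = new_attractor(cycle), transient = hit - 1L))
    }
    t <- t + 1L
    if (t > max_steps) {
      stop("descent exceeded the step cap; this should be impossible for a ",
           "finite deterministic system and signals a bug", call. = FALSE)
    }
    if (t > nrow(path)) {
      path <- rbind(path, matrix(0L, nrow = nrow(path), ncol = ncol(path)))
    }
    seen[[key]] <- t
    path[t, ] <- M[1, ]
    M <- step_matrix(model, M, env, clamps, p = 0)
  }
}

# --- exhaustive machinery over the free-node hypercube -----------------------

# integer state index (0-based) <-> free-node bit matrix; bit j of the index
# is the j-th free node in model order
decode_free <- function(idx0, n_free) {
  M <- matrix(0L, nrow = length(idx0), ncol = n_free)
  for (j in seq_len(n_free)) {
    M[, j] <- as.integer((idx0 %/% 2^(j - 1)) %% 2)
  }
  M
}

encode_free <- function(M) {
  as.numeric(M %*% 2^(seq_len(ncol(M)) - 1))
}

# successor table over the 2^f free states (0-based indices), computed by
# vectorised stepping in chunks
successor_table <- function(model, env, clamps, free, chunk = 2^14) {
  f <- length(free)
  S <- 2^f
  base <- base_state(model, env, clamps)
  succ <- numeric(S)
  done <- 0
  while (done < S) {
    take <- min(chunk, S - done)
    idx0 <- seq(done, done + take - 1)
    M <- matrix(rep(base, each = take), nrow = take,
                dimnames = list(NULL, model$nodes))
    M[, free] <- decode_free(idx0, f)
    nxt <- step_matrix(model, M, env, clamps, p = 0)
    succ[idx0 + 1] <- encode_free(nxt[, free, drop = FALSE])
    done <- done + take
  }
  succ
}

# attractors of a functional graph given by a 0-based successor table;
# returns attr_of (1-based id per state) and cycles (list of 0-based index
# vectors in cycle order)
functional_graph_attractors <- function(succ) {
  S <- length(succ)
  attr_of <- integer(S)
  cycles <- list()
  for (s0 in seq_len(S)) {
    if (attr_of[s0] != 0L) next
    path <- integer(0)
    cur <- s0
    while (attr_of[cur] == 0L) {
      attr_of[cur] <- -1L
      path <- c(path, cur)
      cur <- as.integer(succ[cur]) + 1L
    }
    if (attr_of[cur] == -1L) {
      pos <- match(cur, path)
      cyc <- path[seq(pos, length(path))]
      cycles[[length(cycles) + 1L]] <- cyc - 1L
      id <- length(cycles)
    } else {
      id <- attr_of[cur]
    }
    attr_of[path] <- id
  }
  list(attr_of = attr_of, cycles = cycles)
}

expand_free_states <- function(model, env, clamps, free, idx0) {
  base <- base_state(model, env, clamps)
  M <- matrix(rep(base, each = length(idx0)), nrow = length(idx0),
              dimnames = list(NULL, model$nodes))
  M[, free] <- decode_free(idx0, length(free))
  M
}

#' Exhaustive attractor enumeration with exact basin weights
#'
#' Descends from every state of the free-node hypercube (non-input,
#' non-hard-clamped nodes); basin weight = basin size / 2^(free nodes).
#' The brute-force oracle backing the stochastic sampling procedure.
#'
#' @inheritParams descend_to_attractor
#' @param max_free Cap on the number of free nodes (default 22); above it an
#'   error directs the caller to [sample_attractors()].
#' @return A `bn_attractor_set`: list with `attractors` (list of
#'   `bn_attractor`, basins summing to 1), `env`, `method`, `n_states`.
#' @export
enumerate_attractors <- function(model, env = NULL, clamps = NULL,
                                 max_free = 22) {
  stopifnot(inherits(model, "boolean_model"))
  env <- check_binary_env(model, env)
  clamps <- check_binary_clamps(model, clamps)
  free <- free_nodes(model, clamps)
  f <- length(free)
  if (f > max_free) {
    stop(sprintf(paste0("%d free nodes exceed the enumeration cap of %d; ",
                        "use sample_attractors() for large networks"),
                 f, max_free), call. = FALSE)
  }
  succ <- successor_table(model, env, clamps, free)
  fg <- functional_graph_attractors(succ)
  sizes <- tabulate(fg$attr_of, nbins = length(fg$cycles))
  attractors <- lapply(seq_along(fg$cycles), function(i) {
    states <- expand_free_states(model, env, clamps, free, fg$cycles[[i]])
    new_attractor(states, basin = sizes[[i]] / length(succ))
  })
  ord <- order(-vapply(attractors, `[[`, numeric(1), "basin"),
               vapply(attractors, `[[`, character(1), "key"))
  structure(list(attractors = attractors[ord], env = env,
                 clamps = clamps, method = "enumerate",
                 n_states = length(succ)),
            class = "bn_attractor_set")
}

#' @export
print.bn_attractor_set <- function(x, ...) {
  cat(sprintf("<bn_attractor_set> %s: %d attractor(s) over %s states\n",
              x$method, length(x$attractors), format(x$n_states, big.mark = ",")))
  env_str <- paste(sprintf("%s=%g", names(x$env), x$env), collapse = ", ")
  if (nzchar(env_str)) cat("  environment:", env_str, "\n")
  for (a in x$attractors) {
    kind <- if (a$length == 1) "fixed point" else sprintf("%d-cycle", a$length)
    cat(sprintf("  %s, basin %.4f\n", kind, a$basin))
  }
  invisible(x)
}

#' Sampling configuration for stochastic attractor detection
#'
#' Defaults follow the standard protocol: noisy time courses of length
#' `T = 25` with flip noise `p = 0.02` from `N = 100` random initial
#' conditions per environment (every binary combination of the declared
#' inputs unless `environments` is supplied).
#'
#' @param T_steps Time-course length (number of visited states per
#'   trajectory, counting the initial condition).
#' @param p Flip noise probability.
#' @param N Random initial conditions per environment.
#' @param environments Optional tibble/data frame, one row per environment,
#'   columns = input names with binary values. Default: all 2^k combinations.
#' @return A `sampling_config` list.
#' @export
sampling_config <- function(T_steps = 25, p = 0.02, N = 100,
                            environments = NULL) {
  stopifnot(T_steps >= 1, N >= 1, p >= 0, p <= 1)
  structure(list(T_steps = as.integer(T_steps), p = p, N = as.integer(N),
                 environments = environments),
            class = "sampling_config")
}

all_binary_environments <- function(model) {
  k <- length(model$inputs)
  if (k == 0) return(tibble::tibble(.rows = 1))
  grid <- expand.grid(rep(list(c(0L, 1L)), k), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- model$inputs
  tibble::as_tibble(grid)
}

env_from_row <- function(model, env_tbl, i) {
  if (ncol(env_tbl) == 0) return(check_env(model, NULL))
  check_env(model, unlist(env_tbl[i, , drop = FALSE]))
}

#' Stochastic attractor sampling across environments
#'
#' For each environment, runs `N` noisy trajectories of length `T` with flip
#' noise `p` from uniform-random free-node initial conditions (inputs held at
#' their binary environment values), then descends every visited state
#' deterministically (noise off). Attractors are deduplicated by canonical
#' form. Each carries two basin estimates: `basin`, the fraction of all
#' visited states descending to it (noisy time courses over-sample the
#' neighbourhood of attractors, so this estimates a noise-tilted occupancy
#' measure), and `initial_basin`, the fraction of the `N` uniform-random
#' initial conditions, an unbiased estimator of the deterministic basin
#' weight reported by [enumerate_attractors()]. Reproducible for a fixed
#' seed.
#'
#' @param model A `boolean_model`.
#' @param config A [sampling_config()].
#' @param clamps Optional binary-level clamps held throughout.
#' @param seed Integer seed.
#' @return A `bn_attractor_landscape`: list of per-environment
#'   `bn_attractor_set`s plus `environments` and `n_initial_total`
#'   (`N` times the number of environments).
#' @export
sample_attractors <- function(model, config = sampling_config(),
                              clamps = NULL, seed = 1) {
  stopifnot(inherits(model, "boolean_model"),
            inherits(config, "sampling_config"))
  clamps <- check_binary_clamps(model, clamps)
  env_tbl <- config$environments
  if (is.null(env_tbl)) env_tbl <- all_binary_environments(model)
  env_tbl <- tibble::as_tibble(env_tbl)
  free <- free_nodes(model, clamps)
  f <- length(free)
  n_env <- nrow(env_tbl)

  run <- function() {
    sets <- vector("list", n_env)
    for (ei in seq_len(n_env)) {
      env <- env_from_row(model, env_tbl, ei)
      base <- base_state(model, env, clamps)
      M <- matrix(rep(base, each = config$N), nrow = config$N,
                  dimnames = list(NULL, model$nodes))
      M[, free] <- matrix(as.integer(stats::runif(config$N * f) < 0.5),
                          nrow = config$N)
      visited <- matrix(0L, nrow = config$N * config$T_steps,
                        ncol = length(model$nodes),
                        dimnames = list(NULL, model$nodes))
      visited[seq_len(config$N), ] <- M
      for (t in seq_len(config$T_steps - 1L)) {
        M <- step_matrix(model, M, env, clamps, p = config$p)
        visited[t * config$N + seq_len(config$N), ] <- M
      }
      sets[[ei]] <- descend_visited(model, env, clamps, free, visited,
                                    n_init = config$N)
    }
    structure(list(sets = sets, environments = env_tbl,
                   config = config, seed = seed,
                   n_initial_total = config$N * n_env),
              class = "bn_attractor_landscape")
  }
  withr::with_seed(seed, run())
}

# Map every visited state to its attractor. Two basin estimates are kept:
# `basin` = fraction of all visited states (the sampling protocol's reading
# of "for each observed state ... the attractor basin is determined"), which
# estimates the noise-tilted occupancy measure; and `initial_basin` =
# fraction of the N uniform-random initial conditions, an unbiased estimator
# of the deterministic basin weight (comparable to enumeration).
descend_visited <- function(model, env, clamps, free, visited,
                            n_init = nrow(visited), succ_cap = 16) {
  keys <- state_keys(visited)
  tab <- table(keys)
  uniq_keys <- names(tab)
  counts <- as.numeric(tab)
  first_row <- match(uniq_keys, keys)
  f <- length(free)

  if (f <= succ_cap) {
    succ <- successor_table(model, env, clamps, free)
    fg <- functional_graph_attractors(succ)
    idx1 <- encode_free(visited[first_row, free, drop = FALSE]) + 1
    ids <- fg$attr_of[idx1]
    init_ids <- ids[match(keys[seq_len(n_init)], uniq_keys)]
    hit <- sort(unique(ids))
    attractors <- lapply(hit, function(i) {
      states <- expand_free_states(model, env, clamps, free, fg$cycles[[i]])
      a <- new_attractor(states,
                         basin = sum(counts[ids == i]) / length(keys))
      a$initial_basin <- mean(init_ids == i)
      a
    })
  } else {
    memo <- new.env(hash = TRUE, parent = emptyenv())
    attr_list <- list()
    ids <- integer(length(uniq_keys))
    for (u in seq_along(uniq_keys)) {
      st <- visited[first_row[[u]], ]
      path_keys <- character(0)
      M <- matrix(st, nrow = 1, dimnames = list(NULL, model$nodes))
      id <- NULL
      repeat {
        key <- state_keys(M)
        cached <- memo[[key]]
        if (!is.null(cached)) { id <- cached; break }
        path_keys <- c(path_keys, key)
        dup <- match(key, path_keys[-length(path_keys)])
        if (!is.na(dup)) {
          # new cycle discovered within this walk
          res <- descend_to_attractor(model, st, env, clamps)
          a <- res$attractor
          prev <- match(a$key, vapply(attr_list, `[[`, character(1), "key"))
          if (is.na(prev)) {
            attr_list[[length(attr_list) + 1L]] <- a
            id <- length(attr_list)
          } else id <- prev
          break
        }
        M <- step_matrix(model, M, env, clamps, p = 0)
      }
      if (is.null(id)) {
        res <- descend_to_attractor(model, st, env, clamps)
        a <- res$attractor
        prev <- match(a$key, vapply(attr_list, `[[`, character(1), "key"))
        if (is.na(prev)) {
          attr_list[[length(attr_list) + 1L]] <- a
          id <- length(attr_list)
        } else id <- prev
      }
      for (k in path_keys) memo[[k]] <- id
      ids[[u]] <- id
    }
    init_ids <- ids[match(keys[seq_len(n_init)], uniq_keys)]
    attractors <- lapply(seq_along(attr_list), function(i) {
      a <- attr_list[[i]]
      a$basin <- sum(counts[ids == i]) / length(keys)
      a$initial_basin <- mean(init_ids == i)
      a
    })
  }
  ord <- order(-vapply(attractors, `[[`, numeric(1), "basin"),
               vapply(attractors, `[[`, character(1), "key"))
  structure(list(attractors = attractors[ord], env = env, clamps = clamps,
                 method = "sample", n_states = length(keys)),
            class = "bn_attractor_set")
}

#' @export
print.bn_attractor_landscape <- function(x, ...) {
  cat(sprintf(paste0("<bn_attractor_landscape> %d environment(s), ",
                     "%d initial conditions in total\n"),
              nrow(x$environments), x$n_initial_total))
  for (s in x$sets) print(s)
  invisible(x)
}

#' Enumerate attractors across a set of environments
#'
#' Runs [enumerate_attractors()] for every row of `environments` (default:
#' all binary input combinations).
#'
#' @inheritParams sample_attractors
#' @param environments Tibble of binary input levels, one row per
#'   environment.
#' @param max_free Passed to [enumerate_attractors()].
#' @return A `bn_attractor_landscape` with `method = "enumerate"` sets.
#' @export
enumerate_attractor_landscape <- function(model, environments = NULL,
                                          clamps = NULL, max_free = 22) {
  if (is.null(environments)) environments <- all_binary_environments(model)
  environments <- tibble::as_tibble(environments)
  sets <- lapply(seq_len(nrow(environments)), function(i) {
    enumerate_attractors(model, env_from_row(model, environments, i),
                         clamps = clamps, max_free = max_free)
  })
  structure(list(sets = sets, environments = environments, config = NULL,
                 seed = NULL, n_initial_total = NA_integer_),
            class = "bn_attractor_landscape")
}

#' Long-format attractor table
#'
#' One row per (environment, attractor, cycle position): environment input
#' levels, attractor id, cycle length, cycle position, one column per node,
#' and basin weight. Ordering is deterministic (environments in given order;
#' attractors by descending basin weight, ties by canonical key).
#'
#' @param x A `bn_attractor_set` or `bn_attractor_landscape`.
#' @return A tibble.
#' @export
attractor_table <- function(x) {
  if (inherits(x, "bn_attractor_set")) {
    x <- structure(list(sets = list(x),
                        environments = tibble::as_tibble(as.list(x$env))),
                   class = "bn_attractor_landscape")
  }
  stopifnot(inherits(x, "bn_attractor_landscape"))
  rows <- list()
  for (ei in seq_along(x$sets)) {
    set <- x$sets[[ei]]
    env_cols <- tibble::as_tibble(as.list(set$env))
    for (ai in seq_along(set$attractors)) {
      a <- set$attractors[[ai]]
      st <- tibble::as_tibble(a$states)
      block <- dplyr::bind_cols(
        env_cols[rep(1, a$length), , drop = FALSE],
        tibble::tibble(attractor_id = sprintf("env%d_a%d", ei, ai),
                       cycle_length = a$length,
                       cycle_position = seq_len(a$length)),
        st,
        tibble::tibble(basin_weight = a$basin))
      rows[[length(rows) + 1L]] <- block
    }
  }
  dplyr::bind_rows(rows)
}

#' Write / read an attractor table as CSV
#'
#' @param x A `bn_attractor_set` or `bn_attractor_landscape` (or the tibble
#'   from [attractor_table()]).
#' @param path Output CSV path.
#' @return `write_attractor_table()` returns the table invisibly;
#'   `read_attractor_table()` returns the tibble.
#' @export
write_attractor_table <- function(x, path) {
  tbl <- if (inherits(x, "data.frame")) x else attractor_table(x)
  if (nrow(tbl) == 0) stop("attractor table is empty", call. = FALSE)
  readr::write_csv(tbl, path)
  invisible(tbl)
}

#' @rdname write_attractor_table
#' @export
read_attractor_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
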