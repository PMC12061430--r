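#' @title Synchronous update engine
#' @description Deterministic synchronous Boolean update plus the stochastic
#'   layers used throughout: per-node flip noise, per-step Bernoulli clamping
#'   (partial knockdown / hyper-activation), and non-saturating environmental
#'   inputs.
#'
#' One update step applies, in order:
#' \enumerate{
#'   \item every non-input node's rule, evaluated on the previous state
#'     simultaneously;
#'   \item each environmental input resampled as Bernoulli(level);
#'   \item each clamped node overridden to its forced value with probability
#'     `q` (else it keeps its rule/input value);
#'   \item each non-input, non-clamped node flipped with probability `p`.
#' }
#' With `p = 0`, all input levels in \{0, 1\} and all clamp levels in
#' \{0, 1\}, the step is deterministic. Probability-0 and probability-1 events
#' consume no random draws, so deterministic runs are seed-independent.
#' @name engine
NULL

#' Clamp policies
#'
#' A clamp forces a node towards ON or OFF with per-step probability
#' `level` (`q`). `q = 1` is a hard knockout / constitutive activation;
#' `0 < q < 1` models a partial knockdown or hyper-activation re-drawn
#' independently every step.
#'
#' @param ... Named arguments, one per clamped node, each created by
#'   [clamp_on()] or [clamp_off()].
#' @return A named `clamp_policy` list.
#' @export
#' @examples
#' clamp_policy(VHL = clamp_off(), TGFb_secr = clamp_off(0.05))
clamp_policy <- function(...) {
  cl <- list(...)
  if (length(cl) == 0) return(structure(list(), class = "clamp_policy"))
  if (is.null(names(cl)) || any(names(cl) == "")) {
    stop("every clamp must be named by its target node", call. = FALSE)
  }
  if (anyDuplicated(names(cl))) {
    stop("a node has more than one clamp", call. = FALSE)
  }
  ok <- vapply(cl, function(x) {
    is.list(x) && x$mode %in% c("on", "off") &&
      is.numeric(x$level) && x$level >= 0 && x$level <= 1
  }, logical(1))
  if (!all(ok)) stop("clamps must be built with clamp_on()/clamp_off()",
                     call. = FALSE)
  structure(cl, class = "clamp_policy")
}

#' @rdname clamp_policy
#' @param level Per-step probability `q` in \[0, 1\] that the forced value is
#'   applied.
#' @export
clamp_on <- function(level = 1) list(mode = "on", level = level)

#' @rdname clamp_policy
#' @export
clamp_off <- function(level = 1) list(mode = "off", level = level)

check_clamps <- function(model, clamps) {
  if (is.null(clamps)) return(structure(list(), class = "clamp_policy"))
  if (!inherits(clamps, "clamp_policy")) clamps <- do.call(clamp_policy, clamps)
  unknown <- setdiff(names(clamps), model$nodes)
  if (length(unknown) > 0) {
    stop("clamp on unknown node: ", unknown[[1]], call. = FALSE)
  }
  clamps
}

# Environment assignment: named numeric vector, input -> level in [0,1].
# Unlisted inputs default to 0 (always OFF).
check_env <- function(model, env) {
  levels <- stats::setNames(numeric(length(model$inputs)), model$inputs)
  if (length(env) > 0) {
    if (is.list(env)) env <- unlist(env)
    unknown <- setdiff(names(env), model$inputs)
    if (length(unknown) > 0) {
      stop("environment sets non-input node: ", unknown[[1]], call. = FALSE)
    }
    if (any(env < 0 | env > 1)) {
      stop("input levels must lie in [0, 1]", call. = FALSE)
    }
    levels[names(env)] <- env
  }
  levels
}

check_state <- function(model, state) {
  n <- length(model$nodes)
  if (length(state) != n) {
    stop(sprintf("state has length %d but model has %d nodes",
                 length(state), n), call. = FALSE)
  }
  if (!all(state %in% c(0L, 1L))) stop("state values must be 0/1", call. = FALSE)
  state <- as.integer(state)
  names(state) <- model$nodes
  state
}

# Build a full-length named state from a partial named assignment (rest 0).
make_state <- function(model, ...) {
  vals <- c(...)
  state <- stats::setNames(integer(length(model$nodes)), model$nodes)
  if (length(vals) > 0) {
    unknown <- setdiff(names(vals), model$nodes)
    if (length(unknown) > 0) stop("unknown node: ", unknown[[1]], call. = FALSE)
    state[names(vals)] <- as.integer(vals)
  }
  state
}

rbern_vec <- function(n, prob) {
  if (prob <= 0) return(rep(FALSE, n))
  if (prob >= 1) return(rep(TRUE, n))
  stats::runif(n) < prob
}

# Core vectorised step: M is an integer 0/1 matrix, rows = cells (parallel
# states), columns = model nodes in order. Returns the updated matrix.
step_matrix <- function(model, M, env, clamps, p = 0) {
  n_cells <- nrow(M)
  nodes <- model$nodes
  vals <- lapply(seq_along(nodes), function(j) M[, j] == 1L)
  names(vals) <- nodes

  nxt <- M
  for (nd in names(model$rules)) {
    nxt[, nd] <- as.integer(eval(model$rules[[nd]], vals))
  }
  for (nd in model$inputs) {
    lv <- env[[nd]]
    if (lv <= 0) nxt[, nd] <- 0L
    else if (lv >= 1) nxt[, nd] <- 1L
    else nxt[, nd] <- as.integer(stats::runif(n_cells) < lv)
  }
  for (nd in names(clamps)) {
    cl <- clamps[[nd]]
    if (cl$level <= 0) next
    forced <- if (cl$mode == "on") 1L else 0L
    if (cl$level >= 1) {
      nxt[, nd] <- forced
    } else {
      hit <- rbern_vec(n_cells, cl$level)
      nxt[hit, nd] <- forced
    }
  }
  if (p > 0) {
    free <- setdiff(setdiff(nodes, model$inputs), names(clamps))
    if (length(free) > 0) {
      flips <- matrix(stats::runif(n_cells * length(free)) < p,
                      nrow = n_cells)
      sub <- nxt[, free, drop = FALSE]
      sub[flips] <- 1L - sub[flips]
      nxt[, free] <- sub
    }
  }
  nxt
}

#' One synchronous update step
#'
#' @param model A `boolean_model`.
#' @param state Integer 0/1 state vector in model node order (named or not).
#' @param env Named numeric vector of input levels in \[0, 1\]; unlisted
#'   inputs default to 0.
#' @param clamps A [clamp_policy()] (or `NULL`).
#' @param p Per-node flip probability for non-input, non-clamped nodes.
#' @return The next state as a named integer vector.
#' @export
#' @examples
#' m <- emt_switch_fixture()
#' epi <- c(EMT_signal = 0, SNAI1 = 0, miR34 = 1, ZEB1 = 0, miR200 = 1,
#'          Ecadherin = 1)
#' synchronous_step(m, epi[m$nodes])
synchronous_step <- function(model, state, env = NULL, clamps = NULL, p = 0) {
  stopifnot(inherits(model, "boolean_model"))
  state <- check_state(model, state)
  env <- check_env(model, env)
  clamps <- check_clamps(model, clamps)
  M <- matrix(state, nrow = 1, dimnames = list(NULL, model$nodes))
  drop_state(step_matrix(model, M, env, clamps, p))
}

drop_state <- function(M) {
  stats::setNames(as.integer(M[1, ]), colnames(M))
}

#' Define one simulation window
#'
#' @param steps Positive number of update steps.
#' @param env Named input levels for the window.
#' @param clamps A [clamp_policy()] active during the window.
#' @param noise Flip probability `p` for the window.
#' @return A `sim_window` list.
#' @export
sim_window <- function(steps, env = NULL, clamps = NULL, noise = 0) {
  if (!is.numeric(steps) || steps < 1) {
    stop("window length must be a positive number of steps", call. = FALSE)
  }
  structure(list(steps = as.integer(steps), env = env, clamps = clamps,
                 noise = noise),
            class = "sim_window")
}

#' Simulate a single-cell trajectory over a window schedule
#'
#' Runs the synchronous engine through an ordered sequence of time windows,
#' each with its own environment, clamp policy and noise level. Bit-exact
#' reproducible for a fixed seed; with `noise = 0` and saturating levels the
#' trajectory is identical across seeds.
#'
#' @param model A `boolean_model`.
#' @param initial Initial 0/1 state vector.
#' @param schedule A list of [sim_window()]s (a single window is accepted).
#' @param seed Optional integer seed.
#' @return A `bn_trajectory`: list with `states` (matrix, one row per time
#'   point including the initial state), `window` (window index per row, 0 for
#'   the initial state), `model`, `schedule`, `seed`.
#' @export
simulate_trajectory <- function(model, initial, schedule, seed = NULL) {
  stopifnot(inherits(model, "boolean_model"))
  if (inherits(schedule, "sim_window")) schedule <- list(schedule)
  initial <- check_state(model, initial)
  run <- function() {
    total <- sum(vapply(schedule, `[[`, integer(1), "steps"))
    states <- matrix(0L, nrow = total + 1L, ncol = length(model$nodes),
                     dimnames = list(NULL, model$nodes))
    win_of <- integer(total + 1L)
    states[1, ] <- initial
    M <- matrix(initial, nrow = 1, dimnames = list(NULL, model$nodes))
    row <- 1L
    for (w in seq_along(schedule)) {
      win <- schedule[[w]]
      env <- check_env(model, win$env)
      cl <- check_clamps(model, win$clamps)
      for (s in seq_len(win$steps)) {
        M <- step_matrix(model, M, env, cl, win$noise)
        row <- row + 1L
        states[row, ] <- M[1, ]
        win_of[row] <- w
      }
    }
    structure(list(states = states, window = win_of, model = model$name,
                   schedule = schedule, seed = seed),
              class = "bn_trajectory")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.bn_trajectory <- function(x, ...) {
  cat(sprintf("<bn_trajectory> model %s: %d time points, %d nodes, %d window(s)\n",
              x$model, nrow(x$states), ncol(x$states), max(x$window)))
  invisible(x)
}

#' Tidy a trajectory into long format
#'
#' @param x A `bn_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `step` (0 = initial state), `window`,
#'   `node`, `value`.
#' @export
as_tibble.bn_trajectory <- function(x, ...) {
  tibble::as_tibble(x$states) |>
    dplyr::mutate(step = dplyr::row_number() - 1L, window = x$window) |>
    tidyr::pivot_longer(cols = -c("step", "window"),
                        names_to = "node", values_to = "value") |>
    dplyr::mutate(node = factor(.data$node, levels = colnames(x$states)))
}
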