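#' @title Experiment protocols
#' @description Declare and run windowed experiment patterns over cell
#'   ensembles: pulse sequences, dose series, environment grids and mutation
#'   backgrounds, with apoptosis-aware live-time accounting. Two run modes:
#'   \itemize{
#'     \item fixed mode (no budget): every cell runs the whole window
#'       schedule once; all steps count.
#'     \item continuous mode (`budget` set): the schedule repeats and a cell
#'       whose state matches the death signature is terminated and replaced
#'       by a fresh cell started from the initial condition, until the total
#'       live-step budget is consumed. The step on which death is detected is
#'       the cell's last live step.
#'   }
#' @name protocols
NULL

#' Build an experiment specification
#'
#' @param model A `boolean_model` (or fixture name / file path).
#' @param initial Either an explicit 0/1 state vector or a phenotype name to
#'   be resolved via [resolve_initial_state()] in `initial_env`.
#' @param windows List of [sim_window()]s.
#' @param initial_env Environment used to resolve a named initial phenotype.
#' @param ensemble Number of parallel cells.
#' @param budget Total live-step budget; `NULL` selects fixed mode.
#' @param seed Master seed.
#' @param signatures A `bn_signatures` set (phenotype statistics; required
#'   when `initial` or `death` is a phenotype name).
#' @param death Death signature: a phenotype name present in `signatures`
#'   (e.g. `"Apoptotic"`) or a named 0/1 vector of required node states.
#'   Only acted on in continuous mode.
#' @param name Optional label.
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(model, initial, windows, initial_env = NULL,
                            ensemble = 100, budget = NULL, seed = 1,
                            signatures = NULL, death = NULL, name = "") {
  model <- as_boolean_model(model)
  if (inherits(windows, "sim_window")) windows <- list(windows)
  if (length(windows) == 0) stop("windows must be non-empty", call. = FALSE)
  stopifnot(all(vapply(windows, inherits, logical(1), "sim_window")))
  if (!is.null(signatures)) validate_signatures(signatures, model)
  if (is.character(initial) && length(initial) == 1 && is.null(names(initial))) {
    if (is.null(signatures)) {
      stop("a named initial phenotype requires a signature set", call. = FALSE)
    }
    initial <- resolve_initial_state(model, initial, env = initial_env,
                                     signatures = signatures)
  } else {
    initial <- check_state(model, initial)
  }
  total <- sum(vapply(windows, `[[`, integer(1), "steps"))
  if (!is.null(budget) && budget < ensemble * windows[[1]]$steps) {
    stop("live-step budget is exhausted before the first window completes ",
         "for every cell; increase the budget", call. = FALSE)
  }
  structure(list(model = model, initial = initial, windows = windows,
                 ensemble = as.integer(ensemble),
                 budget = if (is.null(budget)) NULL else as.integer(budget),
                 seed = seed, signatures = signatures, death = death,
                 total_steps = total, name = name),
            class = "experiment_spec")
}

death_requirement <- function(spec) {
  d <- spec$death
  if (is.null(d)) return(NULL)
  if (is.character(d) && length(d) == 1 && is.null(names(d))) {
    row <- which(spec$signatures$phenotype == d)
    if (length(row) != 1) {
      stop("death phenotype '", d, "' not found (once) in the signature set",
           call. = FALSE)
    }
    return(spec$signatures$requires[[row]])
  }
  vapply(d, as.integer, integer(1))
}

#' Resolve an initial state from a named phenotype
#'
#' Enumerates (or, above the free-node cap, samples) the attractors of the
#' model in the given environment and returns a state of the unique
#' attractor whose phenotype profile contains the requested phenotype. For
#' cyclic attractors the canonical first state is returned.
#'
#' @param model A `boolean_model`.
#' @param phenotype Phenotype name defined in `signatures`.
#' @param env Named binary input levels.
#' @param signatures A `bn_signatures` set.
#' @param clamps Optional binary clamps.
#' @param max_free Enumeration cap; larger models fall back to sampling.
#' @param seed Seed for the sampling fallback.
#' @return A named 0/1 state vector.
#' @export
resolve_initial_state <- function(model, phenotype, env = NULL, signatures,
                                  clamps = NULL, max_free = 22, seed = 1) {
  stopifnot(inherits(model, "boolean_model"))
  validate_signatures(signatures, model)
  if (!phenotype %in% signatures$phenotype) {
    stop("phenotype '", phenotype, "' is not defined in the signature set",
         call. = FALSE)
  }
  n_free <- length(free_nodes(model, check_binary_clamps(model, clamps)))
  set <- if (n_free <= max_free) {
    enumerate_attractors(model, env, clamps, max_free = max_free)
  } else {
    env_row <- tibble::as_tibble(as.list(check_binary_env(model, env)))
    sample_attractors(model,
                      sampling_config(environments = env_row),
                      clamps = clamps, seed = seed)$sets[[1]]
  }
  profiles <- lapply(set$attractors, classify_attractor, signatures)
  hits <- which(vapply(profiles, function(p) phenotype %in% p, logical(1)))
  if (length(hits) == 0) {
    stop("no attractor matching phenotype '", phenotype,
         "' in this environment", call. = FALSE)
  }
  if (length(hits) > 1) {
    descr <- vapply(hits, function(i) {
      paste0("#", i, " (", paste(profiles[[i]], collapse = "/"), ")")
    }, character(1))
    stop("multiple attractors match phenotype '", phenotype, "': ",
         paste(descr, collapse = ", "), call. = FALSE)
  }
  st <- set$attractors[[hits]]$states[1, ]
  stats::setNames(as.integer(st), model$nodes)
}

# accumulators shared by both run modes
new_accumulators <- function(spec) {
  n_win <- length(spec$windows)
  n_nodes <- length(spec$model$nodes)
  list(
    node_sums = matrix(0, nrow = n_win, ncol = n_nodes,
                       dimnames = list(NULL, spec$model$nodes)),
    steps = numeric(n_win),
    phen_counts = NULL,  # built lazily: window x module x phenotype
    cell_node_sums = lapply(seq_len(n_win), function(i) {
      matrix(0, nrow = spec$ensemble, ncol = n_nodes,
             dimnames = list(NULL, spec$model$nodes))
    }),
    cell_steps = matrix(0, nrow = spec$ensemble, ncol = n_win))
}

phen_levels_by_module <- function(signatures) {
  mods <- unique(signatures$module)
  stats::setNames(lapply(mods, function(m) {
    c(signatures$phenotype[signatures$module == m], "unclassified")
  }), mods)
}

accumulate_step <- function(acc, spec, M, w, weight_rows = NULL) {
  # weight_rows: optional subset of rows counted (budget trimming)
  if (!is.null(weight_rows)) M <- M[weight_rows, , drop = FALSE]
  acc$node_sums[w, ] <- acc$node_sums[w, ] + colSums(M)
  acc$steps[[w]] <- acc$steps[[w]] + nrow(M)
  if (!is.null(spec$signatures)) {
    cls <- classify_states_matrix(M, spec$signatures)
    if (is.null(acc$phen_counts)) {
      lvls <- phen_levels_by_module(spec$signatures)
      acc$phen_counts <- lapply(lvls, function(ph) {
        matrix(0, nrow = length(spec$windows), ncol = length(ph),
               dimnames = list(NULL, ph))
      })
    }
    for (mod in colnames(cls)) {
      tb <- table(factor(cls[, mod],
                         levels = colnames(acc$phen_counts[[mod]])))
      acc$phen_counts[[mod]][w, ] <- acc$phen_counts[[mod]][w, ] + tb
    }
  }
  if (is.null(weight_rows)) {
    acc$cell_node_sums[[w]] <- acc$cell_node_sums[[w]] + M
    acc$cell_steps[, w] <- acc$cell_steps[, w] + 1
  }
  acc
}

finalize_result <- function(acc, spec, deaths, restarts, live_steps,
                            states = NULL) {
  n_win <- length(spec$windows)
  node_means <- tibble::as_tibble(acc$node_sums / acc$steps) |>
    dplyr::mutate(window = seq_len(n_win), .before = 1) |>
    tidyr::pivot_longer(cols = -"window", names_to = "node",
                        values_to = "mean_activity")
  phen <- NULL
  if (!is.null(acc$phen_counts)) {
    phen <- dplyr::bind_rows(lapply(names(acc$phen_counts), function(mod) {
      m <- acc$phen_counts[[mod]]
      tibble::tibble(window = rep(seq_len(n_win), times = ncol(m)),
                     module = mod,
                     phenotype = rep(colnames(m), each = n_win),
                     fraction = as.vector(m / acc$steps))
    })) |> dplyr::arrange(.data$window, .data$module)
  }
  cell_means <- lapply(seq_len(n_win), function(w) {
    acc$cell_node_sums[[w]] / pmax(acc$cell_steps[, w], 1)
  })
  structure(list(name = spec$name, model = spec$model$name,
                 phenotype_fractions = phen, node_means = node_means,
                 cell_window_means = cell_means,
                 deaths = deaths, restarts = restarts,
                 live_steps = live_steps, ensemble = spec$ensemble,
                 windows = spec$windows, seed = spec$seed,
                 states = states),
            class = "bn_ensemble")
}

#' Run an ensemble experiment
#'
#' @param spec An [experiment_spec()].
#' @param keep_states Keep the full state history (fixed mode only; an array
#'   cells x nodes x time needed by [count_divisions()]).
#' @return A `bn_ensemble`: tibbles `phenotype_fractions` (`window`,
#'   `module`, `phenotype`, `fraction`) and `node_means`, per-cell
#'   per-window mean activities (`cell_window_means`), death/restart counts
#'   and total `live_steps`. Bit-exact reproducible for a fixed seed.
#' @export
run_experiment <- function(spec, keep_states = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  run <- function() {
    if (is.null(spec$budget)) run_fixed(spec, keep_states)
    else run_continuous(spec)
  }
  withr::with_seed(as.integer(spec$seed), run())
}

run_fixed <- function(spec, keep_states) {
  model <- spec$model
  E <- spec$ensemble
  M <- matrix(rep(spec$initial, each = E), nrow = E,
              dimnames = list(NULL, model$nodes))
  acc <- new_accumulators(spec)
  states <- NULL
  if (keep_states) {
    states <- array(0L, dim = c(E, length(model$nodes), spec$total_steps + 1L),
                    dimnames = list(NULL, model$nodes, NULL))
    states[, , 1] <- M
  }
  t <- 1L
  for (w in seq_along(spec$windows)) {
    win <- spec$windows[[w]]
    env <- check_env(model, win$env)
    cl <- check_clamps(model, win$clamps)
    for (s in seq_len(win$steps)) {
      M <- step_matrix(model, M, env, cl, win$noise)
      t <- t + 1L
      if (keep_states) states[, , t] <- M
      acc <- accumulate_step(acc, spec, M, w)
    }
  }
  finalize_result(acc, spec, deaths = 0L, restarts = 0L,
                  live_steps = E * spec$total_steps, states = states)
}

run_continuous <- function(spec) {
  model <- spec$model
  E <- spec$ensemble
  death_req <- death_requirement(spec)
  M <- matrix(rep(spec$initial, each = E), nrow = E,
              dimnames = list(NULL, model$nodes))
  acc <- new_accumulators(spec)
  consumed <- 0L
  deaths <- 0L
  restarts <- 0L
  envs <- lapply(spec$windows, function(w) check_env(model, w$env))
  cls <- lapply(spec$windows, function(w) check_clamps(model, w$clamps))
  w <- 1L
  s_in_win <- 0L
  while (consumed < spec$budget) {
    win <- spec$windows[[w]]
    M <- step_matrix(model, M, envs[[w]], cls[[w]], win$noise)
    remaining <- spec$budget - consumed
    if (remaining >= E) {
      acc <- accumulate_step(acc, spec, M, w)
      consumed <- consumed + E
    } else {
      acc <- accumulate_step(acc, spec, M, w, weight_rows = seq_len(remaining))
      consumed <- spec$budget
    }
    if (!is.null(death_req)) {
      dead <- signature_satisfied(M, death_req)
      if (any(dead)) {
        deaths <- deaths + sum(dead)
        restarts <- restarts + sum(dead)
        M[dead, ] <- matrix(rep(spec$initial, each = sum(dead)),
                            nrow = sum(dead))
      }
    }
    s_in_win <- s_in_win + 1L
    if (s_in_win >= win$steps) {
      s_in_win <- 0L
      w <- if (w >= length(spec$windows)) 1L else w + 1L
    }
  }
  finalize_result(acc, spec, deaths = deaths, restarts = restarts,
                  live_steps = consumed)
}

#' @export
print.bn_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<bn_ensemble> %s: %d cells, %d window(s), ",
                     "%s live steps, %d deaths\n"),
              x$model, x$ensemble, length(x$windows),
              format(x$live_steps, big.mark = ","), x$deaths))
  if (!is.null(x$phenotype_fractions)) print(x$phenotype_fractions, n = 15)
  invisible(x)
}

#' @export
as_tibble.bn_ensemble <- function(x, ...) {
  if (is.null(x$phenotype_fractions)) return(x$node_means)
  x$phenotype_fractions
}

#' Per-cell readout values for assay comparison
#'
#' One value per cell: the mean activity of a node over the window (fraction
#' of ON steps), or the fraction of the cell's steps in the window matching a
#' phenotype (`"phenotype:Name"`).
#'
#' @param result A `bn_ensemble` (run in fixed mode).
#' @param readout Node name, or `"phenotype:<Name>"`.
#' @param window Window index.
#' @param signatures Signature set (needed for phenotype readouts; defaults
#'   to the spec's set if the result has states kept).
#' @return Numeric vector, one value per cell.
#' @export
cell_readouts <- function(result, readout, window = 1,
                          signatures = NULL) {
  stopifnot(inherits(result, "bn_ensemble"))
  if (startsWith(readout, "phenotype:")) {
    ph <- sub("^phenotype:", "", readout)
    if (is.null(result$states)) {
      stop("phenotype readouts require run_experiment(keep_states = TRUE)",
           call. = FALSE)
    }
    if (is.null(signatures)) {
      stop("phenotype readouts require a signature set", call. = FALSE)
    }
    win_of <- rep(seq_along(result$windows),
                  vapply(result$windows, `[[`, integer(1), "steps"))
    steps <- which(win_of == window) + 1L  # state index after each step
    E <- dim(result$states)[1]
    vapply(seq_len(E), function(i) {
      M <- t(result$states[i, , steps, drop = TRUE])
      if (length(steps) == 1) M <- matrix(M, nrow = 1,
                                          dimnames = list(NULL, dimnames(result$states)[[2]]))
      cls <- classify_states_matrix(M, signatures)
      mod <- signatures$module[signatures$phenotype == ph][[1]]
      mean(cls[, mod] == ph)
    }, numeric(1))
  } else {
    m <- result$cell_window_means[[window]]
    if (!readout %in% colnames(m)) {
      stop("unknown readout node: ", readout, call. = FALSE)
    }
    m[, readout]
  }
}

# --- series / grids ----------------------------------------------------------

#' Sweep axes for dose series and grids
#'
#' An axis varies either an environmental input's level or a clamp's
#' per-step probability across all windows of a spec.
#'
#' @param node Input node ([sweep_input()]) or clamped node ([sweep_clamp()]).
#' @param levels Numeric levels in \[0, 1\]; defaults to [dose_ladder()].
#' @param mode Clamp direction, `"on"` (hyper-activation) or `"off"`
#'   (knockdown).
#' @return A `sweep_axis` list.
#' @export
sweep_input <- function(node, levels = dose_ladder()) {
  structure(list(type = "input", node = node, levels = levels),
            class = "sweep_axis")
}

#' @rdname sweep_input
#' @export
sweep_clamp <- function(node, mode = c("off", "on"), levels = dose_ladder()) {
  mode <- match.arg(mode)
  structure(list(type = "clamp", node = node, mode = mode, levels = levels),
            class = "sweep_axis")
}

#' The standard dose ladder
#'
#' The log2-style perturbation ladder used for dose series:
#' 0, 0.625, 1.25, 2.5, 5, 10, 20, 40 and 80 percent, as fractions.
#'
#' @return Numeric vector of levels in \[0, 1\].
#' @export
dose_ladder <- function() {
  c(0, 0.625, 1.25, 2.5, 5, 10, 20, 40, 80) / 100
}

#' Apply a sweep axis level or a clamp background to a spec
#'
#' `apply_axis_to_spec()` sets one axis level (an input level or clamp
#' probability) in every window of the spec; `apply_background()` merges a
#' mutation-background [clamp_policy()] into every window. Both are the
#' building blocks of [run_grid()] and useful on their own for one-off
#' perturbed runs.
#'
#' @param spec An [experiment_spec()].
#' @param axis A [sweep_input()]/[sweep_clamp()] axis.
#' @param level Level in \[0, 1\].
#' @return A modified `experiment_spec`.
#' @export
apply_axis_to_spec <- function(spec, axis, level) {
  spec$windows <- lapply(spec$windows, function(win) {
    if (axis$type == "input") {
      env <- win$env
      if (is.null(env)) env <- c()
      env[axis$node] <- level
      win$env <- env
    } else {
      cl <- win$clamps
      if (is.null(cl)) cl <- clamp_policy()
      cl[[axis$node]] <- if (axis$mode == "on") clamp_on(level) else
        clamp_off(level)
      class(cl) <- "clamp_policy"
      win$clamps <- cl
    }
    win
  })
  spec
}

#' @rdname apply_axis_to_spec
#' @param background A [clamp_policy()] (or `NULL` for wild-type).
#' @export
apply_background <- function(spec, background) {
  if (is.null(background)) return(spec)
  spec$windows <- lapply(spec$windows, function(win) {
    cl <- win$clamps
    if (is.null(cl)) cl <- clamp_policy()
    for (nd in names(background)) cl[[nd]] <- background[[nd]]
    class(cl) <- "clamp_policy"
    win$clamps <- cl
    win
  })
  spec
}

#' Run a 1- or 2-axis simulation series over clamp backgrounds
#'
#' One [run_experiment()] per grid point per background; results as a
#' long-format tibble of phenotype fractions (with node means attached as an
#' attribute).
#'
#' @param spec Base [experiment_spec()].
#' @param axis1,axis2 [sweep_input()] / [sweep_clamp()] axes (`axis2`
#'   optional).
#' @param backgrounds Named list of [clamp_policy()] backgrounds (`NULL`
#'   entries mean wild-type).
#' @return A tibble: `background`, `axis1`, `level1` (and `axis2`, `level2`),
#'   `window`, `module`, `phenotype`, `fraction`; attribute `node_means`
#'   holds the matching per-node table.
#' @export
run_grid <- function(spec, axis1, axis2 = NULL,
                     backgrounds = list(wildtype = NULL)) {
  stopifnot(inherits(spec, "experiment_spec"),
            inherits(axis1, "sweep_axis"))
  if (is.null(names(backgrounds))) {
    names(backgrounds) <- paste0("background", seq_along(backgrounds))
  }
  lv2 <- if (is.null(axis2)) NA_real_ else axis2$levels
  rows <- list(); node_rows <- list()
  for (bg in names(backgrounds)) {
    spec_bg <- apply_background(spec, backgrounds[[bg]])
    for (l1 in axis1$levels) {
      s1 <- apply_axis_to_spec(spec_bg, axis1, l1)
      for (l2 in lv2) {
        s2 <- if (is.null(axis2)) s1 else apply_axis_to_spec(s1, axis2, l2)
        res <- run_experiment(s2)
        tag <- function(tbl) {
          tbl |> dplyr::mutate(background = bg,
                               axis1 = axis1$node, level1 = l1,
                               axis2 = if (is.null(axis2)) NA_character_
                                       else axis2$node,
                               level2 = l2, .before = 1)
        }
        if (!is.null(res$phenotype_fractions)) {
          rows[[length(rows) + 1L]] <- tag(res$phenotype_fractions)
        }
        node_rows[[length(node_rows) + 1L]] <- tag(res$node_means)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "node_means") <- dplyr::bind_rows(node_rows)
  out
}

# --- the metastatic-cascade preset ------------------------------------------

cascade_environments <- function() {
  list(
    primary_tumor      = c(Hypoxia = 0, Stiff_ECM = 1, ECM_attached = 1,
                           Density_High = 1),
    hypoxic_tumor      = c(Hypoxia = 1, Stiff_ECM = 1, ECM_attached = 1,
                           Density_High = 1),
    density_drop       = c(Hypoxia = 1, Stiff_ECM = 1, ECM_attached = 1,
                           Density_High = 0),
    invasion           = c(Hypoxia = 0, Stiff_ECM = 1, ECM_attached = 1,
                           Density_High = 0),
    intravasation      = c(Hypoxia = 0, Stiff_ECM = 0, ECM_attached = 0,
                           Density_High = 0),
    extravasation      = c(Hypoxia = 0, Stiff_ECM = 0, ECM_attached = 1,
                           Density_High = 0),
    secondary_site     = c(Hypoxia = 0, Stiff_ECM = 1, ECM_attached = 1,
                           Density_High = 1))
}

#' Run the seven-pulse metastatic-cascade preset
#'
#' Executes the canonical environment sequence of the metastatic cascade on a
#' hypoxia-EMT model: (1) normoxic stiff high-density primary tissue, (2)
#' hypoxia at high density, (3) hypoxia with a density drop, (4) normoxic
#' invasion at low density, (5) intravasation (no ECM, no neighbours), (6)
#' extravasation onto a soft ECM, (7) MET at a high-density secondary site.
#' Growth factor is saturating and external TGF-beta absent throughout;
#' the autocrine TGF-beta loop can be weakened via `tgfb_secr_knockdown`.
#'
#' @param model A model with inputs `Hypoxia`, `GF`, `TGFb_ext`,
#'   `Stiff_ECM`, `ECM_attached`, `Density_High` (e.g.
#'   [hypoxia_demo_model()]).
#' @param steps_per_pulse Update steps per pulse.
#' @param ensemble Cells in the ensemble.
#' @param noise Flip noise during every pulse.
#' @param tgfb_secr_knockdown Per-step probability of forcing `TGFb_secr`
#'   OFF (0 = saturating autocrine loop).
#' @param pulse_clamps Optional named list, pulse index -> [clamp_policy()],
#'   merged into that pulse only.
#' @param signatures Signature set (defaults to [demo_signatures()]).
#' @param seed Seed.
#' @return A `bn_ensemble` whose 7 windows are the pulses, with the
#'   pulse names attached as attribute `pulse_names`.
#' @export
run_cascade_preset <- function(model = hypoxia_demo_model(),
                               steps_per_pulse = 100, ensemble = 100,
                               noise = 0, tgfb_secr_knockdown = 0,
                               pulse_clamps = NULL,
                               signatures = demo_signatures(), seed = 1) {
  model <- as_boolean_model(model)
  envs <- cascade_environments()
  required <- unique(c(names(envs[[1]]), "GF", "TGFb_ext"))
  missing <- setdiff(required, model$inputs)
  if (length(missing) > 0) {
    stop("model is missing required input(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  base_clamps <- if (tgfb_secr_knockdown > 0) {
    clamp_policy(TGFb_secr = clamp_off(tgfb_secr_knockdown))
  } else NULL
  windows <- lapply(seq_along(envs), function(i) {
    cl <- base_clamps
    extra <- pulse_clamps[[as.character(i)]]
    if (!is.null(extra)) {
      if (is.null(cl)) cl <- clamp_policy()
      for (nd in names(extra)) cl[[nd]] <- extra[[nd]]
      class(cl) <- "clamp_policy"
    }
    sim_window(steps_per_pulse, env = c(envs[[i]], GF = 1, TGFb_ext = 0),
               clamps = cl, noise = noise)
  })
  spec <- experiment_spec(model, initial = "Epithelial", windows = windows,
                          initial_env = c(envs[[1]], GF = 1, TGFb_ext = 0),
                          ensemble = ensemble, seed = seed,
                          signatures = signatures,
                          name = "metastatic_cascade")
  res <- run_experiment(spec)
  attr(res, "pulse_names") <- names(envs)
  res
}

#' Dominant phenotype per window
#'
#' Convenience summary: for each window and module, the phenotype with the
#' largest time fraction.
#'
#' @param result A `bn_ensemble`.
#' @param module Module to summarise (default `"EMT"`).
#' @return Character vector, one phenotype per window.
#' @export
dominant_phenotypes <- function(result, module = "EMT") {
  stopifnot(inherits(result, "bn_ensemble"))
  result$phenotype_fractions |>
    dplyr::filter(.data$module == !!module) |>
    dplyr::group_by(.data$window) |>
    dplyr::slice_max(.data$fraction, n = 1, with_ties = FALSE) |>
    dplyr::pull(.data$phenotype)
}

#' Count division events (rising edges of a mitotic marker)
#'
#' Counts 0-to-1 transitions of the marker node per window; mean cycle
#' length = window length / mean divisions (reported `NA` when no division
#' occurred).
#'
#' @param x A `bn_trajectory`, or a `bn_ensemble` run with
#'   `keep_states = TRUE`.
#' @param marker Marker node name (e.g. a mitotic-exit node).
#' @return A tibble: `window`, `divisions` (mean per cell for ensembles),
#'   `window_steps`, `mean_cycle_length`.
#' @export
count_divisions <- function(x, marker) {
  if (inherits(x, "bn_trajectory")) {
    if (!marker %in% colnames(x$states)) {
      stop("marker node '", marker, "' is not in the model", call. = FALSE)
    }
    series <- matrix(x$states[, marker], nrow = 1)
    win_of <- x$window
  } else if (inherits(x, "bn_ensemble")) {
    if (is.null(x$states)) {
      stop("ensemble division counting requires run_experiment(keep_states = TRUE)",
           call. = FALSE)
    }
    if (!marker %in% dimnames(x$states)[[2]]) {
      stop("marker node '", marker, "' is not in the model", call. = FALSE)
    }
    series <- x$states[, marker, , drop = TRUE]
    if (is.null(dim(series))) series <- matrix(series, nrow = 1)
    win_of <- c(0L, rep(seq_along(x$windows),
                        vapply(x$windows, `[[`, integer(1), "steps")))
  } else {
    stop("x must be a bn_trajectory or bn_ensemble", call. = FALSE)
  }
  rises <- series[, -1, drop = FALSE] == 1L & series[, -ncol(series),
                                                     drop = FALSE] == 0L
  win_after <- win_of[-1]
  out <- lapply(sort(unique(win_after[win_after > 0])), function(w) {
    cols <- which(win_after == w)
    div <- mean(rowSums(rises[, cols, drop = FALSE]))
    tibble::tibble(window = w, divisions = div,
                   window_steps = length(cols),
                   mean_cycle_length = ifelse(div > 0, length(cols) / div,
                                              NA_real_))
  })
  dplyr::bind_rows(out)
}
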