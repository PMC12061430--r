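#' @title Phenotype signatures and classification
#' @description Map states, attractors and trajectory windows to named
#'   phenotypes via module-level signatures: partial node-state patterns that
#'   name cell states (epithelial / hybrid E/M / mesenchymal, proliferative /
#'   quiescent, apoptotic, ...). Within a module the highest-priority
#'   satisfied signature wins (priority 1 is highest); two satisfied
#'   signatures of equal priority are an error (ill-formed signature set).
#' @name phenotyping
NULL

#' Build a phenotype signature set
#'
#' @param ... One signature per argument, each a list with fields `phenotype`
#'   (name), `module` (module label), `requires` (named 0/1 vector of
#'   required node states) and optional `priority` (integer rank, 1 =
#'   highest; default 1).
#' @return A `bn_signatures` tibble with columns `module`, `phenotype`,
#'   `priority`, `requires` (list column).
#' @export
#' @examples
#' signature_set(
#'   list(phenotype = "Epithelial", module = "EMT",
#'        requires = c(SNAI1 = 0, ZEB1 = 0, Ecadherin = 1)),
#'   list(phenotype = "Mesenchymal", module = "EMT",
#'        requires = c(ZEB1 = 1, Ecadherin = 0)))
signature_set <- function(...) {
  sigs <- list(...)
  if (length(sigs) == 1 && is.null(sigs[[1]]$phenotype) &&
      is.list(sigs[[1]]) && !is.null(sigs[[1]][[1]]$phenotype)) {
    sigs <- sigs[[1]]
  }
  rows <- lapply(sigs, function(s) {
    stopifnot(!is.null(s$phenotype), !is.null(s$module),
              !is.null(s$requires), length(s$requires) > 0,
              !is.null(names(s$requires)))
    if (!all(s$requires %in% c(0, 1))) {
      stop("signature node states must be 0/1", call. = FALSE)
    }
    tibble::tibble(module = s$module, phenotype = s$phenotype,
                   priority = as.integer(s$priority %||% 1L),
                   requires = list(vapply(s$requires, as.integer,
                                          integer(1))))
  })
  out <- dplyr::bind_rows(rows)
  dup <- out |> dplyr::count(.data$module, .data$phenotype) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate phenotype name within module: ", dup$phenotype[[1]],
         call. = FALSE)
  }
  class(out) <- c("bn_signatures", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bn_signatures <- function(x, ...) {
  cat(sprintf("<bn_signatures> %d signature(s) across %d module(s)\n",
              nrow(x), length(unique(x$module))))
  for (i in seq_len(nrow(x))) {
    req <- x$requires[[i]]
    cat(sprintf("  [%s] %s (priority %d): %s\n", x$module[[i]],
                x$phenotype[[i]], x$priority[[i]],
                paste(sprintf("%s=%d", names(req), req), collapse = ", ")))
  }
  invisible(x)
}

#' Validate a signature set against a model
#'
#' Checks that every node referenced by a signature exists in the model.
#'
#' @param signatures A `bn_signatures` set.
#' @param model A `boolean_model`.
#' @return The signature set, invisibly.
#' @export
validate_signatures <- function(signatures, model) {
  stopifnot(inherits(signatures, "bn_signatures"),
            inherits(model, "boolean_model"))
  for (i in seq_len(nrow(signatures))) {
    unknown <- setdiff(names(signatures$requires[[i]]), model$nodes)
    if (length(unknown) > 0) {
      stop(sprintf("signature '%s' (module %s) references unknown node '%s'",
                   signatures$phenotype[[i]], signatures$module[[i]],
                   unknown[[1]]), call. = FALSE)
    }
  }
  invisible(signatures)
}

# vectorised: which rows of state matrix M satisfy signature i
signature_satisfied <- function(M, req) {
  ok <- rep(TRUE, nrow(M))
  for (nd in names(req)) ok <- ok & (M[, nd] == req[[nd]])
  ok
}

# classify many states at once; returns a character matrix rows x modules
classify_states_matrix <- function(M, signatures) {
  modules <- unique(signatures$module)
  out <- matrix("unclassified", nrow = nrow(M), ncol = length(modules),
                dimnames = list(NULL, modules))
  for (mod in modules) {
    sigs <- signatures[signatures$module == mod, ]
    sat <- vapply(seq_len(nrow(sigs)),
                  function(i) signature_satisfied(M, sigs$requires[[i]]),
                  logical(nrow(M)))
    sat <- matrix(sat, nrow = nrow(M))
    # equal-priority ambiguity check
    for (pr in unique(sigs$priority)) {
      grp <- which(sigs$priority == pr)
      if (length(grp) > 1) {
        multi <- rowSums(sat[, grp, drop = FALSE]) > 1
        if (any(multi)) {
          stop(sprintf(paste0("ill-formed signature set: a state satisfies ",
                              "two equal-priority signatures in module '%s'"),
                       mod), call. = FALSE)
        }
      }
    }
    # assign from lowest to highest priority so the best match overwrites
    for (i in order(-sigs$priority)) {
      out[sat[, i], mod] <- sigs$phenotype[[i]]
    }
  }
  out
}

#' Classify a single state into module-level phenotypes
#'
#' For each module, returns the highest-priority signature whose required
#' node assignment is satisfied, else `"unclassified"`. A pure function of
#' the state and signature set.
#'
#' @param state 0/1 state vector (named, or in model node order with names
#'   attached).
#' @param signatures A `bn_signatures` set.
#' @return Named character vector: module label -> phenotype name.
#' @export
classify_state <- function(state, signatures) {
  stopifnot(inherits(signatures, "bn_signatures"))
  if (is.null(names(state))) {
    stop("state must carry node names for classification", call. = FALSE)
  }
  M <- matrix(as.integer(state), nrow = 1,
              dimnames = list(NULL, names(state)))
  needed <- unique(unlist(lapply(signatures$requires, names)))
  missing <- setdiff(needed, colnames(M))
  if (length(missing) > 0) {
    stop("state is missing node(s) required by signatures: ",
         missing[[1]], call. = FALSE)
  }
  classify_states_matrix(M, signatures)[1, ]
}

#' Classify an attractor
#'
#' A cyclic attractor is assigned a phenotype per module only if every state
#' of the cycle classifies identically; otherwise the module is reported as
#' `"mixed"`.
#'
#' @param attractor A `bn_attractor`.
#' @param signatures A `bn_signatures` set.
#' @return Named character vector: module -> phenotype (or "mixed").
#' @export
classify_attractor <- function(attractor, signatures) {
  stopifnot(inherits(attractor, "bn_attractor"))
  cls <- classify_states_matrix(attractor$states, signatures)
  vapply(colnames(cls), function(m) {
    u <- unique(cls[, m])
    if (length(u) == 1) u else "mixed"
  }, character(1))
}

#' Per-window phenotype fractions and node mean activities
#'
#' For an ensemble of trajectories sharing one window schedule: for each
#' window and module, the fraction of (live) steps matching each phenotype
#' (plus `"unclassified"`); and for each node, the mean ON-fraction.
#' Fractions within a module and window sum to 1.
#'
#' @param trajectories A `bn_trajectory` or list of them (all sharing the
#'   schedule).
#' @param signatures A `bn_signatures` set.
#' @return A `bn_window_stats` list with tibbles `phenotype_fractions`
#'   (`window`, `module`, `phenotype`, `fraction`) and `node_means`
#'   (`window`, `node`, `mean_activity`).
#' @export
window_statistics <- function(trajectories, signatures) {
  if (inherits(trajectories, "bn_trajectory")) {
    trajectories <- list(trajectories)
  }
  stopifnot(length(trajectories) > 0,
            all(vapply(trajectories, inherits, logical(1), "bn_trajectory")))
  win0 <- trajectories[[1]]$window
  for (tr in trajectories) {
    if (!identical(tr$window, win0)) {
      stop("all trajectories must share the same window schedule",
           call. = FALSE)
    }
  }
  # stack post-step states (window > 0) from all trajectories
  keep <- win0 > 0
  M <- do.call(rbind, lapply(trajectories, function(tr) {
    tr$states[keep, , drop = FALSE]
  }))
  win <- rep(win0[keep], times = length(trajectories))
  new_window_stats(M, win, signatures)
}

new_window_stats <- function(M, win, signatures) {
  cls <- classify_states_matrix(M, signatures)
  modules <- colnames(cls)
  frac_rows <- lapply(modules, function(mod) {
    phen_levels <- c(signatures$phenotype[signatures$module == mod],
                     "unclassified")
    tab <- table(factor(win), factor(cls[, mod], levels = phen_levels))
    tibble::tibble(
      window = rep(as.integer(rownames(tab)), times = ncol(tab)),
      module = mod,
      phenotype = rep(colnames(tab), each = nrow(tab)),
      fraction = as.vector(tab / rowSums(tab)))
  })
  means <- stats::aggregate(M, by = list(window = win), FUN = mean)
  node_means <- tidyr::pivot_longer(tibble::as_tibble(means),
                                    cols = -"window", names_to = "node",
                                    values_to = "mean_activity")
  structure(list(phenotype_fractions = dplyr::bind_rows(frac_rows) |>
                   dplyr::arrange(.data$window, .data$module),
                 node_means = node_means),
            class = "bn_window_stats")
}

#' @export
print.bn_window_stats <- function(x, ...) {
  cat("<bn_window_stats>\n")
  print(x$phenotype_fractions, n = 20)
  invisible(x)
}

#' Read a signature set from YAML
#'
#' Expected layout: one block per module, each a mapping of phenotype name to
#' `{nodes: {node: value, ...}, priority: k}` (priority optional).
#'
#' @param path YAML file path.
#' @return A `bn_signatures` set.
#' @export
read_signatures <- function(path) {
  raw <- yaml::read_yaml(path)
  sigs <- list()
  for (mod in names(raw)) {
    for (ph in names(raw[[mod]])) {
      blk <- raw[[mod]][[ph]]
      sigs[[length(sigs) + 1L]] <- list(
        phenotype = ph, module = mod,
        requires = unlist(blk$nodes),
        priority = blk$priority %||% 1L)
    }
  }
  signature_set(sigs)
}

#' Write a signature set to YAML
#'
#' @param signatures A `bn_signatures` set.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_signatures <- function(signatures, path) {
  out <- list()
  for (i in seq_len(nrow(signatures))) {
    mod <- signatures$module[[i]]
    out[[mod]][[signatures$phenotype[[i]]]] <- list(
      nodes = as.list(signatures$requires[[i]]),
      priority = signatures$priority[[i]])
  }
  yaml::write_yaml(out, path)
  invisible(path)
}
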