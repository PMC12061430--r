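#' @title Protocol files
#' @description Read experiment protocols from YAML and export ensemble
#'   results as long-format CSV. A protocol file holds: `model` (fixture
#'   name or path), `initial` (phenotype name or explicit node states),
#'   `initial_env`, `windows` (each `{steps, inputs, clamps, noise}`; clamps
#'   are `{node, mode, level}` records), `ensemble`, `budget`, `seed`,
#'   `death`, and either a `signatures` block (inline, same layout as
#'   [read_signatures()]) or `signatures_file`.
#' @name protocol-io
NULL

clamps_from_list <- function(lst) {
  if (is.null(lst) || length(lst) == 0) return(NULL)
  cl <- stats::setNames(lapply(lst, function(x) {
    stopifnot(!is.null(x$node), x$mode %in% c("on", "off"))
    lv <- x$level %||% 1
    if (x$mode == "on") clamp_on(lv) else clamp_off(lv)
  }), vapply(lst, `[[`, character(1), "node"))
  do.call(clamp_policy, cl)
}

#' Read an experiment protocol from YAML
#'
#' @param path Protocol YAML path.
#' @param model Optional `boolean_model` overriding the file's `model` field.
#' @return An [experiment_spec()].
#' @export
read_protocol <- function(path, model = NULL) {
  raw <- yaml::read_yaml(path)
  for (field in c("windows")) {
    if (is.null(raw[[field]])) {
      stop("protocol file is missing required field: ", field, call. = FALSE)
    }
  }
  if (is.null(model)) {
    if (is.null(raw$model)) {
      stop("protocol file is missing required field: model", call. = FALSE)
    }
    model <- as_boolean_model(raw$model)
  }
  signatures <- if (!is.null(raw$signatures_file)) {
    read_signatures(file.path(dirname(path), raw$signatures_file))
  } else if (!is.null(raw$signatures)) {
    sigs <- list()
    for (mod in names(raw$signatures)) {
      for (ph in names(raw$signatures[[mod]])) {
        blk <- raw$signatures[[mod]][[ph]]
        sigs[[length(sigs) + 1L]] <- list(
          phenotype = ph, module = mod, requires = unlist(blk$nodes),
          priority = blk$priority %||% 1L)
      }
    }
    signature_set(sigs)
  } else {
    reg <- fixture_registry()
    if (is.character(raw$model) && raw$model %in% names(reg) &&
        !is.null(reg[[raw$model]]$signatures)) {
      reg[[raw$model]]$signatures()
    } else NULL
  }
  windows <- lapply(raw$windows, function(w) {
    if (is.null(w$steps)) {
      stop("every protocol window needs a 'steps' field", call. = FALSE)
    }
    sim_window(w$steps, env = unlist(w$inputs),
               clamps = clamps_from_list(w$clamps),
               noise = w$noise %||% 0)
  })
  initial <- raw$initial
  if (is.list(initial)) initial <- unlist(initial)
  if (!is.null(names(initial))) {
    st <- make_state(model, initial)
  } else {
    st <- initial
  }
  experiment_spec(model, initial = st, windows = windows,
                  initial_env = unlist(raw$initial_env),
                  ensemble = raw$ensemble %||% 100,
                  budget = raw$budget,
                  seed = raw$seed %||% 1,
                  signatures = signatures,
                  death = raw$death,
                  name = raw$name %||% tools::file_path_sans_ext(basename(path)))
}

#' Export ensemble results as long-format CSV
#'
#' Writes a phenotype-fraction table (`window`, `module`, `phenotype`,
#' `fraction`) and a node-means table (`window`, `node`, `mean_activity`).
#'
#' @param result A `bn_ensemble`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (defaults to the experiment name).
#' @return Character vector of the paths written, invisibly.
#' @export
export_ensemble_result <- function(result, dir, prefix = NULL) {
  stopifnot(inherits(result, "bn_ensemble"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(prefix)) {
    prefix <- if (nzchar(result$name)) result$name else result$model
  }
  paths <- character(0)
  if (!is.null(result$phenotype_fractions)) {
    p <- file.path(dir, paste0(prefix, "_phenotype_fractions.csv"))
    readr::write_csv(result$phenotype_fractions, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, paste0(prefix, "_node_means.csv"))
  readr::write_csv(result$node_means, p)
  invisible(c(paths, p))
}
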