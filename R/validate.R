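#' @title In vitro assay validation harness
#' @description Score perturbed vs. control simulation ensembles against
#'   curated in vitro observations. A simulated comparison matches an
#'   expected direction when (i) there is a statistically significant change
#'   in that direction and the change is at least 5% of the average of the
#'   two compared values, or (ii) there is no change / no significant change
#'   / a smaller-than-5% difference and the in vitro result reported no
#'   significant change. Tests are two-sided unpaired Welch t-tests at
#'   alpha = 0.05 by default (configurable via [match_rule()]).
#' @name validation
NULL

ASSAY_DIRECTIONS <- c("increase", "decrease", "no-change")

#' Matching rule configuration
#'
#' @param alpha Significance level of the two-sided unpaired t-test.
#' @param min_rel_change Minimum relevant change, as a fraction of the
#'   average of the two compared values (default 0.05, i.e. 5%).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return A `match_rule` list.
#' @export
match_rule <- function(alpha = 0.05, min_rel_change = 0.05,
                       var_equal = FALSE) {
  stopifnot(alpha > 0, alpha < 1, min_rel_change >= 0)
  structure(list(alpha = alpha, min_rel_change = min_rel_change,
                 var_equal = var_equal),
            class = "match_rule")
}

#' Compare a perturbed ensemble against its control
#'
#' @param control,perturbed Numeric per-cell readout values (each of length
#'   at least 2; typically per-cell mean node activities from
#'   [cell_readouts()]).
#' @param expected Expected in vitro direction: `"increase"`, `"decrease"`
#'   or `"no-change"`.
#' @param rule A [match_rule()].
#' @param assay_id Optional identifier carried into the result.
#' @return A one-row tibble (`bn_match`): means, t statistic, p value,
#'   absolute and relative change, detected direction, and `verdict`
#'   (`"match"` / `"mismatch"`). When both samples are degenerate (zero
#'   variance), significance is decided by exact equality of the means.
#' @export
compare_assay <- function(control, perturbed, expected, rule = match_rule(),
                          assay_id = NA_character_) {
  expected <- match.arg(expected, ASSAY_DIRECTIONS)
  if (length(control) == 0 || length(perturbed) == 0) {
    stop("empty sample in assay comparison", call. = FALSE)
  }
  mean_c <- mean(control)
  mean_p <- mean(perturbed)
  delta <- mean_p - mean_c
  avg <- (mean_c + mean_p) / 2
  threshold <- rule$min_rel_change * abs(avg)
  degenerate <- stats::sd(control) == 0 && stats::sd(perturbed) == 0
  if (degenerate) {
    statistic <- NA_real_
    p_value <- if (mean_c == mean_p) 1 else 0
  } else {
    tt <- stats::t.test(perturbed, control, var.equal = rule$var_equal)
    statistic <- unname(tt$statistic)
    p_value <- tt$p.value
  }
  significant <- p_value < rule$alpha
  big_enough <- abs(delta) >= threshold && delta != 0
  direction <- if (delta > 0) "increase" else if (delta < 0) "decrease" else
    "no-change"
  verdict <- if (expected == "no-change") {
    if (!significant || !big_enough) "match" else "mismatch"
  } else {
    if (significant && big_enough && direction == expected) "match" else
      "mismatch"
  }
  out <- tibble::tibble(
    assay_id = assay_id,
    mean_control = mean_c, mean_perturbed = mean_p,
    statistic = statistic, p_value = p_value,
    change = delta,
    relative_change = if (avg == 0) 0 else delta / abs(avg),
    direction = direction, expected = expected, verdict = verdict)
  class(out) <- c("bn_match", class(out))
  out
}

#' Load a curated assay table
#'
#' @param x Path to a CSV file, or a data frame. Required columns:
#'   `assay_id`, `source`, `perturb_node`, `perturb_mode` (`on`/`off`),
#'   `perturb_level` (in \[0, 1\]), `environment`
#'   (`"Input=level;Input=level"`), `readout` (node name or
#'   `"phenotype:Name"`), `direction` (`increase`/`decrease`/`no-change`),
#'   `window` (integer). Optional: `control_environment` (defaults to
#'   `environment`), `initial_environment` (where the starting epithelial
#'   attractor is resolved; defaults to the control environment),
#'   `contradictory` (logical), `steps`.
#' @return A validated tibble of assay records (`bn_assays`).
#' @export
load_assays <- function(x) {
  tbl <- if (is.character(x)) {
    if (!file.exists(x)) stop("assay file not found: ", x, call. = FALSE)
    readr::read_csv(x, show_col_types = FALSE)
  } else {
    tibble::as_tibble(x)
  }
  required <- c("assay_id", "source", "perturb_node", "perturb_mode",
                "perturb_level", "environment", "readout", "direction",
                "window")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("assay table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_dir <- which(!tbl$direction %in% ASSAY_DIRECTIONS)
  if (length(bad_dir) > 0) {
    stop(sprintf("row %d: unknown direction token '%s' (expected %s)",
                 bad_dir[[1]], tbl$direction[[bad_dir[[1]]]],
                 paste(ASSAY_DIRECTIONS, collapse = "/")), call. = FALSE)
  }
  bad_mode <- which(!tbl$perturb_mode %in% c("on", "off", "none"))
  if (length(bad_mode) > 0) {
    stop(sprintf("row %d: perturb_mode must be on/off/none", bad_mode[[1]]),
         call. = FALSE)
  }
  if (any(tbl$perturb_level < 0 | tbl$perturb_level > 1)) {
    stop("perturbation levels must lie in [0, 1]", call. = FALSE)
  }
  if (!"contradictory" %in% names(tbl)) tbl$contradictory <- FALSE
  tbl$contradictory[is.na(tbl$contradictory)] <- FALSE
  class(tbl) <- c("bn_assays", class(tbl))
  tbl
}

#' Parse an `"Input=level;Input=level"` environment string
#'
#' @param s Environment string; empty/NA means all inputs at 0.
#' @return Named numeric vector.
#' @export
parse_environment_string <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(trimws(s), ";")[[1]]
  kv <- strsplit(trimws(parts), "=")
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) stop("malformed environment string: ", s, call. = FALSE)
  stats::setNames(as.numeric(vapply(kv, `[[`, character(1), 2)),
                  trimws(vapply(kv, `[[`, character(1), 1)))
}

# Build and run the control/perturbed ensemble pair for one assay record.
run_assay <- function(model, record, signatures, ensemble = 40,
                      steps = 50, noise = 0.02, seed = 1,
                      rule = match_rule()) {
  env_pert <- parse_environment_string(record$environment)
  env_ctrl <- if (!is.null(record$control_environment) &&
                  !is.na(record$control_environment) &&
                  nzchar(record$control_environment)) {
    parse_environment_string(record$control_environment)
  } else env_pert
  env_init <- if (!is.null(record$initial_environment) &&
                  !is.na(record$initial_environment) &&
                  nzchar(record$initial_environment)) {
    parse_environment_string(record$initial_environment)
  } else env_ctrl
  if (!is.null(record$steps) && !is.na(record$steps)) steps <- record$steps
  n_win <- max(1L, as.integer(record$window))
  clamps <- if (record$perturb_mode %in% c("on", "off") &&
                record$perturb_level > 0) {
    cl <- if (record$perturb_mode == "on") clamp_on(record$perturb_level)
          else clamp_off(record$perturb_level)
    structure(stats::setNames(list(cl), record$perturb_node),
              class = "clamp_policy")
  } else NULL
  keep <- startsWith(record$readout, "phenotype:")
  mk_spec <- function(env, cl) {
    experiment_spec(
      model, initial = "Epithelial",
      windows = lapply(seq_len(n_win), function(i) {
        sim_window(steps, env = env, clamps = cl, noise = noise)
      }),
      initial_env = env_init, ensemble = ensemble, seed = seed,
      signatures = signatures, name = record$assay_id)
  }
  ctrl <- run_experiment(mk_spec(env_ctrl, NULL), keep_states = keep)
  pert <- run_experiment(mk_spec(env_pert, clamps), keep_states = keep)
  compare_assay(
    cell_readouts(ctrl, record$readout, window = record$window,
                  signatures = signatures),
    cell_readouts(pert, record$readout, window = record$window,
                  signatures = signatures),
    expected = record$direction, rule = rule,
    assay_id = record$assay_id)
}

#' Run the full validation harness
#'
#' For every assay record, simulates the control and perturbed ensembles on
#' the model, extracts per-cell readouts and applies the matching rule.
#'
#' @param model A `boolean_model` (or fixture name / path).
#' @param assays A `bn_assays` table (see [load_assays()]).
#' @param signatures Signature set used for initial-state resolution and
#'   phenotype readouts.
#' @param ensemble,steps,noise Simulation settings per assay arm.
#' @param seed Master seed; each assay derives its own sub-seed.
#' @param rule A [match_rule()].
#' @return A `bn_validation` object: `results` (per-test tibble) and
#'   `summary` (see [summarize_validation()]).
#' @export
run_validation <- function(model, assays, signatures = demo_signatures(),
                           ensemble = 40, steps = 50, noise = 0.02,
                           seed = 1, rule = match_rule()) {
  model <- as_boolean_model(model)
  if (!inherits(assays, "bn_assays")) assays <- load_assays(assays)
  results <- dplyr::bind_rows(lapply(seq_len(nrow(assays)), function(i) {
    rec <- as.list(assays[i, ])
    res <- run_assay(model, rec, signatures, ensemble = ensemble,
                     steps = steps, noise = noise,
                     seed = (seed + i) %% .Machine$integer.max, rule = rule)
    res$source <- rec$source
    res$contradictory <- isTRUE(rec$contradictory)
    res
  }))
  structure(list(results = results,
                 summary = summarize_validation(results)),
            class = "bn_validation")
}

#' Summarise validation results
#'
#' Test-level and assay-level match percentages, a per-source breakdown, and
#' separate flagging of assays whose in vitro sources contradict each other.
#' An assay matches when all of its statistical tests match; a failing assay
#' flagged contradictory is reported as `"contradictory-source"` rather than
#' a plain mismatch.
#'
#' @param results A tibble of [compare_assay()] rows (columns `assay_id`,
#'   `verdict`; optional `source`, `contradictory`).
#' @return A list: `n_assays`, `n_tests`, `assays_matched`, `tests_matched`,
#'   `assay_match_pct`, `test_match_pct`, `assay_table`, `by_source`.
#' @export
summarize_validation <- function(results) {
  if (nrow(results) == 0) stop("no validation results to summarise",
                               call. = FALSE)
  if (!"contradictory" %in% names(results)) results$contradictory <- FALSE
  if (!"source" %in% names(results)) results$source <- NA_character_
  assay_tbl <- results |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::summarise(
      n_tests = dplyr::n(),
      matched = all(.data$verdict == "match"),
      contradictory = any(.data$contradictory),
      source = dplyr::first(.data$source), .groups = "drop") |>
    dplyr::mutate(verdict = dplyr::case_when(
      matched ~ "match",
      .data$contradictory ~ "contradictory-source",
      TRUE ~ "mismatch"))
  by_source <- results |>
    dplyr::group_by(.data$source) |>
    dplyr::summarise(n_tests = dplyr::n(),
                     tests_matched = sum(.data$verdict == "match"),
                     .groups = "drop")
  list(
    n_assays = nrow(assay_tbl),
    n_tests = nrow(results),
    assays_matched = sum(assay_tbl$matched),
    tests_matched = sum(results$verdict == "match"),
    assay_match_pct = 100 * mean(assay_tbl$matched),
    test_match_pct = 100 * mean(results$verdict == "match"),
    assay_table = assay_tbl,
    by_source = by_source)
}

#' @export
print.bn_validation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<bn_validation> %d assays (%d tests): ",
                     "%.1f%% assays matched (%d/%d), ",
                     "%.1f%% tests matched (%d/%d)\n"),
              s$n_assays, s$n_tests, s$assay_match_pct, s$assays_matched,
              s$n_assays, s$test_match_pct, s$tests_matched, s$n_tests))
  n_contra <- sum(s$assay_table$verdict == "contradictory-source")
  if (n_contra > 0) {
    cat(sprintf("  %d failing assay(s) flagged contradictory-source\n",
                n_contra))
  }
  invisible(x)
}

#' @export
tidy.bn_validation <- function(x, ...) x$results

#' @export
glance.bn_validation <- function(x, ...) {
  s <- x$summary
  tibble::tibble(n_assays = s$n_assays, n_tests = s$n_tests,
                 assays_matched = s$assays_matched,
                 tests_matched = s$tests_matched,
                 assay_match_pct = s$assay_match_pct,
                 test_match_pct = s$test_match_pct)
}

#' Write a validation report
#'
#' Per-test CSV plus a plain-text summary.
#'
#' @param x A `bn_validation`.
#' @param path Output CSV path; the text summary goes to
#'   `sub(".csv", "_summary.txt", path)`.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(x, path) {
  stopifnot(inherits(x, "bn_validation"))
  readr::write_csv(x$results, path)
  s <- x$summary
  txt <- c(
    sprintf("assays: %d, matched: %d (%.1f%%)",
            s$n_assays, s$assays_matched, s$assay_match_pct),
    sprintf("tests: %d, matched: %d (%.1f%%)",
            s$n_tests, s$tests_matched, s$test_match_pct),
    sprintf("contradictory-source assays: %d",
            sum(s$assay_table$verdict == "contradictory-source")))
  writeLines(txt, sub("\\.csv$", "_summary.txt", path))
  invisible(path)
}
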