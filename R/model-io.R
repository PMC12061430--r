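#' @title Boolean model input/output
#' @description Parse, validate and serialise Boolean regulatory models in a
#'   BooleanNet-style rule dialect.
#'
#' The dialect is line-oriented, UTF-8 plain text:
#' \itemize{
#'   \item `Name *= expression` defines the update rule of node `Name`.
#'     Expressions use lower-case `and`, `or`, `not`, parentheses, the
#'     constants `True`/`False`, and case-sensitive node identifiers.
#'   \item `inputs: A, B` declares environmental input nodes (no rule;
#'     their value is set by the environment). A node whose rule is exactly
#'     its own name (`A *= A`), or a bare identifier on its own line, is
#'     also treated as an input declaration.
#'   \item `module Label: A, B` assigns nodes to a named regulatory module
#'     (default module is `"core"`).
#'   \item `#` starts a comment; blank lines are ignored.
#' }
#' @name model-io
NULL

RULE_OP_PREC <- c("or" = 1L, "and" = 2L, "not" = 3L)

node_name_rx <- "^[A-Za-z_][A-Za-z0-9_.]*$"

tokenize_rule <- function(expr_text, line_no) {
  rx <- "[A-Za-z_][A-Za-z0-9_.]*|\\(|\\)|\\S"
  toks <- regmatches(expr_text, gregexpr(rx, expr_text))[[1]]
  bad <- toks[!grepl(paste0(node_name_rx, "|^[()]$"), toks)]
  if (length(bad) > 0) {
    stop(sprintf("line %d: unexpected token '%s' in rule expression",
                 line_no, bad[[1]]), call. = FALSE)
  }
  toks
}

# Translate a dialect expression into an R language object using `&`, `|`, `!`.
parse_rule_expr <- function(expr_text, line_no) {
  toks <- tokenize_rule(expr_text, line_no)
  if (length(toks) == 0) {
    stop(sprintf("line %d: empty rule expression", line_no), call. = FALSE)
  }
  mapped <- vapply(toks, function(tk) {
    switch(tk,
      "and" = "&", "or" = "|", "not" = "!",
      "True" = "TRUE", "False" = "FALSE",
      tk)
  }, character(1), USE.NAMES = FALSE)
  lang <- tryCatch(
    str2lang(paste(mapped, collapse = " ")),
    error = function(e) {
      stop(sprintf("line %d: cannot parse rule expression: %s",
                   line_no, conditionMessage(e)), call. = FALSE)
    })
  check_rule_lang(lang, line_no)
  strip_parens(lang)
}

# normalise away `(` call nodes so equivalent texts parse to identical trees
strip_parens <- function(e) {
  if (is.call(e)) {
    if (identical(e[[1]], as.name("("))) return(strip_parens(e[[2]]))
    for (i in seq_along(e)[-1]) e[[i]] <- strip_parens(e[[i]])
  }
  e
}

# Only &, |, !, (, node names and logical constants may appear.
check_rule_lang <- function(e, line_no) {
  if (is.name(e) || isTRUE(e) || isFALSE(e)) return(invisible(TRUE))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (!op %in% c("&", "|", "!", "(")) {
      stop(sprintf("line %d: operator '%s' is not part of the rule dialect",
                   line_no, op), call. = FALSE)
    }
    for (i in seq_along(e)[-1]) check_rule_lang(e[[i]], line_no)
    return(invisible(TRUE))
  }
  stop(sprintf("line %d: invalid element in rule expression", line_no),
       call. = FALSE)
}

#' Parse a Boolean model from rule-dialect text
#'
#' @param text Character scalar (possibly multi-line) or character vector of
#'   lines in the rule dialect described in [model-io].
#' @param name Model name.
#' @return A `boolean_model` object: named list with `name`, `nodes` (ordered
#'   node names), `rules` (named list of R language objects; `NULL` for
#'   inputs), `inputs`, and `modules` (named character, node to module label).
#' @export
#' @examples
#' m <- parse_boolean_model("A *= not B\nB *= not A", name = "toggle")
#' m
parse_boolean_model <- function(text, name = "model") {
  stopifnot(is.character(text))
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines_clean <- sub("#.*$", "", lines)
  nonblank <- which(trimws(lines_clean) != "")
  if (length(nonblank) == 0) {
    stop("empty model source: no rule or input declarations found",
         call. = FALSE)
  }

  nodes <- character(0)
  rules <- list()
  rule_lines <- integer(0)
  inputs <- character(0)
  modules <- character(0)
  declare <- function(nm, line_no) {
    if (nm %in% nodes) {
      stop(sprintf("line %d: duplicate definition of node '%s'", line_no, nm),
           call. = FALSE)
    }
    nodes <<- c(nodes, nm)
  }

  pending_modules <- list()
  for (i in nonblank) {
    ln <- trimws(lines_clean[[i]])
    if (grepl("^inputs\\s*:", ln)) {
      nms <- trimws(strsplit(sub("^inputs\\s*:", "", ln), ",")[[1]])
      nms <- nms[nms != ""]
      bad <- nms[!grepl(node_name_rx, nms)]
      if (length(bad) > 0) {
        stop(sprintf("line %d: invalid input name '%s'", i, bad[[1]]),
             call. = FALSE)
      }
      for (nm in nms) {
        if (!nm %in% inputs) inputs <- c(inputs, nm)
        if (!nm %in% nodes) declare(nm, i)
      }
    } else if (grepl("^module\\s+[^:]+:", ln)) {
      lab <- trimws(sub("^module\\s+([^:]+):.*$", "\\1", ln))
      nms <- trimws(strsplit(sub("^module\\s+[^:]+:", "", ln), ",")[[1]])
      nms <- nms[nms != ""]
      pending_modules[[length(pending_modules) + 1L]] <-
        list(label = lab, nodes = nms, line = i)
    } else if (grepl("\\*=", ln)) {
      parts <- strsplit(ln, "\\*=")[[1]]
      if (length(parts) != 2) {
        stop(sprintf("line %d: malformed rule (expected 'Name *= expression')",
                     i), call. = FALSE)
      }
      nm <- trimws(parts[[1]])
      if (!grepl(node_name_rx, nm)) {
        stop(sprintf("line %d: invalid node name '%s'", i, nm), call. = FALSE)
      }
      rhs <- trimws(parts[[2]])
      if (identical(rhs, nm)) {
        # self-rule convention: environmental input
        if (nm %in% names(rules)) {
          stop(sprintf("line %d: duplicate definition of node '%s'", i, nm),
               call. = FALSE)
        }
        if (!nm %in% inputs) inputs <- c(inputs, nm)
        if (!nm %in% nodes) declare(nm, i)
      } else {
        if (nm %in% names(rules)) {
          stop(sprintf("line %d: duplicate definition of node '%s'", i, nm),
               call. = FALSE)
        }
        if (!nm %in% nodes) declare(nm, i)
        rules[[nm]] <- parse_rule_expr(rhs, i)
        rule_lines[[nm]] <- i
      }
    } else if (grepl(node_name_rx, ln)) {
      # bare identifier: input declaration
      if (!ln %in% inputs) inputs <- c(inputs, ln)
      if (!ln %in% nodes) declare(ln, i)
    } else {
      stop(sprintf("line %d: cannot interpret '%s'", i, ln), call. = FALSE)
    }
  }

  clash <- intersect(inputs, names(rules))
  if (length(clash) > 0) {
    stop(sprintf("node '%s' is declared as an input but also has a rule",
                 clash[[1]]), call. = FALSE)
  }
  missing_rule <- setdiff(nodes, c(inputs, names(rules)))
  if (length(missing_rule) > 0) {
    stop(sprintf("node '%s' is referenced in a module declaration but never defined",
                 missing_rule[[1]]), call. = FALSE)
  }

  # all regulator references must resolve
  for (nm in names(rules)) {
    regs <- all.vars(rules[[nm]])
    undeclared <- setdiff(regs, nodes)
    if (length(undeclared) > 0) {
      stop(sprintf("line %d: rule for '%s' references undeclared node '%s'",
                   rule_lines[[nm]], nm, undeclared[[1]]),
           call. = FALSE)
    }
  }

  modules <- stats::setNames(rep("core", length(nodes)), nodes)
  for (pm in pending_modules) {
    unknown <- setdiff(pm$nodes, nodes)
    if (length(unknown) > 0) {
      stop(sprintf("line %d: module '%s' lists unknown node '%s'",
                   pm$line, pm$label, unknown[[1]]), call. = FALSE)
    }
    modules[pm$nodes] <- pm$label
  }

  new_boolean_model(name = name, nodes = nodes, rules = rules,
                    inputs = inputs, modules = modules)
}

new_boolean_model <- function(name, nodes, rules, inputs, modules) {
  structure(
    list(name = name, nodes = nodes, rules = rules[intersect(nodes, names(rules))],
         inputs = inputs, modules = modules[nodes]),
    class = "boolean_model")
}

#' Read a Boolean model from a rule-dialect file
#'
#' @param path Path to a plain-text model file.
#' @param name Model name; defaults to the file name without extension.
#' @return A `boolean_model`.
#' @export
read_boolean_model <- function(path, name = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  parse_boolean_model(readLines(path, warn = FALSE), name = name)
}

#' @export
print.boolean_model <- function(x, ...) {
  cat(sprintf("<boolean_model> %s: %d nodes (%d inputs), %d links\n",
              x$name, length(x$nodes), length(x$inputs), count_links(x)))
  mods <- split(x$nodes, x$modules[x$nodes])
  for (m in names(mods)) {
    cat(sprintf("  module %s: %s\n", m, paste(mods[[m]], collapse = ", ")))
  }
  invisible(x)
}

#' Syntactic regulators of a node
#'
#' Distinct node names appearing in the node's update rule. An environmental
#' input is treated as regulating itself (the `A *= A` serialisation
#' convention), so it has the single regulator `node`.
#'
#' @param model A `boolean_model`.
#' @param node Node name.
#' @return Character vector of regulator names (may be empty for a constant
#'   rule).
#' @export
regulators <- function(model, node) {
  stopifnot(inherits(model, "boolean_model"))
  if (!node %in% model$nodes) stop("unknown node: ", node, call. = FALSE)
  if (node %in% model$inputs) return(node)
  unique(all.vars(model$rules[[node]]))
}

#' Table of regulatory links
#'
#' One row per distinct ordered (regulator, target) pair where the regulator
#' appears syntactically in the target's rule. Self-loops count; inputs carry
#' their conventional self-loop.
#'
#' @param model A `boolean_model`.
#' @return A tibble with columns `regulator`, `target`.
#' @export
link_table <- function(model) {
  stopifnot(inherits(model, "boolean_model"))
  rows <- lapply(model$nodes, function(nd) {
    regs <- regulators(model, nd)
    if (length(regs) == 0) return(NULL)
    tibble::tibble(regulator = regs, target = nd)
  })
  dplyr::bind_rows(rows)
}

#' Count regulatory links
#'
#' Number of distinct ordered (regulator, target) pairs under the syntactic
#' convention of [link_table()] (no essential-variable reduction; self-loops
#' count, including the conventional self-loop of each environmental input).
#'
#' @param model A `boolean_model`.
#' @return Integer link count.
#' @export
count_links <- function(model) {
  nrow(link_table(model))
}

render_rule <- function(e, parent_prec = 0L, right = FALSE) {
  if (is.name(e)) return(as.character(e))
  if (isTRUE(e)) return("True")
  if (isFALSE(e)) return("False")
  op <- as.character(e[[1]])
  if (op == "(") return(render_rule(e[[2]], parent_prec, right))
  if (op == "!") {
    inner <- render_rule(e[[2]], RULE_OP_PREC[["not"]])
    return(paste0("not ", inner))
  }
  word <- c("&" = "and", "|" = "or")[[op]]
  prec <- RULE_OP_PREC[[word]]
  lhs <- render_rule(e[[2]], prec, right = FALSE)
  rhs <- render_rule(e[[3]], prec, right = TRUE)
  out <- paste(lhs, word, rhs)
  wrap <- prec < parent_prec || (prec == parent_prec && right)
  if (wrap) paste0("(", out, ")") else out
}

#' Serialise a Boolean model to rule-dialect text
#'
#' Round-trip guarantee: `parse_boolean_model(write_boolean_model(m))` is
#' structurally identical to `m` (same node order, inputs, modules and rule
#' expression trees).
#'
#' @param model A `boolean_model`.
#' @param path Optional file path; if given the text is also written there.
#' @return The serialised text, invisibly when `path` is given.
#' @export
write_boolean_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "boolean_model"))
  out <- character(0)
  if (length(model$inputs) > 0) {
    out <- c(out, paste0("inputs: ", paste(model$inputs, collapse = ", ")))
  }
  mods <- model$modules[model$nodes]
  for (lab in unique(mods)) {
    if (lab == "core") next
    out <- c(out, paste0("module ", lab, ": ",
                         paste(names(mods)[mods == lab], collapse = ", ")))
  }
  for (nd in model$nodes) {
    if (nd %in% model$inputs) next
    out <- c(out, paste0(nd, " *= ", render_rule(model$rules[[nd]])))
  }
  text <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(text))
  }
  text
}

# structural equality of two models (node order, inputs, modules, rule trees)
models_identical <- function(a, b) {
  identical(a$nodes, b$nodes) &&
    identical(a$inputs, b$inputs) &&
    identical(a$modules, b$modules) &&
    length(a$rules) == length(b$rules) &&
    all(vapply(names(a$rules),
               function(nm) identical(a$rules[[nm]], b$rules[[nm]]),
               logical(1)))
}
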