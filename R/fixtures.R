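#' @title Bundled fixture models
#' @description Self-contained Boolean models that make every analysis in the
#'   package runnable without external files: a minimal toggle switch, the
#'   6-node EMT core switch, a compact 21-node hypoxia-EMT demonstration
#'   network, and a seeded random-network generator. The fixture rule sets
#'   are constructed to satisfy the established circuit logic of the
#'   hypoxia-EMT literature (double-negative SNAI1/miR-34 and ZEB1/miR-200
#'   loops, hybrid-state stability, autocrine TGF-beta hysteresis,
#'   oxygen-dependent PHD/VHL degradation of HIF-1a); they are compact
#'   stand-ins, not transcriptions of any published full-scale model, which
#'   remains loadable via [load_published_model()].
#' @name fixtures
NULL

#' Minimal toggle-switch model
#'
#' Two mutually repressing nodes (`A *= not B`, `B *= not A`): two fixed
#' points plus one 2-cycle under synchronous update.
#'
#' @return A `boolean_model`.
#' @export
toggle_model <- function() {
  parse_boolean_model("A *= not B\nB *= not A", name = "toggle")
}

#' The 6-node EMT core switch
#'
#' The two double-negative feedback loops at the heart of the
#' epithelial-mesenchymal transition: SNAI1/miR-34 (first switch, hybrid E/M
#' entry) and ZEB1/miR-200 (second switch, full EMT), with E-cadherin as the
#' epithelial readout and a single environmental input `EMT_signal`
#' (any EMT-inducing extracellular signal). Under `EMT_signal = 0` the stable
#' states are epithelial and mesenchymal; under `EMT_signal = 1`, hybrid E/M
#' and mesenchymal - three distinct stable phenotypes in total.
#'
#' @return A `boolean_model`.
#' @export
emt_switch_fixture <- function() {
  parse_boolean_model(paste(
    "inputs: EMT_signal",
    "module EMT: SNAI1, miR34, ZEB1, miR200, Ecadherin",
    "SNAI1 *= (EMT_signal or ZEB1) and not miR34",
    "miR34 *= not SNAI1 and not ZEB1 and not EMT_signal",
    "ZEB1 *= (SNAI1 or ZEB1) and not miR200",
    "miR200 *= not ZEB1 and (miR200 or not SNAI1)",
    "Ecadherin *= miR200 and not ZEB1",
    sep = "\n"), name = "emt_switch")
}

#' Phenotype signatures for the EMT core switch
#'
#' Epithelial (miR-200 and E-cadherin on, SNAI1/ZEB1 off), hybrid E/M
#' (SNAI1 on, ZEB1 off, adherens junctions retained) and mesenchymal
#' (ZEB1 on, miR-200 and E-cadherin lost), attached to module `"EMT"`.
#'
#' @return A `bn_signatures` set.
#' @export
emt_signatures <- function() {
  signature_set(
    list(phenotype = "Epithelial", module = "EMT",
         requires = c(miR200 = 1, Ecadherin = 1, SNAI1 = 0, ZEB1 = 0)),
    list(phenotype = "Hybrid", module = "EMT",
         requires = c(SNAI1 = 1, ZEB1 = 0, Ecadherin = 1)),
    list(phenotype = "Mesenchymal", module = "EMT",
         requires = c(ZEB1 = 1, miR200 = 0, Ecadherin = 0)))
}

#' The 21-node hypoxia-EMT demonstration model
#'
#' A compact single-cell network coupling the acute hypoxic response
#' (oxygen-dependent PHD hydroxylation, VHL-mediated HIF-1a degradation, the
#' basal vs. strongly stabilised HIF-1a regimes), mechanosensing (ECM
#' stiffness, attachment, cell density), autocrine TGF-beta signaling, the
#' EMT switch, a minimal proliferation axis (Myc, Cyclin D, cell cycle) and
#' an apoptosis/anoikis node.
#'
#' Inputs (6): `Hypoxia`, `GF` (growth factor / mitogen), `TGFb_ext`,
#' `Stiff_ECM`, `ECM_attached`, `Density_High`. Configuration constraint on
#' meaningful environments: `Stiff_ECM = 1` implies `ECM_attached = 1`.
#'
#' @return A `boolean_model`.
#' @export
hypoxia_demo_model <- function() {
  parse_boolean_model(paste(
    "inputs: Hypoxia, GF, TGFb_ext, Stiff_ECM, ECM_attached, Density_High",
    "module Hypoxia: PHD, VHL, Hif1a_basal, Hif1a_High, Src",
    "module EMT: SNAI1, miR200, ZEB1, Ecadherin",
    "module TGFb: TGFb_secr, TGFbR",
    "module Proliferation: Myc, CyclinD, CellCycle",
    "module Survival: Apoptosis",
    "PHD *= not Hypoxia",
    "VHL *= True",
    "Hif1a_basal *= GF or Hif1a_High",
    "Hif1a_High *= not (PHD and VHL)",
    "Src *= Hypoxia or Stiff_ECM",
    "SNAI1 *= not Density_High and Stiff_ECM and (GF or Hif1a_High or TGFbR)",
    "miR200 *= not ZEB1 and not (SNAI1 and (Hif1a_High or TGFbR))",
    paste("ZEB1 *= (SNAI1 or ZEB1) and (Hif1a_High or TGFbR)",
          "and not miR200 and not Density_High"),
    "Ecadherin *= not ZEB1",
    "TGFb_secr *= ZEB1",
    "TGFbR *= TGFb_ext or TGFb_secr",
    "Myc *= GF and not Hif1a_High",
    "CyclinD *= GF and not Hif1a_High and not TGFbR",
    paste("CellCycle *= Myc and CyclinD and Hif1a_basal and Stiff_ECM",
          "and ECM_attached and not Density_High"),
    paste("Apoptosis *= Ecadherin and not Src and (not ECM_attached",
          "or (TGFbR and not Stiff_ECM))"),
    sep = "\n"), name = "hypoxia_demo")
}

#' Phenotype signatures for the hypoxia-EMT demonstration model
#'
#' Modules: `EMT` (Epithelial / Hybrid / Mesenchymal on the SNAI1, ZEB1,
#' E-cadherin axis), `Proliferation` (Cycling / Quiescent on `CellCycle`) and
#' `Survival` (Apoptotic / Alive on `Apoptosis`).
#'
#' @return A `bn_signatures` set.
#' @export
demo_signatures <- function() {
  signature_set(
    list(phenotype = "Epithelial", module = "EMT",
         requires = c(SNAI1 = 0, ZEB1 = 0, Ecadherin = 1)),
    list(phenotype = "Hybrid", module = "EMT",
         requires = c(SNAI1 = 1, ZEB1 = 0, Ecadherin = 1)),
    list(phenotype = "Mesenchymal", module = "EMT",
         requires = c(ZEB1 = 1, Ecadherin = 0)),
    list(phenotype = "Cycling", module = "Proliferation",
         requires = c(CellCycle = 1)),
    list(phenotype = "Quiescent", module = "Proliferation",
         requires = c(CellCycle = 0)),
    list(phenotype = "Apoptotic", module = "Survival",
         requires = c(Apoptosis = 1)),
    list(phenotype = "Alive", module = "Survival",
         requires = c(Apoptosis = 0)))
}

# render a truth table over k regulators as a sum-of-products expression
truth_table_expr <- function(regs, outputs) {
  k <- length(regs)
  on_rows <- which(outputs == 1L)
  if (length(on_rows) == 0) return("False")
  if (length(on_rows) == 2^k) return("True")
  terms <- vapply(on_rows, function(r) {
    bits <- as.integer(intToBits(r - 1L))[seq_len(k)]
    lits <- ifelse(bits == 1L, regs, paste0("not ", regs))
    paste0("(", paste(lits, collapse = " and "), ")")
  }, character(1))
  paste(terms, collapse = " or ")
}

#' Seeded random Boolean network generator
#'
#' Each non-input node receives `k` distinct regulators chosen uniformly from
#' all nodes and a uniform random truth table, rendered as a
#' sum-of-products rule. Constant truth tables are redrawn by default so that
#' every non-input node has exactly `k` syntactic regulators.
#'
#' @param n Total node count.
#' @param k In-degree of every non-input node.
#' @param n_inputs Number of environmental inputs (the first `n_inputs`
#'   nodes).
#' @param seed Integer seed (generation is reproducible).
#' @param allow_constant Keep constant truth tables instead of redrawing.
#' @return A `boolean_model` named `rbn_n<k>_...`.
#' @export
random_boolean_network <- function(n, k, n_inputs = 0, seed = 1,
                                   allow_constant = FALSE) {
  if (!is.numeric(n) || !is.numeric(k) || n < 1 || k < 1 || k > n) {
    stop("need n >= k >= 1", call. = FALSE)
  }
  if (n_inputs >= n) stop("n_inputs must be smaller than n", call. = FALSE)
  nodes <- sprintf("N%02d", seq_len(n))
  inputs <- nodes[seq_len(n_inputs)]
  lines <- character(0)
  if (n_inputs > 0) {
    lines <- paste0("inputs: ", paste(inputs, collapse = ", "))
  }
  withr::with_seed(seed, {
    for (nd in setdiff(nodes, inputs)) {
      regs <- sample(nodes, k)
      repeat {
        outputs <- as.integer(stats::runif(2^k) < 0.5)
        if (allow_constant || (any(outputs == 1L) && any(outputs == 0L))) break
      }
      lines <- c(lines, paste0(nd, " *= ", truth_table_expr(regs, outputs)))
    }
  })
  parse_boolean_model(paste(lines, collapse = "\n"),
                      name = sprintf("rbn_n%d_k%d_s%d", n, k, seed))
}

#' Load a published full-scale model file
#'
#' Reads a rule-dialect model file (for example a mechanically transcribed
#' BooleanNet export of a published large network) and reports its node and
#' link counts, so they can be checked against the publication.
#'
#' @param path Model file path.
#' @return A `boolean_model`; node/link counts are reported via `message()`.
#' @export
load_published_model <- function(path) {
  model <- read_boolean_model(path)
  message(sprintf("loaded '%s': %d nodes, %d links (syntactic convention)",
                  model$name, length(model$nodes), count_links(model)))
  model
}

#' Fixture registry
#'
#' Named factories for every bundled model plus its companion signature set
#' (where one is defined).
#'
#' @return A named list: each entry has `model` (factory function) and
#'   `signatures` (factory function or `NULL`).
#' @export
fixture_registry <- function() {
  list(
    toggle = list(model = toggle_model, signatures = NULL),
    emt_switch = list(model = emt_switch_fixture,
                      signatures = emt_signatures),
    hypoxia_demo = list(model = hypoxia_demo_model,
                        signatures = demo_signatures))
}

#' Resolve a model argument that may be a fixture name or a file path
#'
#' @param x A `boolean_model`, fixture name (see [fixture_registry()]) or
#'   path to a rule-dialect file.
#' @return A `boolean_model`.
#' @export
as_boolean_model <- function(x) {
  if (inherits(x, "boolean_model")) return(x)
  if (is.character(x) && length(x) == 1) {
    reg <- fixture_registry()
    if (x %in% names(reg)) return(reg[[x]]$model())
    if (file.exists(x)) return(read_boolean_model(x))
  }
  stop("cannot interpret model argument: supply a boolean_model, a fixture ",
       "name or a file path", call. = FALSE)
}
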