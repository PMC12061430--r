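# Independent oracles: hand-coded steppers and brute-force attractor search
# written directly against the biology / truth tables, without going through
# the package's parser or engine.

# EMT core switch: one deterministic synchronous step, plain R logic.
emt_oracle_step <- function(s) {
  with(as.list(s == 1), c(
    EMT_signal = unname(s[["EMT_signal"]]),
    SNAI1 = as.integer((EMT_signal || ZEB1) && !miR34),
    miR34 = as.integer(!SNAI1 && !ZEB1 && !EMT_signal),
    ZEB1 = as.integer((SNAI1 || ZEB1) && !miR200),
    miR200 = as.integer(!ZEB1 && (miR200 || !SNAI1)),
    Ecadherin = as.integer(miR200 && !ZEB1)))
}

emt_state <- function(signal, SNAI1, miR34, ZEB1, miR200, Ecadherin) {
  c(EMT_signal = signal, SNAI1 = SNAI1, miR34 = miR34, ZEB1 = ZEB1,
    miR200 = miR200, Ecadherin = Ecadherin)
}

# Hypoxia demonstration network: one deterministic synchronous step with
# inputs held at `env` and hard overrides in `forced` (named 0/1).
demo_oracle_step <- function(s, env, forced = NULL) {
  v <- as.list(s == 1)
  for (nm in names(env)) v[[nm]] <- env[[nm]] == 1
  nxt <- with(v, c(
    PHD = !Hypoxia,
    VHL = TRUE,
    Hif1a_basal = GF || Hif1a_High,
    Hif1a_High = !(PHD && VHL),
    Src = Hypoxia || Stiff_ECM,
    SNAI1 = !Density_High && Stiff_ECM && (GF || Hif1a_High || TGFbR),
    miR200 = !ZEB1 && !(SNAI1 && (Hif1a_High || TGFbR)),
    ZEB1 = (SNAI1 || ZEB1) && (Hif1a_High || TGFbR) && !miR200 &&
      !Density_High,
    Ecadherin = !ZEB1,
    TGFb_secr = ZEB1,
    TGFbR = TGFb_ext || TGFb_secr,
    Myc = GF && !Hif1a_High,
    CyclinD = GF && !Hif1a_High && !TGFbR,
    CellCycle = Myc && CyclinD && Hif1a_basal && Stiff_ECM &&
      ECM_attached && !Density_High,
    Apoptosis = Ecadherin && !Src && (!ECM_attached ||
      (TGFbR && !Stiff_ECM))))
  nxt <- as.integer(nxt)
  names(nxt) <- c("PHD", "VHL", "Hif1a_basal", "Hif1a_High", "Src", "SNAI1",
                  "miR200", "ZEB1", "Ecadherin", "TGFb_secr", "TGFbR", "Myc",
                  "CyclinD", "CellCycle", "Apoptosis")
  out <- c(env, nxt)
  if (!is.null(forced)) out[names(forced)] <- forced
  out
}

# iterate the demo oracle until a fixed point (or cap); returns final state
demo_oracle_settle <- function(env, forced = NULL, start = NULL, cap = 60) {
  nodes <- c("Hypoxia", "GF", "TGFb_ext", "Stiff_ECM", "ECM_attached",
             "Density_High", "PHD", "VHL", "Hif1a_basal", "Hif1a_High",
             "Src", "SNAI1", "miR200", "ZEB1", "Ecadherin", "TGFb_secr",
             "TGFbR", "Myc", "CyclinD", "CellCycle", "Apoptosis")
  s <- stats::setNames(integer(length(nodes)), nodes)
  if (!is.null(start)) s[names(start)] <- start
  s[names(env)] <- env
  if (!is.null(forced)) s[names(forced)] <- forced
  for (i in seq_len(cap)) {
    nxt <- demo_oracle_step(s, env, forced)[nodes]
    if (all(nxt == s)) return(s)
    s <- nxt
  }
  s
}

# the quiescent epithelial resting state of the demo network (oracle-derived
# fixed point on a stiff ECM without mitogens)
demo_epithelial_start <- function() {
  demo_oracle_settle(env = c(Hypoxia = 0, GF = 0, TGFb_ext = 0,
                             Stiff_ECM = 1, ECM_attached = 1,
                             Density_High = 0),
                     start = c(miR200 = 1, Ecadherin = 1, PHD = 1, VHL = 1))
}

# Brute-force attractors of an explicit truth-table network, independent of
# the package engine. tables: list per node of list(regs = indices,
# out = 0/1 vector of length 2^k). Returns list of canonical cycles
# (matrices) and basin counts.
tt_step <- function(state, tables) {
  vapply(tables, function(tb) {
    idx <- sum(state[tb$regs] * 2^(seq_along(tb$regs) - 1)) + 1
    tb$out[[idx]]
  }, integer(1))
}

tt_brute_attractors <- function(n, tables) {
  S <- 2^n
  key_of <- function(st) paste(st, collapse = "")
  attr_of <- integer(S)
  cycles <- list()
  decode <- function(i0) as.integer(intToBits(i0))[seq_len(n)]
  encode <- function(st) sum(st * 2^(seq_len(n) - 1)) + 1
  for (s0 in seq_len(S)) {
    if (attr_of[s0] != 0) next
    path <- integer(0)
    cur <- s0
    while (attr_of[cur] == 0) {
      attr_of[cur] <- -1L
      path <- c(path, cur)
      cur <- encode(tt_step(decode(cur - 1), tables))
    }
    if (attr_of[cur] == -1L) {
      pos <- match(cur, path)
      cyc_idx <- path[seq(pos, length(path))]
      states <- do.call(rbind, lapply(cyc_idx - 1, decode))
      keys <- apply(states, 1, key_of)
      start <- which.min(match(keys, sort(keys)))
      k <- nrow(states)
      states <- states[c(seq(start, k), if (start > 1) seq_len(start - 1)), ,
                       drop = FALSE]
      cycles[[length(cycles) + 1L]] <- states
      id <- length(cycles)
    } else id <- attr_of[cur]
    attr_of[path] <- id
  }
  list(cycles = cycles,
       basin = tabulate(attr_of, nbins = length(cycles)) / S)
}

# render a truth-table network in the rule dialect (test-side duplicate kept
# deliberately independent of the package's generator)
tt_to_text <- function(nodes, tables) {
  lines <- vapply(seq_along(nodes), function(i) {
    tb <- tables[[i]]
    regs <- nodes[tb$regs]
    on_rows <- which(tb$out == 1L)
    rhs <- if (length(on_rows) == 0) "False"
    else if (length(on_rows) == 2^length(regs)) "True"
    else paste(vapply(on_rows, function(r) {
      bits <- as.integer(intToBits(r - 1L))[seq_along(regs)]
      paste0("(", paste(ifelse(bits == 1, regs, paste0("not ", regs)),
                        collapse = " and "), ")")
    }, character(1)), collapse = " or ")
    paste0(nodes[[i]], " *= ", rhs)
  }, character(1))
  paste(lines, collapse = "\n")
}

random_tt_network <- function(n, k, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      list(regs = sample.int(n, k),
           out = as.integer(stats::runif(2^k) < 0.5))
    })
  })
}

expect_state_equal <- function(actual, expected) {
  expect_equal(unname(actual[names(expected)]), unname(as.integer(expected)))
}
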