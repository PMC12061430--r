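emt <- emt_switch_fixture()

epi_fp <- emt_state(0, SNAI1 = 0, miR34 = 1, ZEB1 = 0, miR200 = 1,
                    Ecadherin = 1)
mes_fp0 <- emt_state(0, SNAI1 = 1, miR34 = 0, ZEB1 = 1, miR200 = 0,
                     Ecadherin = 0)
mes_fp1 <- emt_state(1, SNAI1 = 1, miR34 = 0, ZEB1 = 1, miR200 = 0,
                     Ecadherin = 0)
hyb_fp <- emt_state(1, SNAI1 = 1, miR34 = 0, ZEB1 = 0, miR200 = 1,
                    Ecadherin = 1)

test_that("deterministic descent finds cycles and transients", {
  tg <- toggle_model()
  d <- descend_to_attractor(tg, c(0L, 0L))
  expect_equal(d$attractor$length, 2)
  expect_equal(d$transient, 0)
  expect_equal(d$attractor$states, matrix(c(0L, 1L, 0L, 1L), 2,
                                          dimnames = list(NULL, c("A", "B"))))

  d2 <- descend_to_attractor(emt, rep(0L, 6), env = c(EMT_signal = 0))
  expect_equal(d2$attractor$length, 1)
  expect_equal(d2$transient, 2)
  expect_state_equal(d2$attractor$states[1, ], epi_fp)

  for (sig in 0:1) {
    mes <- if (sig == 0) mes_fp0 else mes_fp1
    d3 <- descend_to_attractor(emt, mes[emt$nodes],
                               env = c(EMT_signal = sig))
    expect_equal(d3$transient, 0)
    expect_state_equal(d3$attractor$states[1, ], mes)
  }
})

test_that("the same cycle entered at different phases deduplicates", {
  tg <- toggle_model()
  a1 <- descend_to_attractor(tg, c(0L, 0L))$attractor
  a2 <- descend_to_attractor(tg, c(1L, 1L))$attractor
  expect_identical(a1$key, a2$key)
  expect_identical(a1$states, a2$states)
})

test_that("toggle enumeration yields the known attractors and basins", {
  en <- enumerate_attractors(toggle_model())
  expect_length(en$attractors, 3)
  lens <- sort(vapply(en$attractors, `[[`, numeric(1), "length"))
  expect_equal(lens, c(1, 1, 2))
  basins <- vapply(en$attractors, `[[`, numeric(1), "basin")
  expect_equal(sort(basins), c(0.25, 0.25, 0.5))
  expect_equal(sum(basins), 1)
})

test_that("EMT switch fixed points per signal match the derived inventory", {
  e0 <- enumerate_attractors(emt, c(EMT_signal = 0))
  expect_length(e0$attractors, 2)
  expect_true(all(vapply(e0$attractors, `[[`, numeric(1), "length") == 1))
  keys0 <- vapply(e0$attractors, `[[`, character(1), "key")
  expect_setequal(keys0, c(paste(epi_fp[emt$nodes], collapse = ""),
                           paste(mes_fp0[emt$nodes], collapse = "")))

  e1 <- enumerate_attractors(emt, c(EMT_signal = 1))
  keys1 <- vapply(e1$attractors, `[[`, character(1), "key")
  expect_setequal(keys1, c(paste(hyb_fp[emt$nodes], collapse = ""),
                           paste(mes_fp1[emt$nodes], collapse = "")))
})

test_that("enumeration agrees with an independent truth-table brute force", {
  for (s in 1:10) {
    n <- 8
    tables <- random_tt_network(n, 2, seed = 100 + s)
    nodes <- sprintf("N%02d", seq_len(n))
    m <- parse_boolean_model(tt_to_text(nodes, tables))
    en <- enumerate_attractors(m)
    oracle <- tt_brute_attractors(n, tables)
    expect_length(en$attractors, length(oracle$cycles))
    oracle_keys <- vapply(oracle$cycles, function(st) {
      paste(apply(st, 1, paste, collapse = ""), collapse = "|")
    }, character(1))
    for (a in en$attractors) {
      i <- match(a$key, oracle_keys)
      expect_false(is.na(i))
      expect_equal(a$basin, oracle$basin[[i]])
    }
  }
})

test_that("enumeration rejects models above the free-node cap", {
  m <- random_boolean_network(24, 2, seed = 1)
  expect_error(enumerate_attractors(m, max_free = 10), "sample_attractors")
})

test_that("sampling finds the toggle attractors with sane weights", {
  sa <- sample_attractors(toggle_model(),
                          sampling_config(T_steps = 25, p = 0.02, N = 200),
                          seed = 5)$sets[[1]]
  expect_length(sa$attractors, 3)
  w <- vapply(sa$attractors, `[[`, numeric(1), "basin")
  expect_equal(sum(w), 1, tolerance = 1e-9)
  en <- enumerate_attractors(toggle_model())
  ekeys <- vapply(en$attractors, `[[`, character(1), "key")
  for (a in sa$attractors) {
    i <- match(a$key, ekeys)
    expect_false(is.na(i))
    wt <- en$attractors[[i]]$basin
    se <- sqrt(wt * (1 - wt) / 200)
    expect_lt(abs(a$basin - wt), 3 * se)
    expect_lt(abs(a$initial_basin - wt), 3 * se)
  }
})

test_that("sampled attractors are a subset of enumerated attractors", {
  for (s in c(3, 14, 27)) {
    m <- random_boolean_network(10, 2, n_inputs = 1, seed = s)
    for (lvl in 0:1) {
      env <- c(N01 = lvl)
      en <- enumerate_attractors(m, env)
      sa <- sample_attractors(
        m, sampling_config(N = 500,
                           environments = tibble::tibble(N01 = lvl)),
        seed = s)$sets[[1]]
      ekeys <- vapply(en$attractors, `[[`, character(1), "key")
      skeys <- vapply(sa$attractors, `[[`, character(1), "key")
      expect_true(all(skeys %in% ekeys))
      # every attractor with substantial basin is recovered at N = 500
      big <- ekeys[vapply(en$attractors, `[[`, numeric(1), "basin") >= 0.05]
      expect_true(all(big %in% skeys))
      expect_equal(sum(vapply(sa$attractors, `[[`, numeric(1), "basin")), 1,
                   tolerance = 1e-9)
    }
  }
})

test_that("sampling covers every binary input combination", {
  m <- parse_boolean_model(paste(
    "inputs: I1, I2, I3, I4, I5, I6, I7",
    "X *= I1 and I2", "Y *= X or I3", sep = "\n"))
  sa <- sample_attractors(m, sampling_config(T_steps = 3, N = 100), seed = 1)
  expect_equal(nrow(sa$environments), 2^7)
  expect_equal(sa$n_initial_total, 100 * 2^7)
  expect_length(sa$sets, 128)
})

test_that("sampling is reproducible for a fixed seed", {
  m <- random_boolean_network(9, 2, seed = 8)
  s1 <- sample_attractors(m, sampling_config(N = 50), seed = 3)
  s2 <- sample_attractors(m, sampling_config(N = 50), seed = 3)
  expect_identical(attractor_table(s1), attractor_table(s2))
})

test_that("the attractor table has the documented long-format shape", {
  tg_tbl <- attractor_table(enumerate_attractors(toggle_model()))
  expect_equal(nrow(tg_tbl), 4)  # 2 fixed points + 2-cycle x 2 positions
  expect_true(all(c("attractor_id", "cycle_length", "cycle_position",
                    "A", "B", "basin_weight") %in% names(tg_tbl)))

  land <- enumerate_attractor_landscape(emt)
  tbl <- attractor_table(land)
  expect_equal(nrow(tbl), 4)  # two fixed points per signal value
  sig <- emt_signatures()
  profiles <- apply(tbl[, emt$nodes[-1]], 1, function(r) {
    classify_state(stats::setNames(as.integer(r), emt$nodes[-1]), sig)
  })
  expect_setequal(unique(profiles), c("Epithelial", "Mesenchymal", "Hybrid"))

  path <- withr::local_tempfile(fileext = ".csv")
  write_attractor_table(land, path)
  back <- read_attractor_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
})
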