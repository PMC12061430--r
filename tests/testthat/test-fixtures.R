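demo <- hypoxia_demo_model()
dsig <- demo_signatures()

test_that("EMT fixture attractor inventory is exactly the three phenotypes", {
  emt <- emt_switch_fixture()
  profiles <- character(0)
  for (sig_val in 0:1) {
    en <- enumerate_attractors(emt, c(EMT_signal = sig_val))
    # the inventory is fixed points only; surface any unexpected cycle
    lens <- vapply(en$attractors, `[[`, numeric(1), "length")
    expect_equal(lens, rep(1, 2),
                 label = sprintf("cycle lengths under EMT_signal=%d", sig_val))
    profiles <- c(profiles, vapply(en$attractors, function(a) {
      unname(classify_attractor(a, emt_signatures())["EMT"])
    }, character(1)))
  }
  expect_setequal(unique(profiles),
                  c("Epithelial", "Hybrid", "Mesenchymal"))
  expect_length(unique(profiles), 3)
})

# Each scenario fixes an environment and clamp set; the expected end state
# comes from the independent hand-coded stepper in helper-oracles.R.
demo_scenarios <- list(
  normoxia_hybrid_cycling = list(
    env = c(Hypoxia = 0, GF = 1, TGFb_ext = 0, Stiff_ECM = 1,
            ECM_attached = 1, Density_High = 0),
    forced = NULL,
    expect = c(SNAI1 = 1, ZEB1 = 0, Ecadherin = 1, CellCycle = 1)),
  hypoxia_emt_arrest = list(
    env = c(Hypoxia = 1, GF = 1, TGFb_ext = 0, Stiff_ECM = 1,
            ECM_attached = 1, Density_High = 0),
    forced = NULL,
    expect = c(ZEB1 = 1, Ecadherin = 0, TGFb_secr = 1, CellCycle = 0)),
  tgfbr_ko_does_not_block = list(
    env = c(Hypoxia = 1, GF = 1, TGFb_ext = 0, Stiff_ECM = 1,
            ECM_attached = 1, Density_High = 0),
    forced = c(TGFbR = 0),
    expect = c(ZEB1 = 1, Ecadherin = 0, CellCycle = 0)),
  vhl_on_does_not_block = list(
    env = c(Hypoxia = 1, GF = 1, TGFb_ext = 0, Stiff_ECM = 1,
            ECM_attached = 1, Density_High = 0),
    forced = c(VHL = 1),
    expect = c(ZEB1 = 1, Ecadherin = 0)),
  tgfb_stiff_emt_normoxia = list(
    env = c(Hypoxia = 0, GF = 1, TGFb_ext = 1, Stiff_ECM = 1,
            ECM_attached = 1, Density_High = 0),
    forced = NULL,
    expect = c(ZEB1 = 1, Ecadherin = 0)),
  density_blocks_all = list(
    env = c(Hypoxia = 1, GF = 1, TGFb_ext = 1, Stiff_ECM = 1,
            ECM_attached = 1, Density_High = 1),
    forced = NULL,
    expect = c(SNAI1 = 0, ZEB1 = 0, Ecadherin = 1)),
  hif_basal_ko_arrest = list(
    env = c(Hypoxia = 0, GF = 1, TGFb_ext = 0, Stiff_ECM = 1,
            ECM_attached = 1, Density_High = 0),
    forced = c(Hif1a_basal = 0),
    expect = c(CellCycle = 0)),
  hif_high_on_arrest = list(
    env = c(Hypoxia = 0, GF = 1, TGFb_ext = 0, Stiff_ECM = 1,
            ECM_attached = 1, Density_High = 0),
    forced = c(Hif1a_High = 1),
    expect = c(CellCycle = 0)),
  vhl_off_emt_arrest = list(
    env = c(Hypoxia = 0, GF = 1, TGFb_ext = 0, Stiff_ECM = 1,
            ECM_attached = 1, Density_High = 0),
    forced = c(VHL = 0),
    expect = c(ZEB1 = 1, Ecadherin = 0, CellCycle = 0)),
  vhl_off_rescue_needs_both = list(
    env = c(Hypoxia = 0, GF = 1, TGFb_ext = 0, Stiff_ECM = 1,
            ECM_attached = 1, Density_High = 0),
    forced = c(VHL = 0, Myc = 1, CyclinD = 1),
    expect = c(ZEB1 = 1, CellCycle = 1)))

test_that("demo-model scenarios settle where the hand-coded oracle does", {
  start <- demo_epithelial_start()
  for (nm in names(demo_scenarios)) {
    sc <- demo_scenarios[[nm]]
    oracle_end <- demo_oracle_settle(sc$env, sc$forced, start = start)
    clamps <- if (!is.null(sc$forced)) {
      do.call(clamp_policy, lapply(sc$forced, function(v) {
        if (v == 1) clamp_on() else clamp_off()
      }))
    } else NULL
    tr <- simulate_trajectory(demo, start[demo$nodes],
                              sim_window(60, env = sc$env, clamps = clamps))
    end <- tr$states[nrow(tr$states), ]
    expect_equal(unname(end), unname(oracle_end[demo$nodes]), label = nm)
    expect_state_equal(end, sc$expect)
  }
})

test_that("single oncogenes cannot rescue VHL-deficient proliferation", {
  start <- demo_epithelial_start()
  env <- demo_scenarios$vhl_off_emt_arrest$env
  for (forced in list(c(VHL = 0, Myc = 1), c(VHL = 0, CyclinD = 1))) {
    oracle_end <- demo_oracle_settle(env, forced, start = start)
    expect_equal(unname(oracle_end[["CellCycle"]]), 0L)
    clamps <- do.call(clamp_policy, lapply(forced, function(v) {
      if (v == 1) clamp_on() else clamp_off()
    }))
    tr <- simulate_trajectory(demo, start[demo$nodes],
                              sim_window(60, env = env, clamps = clamps))
    expect_equal(unname(tr$states[nrow(tr$states), "CellCycle"]), 0L)
  }
})

test_that("random network generation is seeded and degree-exact", {
  m1 <- random_boolean_network(8, 2, seed = 5)
  m2 <- random_boolean_network(8, 2, seed = 5)
  expect_identical(write_boolean_model(m1), write_boolean_model(m2))
  m3 <- random_boolean_network(8, 2, seed = 6)
  expect_false(identical(write_boolean_model(m1), write_boolean_model(m3)))
  for (nd in setdiff(m1$nodes, m1$inputs)) {
    expect_length(regulators(m1, nd), 2)
  }
  expect_error(random_boolean_network(3, 5, seed = 1), "n >= k")
})

test_that("every registered fixture round-trips and carries valid signatures", {
  reg <- fixture_registry()
  for (nm in names(reg)) {
    m <- reg[[nm]]$model()
    rt <- parse_boolean_model(write_boolean_model(m), name = m$name)
    expect_identical(rt$rules, m$rules, label = nm)
    if (!is.null(reg[[nm]]$signatures)) {
      expect_silent(validate_signatures(reg[[nm]]$signatures(), m))
    }
  }
})

test_that("bundled extdata files mirror the in-code fixtures", {
  for (nm in c("emt_switch", "hypoxia_demo")) {
    path <- system.file("extdata", paste0(nm, ".bnet"), package = "booldyn")
    on_disk <- read_boolean_model(path)
    in_code <- fixture_registry()[[nm]]$model()
    expect_identical(on_disk$rules, in_code$rules)
    expect_identical(on_disk$inputs, in_code$inputs)
  }
  sig_disk <- read_signatures(system.file("extdata", "demo_signatures.yaml",
                                          package = "booldyn"))
  expect_equal(sig_disk$phenotype, dsig$phenotype)
})
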