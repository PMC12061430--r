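demo <- hypoxia_demo_model()
dsig <- demo_signatures()
emt <- emt_switch_fixture()
esig <- emt_signatures()

env_norm <- c(Hypoxia = 0, GF = 1, Stiff_ECM = 1, ECM_attached = 1,
              Density_High = 0)
env_hyp <- replace(env_norm, "Hypoxia", 1)
env_rest <- c(Stiff_ECM = 1, ECM_attached = 1)

test_that("initial states resolve from named phenotypes", {
  epi <- resolve_initial_state(emt, "Epithelial", env = c(EMT_signal = 0),
                               signatures = esig)
  expect_state_equal(epi, emt_state(0, 0, 1, 0, 1, 1))
  expect_error(resolve_initial_state(emt, "Hybrid", env = c(EMT_signal = 0),
                                     signatures = esig),
               "no attractor matching")
  mes <- resolve_initial_state(emt, "Mesenchymal", env = c(EMT_signal = 1),
                               signatures = esig)
  expect_state_equal(mes, emt_state(1, 1, 0, 1, 0, 0))
  expect_error(resolve_initial_state(emt, "NotAPhenotype",
                                     env = c(EMT_signal = 0),
                                     signatures = esig), "not defined")
})

test_that("experiments are bit-exact reproducible per seed", {
  spec <- experiment_spec(demo, "Epithelial",
                          windows = list(sim_window(30, env = env_hyp,
                                                    noise = 0.03)),
                          initial_env = env_rest, ensemble = 40, seed = 12,
                          signatures = dsig)
  r1 <- run_experiment(spec)
  r2 <- run_experiment(spec)
  expect_identical(r1$phenotype_fractions, r2$phenotype_fractions)
  expect_identical(r1$node_means, r2$node_means)
})

test_that("detachment triggers anoikis under normoxia but not hypoxia", {
  env_soft <- c(Hypoxia = 0, GF = 1, Stiff_ECM = 0, ECM_attached = 1)
  detached <- replace(env_soft, "ECM_attached", 0)
  spec <- experiment_spec(demo, "Epithelial",
                          windows = list(sim_window(20, env = env_soft),
                                         sim_window(10, env = detached)),
                          initial_env = env_soft, ensemble = 20, seed = 1,
                          signatures = dsig)
  res <- run_experiment(spec, keep_states = TRUE)
  # every cell reaches Apoptosis = 1 within 3 steps of detachment and stays
  apop <- res$states[, "Apoptosis", ]
  expect_true(all(apop[, (21 + 3):31] == 1))
  expect_true(all(apop[, 1:21] == 0))

  env_soft_h <- replace(env_soft, "Hypoxia", 1)
  spec_h <- experiment_spec(demo, "Epithelial",
                            windows = list(sim_window(20, env = env_soft_h),
                                           sim_window(10,
                                             env = replace(env_soft_h,
                                                           "ECM_attached", 0))),
                            initial_env = env_soft_h, ensemble = 20, seed = 1,
                            signatures = dsig)
  res_h <- run_experiment(spec_h, keep_states = TRUE)
  expect_true(all(res_h$states[, "Apoptosis", ] == 0))
})

test_that("continuous mode conserves the live-step budget through deaths", {
  detached <- c(Hypoxia = 0, GF = 1, Stiff_ECM = 0, ECM_attached = 0)
  spec <- experiment_spec(demo, "Epithelial",
                          windows = list(sim_window(10, env = detached)),
                          initial_env = c(ECM_attached = 1),
                          ensemble = 30, budget = 1000, seed = 4,
                          signatures = dsig, death = "Apoptotic")
  res <- run_experiment(spec)
  expect_equal(res$live_steps, 1000)
  expect_gt(res$deaths, 0)
  expect_equal(res$deaths, res$restarts)
  # phenotype fractions remain normalised over live steps
  sums <- res$phenotype_fractions |>
    dplyr::group_by(window, module) |>
    dplyr::summarise(s = sum(fraction), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))

  expect_error(
    experiment_spec(demo, "Epithelial",
                    windows = list(sim_window(10, env = detached)),
                    initial_env = c(ECM_attached = 1),
                    ensemble = 30, budget = 200, signatures = dsig),
    "budget")
})

test_that("the metastatic cascade follows the seven-pulse fate sequence", {
  res <- run_cascade_preset(demo, steps_per_pulse = 50, ensemble = 10,
                            seed = 2)
  expect_equal(dominant_phenotypes(res, "EMT"),
               c("Epithelial", "Epithelial", "Mesenchymal", "Mesenchymal",
                 "Mesenchymal", "Mesenchymal", "Epithelial"))
  # mesenchymal cells in circulation (pulse 5) survive: E-cadherin loss
  # suppresses anoikis
  expect_equal(dominant_phenotypes(res, "Survival"), rep("Alive", 7))
  frac <- res$phenotype_fractions
  # high density in pulse 2 blocks hypoxia-driven EMT entirely
  expect_equal(frac$fraction[frac$window == 2 &
                               frac$phenotype == "Mesenchymal"], 0)
})

test_that("breaking the autocrine loop in circulation causes apoptosis", {
  res <- run_cascade_preset(
    demo, steps_per_pulse = 50, ensemble = 10, seed = 2,
    pulse_clamps = list("5" = clamp_policy(TGFb_secr = clamp_off(1))))
  frac <- res$phenotype_fractions
  apop5 <- frac$fraction[frac$window == 5 & frac$phenotype == "Apoptotic"]
  expect_gt(apop5, 0.5)
  mes5 <- frac$fraction[frac$window == 5 & frac$phenotype == "Mesenchymal"]
  expect_lt(mes5, 0.5)
})

test_that("VHL loss drives EMT with arrest, rescued only by Myc + CyclinD", {
  spec <- experiment_spec(demo, "Epithelial",
                          windows = list(sim_window(20, env = env_norm),
                                         sim_window(30, env = env_norm)),
                          initial_env = env_rest, ensemble = 5, seed = 1,
                          signatures = dsig)
  run_bg <- function(bg) {
    res <- run_experiment(apply_background(spec, bg))
    f <- res$phenotype_fractions
    c(mes = f$fraction[f$window == 2 & f$phenotype == "Mesenchymal"],
      cyc = f$fraction[f$window == 2 & f$phenotype == "Cycling"])
  }
  vhl_off <- run_bg(clamp_policy(VHL = clamp_off()))
  expect_gt(vhl_off[["mes"]], 0.95)
  expect_lt(vhl_off[["cyc"]], 0.05)
  myc_only <- run_bg(clamp_policy(VHL = clamp_off(), Myc = clamp_on()))
  expect_lt(myc_only[["cyc"]], 0.05)
  ccd_only <- run_bg(clamp_policy(VHL = clamp_off(), CyclinD = clamp_on()))
  expect_lt(ccd_only[["cyc"]], 0.05)
  both <- run_bg(clamp_policy(VHL = clamp_off(), Myc = clamp_on(),
                              CyclinD = clamp_on()))
  expect_gt(both[["cyc"]], 0.95)
})

test_that("a one-point grid reproduces run_experiment exactly", {
  spec <- experiment_spec(demo, "Epithelial",
                          windows = list(sim_window(25, env = env_hyp)),
                          initial_env = env_rest, ensemble = 10, seed = 6,
                          signatures = dsig)
  grid <- run_grid(spec, sweep_input("Hypoxia", levels = 1))
  direct <- run_experiment(spec)
  merged <- dplyr::select(grid, window, module, phenotype, fraction)
  expect_equal(as.data.frame(merged),
               as.data.frame(direct$phenotype_fractions),
               ignore_attr = TRUE)
})

test_that("collapsing a 2-axis grid reproduces the 1-axis series", {
  spec <- experiment_spec(demo, "Epithelial",
                          windows = list(sim_window(20, env = env_norm,
                                                    noise = 0.02)),
                          initial_env = env_rest, ensemble = 10, seed = 9,
                          signatures = dsig)
  g2 <- run_grid(spec, sweep_input("Hypoxia", levels = c(0, 0.5, 1)),
                 sweep_input("Density_High", levels = c(0, 1)))
  spec_d0 <- apply_axis_to_spec(spec, sweep_input("Density_High"), 0)
  g1 <- run_grid(spec_d0, sweep_input("Hypoxia", levels = c(0, 0.5, 1)))
  slice <- g2 |> dplyr::filter(level2 == 0) |>
    dplyr::select(level1, window, module, phenotype, fraction)
  expect_equal(as.data.frame(slice),
               as.data.frame(dplyr::select(g1, level1, window, module,
                                           phenotype, fraction)),
               ignore_attr = TRUE)
})

test_that("division counting detects rising edges of a mitotic marker", {
  osc <- parse_boolean_model(paste("X1 *= X4", "X2 *= X1", "X3 *= X2",
                                   "X4 *= X3", sep = "\n"))
  tr <- simulate_trajectory(osc, c(1L, 0L, 0L, 0L), sim_window(100))
  div <- count_divisions(tr, "X1")
  expect_equal(div$divisions, 25)
  expect_equal(div$mean_cycle_length, 4)

  const <- parse_boolean_model("M *= True")
  tr_on <- simulate_trajectory(const, 0L, sim_window(100))
  d1 <- count_divisions(tr_on, "M")
  expect_equal(d1$divisions, 1)  # a constant marker rises at most once
  tr_already <- simulate_trajectory(const, 1L, sim_window(100))
  d0 <- count_divisions(tr_already, "M")
  expect_equal(d0$divisions, 0)
  expect_true(is.na(d0$mean_cycle_length))
  expect_error(count_divisions(tr_on, "NotHere"), "marker")
})

test_that("protocol YAML files build runnable specs", {
  path <- system.file("extdata", "demo_protocol.yaml", package = "booldyn")
  spec <- read_protocol(path)
  expect_s3_class(spec, "experiment_spec")
  expect_length(spec$windows, 2)
  expect_equal(spec$ensemble, 50)
  res <- run_experiment(spec)
  f <- res$phenotype_fractions
  # the hypoxia window drives the ensemble mesenchymal
  expect_gt(f$fraction[f$window == 2 & f$phenotype == "Mesenchymal"], 0.5)
})
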