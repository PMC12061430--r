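test_that("directional changes match per the significance + 5% rule", {
  ctrl <- rep(c(0.45, 0.55), 10)
  pert <- rep(c(0.75, 0.85), 10)
  res <- compare_assay(ctrl, pert, "increase")
  expect_equal(res$verdict, "match")
  # independent check of the t-test route
  expect_equal(res$p_value, t.test(pert, ctrl)$p.value)
  expect_equal(res$change, 0.3)
  expect_gte(abs(res$change), 0.05 * (mean(ctrl) + mean(pert)) / 2)

  expect_equal(compare_assay(ctrl, pert, "decrease")$verdict, "mismatch")
  expect_equal(compare_assay(pert, ctrl, "decrease")$verdict, "match")
})

test_that("identical samples match an expected no-change", {
  x <- rep(c(0.4, 0.6), 5)
  res <- compare_assay(x, x, "no-change")
  expect_equal(res$verdict, "match")
  expect_equal(res$change, 0)
  # degenerate variance falls back to exact equality of means
  res_deg <- compare_assay(rep(0.5, 10), rep(0.5, 10), "no-change")
  expect_equal(res_deg$verdict, "match")
  expect_equal(res_deg$p_value, 1)
  res_deg2 <- compare_assay(rep(0, 10), rep(1, 10), "increase")
  expect_equal(res_deg2$verdict, "match")
  expect_equal(res_deg2$p_value, 0)
})

test_that("a significant but sub-5% change counts as no-change", {
  set.seed(31)
  n <- 4000
  ctrl <- 0.5 + rnorm(n, sd = 0.01)
  pert <- 0.508 + rnorm(n, sd = 0.01)
  res <- compare_assay(ctrl, pert, "increase")
  expect_lt(res$p_value, 0.05)
  expect_lt(abs(res$relative_change), 0.05)
  expect_equal(res$verdict, "mismatch")
  expect_equal(compare_assay(ctrl, pert, "no-change")$verdict, "match")
})

test_that("swapping control and perturbed flips the direction only", {
  set.seed(7)
  a <- runif(30, 0.2, 0.4)
  b <- runif(30, 0.5, 0.7)
  r1 <- compare_assay(a, b, "increase")
  r2 <- compare_assay(b, a, "decrease")
  expect_equal(r1$direction, "increase")
  expect_equal(r2$direction, "decrease")
  expect_equal(abs(r1$relative_change), abs(r2$relative_change))
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$verdict, r2$verdict)
})

test_that("the verdict flips exactly at a 5% relative change", {
  mk <- function(rel) {
    # means a and b with (b - a) = rel * (a + b) / 2, negligible spread
    a <- 1
    b <- a * (1 + rel / 2) / (1 - rel / 2)
    jitter <- rep(c(-1e-6, 1e-6), 250)
    list(ctrl = a + jitter, pert = b + jitter)
  }
  below <- mk(0.0499)
  r_below <- compare_assay(below$ctrl, below$pert, "increase")
  expect_lt(r_below$p_value, 0.05)
  expect_equal(r_below$verdict, "mismatch")
  expect_equal(compare_assay(below$ctrl, below$pert, "no-change")$verdict,
               "match")
  above <- mk(0.0501)
  r_above <- compare_assay(above$ctrl, above$pert, "increase")
  expect_equal(r_above$verdict, "match")
  expect_equal(compare_assay(above$ctrl, above$pert, "no-change")$verdict,
               "mismatch")
})

test_that("assay tables validate their schema", {
  path <- system.file("extdata", "demo_assays_synthetic.csv",
                      package = "booldyn")
  assays <- load_assays(path)
  expect_equal(nrow(assays), 13)
  expect_equal(length(unique(assays$assay_id)), 12)

  bad <- assays
  bad$direction[5] <- "sideways"
  expect_error(load_assays(bad), "row 5.*sideways")
  expect_error(load_assays(assays[, setdiff(names(assays), "readout")]),
               "readout")
})

test_that("summaries aggregate tests into assay-level percentages", {
  results <- tibble::tibble(
    assay_id = sprintf("a%02d", 1:10),
    verdict = c(rep("match", 9), "mismatch"),
    source = rep(c("s1", "s2"), 5),
    contradictory = FALSE)
  s <- summarize_validation(results)
  expect_equal(s$assay_match_pct, 90)
  expect_equal(s$n_tests, 10)
  expect_equal(s$tests_matched, 9)

  # multi-test assays fail if any test fails; contradictory sources are
  # flagged separately
  results2 <- tibble::tibble(
    assay_id = c("a1", "a1", "a2", "a3"),
    verdict = c("match", "mismatch", "match", "mismatch"),
    source = "s",
    contradictory = c(FALSE, FALSE, FALSE, TRUE))
  s2 <- summarize_validation(results2)
  expect_equal(s2$n_assays, 3)
  expect_equal(s2$assays_matched, 1)
  expect_equal(
    s2$assay_table$verdict[s2$assay_table$assay_id == "a3"],
    "contradictory-source")
})

test_that("the harness reproduces the demonstration model's assay panel", {
  v <- run_validation("hypoxia_demo",
                      system.file("extdata", "demo_assays_synthetic.csv",
                                  package = "booldyn"),
                      seed = 11)
  g <- glance(v)
  expect_equal(g$n_assays, 12)
  expect_equal(g$n_tests, 13)
  expect_equal(g$test_match_pct, 100)
  expect_equal(g$assay_match_pct, 100)
  expect_s3_class(tidy(v), "tbl_df")
  # reproducibility: same seed, same summary
  v2 <- run_validation("hypoxia_demo",
                       system.file("extdata", "demo_assays_synthetic.csv",
                                   package = "booldyn"),
                       seed = 11)
  expect_identical(v$results, v2$results)
})
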