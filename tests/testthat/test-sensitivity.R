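test_that("tornado entries are complete, sorted, and tie-broken by name", {
  p <- default_parameters()
  dsa <- one_way_dsa(p$ug, p$lm)
  expect_equal(nrow(dsa), 12L + 10L)  # 6 probabilities x 2 arms + 10 costs
  expect_true(all(dsa$span >= 0))
  expect_true(all(diff(dsa$span) <= 0))
  ties <- dsa$span == c(dsa$span[-1], NA)
  if (any(ties, na.rm = TRUE)) {
    i <- which(ties)[1]
    expect_lt(order(dsa$parameter[c(i, i + 1)])[1], 2)
  }
})

test_that("a cost with no weight in either strategy has zero tornado span", {
  w <- stats::setNames(c(1, rep(0, 8)),
                       c("thrombosis", "embolism", "hydromediastinum",
                         "hematomediastinum", "hematothorax", "hydrothorax",
                         "pneumothorax", "nerve injury",
                         "subcutaneous emphysema"))
  p <- default_parameters()
  rebuild <- function(sp) strategy_params(sp$strategy, sp$f1, sp$f2, sp$c1,
                                          sp$c2, sp$c3, sp$arterial,
                                          sp$cost_map, w)
  dsa <- one_way_dsa(rebuild(p$ug), rebuild(p$lm))
  dead <- dsa[dsa$parameter == "cost nerve injury", ]
  expect_equal(dead$span_cost, 0)
  expect_equal(dead$span_effect, 0)
})

test_that("symmetric cost variation produces symmetric incremental-cost swings", {
  p <- default_parameters()
  base <- compare_strategies(evaluate_strategy(p$ug),
                             evaluate_strategy(p$lm))$delta_cost
  dsa <- one_way_dsa(p$ug, p$lm)
  costs <- dsa[grepl("^cost ", dsa$parameter), ]
  expect_equal(costs$delta_cost_high - base, -(costs$delta_cost_low - base),
               tolerance = 1e-9)
  # cost bounds never touch the effect side
  expect_equal(costs$span_effect, rep(0, nrow(costs)))
})

test_that("the landmark arterial-puncture CI moves the result only modestly", {
  p <- default_parameters()
  dsa <- one_way_dsa(p$ug, p$lm)
  arterial_lm <- dsa[dsa$parameter == "LM arterial", ]
  expect_equal(c(arterial_lm$low, arterial_lm$high), c(0.069, 0.093))
  expect_lt(arterial_lm$pct_of_base_cost, 10)
  expect_equal(arterial_lm$span_effect, 0)  # arterial share affects cost only
})

test_that("probability bounds outside [0,1] are clamped with a warning", {
  p <- default_parameters()
  expect_warning(
    cvccea:::set_prob_mean(p$ug, "c1", 1.2),
    "clamped")
})

test_that("the PSA is seed-deterministic and collapses to base at zero spread", {
  p <- default_parameters()
  a <- run_psa(p$ug, p$lm, iterations = 300, seed = 17)
  b <- run_psa(p$ug, p$lm, iterations = 300, seed = 17)
  expect_identical(a$summary, b$summary)
  expect_identical(a$draws, b$draws)

  degenerate <- run_psa(p$ug, p$lm, iterations = 1, seed = 1, se_scale = 0)
  base_ug <- evaluate_strategy(p$ug)
  expect_equal(degenerate$draws$cost_ug, base_ug$expected_cost)
  expect_equal(degenerate$draws$effect_ug, base_ug$effectiveness)
})

test_that("PSA iteration means approach base-case values as spread shrinks", {
  p <- default_parameters()
  tight <- run_psa(p$ug, p$lm, iterations = 2000, seed = 4, se_scale = 0.01)
  base <- compare_strategies(evaluate_strategy(p$ug),
                             evaluate_strategy(p$lm))
  expect_equal(mean(tight$draws$delta_effect), base$delta_effect,
               tolerance = 1e-3)
  expect_equal(mean(tight$draws$delta_cost), base$delta_cost,
               tolerance = 0.01 * abs(base$delta_cost))
})

test_that("PSA summaries are internally coherent", {
  p <- default_parameters()
  psa <- run_psa(p$ug, p$lm, iterations = 2000, seed = 8)
  expect_true(psa$dominance_fraction >= 0 && psa$dominance_fraction <= 1)
  with(psa$summary, {
    expect_true(all(p2.5 <= mean & mean <= p97.5))
  })
  expect_match(psa$percentile_method, "linear interpolation")
})

test_that("an over-dispersed probability aborts the PSA naming the culprit", {
  p <- default_parameters()
  wide <- probability_param("c1", 0.029, 0, 1)  # se^2 > mean(1-mean)
  bad <- strategy_params("UG", p$ug$f1, p$ug$f2, wide, p$ug$c2, p$ug$c3,
                         p$ug$arterial, p$ug$cost_map)
  expect_error(run_psa(bad, p$lm, iterations = 10, seed = 1), "'c1'")
})

test_that("the break-even intervention cost mirrors the base-case saving", {
  expect_equal(threshold_intervention_cost(-179), 179)
  expect_equal(threshold_intervention_cost(-1), 1)
  expect_equal(threshold_intervention_cost(0), 0)
  expect_warning(out <- threshold_intervention_cost(25), "not cost saving")
  expect_equal(out, 0)
})

test_that("PSA scatter exports one row per iteration", {
  p <- default_parameters()
  psa <- run_psa(p$ug, p$lm, iterations = 100, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_psa_scatter(psa, path)
  sc <- utils::read.csv(path)
  expect_equal(nrow(sc), 100L)
  expect_named(sc, c("delta_cost", "delta_effect"))
})
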