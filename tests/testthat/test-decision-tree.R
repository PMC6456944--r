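test_that("tree rollback reproduces the published per-person complication risks", {
  p <- default_parameters()
  r_ug <- evaluate_tree(build_tree(p$ug))
  r_lm <- evaluate_tree(build_tree(p$lm))
  expect_equal(round(r_ug$p_any_complication, 3), 0.036)
  expect_equal(r_lm$p_any_complication, 0.1742, tolerance = 1e-3)
  expect_equal(r_ug$effectiveness + r_ug$p_any_complication, 1)
})

test_that("rollback and analytic evaluation agree to machine precision", {
  set.seed(21)
  for (i in 1:25) {
    params <- random_strategy_params()
    roll <- evaluate_tree(build_tree(params))
    closed <- evaluate_strategy(params)
    expect_equal(roll$p_any_complication, closed$p_any_complication,
                 tolerance = 1e-12)
    expect_equal(roll$expected_cost, closed$expected_cost,
                 tolerance = 1e-9)
  }
})

test_that("degenerate trees behave as the pathway dictates", {
  # no failures: only the first attempt is reachable
  p0 <- make_params(f1 = 0, c1 = 0.07, c2 = 0.5, c3 = 0.5)
  r <- evaluate_tree(build_tree(p0))
  expect_equal(r$p_any_complication, 0.07, tolerance = 1e-12)
  # no complication risk anywhere: zero events and zero cost
  pz <- make_params(c1 = 0, c2 = 0, c3 = 0, arterial = 0)
  rz <- evaluate_tree(build_tree(pz))
  expect_equal(rz$p_any_complication, 0)
  expect_equal(rz$expected_cost, 0)
})

test_that("complication risk is monotone in every branch probability", {
  set.seed(22)
  nms <- c("f1", "f2", "c1", "c2", "c3")
  for (i in 1:40) {
    base <- runif(5, 0.05, 0.5)
    names(base) <- nms
    p0 <- oracle_p_any(base[["f1"]], base[["f2"]], base[["c1"]],
                       base[["c2"]], base[["c3"]])
    for (nm in nms) {
      up <- base
      up[[nm]] <- min(up[[nm]] + 0.2, 1)
      p1 <- oracle_p_any(up[["f1"]], up[["f2"]], up[["c1"]],
                         up[["c2"]], up[["c3"]])
      expect_gte(p1, p0)
    }
  }
})

test_that("cost per complication occurrence splits arterial vs composite", {
  p <- default_parameters()
  other_mean <- mean(c(131, 131, 133, 94, 177, 217, 178, 347, 16))
  w_a <- 0.081 / 0.114
  expect_equal(attribute_cost(p$lm), w_a * 94 + (1 - w_a) * other_mean,
               tolerance = 1e-9)
  # all composite weight on the cheapest complication, no arterial share
  w <- stats::setNames(c(rep(0, 8), 1),
                       c("thrombosis", "embolism", "hydromediastinum",
                         "hematomediastinum", "hematothorax", "hydrothorax",
                         "pneumothorax", "nerve injury",
                         "subcutaneous emphysema"))
  params <- make_params(arterial = 0, c1 = 0.1, other_weights = w)
  expect_equal(attribute_cost(params), 16)
  # arterial share of one: arterial puncture cost only
  params2 <- make_params(arterial = 0.1, c1 = 0.1)
  expect_equal(attribute_cost(params2), 94)
  # share is clamped when arterial exceeds the reference total
  params3 <- make_params(arterial = 0.2, c1 = 0.1)
  expect_equal(attribute_cost(params3), 94)
})

test_that("expected cost scales with the per-strategy cost multiplier", {
  params <- make_params()
  scaled <- make_params(cost_multiplier = 2.5)
  r1 <- evaluate_strategy(params)
  r2 <- evaluate_strategy(scaled)
  expect_equal(r2$expected_cost, 2.5 * r1$expected_cost)
  expect_equal(r2$p_any_complication, r1$p_any_complication)  # effects immune
})

test_that("tree JSON export preserves structure and probabilities", {
  p <- default_parameters()
  js <- jsonlite::fromJSON(tree_to_json(build_tree(p$lm)),
                           simplifyVector = FALSE)
  expect_equal(js$type, "chance")
  expect_equal(vapply(js$branches, `[[`, numeric(1), "p"), c(0.114, 0.886))
  path <- withr::local_tempfile(fileext = ".json")
  tree_to_json(build_tree(p$lm), path)
  expect_true(file.exists(path))
})
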