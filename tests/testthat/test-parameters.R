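test_that("CI width converts to a normal-approximation standard error", {
  expect_equal(ci_to_se(0.096, 0.132), 0.036 / 3.92)
  expect_equal(ci_to_se(0.031, 0.067), 0.036 / 3.92)
  expect_equal(ci_to_se(0.5, 0.5), 0)
  expect_error(ci_to_se(0.2, 0.1), "negative")
})

test_that("beta moment matching recovers the requested mean and variance", {
  ab <- beta_from_moments(0.5, 0.05)
  expect_equal(unname(ab), c(49.5, 49.5))

  set.seed(11)
  for (i in 1:50) {
    m <- runif(1, 0.02, 0.98)
    s <- runif(1, 1e-4, 0.9) * sqrt(m * (1 - m))
    ab <- beta_from_moments(m, s)
    expect_true(all(ab > 0))
    fitted_mean <- ab[["alpha"]] / sum(ab)
    fitted_var <- prod(ab) / (sum(ab)^2 * (sum(ab) + 1))
    expect_equal(fitted_mean, m, tolerance = 1e-9)
    expect_equal(fitted_var, s^2, tolerance = 1e-9)
  }
  expect_error(beta_from_moments(0.9, 0.4), "undefined")
  expect_error(beta_from_moments(1, 0.1))
})

test_that("gamma moment matching recovers the requested mean and variance", {
  expect_equal(unname(gamma_from_moments(100, 10)), c(100, 1))
  sh <- gamma_from_moments(94, 23.98)
  expect_equal(sh[["shape"]], (94 / 23.98)^2, tolerance = 1e-9)
  expect_equal(sh[["scale"]], 23.98^2 / 94, tolerance = 1e-9)

  set.seed(12)
  for (i in 1:50) {
    m <- runif(1, 1, 500)
    s <- runif(1, 0.5, 200)
    sh <- gamma_from_moments(m, s)
    expect_equal(sh[["shape"]] * sh[["scale"]], m, tolerance = 1e-9)
    expect_equal(sh[["shape"]] * sh[["scale"]]^2, s^2, tolerance = 1e-9)
  }
  expect_error(gamma_from_moments(0, 1), "positive")
})

test_that("rate-to-probability transform is exact, bounded and monotone", {
  expect_equal(rate_to_probability(0, 1), 0)
  expect_equal(rate_to_probability(log(2), 1), 0.5)
  expect_equal(rate_to_probability(0.1, 1), 1 - exp(-0.1))
  r <- seq(0, 5, by = 0.25)
  p <- rate_to_probability(r, 1)
  expect_true(all(p >= 0 & p < 1))
  expect_true(all(diff(p) > 0))
  # small rate*horizon: probability ~ rate*horizon
  expect_equal(rate_to_probability(1e-4, 1), 1e-4, tolerance = 1e-4)
  expect_error(rate_to_probability(-1, 1), "nonnegative")
})

test_that("odds-ratio escalation is identity at OR 1 and monotone", {
  expect_equal(apply_odds_ratio(0.5, 1), 0.5)
  expect_equal(apply_odds_ratio(0.029, 8.4), 0.2006, tolerance = 5e-4)
  expect_equal(apply_odds_ratio(0.1, 35.6), 0.7983, tolerance = 5e-4)
  p <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(apply_odds_ratio(p, 3)) > 0))
  or <- c(0.5, 1, 2, 8.4, 35.6)
  expect_true(all(diff(apply_odds_ratio(0.1, or)) > 0))
  expect_error(apply_odds_ratio(1, 2), "\\[0, 1\\)")
})

test_that("default parameters carry the published inputs exactly", {
  p <- default_parameters()
  expect_identical(
    vapply(c("f1","f2","c1","c2","c3","arterial"),
           function(nm) p$ug[[nm]]$mean, numeric(1)),
    c(f1 = 0.164, f2 = 0.049, c1 = 0.029, c2 = 0.041, c3 = 0.047,
      arterial = 0.015))
  expect_identical(
    vapply(c("f1","f2","c1","c2","c3","arterial"),
           function(nm) p$lm[[nm]]$mean, numeric(1)),
    c(f1 = 0.376, f2 = 0.166, c1 = 0.114, c2 = 0.156, c3 = 0.177,
      arterial = 0.081))
  expect_identical(c(p$lm$c1$ci_low, p$lm$c1$ci_high), c(0.096, 0.132))
  expect_identical(c(p$ug$f2$ci_low, p$ug$f2$ci_high), c(0.031, 0.067))
  costs <- vapply(p$ug$cost_map, function(x) x$mean_cost, numeric(1))
  expect_identical(
    costs,
    c("arterial puncture" = 94, "thrombosis" = 131, "embolism" = 131,
      "hydromediastinum" = 133, "hematomediastinum" = 94,
      "hematothorax" = 177, "hydrothorax" = 217, "pneumothorax" = 178,
      "nerve injury" = 347, "subcutaneous emphysema" = 16))
  expect_identical(p$budget$annual_catheters, 568000)
  expect_identical(c(p$budget$adoption_low, p$budget$adoption_high),
                   c(0.10, 0.20))
  expect_identical(p$budget$incremental_cost, -179)
})

test_that("derived beta/gamma parameters reproduce each default's moments", {
  p <- default_parameters()
  for (arm in list(p$ug, p$lm)) {
    for (nm in c("f1", "f2", "c1", "c2", "c3", "arterial")) {
      pp <- arm[[nm]]
      expect_equal(pp$alpha / (pp$alpha + pp$beta), pp$mean,
                   tolerance = 1e-9)
      expect_gt(pp$se, 0)
    }
  }
  for (cp in p$ug$cost_map) {
    expect_equal(cp$shape * cp$scale, cp$mean_cost, tolerance = 1e-9)
    expect_equal(c(cp$low, cp$high), c(0.5, 1.5) * cp$mean_cost)
  }
})

test_that("parameter constructors enforce their invariants", {
  expect_error(probability_param("x", 0.5, 0.6, 0.7), "ci_low <= mean")
  expect_error(probability_param("x", 0.5, 0.4, 1.2), "within \\[0, 1\\]")
  expect_error(cost_param("x", -5), ">= 0")
  expect_error(cost_param("x", 10, low = 12), "low <= mean_cost")
  cm <- default_cost_map()
  p <- default_parameters()
  bad_w <- stats::setNames(rep(0.2, 9),
                           setdiff(names(cm), "arterial puncture"))
  expect_error(
    strategy_params("UG", p$ug$f1, p$ug$f2, p$ug$c1, p$ug$c2, p$ug$c3,
                    p$ug$arterial, cm, other_weights = bad_w),
    "sum to 1")
  expect_equal(sum(p$ug$other_weights), 1, tolerance = 1e-12)
  expect_equal(length(p$ug$other_weights), 9L)
})

test_that("parameters round-trip through a YAML configuration file", {
  cfg <- list(
    strategies = list(
      ug = list(c1 = list(mean = 0.05, ci_low = 0.03, ci_high = 0.08)),
      lm = list(f1 = list(mean = 0.4))),
    costs = list("nerve injury" = list(mean = 500)),
    budget = list(annual_catheters = 100000, adoption_low = 0.05,
                  adoption_high = 0.5))
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  p <- load_parameters(path)
  expect_equal(p$ug$c1$mean, 0.05)
  expect_equal(p$ug$c1$ci_low, 0.03)
  expect_equal(p$lm$f1$mean, 0.4)
  expect_equal(p$lm$f1$ci_low, 0.4)  # no CI given: held fixed
  expect_equal(p$ug$cost_map[["nerve injury"]]$mean_cost, 500)
  expect_equal(p$lm$cost_map[["nerve injury"]]$mean_cost, 500)
  # untouched fields keep their defaults
  expect_equal(p$ug$f1$mean, 0.164)
  expect_equal(p$budget$annual_catheters, 100000)
  expect_equal(p$budget$incremental_cost, -179)
})
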