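# Shared fixtures: random valid strategy parameter sets for property tests.

default_cost_map <- function() default_parameters()$ug$cost_map

# Random parameter set with degenerate CIs (deterministic evaluation only).
random_strategy_params <- function(strategy = "UG") {
  p <- stats::runif(5, 0.01, 0.6)
  names(p) <- c("f1", "f2", "c1", "c2", "c3")
  arterial <- stats::runif(1, 0, p[["c1"]])
  pp <- lapply(names(p), function(nm) probability_param(nm, p[[nm]]))
  names(pp) <- names(p)
  strategy_params(strategy, pp$f1, pp$f2, pp$c1, pp$c2, pp$c3,
                  probability_param("arterial", arterial),
                  default_cost_map())
}

# Parameter set with chosen probability means, default costs.
make_params <- function(strategy = "UG", f1 = 0.1, f2 = 0.1, c1 = 0.05,
                        c2 = 0.05, c3 = 0.05, arterial = 0.02,
                        other_weights = NULL, cost_multiplier = 1) {
  vals <- c(f1 = f1, f2 = f2, c1 = c1, c2 = c2, c3 = c3)
  pp <- lapply(names(vals), function(nm) probability_param(nm, vals[[nm]]))
  names(pp) <- names(vals)
  strategy_params(strategy, pp$f1, pp$f2, pp$c1, pp$c2, pp$c3,
                  probability_param("arterial", arterial),
                  default_cost_map(), other_weights, cost_multiplier)
}

# Closed-form probability of >= 1 complication, written independently of
# the package's internals for oracle comparisons.
oracle_p_any <- function(f1, f2, c1, c2, c3) {
  1 - (1 - c1) * ((1 - f1) + f1 * (1 - c2) * ((1 - f2) + f2 * (1 - c3)))
}
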