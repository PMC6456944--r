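# Deterministic one-way sensitivity analysis with tornado ranking,
# probabilistic sensitivity analysis by Monte Carlo over moment-matched
# beta/gamma distributions, and the intervention-cost threshold analysis.

set_prob_mean <- function(params, which, value) {
  if (value < 0 || value > 1) {
    warning(sprintf("%s bound %.4f outside [0, 1]; clamped", which, value))
    value <- min(max(value, 0), 1)
  }
  params[[which]] <- probability_param(which, value)
  strategy_params(params$strategy, params$f1, params$f2, params$c1,
                  params$c2, params$c3, params$arterial, params$cost_map,
                  params$other_weights, params$cost_multiplier)
}

set_cost_mean <- function(params, which, value) {
  cm <- params$cost_map
  cm[[which]] <- cost_param(which, value)
  strategy_params(params$strategy, params$f1, params$f2, params$c1,
                  params$c2, params$c3, params$arterial, cm,
                  params$other_weights, params$cost_multiplier)
}

dsa_outcomes <- function(ug, lm) {
  cea <- compare_strategies(evaluate_strategy(ug), evaluate_strategy(lm))
  c(delta_cost = cea$delta_cost, delta_effect = cea$delta_effect)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Varies each input parameter to its lower and upper bound with all other
#' parameters at base values, re-evaluating both strategies each time.
#' Probability parameters use their 95% CI as bounds; cost parameters use
#' their DSA range (+/-50% of the mean by default). Because the base-case
#' verdict is dominance (so an ICER ratio is undefined in sign), the
#' tornado reports the swing in incremental cost and incremental effect
#' side by side, each with a percent-of-base annotation.
#'
#' @param ug,lm Base-case `strategy_params`.
#' @param metric Which swing to rank by: `"delta_cost"` (default) or
#'   `"delta_effect"`. Ties broken alphabetically by parameter name.
#' @return A `data.frame`, one row per parameter, sorted by `span`
#'   descending: bounds, outcome at each bound, spans, and percent-of-base.
#' @export
one_way_dsa <- function(ug, lm, metric = c("delta_cost", "delta_effect")) {
  metric <- match.arg(metric)
  base <- dsa_outcomes(ug, lm)
  rows <- list()
  prob_names <- c("f1", "f2", "c1", "c2", "c3", "arterial")

  for (arm_i in 1:2) {
    arm <- if (arm_i == 1L) ug else lm
    at_bound <- function(nm, value) {
      if (arm_i == 1L) {
        dsa_outcomes(set_prob_mean(arm, nm, value), lm)
      } else {
        dsa_outcomes(ug, set_prob_mean(arm, nm, value))
      }
    }
    for (nm in prob_names) {
      p <- arm[[nm]]
      out_lo <- at_bound(nm, p$ci_low)
      out_hi <- at_bound(nm, p$ci_high)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = sprintf("%s %s", arm$strategy, nm),
        low = p$ci_low, high = p$ci_high,
        delta_cost_low = out_lo[["delta_cost"]],
        delta_cost_high = out_hi[["delta_cost"]],
        delta_effect_low = out_lo[["delta_effect"]],
        delta_effect_high = out_hi[["delta_effect"]],
        stringsAsFactors = FALSE)
    }
  }
  # costs are model-wide: vary them in both arms simultaneously
  for (nm in names(ug$cost_map)) {
    cp <- ug$cost_map[[nm]]
    out_lo <- dsa_outcomes(set_cost_mean(ug, nm, cp$low),
                           set_cost_mean(lm, nm, cp$low))
    out_hi <- dsa_outcomes(set_cost_mean(ug, nm, cp$high),
                           set_cost_mean(lm, nm, cp$high))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = sprintf("cost %s", nm),
      low = cp$low, high = cp$high,
      delta_cost_low = out_lo[["delta_cost"]],
      delta_cost_high = out_hi[["delta_cost"]],
      delta_effect_low = out_lo[["delta_effect"]],
      delta_effect_high = out_hi[["delta_effect"]],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df$span_cost <- abs(df$delta_cost_high - df$delta_cost_low)
  df$span_effect <- abs(df$delta_effect_high - df$delta_effect_low)
  df$pct_of_base_cost <- 100 * df$span_cost / 2 / abs(base[["delta_cost"]])
  df$pct_of_base_effect <-
    100 * df$span_effect / 2 / abs(base[["delta_effect"]])
  df$span <- if (metric == "delta_cost") df$span_cost else df$span_effect
  df <- df[order(-df$span, df$parameter), ]
  rownames(df) <- NULL
  df
}

draw_beta <- function(n, param, se_scale) {
  se <- param$se * se_scale
  if (se == 0 || param$mean <= 0 || param$mean >= 1) {
    return(rep(param$mean, n))
  }
  ab <- tryCatch(beta_from_moments(param$mean, se),
                 error = function(e) {
                   stop(sprintf("parameter '%s': %s", param$name,
                                conditionMessage(e)), call. = FALSE)
                 })
  stats::rbeta(n, ab[["alpha"]], ab[["beta"]])
}

draw_gamma <- function(n, param, se_scale) {
  se <- param$se * se_scale
  if (se == 0 || param$mean_cost <= 0) return(rep(param$mean_cost, n))
  sh <- gamma_from_moments(param$mean_cost, se)
  stats::rgamma(n, shape = sh[["shape"]], scale = sh[["scale"]])
}

psa_arm_outcomes <- function(draws, cost_draws, params) {
  p_any <- 1 - (1 - draws$c1) *
    ((1 - draws$f1) + draws$f1 * (1 - draws$c2) *
       ((1 - draws$f2) + draws$f2 * (1 - draws$c3)))
  n_comp <- draws$c1 + draws$f1 * draws$c2 + draws$f1 * draws$f2 * draws$c3
  w_a <- pmin(pmax(ifelse(draws$c1 > 0, draws$arterial / draws$c1, 0), 0), 1)
  w <- params$other_weights
  other <- Reduce(`+`, Map(function(nm) w[[nm]] * cost_draws[[nm]], names(w)))
  unit <- w_a * cost_draws[["arterial puncture"]] + (1 - w_a) * other
  list(cost = unit * n_comp * params$cost_multiplier, p_any = p_any)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation: in every iteration each clinical probability is
#' drawn from its moment-matched beta distribution and each complication
#' cost from its moment-matched gamma distribution (all draws independent;
#' costs are model-wide, so one cost draw applies to both strategies), both
#' strategies are re-evaluated, and the incremental results are recorded.
#' Beta draws cannot exceed 1 and gamma draws cannot go negative, so no
#' clamping is applied.
#'
#' @param ug,lm `strategy_params` for the two strategies.
#' @param iterations Number of Monte Carlo iterations (default 10,000).
#' @param seed Integer seed; the run is fully deterministic given the seed.
#' @param se_scale Multiplier applied to every standard error before
#'   moment matching (default 1). `0` collapses every distribution to its
#'   mean, reproducing the base case exactly.
#' @return A `psa_result`: list with `iterations`, `seed`, `draws` (a
#'   `data.frame` of per-iteration cost/effectiveness per strategy and
#'   increments), `summary` (mean and 2.5th/97.5th percentiles per
#'   quantity), `dominance_fraction` (share of iterations in which UG is
#'   less costly and more effective), and `percentile_method`.
#' @examples
#' p <- default_parameters()
#' psa <- run_psa(p$ug, p$lm, iterations = 500, seed = 1)
#' psa$dominance_fraction
#' @export
run_psa <- function(ug, lm, iterations = 10000, seed = 1, se_scale = 1) {
  if (iterations < 1) stop("iterations must be >= 1")
  set.seed(seed)
  prob_names <- c("f1", "f2", "c1", "c2", "c3", "arterial")
  draw_arm <- function(params) {
    d <- lapply(prob_names, function(nm) {
      draw_beta(iterations, params[[nm]], se_scale)
    })
    names(d) <- prob_names
    d
  }
  d_ug <- draw_arm(ug)
  d_lm <- draw_arm(lm)
  cost_draws <- lapply(ug$cost_map, function(cp) {
    draw_gamma(iterations, cp, se_scale)
  })
  out_ug <- psa_arm_outcomes(d_ug, cost_draws, ug)
  out_lm <- psa_arm_outcomes(d_lm, cost_draws, lm)

  draws <- data.frame(
    cost_ug = out_ug$cost, cost_lm = out_lm$cost,
    effect_ug = 1 - out_ug$p_any, effect_lm = 1 - out_lm$p_any,
    delta_cost = out_ug$cost - out_lm$cost,
    delta_effect = out_lm$p_any - out_ug$p_any
  )
  summarize <- function(x) {
    q <- stats::quantile(x, c(0.025, 0.975), type = 7, names = FALSE)
    c(mean = mean(x), p2.5 = q[1], p97.5 = q[2])
  }
  summ <- as.data.frame(t(vapply(draws, summarize, numeric(3))))
  summ$quantity <- rownames(summ)
  rownames(summ) <- NULL
  summ <- summ[c("quantity", "mean", "p2.5", "p97.5")]
  structure(
    list(iterations = iterations, seed = seed, draws = draws,
         summary = summ,
         dominance_fraction =
           mean(draws$delta_cost < 0 & draws$delta_effect > 0),
         percentile_method = "inclusive linear interpolation (R type 7)"),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations (seed %s)\n", x$iterations,
              format(x$seed)))
  cat(sprintf("  UG dominates LM in %.2f%% of iterations\n",
              100 * x$dominance_fraction))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write the PSA cost-effectiveness-plane scatter to CSV
#'
#' Per-iteration incremental cost and incremental effect, for plotting the
#' cost-effectiveness plane.
#'
#' @param psa A `psa_result`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_psa_scatter <- function(psa, path) {
  stopifnot(inherits(psa, "psa_result"))
  utils::write.csv(psa$draws[c("delta_cost", "delta_effect")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Break-even intervention cost
#'
#' The per-procedure cost of providing ultrasound guidance at which its
#' overall cost advantage disappears: with a base-case incremental cost of
#' `delta_cost_base` (negative = cost saving), adding an intervention cost
#' of exactly `-delta_cost_base` to every UG procedure brings the
#' incremental cost to zero. With the published base case (-179), the
#' intervention stays cost saving up to an intervention cost of 179 euro
#' per catheterization.
#'
#' @param delta_cost_base Base-case incremental cost in euro (UG minus LM);
#'   must be negative for a positive threshold.
#' @return The threshold intervention cost in euro (0, with a warning, if
#'   the intervention is not cost saving at base case).
#' @export
threshold_intervention_cost <- function(delta_cost_base) {
  if (delta_cost_base >= 0) {
    if (delta_cost_base > 0) {
      warning("intervention is not cost saving at base case; threshold is 0")
    }
    return(0)
  }
  -delta_cost_base
}
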