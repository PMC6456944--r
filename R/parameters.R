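# Model inputs: branch probabilities with 95% CIs, per-complication costs,
# budget constants, and the moment-matching transforms used by the PSA.

#' Standard error from a 95% confidence interval
#'
#' Converts the printed 95% CI of a probability into a standard error under
#' the normal approximation: the full CI width spans 2 * 1.96 standard errors.
#'
#' @param ci_low,ci_high Lower and upper 95% confidence limits.
#' @return The implied standard error, `(ci_high - ci_low) / 3.92`.
#' @examples
#' ci_to_se(0.096, 0.132)
#' @export
ci_to_se <- function(ci_low, ci_high) {
  if (ci_high < ci_low) {
    stop("ci_high must be >= ci_low (negative interval width)")
  }
  (ci_high - ci_low) / 3.92
}

#' Moment-matched beta distribution parameters
#'
#' Method-of-moments fit of a beta distribution to a probability parameter:
#' given mean m and standard error s, with nu = m(1-m)/s^2 - 1,
#' alpha = m * nu and beta = (1 - m) * nu. The fitted distribution has
#' exactly the requested mean and variance.
#'
#' @param mean Mean probability, strictly inside (0, 1).
#' @param se Standard error; must satisfy `se^2 < mean * (1 - mean)`.
#' @return Named numeric vector with elements `alpha` and `beta`.
#' @examples
#' beta_from_moments(0.5, 0.05)  # alpha = beta = 49.5
#' @export
beta_from_moments <- function(mean, se) {
  if (mean <= 0 || mean >= 1) stop("mean must lie strictly in (0, 1)")
  if (se <= 0) stop("se must be positive")
  if (se^2 >= mean * (1 - mean)) {
    stop("se^2 >= mean*(1-mean): beta distribution undefined")
  }
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Moment-matched gamma distribution parameters
#'
#' Method-of-moments fit of a gamma distribution to a cost parameter:
#' shape = (mean/se)^2, scale = se^2/mean, so that shape * scale = mean and
#' shape * scale^2 = se^2.
#'
#' @param mean Mean cost (> 0), in euro.
#' @param se Standard error (> 0), in euro.
#' @return Named numeric vector with elements `shape` and `scale`.
#' @examples
#' gamma_from_moments(100, 10)  # shape = 100, scale = 1
#' @export
gamma_from_moments <- function(mean, se) {
  if (mean <= 0) stop("mean must be positive")
  if (se <= 0) stop("se must be positive")
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Rate to probability over a time horizon
#'
#' Transforms a constant event rate into the probability of at least one
#' event over the horizon, `1 - exp(-rate * horizon)`.
#'
#' @param rate Events per unit time (>= 0).
#' @param horizon Time horizon in the rate's time unit (> 0). Default 1 year,
#'   the model's horizon.
#' @return A probability in `[0, 1)`.
#' @export
rate_to_probability <- function(rate, horizon = 1) {
  if (any(rate < 0)) stop("rate must be nonnegative")
  if (any(horizon <= 0)) stop("horizon must be positive")
  1 - exp(-rate * horizon)
}

#' Escalate a probability by an odds ratio
#'
#' Applies an odds ratio to a baseline probability: the baseline odds
#' p/(1-p) are multiplied by `odds_ratio` and transformed back. This is the
#' mechanism reported for the increased complication risk on repeated
#' cannulation attempts (OR 8.4 for the second attempt, 35.6 for the third,
#' relative to the first). Note the published per-attempt complication
#' probabilities are pooled estimates and are used verbatim as defaults;
#' this transform is provided for user-defined scenarios.
#'
#' @param p_base Baseline probability in `[0, 1)`.
#' @param odds_ratio Positive odds ratio.
#' @return The escalated probability.
#' @examples
#' apply_odds_ratio(0.029, 8.4)
#' @export
apply_odds_ratio <- function(p_base, odds_ratio) {
  if (any(p_base < 0) || any(p_base >= 1)) stop("p_base must lie in [0, 1)")
  if (any(odds_ratio <= 0)) stop("odds_ratio must be positive")
  odds <- odds_ratio * p_base / (1 - p_base)
  odds / (1 + odds)
}

#' Construct a probability parameter
#'
#' A branch probability together with its 95% CI and the derived standard
#' error and moment-matched beta shape parameters used by the probabilistic
#' sensitivity analysis.
#'
#' @param name Identifier (e.g. `"c1"`).
#' @param mean Point estimate in `[0, 1]`.
#' @param ci_low,ci_high 95% confidence limits. Default to `mean`
#'   (degenerate interval, zero SE: the parameter is held fixed in the PSA).
#' @return An object of class `probability_param`.
#' @export
probability_param <- function(name, mean, ci_low = mean, ci_high = mean) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(ci_low <= mean && mean <= ci_high)) {
    stop(sprintf("'%s': need ci_low <= mean <= ci_high", name))
  }
  if (ci_low < 0 || ci_high > 1) {
    stop(sprintf("'%s': CI must lie within [0, 1]", name))
  }
  se <- ci_to_se(ci_low, ci_high)
  if (se > 0 && mean > 0 && mean < 1 && se^2 < mean * (1 - mean)) {
    ab <- beta_from_moments(mean, se)
  } else {
    # degenerate (fixed) or over-dispersed: no beta fit; the PSA rejects
    # over-dispersed parameters when asked to draw from them
    ab <- c(alpha = NA_real_, beta = NA_real_)
  }
  structure(
    list(name = name, mean = mean, ci_low = ci_low, ci_high = ci_high,
         se = se, alpha = unname(ab["alpha"]), beta = unname(ab["beta"])),
    class = "probability_param"
  )
}

#' Construct a cost parameter
#'
#' A per-complication treatment cost in euro with its deterministic
#' sensitivity-analysis bounds (default +/-50% of the mean) and
#' moment-matched gamma parameters for the PSA. The PSA standard error
#' defaults to a quarter of the mean, so the +/-50% DSA range corresponds to
#' roughly +/-2 SE.
#'
#' @param name Complication identifier.
#' @param mean_cost Mean cost per complication episode, in euro (>= 0).
#' @param low,high DSA bounds; default `0.5 * mean_cost` and `1.5 * mean_cost`.
#' @param se PSA standard error; default `0.25 * mean_cost`.
#' @return An object of class `cost_param`.
#' @export
cost_param <- function(name, mean_cost, low = 0.5 * mean_cost,
                       high = 1.5 * mean_cost, se = 0.25 * mean_cost) {
  stopifnot(is.character(name), length(name) == 1L)
  if (mean_cost < 0) stop(sprintf("'%s': mean_cost must be >= 0", name))
  if (!(low <= mean_cost && mean_cost <= high)) {
    stop(sprintf("'%s': need low <= mean_cost <= high", name))
  }
  if (mean_cost > 0 && se > 0) {
    sh <- gamma_from_moments(mean_cost, se)
  } else {
    sh <- c(shape = NA_real_, scale = NA_real_)
  }
  structure(
    list(name = name, mean_cost = mean_cost, low = low, high = high, se = se,
         shape = unname(sh["shape"]), scale = unname(sh["scale"])),
    class = "cost_param"
  )
}

#' Construct the full parameter set for one catheterization strategy
#'
#' Bundles the per-attempt failure probabilities (f1, f2), the per-attempt
#' total-complication probabilities (c1, c2, c3), the per-attempt arterial
#' puncture probability, the per-complication cost map, and the weights over
#' the nine non-arterial ("other") complications making up the composite
#' endpoint.
#'
#' @param strategy `"UG"` (ultrasound guidance) or `"LM"` (landmark method).
#' @param f1,f2 `probability_param`s: failure on the first/second attempt.
#' @param c1,c2,c3 `probability_param`s: total complications on attempt 1-3.
#' @param arterial `probability_param`: arterial puncture per attempt.
#' @param cost_map Named list of `cost_param`s, one per complication,
#'   including `"arterial puncture"`.
#' @param other_weights Nonnegative weights over the non-arterial
#'   complications, summing to 1. Default: equal weights, since no incidence
#'   breakdown within the composite endpoint is published.
#' @param cost_multiplier Per-strategy scaling hook applied to expected
#'   cost only (never to effects); default 1.
#' @return An object of class `strategy_params`.
#' @export
strategy_params <- function(strategy, f1, f2, c1, c2, c3, arterial,
                            cost_map, other_weights = NULL,
                            cost_multiplier = 1) {
  strategy <- match.arg(strategy, c("UG", "LM"))
  probs <- list(f1 = f1, f2 = f2, c1 = c1, c2 = c2, c3 = c3,
                arterial = arterial)
  for (nm in names(probs)) {
    if (!inherits(probs[[nm]], "probability_param")) {
      stop(sprintf("'%s' must be a probability_param", nm))
    }
  }
  if (!all(vapply(cost_map, inherits, logical(1), "cost_param"))) {
    stop("cost_map entries must be cost_param objects")
  }
  other_names <- setdiff(names(cost_map), "arterial puncture")
  if (is.null(other_weights)) {
    other_weights <- stats::setNames(
      rep(1 / length(other_names), length(other_names)), other_names)
  }
  if (!setequal(names(other_weights), other_names)) {
    stop("other_weights must be named by the non-arterial complications")
  }
  other_weights <- other_weights[other_names]
  if (any(other_weights < 0)) stop("other_weights must be nonnegative")
  if (abs(sum(other_weights) - 1) > 1e-9) {
    stop("other_weights must sum to 1")
  }
  if (cost_multiplier < 0) stop("cost_multiplier must be >= 0")
  structure(
    list(strategy = strategy, f1 = f1, f2 = f2, c1 = c1, c2 = c2, c3 = c3,
         arterial = arterial, cost_map = cost_map,
         other_weights = other_weights, cost_multiplier = cost_multiplier),
    class = "strategy_params"
  )
}

#' @export
print.strategy_params <- function(x, ...) {
  cat(sprintf("<strategy_params: %s>\n", x$strategy))
  for (nm in c("f1", "f2", "c1", "c2", "c3", "arterial")) {
    p <- x[[nm]]
    cat(sprintf("  %-9s %.3f [%.3f, %.3f]\n", nm, p$mean, p$ci_low, p$ci_high))
  }
  cat(sprintf("  %d complication costs; cost multiplier %g\n",
              length(x$cost_map), x$cost_multiplier))
  invisible(x)
}

#' Construct the budget-impact context
#'
#' @param annual_catheters Central venous catheterizations per year
#'   (default 568,000, the German annual volume).
#' @param adoption_low,adoption_high Assumed ultrasound adoption share range
#'   (default 10-20%).
#' @param incremental_cost Per-procedure incremental cost of ultrasound
#'   guidance vs landmark, in euro (default -179, the published base case).
#' @param incremental_effect Averted complications per person (default: the
#'   base-case incremental effect computed by this model).
#' @return An object of class `budget_context`.
#' @export
budget_context <- function(annual_catheters = 568000,
                           adoption_low = 0.10, adoption_high = 0.20,
                           incremental_cost = -179,
                           incremental_effect = NULL) {
  if (annual_catheters <= 0) stop("annual_catheters must be positive")
  if (!(0 <= adoption_low && adoption_low <= adoption_high &&
        adoption_high <= 1)) {
    stop("need 0 <= adoption_low <= adoption_high <= 1")
  }
  if (is.null(incremental_effect)) {
    incremental_effect <- local({
      p <- default_strategy_probs()
      p_any_closed(p$lm) - p_any_closed(p$ug)
    })
  }
  structure(
    list(annual_catheters = annual_catheters, adoption_low = adoption_low,
         adoption_high = adoption_high, incremental_cost = incremental_cost,
         incremental_effect = incremental_effect),
    class = "budget_context"
  )
}

# Published point estimates as plain numeric vectors (internal fast path
# used by closed-form evaluation before the full objects exist).
default_strategy_probs <- function() {
  list(
    ug = c(f1 = 0.164, f2 = 0.049, c1 = 0.029, c2 = 0.041, c3 = 0.047,
           arterial = 0.015),
    lm = c(f1 = 0.376, f2 = 0.166, c1 = 0.114, c2 = 0.156, c3 = 0.177,
           arterial = 0.081)
  )
}

default_cost_values <- function() {
  c("arterial puncture" = 94, "thrombosis" = 131, "embolism" = 131,
    "hydromediastinum" = 133, "hematomediastinum" = 94,
    "hematothorax" = 177, "hydrothorax" = 217, "pneumothorax" = 178,
    "nerve injury" = 347, "subcutaneous emphysema" = 16)
}

#' Default model parameters
#'
#' The published clinical and cost inputs: per-attempt failure and
#' complication probabilities with 95% CIs for ultrasound guidance (UG) and
#' the landmark method (LM), per-complication treatment costs in euro from
#' the statutory-health-insurance perspective, and the budget-impact
#' constants (568,000 catheterizations/year, 10-20% adoption).
#'
#' @return A list with elements `ug` and `lm` (`strategy_params`) and
#'   `budget` (`budget_context`).
#' @examples
#' p <- default_parameters()
#' p$lm$c1$mean  # 0.114
#' @export
default_parameters <- function() {
  ci <- list(
    ug = list(f1 = c(0.143, 0.183), f2 = c(0.031, 0.067),
              c1 = c(0.019, 0.040), c2 = c(0.029, 0.053),
              c3 = c(0.034, 0.059), arterial = c(0.010, 0.021)),
    lm = list(f1 = c(0.356, 0.395), f2 = c(0.138, 0.193),
              c1 = c(0.096, 0.132), c2 = c(0.136, 0.176),
              c3 = c(0.156, 0.197), arterial = c(0.069, 0.093))
  )
  probs <- default_strategy_probs()
  costs <- default_cost_values()
  cost_map <- lapply(names(costs), function(nm) cost_param(nm, costs[[nm]]))
  names(cost_map) <- names(costs)
  mk <- function(arm, strategy) {
    pp <- lapply(names(probs[[arm]]), function(nm) {
      probability_param(nm, probs[[arm]][[nm]],
                        ci[[arm]][[nm]][1], ci[[arm]][[nm]][2])
    })
    names(pp) <- names(probs[[arm]])
    strategy_params(strategy, pp$f1, pp$f2, pp$c1, pp$c2, pp$c3,
                    pp$arterial, cost_map)
  }
  ug <- mk("ug", "UG")
  lm <- mk("lm", "LM")
  budget <- budget_context(
    incremental_effect = p_any_closed(probs$lm) - p_any_closed(probs$ug))
  list(ug = ug, lm = lm, budget = budget)
}

#' Load model parameters from a configuration file
#'
#' Reads a YAML or JSON file with sections
#' `strategies.ug` / `strategies.lm` (each of `f1, f2, c1, c2, c3, arterial`
#' given as `mean`/`ci_low`/`ci_high`), `costs.<complication>`
#' (`mean`, optional `low`/`high`/`se`), and optional `budget`
#' (`annual_catheters`, `adoption_low`, `adoption_high`). Fields omitted
#' from the file fall back to the embedded defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `ug`, `lm`, and `budget`, as
#'   [default_parameters()].
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported parameter file extension: ", ext)
  }
  base <- default_parameters()
  out <- base
  for (arm in c("ug", "lm")) {
    spec <- cfg$strategies[[arm]]
    if (is.null(spec)) next
    sp <- base[[arm]]
    for (nm in intersect(names(spec), c("f1","f2","c1","c2","c3","arterial"))) {
      v <- spec[[nm]]
      m <- v$mean
      sp[[nm]] <- probability_param(
        nm, m,
        if (is.null(v$ci_low)) m else v$ci_low,
        if (is.null(v$ci_high)) m else v$ci_high)
    }
    out[[arm]] <- strategy_params(sp$strategy, sp$f1, sp$f2, sp$c1, sp$c2,
                                  sp$c3, sp$arterial, sp$cost_map,
                                  sp$other_weights, sp$cost_multiplier)
  }
  if (!is.null(cfg$costs)) {
    cost_map <- out$ug$cost_map
    for (nm in names(cfg$costs)) {
      v <- cfg$costs[[nm]]
      m <- v$mean
      cost_map[[nm]] <- cost_param(
        nm, m,
        if (is.null(v$low)) 0.5 * m else v$low,
        if (is.null(v$high)) 1.5 * m else v$high,
        if (is.null(v$se)) 0.25 * m else v$se)
    }
    for (arm in c("ug", "lm")) {
      sp <- out[[arm]]
      out[[arm]] <- strategy_params(sp$strategy, sp$f1, sp$f2, sp$c1, sp$c2,
                                    sp$c3, sp$arterial, cost_map,
                                    NULL, sp$cost_multiplier)
    }
  }
  if (!is.null(cfg$budget)) {
    b <- cfg$budget
    d <- out$budget
    out$budget <- budget_context(
      annual_catheters = b$annual_catheters %||% d$annual_catheters,
      adoption_low = b$adoption_low %||% d$adoption_low,
      adoption_high = b$adoption_high %||% d$adoption_high,
      incremental_cost = b$incremental_cost %||% d$incremental_cost,
      incremental_effect = b$incremental_effect %||% d$incremental_effect)
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
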