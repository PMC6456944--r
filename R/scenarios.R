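# Structural sensitivity analyses: risk-multiplied populations (doubled or
# tripled complication probabilities, emulating higher-baseline-risk
# patients) and replacement parameter sets for alternative populations
# (paediatric patients, indirect cannulation) supplied via configuration.

#' Define a scenario
#'
#' A scenario is either a complication-probability multiplier (`type =
#' "multiplier"`: c1, c2, c3 and the arterial puncture probability are
#' scaled by `value` in both strategies, failure probabilities untouched)
#' or a full replacement parameter set (`type = "replacement"`).
#'
#' @param name Scenario label.
#' @param type `"multiplier"` or `"replacement"`.
#' @param value Multiplier (> 0) for multiplier scenarios.
#' @param params For replacement scenarios: list with `ug` and `lm`
#'   `strategy_params`.
#' @return A `scenario` object.
#' @export
scenario <- function(name, type = c("multiplier", "replacement"),
                     value = NULL, params = NULL) {
  type <- match.arg(type)
  if (type == "multiplier") {
    if (is.null(value) || value <= 0) stop("multiplier must be > 0")
  } else if (is.null(params$ug) || is.null(params$lm)) {
    stop("replacement scenario needs params$ug and params$lm")
  }
  structure(list(name = name, type = type, value = value, params = params),
            class = "scenario")
}

scale_prob <- function(p, m) {
  mean <- p$mean * m
  lo <- p$ci_low * m
  hi <- p$ci_high * m
  if (hi > 0.999 || mean > 0.999) {
    warning(sprintf("'%s' scaled beyond 0.999; clamped", p$name))
    mean <- min(mean, 0.999)
    lo <- min(lo, 0.999)
    hi <- min(hi, 0.999)
  }
  probability_param(p$name, mean, lo, hi)
}

#' Apply a scenario to both strategies
#'
#' @param ug,lm Base `strategy_params`.
#' @param sc A `scenario`.
#' @return List with transformed `ug` and `lm`.
#' @examples
#' p <- default_parameters()
#' doubled <- apply_scenario(p$ug, p$lm, scenario("x2", value = 2))
#' doubled$lm$c1$mean  # 0.228
#' @export
apply_scenario <- function(ug, lm, sc) {
  stopifnot(inherits(sc, "scenario"))
  if (sc$type == "replacement") {
    return(list(ug = sc$params$ug, lm = sc$params$lm))
  }
  m <- sc$value
  transform <- function(params) {
    strategy_params(params$strategy, params$f1, params$f2,
                    scale_prob(params$c1, m), scale_prob(params$c2, m),
                    scale_prob(params$c3, m), scale_prob(params$arterial, m),
                    params$cost_map, params$other_weights,
                    params$cost_multiplier)
  }
  list(ug = transform(ug), lm = transform(lm))
}

#' Run a list of scenarios
#'
#' Evaluates both strategies under each scenario and lays out the results
#' in the standard structural-sensitivity table: per-strategy cost and
#' complications per person, incremental cost and effect, and the
#' ICER-or-dominance verdict.
#'
#' @param ug,lm Base `strategy_params`.
#' @param scenarios List of `scenario` objects. The base case (multiplier
#'   1) is prepended unless `include_base = FALSE`.
#' @param include_base Include a base-case row first (default `TRUE`).
#' @return A `data.frame`, two rows per scenario.
#' @export
run_scenarios <- function(ug, lm, scenarios = default_scenarios(),
                          include_base = TRUE) {
  if (include_base) {
    scenarios <- c(list(scenario("base", value = 1)), scenarios)
  }
  rows <- lapply(scenarios, function(sc) {
    tr <- apply_scenario(ug, lm, sc)
    tab <- cea_table(tr$ug, tr$lm)
    tab$scenario <- sc$name
    tab
  })
  df <- do.call(rbind, rows)
  df[c("scenario", setdiff(names(df), "scenario"))]
}

#' Default structural scenarios: doubled and tripled complication rates
#'
#' @return List of `scenario` objects.
#' @export
default_scenarios <- function() {
  list(scenario("doubled complication rates", value = 2),
       scenario("tripled complication rates", value = 3))
}

#' Load scenarios from a YAML configuration file
#'
#' Expects a top-level list of entries `{name, type: multiplier|replacement,
#' value}`; replacement entries carry `params` in the same layout as the
#' parameter file's `strategies` section.
#'
#' @param path YAML file path.
#' @param base Base parameters (as from [default_parameters()]), used to
#'   fill unspecified fields of replacement scenarios.
#' @return List of `scenario` objects.
#' @export
load_scenarios <- function(path, base = default_parameters()) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(entry) {
    type <- entry$type %||% "multiplier"
    if (type == "multiplier") {
      scenario(entry$name, "multiplier", value = entry$value)
    } else {
      tmp <- tempfile(fileext = ".yaml")
      on.exit(unlink(tmp))
      yaml::write_yaml(list(strategies = entry$params), tmp)
      repl <- load_parameters(tmp)
      scenario(entry$name, "replacement",
               params = list(ug = repl$ug, lm = repl$lm))
    }
  })
}
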