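# Patient-level microsimulation of the catheterization pathway and
# regeneration of trial-like event tables. Serves two purposes: an
# independent Monte Carlo oracle for the analytic tree, and a synthetic-data
# source for testing the Table-1-style estimation round trip.

#' Simulate a patient-level catheterization cohort
#'
#' Each patient walks the three-attempt pathway: on every attempt reached
#' they draw a total-complication Bernoulli (c1, c2, c3) and, on attempts 1
#' and 2, a failure Bernoulli (f1, f2); failures proceed to the next
#' attempt and the third attempt concludes the episode regardless of
#' outcome. Each complication occurrence is typed as arterial puncture with
#' probability `w_a` (the arterial share used by [attribute_cost()]) or as
#' one of the composite "other" complications drawn by `other_weights`, and
#' accrues that complication's cost.
#'
#' Draws are vectorized over patients in fixed order from a single seeded
#' stream, so a given seed always reproduces the identical cohort.
#'
#' @param params A `strategy_params` object.
#' @param n Number of patients (>= 1).
#' @param seed Integer seed.
#' @return A `data.frame` with one row per patient: `attempts_used`,
#'   `success` (`NA` for patients absorbed at the third attempt, whose
#'   cannulation outcome the model does not resolve), complication type per
#'   attempt (`comp1`, `comp2`, `comp3`; `NA` if none), `n_complications`,
#'   and `total_cost` in euro.
#' @export
simulate_cohort <- function(params, n, seed) {
  stopifnot(inherits(params, "strategy_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    stop("n must be a positive integer")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a finite number")
  }
  set.seed(seed)
  p <- prob_vector(params)
  costs <- vapply(params$cost_map, function(x) x$mean_cost, numeric(1))
  w_a <- if (params$c1$mean > 0) {
    min(max(params$arterial$mean / params$c1$mean, 0), 1)
  } else 0

  comp1 <- stats::runif(n) < p[["c1"]]
  fail1 <- stats::runif(n) < p[["f1"]]
  comp2 <- rep(FALSE, n)
  comp2[fail1] <- stats::runif(sum(fail1)) < p[["c2"]]
  fail2 <- rep(FALSE, n)
  fail2[fail1] <- stats::runif(sum(fail1)) < p[["f2"]]
  reach3 <- fail1 & fail2
  comp3 <- rep(FALSE, n)
  comp3[reach3] <- stats::runif(sum(reach3)) < p[["c3"]]

  attempts_used <- 1L + fail1 + reach3
  success <- rep(NA, n)
  success[!fail1] <- TRUE
  success[fail1 & !fail2] <- TRUE

  draw_types <- function(occurred) {
    types <- rep(NA_character_, n)
    k <- sum(occurred)
    if (k > 0) {
      arterial <- stats::runif(k) < w_a
      t <- character(k)
      t[arterial] <- "arterial puncture"
      if (any(!arterial)) {
        t[!arterial] <- sample(names(params$other_weights), sum(!arterial),
                               replace = TRUE, prob = params$other_weights)
      }
      types[occurred] <- t
    }
    types
  }
  t1 <- draw_types(comp1)
  t2 <- draw_types(comp2)
  t3 <- draw_types(comp3)
  cost_of <- function(types) ifelse(is.na(types), 0, costs[types])
  total_cost <- (cost_of(t1) + cost_of(t2) + cost_of(t3)) *
    params$cost_multiplier

  data.frame(
    attempts_used = attempts_used,
    success = success,
    comp1 = t1, comp2 = t2, comp3 = t3,
    n_complications = comp1 + comp2 + comp3,
    total_cost = total_cost,
    stringsAsFactors = FALSE
  )
}

#' Summarize a simulated cohort
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @return List with empirical `p_any_complication`, its Monte Carlo
#'   standard error, mean `expected_cost` with standard error, and `n`.
#' @export
summarize_cohort <- function(cohort) {
  n <- nrow(cohort)
  p_any <- mean(cohort$n_complications > 0)
  list(
    n = n,
    p_any_complication = p_any,
    p_any_se = sqrt(p_any * (1 - p_any) / n),
    expected_cost = mean(cohort$total_cost),
    cost_se = stats::sd(cohort$total_cost) / sqrt(n)
  )
}

#' Simulate a trial-like event table for one arm
#'
#' Draws aggregate event counts along the pathway (binomial at each node):
#' first-attempt failures among `n` patients, second-attempt failures among
#' those, total complications per attempt among patients reaching it, and
#' arterial punctures across all attempts made. Emulates the kind of pooled
#' event table from which the model's per-attempt probabilities and CIs are
#' estimated.
#'
#' @param params Generating `strategy_params`.
#' @param n Patients in the arm.
#' @param seed Integer seed.
#' @return A `synthetic_trial`: list of denominators and event counts.
#' @export
simulate_trial <- function(params, n, seed) {
  stopifnot(inherits(params, "strategy_params"))
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  p <- prob_vector(params)
  a <- params$arterial$mean
  n1 <- as.integer(n)
  fail1 <- stats::rbinom(1, n1, p[["f1"]])
  n2 <- fail1
  fail2 <- if (n2 > 0) stats::rbinom(1, n2, p[["f2"]]) else 0L
  n3 <- fail2
  comp1 <- stats::rbinom(1, n1, p[["c1"]])
  comp2 <- if (n2 > 0) stats::rbinom(1, n2, p[["c2"]]) else 0L
  comp3 <- if (n3 > 0) stats::rbinom(1, n3, p[["c3"]]) else 0L
  n_attempts <- n1 + n2 + n3
  arterial <- stats::rbinom(1, n_attempts, a)
  structure(
    list(strategy = params$strategy,
         denominators = c(f1 = n1, f2 = n2, c1 = n1, c2 = n2, c3 = n3,
                          arterial = n_attempts),
         events = c(f1 = fail1, f2 = fail2, c1 = comp1, c2 = comp2,
                    c3 = comp3, arterial = arterial)),
    class = "synthetic_trial"
  )
}

#' Estimate strategy parameters from a trial event table
#'
#' Point estimates are simple proportions events/denominator; 95% CIs are
#' Wilson score intervals (via `prop.test` without continuity correction),
#' whose coverage is close to nominal at the event counts involved. The CI
#' method is recorded in the result's `ci_method` attribute.
#'
#' @param trial A `synthetic_trial` from [simulate_trial()].
#' @param cost_map Cost parameters to attach (default: the embedded costs).
#' @return A `strategy_params` object with estimated probabilities.
#' @export
estimate_params <- function(trial, cost_map = NULL) {
  stopifnot(inherits(trial, "synthetic_trial"))
  if (any(trial$denominators == 0)) {
    stop("zero denominator for: ",
         paste(names(trial$denominators)[trial$denominators == 0],
               collapse = ", "))
  }
  if (is.null(cost_map)) cost_map <- default_parameters()$ug$cost_map
  pp <- lapply(names(trial$events), function(nm) {
    x <- trial$events[[nm]]
    n <- trial$denominators[[nm]]
    ci <- stats::prop.test(x, n, correct = FALSE)$conf.int
    probability_param(nm, x / n, ci[1], ci[2])
  })
  names(pp) <- names(trial$events)
  out <- strategy_params(trial$strategy, pp$f1, pp$f2, pp$c1, pp$c2, pp$c3,
                         pp$arterial, cost_map)
  attr(out, "ci_method") <- "wilson"
  out
}

#' Write a cohort to CSV
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
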