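# Incremental cost-effectiveness and dominance verdicts.

#' Compare two strategies
#'
#' Computes incremental cost (intervention minus comparator), incremental
#' effect (comparator's complication probability minus the intervention's,
#' i.e. averted complications per person), and the verdict: `"dominates"`
#' when the intervention is less costly and more effective, `"dominated"`
#' when it is more costly and less effective, `"equal-effect"` when the
#' incremental effect is zero (the ICER is undefined), and otherwise
#' `"icer"` with ICER = incremental cost / incremental effect in euro per
#' averted complication. Dominance is always reported as a verdict, never
#' as a negative ratio.
#'
#' @param intervention,comparator `strategy_result` objects (intervention =
#'   ultrasound guidance, comparator = landmark method in the base case).
#' @return A `cea_result`: list with `delta_cost`, `delta_effect`, `icer`
#'   (`NA` unless the verdict is `"icer"`), and `verdict`.
#' @examples
#' p <- default_parameters()
#' compare_strategies(evaluate_strategy(p$ug), evaluate_strategy(p$lm))
#' @export
compare_strategies <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "strategy_result"),
            inherits(comparator, "strategy_result"))
  delta_cost <- intervention$expected_cost - comparator$expected_cost
  delta_effect <- comparator$p_any_complication -
    intervention$p_any_complication
  if (delta_cost < 0 && delta_effect > 0) {
    verdict <- "dominates"; icer <- NA_real_
  } else if (delta_cost > 0 && delta_effect < 0) {
    verdict <- "dominated"; icer <- NA_real_
  } else if (delta_effect == 0) {
    verdict <- "equal-effect"; icer <- NA_real_
  } else {
    verdict <- "icer"; icer <- delta_cost / delta_effect
  }
  structure(
    list(delta_cost = delta_cost, delta_effect = delta_effect,
         icer = icer, verdict = verdict),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> incremental cost €%.2f, incremental effect %.4f\n",
              x$delta_cost, x$delta_effect))
  cat(if (x$verdict == "icer") {
    sprintf("  ICER: €%.0f per averted complication\n", x$icer)
  } else {
    sprintf("  verdict: %s\n", x$verdict)
  })
  invisible(x)
}

#' Base-case comparison table
#'
#' Evaluates both strategies and lays the results out in the conventional
#' two-row incremental cost-effectiveness format (costs, incremental costs,
#' complications per person, incremental effect, ICER-or-verdict).
#'
#' @param ug,lm `strategy_params` for the two strategies.
#' @param path Optional CSV output path.
#' @return A `data.frame`, invisibly written to `path` if given.
#' @export
cea_table <- function(ug, lm, path = NULL) {
  r_ug <- evaluate_strategy(ug)
  r_lm <- evaluate_strategy(lm)
  cea <- compare_strategies(r_ug, r_lm)
  df <- data.frame(
    strategy = c("Ultrasound guidance", "Landmark method"),
    cost = c(r_ug$expected_cost, r_lm$expected_cost),
    incremental_cost = c(cea$delta_cost, NA),
    complications_per_person = c(r_ug$p_any_complication,
                                 r_lm$p_any_complication),
    incremental_effect = c(cea$delta_effect, NA),
    icer_or_verdict = c(if (is.na(cea$icer)) cea$verdict else
      sprintf("%.0f", cea$icer), ""),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
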