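# Payer-level budget impact: annual savings and averted complications from
# partial adoption of ultrasound guidance.

#' Project annual budget impact at a given adoption share
#'
#' Scales the per-procedure incremental cost and incremental effect by the
#' number of ultrasound-guided catheterizations performed per year
#' (adoption share x annual volume). Reported figures round savings to
#' 0.1 million euro and averted complications to the nearest 1,000.
#'
#' @param ctx A `budget_context`.
#' @param adoption Adoption fraction in `[0, 1]`.
#' @return A `data.frame` with one row: `adoption`, `n_ug`
#'   (catheterizations/year), `annual_cost_delta` (euro/year, negative =
#'   saving), `annual_complications_averted`, plus rounded reporting
#'   columns `savings_million_eur` and `averted_rounded`.
#' @examples
#' project_budget(budget_context(), 0.10)
#' @export
project_budget <- function(ctx, adoption) {
  stopifnot(inherits(ctx, "budget_context"))
  if (adoption < 0 || adoption > 1) stop("adoption must lie in [0, 1]")
  n_ug <- adoption * ctx$annual_catheters
  cost_delta <- n_ug * ctx$incremental_cost
  averted <- n_ug * ctx$incremental_effect
  data.frame(
    adoption = adoption,
    n_ug = n_ug,
    annual_cost_delta = cost_delta,
    annual_complications_averted = averted,
    savings_million_eur = round(-cost_delta / 1e6, 1),
    averted_rounded = round(averted / 1000) * 1000
  )
}

#' Budget impact over the configured adoption range
#'
#' @param ctx A `budget_context`.
#' @param adoptions Adoption fractions to project (default: the context's
#'   low and high shares).
#' @param path Optional CSV output path.
#' @return A `data.frame`, one row per adoption share.
#' @export
budget_table <- function(ctx, adoptions = c(ctx$adoption_low,
                                            ctx$adoption_high),
                         path = NULL) {
  df <- do.call(rbind, lapply(adoptions, function(a) project_budget(ctx, a)))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
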