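# Three-attempt catheterization decision tree: construction, expected-value
# rollback, and closed-form evaluation.
#
# Tree semantics: every patient reaching attempt k first faces the
# total-complication chance c_k; attempts 1 and 2 then split into
# success/failure with probabilities f1, f2, failures proceeding to the next
# attempt; attempt 3 is terminal whether or not it succeeds. A patient's
# event indicator is 1 if a complication occurred on any attempt reached;
# complication draws are independent across attempts. Each
# attempt-with-complication accrues the expected cost of one complication
# occurrence (see attribute_cost()).

# Closed-form probability of >= 1 complication. `p` is a named numeric
# vector (f1, f2, c1, c2, c3); vectorized over iterations for the PSA.
p_any_closed <- function(p) {
  f1 <- p[["f1"]]; f2 <- p[["f2"]]
  c1 <- p[["c1"]]; c2 <- p[["c2"]]; c3 <- p[["c3"]]
  1 - (1 - c1) * ((1 - f1) + f1 * (1 - c2) * ((1 - f2) + f2 * (1 - c3)))
}

# Expected number of attempt-with-complication occurrences per patient:
# attempt 2 is reached with probability f1, attempt 3 with f1*f2.
expected_complication_count <- function(p) {
  p[["c1"]] + p[["f1"]] * p[["c2"]] + p[["f1"]] * p[["f2"]] * p[["c3"]]
}

prob_vector <- function(params) {
  vapply(c("f1", "f2", "c1", "c2", "c3"),
         function(nm) params[[nm]]$mean, numeric(1))
}

#' Expected cost of one complication occurrence
#'
#' Splits a complication occurrence into "arterial puncture" and the
#' composite "other complications" endpoint. The arterial share
#' `w_a = arterial / c_ref` is the ratio of the per-attempt arterial
#' puncture probability to a reference total-complication probability
#' (first-attempt total by default), clamped to `[0, 1]`; the remaining
#' share is distributed over the nine other complications by
#' `other_weights`.
#'
#' @param params A `strategy_params` object.
#' @param c_ref Reference total-complication probability used for the
#'   arterial share; defaults to the first-attempt total `c1`.
#' @return Expected cost in euro of a single complication occurrence.
#' @examples
#' p <- default_parameters()
#' attribute_cost(p$lm)  # ~112.6
#' @export
attribute_cost <- function(params, c_ref = params$c1$mean) {
  stopifnot(inherits(params, "strategy_params"))
  costs <- vapply(params$cost_map, function(x) x$mean_cost, numeric(1))
  w_a <- if (c_ref > 0) params$arterial$mean / c_ref else 0
  w_a <- min(max(w_a, 0), 1)
  other <- sum(params$other_weights * costs[names(params$other_weights)])
  w_a * costs[["arterial puncture"]] + (1 - w_a) * other
}

chance_node <- function(label, branches) {
  p <- vapply(branches, `[[`, numeric(1), "p")
  if (any(p < 0 | p > 1)) stop("branch probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("branch probabilities at '%s' sum to %.12f, not 1",
                 label, sum(p)))
  }
  structure(list(label = label, branches = branches), class = "chance_node")
}

terminal_node <- function(label, cost, n_complications) {
  if (cost < 0) stop("terminal cost must be >= 0")
  structure(list(label = label, cost = cost,
                 event = as.integer(n_complications > 0),
                 n_complications = n_complications),
            class = "terminal_node")
}

#' Build the three-attempt catheterization tree for one strategy
#'
#' @param params A `strategy_params` object.
#' @param unit_cost Cost accrued per attempt-with-complication; defaults to
#'   [attribute_cost()] of `params`, scaled by the strategy's
#'   `cost_multiplier`.
#' @return The root `chance_node` of the tree.
#' @export
build_tree <- function(params, unit_cost = NULL) {
  stopifnot(inherits(params, "strategy_params"))
  if (is.null(unit_cost)) {
    unit_cost <- attribute_cost(params) * params$cost_multiplier
  }
  p <- prob_vector(params)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")

  attempt <- function(k, n_comp_so_far) {
    ck <- p[[paste0("c", k)]]
    after_complication <- function(n_comp) {
      if (k == 3L) {
        # third attempt is terminal whether or not cannulation succeeds
        terminal_node(sprintf("attempt 3 done (%d complications)", n_comp),
                      n_comp * unit_cost, n_comp)
      } else {
        fk <- p[[paste0("f", k)]]
        chance_node(
          sprintf("attempt %d cannulation", k),
          list(
            list(p = fk, node = attempt(k + 1L, n_comp)),
            list(p = 1 - fk,
                 node = terminal_node(
                   sprintf("success on attempt %d (%d complications)",
                           k, n_comp),
                   n_comp * unit_cost, n_comp))
          )
        )
      }
    }
    chance_node(
      sprintf("attempt %d complication", k),
      list(
        list(p = ck, node = after_complication(n_comp_so_far + 1L)),
        list(p = 1 - ck, node = after_complication(n_comp_so_far))
      )
    )
  }
  attempt(1L, 0L)
}

#' Evaluate a decision tree by expected-value rollback
#'
#' Enumerates every root-to-terminal path, multiplying branch probabilities,
#' and accumulates expected cost and the probability of at least one
#' complication.
#'
#' @param tree Root `chance_node` as returned by [build_tree()].
#' @return A `strategy_result`: list with `expected_cost` (euro/person),
#'   `p_any_complication`, and `effectiveness = 1 - p_any_complication`.
#' @export
evaluate_tree <- function(tree) {
  acc <- c(prob = 0, cost = 0, event = 0)
  walk <- function(node, prob) {
    if (inherits(node, "terminal_node")) {
      acc["prob"] <<- acc["prob"] + prob
      acc["cost"] <<- acc["cost"] + prob * node$cost
      acc["event"] <<- acc["event"] + prob * node$event
    } else {
      p <- vapply(node$branches, `[[`, numeric(1), "p")
      if (abs(sum(p) - 1) > 1e-9) {
        stop("branch probabilities do not sum to 1 at node: ", node$label)
      }
      for (br in node$branches) walk(br$node, prob * br$p)
    }
  }
  walk(tree, 1)
  if (abs(acc[["prob"]] - 1) > 1e-9) {
    stop("terminal path probabilities do not sum to 1")
  }
  strategy_result(acc[["cost"]], acc[["event"]])
}

strategy_result <- function(expected_cost, p_any_complication) {
  if (p_any_complication < 0 || p_any_complication > 1) {
    stop("p_any_complication must lie in [0, 1]")
  }
  if (expected_cost < 0) stop("expected_cost must be >= 0")
  structure(
    list(expected_cost = expected_cost,
         p_any_complication = p_any_complication,
         effectiveness = 1 - p_any_complication),
    class = "strategy_result"
  )
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf(
    "<strategy_result> cost €%.2f/person, P(>=1 complication) %.4f, effectiveness %.4f\n",
    x$expected_cost, x$p_any_complication, x$effectiveness))
  invisible(x)
}

#' Evaluate one strategy analytically
#'
#' Closed-form counterpart of [build_tree()] + [evaluate_tree()]:
#' `p_any = 1 - (1-c1) * [(1-f1) + f1 (1-c2) ((1-f2) + f2 (1-c3))]` and
#' expected cost = unit cost x expected number of attempt-with-complication
#' occurrences `c1 + f1 c2 + f1 f2 c3`. Both routes agree to machine
#' precision; the analytic route is the fast path used by the sensitivity
#' analyses.
#'
#' @inheritParams build_tree
#' @return A `strategy_result`.
#' @examples
#' p <- default_parameters()
#' evaluate_strategy(p$ug)$p_any_complication  # ~0.0359
#' @export
evaluate_strategy <- function(params, unit_cost = NULL) {
  stopifnot(inherits(params, "strategy_params"))
  if (is.null(unit_cost)) {
    unit_cost <- attribute_cost(params) * params$cost_multiplier
  }
  p <- prob_vector(params)
  strategy_result(unit_cost * expected_complication_count(p),
                  p_any_closed(p))
}

#' Export a decision tree as JSON
#'
#' Serializes the nested node structure (labels, branch probabilities,
#' terminal costs and event indicators) for inspection or comparison with
#' other decision-tree tools.
#'
#' @param tree Root `chance_node`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly if written to `path`.
#' @export
tree_to_json <- function(tree, path = NULL) {
  strip <- function(node) {
    if (inherits(node, "terminal_node")) {
      list(type = "terminal", label = node$label, cost = node$cost,
           event = node$event, n_complications = node$n_complications)
    } else {
      list(type = "chance", label = node$label,
           branches = lapply(node$branches, function(br) {
             list(p = br$p, node = strip(br$node))
           }))
    }
  }
  js <- jsonlite::toJSON(strip(tree), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
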