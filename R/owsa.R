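# One-way (univariate) deterministic sensitivity analysis with tornado
# ordering: each scalar parameter is moved to its lower and upper bound in
# turn, all others held at base, and the outcome range per parameter is
# tabulated in descending order.

OWSA_PARAMS <- c("int_mean_cost", "con_mean_cost",
                 "int_mean_effect", "con_mean_effect",
                 "threshold", "brl_per_usd")

#' Bounds for a one-way sensitivity parameter
#'
#' Bounds come from a reported confidence interval when one exists, from a
#' +/-15% variation otherwise (the conventional fallback), or from explicit
#' custom values.
#'
#' @param param_name One of `"int_mean_cost"`, `"con_mean_cost"`,
#'   `"int_mean_effect"`, `"con_mean_effect"`, `"threshold"`,
#'   `"brl_per_usd"`.
#' @param base_value The base-case value of the parameter.
#' @param source `"pct15"`, `"CI"` or `"custom"`.
#' @param ci Length-2 numeric `(low, high)`; required for `"CI"` and
#'   `"custom"`.
#' @param pct Relative variation for `"pct15"` (default 0.15).
#' @return An object of class `param_bound` with `low <= high`.
#' @export
#' @examples
#' make_bounds("int_mean_cost", 317.73, "pct15")
make_bounds <- function(param_name, base_value,
                        source = c("pct15", "CI", "custom"),
                        ci = NULL, pct = 0.15) {
  source <- match.arg(source)
  stopifnot(is.numeric(base_value), length(base_value) == 1L)
  if (source == "pct15") {
    low <- base_value * (1 - pct)
    high <- base_value * (1 + pct)
    if (low > high) { tmp <- low; low <- high; high <- tmp }  # negative base
  } else {
    if (is.null(ci) || length(ci) != 2L || !is.numeric(ci)) {
      stop("'ci' (low, high) is required for CI/custom bounds", call. = FALSE)
    }
    if (ci[1] > ci[2]) stop("bound low exceeds high", call. = FALSE)
    low <- ci[1]; high <- ci[2]
  }
  structure(list(param_name = param_name, base = base_value,
                 low = low, high = high, bound_source = source),
            class = "param_bound")
}

owsa_base_params <- function(int_arm, con_arm, thr, fx) {
  c(int_mean_cost = int_arm$mean_cost, con_mean_cost = con_arm$mean_cost,
    int_mean_effect = int_arm$mean_effect, con_mean_effect = con_arm$mean_effect,
    threshold = thr$value, brl_per_usd = fx$brl_per_usd)
}

owsa_eval <- function(params, thr_currency, outcome) {
  int <- strategy_arm("INT", max(params[["int_mean_cost"]], 0),
                      max(params[["int_mean_effect"]], 0))
  con <- strategy_arm("CON", max(params[["con_mean_cost"]], 0),
                      max(params[["con_mean_effect"]], 0))
  res <- compute_icer(int, con)
  if (outcome == "icer") {
    res$icer
  } else {
    compute_inmb(res, threshold(params[["threshold"]], thr_currency),
                 currency_spec(params[["brl_per_usd"]]))$inmb
  }
}

#' Run a one-way sensitivity analysis
#'
#' Re-evaluates the chosen outcome (ICER or incremental net monetary
#' benefit) with each parameter at its lower and upper bound while all
#' others stay at base, then sorts rows by descending range (ties keep
#' input order). ICER rows whose bound interval makes the incremental
#' effect or cost change sign are flagged `unstable` -- the ratio scale is
#' not monotone across quadrants there, and the iNMB outcome is the better
#' tornado display.
#'
#' @param int_arm,con_arm Base-case [strategy_arm()] objects.
#' @param bounds List of [make_bounds()] objects.
#' @param outcome `"icer"` or `"inmb"`.
#' @param thr A [threshold()] (base value; also a variable parameter).
#' @param fx A [currency_spec()].
#' @return A `data.frame` of class `tornado` with one row per bound:
#'   `param_name`, `low`, `high`, `outcome_at_low`, `outcome_at_high`,
#'   `outcome_at_base`, `range`, `unstable`.
#' @export
run_owsa <- function(int_arm, con_arm, bounds, outcome = c("icer", "inmb"),
                     thr = threshold(), fx = currency_spec()) {
  outcome <- match.arg(outcome)
  stopifnot(is.list(bounds),
            all(vapply(bounds, inherits, logical(1), "param_bound")))
  base <- owsa_base_params(int_arm, con_arm, thr, fx)
  unknown <- setdiff(vapply(bounds, `[[`, character(1), "param_name"),
                     names(base))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         "; valid names: ", paste(names(base), collapse = ", "),
         call. = FALSE)
  }
  base_out <- owsa_eval(base, thr$currency, outcome)
  rows <- lapply(bounds, function(b) {
    at <- function(v) {
      p <- base; p[[b$param_name]] <- v
      owsa_eval(p, thr$currency, outcome)
    }
    lo <- at(b$low); hi <- at(b$high)
    # sign instability across the bound: dE or dC crosses zero
    delta_at <- function(v, which) {
      p <- base; p[[b$param_name]] <- v
      if (which == "e") p[["int_mean_effect"]] - p[["con_mean_effect"]]
      else p[["int_mean_cost"]] - p[["con_mean_cost"]]
    }
    unstable <- outcome == "icer" &&
      (sign(delta_at(b$low, "e")) != sign(delta_at(b$high, "e")) ||
       sign(delta_at(b$low, "c")) != sign(delta_at(b$high, "c")))
    data.frame(param_name = b$param_name, low = b$low, high = b$high,
               outcome_at_low = lo, outcome_at_high = hi,
               outcome_at_base = base_out,
               range = abs(hi - lo), unstable = unstable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # stable sort: descending range, ties broken by input order
  out <- out[order(-out$range), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}
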