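# Base-case cost-utility computation: QALY accrual, incremental cost and
# effect, ICER with dominance status, net monetary benefit.

#' Quality-adjusted life years over a horizon
#'
#' QALYs integrate duration and quality of life: a utility weight accrued
#' over `weeks / weeks_per_year` of a year. A utility of 1 over a 52-week
#' horizon is exactly 1 QALY.
#'
#' @param u A [utility_param()] (or a bare numeric utility in \[0, 1\]).
#' @param h A [time_horizon()].
#' @return QALYs accrued over the horizon.
#' @export
#' @examples
#' compute_qaly(utility_param("ward", 0.724), time_horizon(12)) # 0.16708
compute_qaly <- function(u, h = time_horizon()) {
  stopifnot(inherits(h, "time_horizon"))
  util <- if (inherits(u, "utility_param")) u$utility else u
  if (!is.numeric(util) || any(util < 0) || any(util > 1)) {
    stop("utility must lie in [0, 1]", call. = FALSE)
  }
  util * (h$weeks / h$weeks_per_year)
}

#' Incremental cost-effectiveness ratio with dominance status
#'
#' Computes `delta_cost = C_int - C_con`, `delta_effect = E_int - E_con` and
#' `ICER = delta_cost / delta_effect`, and classifies the comparison:
#'
#' * `dominant`: strictly cheaper and strictly more effective (`dC < 0`,
#'   `dE > 0`); the ratio is suppressed in reports -- the status carries the
#'   decision.
#' * `dominated`: strictly costlier and strictly less effective.
#' * `trade-off-NE`: more effective at extra cost (north-east quadrant; the
#'   ICER against the threshold decides). Also used, with an infinite-ratio
#'   flag, for `dE = 0, dC > 0`.
#' * `trade-off-SW`: cheaper but less effective (flagged infinite when
#'   `dE = 0, dC < 0`).
#' * `indifferent`: `dC = 0` and `dE = 0`; the ICER is undefined (`NaN`).
#'
#' @param int_arm,con_arm [strategy_arm()] objects (intervention, comparator).
#' @return An object of class `icer_result` with fields `delta_cost`,
#'   `delta_effect`, `icer`, `status`, `infinite` and the two arms.
#' @export
#' @examples
#' compute_icer(strategy_arm("INT", 317.73, 0.23),
#'              strategy_arm("CON", 293.93, 0.20))
compute_icer <- function(int_arm, con_arm) {
  stopifnot(inherits(int_arm, "strategy_arm"), inherits(con_arm, "strategy_arm"))
  dc <- int_arm$mean_cost - con_arm$mean_cost
  de <- int_arm$mean_effect - con_arm$mean_effect
  infinite <- FALSE
  if (de > 0) {
    status <- if (dc < 0) "dominant" else "trade-off-NE"
    icer <- dc / de
  } else if (de < 0) {
    status <- if (dc > 0) "dominated" else "trade-off-SW"
    icer <- dc / de
  } else if (dc == 0) {
    status <- "indifferent"
    icer <- NaN
  } else {
    # equal effect, unequal cost: undefined ratio, decision by cost sign
    status <- if (dc > 0) "trade-off-NE" else "trade-off-SW"
    icer <- sign(dc) * Inf
    infinite <- TRUE
  }
  structure(list(delta_cost = dc, delta_effect = de, icer = icer,
                 status = status, infinite = infinite,
                 int_arm = int_arm, con_arm = con_arm),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("Incremental analysis (%s vs %s)\n", x$int_arm$name, x$con_arm$name))
  cat(sprintf("  delta cost:   %.2f USD\n", round_half_up(x$delta_cost)))
  cat(sprintf("  delta effect: %.2f QALY\n", round_half_up(x$delta_effect)))
  if (x$status %in% c("dominant", "dominated")) {
    cat(sprintf("  status: %s (ICER suppressed)\n", x$status))
  } else if (is.finite(x$icer)) {
    cat(sprintf("  ICER: %.2f USD/QALY (%s)\n", round_half_up(x$icer), x$status))
  } else {
    cat(sprintf("  ICER: undefined (%s)\n", x$status))
  }
  invisible(x)
}

#' Incremental net monetary benefit
#'
#' `iNMB = lambda_usd * delta_effect - delta_cost`, with the threshold
#' converted to USD/QALY when expressed in BRL. A positive iNMB is
#' equivalent, for `delta_effect > 0`, to the ICER falling below the
#' threshold.
#'
#' @param result An `icer_result` from [compute_icer()].
#' @param thr A [threshold()].
#' @param fx A [currency_spec()] for BRL thresholds.
#' @return An object of class `nmb_result` with `lambda_usd` and `inmb`.
#' @export
compute_inmb <- function(result, thr = threshold(), fx = currency_spec()) {
  stopifnot(inherits(result, "icer_result"))
  lambda <- threshold_usd(thr, fx)
  structure(list(lambda_usd = lambda,
                 inmb = lambda * result$delta_effect - result$delta_cost),
            class = "nmb_result")
}

#' @export
print.nmb_result <- function(x, ...) {
  cat(sprintf("iNMB at lambda = %.2f USD/QALY: %.2f USD (%s)\n",
              x$lambda_usd, round_half_up(x$inmb),
              if (x$inmb > 0) "cost-effective" else "not cost-effective"))
  invisible(x)
}
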