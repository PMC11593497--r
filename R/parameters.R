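# Domain types for study inputs: resource cost lines, currency conversion,
# public-tariff correction, utilities, time horizon, willingness-to-pay
# threshold and strategy arms, plus config ingestion.

#' Cost item
#'
#' One resource line of a costing table: a label, a unit count, a unit cost,
#' its currency and the information source. `source` matters because public
#' procedure-tariff lines (source `"SIGTAP"`) may require a correction factor
#' (see [cost_correction()]); `corrected` is a provenance flag that makes a
#' double application of that factor a detectable error.
#'
#' @param resource_label Character description of the resource.
#' @param unit_cost Cost per unit (>= 0).
#' @param n_units Positive integer number of units (default 1).
#' @param currency `"USD"` or `"BRL"`.
#' @param source Information source, e.g. `"SIGTAP"` or `"market price"`.
#' @param period Optional character, e.g. `"per month"` or a printed quantity
#'   note when `unit_cost` already holds a line total.
#' @param corrected Logical; `TRUE` once a tariff correction has been applied.
#' @return An object of class `cost_item`.
#' @seealso [apply_cost_correction()], [total_cost()], [read_cost_items()]
#' @export
#' @examples
#' cost_item("IMT device", 1200, source = "market price")
cost_item <- function(resource_label, unit_cost, n_units = 1L,
                      currency = c("USD", "BRL"), source = "market price",
                      period = NULL, corrected = FALSE) {
  currency <- match.arg(currency)
  stopifnot(is.character(resource_label), length(resource_label) == 1L)
  if (!is.numeric(unit_cost) || length(unit_cost) != 1L || is.na(unit_cost) ||
      unit_cost < 0) {
    stop("'unit_cost' must be a single non-negative number", call. = FALSE)
  }
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 1L) {
    stop("'n_units' must be a positive integer", call. = FALSE)
  }
  structure(
    list(resource_label = resource_label, n_units = n_units,
         unit_cost = as.numeric(unit_cost), currency = currency,
         source = source, period = period, corrected = isTRUE(corrected)),
    class = "cost_item")
}

#' Currency specification
#'
#' Exchange rate between Brazilian reais and US dollars. The default, 5.10
#' BRL per USD, is the study-period average rate used throughout the engine.
#'
#' @param brl_per_usd Positive exchange rate (BRL per 1 USD).
#' @return An object of class `currency_spec`.
#' @export
currency_spec <- function(brl_per_usd = 5.10) {
  if (!is.numeric(brl_per_usd) || length(brl_per_usd) != 1L ||
      is.na(brl_per_usd) || brl_per_usd <= 0) {
    stop("'brl_per_usd' must be a single positive number", call. = FALSE)
  }
  structure(list(brl_per_usd = as.numeric(brl_per_usd)),
            class = "currency_spec")
}

#' Tariff correction specification
#'
#' Public procedure-tariff values (SIGTAP, the Brazilian Ministry of Health
#' procedure table) represent only about a third of actual federal spending,
#' so a multiplicative correction -- 2.8 by default -- is applied to lines
#' whose `source` is in `applies_to`.
#'
#' @param factor Positive multiplier (default 2.8).
#' @param applies_to Character vector of source labels the factor applies to.
#' @return An object of class `cost_correction`.
#' @export
cost_correction <- function(factor = 2.8, applies_to = "SIGTAP") {
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) ||
      factor <= 0) {
    stop("'factor' must be a single positive number", call. = FALSE)
  }
  structure(list(factor = as.numeric(factor),
                 applies_to = as.character(applies_to)),
            class = "cost_correction")
}

#' Health-state utility parameter
#'
#' A preference weight in \[0, 1\] for a health state, with the disutility
#' decrement (in \[-1, 0\]) that produced it and the care setting it refers
#' to (general ward vs intensive care).
#'
#' @param label Character name for the state.
#' @param utility Utility weight in \[0, 1\].
#' @param disutility Decrement in \[-1, 0\] (default 0).
#' @param setting `"ward"` or `"ICU"`.
#' @return An object of class `utility_param`.
#' @export
#' @examples
#' utility_param("post-discharge ward", 0.724, -0.061, "ward")
utility_param <- function(label, utility, disutility = 0,
                          setting = c("ward", "ICU")) {
  setting <- match.arg(setting)
  if (!is.numeric(utility) || length(utility) != 1L || is.na(utility) ||
      utility < 0 || utility > 1) {
    stop("'utility' must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(disutility) || length(disutility) != 1L ||
      is.na(disutility) || disutility < -1 || disutility > 0) {
    stop("'disutility' must lie in [-1, 0]", call. = FALSE)
  }
  structure(list(label = label, utility = as.numeric(utility),
                 disutility = as.numeric(disutility), setting = setting),
            class = "utility_param")
}

#' Analysis time horizon
#'
#' @param weeks Positive integer horizon in weeks (default 12, the usual
#'   duration of a post-acute pulmonary rehabilitation program).
#' @param weeks_per_year Weeks per year used for annualising QALYs
#'   (default 52).
#' @return An object of class `time_horizon`.
#' @export
time_horizon <- function(weeks = 12L, weeks_per_year = 52) {
  weeks <- as.integer(weeks)
  if (is.na(weeks) || weeks < 1L) {
    stop("'weeks' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(weeks_per_year) || weeks_per_year <= 0) {
    stop("'weeks_per_year' must be positive", call. = FALSE)
  }
  structure(list(weeks = weeks, weeks_per_year = as.numeric(weeks_per_year)),
            class = "time_horizon")
}

#' Willingness-to-pay threshold
#'
#' The maximum acceptable cost per QALY (lambda). Default BRL 40,000/QALY,
#' the commonly cited Brazilian reference threshold.
#'
#' @param value Positive money amount per QALY.
#' @param currency `"BRL"` or `"USD"`.
#' @return An object of class `threshold` with fixed `per_unit = "QALY"`.
#' @export
threshold <- function(value = 40000, currency = c("BRL", "USD")) {
  currency <- match.arg(currency)
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value <= 0) {
    stop("threshold 'value' must be a single positive number", call. = FALSE)
  }
  structure(list(value = as.numeric(value), currency = currency,
                 per_unit = "QALY"),
            class = "threshold")
}

#' Express a threshold in USD per QALY
#'
#' @param thr A [threshold()].
#' @param fx A [currency_spec()].
#' @return Numeric threshold in USD/QALY.
#' @export
threshold_usd <- function(thr, fx = currency_spec()) {
  stopifnot(inherits(thr, "threshold"))
  if (thr$currency == "USD") thr$value else brl_to_usd(thr$value, fx)
}

#' Strategy arm
#'
#' A comparator summarised at arm level: mean per-patient cost (USD), mean
#' effect (QALYs over the horizon), and optional standard errors used by the
#' sensitivity analyses.
#'
#' @param name Arm name, e.g. `"INT"` or `"CON"`.
#' @param mean_cost Mean cost in USD (>= 0).
#' @param mean_effect Mean effect in QALYs (>= 0).
#' @param cost_se,effect_se Optional non-negative standard errors.
#' @return An object of class `strategy_arm`.
#' @export
#' @examples
#' strategy_arm("INT", 317.73, 0.23)
strategy_arm <- function(name, mean_cost, mean_effect,
                         cost_se = NULL, effect_se = NULL) {
  if (!is.numeric(mean_cost) || mean_cost < 0) {
    stop("'mean_cost' must be >= 0", call. = FALSE)
  }
  if (!is.numeric(mean_effect) || mean_effect < 0) {
    stop("'mean_effect' must be >= 0", call. = FALSE)
  }
  for (se in list(cost_se = cost_se, effect_se = effect_se)) {
    if (!is.null(se) && (!is.numeric(se) || se < 0)) {
      stop("standard errors, when given, must be >= 0", call. = FALSE)
    }
  }
  structure(list(name = as.character(name), mean_cost = as.numeric(mean_cost),
                 mean_effect = as.numeric(mean_effect),
                 cost_se = if (!is.null(cost_se)) as.numeric(cost_se),
                 effect_se = if (!is.null(effect_se)) as.numeric(effect_se)),
            class = "strategy_arm")
}

#' @export
print.strategy_arm <- function(x, ...) {
  cat(sprintf("Strategy arm %s: mean cost %.2f USD, mean effect %.4g QALY\n",
              x$name, x$mean_cost, x$mean_effect))
  invisible(x)
}

#' Convert BRL to USD
#'
#' @param amount Non-negative amount in BRL.
#' @param spec A [currency_spec()].
#' @return Amount in USD (`amount / brl_per_usd`).
#' @export
#' @examples
#' brl_to_usd(5.10)  # 1
#' brl_to_usd(40000) # 7843.137...
brl_to_usd <- function(amount, spec = currency_spec()) {
  stopifnot(inherits(spec, "currency_spec"))
  if (any(!is.finite(amount)) || any(amount < 0)) {
    stop("'amount' must be finite and non-negative", call. = FALSE)
  }
  amount / spec$brl_per_usd
}

#' Convert USD to BRL
#'
#' Exact inverse of [brl_to_usd()].
#' @inheritParams brl_to_usd
#' @param amount Non-negative amount in USD.
#' @return Amount in BRL.
#' @export
usd_to_brl <- function(amount, spec = currency_spec()) {
  stopifnot(inherits(spec, "currency_spec"))
  if (any(!is.finite(amount)) || any(amount < 0)) {
    stop("'amount' must be finite and non-negative", call. = FALSE)
  }
  amount * spec$brl_per_usd
}

#' Apply a tariff correction to a cost item
#'
#' Multiplies `unit_cost` by `corr$factor` when the item's `source` is in
#' `corr$applies_to`, and marks the item `corrected`. Applying the correction
#' twice to the same item is an error (the provenance flag guards against
#' silent factor-squared inflation); items from other sources pass through
#' unchanged.
#'
#' @param item A [cost_item()].
#' @param corr A [cost_correction()].
#' @return The (possibly corrected) `cost_item`.
#' @export
apply_cost_correction <- function(item, corr = cost_correction()) {
  stopifnot(inherits(item, "cost_item"), inherits(corr, "cost_correction"))
  if (!item$source %in% corr$applies_to) {
    return(item)
  }
  if (item$corrected) {
    stop(sprintf("cost item '%s' has already been corrected; refusing to apply the factor twice",
                 item$resource_label), call. = FALSE)
  }
  item$unit_cost <- item$unit_cost * corr$factor
  item$corrected <- TRUE
  item
}

#' Total cost of a list of cost items, in USD
#'
#' Applies the tariff correction (once, to uncorrected applicable items),
#' converts BRL lines to USD, and sums `unit_cost * n_units`. The sum is
#' invariant under reordering and linear in `n_units`.
#'
#' @param items Non-empty list of [cost_item()] objects.
#' @param spec A [currency_spec()].
#' @param corr A [cost_correction()], or `NULL` to skip correction (use when
#'   the items already hold corrected values).
#' @return Total cost in USD.
#' @export
total_cost <- function(items, spec = currency_spec(), corr = NULL) {
  if (!is.list(items) || length(items) == 0L ||
      !all(vapply(items, inherits, logical(1), "cost_item"))) {
    stop("'items' must be a non-empty list of cost_item objects", call. = FALSE)
  }
  per_line <- vapply(items, function(it) {
    if (!is.null(corr)) it <- apply_cost_correction(it, corr)
    line <- it$unit_cost * it$n_units
    if (it$currency == "BRL") line <- brl_to_usd(line, spec)
    line
  }, numeric(1))
  sum(per_line)
}

#' Read cost items from a delimited table
#'
#' Expects a CSV with columns `resource_label`, `n_units`, `unit_cost`,
#' `currency`, `source` and optionally `period`. A packaged fixture with the
#' six resource lines of the base-case costing table ships at
#' `system.file("extdata", "cost_items.csv", package = "cuaengine")`.
#'
#' @param path Path to the CSV file.
#' @return List of [cost_item()] objects.
#' @export
read_cost_items <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("resource_label", "n_units", "unit_cost", "currency", "source")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("cost table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    cost_item(df$resource_label[i], df$unit_cost[i], df$n_units[i],
              currency = df$currency[i], source = df$source[i],
              period = if ("period" %in% names(df)) df$period[i])
  })
}

# -- config ingestion ---------------------------------------------------------

collect <- function(errs, cond, msg) if (cond) c(errs, msg) else errs

#' Load a full analysis configuration
#'
#' Reads a JSON configuration describing the two strategy arms, cost items,
#' utility parameters, horizon, exchange rate, tariff correction, threshold,
#' and probabilistic/one-way sensitivity-analysis settings. Missing sections
#' take the documented defaults (5.10 BRL/USD, factor 2.8 on SIGTAP lines,
#' 12-week horizon, BRL 40,000/QALY threshold, 1000 draws, 15% dispersion).
#' All invariant violations are collected and reported together, naming each
#' offending field.
#'
#' @param path Path to a JSON config file. A packaged base-case fixture ships
#'   at `system.file("extdata", "base_case.json", package = "cuaengine")`.
#' @return A list of class `cua_config` with elements `arms` (named list of
#'   [strategy_arm()]), `cost_items`, `utilities`, `horizon`, `exchange`,
#'   `correction`, `threshold`, `psa` (`n_draws`, `seed`, `se_pct`) and
#'   `owsa` (`variation`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  errs <- character()

  arms <- list()
  if (is.null(raw$strategies) || length(raw$strategies) < 2L) {
    errs <- c(errs, "strategies: exactly two strategy arms are required")
  } else {
    for (s in raw$strategies) {
      e <- character()
      e <- collect(e, is.null(s$name), "strategies[].name: missing")
      e <- collect(e, is.null(s$mean_cost) || !is.numeric(s$mean_cost) ||
                     s$mean_cost < 0,
                   sprintf("strategies[%s].mean_cost: must be a number >= 0",
                           s$name %||% "?"))
      e <- collect(e, is.null(s$mean_effect) || !is.numeric(s$mean_effect) ||
                     s$mean_effect < 0,
                   sprintf("strategies[%s].mean_effect: must be a number >= 0",
                           s$name %||% "?"))
      if (length(e)) {
        errs <- c(errs, e)
      } else {
        arms[[s$name]] <- strategy_arm(s$name, s$mean_cost, s$mean_effect,
                                       s$cost_se, s$effect_se)
      }
    }
  }

  utilities <- list()
  for (u in raw$utilities %||% list()) {
    bad_u <- is.null(u$utility) || !is.numeric(u$utility) ||
      u$utility < 0 || u$utility > 1
    bad_d <- !is.null(u$disutility) &&
      (!is.numeric(u$disutility) || u$disutility < -1 || u$disutility > 0)
    errs <- collect(errs, bad_u,
                    sprintf("utilities[%s].utility: must lie in [0, 1]",
                            u$label %||% "?"))
    errs <- collect(errs, bad_d,
                    sprintf("utilities[%s].disutility: must lie in [-1, 0]",
                            u$label %||% "?"))
    if (!bad_u && !bad_d) {
      utilities[[u$label %||% (length(utilities) + 1L)]] <-
        utility_param(u$label %||% "state", u$utility, u$disutility %||% 0,
                      u$setting %||% "ward")
    }
  }

  cost_items <- list()
  for (ci in raw$cost_items %||% list()) {
    if (is.null(ci$unit_cost) || !is.numeric(ci$unit_cost) || ci$unit_cost < 0) {
      errs <- c(errs, sprintf("cost_items[%s].unit_cost: must be a number >= 0",
                              ci$resource_label %||% "?"))
    } else {
      cost_items[[length(cost_items) + 1L]] <-
        cost_item(ci$resource_label %||% "item", ci$unit_cost,
                  ci$n_units %||% 1L, currency = ci$currency %||% "USD",
                  source = ci$source %||% "market price", period = ci$period)
    }
  }

  hz <- raw$horizon %||% list()
  horizon <- tryCatch(
    time_horizon(hz$weeks %||% 12L, hz$weeks_per_year %||% 52),
    error = function(e) { errs <<- c(errs, paste0("horizon: ", conditionMessage(e))); NULL })

  exchange <- tryCatch(
    currency_spec((raw$exchange %||% list())$brl_per_usd %||% 5.10),
    error = function(e) { errs <<- c(errs, paste0("exchange.brl_per_usd: ", conditionMessage(e))); NULL })

  corr_raw <- raw$correction %||% list()
  correction <- tryCatch(
    cost_correction(corr_raw$factor %||% 2.8,
                    corr_raw$applies_to %||% "SIGTAP"),
    error = function(e) { errs <<- c(errs, paste0("correction.factor: ", conditionMessage(e))); NULL })

  thr_raw <- raw$threshold %||% list()
  thr <- tryCatch(
    threshold(thr_raw$value %||% 40000, thr_raw$currency %||% "BRL"),
    error = function(e) { errs <<- c(errs, paste0("threshold.value: ", conditionMessage(e))); NULL })

  psa_raw <- raw$psa %||% list()
  psa <- list(n_draws = as.integer(psa_raw$n_draws %||% 1000L),
              seed = psa_raw$seed,
              se_pct = as.numeric(psa_raw$se_pct %||% 0.15))
  errs <- collect(errs, is.na(psa$n_draws) || psa$n_draws < 1L,
                  "psa.n_draws: must be a positive integer")
  errs <- collect(errs, !is.finite(psa$se_pct) || psa$se_pct < 0,
                  "psa.se_pct: must be >= 0")

  owsa <- list(variation = as.numeric((raw$owsa %||% list())$variation %||% 0.15))
  errs <- collect(errs, !is.finite(owsa$variation) || owsa$variation < 0,
                  "owsa.variation: must be >= 0")

  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(list(arms = arms, cost_items = cost_items, utilities = utilities,
                 horizon = horizon, exchange = exchange,
                 correction = correction, threshold = thr,
                 psa = psa, owsa = owsa),
            class = "cua_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Presentation rounding used in all reports (base R `round()` rounds half to
#' even). Applied only at the reporting layer; internal arithmetic keeps full
#' precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
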