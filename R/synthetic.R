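# Synthetic two-arm trial generator: patient-level records with the
# statistical structure the analysis assumes (gamma per-patient costs, beta
# utilities), plus the bridge from patient level back to arm-level inputs.

#' Generate a synthetic two-arm trial
#'
#' Emulates a small two-arm rehabilitation trial (default scale ~25-27
#' patients per arm): per-patient costs are drawn from a gamma distribution
#' and utilities from a beta distribution, each fitted by the method of
#' moments to the stated arm means and standard deviations. Reproducible
#' under `seed`.
#'
#' @param n_int,n_con Number of patients per arm (>= 0, at least one total).
#' @param cost_means,cost_sds Length-2 numeric `(INT, CON)`: per-patient
#'   cost mean and standard deviation in USD. `cost_sds` defaults to 15% of
#'   the means, the same dispersion convention the PSA uses.
#' @param utility_means,utility_sds Length-2 numeric `(INT, CON)` beta
#'   moments on \[0, 1\]; `utility_sds` defaults to 15% of the means.
#' @param horizon_weeks Positive integer horizon attached to every record.
#' @param seed Integer seed.
#' @return A data.frame of patient records: `patient_id`, `arm`
#'   (`"INT"`/`"CON"`), `cost` (>= 0), `utility` (in \[0, 1\]),
#'   `horizon_weeks`.
#' @export
#' @examples
#' trial <- generate_trial(25, 27, seed = 1)
#' table(trial$arm)
generate_trial <- function(n_int = 25L, n_con = 27L,
                           cost_means = c(317.73, 293.93),
                           cost_sds = 0.15 * cost_means,
                           utility_means = c(0.724, 0.693),
                           utility_sds = 0.15 * utility_means,
                           horizon_weeks = 12L, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("'seed' must be supplied explicitly", call. = FALSE)
  }
  n_int <- as.integer(n_int); n_con <- as.integer(n_con)
  if (n_int < 0L || n_con < 0L || n_int + n_con < 1L) {
    stop("need at least one patient across the two arms", call. = FALSE)
  }
  horizon_weeks <- as.integer(horizon_weeks)
  stopifnot(horizon_weeks >= 1L)

  # fitting validates moment feasibility before anything is drawn
  cost_specs <- Map(fit_gamma_moments, cost_means, cost_sds)
  util_specs <- Map(fit_beta_moments, utility_means, utility_sds)

  set.seed(as.integer(seed))
  one_arm <- function(arm, n, cspec, uspec) {
    if (n == 0L) return(NULL)
    data.frame(patient_id = sprintf("%s-%03d", arm, seq_len(n)),
               arm = arm,
               cost = sample_dist(cspec, n),
               utility = sample_dist(uspec, n),
               horizon_weeks = horizon_weeks,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_arm("INT", n_int, cost_specs[[1]], util_specs[[1]]),
               one_arm("CON", n_con, cost_specs[[2]], util_specs[[2]]))
  rownames(out) <- NULL
  out
}

#' Estimate arm-level parameters from patient records
#'
#' Bridges patient-level data to the arm-level inputs of [compute_icer()]:
#' per arm, the sample mean and standard error (sd / sqrt(n)) of cost and of
#' QALYs, where each patient's QALY is `utility * horizon_weeks /
#' weeks_per_year`.
#'
#' @param records A data.frame as returned by [generate_trial()] (columns
#'   `arm`, `cost`, `utility`, `horizon_weeks`).
#' @param weeks_per_year Annualisation constant (default 52).
#' @return A named list of [strategy_arm()] objects (one per arm present),
#'   each carrying `cost_se` and `effect_se`, with an `n` attribute.
#' @export
estimate_arm_params <- function(records, weeks_per_year = 52) {
  stopifnot(is.data.frame(records),
            all(c("arm", "cost", "utility", "horizon_weeks") %in% names(records)))
  arms <- unique(records$arm)
  out <- lapply(arms, function(a) {
    r <- records[records$arm == a, , drop = FALSE]
    n <- nrow(r)
    if (n < 2L) {
      stop(sprintf("arm '%s' has %d record(s); need >= 2 for standard errors",
                   a, n), call. = FALSE)
    }
    qaly <- r$utility * r$horizon_weeks / weeks_per_year
    arm <- strategy_arm(a, mean(r$cost), mean(qaly),
                        cost_se = stats::sd(r$cost) / sqrt(n),
                        effect_se = stats::sd(qaly) / sqrt(n))
    attr(arm, "n") <- n
    arm
  })
  names(out) <- arms
  out
}

COST_TABLE_TEMPLATE <- data.frame(
  resource_label = c("IMT device", "Treadmill", "Resistance exercise station",
                     "Oxygen supplier device",
                     "Rehabilitation team salaries",
                     "Supplies (cleaners, nose catheter, PPE)"),
  unit_cost = c(1200, 1150, 1132, 960, 2347, 1345),
  period = c("1 unit", "1 unit", "2 units", "2 units", "per month",
             "200 units"),
  source = c("market price", "market price", "market price", "market price",
             "Health Secretary", "SIGTAP"),
  stringsAsFactors = FALSE)

#' Generate a resource cost table
#'
#' In fixture mode, emits the six base-case resource lines exactly (USD line
#' totals 1200, 1150, 1132, 960, 2347, 1345, already aggregated and
#' converted -- no tariff correction is to be re-applied). In random mode,
#' keeps the schema and labels but draws each line total from a gamma
#' distribution centred on the fixture value (15% dispersion), producing
#' structurally valid tables for round-trip testing.
#'
#' @param mode `"fixture"` or `"random"`.
#' @param seed Integer seed; required in random mode.
#' @return List of [cost_item()] objects (line totals, `n_units = 1`).
#' @export
generate_cost_table <- function(mode = c("fixture", "random"), seed = NULL) {
  mode <- match.arg(mode)
  tmpl <- COST_TABLE_TEMPLATE
  values <- tmpl$unit_cost
  if (mode == "random") {
    if (is.null(seed)) stop("'seed' is required in random mode", call. = FALSE)
    set.seed(as.integer(seed))
    values <- vapply(values, function(m)
      sample_dist(fit_gamma_moments(m, 0.15 * m), 1L), numeric(1))
  }
  lapply(seq_len(nrow(tmpl)), function(i) {
    cost_item(tmpl$resource_label[i], values[i], 1L, currency = "USD",
              source = tmpl$source[i], period = tmpl$period[i])
  })
}

#' Write cost items to CSV
#'
#' Inverse of [read_cost_items()]: columns `resource_label`, `n_units`,
#' `unit_cost`, `currency`, `source`, `period`.
#'
#' @param items List of [cost_item()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cost_items <- function(items, path) {
  df <- do.call(rbind, lapply(items, function(it)
    data.frame(resource_label = it$resource_label, n_units = it$n_units,
               unit_cost = it$unit_cost, currency = it$currency,
               source = it$source, period = it$period %||% "",
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
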