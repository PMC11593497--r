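# Probabilistic sensitivity analysis: method-of-moments beta/gamma fitting,
# seeded Monte-Carlo sampling, cost-effectiveness plane classification,
# threshold decision rules, acceptability curves.

#' Fit a beta distribution by the method of moments
#'
#' Chooses shape parameters so the analytic mean and standard deviation of
#' `Beta(alpha, beta)` equal the targets: with
#' `nu = mean * (1 - mean) / se^2 - 1`, `alpha = mean * nu` and
#' `beta = (1 - mean) * nu`. Utilities live on \[0, 1\], so beta is the
#' conventional PSA family for them. The moments are feasible only when
#' `se^2 < mean * (1 - mean)`; `se = 0` yields a degenerate point-mass spec
#' whose draws all equal the mean.
#'
#' @param mean Target mean in (0, 1).
#' @param se Target standard deviation (>= 0).
#' @return An object of class `dist_spec` with `family = "beta"`, fitted
#'   `shape1` (alpha) and `shape2` (beta), and a `degenerate` flag.
#' @export
#' @examples
#' fit_beta_moments(0.5, 1 / sqrt(12)) # alpha = beta = 1 (uniform)
fit_beta_moments <- function(mean, se) {
  if (!is.numeric(mean) || length(mean) != 1L || mean <= 0 || mean >= 1) {
    stop("beta 'mean' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(se) || length(se) != 1L || se < 0) {
    stop("'se' must be >= 0", call. = FALSE)
  }
  if (se == 0) {
    return(structure(list(family = "beta", mean = mean, se = 0,
                          shape1 = NA_real_, shape2 = NA_real_,
                          degenerate = TRUE), class = "dist_spec"))
  }
  if (se^2 >= mean * (1 - mean)) {
    stop(sprintf("infeasible beta moments: se^2 = %.4g >= mean*(1-mean) = %.4g",
                 se^2, mean * (1 - mean)), call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  structure(list(family = "beta", mean = mean, se = se,
                 shape1 = mean * nu, shape2 = (1 - mean) * nu,
                 degenerate = FALSE), class = "dist_spec")
}

#' Fit a gamma distribution by the method of moments
#'
#' Shape `k = mean^2 / se^2`, scale `theta = se^2 / mean`, so the analytic
#' mean (`k * theta`) and standard deviation (`sqrt(k) * theta`) equal the
#' targets. Costs are non-negative and right-skewed, hence the gamma family.
#' `se = 0` is allowed and flags a degenerate point mass at the mean.
#'
#' @param mean Target mean (> 0).
#' @param se Target standard deviation (>= 0).
#' @return An object of class `dist_spec` with `family = "gamma"`, `shape1`
#'   (shape k) and `shape2` (scale theta).
#' @export
#' @examples
#' fit_gamma_moments(10, 5) # k = 4, theta = 2.5
fit_gamma_moments <- function(mean, se) {
  if (!is.numeric(mean) || length(mean) != 1L || mean <= 0) {
    stop("gamma 'mean' must be > 0", call. = FALSE)
  }
  if (!is.numeric(se) || length(se) != 1L || se < 0) {
    stop("'se' must be >= 0", call. = FALSE)
  }
  if (se == 0) {
    return(structure(list(family = "gamma", mean = mean, se = 0,
                          shape1 = NA_real_, shape2 = NA_real_,
                          degenerate = TRUE), class = "dist_spec"))
  }
  structure(list(family = "gamma", mean = mean, se = se,
                 shape1 = mean^2 / se^2, shape2 = se^2 / mean,
                 degenerate = FALSE), class = "dist_spec")
}

#' Sample from a fitted distribution specification
#'
#' Degenerate (zero-se) specs return the mean without consuming the random
#' number stream.
#'
#' @param spec A `dist_spec` from [fit_beta_moments()] or
#'   [fit_gamma_moments()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$degenerate) return(rep(spec$mean, n))
  switch(spec$family,
         beta = stats::rbeta(n, spec$shape1, spec$shape2),
         gamma = stats::rgamma(n, shape = spec$shape1, scale = spec$shape2))
}

CE_CATEGORIES <- c("dominant", "ne_below", "ne_above", "sw", "dominated",
                   "boundary")

#' Classify points on the cost-effectiveness plane
#'
#' For each `(delta_cost, delta_effect)` pair:
#' * `dominant` -- cheaper and more effective (`dC < 0`, `dE > 0`);
#' * `ne_below` -- costlier and more effective with `dC / dE <= lambda`
#'   (inclusive comparison, a fixed documented convention);
#' * `ne_above` -- costlier and more effective with `dC / dE > lambda`;
#' * `sw` -- cheaper and less effective (not cost-effective under the
#'   quadrant rule used here, regardless of the ratio);
#' * `dominated` -- costlier and less effective;
#' * `boundary` -- an exact zero in `dC` or `dE` (measure-zero but possible
#'   in floating point; resolved by net monetary benefit downstream).
#'
#' @param delta_cost,delta_effect Numeric vectors (recycled to a common
#'   length) of incremental costs (USD) and effects (QALYs).
#' @param lambda_usd Positive willingness-to-pay threshold in USD/QALY.
#' @return Character vector of categories.
#' @export
#' @examples
#' classify_ce_plane(23.80, 0.03, 40000 / 5.10) # "ne_below"
classify_ce_plane <- function(delta_cost, delta_effect, lambda_usd) {
  if (!is.numeric(lambda_usd) || length(lambda_usd) != 1L || lambda_usd <= 0) {
    stop("'lambda_usd' must be a single positive number", call. = FALSE)
  }
  n <- max(length(delta_cost), length(delta_effect))
  dc <- rep_len(delta_cost, n); de <- rep_len(delta_effect, n)
  out <- character(n)
  out[dc == 0 | de == 0] <- "boundary"
  out[dc < 0 & de > 0] <- "dominant"
  out[dc > 0 & de < 0] <- "dominated"
  out[dc < 0 & de < 0] <- "sw"
  ne <- dc > 0 & de > 0
  out[ne & dc / de <= lambda_usd] <- "ne_below"
  out[ne & dc / de > lambda_usd] <- "ne_above"
  out
}

#' Cost-effective proportion from quadrant counts
#'
#' The quadrant decision rule: draws that are dominant, plus north-east
#' draws below the threshold, are cost-effective; south-west draws are not,
#' whatever their ratio. `boundary` draws, when present as a count, are
#' excluded here (the full rule in [run_psa()] resolves them by net monetary
#' benefit).
#'
#' @param counts Named integer vector or list with (a subset of) names
#'   `dominant`, `ne_below`, `ne_above`, `sw`, `dominated`, `boundary`.
#' @return Proportion in \[0, 1\]: `(dominant + ne_below) / sum(counts)`.
#' @export
#' @examples
#' ce_proportion(c(dominant = 122, ne_below = 390, ne_above = 103,
#'                 sw = 80, dominated = 305)) # 0.512
ce_proportion <- function(counts) {
  counts <- unlist(counts)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("'counts' must be non-negative with a positive total", call. = FALSE)
  }
  get0n <- function(nm) if (nm %in% names(counts)) counts[[nm]] else 0
  (get0n("dominant") + get0n("ne_below")) / sum(counts)
}

#' Run a probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: per draw, the four arm
#' quantities are sampled in the fixed order `cost_int, cost_con, eff_int,
#' eff_con` from their fitted distributions (gamma for costs, beta-scale for
#' effects), the incremental pair is classified on the cost-effectiveness
#' plane, and the quadrant-rule cost-effective proportion is computed.
#' Boundary draws count as cost-effective iff their incremental net monetary
#' benefit is non-negative. The run is reproducible: the same `seed`,
#' settings and specs give a bit-identical result.
#'
#' @param specs Named list with elements `cost_int`, `cost_con`, `eff_int`,
#'   `eff_con`, each a `dist_spec` (possibly degenerate). Effect specs may be
#'   beta on \[0, 1\] (QALYs over a sub-year horizon) or gamma.
#' @param thr A [threshold()].
#' @param fx A [currency_spec()].
#' @param n_draws Number of Monte-Carlo draws (default 1000).
#' @param seed Integer seed; must be supplied explicitly.
#' @return An object of class `psa_result`: `n_draws`, `seed`, `lambda_usd`,
#'   `counts` (named, summing to `n_draws`), `proportion_ce`, and `draws`, a
#'   data.frame with one row per draw (`cost_int`, `cost_con`, `eff_int`,
#'   `eff_con`, `delta_cost`, `delta_effect`, `category`).
#' @export
run_psa <- function(specs, thr = threshold(), fx = currency_spec(),
                    n_draws = 1000L, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("'seed' must be supplied explicitly for a reproducible PSA",
         call. = FALSE)
  }
  need <- c("cost_int", "cost_con", "eff_int", "eff_con")
  miss <- need[!vapply(need, function(nm)
    inherits(specs[[nm]], "dist_spec"), logical(1))]
  if (length(miss)) {
    stop("missing distribution spec for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n_draws <- as.integer(n_draws)
  stopifnot(n_draws >= 1L)
  lambda <- threshold_usd(thr, fx)

  set.seed(as.integer(seed))
  m <- matrix(NA_real_, nrow = n_draws, ncol = 4L,
              dimnames = list(NULL, need))
  # per-draw stream order (cost_int, cost_con, eff_int, eff_con) keeps the
  # exported table auditable against the seed
  for (i in seq_len(n_draws)) {
    for (j in seq_along(need)) m[i, j] <- sample_dist(specs[[need[j]]], 1L)
  }
  draws <- as.data.frame(m)
  draws$delta_cost <- draws$cost_int - draws$cost_con
  draws$delta_effect <- draws$eff_int - draws$eff_con
  draws$category <- classify_ce_plane(draws$delta_cost, draws$delta_effect,
                                      lambda)
  counts <- vapply(CE_CATEGORIES, function(k) sum(draws$category == k),
                   integer(1))
  boundary_ce <- sum(draws$category == "boundary" &
                       lambda * draws$delta_effect - draws$delta_cost >= 0)
  structure(list(n_draws = n_draws, seed = as.integer(seed),
                 lambda_usd = lambda, counts = counts,
                 boundary_ce = boundary_ce,
                 proportion_ce = (counts[["dominant"]] + counts[["ne_below"]] +
                                    boundary_ce) / n_draws,
                 draws = draws),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %d), lambda = %.2f USD/QALY\n",
              x$n_draws, x$seed, x$lambda_usd))
  for (k in names(x$counts)) {
    if (x$counts[[k]] > 0 || k != "boundary") {
      cat(sprintf("  %-10s %5d (%.1f%%)\n", k, x$counts[[k]],
                  100 * x$counts[[k]] / x$n_draws))
    }
  }
  cat(sprintf("  cost-effective: %.1f%%\n", 100 * x$proportion_ce))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Probability of cost-effectiveness as a function of the willingness-to-pay
#' threshold, over a stored draw table. Under `rule = "nmb"`, acceptance at
#' `lambda` is the fraction of draws with `lambda * dE - dC > 0`; as
#' `lambda -> 0+` this tends to `P(dC < 0)` and as `lambda -> Inf` to
#' `P(dE > 0)` (plus boundary draws with `dE = 0, dC < 0`, which stay
#' accepted at every lambda). Under `rule = "paper_quadrant"`, each lambda
#' re-runs the quadrant classification of [run_psa()], so south-west draws
#' are never accepted.
#'
#' @param result A `psa_result`.
#' @param lambda_grid Increasing vector of positive thresholds (USD/QALY).
#' @param rule `"nmb"` or `"paper_quadrant"`.
#' @return A data.frame with columns `lambda` and `p_ce`.
#' @export
compute_ceac <- function(result, lambda_grid,
                         rule = c("nmb", "paper_quadrant")) {
  rule <- match.arg(rule)
  stopifnot(inherits(result, "psa_result"))
  if (length(lambda_grid) == 0L || any(lambda_grid <= 0)) {
    stop("'lambda_grid' must be non-empty with positive values", call. = FALSE)
  }
  d <- result$draws
  p <- vapply(lambda_grid, function(l) {
    if (rule == "nmb") {
      mean(l * d$delta_effect - d$delta_cost > 0)
    } else {
      cat_l <- classify_ce_plane(d$delta_cost, d$delta_effect, l)
      (sum(cat_l %in% c("dominant", "ne_below")) +
          sum(cat_l == "boundary" &
                l * d$delta_effect - d$delta_cost >= 0)) / nrow(d)
    }
  }, numeric(1))
  data.frame(lambda = lambda_grid, p_ce = p)
}
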