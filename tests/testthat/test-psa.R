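test_that("method-of-moments fits recover closed-form shapes", {
  u <- fit_beta_moments(0.5, 1 / sqrt(12))
  expect_equal(u$shape1, 1, tolerance = 1e-9)   # uniform
  expect_equal(u$shape2, 1, tolerance = 1e-9)

  g <- fit_gamma_moments(10, 5)
  expect_equal(g$shape1, 4)
  expect_equal(g$shape2, 2.5)

  g15 <- fit_gamma_moments(317.73, 0.15 * 317.73)
  expect_equal(g15$shape1, 1 / 0.15^2, tolerance = 1e-9)
  expect_equal(g15$shape2, 317.73 * 0.15^2, tolerance = 1e-9)

  # analytic moments of the fitted distributions equal the targets
  b <- fit_beta_moments(0.724, 0.1086)
  expect_equal(b$shape1 / (b$shape1 + b$shape2), 0.724, tolerance = 1e-12)
  v <- b$shape1 * b$shape2 /
    ((b$shape1 + b$shape2)^2 * (b$shape1 + b$shape2 + 1))
  expect_equal(sqrt(v), 0.1086, tolerance = 1e-12)
})

test_that("infeasible or degenerate moments are handled explicitly", {
  expect_error(fit_beta_moments(0.5, 0.5), "infeasible")
  expect_error(fit_beta_moments(1.2, 0.1), "strictly in")
  expect_error(fit_gamma_moments(-1, 1), "> 0")

  pm <- fit_gamma_moments(317.73, 0)
  expect_true(pm$degenerate)
  expect_equal(sample_dist(pm, 5), rep(317.73, 5))
  expect_true(fit_beta_moments(0.724, 0)$degenerate)
})

test_that("large-sample moments of fitted distributions match targets (4 MC SE)", {
  n <- 1e5
  cases <- list(fit_gamma_moments(317.73, 0.15 * 317.73),
                fit_gamma_moments(293.93, 0.15 * 293.93),
                fit_beta_moments(0.724, 0.1086),
                fit_beta_moments(0.2, 0.03))
  set.seed(104)
  for (spec in cases) {
    x <- sample_dist(spec, n)
    expect_lt(abs(mean(x) - spec$mean), 4 * spec$se / sqrt(n))
    expect_lt(abs(sd(x) - spec$se), 4 * se_of_sample_sd(spec, n))
  }
})

test_that("CE-plane classification follows the quadrant/threshold rule", {
  lam <- lambda_base_usd()
  expect_identical(classify_ce_plane(23.80, 0.03, lam), "ne_below")
  expect_identical(classify_ce_plane(-5, 0.01, lam), "dominant")
  expect_identical(classify_ce_plane(-5, -0.01, lam), "sw")
  expect_identical(classify_ce_plane(5, -0.01, lam), "dominated")
  expect_identical(classify_ce_plane(0.04 * lam, 0.03, lam), "ne_above")
  expect_identical(classify_ce_plane(0, 0.03, lam), "boundary")
  expect_identical(classify_ce_plane(5, 0, lam), "boundary")
  # inclusive threshold comparison: dC/dE == lambda counts as below
  expect_identical(classify_ce_plane(lam * 0.5, 0.5, lam), "ne_below")
  # sw draws are never cost-effective under the quadrant rule, whatever the ratio
  expect_equal(ce_proportion(c(sw = 10, dominant = 0)), 0)
})

test_that("quadrant-rule proportion from counts", {
  expect_equal(ce_proportion(c(dominant = 122, ne_below = 390, ne_above = 103,
                               sw = 80, dominated = 305)), 0.512)
  expect_error(ce_proportion(c(dominant = -1, sw = 2)), "non-negative")
})

test_that("run_psa is seed-reproducible and matches an independent draw-table oracle", {
  cfg <- load_config(base_config_path())
  specs <- cuaengine:::psa_specs_from_config(cfg)

  a <- run_psa(specs, cfg$threshold, cfg$exchange, n_draws = 200, seed = 42)
  b <- run_psa(specs, cfg$threshold, cfg$exchange, n_draws = 200, seed = 42)
  expect_identical(serialize(a, NULL), serialize(b, NULL))

  expect_equal(sum(a$counts), 200)
  expect_equal(a$draws$delta_cost, a$draws$cost_int - a$draws$cost_con)
  expect_equal(a$draws$delta_effect, a$draws$eff_int - a$draws$eff_con)
  expect_identical(a$draws$category,
                   oracle_classify(a$draws$delta_cost, a$draws$delta_effect,
                                   a$lambda_usd))

  c10 <- run_psa(specs, cfg$threshold, cfg$exchange, n_draws = 10, seed = 7)
  expect_identical(c10$draws$category,
                   oracle_classify(c10$draws$delta_cost, c10$draws$delta_effect,
                                   c10$lambda_usd))

  expect_error(run_psa(specs[-1], n_draws = 5, seed = 1), "cost_int")
  expect_error(run_psa(specs, n_draws = 5), "seed")
})

test_that("counts conservation holds across random configurations", {
  set.seed(31)
  for (i in 1:20) {
    specs <- list(
      cost_int = fit_gamma_moments(runif(1, 50, 500), runif(1, 5, 50)),
      cost_con = fit_gamma_moments(runif(1, 50, 500), runif(1, 5, 50)),
      eff_int = fit_beta_moments(runif(1, 0.1, 0.9), runif(1, 0.01, 0.05)),
      eff_con = fit_beta_moments(runif(1, 0.1, 0.9), runif(1, 0.01, 0.05)))
    n <- sample(10:200, 1)
    res <- run_psa(specs, n_draws = n, seed = i)
    expect_equal(sum(res$counts), n)
    expect_gte(res$proportion_ce, 0)
    expect_lte(res$proportion_ce, 1)
  }
})

test_that("zero-variance PSA collapses to the deterministic base case", {
  specs <- list(cost_int = fit_gamma_moments(317.73, 0),
                cost_con = fit_gamma_moments(293.93, 0),
                eff_int = fit_beta_moments(0.23, 0),
                eff_con = fit_beta_moments(0.20, 0))
  res <- run_psa(specs, n_draws = 50, seed = 99)
  expect_equal(unname(res$counts[["ne_below"]]), 50)
  expect_equal(res$proportion_ce, 1.0)
})

test_that("CEAC limits and cross-rule consistency", {
  cfg <- load_config(base_config_path())
  specs <- cuaengine:::psa_specs_from_config(cfg)
  res <- run_psa(specs, cfg$threshold, cfg$exchange, n_draws = 500, seed = 5)

  lo <- compute_ceac(res, 1e-9, rule = "nmb")$p_ce
  expect_equal(lo, mean(res$draws$delta_cost < 0))
  hi <- compute_ceac(res, 1e9, rule = "nmb")$p_ce
  expect_equal(hi, mean(res$draws$delta_effect > 0))

  at_lambda <- compute_ceac(res, res$lambda_usd, rule = "paper_quadrant")$p_ce
  expect_equal(at_lambda, res$proportion_ce)

  # quadrant rule = NMB rule minus accepted-sw draws, by enumeration
  lam <- res$lambda_usd
  nmb_set <- lam * res$draws$delta_effect - res$draws$delta_cost > 0
  sw_accepted <- nmb_set & res$draws$category == "sw"
  expect_equal(res$proportion_ce, mean(nmb_set & !sw_accepted))

  # degenerate draws step from 0 to 1 at the base-case ICER
  dspecs <- list(cost_int = fit_gamma_moments(317.73, 0),
                 cost_con = fit_gamma_moments(293.93, 0),
                 eff_int = fit_beta_moments(0.23, 0),
                 eff_con = fit_beta_moments(0.20, 0))
  dres <- run_psa(dspecs, n_draws = 10, seed = 1)
  curve <- compute_ceac(dres, c(100, 700, 900, 5000), rule = "nmb")
  expect_equal(curve$p_ce, c(0, 0, 1, 1))

  expect_error(compute_ceac(res, c(-1, 10)), "positive")
})
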