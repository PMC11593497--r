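test_that("currency conversion matches the fixed rate and round-trips", {
  fx <- currency_spec()
  expect_equal(brl_to_usd(5.10, fx), 1)
  expect_equal(brl_to_usd(0, fx), 0)
  expect_equal(brl_to_usd(40000, fx), 40000 / 5.10, tolerance = 1e-12)

  set.seed(11)
  x <- c(0, 10^runif(50, 0, 9))
  expect_equal(usd_to_brl(brl_to_usd(x, fx), fx), x, tolerance = 1e-12)
  expect_error(brl_to_usd(-1, fx), "non-negative")
})

test_that("tariff correction applies once, by source, and flags re-application", {
  corr <- cost_correction()
  sig <- cost_item("supplies", 100, source = "SIGTAP")
  out <- apply_cost_correction(sig, corr)
  expect_equal(out$unit_cost, 280)
  expect_true(out$corrected)
  expect_error(apply_cost_correction(out, corr), "twice")

  market <- cost_item("device", 1200, source = "market price")
  expect_identical(apply_cost_correction(market, corr), market)

  zero <- apply_cost_correction(cost_item("free", 0, source = "SIGTAP"), corr)
  expect_equal(zero$unit_cost, 0)
})

test_that("total_cost sums corrected USD lines; reorder-invariant and linear in units", {
  expect_equal(total_cost(list(cost_item("x", 1))), 1)
  two <- list(cost_item("x", 3.5), cost_item("x", 3.5))
  expect_equal(total_cost(two), 2 * total_cost(two[1]))

  items <- list(cost_item("a", 10, 2L, source = "SIGTAP"),
                cost_item("b", 51, 1L, currency = "BRL"),
                cost_item("c", 7, 3L))
  corr <- cost_correction()
  # hand oracle: 10*2*2.8 + 51/5.10 + 7*3
  expect_equal(total_cost(items, corr = corr), 56 + 10 + 21)
  expect_equal(total_cost(rev(items), corr = corr),
               total_cost(items, corr = corr))

  dbl <- items
  dbl[[3]]$n_units <- 6L
  expect_equal(total_cost(dbl, corr = corr) - total_cost(items, corr = corr), 21)
  expect_error(total_cost(list()), "non-empty")
})

test_that("constructors enforce invariants", {
  expect_error(utility_param("u", 1.2), "\\[0, 1\\]")
  expect_error(utility_param("u", 0.5, 0.5), "\\[-1, 0\\]")
  expect_error(strategy_arm("A", -1, 0.2), ">= 0")
  expect_error(cost_item("x", -5), "non-negative")
  expect_error(cost_item("x", 5, 0), "positive integer")
  expect_error(threshold(-1), "positive")
  expect_error(time_horizon(0), "positive integer")
  expect_error(currency_spec(0), "positive")
})

test_that("load_config reproduces the packaged base case with defaults", {
  cfg <- load_config(base_config_path())
  expect_s3_class(cfg, "cua_config")
  expect_equal(cfg$arms$INT$mean_cost, 317.73)
  expect_equal(cfg$arms$INT$mean_effect, 0.23)
  expect_equal(cfg$arms$CON$mean_cost, 293.93)
  expect_equal(cfg$arms$CON$mean_effect, 0.20)
  expect_equal(cfg$threshold$value, 40000)
  expect_equal(cfg$threshold$currency, "BRL")
  expect_equal(cfg$exchange$brl_per_usd, 5.10)
  expect_equal(cfg$horizon$weeks, 12L)
  expect_equal(cfg$psa$n_draws, 1000L)
  expect_equal(length(cfg$cost_items), 6L)
})

test_that("load_config fills defaults and enumerates every invalid field", {
  minimal <- tempfile(fileext = ".json")
  writeLines('{"strategies": [
      {"name": "A", "mean_cost": 10, "mean_effect": 0.1},
      {"name": "B", "mean_cost": 12, "mean_effect": 0.2}]}', minimal)
  cfg <- load_config(minimal)
  expect_equal(cfg$threshold$value, 40000)      # default lambda
  expect_equal(cfg$correction$factor, 2.8)
  expect_equal(cfg$psa$se_pct, 0.15)

  bad <- tempfile(fileext = ".json")
  writeLines('{"strategies": [
      {"name": "A", "mean_cost": -10, "mean_effect": 0.1},
      {"name": "B", "mean_cost": 12, "mean_effect": 0.2}],
      "utilities": [{"label": "u1", "utility": 1.2}],
      "psa": {"n_draws": 0}}', bad)
  err <- tryCatch(load_config(bad), error = conditionMessage)
  expect_match(err, "strategies\\[A\\].mean_cost")
  expect_match(err, "utilities\\[u1\\].utility")
  expect_match(err, "psa.n_draws")
  expect_error(load_config(tempfile()), "not found")
})

test_that("cost-item CSV fixture round-trips through the reader", {
  items <- read_cost_items(system.file("extdata", "cost_items.csv",
                                       package = "cuaengine"))
  expect_length(items, 6L)
  expect_equal(vapply(items, `[[`, numeric(1), "unit_cost"),
               c(1200, 1150, 1132, 960, 2347, 1345))
  expect_true(all(vapply(items, `[[`, character(1), "currency") == "USD"))
})

test_that("round_half_up rounds halves away from zero at the reporting layer", {
  expect_equal(round_half_up(793.335, 2), 793.34)
  expect_equal(round_half_up(-0.005, 2), -0.01)
  expect_equal(round_half_up(2.5, 0), 3)
})
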