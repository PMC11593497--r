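# Shared fixtures and independent oracles for the suite.

base_int <- function() strategy_arm("INT", 317.73, 0.23)
base_con <- function() strategy_arm("CON", 293.93, 0.20)
lambda_base_usd <- function() 40000 / 5.10

base_config_path <- function() {
  system.file("extdata", "base_case.json", package = "cuaengine")
}

# independent CE-plane oracle: scalar re-derivation of the quadrant rule,
# kept free of the vectorised implementation it checks
oracle_classify <- function(dc, de, lam) {
  mapply(function(c, e) {
    if (c == 0 || e == 0) return("boundary")
    if (c < 0 && e > 0) return("dominant")
    if (c > 0 && e < 0) return("dominated")
    if (c < 0 && e < 0) return("sw")
    if (c / e <= lam) "ne_below" else "ne_above"
  }, dc, de, USE.NAMES = FALSE)
}

# analytic kurtosis of a fitted spec, for Monte-Carlo standard errors of the
# sample sd: SE(s) ~= s * sqrt((kurtosis - 1) / (4 n))
spec_kurtosis <- function(spec) {
  if (spec$family == "gamma") {
    3 + 6 / spec$shape1
  } else {
    a <- spec$shape1; b <- spec$shape2
    3 + 6 * ((a - b)^2 * (a + b + 1) - a * b * (a + b + 2)) /
      (a * b * (a + b + 2) * (a + b + 3))
  }
}

se_of_sample_sd <- function(spec, n) spec$se * sqrt((spec_kurtosis(spec) - 1) / (4 * n))
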