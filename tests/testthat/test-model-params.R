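# Parameter handling: period conversions, duration-dependent mortality,
# distributions, config loading and PSA sampling.

test_that("probability period conversion round-trips and handles bounds", {
  expect_equal(annualize_probability(0, 5), 0)
  expect_equal(annualize_probability(0.75, 2), 0.5)
  # brute-force check: recompounding the annual probability recovers the input
  p1 <- annualize_probability(0.2, 5)
  expect_equal(1 - (1 - p1)^5, 0.2, tolerance = 1e-12)
  expect_equal(round(p1, 5), 0.04365)
  for (p in seq(0, 1, by = 0.1))
    for (T in c(1, 2, 3, 5, 10))
      expect_equal(1 - (1 - annualize_probability(p, T))^T, p,
                   tolerance = 1e-12)
  expect_error(annualize_probability(1.2, 5), "0, 1")
  expect_error(annualize_probability(0.5, 0), "integer")
})

test_that("rate-to-probability conversion is monotone and bounded", {
  expect_equal(rate_to_probability(0), 0)
  expect_equal(rate_to_probability(log(2)), 0.5, tolerance = 1e-6)
  expect_lt(abs(rate_to_probability(20) - 1), 1e-8)
  r <- seq(0, 3, by = 0.1)
  expect_true(all(diff(rate_to_probability(r)) > 0))
  expect_error(rate_to_probability(-0.1), "non-negative")
})

test_that("advanced-cancer duration series reproduces 5-year survival", {
  expect_equal(derive_advanced_mortality(1), rep(0, 6))
  expect_equal(derive_advanced_mortality(0.32768), rep(0.2, 6),
               tolerance = 1e-12)
  for (S5 in c(0.05, 0.2, 0.5, 0.9)) {
    q <- derive_advanced_mortality(S5)
    expect_length(q, 6)
    expect_equal(q[6], q[1])                       # constant 6+ tail
    expect_equal(prod(1 - q[1:5]), S5, tolerance = 1e-9)
  }
  expect_error(derive_advanced_mortality(0), "0, 1")
})

test_that("distribution samplers match closed-form moments", {
  specs <- list(
    dist_spec("triangular", c(0.30, 0.60, 0.80)),
    dist_spec("beta", c(20, 5)),
    dist_spec("gamma", c(100, 0.15)))
  set.seed(99)
  for (sp in specs) {
    x <- sample_dist(sp, 1e5)
    se <- sqrt(dist_var(sp) / 1e5)
    expect_lt(abs(mean(x) - dist_mean(sp)), 3 * se)
  }
  # triangular support equals its parameters
  x <- sample_dist(dist_spec("triangular", c(0.30, 0.60, 0.80)), 1e4)
  expect_true(all(x >= 0.30 & x <= 0.80))
  expect_lt(abs(mean(x) - (0.30 + 0.60 + 0.80) / 3), 0.01)
})

test_that("truncation is enforced by resampling", {
  set.seed(3)
  sp <- dist_spec("gamma", c(2, 0.01), truncation = c(100, 300))
  x <- sample_dist(sp, 5000)
  expect_true(all(x >= 100 & x <= 300))
  tight <- dist_spec("gamma", c(2, 0.01), truncation = c(1e6, 1e6 + 1))
  expect_error(sample_dist(tight, 10, max_iter = 5), "cap")
})

test_that("recentered beta/gamma sampling is centered on the base value", {
  ps <- default_ps()
  set.seed(11)
  for (path in c("utilities.es_SDCIS", "costs.screening_total")) {
    pv <- ugcscreen:::get_param(ps, path)
    d <- ugcscreen:::effective_dist(pv, "recentered")
    x <- sample_dist(d, 1e5)
    se <- sqrt(dist_var(d) / 1e5)
    expect_lt(abs(mean(x) - pv$base), 3 * se)
    expect_equal(dist_mean(d), pv$base, tolerance = 1e-9)
  }
  # raw mode keeps the printed pair verbatim
  pv <- ugcscreen:::get_param(ps, "costs.screening_total")
  expect_equal(ugcscreen:::effective_dist(pv, "raw")$params, c(2.16, 0.003))
})

test_that("config fixture loads with printed values and defaults fill in", {
  cfg <- system.file("extdata", "ugc_params_synthetic.yaml",
                     package = "ugcscreen")
  ps <- load_parameter_set(cfg)
  expect_equal(ps$test$sensitivity$base, 0.96)
  expect_equal(ps$test$sensitivity$low, 0.90)
  expect_equal(ps$test$sensitivity$high, 0.99)
  expect_equal(ps$wtp, 70653)
  expect_equal(ps$cohort_size, 100000L)
  expect_equal(ps$age_span, c(40L, 80L))

  # omitting optional top-level keys falls back to documented defaults
  doc <- yaml::read_yaml(cfg)
  doc$wtp <- NULL; doc$cohort_size <- NULL; doc$discount_rate <- NULL
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, tmp)
  ps2 <- load_parameter_set(tmp)
  expect_equal(ps2$wtp, 70653)
  expect_equal(ps2$cohort_size, 100000L)
  expect_equal(ps2$discount_rate$base, 0.03)
})

test_that("validation failures are aggregated and name the offending block", {
  ps <- default_ps()
  bad <- ps
  bad$initial_distribution <- ps$initial_distribution * 0.9
  bad$test$sensitivity$base <- 1.5
  err <- tryCatch(validate_parameter_set(bad), error = conditionMessage)
  expect_match(err, "initial_distribution")
  expect_match(err, "test\\$sensitivity")

  bad2 <- ps
  bad2$transitions <- rbind(ps$transitions,
                            data.frame(from = "es_early", to = "es_mD",
                                       prob = 0.1, period_years = 1))
  expect_error(validate_parameter_set(bad2), "post-intramucosal")
})

test_that("config parse errors name the offending key", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines("format: something-else", tmp)
  expect_error(load_parameter_set(tmp), "format")
  writeLines("format: ugc-cea/1", tmp)
  expect_error(load_parameter_set(tmp), "transitions")
})

test_that("PSA sampling is seed-deterministic, respects domains and validates", {
  ps <- default_ps()
  s1 <- sample_parameter_set(ps, 7)
  s2 <- sample_parameter_set(ps, 7)
  expect_identical(s1, s2)
  s3 <- sample_parameter_set(ps, 8)
  expect_false(identical(s1$compliance$screening$base,
                         s3$compliance$screening$base))
  # structural fields unchanged
  expect_identical(s1$transitions, ps$transitions)
  expect_identical(s1$mortality, ps$mortality)
  for (seed in 1:20) {
    s <- sample_parameter_set(ps, seed)   # validator runs inside
    expect_true(all(vapply(s$utilities, function(u) u$base <= 1, TRUE)))
    expect_true(s$compliance$screening$base >= 0.30)
    expect_true(s$compliance$screening$base <= 0.80)
  }
})

test_that("parameter table lists every tunable with range and family", {
  pt <- parameter_table(default_ps())
  expect_true(all(c("compliance.screening", "discount_rate",
                    "costs.treatment.ga.advanced_screen",
                    "utilities.ca_adv") %in% pt$name))
  expect_true(all(pt$low <= pt$base & pt$base <= pt$high))
  row <- pt[pt$name == "test.sensitivity", ]
  expect_equal(row$base, 0.96)
  expect_equal(row$family, "triangular")
})
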