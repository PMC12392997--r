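# Cohort propagation: cycle operator assembly, conservation, tunnels,
# absorption and event tallies.

test_that("cycle operators are stochastic matrices at every age", {
  ps <- default_ps()
  for (age in c(40, 55, 80)) {
    M <- assemble_cycle_matrix(ps, age)
    expect_equal(unname(rowSums(M)), rep(1, nrow(M)), tolerance = 1e-12)
    expect_true(all(M >= 0))
    # absorbing death states
    expect_equal(unname(M["death_ugc", "death_ugc"]), 1)
    expect_equal(unname(M["death_other", "death_other"]), 1)
  }
  expect_error(assemble_cycle_matrix(ps, 39), "age")
  expect_error(assemble_cycle_matrix(ps, 81), "age")
})

test_that("operator entries match hand-built competing-risk composition", {
  ps <- default_ps()
  age <- 50
  M <- assemble_cycle_matrix(ps, age)
  q_o <- ps$mortality$other$prob[ps$mortality$other$age == age]
  q_u <- ps$mortality$ugc$prob[ps$mortality$ugc$age == age]
  tr <- ps$transitions
  p_fwd <- tr$prob[tr$from == "es_mD" & tr$to == "es_MD"]
  p_bwd <- tr$prob[tr$from == "es_mD" & tr$to == "healthy"]
  # other-cause death first, then disease transitions on survivors
  expect_equal(unname(M["es_mD", "es_MD"]), (1 - q_o) * p_fwd)
  expect_equal(unname(M["es_mD", "healthy"]), (1 - q_o) * p_bwd)
  expect_equal(unname(M["es_mD", "death_other"]), q_o)
  expect_equal(unname(M["es_mD", "es_mD"]), (1 - q_o) * (1 - p_fwd - p_bwd))
  # early cancer: UGC death applied after other-cause death
  p_adv <- tr$prob[tr$from == "es_early" & tr$to == "es_adv"]
  expect_equal(unname(M["es_early", "death_ugc"]), (1 - q_o) * q_u)
  expect_equal(unname(M["es_early", "es_adv_d1"]),
               (1 - q_o) * (1 - q_u) * p_adv)
  # advanced tunnel: duration-specific death, duration increments by one
  qd <- ps$mortality$advanced$es
  expect_equal(unname(M["es_adv_d2", "death_ugc"]), (1 - q_o) * qd[2])
  expect_equal(unname(M["es_adv_d2", "es_adv_d3"]), (1 - q_o) * (1 - qd[2]))
  expect_equal(unname(M["es_adv_d6", "es_adv_d6"]), (1 - q_o) * (1 - qd[6]))
  # no regression out of post-intramucosal states
  expect_equal(unname(M["es_early", "es_SDCIS"]), 0)
})

test_that("advancing a cohort matches explicit matrix multiplication", {
  # identity operator leaves any vector unchanged
  ps <- inert_ps()
  M <- assemble_cycle_matrix(ps, 60)
  v <- ugcscreen:::expand_initial(ps$initial_distribution)
  expect_equal(advance_cohort(v, M), v)
  # 2-state toy embedded in a plain matrix: p = 0.3 per cycle, 2 cycles
  A <- matrix(c(0.7, 0.3, 0, 1), 2, 2, byrow = TRUE)
  x <- c(1, 0)
  x <- advance_cohort(x, A); x <- advance_cohort(x, A)
  expect_equal(x[1], 0.49)
  expect_error(advance_cohort(c(1, 0, 0), A), "dimension")
  # small-instance oracle: trace equals repeated multiplication
  ps2 <- default_ps()
  tr <- run_cohort(ps2, NULL)
  eng <- ugcscreen:::build_engine(ps2)
  v <- ugcscreen:::expand_initial(ps2$initial_distribution)
  for (t in 1:5) v <- drop(v %*% eng$matrices[[t]])
  expect_equal(unname(tr$occupancy[6, ]), unname(v), tolerance = 1e-12)
})

test_that("occupancy is conserved at every cycle for every arm", {
  ps <- default_ps()
  for (strat in list(NULL, screening_strategy(40, 1, FALSE),
                     screening_strategy(45, 5, TRUE))) {
    tr <- run_cohort(ps, strat)
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, nrow(tr$occupancy)),
                 tolerance = 1e-9)
    expect_true(all(tr$occupancy >= -1e-15))
  }
})

test_that("cumulative deaths never decrease and the cohort is absorbed", {
  ps <- default_ps()
  tr <- run_cohort(ps, NULL)
  dead <- tr$occupancy[, "death_ugc"] + tr$occupancy[, "death_other"]
  expect_true(all(diff(dead) > 0))
  # extend the horizon: with mortality bounded below, live mass vanishes
  ps2 <- ps
  ps2$age_span <- c(40L, 200L)
  extra <- data.frame(age = 81:200, prob = ps$mortality$other$prob[41])
  ps2$mortality$other <- rbind(ps$mortality$other, extra)
  ps2$mortality$ugc <- rbind(ps$mortality$ugc,
                             data.frame(age = 81:200,
                                        prob = ps$mortality$ugc$prob[41]))
  tr2 <- run_cohort(ps2, NULL)
  live <- 1 - tr2$occupancy[, "death_ugc"] - tr2$occupancy[, "death_other"]
  expect_true(all(diff(live) < 1e-15))
  expect_lt(live[length(live)], 1e-3)
})

test_that("tunnel states reproduce 5-year survival on a forced cohort", {
  ps <- inert_ps(c(es_adv = 1))
  S5 <- 0.37
  ps$mortality$advanced$es <- derive_advanced_mortality(S5)
  tr <- run_cohort(ps, NULL)
  # after 5 cycles the surviving advanced mass equals S5
  live5 <- 1 - tr$occupancy[6, "death_ugc"]
  expect_equal(unname(live5), S5, tolerance = 1e-6)
})

test_that("cohort propagation is deterministic and tallies audit the flows", {
  ps <- default_ps()
  t1 <- run_cohort(ps, screening_strategy(50, 5, TRUE))
  t2 <- run_cohort(ps, screening_strategy(50, 5, TRUE))
  expect_identical(t1$occupancy, t2$occupancy)
  expect_identical(t1$events, t2$events)

  s <- tally_events(t1)
  expect_equal(unname(s$cases), unname(sum(s$cases_by_organ)))
  expect_equal(s$ugc_deaths,
               t1$occupancy[nrow(t1$occupancy), "death_ugc"] * ps$cohort_size,
               tolerance = 1e-6, ignore_attr = TRUE)
  # zero-disease cohort: no cases, no UGC deaths
  ps0 <- inert_ps(c(healthy = 1))
  s0 <- tally_events(run_cohort(ps0, NULL))
  expect_equal(unname(s0$cases), 0)
  expect_equal(unname(s0$ugc_deaths), 0)
  expect_equal(s0$life_years, ps0$cohort_size * 41, ignore_attr = TRUE)
})
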