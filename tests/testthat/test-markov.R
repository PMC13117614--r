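stg <- c("I", "II", "III", "IV")

test_that("one cycle from undiagnosed stage I matches the hand computation", {
  # event order: other-cause death 0.1, then diagnosis 0.3 among survivors,
  # then progression 0.2 among the undiagnosed remainder
  p <- test_params(
    p_diag = c(0.3, 0.15, 0.3, 0.5),
    p_progress = c(0.2, 0.18, 0.22),
    oc_death_3m = 0.1
  )
  st <- step_cohort(
    cohort_state(age = 60, no_lc = 0, undiag = c(1, 0, 0, 0)),
    p,
    stratum = tibble::tibble(sex = "male")
  )
  occ <- st$occupancy
  expect_equal(occ[["dead_other"]], 0.1, tolerance = 1e-12)
  expect_equal(occ[["diag_I_slot1"]], 0.9 * 0.3, tolerance = 1e-12) # 0.27
  expect_equal(occ[["undiag_II"]], 0.9 * 0.7 * 0.2, tolerance = 1e-12) # 0.126
  expect_equal(occ[["undiag_I"]], 0.9 * 0.7 * 0.8, tolerance = 1e-12) # 0.504
  expect_equal(sum(occ), 1, tolerance = 1e-12)
  expect_equal(unname(st$newly_diagnosed[["I"]]), 0.27, tolerance = 1e-12)
})

test_that("dead states are absorbing", {
  p <- test_params()
  st <- cohort_state(age = 70, no_lc = 0) # everyone dead at construction
  out <- step_cohort(st, p, stratum = tibble::tibble(sex = "male"))
  expect_equal(out$occupancy[["dead_other"]], 1)
  expect_equal(sum(out$occupancy), 1, tolerance = 1e-12)
  expect_equal(out$age, 70.25)
})

test_that("with all probabilities zero the occupancy is frozen and age advances", {
  p <- test_params(
    p_diag = c(0, 0, 0, 0), p_progress = c(0, 0, 0),
    lc_death_3m = c(I = 0, II = 0, III = 0, IV = 0),
    lc_post5 = 0, oc_death_3m = 0
  )
  st <- cohort_state(age = 60, no_lc = 0.4, undiag = c(0.3, 0, 0, 0), diag = c(0.3, 0, 0, 0))
  out <- step_cohort(st, p, stratum = tibble::tibble(sex = "male"))
  expect_equal(out$occupancy[["no_lc"]], 0.4)
  expect_equal(out$occupancy[["undiag_I"]], 0.3)
  # the diagnosed tunnel advanced one slot
  expect_equal(out$occupancy[["diag_I_slot2"]], 0.3)
  expect_equal(out$occupancy[["diag_I_slot1"]], 0)
  expect_equal(out$age, 60.25)
})

test_that("occupancy is conserved every cycle and deaths accumulate monotonically", {
  for (seed in c(2, 13, 27)) {
    p <- random_paramset(seed)
    for (arm in c("screening", "standard_care")) {
      res <- run_arm(p, arm, trace = TRUE)
      sums <- trace_cycle_sums(res)
      expect_true(all(abs(sums$total - 1) < 1e-9))
      tr <- attr(res, "trace")
      dead <- dplyr::summarise(
        tr[tr$state %in% c("dead_lc", "dead_other"), ],
        dead = sum(occupancy), .by = c("cycle", "stratum")
      )
      by_str <- split(dead, dead$stratum)
      expect_true(all(vapply(
        by_str,
        function(d) all(diff(d$dead[order(d$cycle)]) >= -1e-12), logical(1)
      )))
    }
  }
})

test_that("the screening arm never occupies undiagnosed states", {
  p <- calibrate_params(default_paramset())
  res <- run_arm(p, "screening", trace = TRUE)
  tr <- attr(res, "trace")
  undiag <- tr$occupancy[startsWith(tr$state, "undiag_")]
  expect_true(all(undiag == 0))
})

test_that("life years without mortality reach the age cap, within half a cycle", {
  p <- test_params(
    prevalence = 0, oc_death_3m = 0, discount = 0,
    u_no = c(male = 1, female = 1), u_band_decline = c(1, 1, 1)
  )
  res <- run_arm(p, "screening")
  # start age 57.5; certain death on arrival at age 100; trapezoidal
  # correction adds half a cycle for the final death cycle
  expect_equal(res$life_years, 100 - 57.5 + 0.125, tolerance = 1e-9)
  expect_equal(res$qalys, res$life_years, tolerance = 1e-9)
})

test_that("without half-cycle correction the accrual is the plain Riemann sum", {
  p <- test_params(
    prevalence = 0, oc_death_3m = 0, discount = 0, hcc = FALSE,
    u_no = c(male = 1, female = 1), u_band_decline = c(1, 1, 1)
  )
  res <- run_arm(p, "screening")
  # alive at snapshots 0..170 (ages 57.5 to 100), 0.25 years each
  expect_equal(res$life_years, 171 * 0.25, tolerance = 1e-9)
})

test_that("discounting can only shrink totals", {
  p0 <- test_params(discount = 0)
  p3 <- test_params(discount = 0.03)
  for (arm in c("screening", "standard_care")) {
    r0 <- run_arm(p0, arm)
    r3 <- run_arm(p3, arm)
    expect_lt(r3$life_years, r0$life_years)
    expect_lt(r3$qalys, r0$qalys)
    expect_lte(r3$cost_dxtx, r0$cost_dxtx + 1e-9)
  }
})

test_that("QALYs never exceed life years and everyone eventually dies", {
  for (p in list(calibrate_params(default_paramset()), random_paramset(4))) {
    for (arm in c("screening", "standard_care")) {
      r <- run_arm(p, arm)
      expect_true(all(r$qalys <= r$life_years + 1e-9))
      expect_equal(r$lc_deaths + r$oc_deaths, rep(1, nrow(r)), tolerance = 1e-9)
    }
  }
})

test_that("removing the stage shift removes the QALY benefit", {
  p <- calibrate_params(default_paramset())
  incr <- function(pp) {
    agg <- aggregate_subgroups(incremental(
      run_arm(pp, "screening"), run_arm(pp, "standard_care")
    ))
    agg$d_qalys
  }
  base_gain <- incr(p)
  p_noshift <- p
  p_noshift$screening$stage_dist_screen <- p$screening$stage_dist_standard
  expect_lt(incr(p_noshift), base_gain)
})

test_that("diagnosis-and-treatment costs are charged once per diagnosis", {
  # with zero prevalence and no progression out of nothing, no dx/tx costs
  p <- test_params(prevalence = 0)
  for (arm in c("screening", "standard_care")) {
    expect_equal(run_arm(p, arm)$cost_dxtx, 0)
  }
  # screen-detected baseline cases are charged undiscounted at time zero
  p <- test_params(prevalence = 0.1, stage_screen = c(1, 0, 0, 0))
  r <- run_arm(p, "screening")
  expect_equal(r$cost_dxtx, 0.1 * p$costs$c_dx_tx[["I"]], tolerance = 1e-12)
})

test_that("cumulative diagnoses and deaths are consistent", {
  p <- calibrate_params(default_paramset())
  r <- run_arm(p, "standard_care")
  dx_total <- rowSums(as.matrix(dplyr::select(r, dplyr::starts_with("dx_"))))
  # everyone dying of lung cancer was diagnosed first
  expect_true(all(r$lc_deaths <= dx_total + 1e-9))
})
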