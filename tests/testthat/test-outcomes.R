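fake_arm <- function(arm, ly, qaly, lcd, det, fp, dxtx,
                     sex = "male", age_group = "55-59", weight = 1) {
  tibble::tibble(
    sex = sex, age_group = age_group, weight = weight, arm = arm,
    life_years = ly, qalys = qaly,
    cost_detection = det, cost_fp = fp, cost_dxtx = dxtx,
    cost_total = det + fp + dxtx,
    lc_deaths = lcd, oc_deaths = 1 - lcd,
    dx_I = 0, dx_II = 0, dx_III = 0, dx_IV = 0
  )
}

test_that("identical arms give zero deltas", {
  a <- fake_arm("screening", 10, 8, 0.2, 100, 50, 2000)
  b <- fake_arm("standard_care", 10, 8, 0.2, 100, 50, 2000)
  d <- incremental(a, b)
  expect_equal(d$d_life_years, 0)
  expect_equal(d$d_cost_total, 0)
  expect_equal(d$d_qalys, 0)
})

test_that("published cost components sum and divide to the published ICER", {
  scr <- fake_arm("screening", 10.0481, 8.0395, 0.2, 164, 66, 0)
  soc <- fake_arm("standard_care", 10, 8, 0.2, 0, 0, 121)
  d <- incremental(scr, soc)
  expect_equal(d$d_cost_detection, 164)
  expect_equal(d$d_cost_fp, 66)
  expect_equal(d$d_cost_dxtx, -121)
  expect_equal(d$d_cost_total, 109, tolerance = 1e-12)
  expect_equal(d$d_qalys, 0.0395, tolerance = 1e-9)
  # ICER on unrounded deltas: 109 / 0.0395
  expect_equal(d$icer_per_qaly, 2759.4937, tolerance = 1e-4)
  expect_identical(d$icer_label, "ratio")
})

test_that("dominance labels match the cost-effectiveness plane quadrant", {
  mk <- function(dc, dq) {
    incremental(
      fake_arm("screening", 10, 8 + dq, 0.2, dc, 0, 0),
      fake_arm("standard_care", 10, 8, 0.2, 0, 0, 0)
    )
  }
  expect_identical(mk(-50, 0.1)$icer_label, "dominant")
  expect_identical(mk(50, -0.1)$icer_label, "dominated")
  expect_identical(mk(50, 0)$icer_label, "undefined")
  expect_true(is.na(mk(50, 0)$icer_per_qaly))
  expect_identical(mk(50, 0.1)$icer_label, "ratio")
  # random inputs: label consistent with the quadrant
  set.seed(42)
  for (i in 1:50) {
    dc <- stats::runif(1, -200, 200)
    dq <- stats::runif(1, -0.2, 0.2)
    lab <- mk(dc, dq)$icer_label
    expect_identical(lab, if (dc < 0 && dq > 0) {
      "dominant"
    } else if (dc > 0 && dq < 0) {
      "dominated"
    } else if (dq == 0 && dc != 0) {
      "undefined"
    } else {
      "ratio"
    })
  }
})

test_that("subgroup aggregation is a weighted mean with ratio-of-averages ICERs", {
  two <- dplyr::bind_rows(
    incremental(
      fake_arm("screening", 10.01, 8.01, 0.2, 100, 0, 0, weight = 0.5),
      fake_arm("standard_care", 10, 8, 0.2, 0, 0, 0, weight = 0.5)
    ),
    incremental(
      fake_arm("screening", 10.03, 8.03, 0.2, 200, 0, 0,
        weight = 0.5, age_group = "60-64"
      ),
      fake_arm("standard_care", 10, 8, 0.2, 0, 0, 0,
        weight = 0.5, age_group = "60-64"
      )
    )
  )
  agg <- aggregate_subgroups(two)
  expect_equal(agg$d_cost_total, 150)
  expect_equal(agg$d_qalys, 0.02, tolerance = 1e-9)
  expect_equal(agg$icer_per_qaly, 7500, tolerance = 1e-6)
})

test_that("a single subgroup with weight one aggregates to itself", {
  d <- incremental(
    fake_arm("screening", 10.1, 8.1, 0.18, 150, 60, -30),
    fake_arm("standard_care", 10, 8, 0.2, 10, 5, 100)
  )
  agg <- aggregate_subgroups(d)
  for (cn in c("d_life_years", "d_qalys", "d_cost_total", "icer_per_qaly")) {
    expect_equal(agg[[cn]], d[[cn]], tolerance = 1e-12)
  }
})

test_that("weights that do not sum to one are a domain error", {
  d <- incremental(
    fake_arm("screening", 10, 8, 0.2, 0, 0, 0, weight = 0.7),
    fake_arm("standard_care", 10, 8, 0.2, 0, 0, 0, weight = 0.7)
  )
  expect_error(aggregate_subgroups(d), "sum")
})

test_that("aggregation is additive against the pooled hand computation", {
  p <- calibrate_params(default_paramset())
  incr <- incremental(run_arm(p, "screening"), run_arm(p, "standard_care"))
  agg <- aggregate_subgroups(incr)
  expect_equal(
    agg$d_qalys, sum(incr$weight * incr$d_qalys),
    tolerance = 1e-9
  )
  expect_equal(
    agg$d_cost_total, sum(incr$weight * incr$d_cost_total),
    tolerance = 1e-9
  )
})

test_that("per-10,000 scaling reproduces the published table arithmetic", {
  d <- incremental(
    fake_arm("screening", 10.0481, 8.0395, 0.1961, 164, 66, 0),
    fake_arm("standard_care", 10, 8, 0.2, 0, 0, 121)
  )
  t10k <- scale_per_10k(d)
  expect_equal(t10k$qalys_gained, 395)
  expect_equal(t10k$life_years_saved, 481)
  expect_equal(t10k$lc_deaths_averted, 39)
  expect_equal(t10k$cost_total, 1090000)
})

test_that("false-positive surgery counts match the published arithmetic", {
  p <- default_paramset()
  # 10,000 x 0.180 x 0.008 = 14.4 -> 14
  expect_equal(fp_surgeries(10000, p), 14)
  expect_equal(fp_surgeries(10000, p, round = FALSE), 14.4, tolerance = 1e-9)
  p0 <- test_params(p_fp_ldct = c(under65 = 0, `65plus` = 0))
  expect_equal(fp_surgeries(10000, p0), 0)
  p2 <- test_params(p_fp_ldct = c(under65 = 0.5, `65plus` = 0.5), p_surgery_fp = 0.1)
  expect_equal(fp_surgeries(1000, p2), 50)
})

test_that("overdiagnosis is zero without competing mortality", {
  p <- test_params(oc_death_3m = 0)
  expect_equal(overdiagnosis_fraction(p), 0, tolerance = 1e-12)
})

test_that("certain diagnosis leaves only the single-cycle competing deaths", {
  # other-cause death is applied first within the cycle, so with certain
  # diagnosis the overdiagnosed fraction is exactly the one-cycle death
  # probability
  p <- test_params(p_diag = c(1, 1, 1, 1), oc_death_3m = 0.1)
  expect_equal(overdiagnosis_fraction(p), 0.1, tolerance = 1e-12)
})

test_that("overdiagnosis increases with other-cause mortality", {
  od <- vapply(c(0.5, 1, 2), function(k) {
    overdiagnosis_fraction(test_params(oc_death_3m = 0.008 * k))
  }, numeric(1))
  expect_true(all(diff(od) > 0))
})

test_that("the full deterministic pipeline returns a coherent result object", {
  fit <- run_cea(default_paramset())
  expect_s3_class(fit, "lcs_cea")
  agg <- glance(fit)
  expect_equal(
    agg$d_cost_total,
    agg$d_cost_detection + agg$d_cost_fp + agg$d_cost_dxtx,
    tolerance = 1e-9
  )
  expect_identical(nrow(tidy(fit, "incremental")), 12L)
  expect_identical(nrow(tidy(fit, "arms")), 24L)
  expect_gt(agg$overdiagnosis_per_10k, 0)
  expect_equal(agg$fp_surgeries_per_10k, 14.4, tolerance = 1e-9)
})
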