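test_that("without progression or deaths, stage at diagnosis equals the baseline mix", {
  # diagnosis fast enough that the chain is exhausted well before the age cap
  p <- test_params(
    p_progress = c(0, 0, 0), oc_death_3m = 0,
    p_diag = c(0.3, 0.3, 0.3, 0.5),
    stage_screen = c(0.6, 0.1, 0.1, 0.2)
  )
  d <- simulate_stage_at_diagnosis(p)
  expect_equal(unname(d), c(0.6, 0.1, 0.1, 0.2), tolerance = 1e-9)
})

test_that("certain diagnosis in the first cycle returns the baseline mix", {
  p <- test_params(
    p_diag = c(1, 1, 1, 1), p_progress = c(0.3, 0.3, 0.3),
    stage_screen = c(0.4, 0.3, 0.2, 0.1)
  )
  d <- simulate_stage_at_diagnosis(p)
  expect_equal(unname(d), c(0.4, 0.3, 0.2, 0.1), tolerance = 1e-12)
})

test_that("the 2-stage toy reproduces the geometric-series closed form", {
  # everyone starts undiagnosed stage I; each cycle: diagnose w.p. 0.5,
  # else progress w.p. 0.5; stage II diagnosed with certainty. Then
  # P(diagnosed at I) = sum_k (0.25)^k * 0.5 = 2/3.
  p <- test_params(
    stage_screen = c(1, 0, 0, 0),
    p_progress = c(0.5, 0, 0),
    p_diag = c(0.5, 1, 1, 1),
    oc_death_3m = 0
  )
  d <- simulate_stage_at_diagnosis(p)
  expect_equal(unname(d[["I"]]), 2 / 3, tolerance = 1e-8)
  expect_equal(unname(d[["II"]]), 1 / 3, tolerance = 1e-8)
})

test_that("the sub-chain agrees with absorbing-state linear algebra to 1e-8", {
  # time-homogeneous instance: constant other-cause mortality, fast enough
  # diagnosis that the chain is exhausted long before the age cap
  pi0 <- c(0.5, 0.2, 0.2, 0.1)
  pd <- c(0.35, 0.4, 0.5, 0.6)
  pp <- c(0.15, 0.2, 0.25)
  poc <- 0.012
  p <- test_params(
    stage_screen = pi0, p_diag = pd, p_progress = pp, oc_death_3m = poc
  )
  Q <- matrix(0, 4, 4)
  for (s in 1:3) {
    Q[s, s] <- (1 - poc) * (1 - pd[s]) * (1 - pp[s])
    Q[s, s + 1] <- (1 - poc) * (1 - pd[s]) * pp[s]
  }
  Q[4, 4] <- (1 - poc) * (1 - pd[4])
  R <- diag((1 - poc) * pd)
  absorbed <- pi0 %*% solve(diag(4) - Q) %*% R
  expected <- as.vector(absorbed / sum(absorbed))
  d <- simulate_stage_at_diagnosis(p)
  expect_equal(unname(d), expected, tolerance = 1e-8)
})

test_that("calibration recovers a self-generated target", {
  p <- test_params()
  truth <- c(I = 0.07, II = 0.18, III = 0.33)
  target <- simulate_stage_at_diagnosis(p, diag_probs = truth)
  rec <- calibrate_diagnosis_probs(p,
    target = target,
    init = c(I = 0.3, II = 0.3, III = 0.3)
  )
  expect_true(rec$converged)
  expect_lte(rec$max_dev, 1e-4)
  reproduced <- simulate_stage_at_diagnosis(p, diag_probs = rec$p_diag)
  expect_lt(max(abs(reproduced - target)), 1e-4 + 1e-9) # absolute, per stage
})

test_that("the 2-stage toy inverts to the known diagnosis probability", {
  p <- test_params(
    stage_screen = c(1, 0, 0, 0),
    p_progress = c(0.5, 0, 0),
    p_diag = c(0.2, 1, 1, 1), # deliberately wrong start for stage I
    oc_death_3m = 0
  )
  rec <- calibrate_diagnosis_probs(p,
    target = c(I = 2 / 3, II = 1 / 3, III = 0, IV = 0),
    tolerance = 1e-6
  )
  expect_true(rec$converged)
  expect_equal(unname(rec$p_diag[["I"]]), 0.5, tolerance = 1e-3)
})

test_that("a target equal to the baseline mix with no progression converges immediately", {
  # no progression and no competing deaths: the sub-chain cannot reshape
  # the stage mix, so the first simulated distribution already matches
  dist <- c(0.6, 0.1, 0.1, 0.2)
  p <- test_params(
    stage_screen = dist, stage_standard = dist, p_progress = c(0, 0, 0),
    oc_death_3m = 0
  )
  rec <- calibrate_diagnosis_probs(p)
  expect_true(rec$converged)
  expect_identical(rec$iterations, 1L)
})

test_that("the stage-I share at diagnosis is monotone in its diagnosis probability", {
  p <- test_params()
  shares <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(pd) {
    simulate_stage_at_diagnosis(
      p,
      diag_probs = c(I = pd, II = 0.15, III = 0.3)
    )[["I"]]
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
})

test_that("per-stratum calibration returns one record per stratum", {
  p <- default_paramset()
  p$strata <- p$strata[p$strata$age_group %in% c("55-59", "80"), ]
  p$strata$weight <- p$strata$weight / sum(p$strata$weight)
  p$screening$overall_prevalence <- weighted_prevalence(p)
  res <- calibrate_diagnosis_probs(p, by_stratum = TRUE)
  expect_identical(nrow(res), 4L)
  expect_true(all(res$converged))
  expect_true(all(res$max_dev <= 1e-4))
})

test_that("calibrate_params writes the probabilities back with a record", {
  p <- calibrate_params(default_paramset())
  rec <- attr(p, "calibration")
  expect_true(rec$converged)
  d <- simulate_stage_at_diagnosis(p)
  expect_equal(
    unname(d), unname(p$screening$stage_dist_standard),
    tolerance = 2e-4
  )
})
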