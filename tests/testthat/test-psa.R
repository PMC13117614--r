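test_that("draws are deterministic in (seed, iteration) and vary across iterations", {
  base <- default_paramset()
  d1 <- draw_paramset(base, dist_spec(), rng_seed = 1, iteration = 3)
  d2 <- draw_paramset(base, dist_spec(), rng_seed = 1, iteration = 3)
  d3 <- draw_paramset(base, dist_spec(), rng_seed = 1, iteration = 4)
  expect_equal(d1, d2)
  expect_false(isTRUE(all.equal(d1, d3)))
  expect_identical(nrow(validate_params(d1)), 0L)
})

test_that("a point-mass spec returns the base values exactly", {
  base <- default_paramset()
  d <- draw_paramset(base, point_mass_spec(), rng_seed = 9, iteration = 1)
  expect_equal(d, base, tolerance = 1e-15)
})

test_that("draws keep the stage distributions on the simplex", {
  base <- default_paramset()
  for (i in 1:25) {
    d <- draw_paramset(base, dist_spec(), rng_seed = 5, iteration = i)
    expect_equal(sum(d$screening$stage_dist_screen), 1, tolerance = 1e-12)
    expect_equal(sum(d$screening$stage_dist_standard), 1, tolerance = 1e-12)
    expect_identical(nrow(validate_params(d)), 0L)
  }
})

test_that("Beta draws are centred on the base value", {
  # method-of-moments Beta around the published mean false-positive
  # probability: the empirical mean of 10,000 draws sits within 3 standard
  # errors of the base value
  m <- 0.18
  cv <- 0.2
  draws <- lcscea:::with_local_seed(
    101,
    lcscea:::beta_draw(rep(m, 10000), cv)
  )
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - m), 3 * se)
  expect_equal(stats::sd(draws), cv * m, tolerance = 0.05)
})

test_that("credible intervals use linear interpolation between closest ranks", {
  expect_equal(
    credible_interval(1:1000),
    c(lower = 25.975, upper = 975.025),
    tolerance = 1e-12
  )
  expect_equal(credible_interval(rep(3.5, 10)), c(lower = 3.5, upper = 3.5))
  sym <- c(-5, -2, -1, 0, 1, 2, 5)
  ci <- credible_interval(sym)
  expect_equal(ci[["lower"]] + ci[["upper"]], 2 * mean(sym), tolerance = 1e-9)
  expect_error(credible_interval(1), "at least 2")
})

test_that("a point-mass PSA collapses to the deterministic base case", {
  p <- calibrate_params(default_paramset())
  det <- glance(run_cea(p, calibrate = FALSE))
  psa <- run_psa(p, point_mass_spec(), n_iter = 3, seed = 1)
  expect_identical(psa$n_excluded, 0L)
  it <- tidy(psa, "iterations")
  expect_equal(unique(it$d_qalys), det$d_qalys, tolerance = 1e-12)
  expect_equal(unique(it$d_cost_total), det$d_cost_total, tolerance = 1e-12)
  s <- tidy(psa, "summary")
  expect_equal(
    s$ci_lower[s$outcome == "d_qalys"],
    s$ci_upper[s$outcome == "d_qalys"]
  )
})

test_that("the PSA is bitwise reproducible under a fixed seed", {
  p <- calibrate_params(default_paramset())
  a <- run_psa(p, dist_spec(), n_iter = 8, seed = 42)
  b <- run_psa(p, dist_spec(), n_iter = 8, seed = 42)
  expect_identical(a$iterations, b$iterations)
  expect_identical(a$ceac, b$ceac)
})

test_that("the CEAC at a zero threshold is the fraction of cost-saving iterations", {
  p <- calibrate_params(default_paramset())
  psa <- run_psa(p, dist_spec(), n_iter = 30, seed = 7)
  it <- tidy(psa, "iterations")
  expect_equal(
    psa$ceac$prob_cost_effective[psa$ceac$threshold == 0],
    mean(it$d_cost_total <= 0)
  )
  expect_true(all(psa$ceac$prob_cost_effective >= 0 &
    psa$ceac$prob_cost_effective <= 1))
})

test_that("the CEAC is monotone in the threshold when all iterations gain QALYs", {
  p <- calibrate_params(default_paramset())
  psa <- run_psa(p, dist_spec(cv_prob = 0.05, cv_cost = 0.2, dirichlet_conc = 400),
    n_iter = 40, seed = 3
  )
  it <- tidy(psa, "iterations")
  expect_true(all(it$d_qalys > 0))
  expect_true(all(diff(psa$ceac$prob_cost_effective) >= 0))
})

test_that("shrinking the distributions drives the PSA mean to the base case", {
  p <- calibrate_params(default_paramset())
  det <- glance(run_cea(p, calibrate = FALSE))$d_qalys
  dev <- vapply(c(0.2, 0.1, 0.02), function(cv) {
    psa <- run_psa(p, dist_spec(cv, cv, 100 / cv), n_iter = 40, seed = 11)
    abs(glance(psa)$d_qalys - det)
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
})

test_that("subgroup PSA means carry the registry weights and strata", {
  p <- calibrate_params(default_paramset())
  psa <- run_psa(p, dist_spec(), n_iter = 10, seed = 2)
  sub <- tidy(psa, "subgroup")
  expect_identical(nrow(sub), 12L)
  expect_equal(sum(sub$weight), 1, tolerance = 1e-9)
  # weighted subgroup means reproduce the mean of the aggregate iterations
  expect_equal(
    sum(sub$weight * sub$d_qalys),
    mean(tidy(psa, "iterations")$d_qalys),
    tolerance = 1e-9
  )
})

test_that("PSA plots build without error", {
  p <- calibrate_params(default_paramset())
  psa <- run_psa(p, dist_spec(), n_iter = 5, seed = 1)
  expect_s3_class(autoplot(psa, "ce_plane"), "ggplot")
  expect_s3_class(autoplot(psa, "ceac"), "ggplot")
})
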