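## Probabilistic sensitivity analysis.
##
## Parameter uncertainty follows the conventional families for
## cost-effectiveness models: Beta for probabilities and utilities
## (method-of-moments from the base-case mean and a coefficient of
## variation), Gamma for costs, Dirichlet for the two stage distributions
## (drawn jointly so they still sum to one), point mass for structural
## settings (discount rate, cycle length, stratum weights). Distinct
## parameters are sampled independently; within a table-valued block fed by
## a single source (the mortality tables, the prevalence age profile, the
## no-cancer utility table) one anchored draw moves the whole block on the
## hazard scale, preserving its internal orderings. Each iteration re-runs
## the whole pipeline, including recalibration of the stage I-III diagnosis
## probabilities against the sampled standard-care stage distribution.

# Beta draw with mean m and sd cv*m (vectorised). Degenerate means and
# cv = 0 return the mean; the variance is capped just inside the feasible
# Beta region so large cv on means near 1 stays well defined.
beta_draw <- function(m, cv) {
  out <- m
  ok <- is.finite(m) & m > 0 & m < 1 & cv > 0
  if (any(ok)) {
    mm <- m[ok]
    v <- pmin((cv * mm)^2, 0.95 * mm * (1 - mm))
    k <- mm * (1 - mm) / v - 1
    out[ok] <- rbeta(length(mm), mm * k, (1 - mm) * k)
  }
  out
}

# Gamma draw with mean m and sd cv*m (vectorised).
gamma_draw <- function(m, cv) {
  out <- m
  ok <- is.finite(m) & m > 0 & cv > 0
  if (any(ok)) {
    out[ok] <- rgamma(sum(ok), shape = 1 / cv^2, scale = m[ok] * cv^2)
  }
  out
}

dirichlet_draw <- function(p, conc) {
  if (conc <= 0 || !is.finite(conc)) {
    return(p)
  }
  g <- rgamma(length(p), shape = conc * p)
  setNames(g / sum(g), names(p))
}

#' Distribution specification for the PSA
#'
#' @param cv_prob coefficient of variation for Beta-distributed
#'   probabilities and utilities (0 = point mass). Default 0.2.
#' @param cv_cost coefficient of variation for Gamma-distributed costs.
#'   Default 0.2.
#' @param dirichlet_conc concentration of the Dirichlet draws for the two
#'   stage distributions (`Inf` or 0 = point mass). Default 100.
#' @return a list of class `lcs_dist_spec`.
#' @export
dist_spec <- function(cv_prob = 0.2, cv_cost = 0.2, dirichlet_conc = 100) {
  if (cv_prob < 0 || cv_cost < 0) abort("coefficients of variation must be >= 0")
  structure(
    list(
      cv_prob = cv_prob, cv_cost = cv_cost,
      dirichlet_conc = if (is.infinite(dirichlet_conc)) 0 else dirichlet_conc
    ),
    class = "lcs_dist_spec"
  )
}

#' Point-mass distribution specification
#'
#' All draws return the base-case values exactly; the PSA collapses to the
#' deterministic result.
#' @export
point_mass_spec <- function() dist_spec(cv_prob = 0, cv_cost = 0, dirichlet_conc = 0)

#' Draw one parameter set from the PSA distributions
#'
#' Every uncertain parameter is sampled around its base-case mean:
#' probabilities and utilities from Beta, costs from Gamma, stage
#' distributions jointly from Dirichlet. Table-valued blocks that come from
#' a single source (lung-cancer mortality per stage, other-cause mortality
#' per sex, the prevalence age profile, the no-cancer utility table) move
#' together through one anchored draw applied on the hazard scale, so their
#' internal age/year orderings are preserved while the level carries the
#' uncertainty. Stratum weights, economic settings, the age cap and the
#' calibrated stage I-III diagnosis probabilities (which are re-derived
#' downstream, not inputs) are kept at their base values. Deterministic
#' given `(rng_seed, iteration)`.
#'
#' @param base a validated `lcs_params`.
#' @param spec a [dist_spec()].
#' @param rng_seed integer master seed.
#' @param iteration iteration number (>= 1).
#' @return a valid `lcs_params` draw.
#' @export
draw_paramset <- function(base, spec = dist_spec(), rng_seed = 1L, iteration = 1L) {
  seed_i <- as.integer((as.numeric(rng_seed) * 100003 + as.numeric(iteration)) %%
    (.Machine$integer.max - 1))
  with_local_seed(seed_i, draw_paramset_impl(base, spec))
}

# Scale a probability vector on the hazard scale by the ratio of a drawn
# anchor to its mean: p' = 1 - (1 - p)^(draw/anchor). Used for table-valued
# parameter blocks (mortality by age/stage/year, the prevalence age profile)
# where a single source feeds the whole table: one Beta draw per block keeps
# the within-table structure (age gradients, stage and year orderings)
# intact while the block's level carries the uncertainty. Certain events
# (p = 1) stay certain.
hazard_scaled_draw <- function(p_vec, cv) {
  anchor <- mean(p_vec[p_vec < 1], na.rm = TRUE)
  if (!is.finite(anchor) || anchor <= 0 || anchor >= 1 || cv <= 0) {
    return(p_vec)
  }
  f <- beta_draw(anchor, cv) / anchor
  ifelse(p_vec >= 1, 1, 1 - (1 - p_vec)^f)
}

draw_paramset_impl <- function(base, spec) {
  cp <- spec$cv_prob
  cc <- spec$cv_cost
  p <- base

  scr <- p$screening
  scr$prevalence$prevalence <- hazard_scaled_draw(scr$prevalence$prevalence, cp)
  scr$stage_dist_screen <- dirichlet_draw(scr$stage_dist_screen, spec$dirichlet_conc)
  scr$stage_dist_standard <- dirichlet_draw(scr$stage_dist_standard, spec$dirichlet_conc)
  scr$p_fp_ldct <- beta_draw(scr$p_fp_ldct, cp)
  scr$p_fp_xray <- beta_draw(scr$p_fp_xray, cp)
  scr$p_checkup_year1 <- beta_draw(scr$p_checkup_year1, cp)
  scr$p_surgery_given_fp <- beta_draw(scr$p_surgery_given_fp, cp)
  p$screening <- scr

  tr <- p$transitions
  tr$p_progress_3m <- beta_draw(tr$p_progress_3m, cp)
  tr$p_diagnose_3m["IV"] <- beta_draw(tr$p_diagnose_3m[["IV"]], cp)
  # lung-cancer mortality: one anchored draw per stage (year/sex/band
  # structure from the shared source is preserved on the hazard scale)
  for (s in STAGES) {
    rows <- tr$p_lc_death_3m$stage == s
    tr$p_lc_death_3m$p[rows] <- hazard_scaled_draw(tr$p_lc_death_3m$p[rows], cp)
  }
  tr$p_lc_death_3m_post5 <- beta_draw(tr$p_lc_death_3m_post5, cp)
  # other-cause mortality: one anchored draw per sex preserving the age
  # gradient; certain death at the age cap is structural and stays certain
  for (sx in SEXES) {
    rows <- tr$p_oc_death_3m$sex == sx
    tr$p_oc_death_3m$p[rows] <- hazard_scaled_draw(tr$p_oc_death_3m$p[rows], cp)
  }
  p$transitions <- tr

  ut <- p$utilities
  # one anchored draw scales the whole no-cancer utility table, keeping the
  # sex and age-band ordering from the shared source
  u_anchor <- max(ut$u_no_lc$u)
  if (cp > 0 && u_anchor > 0 && u_anchor < 1) {
    ut$u_no_lc$u <- ut$u_no_lc$u * beta_draw(u_anchor, cp) / u_anchor
  }
  # keep the stage-I reference inside the feasible region of the drawn
  # no-cancer utilities
  ut$u_lc_stageI <- min(beta_draw(ut$u_lc_stageI, cp), max(ut$u_no_lc$u))
  ut$ratios <- pmax(pmin(beta_draw(ut$ratios, cp), 1), 1e-6)
  ut$disutility_screen <- gamma_draw(ut$disutility_screen, cc)
  ut$disutility_fp <- gamma_draw(ut$disutility_fp, cc)
  p$utilities <- ut

  co <- p$costs
  for (nm in c(
    "c_detection_screen", "c_checkup_standard",
    "c_detection_standard_dx", "c_fp_ldct", "c_fp_xray"
  )) {
    co[[nm]] <- gamma_draw(co[[nm]], cc)
  }
  co$c_dx_tx <- gamma_draw(co$c_dx_tx, cc)
  p$costs <- co

  p$screening$overall_prevalence <- weighted_prevalence(p)
  p
}

#' Empirical credible interval
#'
#' Central interval from the empirical percentiles, using linear
#' interpolation between closest order statistics (R's default quantile
#' definition, type 7), which makes the bounds reproducible.
#'
#' @param samples numeric vector (at least 2 values).
#' @param level interval mass (default 0.95: the 2.5th and 97.5th
#'   percentiles).
#' @return named numeric `c(lower, upper)`.
#' @examples
#' credible_interval(1:1000) # 25.975, 975.025
#' @export
credible_interval <- function(samples, level = 0.95) {
  if (length(samples) < 2) abort("need at least 2 samples")
  a <- (1 - level) / 2
  q <- quantile(samples, c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Run the probabilistic sensitivity analysis
#'
#' For each iteration: draw a parameter set, recalibrate the stage I-III
#' diagnosis probabilities against the sampled standard-care stage
#' distribution (warm-started from the base-case calibration), run both
#' arms for every stratum, and aggregate the incremental results across
#' subgroups. Summaries are means and 95% credible intervals; the
#' cost-effectiveness acceptability curve is the fraction of iterations with
#' `lambda * dQALY - dCost >= 0` over a threshold grid. Iterations whose
#' calibration fails to converge are flagged and excluded from the
#' summaries, never silently dropped.
#'
#' @param base a validated `lcs_params`; calibrated internally if the
#'   attached calibration record is missing.
#' @param spec a [dist_spec()] (default: conventional CVs of 0.2,
#'   Dirichlet concentration 100).
#' @param n_iter number of iterations (default 2000).
#' @param seed integer master seed; draws are deterministic given
#'   `(seed, iteration)`.
#' @param recalibrate recalibrate diagnosis probabilities per iteration
#'   (default TRUE); FALSE keeps the base-case calibration (faster).
#' @param wtp_grid thresholds (EUR/QALY) for the acceptability curve.
#' @param calib_tolerance,calib_max_iter per-iteration calibration settings.
#' @return an object of class `lcs_psa`: `iterations` (per-iteration
#'   aggregate incremental results), `summary` (mean and credible interval
#'   per outcome), `ceac` (threshold, probability cost-effective),
#'   `subgroup` (per-stratum PSA means with ICERs as ratios of means),
#'   `n_iter`, `n_excluded`, `seed`, `spec`.
#' @export
run_psa <- function(base, spec = dist_spec(), n_iter = 2000L, seed = 1L,
                    recalibrate = TRUE,
                    wtp_grid = seq(0, 60000, by = 1000),
                    calib_tolerance = 1e-4, calib_max_iter = 200L) {
  if (n_iter < 1) abort("`n_iter` must be >= 1")
  n_iter <- as.integer(n_iter)
  seed <- as.integer(seed)
  if (is.null(attr(base, "calibration"))) {
    base <- calibrate_params(base)
  }
  init <- attr(base, "calibration")$p_diag

  iter_rows <- vector("list", n_iter)
  sub_sum <- NULL
  n_sub <- nrow(base$strata)
  excluded <- integer(0)
  for (i in seq_len(n_iter)) {
    pars <- draw_paramset(base, spec, seed, i)
    if (recalibrate) {
      rec <- withCallingHandlers(
        calibrate_diagnosis_probs(pars,
          tolerance = calib_tolerance,
          max_iterations = calib_max_iter, init = init
        ),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (!rec$converged) {
        excluded <- c(excluded, i)
        next
      }
      pars <- set_diagnosis_probs(pars, rec$p_diag)
    }
    scr <- run_arm(pars, "screening")
    soc <- run_arm(pars, "standard_care")
    incr <- incremental(scr, soc)
    agg <- aggregate_subgroups(incr)
    iter_rows[[i]] <- dplyr::mutate(
      dplyr::select(agg, -"sex", -"age_group", -"weight"),
      iteration = i, .before = 1
    )
    m <- as.matrix(incr[, c(
      "d_life_years", "d_qalys", "d_lc_deaths",
      "d_cost_detection", "d_cost_fp", "d_cost_dxtx", "d_cost_total"
    )])
    sub_sum <- if (is.null(sub_sum)) m else sub_sum + m
  }
  iterations <- dplyr::bind_rows(iter_rows)
  n_used <- nrow(iterations)
  if (n_used == 0) abort("all PSA iterations failed calibration")

  outcome_cols <- c(
    "d_life_years", "d_qalys", "d_lc_deaths",
    "d_cost_detection", "d_cost_fp", "d_cost_dxtx", "d_cost_total"
  )
  summary <- purrr::map_dfr(outcome_cols, function(cn) {
    x <- iterations[[cn]]
    ci <- if (n_used >= 2) credible_interval(x) else c(lower = NA_real_, upper = NA_real_)
    tibble(
      outcome = cn, mean = mean(x),
      ci_lower = ci[["lower"]], ci_upper = ci[["upper"]]
    )
  })
  mean_of <- function(cn) summary$mean[summary$outcome == cn]
  icers <- tibble(
    outcome = c("icer_per_qaly", "icer_per_ly", "cost_per_death_averted"),
    mean = c(
      mean_of("d_cost_total") / mean_of("d_qalys"),
      mean_of("d_cost_total") / mean_of("d_life_years"),
      mean_of("d_cost_total") / -mean_of("d_lc_deaths")
    ),
    ci_lower = NA_real_, ci_upper = NA_real_
  )
  summary <- dplyr::bind_rows(summary, icers)

  ceac <- tibble(
    threshold = wtp_grid,
    prob_cost_effective = purrr::map_dbl(
      wtp_grid,
      function(l) mean(l * iterations$d_qalys - iterations$d_cost_total >= 0)
    )
  )

  subgroup <- dplyr::bind_cols(
    base$strata[, c("sex", "age_group", "weight")],
    as_tibble(sub_sum / n_used)
  )
  subgroup$icer_per_qaly <- subgroup$d_cost_total / subgroup$d_qalys
  subgroup$icer_per_ly <- subgroup$d_cost_total / subgroup$d_life_years

  structure(
    list(
      iterations = iterations, summary = summary, ceac = ceac,
      subgroup = subgroup, n_iter = n_iter, n_excluded = length(excluded),
      excluded = excluded, seed = seed, spec = spec,
      wtp_threshold = base$econ$wtp_threshold
    ),
    class = "lcs_psa"
  )
}

#' @export
print.lcs_psa <- function(x, ...) {
  cat(sprintf(
    "<lcs_psa> %d iterations (%d excluded), seed %d\n",
    x$n_iter, x$n_excluded, x$seed
  ))
  s <- x$summary
  row <- function(nm) s[s$outcome == nm, ]
  q <- row("d_qalys")
  ct <- row("d_cost_total")
  cat(sprintf(
    "  dQALY %.4f (%.4f, %.4f); dCost EUR %.0f (%.0f, %.0f)\n",
    q$mean, q$ci_lower, q$ci_upper, ct$mean, ct$ci_lower, ct$ci_upper
  ))
  cat(sprintf("  ICER EUR %.0f/QALY\n", row("icer_per_qaly")$mean))
  pce <- x$ceac$prob_cost_effective[
    which.min(abs(x$ceac$threshold - x$wtp_threshold))
  ]
  cat(sprintf(
    "  P(cost-effective at EUR %s) = %.1f%%\n",
    format(x$wtp_threshold, big.mark = ","), 100 * pce
  ))
  invisible(x)
}

#' Tidy a PSA result
#'
#' @param x an `lcs_psa` object.
#' @param what `"summary"` (default), `"iterations"` (CE-plane points),
#'   `"ceac"` or `"subgroup"`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.lcs_psa <- function(x, what = c("summary", "iterations", "ceac", "subgroup"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' @rdname tidy.lcs_psa
#' @return `glance()`: one row with the headline PSA quantities.
#' @export
glance.lcs_psa <- function(x, ...) {
  s <- function(nm) x$summary$mean[x$summary$outcome == nm]
  tibble(
    n_iter = x$n_iter, n_excluded = x$n_excluded,
    d_qalys = s("d_qalys"), d_life_years = s("d_life_years"),
    d_lc_deaths = s("d_lc_deaths"), d_cost_total = s("d_cost_total"),
    icer_per_qaly = s("icer_per_qaly"),
    prob_ce_at_wtp = x$ceac$prob_cost_effective[
      which.min(abs(x$ceac$threshold - x$wtp_threshold))
    ]
  )
}
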