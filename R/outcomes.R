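icer_of <- function(d_cost, d_effect) {
  # ratio plus dominance label; ICERs are meaningless as plain ratios off
  # the north-east/south-west diagonal
  label <- dplyr::case_when(
    d_cost < 0 & d_effect > 0 ~ "dominant",
    d_cost > 0 & d_effect < 0 ~ "dominated",
    d_effect == 0 & d_cost != 0 ~ "undefined",
    TRUE ~ "ratio"
  )
  list(value = ifelse(label == "ratio", d_cost / d_effect, NA_real_), label = label)
}

#' Incremental results (screening minus standard care)
#'
#' Componentwise differences of the two arm results, per stratum, with ICERs
#' computed on the unrounded deltas. The effect for the death-averted ratio
#' is the *reduction* in lung-cancer deaths. ICERs carry a label:
#' `"dominant"` (cheaper and more effective), `"dominated"` (more expensive
#' and less effective), `"undefined"` (zero effect difference at nonzero
#' cost) or `"ratio"`.
#'
#' @param screen,soc arm results from [run_arm()] for the screening and
#'   standard-care arms of the same parameter set (matched by stratum).
#' @return tibble per stratum: `d_life_years`, `d_qalys`, `d_lc_deaths`,
#'   `d_cost_detection`, `d_cost_fp`, `d_cost_dxtx`, `d_cost_total`,
#'   `icer_per_qaly`, `icer_per_ly`, `cost_per_death_averted`, `icer_label`.
#' @export
incremental <- function(screen, soc) {
  stopifnot(nrow(screen) == nrow(soc))
  j <- dplyr::left_join(screen, soc,
    by = c("sex", "age_group", "weight"), suffix = c("_scr", "_soc")
  )
  if (nrow(j) != nrow(screen) || anyNA(j$life_years_soc)) {
    abort("arm results do not share the same strata")
  }
  out <- tibble(
    sex = j$sex, age_group = j$age_group, weight = j$weight,
    d_life_years = j$life_years_scr - j$life_years_soc,
    d_qalys = j$qalys_scr - j$qalys_soc,
    d_lc_deaths = j$lc_deaths_scr - j$lc_deaths_soc,
    d_cost_detection = j$cost_detection_scr - j$cost_detection_soc,
    d_cost_fp = j$cost_fp_scr - j$cost_fp_soc,
    d_cost_dxtx = j$cost_dxtx_scr - j$cost_dxtx_soc
  )
  out$d_cost_total <- out$d_cost_detection + out$d_cost_fp + out$d_cost_dxtx
  iq <- icer_of(out$d_cost_total, out$d_qalys)
  il <- icer_of(out$d_cost_total, out$d_life_years)
  id <- icer_of(out$d_cost_total, -out$d_lc_deaths)
  out$icer_per_qaly <- iq$value
  out$icer_per_ly <- il$value
  out$cost_per_death_averted <- id$value
  out$icer_label <- iq$label
  out
}

#' Aggregate incremental results across subgroups
#'
#' Weight-averages every delta and recomputes the ICERs as the ratio of
#' weighted-average costs to weighted-average effects (a ratio of averages,
#' not an average of ratios).
#'
#' @param incr incremental results from [incremental()], one row per
#'   subgroup.
#' @param weights subgroup weights; defaults to the `weight` column. Must
#'   sum to 1 (tolerance 1e-9).
#' @return one-row tibble with the same outcome columns, `sex` and
#'   `age_group` set to `"all"`.
#' @export
aggregate_subgroups <- function(incr, weights = NULL) {
  w <- if (is.null(weights)) incr$weight else weights
  if (abs(sum(w) - 1) > 1e-9) {
    abort(sprintf("subgroup weights sum to %.12f, not 1", sum(w)))
  }
  agg <- tibble(
    sex = "all", age_group = "all", weight = 1,
    d_life_years = sum(w * incr$d_life_years),
    d_qalys = sum(w * incr$d_qalys),
    d_lc_deaths = sum(w * incr$d_lc_deaths),
    d_cost_detection = sum(w * incr$d_cost_detection),
    d_cost_fp = sum(w * incr$d_cost_fp),
    d_cost_dxtx = sum(w * incr$d_cost_dxtx),
    d_cost_total = sum(w * incr$d_cost_total)
  )
  iq <- icer_of(agg$d_cost_total, agg$d_qalys)
  il <- icer_of(agg$d_cost_total, agg$d_life_years)
  id <- icer_of(agg$d_cost_total, -agg$d_lc_deaths)
  agg$icer_per_qaly <- iq$value
  agg$icer_per_ly <- il$value
  agg$cost_per_death_averted <- id$value
  agg$icer_label <- iq$label
  agg
}

#' Scale incremental results to a cohort of 10,000 screened
#'
#' Per-participant deltas times 10,000, rounded half away from zero for
#' reporting (internal values are never rounded). Deaths are reported as
#' deaths averted (sign flipped).
#'
#' @param incr incremental results (typically the aggregate row).
#' @param n cohort size (default 10,000).
#' @return tibble with `lc_deaths_averted`, `life_years_saved`,
#'   `qalys_gained` and the four cost columns, per `n` screened.
#' @export
scale_per_10k <- function(incr, n = 10000) {
  tibble(
    sex = incr$sex, age_group = incr$age_group,
    lc_deaths_averted = round_half_up(-incr$d_lc_deaths * n),
    life_years_saved = round_half_up(incr$d_life_years * n),
    qalys_gained = round_half_up(incr$d_qalys * n),
    cost_detection = round_half_up(incr$d_cost_detection * n),
    cost_fp = round_half_up(incr$d_cost_fp * n),
    cost_dxtx = round_half_up(incr$d_cost_dxtx * n),
    cost_total = round_half_up(incr$d_cost_total * n)
  )
}

#' Expected surgeries on false-positive benign nodules
#'
#' `n_screened` times the population-weighted LDCT false-positive
#' probability times the probability of surgery in a false positive, rounded
#' to the nearest integer for reporting.
#'
#' @param n_screened number of people screened.
#' @param params a validated `lcs_params`.
#' @param round round the count for reporting (default TRUE).
#' @return expected number of surgeries.
#' @export
fp_surgeries <- function(n_screened, params, round = TRUE) {
  x <- n_screened * weighted_fp_ldct(params) * params$screening$p_surgery_given_fp
  if (round) round_half_up(x) else x
}

#' Run the full deterministic analysis
#'
#' The base-case pipeline for one parameter set: calibrate the diagnosis
#' probabilities (optional), allocate both arms' baselines, run the Markov
#' engine per stratum and arm, form incremental results, aggregate across
#' subgroups with the registry weights, and attach the overdiagnosis and
#' false-positive surgery counts per 10,000 screened.
#'
#' @param params a validated `lcs_params`.
#' @param calibrate run [calibrate_params()] first (default TRUE).
#' @param ... passed to [calibrate_diagnosis_probs()].
#' @return an object of class `lcs_cea`: list with `params` (post
#'   calibration), `arms` (per-stratum arm results, both arms), `incremental`
#'   (per stratum), `aggregate` (one row, including `overdiagnosis_per_10k`
#'   and `fp_surgeries_per_10k`), and `calibration` (convergence record, if
#'   run). Use [tidy()] / [glance()] to extract tibbles.
#' @examples
#' \donttest{
#' fit <- run_cea(default_paramset())
#' glance(fit)
#' }
#' @export
run_cea <- function(params, calibrate = TRUE, ...) {
  if (calibrate) params <- calibrate_params(params, ...)
  scr <- run_arm(params, "screening")
  soc <- run_arm(params, "standard_care")
  incr <- incremental(scr, soc)
  agg <- aggregate_subgroups(incr)
  w_prev <- dplyr::left_join(params$strata, params$screening$prevalence,
    by = c("sex", "age_group")
  )
  od_frac <- overdiagnosis_fraction(params)
  agg$overdiagnosis_per_10k <-
    od_frac * sum(w_prev$weight * w_prev$prevalence) / sum(w_prev$weight) * 1e4
  agg$fp_surgeries_per_10k <- fp_surgeries(1e4, params, round = FALSE)
  structure(
    list(
      params = params,
      arms = dplyr::bind_rows(scr, soc),
      incremental = incr,
      aggregate = agg,
      calibration = attr(params, "calibration")
    ),
    class = "lcs_cea"
  )
}

#' @export
print.lcs_cea <- function(x, ...) {
  a <- x$aggregate
  cat("<lcs_cea> deterministic base-case result (per screening participant)\n")
  cat(sprintf(
    "  dLY %.4f  dQALY %.4f  dLCdeaths %.4f\n",
    a$d_life_years, a$d_qalys, a$d_lc_deaths
  ))
  cat(sprintf(
    "  dCost EUR %.0f (detection %.0f, FP %.0f, dx/tx %.0f)\n",
    a$d_cost_total, a$d_cost_detection, a$d_cost_fp, a$d_cost_dxtx
  ))
  icer <- if (a$icer_label == "ratio") sprintf("EUR %.0f/QALY", a$icer_per_qaly) else a$icer_label
  cat(sprintf("  ICER %s\n", icer))
  invisible(x)
}

#' Tidy a deterministic analysis
#'
#' @param x an `lcs_cea` object.
#' @param what `"incremental"` (default, per stratum), `"aggregate"` or
#'   `"arms"`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.lcs_cea <- function(x, what = c("incremental", "aggregate", "arms"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' @rdname tidy.lcs_cea
#' @return `glance()`: the one-row aggregate tibble.
#' @export
glance.lcs_cea <- function(x, ...) {
  x$aggregate
}
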