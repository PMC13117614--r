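#' Allocate the cohort across health states at model start
#'
#' Implements the decision tree that feeds the long-term Markov model. In the
#' screening arm, the stratum's screen-detectable prevalence enters the
#' diagnosed stages with the screening-arm stage distribution; everyone else
#' has no lung cancer, and a band-specific fraction of them experiences an
#' LDCT false positive (returned to the no-cancer state for the long-term
#' model, with a one-off cost and disutility). In the standard-care arm the
#' same prevalence mass enters the *undiagnosed* stages with the same stage
#' distribution (false negatives at screening are not modelled, so the two
#' arms start with identical cancer mass stage by stage); among the
#' cancer-free, the first-year check-up attendance fraction can experience an
#' X-ray false positive.
#'
#' @param params a validated `lcs_params`.
#' @param arm `"screening"` or `"standard_care"`.
#' @param strata optional subset of `params$strata` rows; defaults to all.
#' @return tibble with one row per stratum: identifiers (`sex`, `age_group`,
#'   `weight`, `start_age`, `arm`), occupancy (`no_lc`, `undiag_I` ...
#'   `undiag_IV`, `diag_I` ... `diag_IV`, proportions summing to 1),
#'   `fp_fraction`, one-off per-person costs (`cost_detection`, `cost_fp`)
#'   and `qaly_decrement`.
#' @examples
#' allocate_baseline(default_paramset(), "screening")
#' @export
allocate_baseline <- function(params, arm, strata = NULL) {
  arm <- match.arg(arm, ARMS)
  st <- if (is.null(strata)) params$strata else strata
  st <- dplyr::left_join(st, params$screening$prevalence,
    by = c("sex", "age_group")
  )
  scr <- params$screening
  co <- params$costs
  ut <- params$utilities

  p <- st$prevalence
  dist <- scr$stage_dist_screen # same at baseline in both arms
  cancer <- outer(p, dist) # strata x stages
  colnames(cancer) <- STAGES

  if (arm == "screening") {
    fp_prob <- unname(scr$p_fp_ldct[fp_band_of(st$start_age)])
    fp_fraction <- (1 - p) * fp_prob
    out <- tibble(
      sex = st$sex, age_group = st$age_group, weight = st$weight,
      start_age = st$start_age, arm = arm, prevalence = p,
      no_lc = 1 - p
    )
    for (s in STAGES) out[[paste0("undiag_", s)]] <- 0
    for (s in STAGES) out[[paste0("diag_", s)]] <- unname(cancer[, s])
    out$fp_fraction <- fp_fraction
    out$cost_detection <- co$c_detection_screen
    out$cost_fp <- fp_fraction * co$c_fp_ldct
    out$qaly_decrement <- ut$disutility_screen + ut$disutility_fp * fp_fraction
  } else {
    fp_fraction <- (1 - p) * scr$p_checkup_year1 * scr$p_fp_xray
    out <- tibble(
      sex = st$sex, age_group = st$age_group, weight = st$weight,
      start_age = st$start_age, arm = arm, prevalence = p,
      no_lc = 1 - p
    )
    for (s in STAGES) out[[paste0("undiag_", s)]] <- unname(cancer[, s])
    for (s in STAGES) out[[paste0("diag_", s)]] <- 0
    out$fp_fraction <- fp_fraction
    out$cost_detection <- scr$p_checkup_year1 * co$c_checkup_standard
    out$cost_fp <- fp_fraction * co$c_fp_xray
    out$qaly_decrement <- ut$disutility_fp * fp_fraction
  }
  out
}

#' One-off detection cost per person
#'
#' EUR per person at time zero: the full LDCT screening pathway (including
#' operating and administrative costs) in the screening arm; the check-up
#' cost times first-year attendance in the standard-care arm.
#'
#' @inheritParams allocate_baseline
#' @return scalar EUR per person.
#' @export
oneoff_detection_cost <- function(params, arm) {
  arm <- match.arg(arm, ARMS)
  if (arm == "screening") {
    params$costs$c_detection_screen
  } else {
    params$screening$p_checkup_year1 * params$costs$c_checkup_standard
  }
}

#' One-off false-positive cost and QALY decrement per person
#'
#' Both are incurred once at time zero, undiscounted: the false-positive
#' work-up cost for the arm's modality times the fraction experiencing a
#' false positive, and the anxiety disutilities (screening participation in
#' the screening arm; false-positive results in both arms).
#'
#' @inheritParams allocate_baseline
#' @return tibble per stratum with `fp_fraction`, `cost_fp` (EUR) and
#'   `qaly_decrement` (QALYs).
#' @export
oneoff_fp_cost_and_disutility <- function(params, arm, strata = NULL) {
  allocate_baseline(params, arm, strata) |>
    dplyr::select(
      "sex", "age_group", "weight", "fp_fraction",
      "cost_fp", "qaly_decrement"
    )
}
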