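#' Construct a model parameter set
#'
#' Bundles every quantity the screening model needs into a single validated
#' object: the sex/age strata with their population weights, screening-round
#' parameters (screen-detectable prevalence, stage distributions, false
#' positives), 3-month transition probabilities (stage progression, diagnosis,
#' lung-cancer death by stage and years since diagnosis, other-cause death by
#' sex and single year of age), utilities and disutilities, costs in 2023 EUR,
#' and economic settings (cycle length, discount rate, willingness-to-pay
#' threshold).
#'
#' All probabilities are stored on the 3-month cycle scale; use
#' [to_cycle_prob()] to convert annual values. Construction does not validate;
#' call [validate_params()] (all shipped generators return sets that validate
#' cleanly).
#'
#' @param strata tibble with columns `sex` ("male"/"female"), `age_group`
#'   (one of "55-59", "60-64", "65-69", "70-74", "75-79", "80"), `weight`
#'   (population proportions summing to 1) and optionally `start_age`
#'   (defaults to the band midpoint, 80 for the open band).
#' @param screening list with `prevalence` (tibble `sex`, `age_group`,
#'   `prevalence`), `overall_prevalence` (the weighted mean the per-stratum
#'   values must reproduce), `stage_dist_screen` and `stage_dist_standard`
#'   (named proportions over stages I-IV), `p_fp_ldct` (named per false
#'   positive band, `under65`/`65plus`), `p_fp_xray`, `p_checkup_year1`,
#'   `p_surgery_given_fp`.
#' @param transitions list with `p_progress_3m` (named I-III), `p_diagnose_3m`
#'   (named I-IV; I-III are calibration outputs, IV is fixed from its source),
#'   `p_lc_death_3m` (tibble `stage`, `year` 1-5, `sex`, `age_band`
#'   "55-69"/"70-84", `p`), `p_lc_death_3m_post5` (scalar, applied from year 6
#'   until death), `p_oc_death_3m` (tibble `sex`, `age`, `p`, single years of
#'   age up to `max_age`; death is certain at `max_age`), `max_age` (100).
#' @param utilities list with `u_no_lc` (tibble `sex`, `age_band`
#'   "55-64"/"65-74"/"75+", `u`), `u_lc_stageI` (reference stage-I utility),
#'   `ratios` (named II-IV, utility ratios vs stage I), `disutility_screen`,
#'   `disutility_fp` (one-off QALY decrements), `post5_equal_no_lc` (logical;
#'   when TRUE people beyond the fifth year since diagnosis take the no-cancer
#'   utility, used by the cure-after-year-5 scenario).
#' @param costs list with `c_detection_screen` (per screening participant),
#'   `c_checkup_standard` (per attended standard-care check-up; the
#'   standard-care year-1 detection cost per person is this times
#'   `p_checkup_year1`), `c_detection_standard_dx` (per newly diagnosed
#'   person in the standard care arm after the first year), `c_fp_ldct`,
#'   `c_fp_xray`, `c_dx_tx`
#'   (named I-IV, one-off diagnosis + treatment cost at entry into a
#'   diagnosed state). EUR, 2023 prices.
#' @param econ list with `cycle_length` (years, 0.25), `annual_discount_rate`,
#'   `wtp_threshold` (EUR/QALY), `half_cycle_correction` (logical),
#'   `max_age`.
#' @return an object of class `lcs_params`.
#' @seealso [validate_params()], [default_paramset()], [random_paramset()]
#' @export
lcs_params <- function(strata, screening, transitions, utilities, costs, econ) {
  if (!"start_age" %in% names(strata)) {
    strata$start_age <- unname(AGE_GROUP_START[as.character(strata$age_group)])
  }
  structure(
    list(
      strata = as_tibble(strata), screening = screening,
      transitions = transitions, utilities = utilities,
      costs = costs, econ = econ
    ),
    class = "lcs_params"
  )
}

#' @export
print.lcs_params <- function(x, ...) {
  cat("<lcs_params>\n")
  cat(sprintf(
    "  %d strata; overall screen-detectable prevalence %.4f\n",
    nrow(x$strata), weighted_prevalence(x)
  ))
  cat(sprintf(
    "  cycle %.2fy, discount %.1f%%, WTP EUR %s, max age %d\n",
    x$econ$cycle_length, 100 * x$econ$annual_discount_rate,
    format(x$econ$wtp_threshold, big.mark = ","), x$econ$max_age
  ))
  nviol <- nrow(validate_params(x))
  cat(sprintf("  validation: %s\n", if (nviol == 0) "clean" else paste(nviol, "violation(s)")))
  invisible(x)
}

#' Population-weighted screen-detectable prevalence
#'
#' @param params an `lcs_params` object.
#' @return scalar weighted mean of per-stratum prevalence.
#' @export
weighted_prevalence <- function(params) {
  st <- dplyr::left_join(params$strata, params$screening$prevalence,
    by = c("sex", "age_group")
  )
  sum(st$weight * st$prevalence) / sum(st$weight)
}

#' Population-weighted LDCT false-positive probability
#'
#' Weights the band-specific false-positive probabilities by the stratum
#' weights, mapping each stratum's starting age to its band (<65 / >=65).
#'
#' @param params an `lcs_params` object.
#' @return scalar weighted mean probability.
#' @export
weighted_fp_ldct <- function(params) {
  band <- fp_band_of(params$strata$start_age)
  sum(params$strata$weight * params$screening$p_fp_ldct[band]) /
    sum(params$strata$weight)
}

# Stage utility for a diagnosed stage in a given sex/age band. Stage
# utilities scale with the no-cancer utility of the same sex/age band so the
# published age decline carries into the cancer states:
#   u_lc(s, sex, band) = u_lc_stageI * ratio_s * u_no_lc(sex, band) / max(u_no_lc)
u_lc_value <- function(params, stage, sex, age_band) {
  u <- params$utilities
  ratio <- c(I = 1, u$ratios)[stage]
  tab <- u$u_no_lc
  u_ref <- max(tab$u)
  u_no <- tab$u[match(
    paste(sex, age_band),
    paste(tab$sex, tab$age_band)
  )]
  unname(u$u_lc_stageI * ratio * u_no / u_ref)
}

SUM_TOL <- 1e-9

#' Validate a parameter set
#'
#' Checks every structural and numeric invariant of the model configuration:
#' required fields present, stratum weights and stage distributions summing
#' to one (tolerance 1e-9), all probabilities and utilities in \[0, 1\],
#' per-stratum prevalence reproducing the configured overall prevalence
#' (tolerance 1e-6), certain death at the age cap, stage utilities not
#' exceeding the no-cancer utility of the same sex/age band, non-negative
#' disutilities and costs, and positive cycle length.
#'
#' @param params an `lcs_params` object.
#' @return tibble with columns `path` (location of the offending field) and
#'   `message`; zero rows when the set is valid.
#' @examples
#' validate_params(default_paramset()) # 0 rows
#' @export
validate_params <- function(params) {
  viol <- list()
  bad <- function(path, message) {
    viol[[length(viol) + 1]] <<- tibble(path = path, message = message)
  }

  required <- list(
    strata = c("sex", "age_group", "weight"),
    screening = c(
      "prevalence", "overall_prevalence", "stage_dist_screen",
      "stage_dist_standard", "p_fp_ldct", "p_fp_xray",
      "p_checkup_year1", "p_surgery_given_fp"
    ),
    transitions = c(
      "p_progress_3m", "p_diagnose_3m", "p_lc_death_3m",
      "p_lc_death_3m_post5", "p_oc_death_3m", "max_age"
    ),
    utilities = c(
      "u_no_lc", "u_lc_stageI", "ratios",
      "disutility_screen", "disutility_fp"
    ),
    costs = c(
      "c_detection_screen", "c_checkup_standard",
      "c_detection_standard_dx", "c_fp_ldct", "c_fp_xray", "c_dx_tx"
    ),
    econ = c("cycle_length", "annual_discount_rate", "wtp_threshold", "max_age")
  )
  structural_ok <- TRUE
  for (block in names(required)) {
    if (is.null(params[[block]])) {
      bad(block, "required section missing")
      structural_ok <- FALSE
      next
    }
    missing <- setdiff(required[[block]], names(params[[block]]))
    for (f in missing) {
      bad(paste(block, f, sep = "$"), "required field missing")
      structural_ok <- FALSE
    }
  }
  if (!structural_ok) {
    return(dplyr::bind_rows(viol))
  }

  st <- params$strata
  if (abs(sum(st$weight) - 1) > SUM_TOL) {
    bad("strata$weight", sprintf("weights sum to %.12f, not 1", sum(st$weight)))
  }
  if (!all(st$sex %in% SEXES)) bad("strata$sex", "sex must be male/female")
  if (!all(as.character(st$age_group) %in% AGE_GROUPS)) {
    bad("strata$age_group", "age groups must be the six model bands")
  }
  if (anyDuplicated(paste(st$sex, st$age_group))) {
    bad("strata", "duplicate sex x age_group stratum")
  }

  scr <- params$screening
  prob_in_01 <- function(x, path) {
    x <- unlist(x)
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      bad(path, "probability outside [0, 1]")
    }
  }
  prob_in_01(scr$prevalence$prevalence, "screening$prevalence")
  prob_in_01(scr$p_fp_ldct, "screening$p_fp_ldct")
  prob_in_01(scr$p_fp_xray, "screening$p_fp_xray")
  prob_in_01(scr$p_checkup_year1, "screening$p_checkup_year1")
  prob_in_01(scr$p_surgery_given_fp, "screening$p_surgery_given_fp")
  for (nm in c("stage_dist_screen", "stage_dist_standard")) {
    d <- scr[[nm]]
    path <- paste0("screening$", nm)
    if (length(d) != 4 || any(d < 0) || any(d > 1)) {
      bad(path, "stage proportions must be 4 values in [0, 1]")
    } else if (abs(sum(d) - 1) > SUM_TOL) {
      bad(path, sprintf("stage proportions sum to %.12f, not 1", sum(d)))
    }
  }
  miss <- dplyr::anti_join(st, scr$prevalence, by = c("sex", "age_group"))
  if (nrow(miss) > 0) {
    bad("screening$prevalence", "prevalence missing for some strata")
  } else {
    wp <- weighted_prevalence(params)
    if (abs(wp - scr$overall_prevalence) > 1e-6) {
      bad(
        "screening$prevalence",
        sprintf(
          "weighted prevalence %.8f != overall_prevalence %.8f",
          wp, scr$overall_prevalence
        )
      )
    }
  }

  tr <- params$transitions
  prob_in_01(tr$p_progress_3m, "transitions$p_progress_3m")
  prob_in_01(tr$p_diagnose_3m, "transitions$p_diagnose_3m")
  prob_in_01(tr$p_lc_death_3m$p, "transitions$p_lc_death_3m")
  prob_in_01(tr$p_lc_death_3m_post5, "transitions$p_lc_death_3m_post5")
  prob_in_01(tr$p_oc_death_3m$p, "transitions$p_oc_death_3m")
  oc_cap <- tr$p_oc_death_3m$p[tr$p_oc_death_3m$age >= tr$max_age]
  if (length(oc_cap) == 0 || any(oc_cap < 1)) {
    bad(
      "transitions$p_oc_death_3m",
      sprintf("death must be certain at age %d", tr$max_age)
    )
  }
  need_lc <- expand.grid(
    stage = STAGES, year = 1:5, sex = SEXES,
    age_band = MORTALITY_BANDS, stringsAsFactors = FALSE
  )
  have <- paste(tr$p_lc_death_3m$stage, tr$p_lc_death_3m$year,
    tr$p_lc_death_3m$sex, tr$p_lc_death_3m$age_band,
    sep = "|"
  )
  if (!all(paste(need_lc$stage, need_lc$year, need_lc$sex, need_lc$age_band,
    sep = "|"
  ) %in% have)) {
    bad(
      "transitions$p_lc_death_3m",
      "table must cover stage x year 1-5 x sex x age band"
    )
  }

  ut <- params$utilities
  prob_in_01(ut$u_no_lc$u, "utilities$u_no_lc")
  prob_in_01(ut$u_lc_stageI, "utilities$u_lc_stageI")
  if (any(ut$ratios <= 0) || any(ut$ratios > 1)) {
    bad("utilities$ratios", "stage utility ratios must be in (0, 1]")
  }
  if (ut$disutility_screen < 0 || ut$disutility_fp < 0) {
    bad("utilities$disutility_screen", "disutilities must be >= 0")
  }
  for (i in seq_len(nrow(ut$u_no_lc))) {
    row <- ut$u_no_lc[i, ]
    for (s in STAGES) {
      if (u_lc_value(params, s, row$sex, row$age_band) > row$u + SUM_TOL) {
        bad(
          "utilities$u_lc_stageI",
          sprintf(
            "stage %s utility exceeds no-cancer utility for %s %s",
            s, row$sex, row$age_band
          )
        )
      }
    }
  }

  co <- params$costs
  # ordering of c_dx_tx across stages is configuration data, not enforced
  cost_vals <- unlist(co[required$costs])
  if (any(!is.finite(cost_vals)) || any(cost_vals < 0)) {
    bad("costs", "costs must be finite and >= 0")
  }

  ec <- params$econ
  if (!is.numeric(ec$cycle_length) || ec$cycle_length <= 0) {
    bad("econ$cycle_length", "cycle length must be > 0")
  }
  if (ec$annual_discount_rate < 0) {
    bad("econ$annual_discount_rate", "discount rate must be >= 0")
  }

  out <- dplyr::bind_rows(viol)
  if (nrow(out) == 0) {
    tibble(path = character(), message = character())
  } else {
    out
  }
}

#' Convert an annual probability to a per-cycle probability
#'
#' Uses the constant-rate transformation `1 - (1 - p)^(1/n)`, the standard
#' conversion in state-transition cost-effectiveness models; sources report
#' annual quantities while the model runs 3-month cycles.
#'
#' @param p_annual annual probability (vectorised), in \[0, 1\].
#' @param cycles_per_year number of cycles per year (>= 1); 4 for 3-month
#'   cycles.
#' @return per-cycle probability of the same length.
#' @examples
#' to_cycle_prob(0.1, 4) # 0.02600341...
#' @export
to_cycle_prob <- function(p_annual, cycles_per_year) {
  if (any(!is.finite(p_annual)) || any(p_annual < 0) || any(p_annual > 1)) {
    abort("`p_annual` must be in [0, 1].")
  }
  if (cycles_per_year < 1) abort("`cycles_per_year` must be >= 1.")
  1 - (1 - p_annual)^(1 / cycles_per_year)
}

#' @rdname to_cycle_prob
#' @param p_cycle per-cycle probability, in \[0, 1\].
#' @export
from_cycle_prob <- function(p_cycle, cycles_per_year) {
  if (any(!is.finite(p_cycle)) || any(p_cycle < 0) || any(p_cycle > 1)) {
    abort("`p_cycle` must be in [0, 1].")
  }
  1 - (1 - p_cycle)^cycles_per_year
}

#' Replace the calibrated diagnosis probabilities in a parameter set
#'
#' @param params an `lcs_params` object.
#' @param p_diag named (I-III, optionally IV) 3-month diagnosis
#'   probabilities; unnamed vectors of length 3 are taken as stages I-III.
#' @return the updated `lcs_params`.
#' @export
set_diagnosis_probs <- function(params, p_diag) {
  if (is.null(names(p_diag))) {
    names(p_diag) <- STAGES[seq_along(p_diag)]
  }
  params$transitions$p_diagnose_3m[names(p_diag)] <- p_diag
  params
}
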