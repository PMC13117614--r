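# Configurable small parameter sets for unit tests. Defaults give a single
# male 55-59 stratum with flat (age-constant) other-cause mortality and
# stage-constant lung-cancer mortality so expected values can be computed by
# hand; every piece can be overridden.
test_params <- function(sexes = "male",
                        age_groups = "55-59",
                        weights = NULL,
                        prevalence = 0.0253,
                        stage_screen = c(0.6, 0.1, 0.1, 0.2),
                        stage_standard = c(0.15, 0.10, 0.27, 0.48),
                        p_fp_ldct = c(under65 = 0.15625, `65plus` = 0.1875),
                        p_fp_xray = 0.086,
                        p_checkup = 0.10,
                        p_surgery_fp = 0.008,
                        p_progress = c(0.12, 0.18, 0.22),
                        p_diag = c(0.08, 0.15, 0.30, 0.50),
                        lc_death_3m = c(I = 0.026, II = 0.054, III = 0.12, IV = 0.29),
                        lc_year_decline = 0.85, # multiplier per year since dx
                        lc_post5 = 0.0076,
                        oc_death_3m = 0.005, # constant across ages below the cap
                        u_no = c(male = 0.82, female = 0.79),
                        u_band_decline = c(1, 0.95, 0.88),
                        u_lcI = 0.75,
                        ratios = c(II = 0.95, III = 0.87, IV = 0.75),
                        dis_screen = 0,
                        dis_fp = 0,
                        c_screen = 179,
                        c_checkup = 140,
                        c_dx_detect = 140,
                        c_fp_ldct = 380,
                        c_fp_xray = 90,
                        c_dxtx = c(I = 11000, II = 10000, III = 20000, IV = 27000),
                        discount = 0.03,
                        hcc = TRUE,
                        max_age = 100L) {
  strata <- tidyr::expand_grid(sex = sexes, age_group = age_groups)
  strata$weight <- if (is.null(weights)) rep(1 / nrow(strata), nrow(strata)) else weights

  prev_tab <- tidyr::expand_grid(sex = sexes, age_group = age_groups)
  prev_tab$prevalence <- prevalence

  lc_tab <- tidyr::expand_grid(
    stage = c("I", "II", "III", "IV"), year = 1:5,
    sex = c("male", "female"), age_band = c("55-69", "70-84")
  )
  lc_tab$p <- unname(pmin(1, lc_death_3m[lc_tab$stage] * lc_year_decline^(lc_tab$year - 1)))

  ages <- 55:max_age
  oc_tab <- dplyr::bind_rows(
    tibble::tibble(sex = "male", age = ages, p = oc_death_3m),
    tibble::tibble(sex = "female", age = ages, p = oc_death_3m)
  )
  oc_tab$p[oc_tab$age >= max_age] <- 1

  u_tab <- dplyr::bind_rows(
    tibble::tibble(
      sex = "male", age_band = c("55-64", "65-74", "75+"),
      u = u_no[["male"]] * u_band_decline
    ),
    tibble::tibble(
      sex = "female", age_band = c("55-64", "65-74", "75+"),
      u = u_no[["female"]] * u_band_decline
    )
  )

  p <- lcs_params(
    strata = strata,
    screening = list(
      prevalence = prev_tab,
      overall_prevalence = sum(strata$weight * prev_tab$prevalence[
        match(
          paste(strata$sex, strata$age_group),
          paste(prev_tab$sex, prev_tab$age_group)
        )
      ]),
      stage_dist_screen = stats::setNames(stage_screen, c("I", "II", "III", "IV")),
      stage_dist_standard = stats::setNames(stage_standard, c("I", "II", "III", "IV")),
      p_fp_ldct = p_fp_ldct,
      p_fp_xray = p_fp_xray,
      p_checkup_year1 = p_checkup,
      p_surgery_given_fp = p_surgery_fp
    ),
    transitions = list(
      p_progress_3m = stats::setNames(p_progress, c("I", "II", "III")),
      p_diagnose_3m = stats::setNames(p_diag, c("I", "II", "III", "IV")),
      p_lc_death_3m = lc_tab,
      p_lc_death_3m_post5 = lc_post5,
      p_oc_death_3m = oc_tab,
      max_age = max_age
    ),
    utilities = list(
      u_no_lc = u_tab,
      u_lc_stageI = u_lcI,
      ratios = ratios,
      disutility_screen = dis_screen,
      disutility_fp = dis_fp,
      post5_equal_no_lc = FALSE
    ),
    costs = list(
      c_detection_screen = c_screen,
      c_checkup_standard = c_checkup,
      c_detection_standard_dx = c_dx_detect,
      c_fp_ldct = c_fp_ldct,
      c_fp_xray = c_fp_xray,
      c_dx_tx = c_dxtx
    ),
    econ = list(
      cycle_length = 0.25,
      annual_discount_rate = discount,
      wtp_threshold = 25000,
      half_cycle_correction = hcc,
      max_age = max_age
    )
  )
  stopifnot(nrow(validate_params(p)) == 0)
  p
}

# Per-cycle occupancy sums from a traced run; used for conservation checks.
trace_cycle_sums <- function(arm_result) {
  tr <- attr(arm_result, "trace")
  stopifnot(!is.null(tr))
  dplyr::summarise(tr, total = sum(occupancy), .by = c("cycle", "stratum"))
}
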