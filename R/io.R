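## Parameter file IO.
##
## Parameter sets round-trip through YAML (JSON accepted on load by file
## extension). Probabilities are written on the 3-month cycle scale; a file
## may instead declare `probability_scale: annual` and have every transition
## probability converted with the constant-rate formula on load. Currency is
## a label only (EUR, 2023 prices).

PARAM_FILE_SECTIONS <- c(
  "strata", "screening", "transitions", "utilities", "costs", "econ"
)

#' Save a parameter set to YAML
#'
#' Writes the full parameter set with a header marking the values as
#' synthetic stand-ins. The file round-trips through [load_params()] to a
#' set equal in value to the original (YAML numbers are written with 15
#' digits of precision; JSON at full precision).
#'
#' @param params a validated `lcs_params`.
#' @param path output file path (`.yaml`/`.yml`, or `.json` for JSON).
#' @return `path`, invisibly.
#' @export
save_params <- function(params, path) {
  obj <- list(
    currency = "EUR 2023",
    probability_scale = "cycle",
    strata = purrr::transpose(as.list(params$strata)),
    screening = list(
      prevalence = purrr::transpose(as.list(params$screening$prevalence)),
      overall_prevalence = params$screening$overall_prevalence,
      stage_dist_screen = as.list(params$screening$stage_dist_screen),
      stage_dist_standard = as.list(params$screening$stage_dist_standard),
      p_fp_ldct = as.list(params$screening$p_fp_ldct),
      p_fp_xray = params$screening$p_fp_xray,
      p_checkup_year1 = params$screening$p_checkup_year1,
      p_surgery_given_fp = params$screening$p_surgery_given_fp
    ),
    transitions = list(
      p_progress_3m = as.list(params$transitions$p_progress_3m),
      p_diagnose_3m = as.list(params$transitions$p_diagnose_3m),
      p_lc_death_3m = purrr::transpose(as.list(params$transitions$p_lc_death_3m)),
      p_lc_death_3m_post5 = params$transitions$p_lc_death_3m_post5,
      p_oc_death_3m = purrr::transpose(as.list(params$transitions$p_oc_death_3m)),
      max_age = params$transitions$max_age
    ),
    utilities = list(
      u_no_lc = purrr::transpose(as.list(params$utilities$u_no_lc)),
      u_lc_stageI = params$utilities$u_lc_stageI,
      ratios = as.list(params$utilities$ratios),
      disutility_screen = params$utilities$disutility_screen,
      disutility_fp = params$utilities$disutility_fp,
      post5_equal_no_lc = isTRUE(params$utilities$post5_equal_no_lc)
    ),
    costs = list(
      c_detection_screen = params$costs$c_detection_screen,
      c_checkup_standard = params$costs$c_checkup_standard,
      c_detection_standard_dx = params$costs$c_detection_standard_dx,
      c_fp_ldct = params$costs$c_fp_ldct,
      c_fp_xray = params$costs$c_fp_xray,
      c_dx_tx = as.list(params$costs$c_dx_tx)
    ),
    econ = params$econ
  )
  header <- c(
    "# lcscea parameter set",
    "# Values are synthetic stand-ins calibrated to published aggregates,",
    "# not the original study's unpublished appendix tables.",
    "# Probabilities are on the 3-month cycle scale unless",
    "# probability_scale: annual is declared."
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(
      c(header, yaml::as.yaml(obj, precision = 15L)),
      path
    )
  }
  invisible(path)
}

# rebuild a tibble from a transposed row list
rows_to_tibble <- function(rows, numeric_cols) {
  out <- purrr::map_dfr(rows, as_tibble)
  for (cn in intersect(numeric_cols, names(out))) {
    out[[cn]] <- as.numeric(out[[cn]])
  }
  out
}

#' Load a parameter set from YAML or JSON
#'
#' Reads a file written by [save_params()] (or hand-edited in the same
#' schema). A missing required section is a parse error naming the section;
#' unknown top-level keys are kept out of the parameter set with a warning.
#' If the file declares `probability_scale: annual`, every transition
#' probability is converted to the 3-month scale with [to_cycle_prob()]
#' (certain death at the age cap stays certain).
#'
#' @param path file path (`.yaml`/`.yml`/`.json`).
#' @param validate validate the loaded set and error on violations
#'   (default TRUE).
#' @return a `lcs_params` object.
#' @export
load_params <- function(path, validate = TRUE) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  missing <- setdiff(PARAM_FILE_SECTIONS, names(obj))
  if (length(missing) > 0) {
    abort(sprintf(
      "parameter file is missing required section(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  known <- c(PARAM_FILE_SECTIONS, "currency", "probability_scale")
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0) {
    warn(sprintf(
      "ignoring unknown key(s) in parameter file: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  scale <- obj$probability_scale %||% "cycle"
  if (!scale %in% c("cycle", "annual")) {
    abort("probability_scale must be 'cycle' or 'annual'")
  }

  num <- function(x) setNames(as.numeric(unlist(x)), names(x))
  scr <- obj$screening
  tr <- obj$transitions
  ut <- obj$utilities
  co <- obj$costs
  ec <- obj$econ

  params <- lcs_params(
    strata = rows_to_tibble(obj$strata, c("weight", "start_age")),
    screening = list(
      prevalence = rows_to_tibble(scr$prevalence, "prevalence"),
      overall_prevalence = as.numeric(scr$overall_prevalence),
      stage_dist_screen = num(scr$stage_dist_screen)[STAGES],
      stage_dist_standard = num(scr$stage_dist_standard)[STAGES],
      p_fp_ldct = num(scr$p_fp_ldct)[FP_BANDS],
      p_fp_xray = as.numeric(scr$p_fp_xray),
      p_checkup_year1 = as.numeric(scr$p_checkup_year1),
      p_surgery_given_fp = as.numeric(scr$p_surgery_given_fp)
    ),
    transitions = list(
      p_progress_3m = num(tr$p_progress_3m)[c("I", "II", "III")],
      p_diagnose_3m = num(tr$p_diagnose_3m)[STAGES],
      p_lc_death_3m = rows_to_tibble(tr$p_lc_death_3m, c("year", "p")),
      p_lc_death_3m_post5 = as.numeric(tr$p_lc_death_3m_post5),
      p_oc_death_3m = rows_to_tibble(tr$p_oc_death_3m, c("age", "p")),
      max_age = as.integer(tr$max_age)
    ),
    utilities = list(
      u_no_lc = rows_to_tibble(ut$u_no_lc, "u"),
      u_lc_stageI = as.numeric(ut$u_lc_stageI),
      ratios = num(ut$ratios)[c("II", "III", "IV")],
      disutility_screen = as.numeric(ut$disutility_screen),
      disutility_fp = as.numeric(ut$disutility_fp),
      post5_equal_no_lc = isTRUE(ut$post5_equal_no_lc)
    ),
    costs = list(
      c_detection_screen = as.numeric(co$c_detection_screen),
      c_checkup_standard = as.numeric(co$c_checkup_standard),
      c_detection_standard_dx = as.numeric(co$c_detection_standard_dx),
      c_fp_ldct = as.numeric(co$c_fp_ldct),
      c_fp_xray = as.numeric(co$c_fp_xray),
      c_dx_tx = num(co$c_dx_tx)[STAGES]
    ),
    econ = list(
      cycle_length = as.numeric(ec$cycle_length),
      annual_discount_rate = as.numeric(ec$annual_discount_rate),
      wtp_threshold = as.numeric(ec$wtp_threshold),
      half_cycle_correction = isTRUE(ec$half_cycle_correction),
      max_age = as.integer(ec$max_age)
    )
  )

  if (scale == "annual") {
    n <- round(1 / params$econ$cycle_length)
    tr <- params$transitions
    tr$p_progress_3m <- to_cycle_prob(tr$p_progress_3m, n)
    tr$p_diagnose_3m <- to_cycle_prob(tr$p_diagnose_3m, n)
    tr$p_lc_death_3m$p <- to_cycle_prob(tr$p_lc_death_3m$p, n)
    tr$p_lc_death_3m_post5 <- to_cycle_prob(tr$p_lc_death_3m_post5, n)
    tr$p_oc_death_3m$p <- to_cycle_prob(tr$p_oc_death_3m$p, n)
    tr$p_oc_death_3m$p[tr$p_oc_death_3m$age >= tr$max_age] <- 1
    params$transitions <- tr
  }

  if (validate) {
    bad <- validate_params(params)
    if (nrow(bad) > 0) {
      abort(paste(
        "parameter file fails validation:",
        paste(bad$path, bad$message, sep = ": ", collapse = "; ")
      ))
    }
  }
  params
}
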