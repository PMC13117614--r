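## End-to-end analysis runner and CSV report writers.
##
## Every emitted CSV carries '#'-prefixed header lines recording the seed
## and a hash of the run configuration, so outputs are traceable to the run
## that produced them; the files re-parse with `readr::read_csv(comment =
## "#")`. Internal values are written unrounded; "report" variants mirror
## printed precision (costs to whole EUR, effects to 4 decimals).

# Small FNV-1a hash over a serialised object (configuration fingerprinting
# for output headers; no cryptographic intent).
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_report_csv <- function(df, path, seed, hash, round_spec = NULL) {
  if (!is.null(round_spec)) {
    for (cn in intersect(names(round_spec), names(df))) {
      df[[cn]] <- round_half_up(df[[cn]], round_spec[[cn]])
    }
  }
  writeLines(
    c(
      sprintf("# lcscea %s", utils::packageVersion("lcscea")),
      sprintf("# seed: %s", seed),
      sprintf("# config: %s", hash)
    ),
    path
  )
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full analysis and write all report files
#'
#' Executes the whole pipeline on one parameter set: calibration,
#' deterministic base case, base-case PSA, scenario analyses (PSA each,
#' common random numbers), and writes the result tables and curve data as
#' CSV into `out_dir`:
#'
#' * `table1_psa_summary.csv` — PSA means and 95% credible intervals per
#'   outcome, weighted across all subgroups (per participant).
#' * `table1_per_10k.csv` — the headline outcomes scaled to 10,000 screened.
#' * `table2_subgroups.csv` — PSA mean incremental results by sex and age
#'   subgroup, ICERs as ratios of means.
#' * `table3_scenarios.csv` — mean incremental results per scenario.
#' * `ce_plane.csv` — per-iteration incremental QALYs and costs.
#' * `ceac.csv` — probability cost-effective per threshold.
#' * `counts_per_10k.csv` — overdiagnosis and false-positive surgeries.
#' * `params_calibrated.yaml` — the calibrated parameter set used.
#'
#' @param params a validated `lcs_params` (default: the synthetic default
#'   set).
#' @param out_dir output directory (created if missing).
#' @param seed master seed for all sampling.
#' @param n_iter PSA iterations (default 2000).
#' @param spec a [dist_spec()].
#' @param ids scenarios to run (default all).
#' @param cohort_size cohort for the per-10k scaling (default 10,000).
#' @param report_rounding round the report CSVs to printed precision
#'   (costs to whole EUR, effects to 4 decimals); curve data are always
#'   unrounded.
#' @param verbose log progress to stderr.
#' @param ... passed to [run_psa()].
#' @return invisibly, a list with `cea`, `psa`, `scenarios`, `per_10k` and
#'   `files` (paths written).
#' @export
run_full_analysis <- function(params = default_paramset(),
                              out_dir,
                              seed = 1L,
                              n_iter = 2000L,
                              spec = dist_spec(),
                              ids = scenario_ids(),
                              cohort_size = 10000,
                              report_rounding = TRUE,
                              verbose = TRUE,
                              ...) {
  if (n_iter < 1) abort("`n_iter` must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) {
    if (verbose) message(sprintf(paste0("[lcscea] ", fmt), ...))
  }
  t0 <- Sys.time()
  hash <- config_hash(list(params = params, seed = seed, n_iter = n_iter, spec = spec, ids = ids))

  say("calibrating diagnosis probabilities")
  params <- calibrate_params(params)
  rec <- attr(params, "calibration")
  say(
    "calibration: %s after %d iterations (max dev %.2g)",
    if (rec$converged) "converged" else "NOT converged", rec$iterations, rec$max_dev
  )

  say("deterministic base case")
  cea <- run_cea(params, calibrate = FALSE)

  say("base-case PSA: %d iterations, seed %d", n_iter, seed)
  psa <- run_psa(params, spec = spec, n_iter = n_iter, seed = seed, ...)
  if (psa$n_excluded > 0) {
    say("excluded %d iteration(s) with failed calibration", psa$n_excluded)
  }

  say("scenario analyses: %s", paste(ids, collapse = ", "))
  scen <- run_scenarios(params,
    ids = ids, psa = TRUE, spec = spec,
    n_iter = n_iter, seed = seed, ...
  )

  per10k_base <- dplyr::bind_cols(
    scale_per_10k(cea$aggregate, cohort_size),
    tibble(
      overdiagnosis = round_half_up(
        cea$aggregate$overdiagnosis_per_10k * cohort_size / 1e4
      ),
      fp_surgeries = fp_surgeries(cohort_size, params)
    )
  )
  psa_means <- tidy(psa, "summary")
  per10k_psa <- psa_means |>
    dplyr::filter(startsWith(.data$outcome, "d_")) |>
    dplyr::mutate(dplyr::across(
      c("mean", "ci_lower", "ci_upper"),
      ~ round_half_up(.x * cohort_size *
        ifelse(.data$outcome == "d_lc_deaths", -1, 1))
    )) |>
    dplyr::mutate(outcome = sub(
      "^d_lc_deaths$", "lc_deaths_averted",
      sub("^d_", "per10k_", .data$outcome)
    ))

  eff4 <- c(
    d_life_years = 4, d_qalys = 4, d_lc_deaths = 4,
    mean = 4, ci_lower = 4, ci_upper = 4
  )
  cost0 <- c(
    d_cost_detection = 0, d_cost_fp = 0, d_cost_dxtx = 0,
    d_cost_total = 0, icer_per_qaly = 0, icer_per_ly = 0,
    cost_per_death_averted = 0
  )
  files <- c(
    table1_psa_summary = write_report_csv(
      dplyr::mutate(
        psa_means,
        dplyr::across(
          c("mean", "ci_lower", "ci_upper"),
          ~ ifelse(startsWith(psa_means$outcome, "d_cost") |
            grepl("icer|death_averted", psa_means$outcome),
          round_half_up(.x, if (report_rounding) 0 else 9),
          round_half_up(.x, if (report_rounding) 4 else 9)
          )
        )
      ),
      file.path(out_dir, "table1_psa_summary.csv"), seed, hash
    ),
    table1_per_10k = write_report_csv(
      per10k_psa, file.path(out_dir, "table1_per_10k.csv"), seed, hash
    ),
    table2_subgroups = write_report_csv(
      tidy(psa, "subgroup"), file.path(out_dir, "table2_subgroups.csv"),
      seed, hash,
      round_spec = if (report_rounding) as.list(c(eff4, cost0)) else NULL
    ),
    table3_scenarios = write_report_csv(
      scen, file.path(out_dir, "table3_scenarios.csv"), seed, hash,
      round_spec = if (report_rounding) as.list(c(eff4, cost0)) else NULL
    ),
    ce_plane = write_report_csv(
      dplyr::select(
        tidy(psa, "iterations"),
        "iteration", "d_qalys", "d_cost_total"
      ),
      file.path(out_dir, "ce_plane.csv"), seed, hash
    ),
    ceac = write_report_csv(
      tidy(psa, "ceac"), file.path(out_dir, "ceac.csv"), seed, hash
    ),
    counts_per_10k = write_report_csv(
      per10k_base, file.path(out_dir, "counts_per_10k.csv"), seed, hash
    )
  )
  params_path <- file.path(out_dir, "params_calibrated.yaml")
  save_params(params, params_path)
  files <- c(files, params_calibrated = params_path)

  say(
    "done in %.1f s; %d files in %s",
    as.numeric(difftime(Sys.time(), t0, units = "secs")),
    length(files), out_dir
  )
  invisible(list(
    cea = cea, psa = psa, scenarios = scen,
    per_10k = per10k_base, files = files
  ))
}
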