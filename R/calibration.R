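## Calibration of the 3-month diagnosis probabilities.
##
## The standard-care arm starts with undiagnosed cancer distributed like the
## screen-detected stage distribution; progression then shifts diagnoses to
## later stages. The diagnosis probabilities for undiagnosed stages I-III are
## free parameters found by iterative calculation so that the distribution of
## stage at diagnosis reproduces the observed standard-care distribution
## (stage IV's diagnosis probability is fixed from its source). Undiagnosed
## people die only from other causes; event order matches the main engine
## (other-cause death, then diagnosis, then progression).

# Run the undiagnosed sub-chain for all strata simultaneously.
# Returns diagnosed mass by stage (4 x S), other-cause deaths before
# diagnosis (S) and residual undiagnosed mass (S). Each stratum starts with
# mass 1 spread over the screen-detected stage distribution (other-cause
# mortality acts equally on all stages, so the within-stratum stage
# distribution is invariant to the starting mass).
undx_subchain <- function(params, diag_probs = NULL, strata = NULL,
                          ctx = NULL, tol_mass = 1e-10) {
  st <- if (is.null(strata)) params$strata else strata
  if (is.null(ctx)) ctx <- build_context(params, st)
  p_diag <- ctx$p_diag
  if (!is.null(diag_probs)) {
    if (is.null(names(diag_probs))) {
      names(diag_probs) <- STAGES[seq_along(diag_probs)]
    }
    p_diag[match(names(diag_probs), STAGES)] <- diag_probs
  }
  S <- ctx$S
  U <- matrix(params$screening$stage_dist_screen, 4, S)
  diag_cum <- matrix(0, 4, S)
  dead <- numeric(S)
  t <- 1L
  while (any(colSums(U) > tol_mass)) {
    if (t > ctx$n_cycles) break # age cap guard; p_oc = 1 there anyway
    p_oc <- ctx$P_oc[t, ]
    dead <- dead + colSums(U) * p_oc
    U <- U * rep(1 - p_oc, each = 4)
    newdx <- U * p_diag
    diag_cum <- diag_cum + newdx
    U <- U - newdx
    prog <- U[1:3, , drop = FALSE] * ctx$p_prog
    U[2:4, ] <- U[2:4, , drop = FALSE] + prog
    U[1:3, ] <- U[1:3, , drop = FALSE] - prog
    t <- t + 1L
  }
  list(diag_by_stage = diag_cum, dead_before_dx = dead, residual = colSums(U))
}

# Population weights for pooling stage-at-diagnosis distributions: stratum
# weight times screen-detectable prevalence (the undiagnosed mass each
# stratum contributes).
pool_weights <- function(params, strata) {
  st <- dplyr::left_join(strata, params$screening$prevalence,
    by = c("sex", "age_group")
  )
  w <- st$weight * st$prevalence
  if (sum(w) <= 0) st$weight else w
}

#' Simulate the stage distribution at diagnosis under standard care
#'
#' Runs the undiagnosed sub-chain (stage progression, diagnosis, other-cause
#' death; no lung-cancer death before diagnosis) from the baseline
#' undiagnosed stage distribution until the undiagnosed mass is exhausted,
#' and returns the stage distribution among everyone ever diagnosed.
#'
#' @param params a validated `lcs_params`.
#' @param diag_probs optional named (I-III or I-IV) 3-month diagnosis
#'   probabilities overriding those in `params`; stage IV defaults to the
#'   fixed value in `params`.
#' @param by_stratum if TRUE return a tibble with one row per stratum and
#'   columns `p_I` ... `p_IV`; otherwise a single named distribution pooled
#'   with weights stratum weight x prevalence.
#' @return named numeric stage distribution (sums to 1), or a tibble when
#'   `by_stratum = TRUE`. If no mass is ever diagnosed the distribution is
#'   returned as `NaN` with a warning (flagged, not an error).
#' @export
simulate_stage_at_diagnosis <- function(params, diag_probs = NULL,
                                        by_stratum = FALSE) {
  res <- undx_subchain(params, diag_probs)
  if (by_stratum) {
    tot <- colSums(res$diag_by_stage)
    d <- sweep(res$diag_by_stage, 2, tot, "/")
    out <- tibble(
      sex = params$strata$sex, age_group = params$strata$age_group
    )
    for (s in 1:4) out[[paste0("p_", STAGES[s])]] <- d[s, ]
    if (any(tot <= 0)) warn("some strata never reach diagnosis; NaN shares")
    out
  } else {
    w <- pool_weights(params, params$strata)
    mass <- as.vector(res$diag_by_stage %*% w)
    if (sum(mass) <= 0) warn("no mass ever diagnosed; degenerate distribution")
    setNames(mass / sum(mass), STAGES)
  }
}

#' Calibrate the stage I-III diagnosis probabilities
#'
#' Damped fixed-point iteration on stage-share ratios: each 3-month
#' diagnosis probability is updated by
#' `p_s <- p_s * (target_s / simulated_s)^lambda` (clipped to
#' \[1e-6, 1\]) until the simulated stage distribution at diagnosis matches
#' the target within tolerance on every stage. Falls back to a
#' derivative-free Nelder-Mead search on the log scale if the fixed point
#' does not converge. Stage IV's diagnosis probability stays fixed at its
#' configured value throughout.
#'
#' @param params a validated `lcs_params`.
#' @param target target stage-at-diagnosis distribution (named I-IV,
#'   sums to 1); defaults to `params$screening$stage_dist_standard`.
#' @param tolerance maximum absolute deviation per stage (default 1e-4).
#' @param max_iterations fixed-point iteration cap (default 500).
#' @param lambda damping exponent in (0, 1\] (default 0.5).
#' @param init optional starting values (named I-III); defaults to the
#'   values in `params`.
#' @param by_stratum calibrate each stratum separately (mortality differs by
#'   stratum) instead of pooling across strata with weights stratum weight x
#'   prevalence. Default pooled.
#' @return list with `p_diag` (named I-III), `converged`, `iterations`,
#'   `max_dev` and `method` ("fixed_point" or "nelder_mead"); with
#'   `by_stratum = TRUE`, a tibble with those columns per stratum.
#'   Non-convergence returns the best-found values with `converged = FALSE`
#'   and a warning, never silently.
#' @export
calibrate_diagnosis_probs <- function(params,
                                      target = NULL,
                                      tolerance = 1e-4,
                                      max_iterations = 500L,
                                      lambda = 0.5,
                                      init = NULL,
                                      by_stratum = FALSE) {
  if (is.null(target)) target <- params$screening$stage_dist_standard
  if (is.null(names(target))) names(target) <- STAGES
  target <- target[STAGES]
  if (tolerance <= 0) abort("`tolerance` must be > 0.")

  if (by_stratum) {
    rows <- purrr::map(seq_len(nrow(params$strata)), function(i) {
      p_i <- params
      p_i$strata <- params$strata[i, ]
      r <- calibrate_diagnosis_probs(p_i, target, tolerance, max_iterations,
        lambda,
        init = init, by_stratum = FALSE
      )
      tibble(
        sex = params$strata$sex[i], age_group = params$strata$age_group[i],
        p_diag_I = r$p_diag[["I"]], p_diag_II = r$p_diag[["II"]],
        p_diag_III = r$p_diag[["III"]],
        converged = r$converged, iterations = r$iterations,
        max_dev = r$max_dev, method = r$method
      )
    })
    return(dplyr::bind_rows(rows))
  }

  ctx <- build_context(params, params$strata)
  w <- pool_weights(params, params$strata)
  sim_dist <- function(p3) {
    res <- undx_subchain(params, setNames(p3, c("I", "II", "III")), ctx = ctx)
    mass <- as.vector(res$diag_by_stage %*% w)
    tot <- sum(mass)
    if (tot <= 0) rep(NaN, 4) else mass / tot
  }

  p <- if (!is.null(init)) {
    unname(init[c("I", "II", "III")])
  } else {
    unname(params$transitions$p_diagnose_3m[c("I", "II", "III")])
  }
  p <- pmin(pmax(p, 1e-6), 1)
  best <- list(p = p, dev = Inf)
  iter <- 0L
  converged <- FALSE
  eps <- 1e-12
  while (iter < max_iterations) {
    iter <- iter + 1L
    sim <- sim_dist(p)
    dev <- max(abs(sim - target))
    if (is.finite(dev) && dev < best$dev) best <- list(p = p, dev = dev)
    if (is.finite(dev) && dev <= tolerance) {
      converged <- TRUE
      break
    }
    ratio <- (target[1:3] + eps) / (sim[1:3] + eps)
    if (any(!is.finite(ratio))) ratio[!is.finite(ratio)] <- 1
    p <- pmin(pmax(p * ratio^lambda, 1e-6), 1)
  }
  method <- "fixed_point"

  if (!converged) {
    obj <- function(lp) {
      s <- sim_dist(pmin(pmax(exp(lp), 1e-6), 1))
      if (any(!is.finite(s))) {
        return(1e6)
      }
      sum((s - target)^2)
    }
    opt <- stats::optim(log(best$p), obj,
      method = "Nelder-Mead",
      control = list(maxit = 400, reltol = 1e-12)
    )
    p_nm <- pmin(pmax(exp(opt$par), 1e-6), 1)
    dev_nm <- max(abs(sim_dist(p_nm) - target))
    if (is.finite(dev_nm) && dev_nm < best$dev) {
      best <- list(p = p_nm, dev = dev_nm)
      method <- "nelder_mead"
    }
    iter <- iter + opt$counts[["function"]]
    converged <- best$dev <= tolerance
    if (!converged) {
      warn(sprintf(
        "calibration did not converge: max deviation %.3g > tolerance %.3g",
        best$dev, tolerance
      ))
    }
  }

  list(
    p_diag = setNames(best$p, c("I", "II", "III")),
    converged = converged, iterations = iter,
    max_dev = best$dev, method = method
  )
}

#' Calibrate a parameter set in place
#'
#' Convenience wrapper: runs [calibrate_diagnosis_probs()] (pooled) and
#' writes the calibrated stage I-III diagnosis probabilities back into the
#' parameter set. The convergence record is attached as attribute
#' `"calibration"`.
#'
#' @inheritParams calibrate_diagnosis_probs
#' @param ... passed to [calibrate_diagnosis_probs()].
#' @return the updated `lcs_params`.
#' @export
calibrate_params <- function(params, ...) {
  rec <- calibrate_diagnosis_probs(params, ...)
  params <- set_diagnosis_probs(params, rec$p_diag)
  attr(params, "calibration") <- rec
  params
}

#' Overdiagnosis under the counterfactual standard-care pathway
#'
#' The proportion of screen-diagnosed cancers that would never have
#' presented clinically: the screen-detected cohort (screening-arm stage
#' distribution) is run through the standard-care undiagnosed sub-chain with
#' the calibrated diagnosis probabilities, and the mass absorbed by
#' other-cause death before diagnosis is returned.
#'
#' @param params a validated, calibrated `lcs_params`.
#' @param by_stratum if TRUE, a tibble with the fraction per stratum;
#'   otherwise the pooled proportion of screen-diagnosed (weights stratum
#'   weight x prevalence).
#' @return proportion in \[0, 1\], or a per-stratum tibble.
#' @export
overdiagnosis_fraction <- function(params, by_stratum = FALSE) {
  res <- undx_subchain(params)
  if (by_stratum) {
    tibble(
      sex = params$strata$sex, age_group = params$strata$age_group,
      overdiagnosis = res$dead_before_dx
    )
  } else {
    w <- pool_weights(params, params$strata)
    sum(res$dead_before_dx * w) / sum(w)
  }
}
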