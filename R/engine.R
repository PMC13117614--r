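## Markov cohort engine.
##
## State space per stratum (91 states):
##   1        no_lc
##   2-5      undiagnosed stage I-IV (standard-care arm only; the screening
##            arm never occupies them)
##   6-89     diagnosed stage x tunnel slot: 20 quarterly slots for years 1-5
##            since diagnosis plus one absorbing 6+ slot, per stage
##   90       dead from lung cancer
##   91       dead from other causes
##
## Event order within a cycle (a model constant, shared with calibration):
## other-cause death on all alive states, then lung-cancer death on diagnosed
## states (tunnel-slot-specific probability), then diagnosis from undiagnosed
## states (entering tunnel year 1 of the same stage), then stage progression
## of the remaining undiagnosed I-III. Tunnel slots advance one cycle at the
## end of each step. The cohort is evolved vectorised across strata (state x
## stratum matrices).

I_NOLC <- 1L
I_U <- 2:5
I_D0 <- 5L # diagnosed block offset: state of (stage s, slot k) = I_D0 + (s-1)*21 + k
I_D <- 6:89
I_DLC <- 90L
I_DOC <- 91L
I_ALIVE <- 1:89
N_STATES <- 91L

d_idx <- function(stage, slot) I_D0 + (stage - 1L) * N_TUNNEL_SLOTS + slot

state_names <- function() {
  c(
    "no_lc", paste0("undiag_", STAGES),
    unlist(lapply(STAGES, function(s) paste0("diag_", s, "_slot", seq_len(N_TUNNEL_SLOTS)))),
    "dead_lc", "dead_other"
  )
}

#' Discount factor
#'
#' `(1 + annual_rate)^(-t)`. Flow quantities (life years, QALYs) are
#' discounted at cycle midpoints; one-off costs at the event cycle.
#'
#' @param t time in years (>= 0, vectorised).
#' @param annual_rate annual discount rate.
#' @return discount factor(s) in (0, 1].
#' @export
discount_factor <- function(t, annual_rate) {
  if (any(t < 0)) abort("`t` must be >= 0.")
  (1 + annual_rate)^(-t)
}

# Precompute everything age-dependent for a set of strata: per-cycle
# other-cause death probabilities, no-cancer utilities, and the column
# selector into the tunnel-slot lung-cancer mortality table (sex x mortality
# band). Snapshot t (1-based) is at time (t-1) * cycle_length.
build_context <- function(params, strata) {
  tr <- params$transitions
  ut <- params$utilities
  cl <- params$econ$cycle_length
  max_age <- tr$max_age
  S <- nrow(strata)
  start_age <- strata$start_age
  sex_idx <- match(strata$sex, SEXES)

  n_cycles <- ceiling((max_age - min(start_age)) / cl) + 3L
  tseq <- seq_len(n_cycles)
  # ages[t, j]: age at snapshot t for stratum j
  ages <- outer(tseq - 1, rep(1, S)) * cl + outer(rep(1, n_cycles), start_age)
  age_year <- floor(ages + 1e-9)

  # other-cause death lookup (sex x single year of age), certain at max_age
  oc <- tr$p_oc_death_3m
  oc_ages <- sort(unique(oc$age))
  oc_mat <- matrix(NA_real_, length(oc_ages), 2)
  oc_mat[cbind(match(oc$age, oc_ages), match(oc$sex, SEXES))] <- oc$p
  ay <- pmin(pmax(age_year, min(oc_ages)), max(oc_ages))
  P_oc <- matrix(
    oc_mat[cbind(match(ay, oc_ages), rep(sex_idx, each = n_cycles))],
    n_cycles, S
  )
  P_oc[age_year >= max_age] <- 1

  # no-cancer utility lookup (sex x utility band)
  un <- ut$u_no_lc
  u_mat <- matrix(NA_real_, length(UTILITY_BANDS), 2)
  u_mat[cbind(match(un$age_band, UTILITY_BANDS), match(un$sex, SEXES))] <- un$u
  band_u <- 1L + (age_year >= 65) + (age_year >= 75)
  U_no <- matrix(
    u_mat[cbind(as.vector(band_u), rep(sex_idx, each = n_cycles))],
    n_cycles, S
  )

  # lung-cancer death probability by tunnel slot, for each sex x band column;
  # band re-evaluated from current age each cycle, ages > 84 carry the 70-84
  # band forward
  lc <- tr$p_lc_death_3m
  L <- array(NA_real_, c(4, N_TUNNEL_YEARS, 2, 2))
  L[cbind(
    match(lc$stage, STAGES), lc$year,
    match(lc$sex, SEXES), match(lc$age_band, MORTALITY_BANDS)
  )] <- lc$p
  slot_year <- pmin(ceiling(seq_len(N_TUNNEL_SLOTS) / SLOTS_PER_YEAR), N_TUNNEL_YEARS)
  DP <- matrix(NA_real_, 4 * N_TUNNEL_SLOTS, 4) # columns: (sex-1)*2 + band
  for (sx in 1:2) {
    for (bd in 1:2) {
      col <- (sx - 1L) * 2L + bd
      for (s in 1:4) {
        rows <- (s - 1L) * N_TUNNEL_SLOTS + seq_len(N_TUNNEL_SLOTS)
        v <- L[s, slot_year, sx, bd]
        v[N_TUNNEL_SLOTS] <- tr$p_lc_death_3m_post5
        DP[rows, col] <- v
      }
    }
  }
  band_m <- 1L + (age_year >= 70)
  COL <- matrix(rep((sex_idx - 1L) * 2L, each = n_cycles) + as.vector(band_m),
    n_cycles, S
  )

  # tunnel shift index vectors (within the 84-row diagnosed block)
  blocks <- (0:3) * N_TUNNEL_SLOTS
  rows_first <- 1L + blocks
  rows_last <- N_TUNNEL_SLOTS + blocks
  rows_mid_dst <- as.vector(outer(2:(N_TUNNEL_SLOTS - 1L), blocks, `+`))
  rows_mid_src <- rows_mid_dst - 1L
  rows_pre_last <- rows_last - 1L

  u_ref <- max(un$u)
  mult_lc <- ut$u_lc_stageI * c(I = 1, ut$ratios)[STAGES] / u_ref

  list(
    S = S, n_cycles = n_cycles, cl = cl, max_age = max_age,
    start_age = start_age, sex_idx = sex_idx,
    P_oc = P_oc, U_no = U_no, DP = DP, COL = COL,
    p_prog = unname(tr$p_progress_3m[c("I", "II", "III")]),
    p_diag = unname(tr$p_diagnose_3m[STAGES]),
    mult_lc = unname(mult_lc),
    post5_equal = isTRUE(ut$post5_equal_no_lc),
    rows_first = rows_first, rows_last = rows_last,
    rows_mid_dst = rows_mid_dst, rows_mid_src = rows_mid_src,
    rows_pre_last = rows_pre_last,
    rows_y1to5 = setdiff(seq_len(4 * N_TUNNEL_SLOTS), rows_last)
  )
}

# One transition of the occupancy matrix M (N_STATES x S) at snapshot t.
# Returns list(M = next occupancy, newdx = 4 x S newly diagnosed mass).
engine_step <- function(M, t, ctx) {
  p_oc <- ctx$P_oc[t, ]
  surv <- rep(1 - p_oc, each = length(I_ALIVE))
  M[I_DOC, ] <- M[I_DOC, ] + colSums(M[I_ALIVE, , drop = FALSE]) * p_oc
  M[I_ALIVE, ] <- M[I_ALIVE, , drop = FALSE] * surv

  Dmat <- ctx$DP[, ctx$COL[t, ], drop = FALSE]
  Ds <- M[I_D, , drop = FALSE]
  M[I_DLC, ] <- M[I_DLC, ] + colSums(Ds * Dmat)
  Ds <- Ds * (1 - Dmat)

  U <- M[I_U, , drop = FALSE]
  newdx <- U * ctx$p_diag
  U <- U - newdx
  prog <- U[1:3, , drop = FALSE] * ctx$p_prog
  U[2:4, ] <- U[2:4, , drop = FALSE] + prog
  U[1:3, ] <- U[1:3, , drop = FALSE] - prog
  M[I_U, ] <- U

  # advance tunnels and seed year-1 slot-1 with the newly diagnosed
  Dn <- Ds
  Dn[ctx$rows_mid_dst, ] <- Ds[ctx$rows_mid_src, , drop = FALSE]
  Dn[ctx$rows_last, ] <- Ds[ctx$rows_pre_last, , drop = FALSE] +
    Ds[ctx$rows_last, , drop = FALSE]
  Dn[ctx$rows_first, ] <- newdx
  M[I_D, ] <- Dn

  list(M = M, newdx = newdx)
}

# Utility-weighted alive occupancy per stratum at snapshot t.
qaly_weight <- function(M, t, ctx) {
  u_no <- ctx$U_no[t, ]
  w <- (M[I_NOLC, ] + colSums(M[I_U, , drop = FALSE])) * u_no
  Ds <- M[I_D, , drop = FALSE]
  for (s in 1:4) {
    rows <- (s - 1L) * N_TUNNEL_SLOTS + seq_len(N_TUNNEL_SLOTS - 1L)
    w <- w + colSums(Ds[rows, , drop = FALSE]) * ctx$mult_lc[s] * u_no
  }
  last <- Ds[ctx$rows_last, , drop = FALSE]
  if (ctx$post5_equal) {
    w <- w + colSums(last) * u_no
  } else {
    w <- w + colSums(last * ctx$mult_lc) * u_no
  }
  w
}

#' Run one arm of the model over the lifetime horizon
#'
#' Evolves the cohort from its baseline allocation through 3-month cycles
#' until extinction (all-cause death; certain by the age cap) and accumulates
#' discounted, half-cycle-corrected life years, QALYs and costs. One-off
#' diagnosis and treatment costs are charged when people enter a diagnosed
#' state, discounted to that cycle; baseline (decision-tree) costs,
#' screen-detected diagnosis costs and the screening/false-positive
#' disutilities are charged undiscounted at time zero. In the standard-care
#' arm, detection costs after the first year accrue only to the newly
#' diagnosed.
#'
#' @param params a validated `lcs_params` (diagnosis probabilities should be
#'   calibrated first, see [calibrate_params()]).
#' @param arm `"screening"` or `"standard_care"`.
#' @param baseline baseline allocation from [allocate_baseline()]; computed
#'   from `params` when omitted.
#' @param trace if TRUE, attach a per-cycle occupancy trace (attribute
#'   `"trace"`: tibble with cycle, age, stratum, state, occupancy).
#' @return tibble with one row per stratum: `life_years`, `qalys`
#'   (discounted), `cost_detection`, `cost_fp`, `cost_dxtx`, `cost_total`
#'   (EUR, discounted), `lc_deaths`, `oc_deaths` (lifetime proportions),
#'   `dx_I` ... `dx_IV` (lifetime proportions ever entering each diagnosed
#'   stage, including screen-detected).
#' @export
run_arm <- function(params, arm, baseline = NULL, trace = FALSE) {
  arm <- match.arg(arm, ARMS)
  if (is.null(baseline)) baseline <- allocate_baseline(params, arm)
  ctx <- build_context(params, baseline)
  S <- ctx$S
  cl <- ctx$cl
  r <- params$econ$annual_discount_rate
  hcc <- isTRUE(params$econ$half_cycle_correction)
  dxtx <- unname(params$costs$c_dx_tx[STAGES])

  M <- matrix(0, N_STATES, S)
  M[I_NOLC, ] <- baseline$no_lc
  M[I_U, ] <- t(as.matrix(baseline[paste0("undiag_", STAGES)]))
  for (s in 1:4) M[d_idx(s, 1L), ] <- baseline[[paste0("diag_", STAGES[s])]]

  diag0 <- t(as.matrix(baseline[paste0("diag_", STAGES)]))
  ly <- qaly <- numeric(S)
  cost_det <- baseline$cost_detection
  cost_fp <- baseline$cost_fp
  cost_dxtx <- as.vector(dxtx %*% diag0) # screen-detected, charged at time 0
  qaly <- qaly - baseline$qaly_decrement
  dx_cum <- diag0

  alive <- colSums(M[I_ALIVE, , drop = FALSE])
  w <- qaly_weight(M, 1L, ctx)
  tr_list <- if (trace) list() else NULL
  snap <- function(t) {
    tibble(
      cycle = t - 1L,
      age = rep(ctx$start_age, each = N_STATES) + (t - 1L) * cl,
      stratum = rep(seq_len(S), each = N_STATES),
      state = rep(state_names(), S), occupancy = as.vector(M)
    )
  }
  t <- 1L
  while (any(alive > 1e-12)) {
    if (t > ctx$n_cycles) {
      abort("cohort not extinct before the age cap (horizon error)")
    }
    if (trace) tr_list[[t]] <- snap(t)
    stp <- engine_step(M, t, ctx)
    M <- stp$M
    alive_new <- colSums(M[I_ALIVE, , drop = FALSE])
    w_new <- qaly_weight(M, t + 1L, ctx)

    if (hcc) {
      disc <- discount_factor(((t - 1L) + 0.5) * cl, r)
      ly <- ly + cl * (alive + alive_new) / 2 * disc
      qaly <- qaly + cl * (w + w_new) / 2 * disc
    } else {
      disc <- discount_factor((t - 1L) * cl, r)
      ly <- ly + cl * alive * disc
      qaly <- qaly + cl * w * disc
    }

    disc_ev <- discount_factor(t * cl, r)
    cost_dxtx <- cost_dxtx + as.vector(dxtx %*% stp$newdx) * disc_ev
    if (arm == "standard_care" && t * cl > 1 + 1e-12) {
      cost_det <- cost_det +
        colSums(stp$newdx) * params$costs$c_detection_standard_dx * disc_ev
    }
    dx_cum <- dx_cum + stp$newdx
    alive <- alive_new
    w <- w_new
    t <- t + 1L
  }

  out <- tibble(
    sex = baseline$sex, age_group = baseline$age_group,
    weight = baseline$weight, arm = arm,
    life_years = ly, qalys = qaly,
    cost_detection = cost_det, cost_fp = cost_fp, cost_dxtx = cost_dxtx,
    cost_total = cost_det + cost_fp + cost_dxtx,
    lc_deaths = M[I_DLC, ], oc_deaths = M[I_DOC, ]
  )
  for (s in 1:4) out[[paste0("dx_", STAGES[s])]] <- dx_cum[s, ]
  if (trace) {
    if (length(tr_list)) attr(out, "trace") <- dplyr::bind_rows(tr_list)
  }
  out
}

#' Advance a single-stratum cohort state by one cycle
#'
#' Single-step interface to the engine, mainly for inspection and testing.
#' Applies, in order: other-cause death, lung-cancer death (tunnel-specific),
#' diagnosis, stage progression; then advances the tunnels and the age by
#' one cycle length.
#'
#' @param state list with `age` (years) and `occupancy` (named vector over
#'   the full state space, see [cohort_state()]).
#' @param params a validated `lcs_params`.
#' @param stratum one-row tibble with `sex` (and optionally `age_group`,
#'   `weight`).
#' @return a state list of the same shape with `occupancy` advanced, `age`
#'   increased by one cycle, `cycle_index` incremented, plus `newly_diagnosed`
#'   (named by stage).
#' @export
step_cohort <- function(state, params, stratum) {
  occ <- state$occupancy
  if (any(occ < -1e-12) || abs(sum(occ) - 1) > 1e-9) {
    abort("invalid occupancy: must be >= 0 and sum to 1")
  }
  st <- tibble(
    sex = stratum$sex,
    age_group = if ("age_group" %in% names(stratum)) stratum$age_group else AGE_GROUPS[1],
    weight = if ("weight" %in% names(stratum)) stratum$weight else 1,
    start_age = state$age
  )
  ctx <- build_context(params, st)
  M <- matrix(occ, ncol = 1)
  stp <- engine_step(M, 1L, ctx)
  list(
    cycle_index = (state$cycle_index %||% 0L) + 1L,
    age = state$age + ctx$cl,
    occupancy = setNames(as.vector(stp$M), state_names()),
    newly_diagnosed = setNames(as.vector(stp$newdx), STAGES)
  )
}

#' Construct a single-stratum cohort state
#'
#' @param age age in years at this snapshot.
#' @param no_lc,undiag,diag occupancy of the no-cancer state, the undiagnosed
#'   stages (named or positional I-IV) and the diagnosed stages (placed in
#'   tunnel year 1, slot 1).
#' @return a state list for [step_cohort()].
#' @export
cohort_state <- function(age, no_lc = 1, undiag = c(0, 0, 0, 0), diag = c(0, 0, 0, 0)) {
  occ <- setNames(numeric(N_STATES), state_names())
  occ["no_lc"] <- no_lc
  occ[paste0("undiag_", STAGES)] <- undiag
  occ[paste0("diag_", STAGES, "_slot1")] <- diag
  dead <- 1 - sum(occ)
  if (dead < -1e-9) abort("occupancy exceeds 1")
  occ["dead_other"] <- max(dead, 0)
  list(cycle_index = 0L, age = age, occupancy = occ)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
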