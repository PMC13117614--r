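# Independent individual-level microsimulation oracle for a single-stratum
# parameter set. Implemented directly from the model definition (per-person
# Bernoulli transitions, the same event order: other-cause death, lung-cancer
# death, diagnosis, progression) without touching the cohort engine, so the
# two can be compared. Accrual matches the engine's definition: trapezoidal
# half-cycle correction, flows discounted at cycle midpoints.
microsim_arm <- function(params, arm, n, seed) {
  stopifnot(nrow(params$strata) == 1)
  set.seed(seed)
  st <- params$strata
  sex <- st$sex
  start_age <- st$start_age
  cl <- params$econ$cycle_length
  r <- params$econ$annual_discount_rate
  max_age <- params$transitions$max_age
  scr <- params$screening
  tr <- params$transitions
  ut <- params$utilities

  prev_tab <- scr$prevalence
  prev <- prev_tab$prevalence[prev_tab$sex == sex &
    prev_tab$age_group == st$age_group]

  oc_tab <- tr$p_oc_death_3m[tr$p_oc_death_3m$sex == sex, ]
  p_oc_at <- function(age) {
    y <- floor(age + 1e-9)
    if (y >= max_age) {
      return(1)
    }
    y <- min(max(y, min(oc_tab$age)), max(oc_tab$age))
    oc_tab$p[match(y, oc_tab$age)]
  }
  u_tab <- ut$u_no_lc[ut$u_no_lc$sex == sex, ]
  u_ref <- max(ut$u_no_lc$u)
  u_no_at <- function(age) {
    band <- if (age < 65) "55-64" else if (age < 75) "65-74" else "75+"
    u_tab$u[match(band, u_tab$age_band)]
  }
  stage_names <- c("I", "II", "III", "IV")
  ratio_full <- c(1, unname(ut$ratios[c("II", "III", "IV")]))
  lc_tab <- tr$p_lc_death_3m[tr$p_lc_death_3m$sex == sex, ]
  p_lc_at <- function(stage_i, slot, age) {
    # stage_i, slot vectors; age scalar
    band <- if (age < 70) "55-69" else "70-84"
    year <- pmin(ceiling(slot / 4), 5)
    p <- tr$p_lc_death_3m_post5 + numeric(length(slot))
    pre <- slot <= 20
    if (any(pre)) {
      key <- paste(stage_names[stage_i[pre]], year[pre], band)
      tab_key <- paste(lc_tab$stage, lc_tab$year, lc_tab$age_band)
      p[pre] <- lc_tab$p[match(key, tab_key)]
    }
    p
  }

  # baseline allocation per individual
  stage <- sample(0:4, n,
    replace = TRUE,
    prob = c(1 - prev, prev * unname(scr$stage_dist_screen))
  )
  slot <- ifelse(arm == "screening" & stage > 0, 1L, 0L)
  alive <- rep(TRUE, n)
  dead_lc <- rep(FALSE, n)
  ly <- qaly <- numeric(n)

  weight_at <- function(age) {
    w <- numeric(n)
    idx <- which(alive)
    if (length(idx) == 0) {
      return(w)
    }
    un <- u_no_at(age)
    undiag <- stage[idx] == 0 | slot[idx] == 0
    w[idx[undiag]] <- un
    dx <- idx[!undiag]
    if (length(dx) > 0) {
      w[dx] <- ut$u_lc_stageI * ratio_full[stage[dx]] * un / u_ref
    }
    w
  }

  t <- 1L
  a_prev <- as.numeric(alive)
  w_prev <- weight_at(start_age)
  while (any(alive)) {
    age <- start_age + (t - 1L) * cl
    idx <- which(alive)
    # other-cause death
    die <- runif(length(idx)) < p_oc_at(age)
    alive[idx[die]] <- FALSE
    idx <- idx[!die]
    # lung-cancer death (diagnosed only, tunnel-slot-specific)
    dxed <- idx[stage[idx] > 0 & slot[idx] > 0]
    if (length(dxed) > 0) {
      p <- p_lc_at(stage[dxed], slot[dxed], age)
      die_lc <- runif(length(dxed)) < p
      alive[dxed[die_lc]] <- FALSE
      dead_lc[dxed[die_lc]] <- TRUE
      idx <- setdiff(idx, dxed[die_lc])
    }
    # diagnosis of undiagnosed
    undx <- idx[stage[idx] > 0 & slot[idx] == 0]
    newly <- integer(0)
    if (length(undx) > 0) {
      p <- unname(tr$p_diagnose_3m[stage_names[stage[undx]]])
      newly <- undx[runif(length(undx)) < p]
    }
    # progression of remaining undiagnosed I-III
    prog_pool <- setdiff(idx[stage[idx] %in% 1:3 & slot[idx] == 0], newly)
    if (length(prog_pool) > 0) {
      p <- unname(tr$p_progress_3m[stage_names[stage[prog_pool]]])
      up <- prog_pool[runif(length(prog_pool)) < p]
      stage[up] <- stage[up] + 1L
    }
    # tunnels advance, then the newly diagnosed enter year-1 slot 1
    in_tunnel <- slot > 0
    slot[in_tunnel] <- pmin(slot[in_tunnel] + 1L, 21L)
    slot[newly] <- 1L

    a_now <- as.numeric(alive)
    w_now <- weight_at(start_age + t * cl)
    disc <- (1 + r)^-(((t - 1L) + 0.5) * cl)
    ly <- ly + cl * (a_prev + a_now) / 2 * disc
    qaly <- qaly + cl * (w_prev + w_now) / 2 * disc
    a_prev <- a_now
    w_prev <- w_now
    t <- t + 1L
  }
  list(ly = ly, qaly = qaly, lc_death = dead_lc)
}
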