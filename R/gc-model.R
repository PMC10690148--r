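#' Stochastic germinal center model with antigen degradation and
#' antibody-mediated FDC capture
#'
#' The lymph node is modelled as a deterministic antigen/antibody layer
#' coupled to `n_gc` stochastic agent-based germinal centers (GCs).
#' Antigen arrives native (intact), converts to a non-native (partially
#' degraded) form with a 6.2-hour half-life, and both soluble forms are
#' cleared; circulating antibody of the matching specificity deposits
#' soluble antigen onto follicular dendritic cells (FDCs) as immune
#' complexes (ICs), where it is protected from further degradation. GC B
#' cells target either the native or the non-native epitope, capture
#' FDC-held antigen in proportion to their affinity, and compete for a
#' limited birth (T-cell help) budget; daughters mutate. Exiting cells
#' become antibody-secreting plasma cells, closing the feedback loop
#' between GC output and antigen capture.
#'
#' Affinities are on a -log10 Kd scale. Antigen amounts are normalized to
#' the total dose of the immunization.
#'
#' @name gc_model
NULL

.epitopes <- c("native", "nonnative")

#' Default parameters of the germinal center model
#'
#' The native-to-non-native conversion rate `k_deg` is fixed from the
#' ~6.2 hour half-life of intact antigen in the lymph node:
#' `log(2) / (6.2/24) ~= 2.68` per day. Non-native immunodominance is
#' encoded both as a higher precursor frequency and a higher mean
#' germline affinity. Desk-scale ensemble: 20 GCs per lymph node with a
#' 2000-cell capacity each.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `gc_params`.
#' @export
gc_params <- function(...) {
  p <- list(
    # antigen kinetics (1/day unless noted)
    k_deg = log(2) / (6.2 / 24), # native -> non-native conversion
    delta_sol = 1,               # clearance of soluble antigen (both forms)
    k_dep = 60,                  # IC deposition per titer unit per day
    delta_ic = 0.4,              # decay/consumption of FDC-held IC
    # lymph node / GC ensemble
    n_gc = 20,                   # GCs per lymph node
    gc_capacity = 2000,          # max B cells per GC
    seed_rate = 20,              # max naive seeding, cells/GC/day
    K_seed = 1e-4,               # antigen half-saturation for seeding
    n_founders = 200,            # naive founders admitted per GC
    pf_native = 0.3,             # precursor epitope frequencies
    pf_nonnative = 0.7,
    burst_divisions = 4,         # programmed founder divisions before selection
    germline_mean = c(native = 6.2, nonnative = 6.6), # -log10 Kd
    germline_sd = 0.5,
    aff_min = 5,                 # germline floor
    aff_cap = 10,                # affinity ceiling (0.1 nM)
    # selection
    a_capture = 6.2,             # reference affinity for antigen capture
    K_help = 0.1,                # scarcity constant in the help share
    lambda_help = 0.3,           # weight of the GC-mean capture in the share
    n_compete = 100,             # cells of one epitope that halve its antigen access
    beta_max = 2,                # 1/day max birth rate
    mu_death = 0.5,              # 1/day death rate
    # mutation (per division)
    p_silent = 0.5,
    p_lethal = 0.3,
    p_affinity = 0.2,
    mut_shift = 0.6,             # affinity change = mut_scale*(mut_shift - lognormal)
    mut_sdlog = 0.45,            # ~13% of affinity-changing mutations beneficial
    mut_scale = 2,               # step-size multiplier
    # output / antibodies
    p_exit = 0.08,               # 1/day differentiation to plasma cells
    k_ab = 0.0008,               # antibody production per plasma cell/day
    delta_ab = 0.15,             # 1/day antibody decay
    a_ref = 8,                   # affinity with titer weight 1
    # numerics
    dt = 0.04                    # day, agent step
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown gc parameters: ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  if (abs(p$p_silent + p$p_lethal + p$p_affinity - 1) > 1e-9) {
    stop("mutation outcome probabilities must sum to 1")
  }
  probs <- c(p$p_silent, p$p_lethal, p$p_affinity, p$pf_native, p$pf_nonnative)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(p$pf_native + p$pf_nonnative - 1) > 1e-9) {
    stop("precursor frequencies must sum to 1")
  }
  if (p$k_deg <= 0) stop("k_deg must be > 0")
  if (p$dt <= 0) stop("dt must be > 0")
  structure(p, class = c("gc_params", "list"))
}

#' Antigen pools of one lymph node
#'
#' Soluble native/non-native antigen and FDC-bound immune-complexed
#' antigen of each form, as fractions of the total dose, plus running
#' mass-balance accumulators (cumulative input, cumulative soluble
#' clearance, cumulative IC decay).
#'
#' @param sol_native,sol_nonnative,ic_native,ic_nonnative Initial pools.
#' @return Named numeric vector of class `antigen_state`.
#' @export
antigen_state <- function(sol_native = 0, sol_nonnative = 0,
                          ic_native = 0, ic_nonnative = 0) {
  x <- c(sol_native = sol_native, sol_nonnative = sol_nonnative,
         ic_native = ic_native, ic_nonnative = ic_nonnative,
         cum_input = sol_native + sol_nonnative + ic_native + ic_nonnative,
         cum_cleared = 0, cum_ic_decay = 0)
  if (any(x[1:4] < 0)) stop("antigen pools must be >= 0")
  structure(x, class = "antigen_state")
}

#' Antibody concentrations and affinity-weighted titers
#'
#' Titers are antibody concentration weighted by affinity: mass produced
#' by a plasma cell of affinity `a` carries weight `10^(a - a_ref)`, so
#' a clone at the reference affinity has titer equal to its
#' concentration. `mean_affinity` is derived as
#' `a_ref + log10(titer / conc)`.
#'
#' @param conc,titer Named numeric vectors over epitopes
#'   (`native`, `nonnative`).
#' @return List of class `antibody_state`.
#' @export
antibody_state <- function(conc = c(native = 0, nonnative = 0),
                           titer = c(native = 0, nonnative = 0)) {
  stopifnot(all(.epitopes %in% names(conc)), all(.epitopes %in% names(titer)))
  if (any(conc < 0) || any(titer < 0)) stop("concentrations must be >= 0")
  if (any(conc == 0 & titer != 0)) stop("titer must be 0 when conc is 0")
  structure(list(conc = conc[.epitopes], titer = titer[.epitopes]),
            class = "antibody_state")
}

#' @rdname antibody_state
#' @param ab An `antibody_state`.
#' @export
mean_affinity <- function(ab) {
  stopifnot(inherits(ab, "antibody_state"))
  ifelse(ab$conc > 0, attr(ab, "a_ref", exact = TRUE) %||% 8 +
           log10(ab$titer / ab$conc), NA_real_)
}

#' Advance the antigen pools over one step
#'
#' Integrates, with the antibody titers held fixed over the step,
#' \deqn{dS_N/dt = u(t) - (k_{deg} + \delta_{sol} + k_{dep} T_N) S_N}
#' \deqn{dS_D/dt = k_{deg} S_N - (\delta_{sol} + k_{dep} T_D) S_D}
#' \deqn{dIC_i/dt = k_{dep} T_i S_i - \delta_{ic} IC_i}
#' where \eqn{S} are soluble pools, \eqn{IC} FDC-bound pools, \eqn{T_i}
#' the per-epitope titers and \eqn{u} the constant dose-input rate over
#' the step. With titers frozen the system is linear, so the update is
#' the exact matrix exponential of the augmented system (pools plus
#' mass-balance accumulators): unconditionally stable, non-negative,
#' and conserving the identity input = pools + cleared + decayed to
#' round-off for any step size.
#'
#' @param state An [antigen_state()].
#' @param ab An [antibody_state()].
#' @param input_rate Constant native-antigen input rate over the step
#'   (dose fraction per day).
#' @param dt Step length, days (> 0).
#' @param params A [gc_params()] list.
#' @return Updated `antigen_state`.
#' @export
step_antigen <- function(state, ab, input_rate, dt, params = gc_params()) {
  stopifnot(inherits(state, "antigen_state"), inherits(ab, "antibody_state"),
            dt > 0, input_rate >= 0)
  p <- params
  cap_n <- p$k_dep * ab$titer[["native"]]
  cap_d <- p$k_dep * ab$titer[["nonnative"]]
  x <- unclass(state)
  # augmented linear system: (solN, solD, icN, icD, cleared, icdecay, 1)
  M <- matrix(0, 7, 7)
  M[1, 1] <- -(p$k_deg + p$delta_sol + cap_n); M[1, 7] <- input_rate
  M[2, 1] <- p$k_deg; M[2, 2] <- -(p$delta_sol + cap_d)
  M[3, 1] <- cap_n; M[3, 3] <- -p$delta_ic
  M[4, 2] <- cap_d; M[4, 4] <- -p$delta_ic
  M[5, 1] <- p$delta_sol; M[5, 2] <- p$delta_sol
  M[6, 3] <- p$delta_ic; M[6, 4] <- p$delta_ic
  z <- c(x[1:4], x[["cum_cleared"]], x[["cum_ic_decay"]], 1)
  z2 <- as.numeric(Matrix::expm(M * dt) %*% z)
  if (any(z2[1:6] < -1e-9)) {
    stop("step-size error: negative antigen pool after update (",
         paste(names(x)[1:4][z2[1:4] < -1e-9], collapse = ", "), ")")
  }
  x[1:4] <- pmax(z2[1:4], 0)
  x[["cum_input"]] <- x[["cum_input"]] + input_rate * dt
  x[["cum_cleared"]] <- z2[5]
  x[["cum_ic_decay"]] <- z2[6]
  structure(x, class = "antigen_state")
}

#' Check the antigen mass balance
#'
#' @param state An [antigen_state()].
#' @return Absolute mass-balance defect: |cumulative input - (pools +
#'   cumulative cleared + cumulative IC decay)|.
#' @export
mass_balance_error <- function(state) {
  x <- unclass(state)
  abs(x[["cum_input"]] -
        (sum(x[1:4]) + x[["cum_cleared"]] + x[["cum_ic_decay"]]))
}

# aggregate a plasma pool listing into per-epitope counts and
# affinity weights; internal
.aggregate_plasma <- function(plasma_pool, a_ref) {
  agg <- list(count = c(native = 0, nonnative = 0),
              weight = c(native = 0, nonnative = 0))
  if (is.null(plasma_pool)) return(agg)
  if (is.data.frame(plasma_pool)) {
    stopifnot(all(c("epitope", "affinity", "count") %in% names(plasma_pool)))
    for (e in .epitopes) {
      sel <- plasma_pool$epitope == e
      agg$count[[e]] <- sum(plasma_pool$count[sel])
      agg$weight[[e]] <- sum(plasma_pool$count[sel] *
                               10^(plasma_pool$affinity[sel] - a_ref))
    }
    return(agg)
  }
  stopifnot(is.list(plasma_pool), all(c("count", "weight") %in% names(plasma_pool)))
  plasma_pool
}

#' Advance antibody concentrations and titers over one step
#'
#' Concentration obeys `d conc_i/dt = k_ab * N_i - delta_ab * conc_i`
#' with `N_i` the plasma-cell count for epitope `i`; the titer obeys the
#' same kinetics with the plasma count replaced by the affinity-weighted
#' count `sum(count * 10^(affinity - a_ref))`. Both are updated with the
#' exact solution of the linear ODE over the step.
#'
#' @param ab An [antibody_state()].
#' @param plasma_pool Either a data frame with columns `epitope`,
#'   `affinity`, `count`, or a pre-aggregated list with `count` and
#'   `weight` per epitope.
#' @param dt Step length, days.
#' @param params A [gc_params()] list.
#' @return Updated `antibody_state`.
#' @export
update_antibodies <- function(ab, plasma_pool, dt, params = gc_params()) {
  stopifnot(inherits(ab, "antibody_state"), dt > 0)
  p <- params
  agg <- .aggregate_plasma(plasma_pool, p$a_ref)
  decay <- exp(-p$delta_ab * dt)
  gain <- if (p$delta_ab > 0) (1 - decay) / p$delta_ab else dt
  conc <- ab$conc * decay + p$k_ab * agg$count[.epitopes] * gain
  titer <- ab$titer * decay + p$k_ab * agg$weight[.epitopes] * gain
  structure(list(conc = conc, titer = titer), class = "antibody_state")
}

#' Create a germinal center B-cell population
#'
#' @param epitope Integer (1 = native, 2 = nonnative) or character
#'   vector of epitope targets.
#' @param affinity Numeric -log10 Kd values.
#' @param lineage Integer lineage identifiers (defaults to 1..n).
#' @param n_mut Mutation counts (defaults to 0).
#' @param burst Remaining antigen-independent programmed divisions
#'   (defaults to 0; freshly seeded founders carry
#'   `burst_divisions`).
#' @return List of class `gc_pop` with parallel vectors `epitope`,
#'   `affinity`, `lineage`, `n_mut`, `burst`.
#' @export
gc_population <- function(epitope = integer(0), affinity = numeric(0),
                          lineage = NULL, n_mut = NULL, burst = NULL) {
  if (is.character(epitope)) epitope <- match(epitope, .epitopes)
  stopifnot(length(epitope) == length(affinity),
            all(epitope %in% c(1L, 2L)) || length(epitope) == 0L)
  n <- length(epitope)
  structure(list(
    epitope = as.integer(epitope),
    affinity = as.numeric(affinity),
    lineage = if (is.null(lineage)) seq_len(n) else as.integer(lineage),
    n_mut = if (is.null(n_mut)) integer(n) else as.integer(n_mut),
    burst = if (is.null(burst)) integer(n) else as.integer(burst)
  ), class = "gc_pop")
}

# draw affinity changes for nb affinity-altering mutations; internal
.mutate_affinity <- function(nb, p) {
  p$mut_scale * (p$mut_shift - stats::rlnorm(nb, meanlog = 0,
                                             sdlog = p$mut_sdlog))
}

#' One stochastic step of a single germinal center
#'
#' Each cell captures antigen in proportion to the FDC-held IC of its
#' epitope and its affinity, `c = q / (1 + q)` with
#' `q = ic_eff * 10^(affinity - a_capture)`, where
#' `ic_eff = ic / (1 + n_epitope / n_compete)` divides each epitope's
#' antigen among the cells targeting it — clones of an abundant
#' specificity crowd each other's antigen access, which is what lets a
#' rare specificity with a well-stocked antigen pool overcome an
#' established immunodominant response. The share of T-cell help is
#' `min(1, c / (lambda_help * mean(c) + K_help))` — competitive
#' (normalized partly by the GC mean) but damped when antigen is
#' scarce, so an empty FDC network supports no births. Per step, with
#' probabilities proportional to `dt`: cells exit to the plasma
#' compartment, remaining cells divide (daughters mutate: silent,
#' lethal, or affinity-changing) and die. Births beyond `gc_capacity`
#' are rejected.
#'
#' Uses the current R random number stream; wrap in
#' [withr::with_seed()] for reproducibility.
#'
#' @param gc A [gc_population()].
#' @param antigen An [antigen_state()].
#' @param params A [gc_params()] list; per-step probabilities
#'   (`beta_max * dt`, `mu_death * dt`, `p_exit * dt`) must each be
#'   below 0.3.
#' @return List with `gc` (updated population), `exits` (data frame
#'   `epitope`, `affinity` of cells leaving as plasma cells), and the
#'   step tallies `n_births`, `n_deaths`, `n_exits`.
#' @export
gc_step <- function(gc, antigen, params = gc_params()) {
  stopifnot(inherits(gc, "gc_pop"), inherits(antigen, "antigen_state"))
  p <- params
  pb_max <- p$beta_max * p$dt
  pd <- p$mu_death * p$dt
  pe <- p$p_exit * p$dt
  if (max(pb_max, pd, pe) >= 0.3) {
    stop("configuration error: per-step probability >= 0.3 at dt = ", p$dt)
  }
  n <- length(gc$epitope)
  empty_exits <- data.frame(epitope = character(0), affinity = numeric(0))
  if (n == 0L) {
    return(list(gc = gc, exits = empty_exits,
                n_births = 0L, n_deaths = 0L, n_exits = 0L))
  }
  ic <- c(antigen[["ic_native"]], antigen[["ic_nonnative"]])
  # cells targeting the same epitope crowd each other's antigen access
  n_epi <- tabulate(gc$epitope, nbins = 2L)
  ic_eff <- ic / (1 + n_epi / p$n_compete)
  q <- ic_eff[gc$epitope] * 10^(gc$affinity - p$a_capture)
  cap <- q / (1 + q)
  denom <- p$lambda_help * mean(cap) + p$K_help
  help <- if (denom > 0) pmin(1, cap / denom) else rep(0, n)
  if (all(ic == 0)) help <- rep(0, n)
  # founders still in their programmed burst divide whenever antigen is
  # around, independent of FDC capture
  a_tot <- ic[1] + ic[2] + antigen[["sol_native"]] + antigen[["sol_nonnative"]]
  bursting <- gc$burst > 0L
  if (any(bursting)) {
    help[bursting] <- if (a_tot > 0) a_tot / (a_tot + p$K_seed) else 0
  }

  exits <- stats::runif(n) < pe
  stay <- which(!exits)
  born <- stay[stats::runif(length(stay)) < p$beta_max * help[stay] * p$dt]
  dead <- stay[stats::runif(length(stay)) < pd]

  # daughters: burst divisions copy the parent; GC divisions mutate
  nb <- length(born)
  keep_parent <- setdiff(stay, dead)
  d_epi <- gc$epitope[born]
  d_aff <- gc$affinity[born]
  d_lin <- gc$lineage[born]
  d_mut <- gc$n_mut[born]
  d_burst <- pmax(gc$burst[born] - 1L, 0L)
  parent_burst <- gc$burst
  parent_burst[born] <- pmax(parent_burst[born] - 1L, 0L)
  if (nb > 0L) {
    in_gc <- gc$burst[born] == 0L    # selection-phase divisions mutate
    d_mut[in_gc] <- d_mut[in_gc] + 1L
    n_gc_div <- sum(in_gc)
    viable <- rep(TRUE, nb)
    if (n_gc_div > 0L) {
      outcome <- sample.int(3L, n_gc_div, replace = TRUE,
                            prob = c(p$p_silent, p$p_lethal, p$p_affinity))
      alter_local <- which(outcome == 3L)
      idx_gc <- which(in_gc)
      if (length(alter_local)) {
        ai <- idx_gc[alter_local]
        d_aff[ai] <- pmin(pmax(d_aff[ai] +
                                 .mutate_affinity(length(ai), p),
                               p$aff_min), p$aff_cap)
      }
      viable[idx_gc[outcome == 2L]] <- FALSE
    }
    d_epi <- d_epi[viable]; d_aff <- d_aff[viable]
    d_lin <- d_lin[viable]; d_mut <- d_mut[viable]; d_burst <- d_burst[viable]
  }
  # capacity: reject surplus daughters at random
  room <- p$gc_capacity - length(keep_parent)
  if (length(d_epi) > room) {
    keep <- if (room > 0L) sample.int(length(d_epi), room) else integer(0)
    d_epi <- d_epi[keep]; d_aff <- d_aff[keep]
    d_lin <- d_lin[keep]; d_mut <- d_mut[keep]; d_burst <- d_burst[keep]
  }
  new_gc <- gc_population(
    epitope = c(gc$epitope[keep_parent], d_epi),
    affinity = c(gc$affinity[keep_parent], d_aff),
    lineage = c(gc$lineage[keep_parent], d_lin),
    n_mut = c(gc$n_mut[keep_parent], d_mut),
    burst = c(parent_burst[keep_parent], d_burst)
  )
  exit_frame <- if (any(exits)) {
    data.frame(epitope = .epitopes[gc$epitope[exits]],
               affinity = gc$affinity[exits])
  } else empty_exits
  list(gc = new_gc, exits = exit_frame,
       n_births = nb, n_deaths = length(dead), n_exits = sum(exits))
}
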