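#' Simulate the full germinal center response to a dosing regimen
#'
#' Couples the deterministic antigen/antibody layer ([step_antigen()],
#' [update_antibodies()]) with `n_gc` stochastic germinal centers
#' ([gc_step()]) per lymph node, replicated `n_replicates` times with
#' per-replicate seeds derived deterministically from `seed`. Antigen
#' impulses enter the soluble native pool at their event times (snapped
#' to the agent grid); constant-rate release events enter as a
#' continuous input. Naive B cells seed each GC at a rate saturating in
#' the total available antigen (soluble + FDC-bound), with
#' epitope-specific precursor frequencies and germline affinities, so
#' GCs can form before any antibody exists. Cells exiting GCs become
#' plasma cells whose affinity-weighted output drives the titers that
#' capture antigen onto FDCs.
#'
#' @param params A [gc_params()] list.
#' @param regimen A `regimen` (its antigen events drive this model).
#' @param t_end End of simulation, days.
#' @param n_replicates Independent stochastic lymph node replicates
#'   (replicate means are reported).
#' @param seed Integer seed; identical seeds give identical output.
#' @param dt_out Output recording interval, days (rounded to a multiple
#'   of the agent step).
#' @return A `gc_output`: list with `times`, `mean` (data frame of
#'   replicate-mean time courses: `gc_b_mean`, `native_gc_b_mean`,
#'   `titer_native`, `titer_nonnative`, `sol_native`, `sol_nonnative`,
#'   `ic_native`, `ic_nonnative`, `mean_aff_native`, `plasma_cells`,
#'   `mass_defect`), `replicates` (list of per-replicate frames),
#'   `n_replicates`, `seeds`, `regimen_label`, `params`.
#' @export
simulate_gc <- function(params, regimen, t_end = 21, n_replicates = 10,
                        seed = 1, dt_out = 0.2) {
  stopifnot(inherits(params, "gc_params"), inherits(regimen, "regimen"),
            t_end > 0, n_replicates >= 1)
  seeds <- vapply(seq_len(n_replicates), function(r) {
    as.integer((as.numeric(seed) * 7919 + r * 104729) %% 2147483647)
  }, integer(1))
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    reps[[r]] <- tryCatch(
      withr::with_seed(seeds[r],
                       .simulate_gc_one(params, regimen, t_end, dt_out)),
      error = function(e) {
        stop("replicate ", r, ": ", conditionMessage(e), call. = FALSE)
      })
  }
  times <- reps[[1]]$time
  num_cols <- setdiff(names(reps[[1]]), "time")
  mean_df <- data.frame(time = times)
  for (cn in num_cols) {
    mean_df[[cn]] <- Reduce(`+`, lapply(reps, `[[`, cn)) / n_replicates
  }
  structure(list(times = times, mean = mean_df, replicates = reps,
                 n_replicates = n_replicates, seeds = seeds,
                 regimen_label = regimen$label, params = params),
            class = "gc_output")
}

#' @export
print.gc_output <- function(x, ...) {
  cat("<gc_output>", x$regimen_label, "|", x$n_replicates, "replicates |",
      length(x$times), "time points over", max(x$times), "days\n")
  invisible(x)
}

# one stochastic lymph node; uses the current RNG stream
.simulate_gc_one <- function(p, regimen, t_end, dt_out) {
  dt <- p$dt
  n_steps <- ceiling(t_end / dt)
  rec_every <- max(1L, round(dt_out / dt))
  imp <- .impulse_events(regimen, "antigen")
  imp <- imp[imp$time <= t_end, , drop = FALSE]  # later doses never arrive
  imp_step <- if (nrow(imp)) pmin(round(imp$time / dt), n_steps) else integer(0)
  rel_tab <- .release_table(regimen, "antigen")

  ag <- antigen_state()
  ab <- antibody_state()
  plasma <- list(count = c(native = 0, nonnative = 0),
                 weight = c(native = 0, nonnative = 0))
  gcs <- replicate(p$n_gc, gc_population(), simplify = FALSE)
  founders_used <- integer(p$n_gc)
  lineage_next <- 1L

  rec_steps <- unique(c(seq(0L, n_steps - 1L, by = rec_every), n_steps))
  out <- matrix(0, nrow = length(rec_steps), ncol = 12,
                dimnames = list(NULL, c(
                  "time", "gc_b_mean", "native_gc_b_mean", "titer_native",
                  "titer_nonnative", "sol_native", "sol_nonnative",
                  "ic_native", "ic_nonnative", "mean_aff_native",
                  "plasma_cells", "mass_defect")))
  ri <- 1L

  record <- function(step) {
    sizes <- vapply(gcs, function(g) length(g$epitope), integer(1))
    n_native <- vapply(gcs, function(g) sum(g$epitope == 1L), integer(1))
    aff_n <- unlist(lapply(gcs, function(g) g$affinity[g$epitope == 1L]))
    out[ri, ] <<- c(step * dt, sum(sizes), sum(n_native),
                    ab$titer[["native"]], ab$titer[["nonnative"]],
                    ag[["sol_native"]], ag[["sol_nonnative"]],
                    ag[["ic_native"]], ag[["ic_nonnative"]],
                    if (length(aff_n)) mean(aff_n) else NA_real_,
                    sum(plasma$count), mass_balance_error(ag))
    ri <<- ri + 1L
  }

  for (step in 0:(n_steps - 1L)) {
    # impulse doses landing at this grid time enter the native pool
    hit <- which(imp_step == step)
    for (i in hit) {
      ag[["sol_native"]] <- ag[["sol_native"]] + imp$amount[i]
      ag[["cum_input"]] <- ag[["cum_input"]] + imp$amount[i]
    }
    if (step %in% rec_steps) record(step)

    # naive seeding: antigen-gated, limited to n_founders per GC (GCs
    # close to new entrants once their founder complement is in place)
    avail <- ag[["sol_native"]] + ag[["sol_nonnative"]] +
      ag[["ic_native"]] + ag[["ic_nonnative"]]
    s_rate <- p$seed_rate * avail / (avail + p$K_seed)
    if (s_rate > 0 && any(founders_used < p$n_founders)) {
      n_new <- stats::rpois(p$n_gc, s_rate * dt)
      n_new <- pmin(n_new, p$n_founders - founders_used)
      for (g in which(n_new > 0L)) {
        k <- n_new[g]
        founders_used[g] <- founders_used[g] + k
        epi <- ifelse(stats::runif(k) < p$pf_native, 1L, 2L)
        aff <- pmin(pmax(stats::rnorm(k, p$germline_mean[epi], p$germline_sd),
                         p$aff_min), p$aff_cap)
        gcs[[g]] <- gc_population(
          epitope = c(gcs[[g]]$epitope, epi),
          affinity = c(gcs[[g]]$affinity, aff),
          lineage = c(gcs[[g]]$lineage, lineage_next + seq_len(k) - 1L),
          n_mut = c(gcs[[g]]$n_mut, integer(k)),
          burst = c(gcs[[g]]$burst, rep(p$burst_divisions, k))
        )
        lineage_next <- lineage_next + k
      }
    }

    # stochastic GC dynamics; exits feed the plasma pool
    for (g in seq_len(p$n_gc)) {
      res <- gc_step(gcs[[g]], ag, p)
      gcs[[g]] <- res$gc
      if (nrow(res$exits)) {
        for (e in .epitopes) {
          sel <- res$exits$epitope == e
          if (any(sel)) {
            plasma$count[[e]] <- plasma$count[[e]] + sum(sel)
            plasma$weight[[e]] <- plasma$weight[[e]] +
              sum(10^(res$exits$affinity[sel] - p$a_ref))
          }
        }
      }
    }

    # deterministic antibody and antigen kinetics over the step
    ab <- update_antibodies(ab, plasma, dt, p)
    u <- .table_rate(rel_tab, (step + 0.5) * dt)
    ag <- step_antigen(ag, ab, u, dt, p)
  }
  # final impulses exactly at t_end, then record the last state
  hit <- which(imp_step == n_steps)
  for (i in hit) {
    ag[["sol_native"]] <- ag[["sol_native"]] + imp$amount[i]
    ag[["cum_input"]] <- ag[["cum_input"]] + imp$amount[i]
  }
  record(n_steps)
  as.data.frame(out)
}

#' Interpolate a replicate-mean GC metric at a given day
#'
#' @param output A `gc_output`.
#' @param metric Column name of `output$mean`.
#' @param day Day(s) within the simulated range.
#' @return Interpolated value(s).
#' @export
gc_metric_at <- function(output, metric, day) {
  stopifnot(inherits(output, "gc_output"), metric %in% names(output$mean))
  rng <- range(output$times)
  if (any(day < rng[1] | day > rng[2])) {
    stop("day outside simulated range [", rng[1], ", ", rng[2], "]")
  }
  stats::approx(output$times, output$mean[[metric]], xout = day)$y
}

#' Native (intact) share of FDC-held immune-complexed antigen
#'
#' `ic_native / (ic_native + ic_nonnative)` evaluated on the
#' replicate-mean trajectories at the requested day.
#'
#' @param output A `gc_output`.
#' @param day Day within the simulated range.
#' @return Fraction in [0, 1].
#' @export
native_ic_fraction <- function(output, day) {
  icn <- gc_metric_at(output, "ic_native", day)
  icd <- gc_metric_at(output, "ic_nonnative", day)
  if (icn + icd <= 0) {
    stop("undefined fraction: no FDC-held immune complexes at day ", day)
  }
  icn / (icn + icd)
}

#' Native-epitope share of GC B cells
#'
#' @inheritParams native_ic_fraction
#' @return Fraction of GC B cells targeting the native epitope, from
#'   the replicate-mean trajectories.
#' @export
native_gc_fraction <- function(output, day) {
  nat <- gc_metric_at(output, "native_gc_b_mean", day)
  tot <- gc_metric_at(output, "gc_b_mean", day)
  if (tot <= 0) stop("undefined fraction: no GC B cells at day ", day)
  nat / tot
}

#' Total FDC-held immune-complexed antigen at a day
#'
#' @inheritParams native_ic_fraction
#' @return `ic_native + ic_nonnative` (dose fraction).
#' @export
total_ic <- function(output, day) {
  gc_metric_at(output, "ic_native", day) +
    gc_metric_at(output, "ic_nonnative", day)
}
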