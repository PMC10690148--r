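#' Synthetic cohort readouts
#'
#' Generates pseudo-experimental per-animal readouts (e.g. day-14 Tfh
#' counts per dosing regimen, n = 5 animals per group) by multiplying the
#' model-predicted group mean by lognormal animal-to-animal noise. The
#' lognormal is parameterized so the noise is mean-unbiased: with
#' coefficient of variation `cv`, `sdlog = sqrt(log(1 + cv^2))` and
#' `meanlog = -sdlog^2 / 2`, giving a multiplier with expectation exactly
#' 1 and coefficient of variation exactly `cv`.
#'
#' @param regimens Named list of `regimen` objects, one group per entry.
#' @param n_animals Animals per group (default 5).
#' @param readouts Character subset of `"tfh_day14"`, `"gcb_day14"`,
#'   `"native_gcb_day14"`. GC readouts need `gc_params`.
#' @param noise_cv Coefficient of variation of the lognormal animal
#'   noise (>= 0; 0 returns the model mean for every animal).
#' @param seed Integer seed; output is reproducible given the seed.
#' @param priming_pars [priming_params()] used for the Tfh readout.
#' @param gc_params [gc_params()] used for GC readouts; `n_replicates`
#'   and `gc_seed` control the underlying stochastic GC run.
#' @param n_replicates Stochastic LN replicates for GC readouts.
#' @return A data frame of class `cohort_data` with columns
#'   `regimen_label`, `readout`, `animal_index`, `value`, and attributes
#'   `spec` (the generating settings) and `model_means`.
#' @export
gen_cohort <- function(regimens, n_animals = 5,
                       readouts = "tfh_day14", noise_cv = 0.5, seed = 1,
                       priming_pars = priming_params(), gc_params = NULL,
                       n_replicates = 5) {
  stopifnot(is.list(regimens), length(regimens) >= 1,
            !is.null(names(regimens)), all(nzchar(names(regimens))),
            n_animals >= 1, noise_cv >= 0)
  known <- c("tfh_day14", "gcb_day14", "native_gcb_day14")
  if (!all(readouts %in% known)) {
    stop("unknown readouts: ", paste(setdiff(readouts, known), collapse = ", "))
  }
  needs_gc <- any(readouts %in% c("gcb_day14", "native_gcb_day14"))
  if (needs_gc && is.null(gc_params)) {
    stop("GC readouts requested but no gc_params supplied")
  }

  means <- list()
  for (lab in names(regimens)) {
    reg <- regimens[[lab]]
    row <- c()
    if ("tfh_day14" %in% readouts) {
      tr <- simulate_priming(priming_pars, reg, t_end = 14, dt_out = 0.25)
      row["tfh_day14"] <- tfh_at(tr, 14)
    }
    if (needs_gc) {
      out <- simulate_gc(gc_params, reg, t_end = 14,
                         n_replicates = n_replicates,
                         seed = seed + 7919L)
      if ("gcb_day14" %in% readouts) {
        row["gcb_day14"] <- gc_metric_at(out, "gc_b_mean", 14)
      }
      if ("native_gcb_day14" %in% readouts) {
        row["native_gcb_day14"] <- gc_metric_at(out, "native_gc_b_mean", 14)
      }
    }
    means[[lab]] <- row
  }

  sdlog <- sqrt(log(1 + noise_cv^2))
  out <- withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    rows <- list()
    for (lab in names(regimens)) {
      for (rd in readouts) {
        mult <- if (noise_cv == 0) rep(1, n_animals) else {
          exp(stats::rnorm(n_animals, mean = -sdlog^2 / 2, sd = sdlog))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          regimen_label = lab, readout = rd,
          animal_index = seq_len(n_animals),
          value = unname(means[[lab]][rd]) * mult
        )
      }
    }
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  attr(out, "spec") <- list(n_animals = n_animals, readouts = readouts,
                            noise_cv = noise_cv, seed = seed)
  attr(out, "model_means") <- means
  class(out) <- c("cohort_data", class(out))
  out
}

#' Write a synthetic cohort to CSV with a JSON settings echo
#'
#' @param cohort A `cohort_data` frame from [gen_cohort()].
#' @param path CSV path; the generating settings are written next to it
#'   as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  jsonlite::write_json(attr(cohort, "spec"), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
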