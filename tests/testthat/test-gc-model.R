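test_that("intact antigen decays with its 6.2-hour half-life", {
  # no antibody, no nonspecific clearance: sol_native halves in 6.2 h
  p <- gc_params(delta_sol = 0)
  st <- antigen_state(sol_native = 1)
  ab <- antibody_state()
  st2 <- step_antigen(st, ab, input_rate = 0, dt = 6.2 / 24, params = p)
  expect_equal(st2[["sol_native"]], 0.5, tolerance = 1e-9)
  # and nothing lands on FDCs without antibody
  expect_equal(st2[["ic_native"]], 0)
  expect_equal(st2[["ic_nonnative"]], 0)
})

test_that("no degradation means no non-native antigen, ever", {
  p <- gc_params(k_deg = 1e-12)  # k_deg must be > 0; effectively zero
  st <- antigen_state(sol_native = 1)
  ab <- antibody_state()
  for (i in 1:20) st <- step_antigen(st, ab, 0, 0.25, p)
  expect_lt(st[["sol_nonnative"]], 1e-10)
})

test_that("the antigen mass balance audits to 1e-8 with antibody present", {
  p <- gc_params()
  ab <- antibody_state(conc = c(native = 1, nonnative = 2),
                       titer = c(native = 0.5, nonnative = 1.5))
  st <- antigen_state()
  # impulse then constant infusion, stepped over 5 days
  st[["sol_native"]] <- st[["sol_native"]] + 0.3
  st[["cum_input"]] <- st[["cum_input"]] + 0.3
  for (i in 1:100) st <- step_antigen(st, ab, input_rate = 0.14, dt = 0.05,
                                      params = p)
  expect_equal(st[["cum_input"]], 0.3 + 0.14 * 5, tolerance = 1e-12)
  expect_lt(mass_balance_error(st), 1e-8)
  expect_true(all(unclass(st)[1:4] >= 0))
})

test_that("titer weighting matches a brute-force sum over clones", {
  p <- gc_params(delta_ab = 0)
  pool <- data.frame(
    epitope = c("native", "native", "nonnative"),
    affinity = c(6.4, 8.9, 7.2),
    count = c(12, 3, 40)
  )
  ab <- update_antibodies(antibody_state(), pool, dt = 1, params = p)
  # with no decay, production integrates linearly over one day
  brute_n <- p$k_ab * sum(pool$count[1:2] * 10^(pool$affinity[1:2] - p$a_ref))
  brute_d <- p$k_ab * sum(pool$count[3] * 10^(pool$affinity[3] - p$a_ref))
  expect_equal(ab$titer[["native"]], brute_n, tolerance = 1e-12)
  expect_equal(ab$titer[["nonnative"]], brute_d, tolerance = 1e-12)
  # a single clone at the reference affinity: titer equals concentration
  one <- data.frame(epitope = "native", affinity = p$a_ref, count = 5)
  ab1 <- update_antibodies(antibody_state(), one, dt = 1, params = p)
  expect_equal(ab1$titer[["native"]], ab1$conc[["native"]], tolerance = 1e-12)
})

test_that("no plasma cells means titers stay at zero", {
  ab <- antibody_state()
  for (i in 1:10) ab <- update_antibodies(ab, NULL, dt = 0.5)
  expect_equal(unname(ab$titer), c(0, 0))
  expect_equal(unname(ab$conc), c(0, 0))
})

test_that("without FDC antigen a GC only loses cells", {
  p <- gc_params()
  gc <- gc_population(epitope = rep(1:2, 25), affinity = rep(c(6.5, 7), 25))
  ag <- antigen_state(sol_native = 0.5)  # soluble only; FDC pools empty
  res <- withr::with_seed(1, gc_step(gc, ag, p))
  expect_equal(res$n_births, 0L)
  expect_lte(length(res$gc$epitope), length(gc$epitope))
})

test_that("identical cells receive identical help (exchangeability)", {
  p <- gc_params()
  ag <- antigen_state(ic_native = 0.2, ic_nonnative = 0.2)
  gc <- gc_population(epitope = rep(1L, 2000), affinity = rep(7, 2000))
  # with exchangeable cells, per-cell birth probabilities are equal, so
  # the realized birth count concentrates near n * p_birth
  res <- withr::with_seed(42, gc_step(gc, ag, p))
  q <- 0.2 / (1 + 2000 / p$n_compete) * 10^(7 - p$a_capture)
  cap <- q / (1 + q)
  help <- min(1, cap / (p$lambda_help * cap + p$K_help))
  expected <- 2000 * (1 - p$p_exit * p$dt) * p$beta_max * help * p$dt
  expect_lt(abs(res$n_births - expected) / expected, 0.2)
})

test_that("one GC step matches exhaustive enumeration on a 3-cell toy", {
  # three cells with distinct affinities; expectation of births, deaths
  # and exits computed in closed form from the per-cell probabilities
  p <- gc_params(dt = 0.1, beta_max = 2, mu_death = 0.8, p_exit = 0.5,
                 p_silent = 0.6, p_lethal = 0.4, p_affinity = 0)
  ag <- antigen_state(ic_native = 0.3, ic_nonnative = 0.1)
  gc <- gc_population(epitope = c(1L, 1L, 2L), affinity = c(6.5, 7.5, 7))
  ic_eff <- c(0.3 / (1 + 2 / p$n_compete), 0.1 / (1 + 1 / p$n_compete))
  q <- ic_eff[gc$epitope] * 10^(gc$affinity - p$a_capture)
  cap <- q / (1 + q)
  help <- pmin(1, cap / (p$lambda_help * mean(cap) + p$K_help))
  pe <- p$p_exit * p$dt; pb <- p$beta_max * help * p$dt; pd <- p$mu_death * p$dt
  exp_births <- sum((1 - pe) * pb)          # division events
  exp_deaths <- 3 * (1 - pe) * pd
  exp_exits <- 3 * pe
  exp_pop <- 3 * (1 - pe) * (1 - pd) + exp_births * (1 - p$p_lethal)

  n_trials <- 1e4
  tot <- c(births = 0, deaths = 0, exits = 0, pop = 0)
  withr::with_seed(7, {
    for (i in seq_len(n_trials)) {
      res <- gc_step(gc, ag, p)
      tot <- tot + c(res$n_births, res$n_deaths, res$n_exits,
                     length(res$gc$epitope))
    }
  })
  obs <- tot / n_trials
  # 5-sigma Monte-Carlo tolerances (binomial-scale sd ~ sqrt(p/n))
  mc_tol <- 5 * sqrt(c(exp_births, exp_deaths, exp_exits, exp_pop) / n_trials)
  expect_lt(abs(obs[["births"]] - exp_births), mc_tol[1])
  expect_lt(abs(obs[["deaths"]] - exp_deaths), mc_tol[2])
  expect_lt(abs(obs[["exits"]] - exp_exits), mc_tol[3])
  expect_lt(abs(obs[["pop"]] - exp_pop), mc_tol[4])
})

test_that("per-step probabilities above 0.3 are rejected as configuration", {
  p <- gc_params(dt = 0.2)  # beta_max * dt = 0.5
  gc <- gc_population(1L, 7)
  expect_error(gc_step(gc, antigen_state(), p), "configuration error")
})

test_that("a GC never exceeds its capacity", {
  p <- gc_params(gc_capacity = 50)
  ag <- antigen_state(ic_native = 0.5, ic_nonnative = 0.5)
  gc <- gc_population(epitope = rep(1:2, 24), affinity = rep(8, 48))
  withr::with_seed(3, {
    for (i in 1:200) {
      gc <- gc_step(gc, ag, p)$gc
      expect_lte(length(gc$epitope), 50)
    }
  })
  expect_gte(length(gc$epitope), 45)  # abundant antigen keeps it full
})

test_that("affinity-changing mutations respect the configured bounds", {
  p <- gc_params(p_silent = 0, p_lethal = 0, p_affinity = 1)
  ag <- antigen_state(ic_native = 1)
  gc <- gc_population(epitope = rep(1L, 200), affinity = rep(9.9, 200))
  res <- withr::with_seed(11, gc_step(gc, ag, p))
  expect_true(all(res$gc$affinity >= p$aff_min))
  expect_true(all(res$gc$affinity <= p$aff_cap))
  daughters <- res$gc$n_mut > 0
  expect_gt(sum(daughters), 0)
})
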