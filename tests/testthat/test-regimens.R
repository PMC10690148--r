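# numeric integral of the continuous release rate plus impulse sums
# over [0, t_max]; independent quadrature check of input_rate()
total_delivered <- function(regimen, component, t_max = 30, n = 6001) {
  ts <- seq(0, t_max, length.out = n)
  rates <- vapply(ts, function(t) input_rate(regimen, t, component)$rate,
                  numeric(1))
  cont <- sum((rates[-1] + rates[-n]) / 2 * diff(ts))
  imps <- sum(vapply(unique(regimen$events$start_time), function(t0) {
    sum(input_rate(regimen, t0, component)$impulses)
  }, numeric(1)))
  cont + imps
}

test_that("bolus is a single day-0 impulse carrying the whole dose", {
  reg <- make_bolus()
  expect_equal(nrow(reg$events), 1L)
  expect_equal(reg$events$start_time, 0)
  expect_equal(reg$events$amount, 1)
  expect_equal(reg$events$duration, 0)
  expect_equal(regimen_total(reg, "antigen"), 1)
  expect_equal(regimen_total(reg, "adjuvant"), 1)
  # impulse semantics: nothing flows except exactly at t = 0
  expect_equal(input_rate(reg, 3, "antigen"), list(rate = 0, impulses = numeric(0)))
  expect_equal(input_rate(reg, 0, "antigen")$impulses, 1)
})

test_that("exponential escalation reproduces the closed-form fractions", {
  # 3 doses: fractions (1, e, e^2) / (1 + e + e^2), by direct summation
  k <- 0:2
  expected <- exp(k) / sum(exp(k))
  reg <- make_exponential_ed(3, 6)
  expect_equal(reg$events$amount, expected, tolerance = 1e-12)
  expect_equal(reg$events$start_time, c(0, 6, 12))

  # 7 doses, 2-day interval: final dose lands on day 12 at 63% of total
  reg7 <- make_exponential_ed(7, 2)
  expect_equal(reg7$events$start_time[7], 12)
  expect_equal(round(100 * reg7$events$amount[7]), 63)

  # degenerate single dose
  reg1 <- make_exponential_ed(1, 2)
  expect_equal(reg1$events$amount, 1)
  expect_equal(reg1$events$start_time, 0)

  expect_error(make_exponential_ed(3, 0), "interval")
  expect_error(make_exponential_ed(0, 2), "n_doses")
})

test_that("two-dose regimen splits the dose at the stated ratio", {
  reg <- make_two_dose(0.2, 7)
  expect_equal(reg$events$start_time, c(0, 7))
  expect_equal(reg$events$amount, c(0.2, 0.8))
  expect_equal(make_two_dose(0.5, 7)$events$amount, c(0.5, 0.5))
  # first_fraction = 1 collapses to a bolus-equivalent single event
  expect_equal(nrow(make_two_dose(1, 7)$events), 1L)
  expect_error(make_two_dose(0, 7), "first_fraction")
  expect_error(make_two_dose(1.2, 7), "first_fraction")
})

test_that("a 2-dose exponential schedule is not the 20/80 split", {
  reg <- make_exponential_ed(2, 7)
  expect_equal(reg$events$amount[1], 1 / (1 + exp(1)), tolerance = 1e-12)
  expect_gt(abs(reg$events$amount[1] - 0.2), 0.05)
})

test_that("extended release preserves amounts and degenerates cleanly", {
  base <- make_two_dose(0.2, 7)
  ext <- with_extended_release(base, 2, 10)
  expect_equal(ext$events$duration[2], 10)
  expect_equal(ext$events$amount[2], 0.8)
  # constant rate 0.8/10 inside the window, for any query time
  expect_equal(input_rate(ext, 12, "antigen")$rate, 0.08)
  expect_equal(input_rate(ext, 17.01, "antigen")$rate, 0)
  # duration 0 leaves the impulse untouched
  expect_equal(with_extended_release(base, 2, 0)$events, base$events)
  expect_error(with_extended_release(base, 3, 10), "out of range")
  # conservation for arbitrary durations
  for (d in c(0.5, 3, 10, 21)) {
    expect_equal(regimen_total(with_extended_release(base, 2, d), "antigen"),
                 1, tolerance = 1e-12)
  }
})

test_that("every shipped regimen delivers exactly one total dose", {
  shipped <- list(make_bolus(), make_two_dose(0.2, 7), make_two_dose(0.5, 7),
                  make_exponential_ed(7, 2), make_exponential_ed(3, 6),
                  make_mismatched_ed(7, 2),
                  with_extended_release(make_two_dose(0.2, 7), 2, 10),
                  regimen_by_name("ned:4"), regimen_by_name("2ed-ext:21"))
  for (reg in shipped) {
    for (comp in c("antigen", "adjuvant")) {
      expect_equal(regimen_total(reg, comp), 1, tolerance = 1e-9,
                   label = paste(reg$label, comp, "scheduled total"))
      # trapezoid quadrature; release-window edges limit the accuracy
      expect_equal(total_delivered(reg, comp), 1, tolerance = 1e-3,
                   label = paste(reg$label, comp, "quadrature total"))
    }
  }
})

test_that("mismatched regimen separates antigen and adjuvant schedules", {
  reg <- make_mismatched_ed(7, 2)
  adj <- reg$events[reg$events$component == "adjuvant", ]
  ag <- reg$events[reg$events$component == "antigen", ]
  expect_equal(nrow(adj), 1L)
  expect_equal(adj$start_time, 0)
  expect_equal(nrow(ag), 7L)
})

test_that("regimens survive a serialization round trip", {
  path <- withr::local_tempfile(fileext = ".json")
  reg <- with_extended_release(make_two_dose(0.2, 7), 2, 10)
  write_regimen(reg, path)
  back <- read_regimen(path)
  expect_equal(back$events, reg$events)
  expect_equal(back$label, reg$label)
})

test_that("regimen_by_name understands the documented shorthands", {
  expect_equal(regimen_by_name("bolus")$events, make_bolus()$events)
  expect_equal(regimen_by_name("2ed")$events, make_two_dose(0.2, 7)$events)
  expect_equal(regimen_by_name("7ed")$events, make_exponential_ed(7, 2)$events)
  # n-dose series spans the 12-day window
  r4 <- regimen_by_name("ned:4")
  expect_equal(max(r4$events$start_time), 12)
  expect_equal(regimen_by_name("2dose:0.3:5")$events$amount, c(0.3, 0.7))
  expect_error(regimen_by_name("nope"), "unknown regimen")
})
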