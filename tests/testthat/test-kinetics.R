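test_that("initiator decay law gives the expected initiation rate", {
  ir <- initiation_rate(348, AIBN_conc = 1)
  # direct evaluation of 10^(17.70 - 35/(4.575e-3 * 348))
  expect_equal(ir$kp, 10^(17.70 - 35 / (4.575e-3 * 348)))
  expect_equal(ir$kp, 5.2054e-5, tolerance = 1e-4)
  # e = 0.5 collapses Vi to kp * [AIBN]
  expect_equal(initiation_rate(348, 2e-3, e = 0.5)$Vi,
               initiation_rate(348, 2e-3)$kp * 2e-3)
  expect_equal(initiation_rate(348, 0)$Vi, 0)
})

test_that("initial rates come from least-squares slopes of the early window", {
  t <- seq(0, 500, by = 10)
  ex <- suppressWarnings(initial_rate(t, 2.3e-6 * t, window = 10))
  expect_equal(ex$rate, 2.3e-6)
  expect_equal(ex$se, 0, tolerance = 1e-18)
  expect_equal(ex$r_squared, 1)

  set.seed(4)
  noisy <- 2.3e-6 * t + rnorm(length(t), 0, 2e-6)
  nr <- initial_rate(t, noisy, window = 25)
  expect_lt(abs(nr$rate - 2.3e-6), 3 * nr$se)

  expect_error(initial_rate(t[1:2], noisy[1:2]), "at least 3")
  expect_error(initial_rate(t, noisy, window = 1000), "exceeds|at least")
})

test_that("inhibition parameter F behaves per definition", {
  expect_equal(f_parameter(2e-6, 2e-6), 0)
  expect_equal(f_parameter(2e-6, 1e-6), 1.5)        # V = V0/2
  expect_equal(f_parameter(2.30e-6, 1.13e-6), 2.30 / 1.13 - 1.13 / 2.30)
  expect_equal(round(f_parameter(2.30e-6, 1.13e-6), 3), 1.544)
  expect_error(f_parameter(0, 1e-6), "positive")
  expect_warning(f_parameter(1e-6, 2e-6), "exceeds")
  # strictly decreasing in V
  V <- seq(0.5e-6, 2.3e-6, length.out = 20)
  expect_true(all(diff(f_parameter(2.3e-6, V)) < 0))
})

test_that("fk7 fit reproduces the experimental value for the bundled AO1 data", {
  tab <- ao_rate_table("AO1")
  expect_equal(attr(tab, "V0"), 2.30e-6)
  fit <- fit_fk7(tab)
  expect_equal(fit$fk7, 1.32e6, tolerance = 0.02)
  expect_gt(fit$se, 0)
  # single-point slope is exact division
  one <- rate_table(c(0, 1e-6), c(2.3e-6, 1.5e-6))
  f1 <- fit_fk7(one)
  expect_equal(f1$slope, f_parameter(2.3e-6, 1.5e-6) / 1e-6)
})

test_that("noise-free simulated tables round-trip fk7 exactly", {
  for (fk in c(5e5, 1.0e6, 1.32e6)) {
    tab <- generate_rate_table(fk)
    expect_equal(suppressWarnings(fit_fk7(tab)$fk7), fk, tolerance = 1e-9)
  }
})

test_that("induction period is the two-tangent intersection", {
  cv <- generate_curves(30, 1.32e6, conc = 3.13e-6, t_end = 3000,
                        n_points = 301)[[1]]
  ip <- induction_period(cv$time, cv$uptake)
  expect_equal(ip$tau, 939)  # f [InH] / Vi = 30 * 3.13e-6 / 1e-7
  expect_false(ip$flagged)

  line <- generate_curves(30, 1.32e6, conc = 0)[[1]]
  ipl <- induction_period(line$time, line$uptake)
  expect_equal(ipl$tau, 0)
  expect_true(ipl$flagged)

  noisy <- generate_curves(30, 1.32e6, conc = 3.13e-6, t_end = 3000,
                           n_points = 301, noise_sd = 2e-5, seed = 12)[[1]]
  ipn <- induction_period(noisy$time, noisy$uptake)
  expect_lt(abs(ipn$tau - 939) / 939, 0.05)
})

test_that("stoichiometric coefficient comes from the tau-vs-conc slope", {
  conc <- c(0.44, 1.24, 1.88, 2.50, 3.13) * 1e-6
  tau <- 30 * conc / 1e-7
  expect_equal(suppressWarnings(fit_f_stoich(conc, tau, Vi = 1e-7)$f), 30)
  expect_equal(suppressWarnings(
    fit_f_stoich(c(0.5e-6, 1.0e-6), c(100, 200), Vi = 1e-7)$f), 20)
  expect_equal(fit_f_stoich(1e-6, 300, Vi = 1e-7)$f, 300 * 1e-7 / 1e-6)
  expect_error(suppressWarnings(fit_f_stoich(conc, -tau, Vi = 1e-7)),
               "negative")
})

test_that("k7 bookkeeping follows k7 = fk7 / f with propagated error", {
  r <- k7_from(1.08e6, 40, fk7_se = 0.2e6, f_se = 2)
  expect_equal(r$k7, 2.7e4)
  expect_equal(round(r$logk7, 2), 4.43)
  expect_equal(r$k7_se, 2.7e4 * sqrt((0.2 / 1.08)^2 + (2 / 40)^2))
  expect_equal(k7_from(5e5, 1)$k7, 5e5)
  expect_error(k7_from(1e6, 0), "positive")
  # identity k7 * f = fk7 across random inputs
  set.seed(2)
  for (i in 1:10) {
    fk <- runif(1, 1e5, 5e6); f <- runif(1, 5, 60)
    rr <- k7_from(fk, f)
    expect_equal(rr$k7 * rr$f_stoich, rr$fk7)
  }
})

test_that("rate tables validate their structure", {
  expect_error(rate_table(c(1e-6, 2e-6), c(1e-6, 2e-6)), "conc = 0")
  expect_error(rate_table(c(0, 1e-6), c(1e-6, -1)), "> 0")
  expect_warning(rate_table(c(0, 1e-6, 2e-6), c(2e-6, 1.2e-6, 1.5e-6)),
                 "monoton")
})

test_that("full kinetic chain on bundled data matches the reported logk7", {
  ref <- ao_reference()
  res1 <- determine_k7(ao_rate_table("AO1"), ref$AO1$f, f_se = ref$AO1$f_se)
  expect_equal(round(res1$logk7, 2), 4.64)
  res2 <- k7_from(ref$AO2$fk7, ref$AO2$f, ref$AO2$fk7_se, ref$AO2$f_se)
  expect_equal(round(res2$logk7, 2), 4.43)
})
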