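test_that("net release rate follows the closed-chamber sign convention", {
  expect_equal(net_release_rate(73.5, 75.5, 4.8, 10), 0.96)
  expect_equal(net_release_rate(100, 100, 4.8, 10), 0)
  expect_lt(net_release_rate(100, 95, 4.8, 10), 0)  # net uptake
  expect_error(net_release_rate(1, 2, 0, 10), "invalid geometry")
  expect_error(net_release_rate(1, 2, 4.8, -1), "invalid geometry")
})

test_that("flux pipeline is linear in concentrations", {
  set.seed(6)
  for (i in 1:10) {
    cs <- runif(1, 10, 100); ce <- runif(1, 10, 100); k <- runif(1, 0.5, 3)
    expect_equal(net_release_rate(k * cs, k * ce, 4.8, 10),
                 k * net_release_rate(cs, ce, 4.8, 10))
  }
})

test_that("refill correction is an exact mixing balance", {
  expect_equal(refill_corrected_start(100, 50, 1, 4.8),
               100 * (3.8 / 4.8) + 50 / 4.8)
  expect_equal(refill_corrected_start(100, 50, 0, 4.8), 100)
  expect_equal(refill_corrected_start(80, 80, 2, 4.8), 80)
  expect_error(refill_corrected_start(100, 50, 4.8, 4.8), "invalid refill")
  expect_error(refill_corrected_start(100, 50, -1, 4.8), "invalid refill")
})

test_that("refill correction is a convex combination of its inputs", {
  set.seed(7)
  for (i in 1:50) {
    cm <- runif(1, 0, 200); cr <- runif(1, 0, 200)
    v <- runif(1, 1, 10); rv <- runif(1, 0, v * 0.999)
    out <- refill_corrected_start(cm, cr, rv, v)
    expect_gte(out, min(cm, cr) - 1e-12)
    expect_lte(out, max(cm, cr) + 1e-12)
  }
})

test_that("oxygen consumption equals the least-squares slope", {
  t <- seq(0, 10, by = 0.5)
  fit <- oxygen_consumption_rate(t, 300 - 10 * t, volume = 1.3)
  expect_equal(fit$rate, 13)
  expect_equal(fit$r_squared, 1)
  expect_equal(oxygen_consumption_rate(t, rep(250, length(t)), 1.3)$rate, 0)
  expect_error(oxygen_consumption_rate(c(0, 1), c(1, 2), 1),
               "insufficient series")
  expect_error(oxygen_consumption_rate(c(0, 0, 0), c(1, 2, 3), 1),
               "insufficient series")
})

test_that("noisy O2 series matches the closed-form OLS slope", {
  set.seed(8)
  t <- seq(0, 8, by = 0.25)
  y <- 310 - 4.2 * t + rnorm(length(t), 0, 1.5)
  slope_hand <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  fit <- oxygen_consumption_rate(t, y, volume = 4.8)
  expect_equal(fit$rate, -slope_hand * 4.8, tolerance = 1e-10)
})

test_that("respiratory quotient converts O2 to C rates", {
  expect_equal(respiration_from_oxygen(13), 13)       # RQ = 1 identity
  expect_equal(respiration_from_oxygen(0), 0)
  cst <- iso_constants(respiratory_quotient = 0.8)
  expect_equal(respiration_from_oxygen(10, cst), 8)
})

test_that("tracer release is zero without isotope change", {
  # no concentration or delta change
  expect_equal(tracer_release_rate(100, 100, -20, -20, 4.8, 10, 0.25), 0)
  # end delta at the start-sample background with changed concentration:
  # all added carbon is unlabelled
  expect_equal(tracer_release_rate(100, 150, -20, -20, 4.8, 10, 0.25), 0)
  expect_error(tracer_release_rate(100, 150, NA, -20, 4.8, 10, 0.25),
               "missing isotope")
})

test_that("tracer release recovers a constructed enrichment exactly", {
  cst <- iso_constants()
  vol <- 4.8; dur <- 10; fsub <- 0.955
  d_bg <- 0.5; c_end <- 2170
  true_rate <- 0.31  # umol substrate C / h
  e_end <- true_rate * fsub * dur
  f_end <- delta_to_atom_fraction(d_bg, cst) + e_end / (c_end * vol)
  d_end <- atom_fraction_to_delta(f_end, cst)
  got <- tracer_release_rate(2150, c_end, d_bg, d_end, vol, dur, fsub,
                             constants = cst)
  expect_equal(got, true_rate, tolerance = 1e-9)
})

test_that("control correction subtracts the control mean", {
  expect_equal(control_corrected(5, c(0, 0)), 5)
  expect_equal(control_corrected(5, c(1, 3)), 3)
  expect_equal(control_corrected(1, c(2, 2)), -1)  # apparent uptake
  expect_warning(out <- control_corrected(5, numeric(0)), "no control")
  expect_equal(out, 5)
})

test_that("biomass standardization has the budget units", {
  expect_equal(standardize_to_biomass(2, 0.02), 100)
  expect_equal(standardize_to_biomass(0, 0.5), 0)
  expect_equal(standardize_to_biomass(3, 0.2),
               standardize_to_biomass(3, 0.1) / 2)
  expect_error(standardize_to_biomass(1, 0), "invalid biomass")
})

test_that("POC filter subsamples pool into carbon-weighted values", {
  out <- pool_poc_filters(c_umol = c(10, 30), volume_l = c(1, 2),
                          d13c = c(-20, -10))
  expect_equal(out$concentration_um, 40 / 3)
  expect_equal(out$d13c, (-20 * 10 - 10 * 30) / 40)
  one <- pool_poc_filters(5, 2, -15)
  expect_equal(one$concentration_um, 2.5)
  expect_equal(one$d13c, -15)
})
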