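test_that("delta to atom fraction matches frozen high-precision values", {
  # reference values evaluated with arbitrary-precision arithmetic
  expect_equal(delta_to_atom_fraction(0), 0.0111802 / 1.0111802,
               tolerance = 1e-12)
  frozen <- c(`-50` = 0.0105095659037191,
              `0` = 0.0110565851665213,
              `500` = 0.0164936957737652,
              `1000` = 0.0218713479121453,
              `5000` = 0.0628641944024503)
  expect_equal(
    unname(delta_to_atom_fraction(as.numeric(names(frozen)))),
    unname(frozen), tolerance = 1e-12)
})

test_that("delta to atom fraction is monotone and respects its domain", {
  d <- seq(-999, 10000, length.out = 400)
  f <- delta_to_atom_fraction(d)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f < 1))
  # limit: F -> 0 as delta -> -1000
  expect_lt(delta_to_atom_fraction(-1000 + 1e-9), 1e-10)
  expect_error(delta_to_atom_fraction(-1000), "invalid delta")
  expect_error(delta_to_atom_fraction(-1500), "invalid delta")
})

test_that("atom fraction to delta inverts the forward conversion", {
  cst <- iso_constants()
  expect_equal(atom_fraction_to_delta(cst$r_vpdb / (1 + cst$r_vpdb)), 0,
               tolerance = 1e-9)
  # diatom batch: closed-form inversion checked by forward re-substitution
  d_diatom <- atom_fraction_to_delta(0.292)
  expect_equal(d_diatom, 35889.2666080279, tolerance = 1e-10)
  expect_equal(delta_to_atom_fraction(d_diatom), 0.292, tolerance = 1e-12)
  expect_error(atom_fraction_to_delta(0), "invalid fraction")
  expect_error(atom_fraction_to_delta(1), "invalid fraction")
})

test_that("delta <-> atom fraction round trip is identity to 1e-9 per-mil", {
  deltas <- seq(-900, 10000, length.out = 1000)
  back <- atom_fraction_to_delta(delta_to_atom_fraction(deltas))
  expect_lt(max(abs(back - deltas)), 1e-9)
})

test_that("excess 13C follows the mass-balance definition", {
  expect_equal(excess_carbon13(0.030, 0.011, 100), 1.9)
  expect_equal(excess_carbon13(0.02, 0.02, 500), 0)
  expect_equal(excess_carbon13(0.5, 0.1, 0), 0)
  expect_error(excess_carbon13(0.03, 0.01, -1), "invalid amount")
  # antisymmetric under swapping sample and background
  expect_warning(
    e_rev <- excess_carbon13(0.011, 0.030, 100), "negative excess")
  expect_equal(e_rev, -1.9)
})

test_that("excess 13C is linear in the pool size", {
  set.seed(4)
  for (i in 1:20) {
    fs <- runif(1, 0.02, 0.9); fb <- runif(1, 0, fs); c0 <- runif(1, 1, 1e4)
    k <- runif(1, 0.1, 10)
    expect_equal(excess_carbon13(fs, fb, k * c0),
                 k * excess_carbon13(fs, fb, c0))
  }
})

test_that("tracer carbon divides excess 13C by the substrate fraction", {
  expect_equal(tracer_carbon(1.9, 0.95), 2)
  expect_equal(tracer_carbon(3.7, 1), 3.7)
  expect_equal(tracer_carbon(0, 0.25), 0)
  expect_error(tracer_carbon(1, 0), "invalid substrate fraction")
  expect_error(tracer_carbon(1, -0.2), "invalid substrate fraction")
  # scales linearly in C and inversely in F_substrate
  set.seed(5)
  for (i in 1:20) {
    fs <- runif(1, 0.3, 0.9); fb <- runif(1, 0.01, 0.2)
    c0 <- runif(1, 1, 1e3); fsub <- runif(1, 0.2, 1)
    expect_equal(tracer_carbon(excess_carbon13(fs, fb, c0), fsub),
                 (fs - fb) * c0 / fsub)
  }
})

test_that("constants are validated and overridable", {
  expect_error(iso_constants(r_vpdb = 0), "r_vpdb")
  expect_error(iso_constants(respiratory_quotient = -1),
               "respiratory_quotient")
  cst <- iso_constants(r_vpdb = 0.012)
  expect_equal(delta_to_atom_fraction(0, cst), 0.012 / 1.012)
})
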