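test_that("the generator is deterministic given seed and config", {
  cfg <- sim_config(seed = 21, n_animals_per_group = 2)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1, s2)
  f1 <- simulate_food_chain(cfg)
  expect_identical(f1, simulate_food_chain(cfg))
  s3 <- simulate_experiment(sim_config(seed = 22, n_animals_per_group = 2))
  expect_false(identical(s1$incubations$dic_end_um,
                         s3$incubations$dic_end_um))
})

test_that("generated O2 never drops below the saturation floor", {
  cfg <- sim_config(seed = 23, n_animals_per_group = 4)
  sim <- simulate_experiment(cfg)
  floor_um <- cfg$o2_saturation_min * cfg$ambient$o2_saturation_um
  # pre-noise floor: allow the measurement noise margin
  expect_gt(min(sim$o2_series$o2_um), floor_um - 5 * cfg$noise$o2_sd)
})

test_that("an infeasible design is rejected with the offending pool named", {
  taxa <- default_taxa()
  taxa$respiration <- c(6000, 6000, 6000)  # would breach the O2 floor
  expect_error(
    simulate_experiment(sim_config(seed = 24, taxa = taxa)),
    "infeasible design: O2")
  expect_error(sim_config(taxa = within(default_taxa(),
                                        doc_release <- -5)),
               "rates must be >= 0")
})

test_that("substrate depletion during feeding is capped with a warning", {
  taxa <- default_taxa()[1, ]
  taxa$incorporation <- 500  # demand far above the bacteria supply
  cfg <- sim_config(seed = 25, taxa = taxa,
                    substrates = default_substrates()[2, ],
                    noise = zero_noise())
  warns <- capture_warnings(sim <- simulate_experiment(cfg))
  expect_true(any(grepl("substrate depleted", warns)))
  out <- suppressWarnings(run_pipeline(sim))
  expect_true(all(out$incorporation$pct_of_provided <= 100 + 1e-9))
})

test_that("zero-noise simulation is inverted exactly by the pipeline", {
  cfg <- sim_config(seed = 26, n_animals_per_group = 2,
                    noise = zero_noise())
  sim <- simulate_experiment(cfg)
  rec <- recovery_table(run_pipeline(sim)$budget, sim$ground_truth)
  expect_lt(max(abs(rec$rel_error)), 1e-9)
  fc <- simulate_food_chain(cfg)
  expect_equal(estimate_transfer_efficiency(fc$foodchain), 37,
               tolerance = 1e-12)
})

test_that("a fully transferred food chain conserves the 13C pool", {
  cfg <- sim_config(seed = 27, noise = zero_noise())
  cfg$foodchain$true_transfer_efficiency <- 100
  fc <- simulate_food_chain(cfg)
  fecal <- sum(fc$foodchain$excess_13c_umol[fc$foodchain$pool == "fecal"])
  tissue <- sum(fc$foodchain$excess_13c_umol[fc$foodchain$pool == "tissue"])
  expect_equal(tissue, fecal, tolerance = 1e-12)
})

test_that("noisy food-chain replicates recover the efficiency on average", {
  effs <- vapply(1:30, function(s) {
    fc <- simulate_food_chain(sim_config(seed = 100 + s))
    estimate_transfer_efficiency(fc$foodchain)
  }, 1.0)
  expect_lt(abs(mean(effs) - 37), 2)
})

test_that("null experiments give control-corrected rates centered on zero", {
  taxa <- default_taxa()
  taxa[, c("respiration", "poc_release", "doc_release",
           "incorporation")] <- 0
  cfg <- sim_config(seed = 28, n_animals_per_group = 32, n_controls = 2,
                    taxa = taxa)
  sim <- simulate_experiment(cfg)   # 6 conditions x 34 = 204 chambers
  fx <- compute_fluxes(sim)
  an <- fx$animals
  for (q in c("respiration_total", "doc_total", "poc_total")) {
    # the control mean is shared within a condition, so the standard error
    # of the grand mean carries both the animal and the control terms
    cond_means <- tapply(an[[q]], an$condition, mean)
    sd_a <- sd(an[[q]])
    n_cond <- length(cond_means)
    se <- sd_a * sqrt(1 / nrow(an) + 1 / (cfg$n_controls * n_cond))
    expect_lt(abs(mean(cond_means)), 2 * se)
  }
})
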