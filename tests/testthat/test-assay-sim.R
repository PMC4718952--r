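test_that("degradation follows first-order decay with calibrated rates", {
  expect_equal(degradation_remaining("heroin", Inf, t = 0), 1)
  # spontaneous hydrolysis in buffer: 79.9 % intact at 24 h by calibration
  expect_equal(degradation_remaining("heroin", Inf, t = 24), 0.799)
  # morphine is stable at >= 1:100 dilutions
  expect_equal(degradation_remaining("morphine", 400, t = 24), 1)
  expect_equal(degradation_remaining("morphine", 100, t = 24), 1)
  # but not below
  expect_lt(degradation_remaining("morphine", 25, t = 24), 1)
  # 6-AM: stable at >= 1:200, degrading below, serum rate scales with 1/dilution
  expect_equal(degradation_remaining("6-am", 200, t = 24), 1)
  r50 <- degradation_remaining("6-am", 50, t = 24)
  r25 <- degradation_remaining("6-am", 25, t = 24)
  expect_lt(r25, r50)
  expect_equal(log(r50), log(r25) / 2, tolerance = 1e-12)
  # heroin in serum is destroyed at any practical dilution
  expect_lt(degradation_remaining("heroin", 400, t = 24), 0.05)
  expect_error(degradation_remaining("oxycodone", 400),
               class = "dialyzr_invalid")
})

test_that("esterase inhibitors reduce heroin decay to its buffer rate", {
  with_inh <- degradation_remaining("heroin", 400,
                                    esterase_inhibitors = TRUE, t = 24)
  buffer_only <- degradation_remaining("heroin", Inf, t = 24)
  expect_equal(log(with_inh), log(buffer_only), tolerance = 1e-12)
  # morphine is not an ester: inhibitors do not rescue it
  expect_equal(degradation_remaining("morphine", 25, TRUE, 24),
               degradation_remaining("morphine", 25, FALSE, 24))
})

test_that("passive time course relaxes to the 50/50 concentration split", {
  sys <- binding_system(0, tracer_ligand(kd_site = Inf))
  tc <- simulate_timecourse(sys, times = c(0, 6, 24))
  w <- tidyr::pivot_wider(tc[, c("time_h", "chamber", "conc_nM")],
                          names_from = "chamber", values_from = "conc_nM")
  # t = 0: everything still in the loaded chamber
  expect_equal(w$sample[w$time_h == 0], 5)
  expect_equal(w$buffer[w$time_h == 0], 0)
  # default permeability closes >= 99 % of the free-concentration gap by 6 h
  # (closed form: the chamber difference decays as exp(-permeability * t))
  diff6 <- w$sample[w$time_h == 6] - w$buffer[w$time_h == 6]
  expect_lt(abs(diff6), 5 * 0.0101)
  expect_equal(diff6, 5 * exp(-log(100) / 6 * 6), tolerance = 1e-3)
  # 24 h: equilibrated
  pct24 <- percent_drug(w$sample[w$time_h == 24], w$buffer[w$time_h == 24])
  expect_equal(pct24, 50, tolerance = 1e-4)
  expect_error(simulate_timecourse(sys, permeability = -1),
               class = "dialyzr_invalid")
})

test_that("time course converges to the equilibrium solver's state", {
  sys <- monoclonal_system(inhibitor_amount = 1000)
  tc <- simulate_timecourse(sys, times = 48)
  eq <- solve_equilibrium(sys)
  tr <- tc[tc$analyte == "d3-morphine", ]
  expect_equal(tr$conc_nM[tr$chamber == "sample"],
               eq$total_tracer_sample, tolerance = 1e-4)
  expect_equal(tr$conc_nM[tr$chamber == "buffer"],
               eq$total_tracer_buffer, tolerance = 1e-4)
  inh <- tc[tc$analyte == "morphine", ]
  expect_equal(inh$conc_nM[inh$chamber == "sample"],
               eq$total_inhibitor_sample, tolerance = 1e-4)
})

test_that("dataset generation is seed-reproducible and noise-faithful", {
  des <- assay_design(site_conc = 3, tracer_kd = 2, inhibitor_kd = 2,
                      seed = 11)
  d1 <- generate_dataset(des)
  d2 <- generate_dataset(des)
  expect_identical(d1, d2)
  d3 <- generate_dataset(assay_design(site_conc = 3, tracer_kd = 2,
                                      inhibitor_kd = 2, seed = 12))
  expect_false(identical(d1$conc_nM, d3$conc_nM))

  # noiseless negative control: the passive 1.25 nM split in every row
  d0 <- generate_dataset(assay_design(site_conc = 0, noise_cv = 0,
                                      inhibitor_amounts = numeric(0),
                                      seed = 1))
  expect_true(all(abs(d0$conc_nM - 1.25) < 1e-12))

  # noiseless monoclonal condition: downstream b matches the solver
  dm <- generate_dataset(assay_design(site_conc = 2.4, tracer_kd = 2,
                                      inhibitor_kd = 2, noise_cv = 0,
                                      inhibitor_amounts = numeric(0),
                                      seed = 1))
  z <- dm[dm$condition_id == "test_I00" & dm$replicate == 1, ]
  b <- compute_b(z$conc_nM[z$chamber == "sample"],
                 z$conc_nM[z$chamber == "buffer"])
  expect_equal(b, 0.44, tolerance = 2e-3)
})

test_that("multiplicative lognormal noise is unbiased at 2 % CV", {
  d <- generate_dataset(assay_design(site_conc = 0, noise_cv = 0.02,
                                     inhibitor_amounts = numeric(0),
                                     replicates = 10000, seed = 99))
  m <- mean(d$conc_nM[d$condition_id == "test_I00" & d$chamber == "sample"])
  expect_lt(abs(m / 1.25 - 1), 0.005)
})

test_that("generated datasets carry the tidy schema and row structure", {
  des <- assay_design(site_conc = 3, tracer_kd = 2, inhibitor_kd = 2,
                      replicates = 3, seed = 5)
  d <- generate_dataset(des)
  expect_s3_class(d, "measured_dataset")
  expect_named(d, c("condition_id", "inhibitor_level_nM", "chamber",
                    "analyte", "replicate", "conc_nM", "dilution",
                    "esterase_inhibitors"))
  # tracer rows: one per condition x chamber x replicate
  tr <- d[d$analyte == "d3-morphine", ]
  n_cond <- length(unique(d$condition_id))
  expect_equal(nrow(tr), n_cond * 2 * 3)
  expect_true(all(d$conc_nM >= 0))
})
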