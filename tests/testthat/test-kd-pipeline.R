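test_that("chamber arithmetic: percent drug, remaining, b, Tt, inhibition", {
  expect_equal(percent_drug(1, 1), 50)
  expect_equal(percent_drug(3, 1), 75)
  expect_equal(percent_drug(1.864, 1.042), 64.14, tolerance = 1e-4)
  expect_equal(percent_drug(3, 1, chamber = "buffer"), 25)
  expect_error(percent_drug(0, 0), class = "dialyzr_invalid")

  expect_equal(percent_remaining(4, 5), 80)
  expect_equal(percent_remaining(5, 5), 100)
  expect_equal(percent_remaining(0, 5), 0)
  expect_error(percent_remaining(1, 0), class = "dialyzr_invalid")

  expect_equal(compute_b(2, 2), 0)
  expect_equal(compute_b(2, 0), 1)
  expect_equal(compute_b(1.864, 1.042), 0.441, tolerance = 1e-3)
  expect_warning(b <- compute_b(1, 1.1), "clamped")
  expect_equal(b, 0)
  expect_error(compute_b(0, 1), class = "dialyzr_invalid")

  expect_equal(compute_tt(1.7, 1.7), 1.7)
  expect_equal(compute_tt(1.864, 1.042), 1.2475)
  expect_error(compute_b(-1, 0), class = "dialyzr_invalid")

  expect_equal(percent_inhibition(0.82, 0.82), 0)
  expect_equal(percent_inhibition(0, 0.82), 100)
  expect_equal(percent_inhibition(0.41, 0.82), 50)
  expect_warning(p <- percent_inhibition(0.9, 0.82), "clamped")
  expect_equal(p, 0)
  expect_error(percent_inhibition(0.1, 0), class = "dialyzr_invalid")
})

test_that("percent bound heroin is compute_b expressed as a percentage", {
  expect_equal(percent_bound_heroin(2, 1), 50)
  expect_equal(percent_bound_heroin(2, 2), 0)
  expect_equal(percent_bound_heroin(1.864, 1.042), 44.1, tolerance = 1e-3)
  cs <- runif(20, 1, 3)
  cb <- runif(20, 0.5, 1)
  expect_equal(percent_bound_heroin(cs, cb), 100 * compute_b(cs, cb))
})

test_that("I50 interpolation is log-linear with first-ascending-crossing", {
  expect_equal(interpolate_i50(inhibition_curve(c(5, 50), c(50, 80))), 5)
  expect_equal(interpolate_i50(inhibition_curve(c(10, 100), c(40, 60))),
               31.6227766, tolerance = 1e-8)
  expect_error(interpolate_i50(inhibition_curve(c(10, 100), c(10, 30))),
               class = "dialyzr_i50_error")
  # the zero level anchors the curve but cannot enter the log grid
  expect_equal(interpolate_i50(inhibition_curve(c(0, 10, 100), c(0, 40, 60))),
               31.6227766, tolerance = 1e-8)
  # multiple crossings: the first ascending one wins
  wavy <- inhibition_curve(c(1, 10, 100, 1000), c(40, 60, 45, 70))
  expect_equal(interpolate_i50(wavy),
               10^(0 + 10 / 20), tolerance = 1e-8)
})

test_that("binding classification applies the 5 % rules", {
  expect_equal(classify_binding(61.5, 3), "low_affinity")
  expect_equal(classify_binding(3, NA), "no_binding")
  expect_equal(classify_binding(61.5, 45), "quantifiable")
  expect_equal(classify_binding(9.1, 2), "low_affinity")
  expect_equal(classify_binding(4.9, 50), "no_binding")
})

test_that("stability gate passes only near-intact analytes", {
  expect_equal(stability_gate(1.0), "pass")
  expect_equal(stability_gate(0.799), "fail")
  expect_equal(stability_gate(0.95), "pass")
  expect_equal(stability_gate(0.95, threshold = 0.99), "fail")
})

test_that("Mueller-consistent data are recovered exactly (self-consistency)", {
  for (case in list(c(2, 0.5, 1.25), c(0.5, 0.41, 1.25), c(5, 0.7, 1.1))) {
    kd <- case[1]; b <- case[2]; tt <- case[3]
    d <- muller_consistent_dataset(kd, b, tt)
    est <- estimate_kd(d, scale = "buffer-initial")
    expect_equal(est$b, b, tolerance = 1e-12)
    expect_equal(est$tt, tt, tolerance = 1e-12)
    expect_equal(est$i50, kd / correction_factor(b) + tt, tolerance = 1e-10)
    expect_equal(est$kd, kd, tolerance = 1e-9)
    expect_equal(est$kd_sd, 0, tolerance = 1e-12)
    expect_equal(est$classification, "quantifiable")
  }
})

test_that("per-replicate and pooled estimates coincide on noiseless data", {
  d <- muller_consistent_dataset(2, 0.5, 1.25)
  a <- estimate_kd(d, method = "per-replicate", scale = "buffer-initial")
  b <- estimate_kd(d, method = "pooled", scale = "buffer-initial")
  expect_equal(a$kd, b$kd, tolerance = 1e-10)
  expect_equal(a$b, b$b, tolerance = 1e-12)
})

test_that("mechanistic noiseless data give a Kd within a factor of 2", {
  des <- assay_design(site_conc = site_conc_for_b(0.5, 2), tracer_kd = 2,
                      inhibitor_kd = 2, noise_cv = 0, seed = 1)
  est <- estimate_kd(generate_dataset(des))
  expect_gt(est$kd, 1)
  expect_lt(est$kd, 4)
  expect_equal(est$qc_b_window, "pass")
})

test_that("b outside the 0.4-0.7 window is flagged but still quantified", {
  # steer b to ~0.94 as in the strongest monoclonal condition
  s <- site_conc_for_b(0.94, 2)
  des <- assay_design(site_conc = s, tracer_kd = 2, inhibitor_kd = 2,
                      noise_cv = 0, seed = 1)
  est <- estimate_kd(generate_dataset(des))
  expect_equal(est$b, 0.94, tolerance = 1e-6)
  expect_equal(est$qc_b_window, "fail")
  expect_equal(est$classification, "quantifiable")
  expect_false(is.na(est$kd))
  # the out-of-window condition shows the documented strong low bias
  expect_lt(est$kd, 2)
})

test_that("negative-control-style data classify as no binding", {
  des <- assay_design(site_conc = 0, tracer_kd = 2, inhibitor_kd = 2,
                      noise_cv = 0, seed = 1)
  est <- suppressWarnings(estimate_kd(generate_dataset(des)))
  expect_lt(100 * est$b, 5)
  expect_equal(est$classification, "no_binding")
  expect_true(is.na(est$kd))
})

test_that("estimation demands a zero-inhibitor condition", {
  d <- generate_dataset(assay_design(site_conc = 3, tracer_kd = 2,
                                     inhibitor_kd = 2, seed = 1))
  d2 <- d[d$inhibitor_level_nM > 0 | grepl("^neg", d$condition_id), ]
  class(d2) <- class(d)
  expect_error(estimate_kd(d2), class = "dialyzr_invalid")
})

test_that("Kd estimates are stable to 2 % replicate noise", {
  s <- site_conc_for_b(0.5, 2)
  kds <- vapply(1:200, function(i) {
    d <- generate_dataset(assay_design(site_conc = s, tracer_kd = 2,
                                       inhibitor_kd = 2, noise_cv = 0.02,
                                       replicates = 3, seed = 1000 + i))
    suppressWarnings(estimate_kd(d)$kd)
  }, numeric(1))
  expect_true(all(is.finite(kds)))
  expect_lt(stats::sd(kds) / mean(kds), 0.15)
})

test_that("tidy and glance summarize a kd_estimate", {
  d <- muller_consistent_dataset(2, 0.5, 1.25)
  est <- estimate_kd(d, scale = "buffer-initial")
  td <- tidy(est)
  expect_equal(nrow(td), 1)
  expect_equal(td$kd_nM, 2, tolerance = 1e-9)
  expect_equal(td$classification, "quantifiable")
  gl <- glance(est)
  expect_equal(gl$n, 3)
  expect_equal(gl$qc_b_window, "pass")
})
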