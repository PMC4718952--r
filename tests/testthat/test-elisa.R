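test_that("4PL fitting recovers noiseless generating parameters exactly", {
  for (pars in list(c(1, 1), c(0.25, 1.6), c(10, 0.7))) {
    d <- simulate_elisa_curve(ic50_true = pars[1], hill = pars[2],
                              noise_cv = 0)
    fit <- fit_4pl(d)
    expect_true(fit$converged)
    expect_equal(fit$ic50, pars[1], tolerance = 1e-6)
    expect_equal(fit$hill, pars[2], tolerance = 1e-5)
    expect_equal(fit$top, 100, tolerance = 1e-5)
  }
})

test_that("the IC50 estimate is scale-equivariant", {
  d <- simulate_elisa_curve(1, noise_cv = 0.02, seed = 21)
  base <- fit_4pl(d)$ic50
  d10 <- dplyr::mutate(d, level_uM = level_uM * 10)
  expect_equal(fit_4pl(d10)$ic50, 10 * base, tolerance = 1e-6)
})

test_that("noisy seeded curves recover IC50 within 10 %", {
  d <- simulate_elisa_curve(1, noise_cv = 0.02, n_replicates = 3, seed = 7)
  fit <- fit_4pl(d)
  expect_lt(abs(fit$ic50 - 1), 0.1)
})

test_that("flat responses are flagged as no inhibition", {
  d <- tibble::tibble(level_uM = 10^seq(-2, 1.5, 0.5),
                      response_pct = 100)
  fit <- fit_4pl(d)
  expect_true(fit$no_inhibition)
  expect_true(is.na(fit$ic50))
  expect_error(fit_4pl(tibble::tibble(level_uM = c(1, 2, 3),
                                      response_pct = c(90, 50, 10))),
               class = "dialyzr_invalid")
  expect_error(fit_4pl(tibble::tibble(level_uM = c(0, 1, 2, 3, 4),
                                      response_pct = c(100, 90, 50, 10, 0))),
               class = "dialyzr_invalid")
})

test_that("ELISA curve simulation is seeded and unbiased", {
  a <- simulate_elisa_curve(1.1, seed = 5)
  b <- simulate_elisa_curve(1.1, seed = 5)
  expect_identical(a, b)

  exact <- simulate_elisa_curve(1.1, noise_cv = 0)
  mu <- unique(exact$response_pct[exact$level_uM == exact$level_uM[1]])
  expect_equal(length(mu), 1)

  # law of large numbers at one level across 100 seeds
  lvl <- 1.1
  means <- vapply(1:100, function(s) {
    d <- simulate_elisa_curve(1.1, noise_cv = 0.02, seed = s,
                              levels = lvl, n_replicates = 3)
    mean(d$response_pct)
  }, numeric(1))
  noiseless <- simulate_elisa_curve(1.1, noise_cv = 0,
                                    levels = lvl)$response_pct[1]
  expect_lt(abs(mean(means) / noiseless - 1), 0.01)
})

test_that("IC50/Kd ratios reproduce the printed-table gap", {
  rep <- ic50_kd_ratio()
  r6am <- rep$ratio[rep$serum == "6-AcMorHap" & rep$drug == "6-AM"]
  expect_equal(r6am, 1.1 * 1e3 / 0.563, tolerance = 1e-9)
  expect_gt(r6am, 1e3)
  morhap <- rep$ratio[rep$serum == "MorHap" & rep$drug == "morphine"]
  expect_gt(morhap, 1e3)
  # every quantifiable, uncensored pair sits 2-4 orders of magnitude high
  ok <- rep[rep$status == "ok", ]
  expect_true(all(ok$ratio > 1e2 & ok$ratio < 1e4))
})

test_that("censored or classified entries never yield a ratio", {
  rep <- ic50_kd_ratio()
  bad <- rep[rep$censored | rep$classification != "quantifiable", ]
  expect_gt(nrow(bad), 0)
  expect_true(all(is.na(bad$ratio)))
  expect_true(all(bad$status == "not_computable"))

  # equal affinities give a unit ratio
  kd <- tibble::tibble(serum = "x", drug = "d", kd_nM = 1,
                       classification = "quantifiable")
  ic <- tibble::tibble(serum = "x", drug = "d", ic50_uM = 1e-3,
                       censored = FALSE)
  expect_equal(ic50_kd_ratio(kd, ic)$ratio, 1)
})

test_that("packaged reference tables carry the expected structure", {
  t1 <- ed_monoclonal_affinity()
  expect_equal(nrow(t1), 5)
  in_window <- t1[t1$b >= 0.4 & t1$b <= 0.7, ]
  expect_equal(nrow(in_window), 1)
  expect_equal(in_window$kd_nM, 1.96)

  t2 <- ed_serum_kd()
  expect_equal(nrow(t2), 10)
  expect_true(all(is.na(t2$kd_nM[t2$classification != "quantifiable"])))

  t3 <- elisa_titer_ic50()
  expect_equal(nrow(t3), 15)
  expect_true(all(is.na(t3$ic50_uM[t3$censored])))
  expect_true(all(!is.na(t3$ic50_uM[!t3$censored])))
})
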