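test_that("without antibody the tracer splits passively over the insert", {
  sys <- binding_system(0, tracer_ligand(kd_site = 2))
  st <- solve_equilibrium(sys)
  expect_equal(st$free_tracer, 1.25)
  expect_equal(st$bound_tracer, 0)
  expect_equal(st$total_tracer_sample, st$total_tracer_buffer)

  # a vanishingly weak binder is numerically a non-binder
  weak <- binding_system(2.4, tracer_ligand(kd_site = 1e9))
  stw <- solve_equilibrium(weak)
  expect_equal(stw$free_tracer, 1.25, tolerance = 1e-6)
  expect_lt(stw$bound_tracer, 1e-6)
})

test_that("the monoclonal worked case matches the 1-D mass-balance root", {
  f_ref <- ref_free_tracer(2.4, 2)        # independent uniroot on the balance
  st <- solve_equilibrium(monoclonal_system(inhibitor_amount = NULL))
  expect_equal(st$free_tracer, f_ref, tolerance = 1e-9)
  expect_equal(st$free_tracer, 1.044193, tolerance = 1e-6)
  expect_equal(st$bound_tracer, 0.8232275, tolerance = 1e-6)

  b <- compute_b(st$total_tracer_sample, st$total_tracer_buffer)
  expect_equal(b, 0.4408, tolerance = 1e-3)
  # mass conservation makes Tt exactly amount / total volume
  tt <- compute_tt(st$total_tracer_sample, st$total_tracer_buffer)
  expect_equal(tt, 1.25, tolerance = 1e-9)
})

test_that("solver and brute-force oracle agree over a sampled grid", {
  set.seed(101)
  for (i in 1:25) {
    site <- runif(1, 0, 50)
    sys <- binding_system(
      site,
      ligand("tracer", kd_site = 10^runif(1, -1, 2),
             amount = 10^runif(1, 1, 4), chamber = "sample"),
      inhibitor = ligand("inh", kd_site = 10^runif(1, -1, 2),
                         amount = 10^runif(1, 1, 4), chamber = "buffer"))
    a <- solve_equilibrium(sys)
    b <- oracle_equilibrium(sys)
    expect_equal(a$free_tracer, b$free_tracer, tolerance = 1e-6)
    expect_equal(a$free_inhibitor, b$free_inhibitor, tolerance = 1e-6)
    expect_equal(a$bound_tracer, b$bound_tracer, tolerance = 1e-6)
    # mass conservation to 1e-9 relative (the solver verifies, we assert)
    expect_lt(a$residual_tracer, 1e-9)
    expect_lt(a$residual_inhibitor, 1e-9)
  }
})

test_that("oracle respects the no-binder closed form and ligand symmetry", {
  sys <- binding_system(0, ligand("t", 2, 500, "sample"),
                        ligand("i", 2, 900, "buffer"))
  st <- oracle_equilibrium(sys)
  expect_equal(st$free_tracer, 500 / 400)
  expect_equal(st$free_inhibitor, 900 / 400)

  # equal Kd and equal amounts in the same chamber: bound equally
  sym <- binding_system(5, ligand("t", 2, 500, "sample"),
                        ligand("i", 2, 500, "sample"))
  sts <- oracle_equilibrium(sym)
  expect_equal(sts$bound_tracer, sts$bound_inhibitor, tolerance = 1e-9)
})

test_that("bound tracer falls with inhibitor and b rises with antibody", {
  amounts <- c(0, 10^seq(2, 5, by = 0.5))
  bound <- vapply(amounts, function(a) {
    solve_equilibrium(monoclonal_system(inhibitor_amount = a))$bound_tracer
  }, numeric(1))
  expect_true(all(diff(bound) < 0))

  bs <- vapply(c(0.5, 1, 2, 4, 8, 16), function(s) {
    st <- solve_equilibrium(monoclonal_system(site_conc = s,
                                              inhibitor_amount = NULL))
    st$bound_tracer / st$total_tracer_sample
  }, numeric(1))
  expect_true(all(diff(bs) > 0))
})

test_that("correction factor follows 1 - 1.5b + 0.5b^2 on [0, 1]", {
  expect_identical(correction_factor(0), 1)
  expect_identical(correction_factor(1), 0)
  expect_equal(correction_factor(0.41), 0.46905)
  # algebraic identity (1 - b)(1 - b/2)
  b <- seq(0, 1, by = 0.05)
  expect_equal(correction_factor(b), (1 - b) * (1 - b / 2))
  expect_error(correction_factor(-0.1), class = "dialyzr_invalid")
  expect_error(correction_factor(1.2), class = "dialyzr_invalid")
})

test_that("Mueller's equation multiplies the excess I50 by the correction", {
  expect_equal(muller_kd(3.25, 1.25, 0), 2)
  expect_equal(muller_kd(1.25, 1.25, 0.3), 0)
  expect_equal(muller_kd(5.43, 1.25, 0.41), 4.18 * 0.46905)
  expect_warning(res <- muller_kd(1.0, 1.25, 0.5), "invalid")
  expect_true(is.na(res))
})

test_that("predicted inhibition curves start at zero and saturate", {
  sys <- monoclonal_system()
  curve <- predict_inhibition_curve(sys, c(0, 10^seq(1, 6, by = 0.5)))
  expect_equal(curve$pct_inhibition[1], 0)
  expect_gt(dplyr::last(curve$pct_inhibition), 99)
  expect_true(all(diff(curve$pct_inhibition) > 0))

  expect_error(predict_inhibition_curve(sys, c(10, 0)),
               class = "dialyzr_invalid")
  no_binding <- binding_system(0, tracer_ligand(kd_site = 2),
                               ligand("morphine", 2, 0, "buffer"))
  expect_error(predict_inhibition_curve(no_binding, c(0, 100)),
               class = "dialyzr_invalid")
})

test_that("self-competition curve crosses 50 % at the oracle-computed I50", {
  sys <- monoclonal_system()
  a50 <- oracle_i50_amount(sys)
  curve <- predict_inhibition_curve(sys, sort(unique(c(0, a50,
                                                       10^seq(1, 6, 0.5)))))
  at_a50 <- curve$pct_inhibition[curve$level_nM ==
                                   level_from_amount(a50)]
  expect_equal(at_a50, 50, tolerance = 1e-2)
})
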