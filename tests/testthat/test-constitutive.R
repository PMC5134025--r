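# Pointwise constitutive laws: Quemada rheology, clot porosity, switching
# functions, momentum sink, coagulant wall flux and bulk sources.

test_that("Quemada viscosity matches its closed-form limits and is monotone", {
  props <- fluid_props(mu_p = 1.2e-3, H = 0.45, k0 = 4.33, kinf = 2.07,
                       gamma_c = 1.88)
  # infinite-shear limit mu_p (1 - kinf H / 2)^-2, hand-evaluated
  mu_inf <- 1.2e-3 * (1 - 0.5 * 2.07 * 0.45)^-2
  expect_equal(mu_inf, 4.2043e-3, tolerance = 1e-4)
  expect_equal(quemada_viscosity(1e9, props), mu_inf, tolerance = 1e-4)
  # at the critical shear rate the intrinsic viscosity is (k0 + kinf)/2
  k_mid <- (4.33 + 2.07) / 2
  expect_equal(quemada_viscosity(1.88, props),
               1.2e-3 * (1 - 0.5 * k_mid * 0.45)^-2, tolerance = 1e-12)
  # no-cells limit
  expect_equal(quemada_viscosity(c(0.1, 10, 1000), fluid_props(H = 0)),
               rep(1.2e-3, 3))
  # strictly decreasing above the shear floor, bounded by the two limits
  g <- 10^seq(log10(props$gamma_min), 5, length.out = 200)
  mu <- quemada_viscosity(g, props)
  expect_true(all(diff(mu) < 0))
  expect_true(all(mu >= mu_inf & mu <= quemada_viscosity(0, props)))
  expect_error(quemada_viscosity(NaN, props), "finite")
  expect_error(quemada_viscosity(-1, props), "non-negative")
})

test_that("clot porosity spans [0.75, 1] with a linear ramp to BP_t", {
  p <- thrombosis_params()
  expect_identical(clot_porosity(0, p), 1)
  expect_identical(clot_porosity(20, p), 0.75)
  expect_identical(clot_porosity(200, p), 0.75)
  expect_identical(clot_porosity(10, p), 0.875)
  bp <- seq(0, 100, by = 0.5)
  eps <- clot_porosity(bp, p)
  expect_true(all(eps >= 0.75 & eps <= 1))
  expect_true(all(diff(eps) <= 0))
  expect_error(clot_porosity(-1, p), "non-negative")
})

test_that("switching functions partition to one and hit their midpoints", {
  expect_identical(switch_up(0, 10, 2), 0)
  expect_equal(switch_up(10, 10, 2), 0.5)
  expect_equal(switch_up(20, 20, 2), 0.5) # phi_BP at BP = BP_t
  x <- c(0, 0.1, 1, 5, 10, 50, 1e4)
  expect_equal(switch_up(x, 7, 2) + switch_down(x, 7, 2), rep(1, length(x)),
               tolerance = 1e-15)
  expect_true(all(diff(switch_up(x, 7, 2)) > 0))
  expect_true(all(switch_up(x, 7, 2) >= 0 & switch_up(x, 7, 2) <= 1))
  expect_error(switch_up(1, -1, 2), "positive")
})

test_that("momentum sink opposes flow, saturates at k_M and is odd in u", {
  p <- thrombosis_params()
  expect_identical(momentum_sink(0, 0.3, p), 0)
  expect_identical(momentum_sink(50, 0, p), 0)
  # saturation: BP >> BP_t, |u| = 1e-3 -> |S_M| ~ k_M * 1e-3 = 1e4
  s <- momentum_sink(1e4, 1e-3, p)
  expect_lt(abs(abs(s) - 1e4) / 1e4, 1e-5)
  expect_identical(momentum_sink(30, -0.2, p), -momentum_sink(30, 0.2, p))
  bp <- seq(0, 100, by = 5)
  expect_true(all(diff(abs(momentum_sink(bp, 0.1, p))) >= 0))
})

test_that("coagulant wall flux follows the TAWSS and BP shutoff gates", {
  p <- thrombosis_params()
  expect_identical(coagulant_wall_flux(0.05, 0, p), 20)
  expect_identical(coagulant_wall_flux(0.05, 250, p), 0)
  expect_identical(coagulant_wall_flux(0.5, 0, p), 0)
  expect_identical(coagulant_wall_flux(0.2, 0, p), 0)   # threshold is strict
  expect_identical(coagulant_wall_flux(0.199, 200, p), 20) # shutoff above 200
  tawss <- runif(100, 0, 0.5)
  bp <- runif(100, 0, 400)
  fx <- coagulant_wall_flux(tawss, bp, p)
  expect_true(all(fx[tawss >= 0.2 | bp > 200] == 0))
  expect_true(all(fx[tawss < 0.2 & bp <= 200] == 20))
  expect_error(coagulant_wall_flux(-0.1, 0, p), "non-negative")
})

test_that("coagulant bulk source produces in thrombus and consumes at high shear", {
  p <- thrombosis_params()
  expect_identical(coagulant_bulk_source(0, 0, 0, p), 0)
  # production saturates at k_c = 200 inside fully formed thrombus at rest
  expect_equal(coagulant_bulk_source(0, 1e4, 0, p), 200, tolerance = 1e-5)
  # consumption branch: negative and linear in C at high averaged shear
  r1 <- coagulant_bulk_source(5, 0, 500, p)
  r2 <- coagulant_bulk_source(10, 0, 500, p)
  expect_lt(r1, 0)
  expect_equal(r2 / r1, 2, tolerance = 1e-12)
  # hand value: -k_c * (C/C_t) * switch_up(500, 50, 2)
  expect_equal(r1, -200 * 0.5 * (100 / 101), tolerance = 1e-12)
})

test_that("bound-platelet formation is linear in activated platelets and shear-gated", {
  p <- thrombosis_params()
  expect_identical(bound_platelet_source(0, 1e3, 0, p), 0)
  r1 <- bound_platelet_source(0.5, 30, 10, p)
  r2 <- bound_platelet_source(1.0, 30, 10, p)
  expect_equal(r2 / r1, 2, tolerance = 1e-12)
  expect_identical(bound_platelet_source(1, 0, 0, p), 0)
  # switch_down(500, 50, 2) = 1/101 relative to zero shear
  ratio <- bound_platelet_source(1, 1e6, 500, p) /
    bound_platelet_source(1, 1e6, 0, p)
  expect_equal(ratio, 1 / 101, tolerance = 1e-9)
})

test_that("parameter containers validate their invariants", {
  expect_error(thrombosis_params(k_M = -1), "k_M")
  expect_error(thrombosis_params(eps_min = 0), "eps_min")
  expect_error(thrombosis_params(BP_complete = 10), "BP_complete")
  expect_error(fluid_props(H = 1.2), "H")
  expect_error(pas_params(PAS_0 = 1.5), "PAS_0")
  # Table-style defaults
  p <- thrombosis_params()
  expect_identical(c(p$k_c, p$k_c_wall, p$k_M, p$D_c, p$BP_t, p$gamma_t),
                   c(200, 20, 1e7, 1e-8, 20, 50))
  expect_identical(p$D_c_eff, 150 * 1e-8)
  expect_identical(c(p$tau_w_t, p$eps_min, p$BP_complete), c(0.2, 0.75, 200))
})
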