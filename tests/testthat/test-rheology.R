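test_that("Casson parameters derive from hematocrit as specified", {
  # threshold case: no yield stress at H = 0.1
  expect_identical(derive_casson_parameters(0.1)$yield_stress, 0)
  # closed-form arithmetic at H = 0.45
  b <- derive_casson_parameters(0.45, plasma_viscosity = 0.00145)
  expect_equal(b$yield_stress, 0.117 * 0.35^3, tolerance = 1e-12)
  expect_equal(b$casson_viscosity,
               0.00145 * (1 + 2.5 * 0.45 + 7.35 * 0.45^2), tolerance = 1e-12)
  # both parameters strictly increasing in hematocrit
  hs <- seq(0.15, 0.6, by = 0.05)
  ty <- vapply(hs, function(h) derive_casson_parameters(h)$yield_stress, 0)
  mc <- vapply(hs, function(h) derive_casson_parameters(h)$casson_viscosity, 0)
  expect_true(all(diff(ty) > 0))
  expect_true(all(diff(mc) > 0))
  expect_error(derive_casson_parameters(0.7), class = "aneuflow_rheology_error")
})

test_that("regularized effective viscosity matches its closed forms", {
  # Newtonian reduction: zero yield stress
  bn <- blood_properties(plasma_viscosity = 0.004, casson_viscosity = 0.004,
                         yield_stress = 0)
  g <- c(0, 0.01, 1, 100, 1e6)
  expect_equal(effective_viscosity(g, bn), rep(0.004, 5), tolerance = 1e-14)
  # unregularized Casson at moderate shear, regularization saturated
  b <- blood_properties(plasma_viscosity = 0.00145, casson_viscosity = 0.004,
                        yield_stress = 0.005, regularization_m = 1e4)
  mu100 <- effective_viscosity(100, b)
  expect_equal(mu100, (sqrt(0.005 / 100) + sqrt(0.004))^2, tolerance = 1e-3)
  # high-shear asymptote
  bm <- blood_properties(plasma_viscosity = 0.00145, casson_viscosity = 0.004,
                         yield_stress = 0.005, regularization_m = 100)
  expect_lt(abs(effective_viscosity(1e6, bm) - 0.004) / 0.004, 0.01)
  # finite continuous zero-shear limit
  mu0 <- effective_viscosity(0, bm)
  expect_equal(mu0, (sqrt(0.004) + sqrt(0.005 * 100))^2, tolerance = 1e-12)
  expect_equal(effective_viscosity(1e-30, bm), mu0, tolerance = 1e-6)
  expect_error(effective_viscosity(-1, bm), class = "aneuflow_domain_error")
})

test_that("shear-thinning and hematocrit-ordering properties hold", {
  gs <- 10^seq(-4, 5, length.out = 60)
  for (h in c(0.35, 0.425, 0.5)) {
    b <- derive_casson_parameters(h)
    mu <- effective_viscosity(gs, b)
    expect_true(all(diff(mu) <= 1e-15), label = sprintf("monotone at H=%g", h))
    expect_true(all(is.finite(mu)))
  }
  # fixed shear: viscosity non-decreasing in hematocrit
  for (g in c(0.1, 10, 1000)) {
    mus <- vapply(seq(0.35, 0.5, by = 0.025),
                  function(h) effective_viscosity(g, derive_casson_parameters(h)), 0)
    expect_true(all(diff(mus) >= 0), label = sprintf("HCT order at g=%g", g))
  }
})
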