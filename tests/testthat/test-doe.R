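four_factors <- function() list(
  factor_spec("sac_area", 11.65, 94.57, "mm^2"),
  factor_spec("parent_radius", 1.59, 2.24, "mm"),
  factor_spec("hct", 0.35, 0.5),
  factor_spec("porosity", 0.73, 0.96))

test_that("face-centered CCD has the canonical run count and layout", {
  d <- ccd_design(four_factors(), n_center = 1)
  expect_identical(nrow(d$coded_matrix), 25L)
  expect_true(all(d$coded_matrix %in% c(-1, 0, 1)))
  # block structure: 16 factorial, 8 axial, 1 center
  expect_true(all(abs(d$coded_matrix[1:16, ]) == 1))
  expect_true(all(rowSums(d$coded_matrix[17:24, ] != 0) == 1))
  expect_true(all(d$coded_matrix[25, ] == 0))
  # counting formula for other k
  for (k in 2:5) {
    fs <- lapply(seq_len(k), function(i) factor_spec(paste0("f", i), 0, 1))
    expect_identical(nrow(ccd_design(fs, 1)$coded_matrix),
                     as.integer(2^k + 2 * k + 1))
  }
  # endpoint mapping: coded -1 on sac area is the low bound
  expect_equal(min(d$physical_matrix[, "sac_area"]), 11.65)
  expect_equal(max(d$physical_matrix[, "sac_area"]), 94.57)
  expect_error(ccd_design(list(factor_spec("a", 0, 1), factor_spec("a", 0, 2))),
               class = "aneuflow_spec_error")
})

test_that("quadratic surfaces are recovered exactly from noise-free data", {
  d <- ccd_design(four_factors(), n_center = 3)
  X <- d$coded_matrix
  y <- 2 + 3 * X[, 1] - X[, 2] + 0.5 * X[, 1] * X[, 3] + X[, 4]^2
  fit <- fit_quadratic_surface(d, y)
  expect_equal(unname(fit$coefficients[c("(Intercept)", "sac_area", "parent_radius")]),
               c(2, 3, -1), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["sac_area:hct"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["porosity^2"]), 1, tolerance = 1e-10)
  others <- setdiff(fit$terms, c("(Intercept)", "sac_area", "parent_radius",
                                 "sac_area:hct", "porosity^2"))
  expect_lt(max(abs(fit$coefficients[others])), 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("fit agrees with the reference linear-model solver", {
  d <- ccd_design(four_factors(), n_center = 3)
  set.seed(7)
  y <- rnorm(nrow(d$coded_matrix))
  fit <- fit_quadratic_surface(d, y)
  X <- d$coded_matrix
  df <- data.frame(y = y, x1 = X[, 1], x2 = X[, 2], x3 = X[, 3], x4 = X[, 4])
  ref <- lm(y ~ x1 + x2 + x3 + x4 + I(x1^2) + I(x2^2) + I(x3^2) + I(x4^2) +
              x1:x2 + x1:x3 + x1:x4 + x2:x3 + x2:x4 + x3:x4, data = df)
  sref <- summary(ref)$coefficients
  # same span: compare by term meaning
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               unname(coef(ref)["(Intercept)"]), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["sac_area"]),
               unname(coef(ref)["x1"]), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["hct^2"]),
               unname(coef(ref)["I(x3^2)"]), tolerance = 1e-10)
  expect_equal(unname(fit$standard_errors["sac_area"]),
               unname(sref["x1", "Std. Error"]), tolerance = 1e-8)
  expect_equal(unname(fit$standardized_effects["porosity"]),
               unname(sref["x4", "t value"]), tolerance = 1e-8)
  expect_equal(fit$residual_df, unname(ref$df.residual))
})

test_that("degenerate responses and designs behave as documented", {
  d <- ccd_design(four_factors(), n_center = 3)
  # constant responses
  fitc <- fit_quadratic_surface(d, rep(7, nrow(d$coded_matrix)))
  expect_equal(unname(fitc$coefficients[1]), 7)
  expect_lt(max(abs(fitc$coefficients[-1])), 1e-12)
  expect_identical(fitc$r_squared, 0)
  expect_true(all(fitc$standardized_effects[-1] == 0))
  # permutation invariance
  set.seed(11)
  y <- rnorm(nrow(d$coded_matrix))
  perm <- sample(nrow(d$coded_matrix))
  d2 <- d
  d2$coded_matrix <- d$coded_matrix[perm, ]
  d2$physical_matrix <- d$physical_matrix[perm, ]
  f1 <- fit_quadratic_surface(d, y)
  f2 <- fit_quadratic_surface(d2, y[perm])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  # aliasing: a constant factor column is rank deficient and named
  d3 <- d
  d3$coded_matrix[, "porosity"] <- 0
  err <- tryCatch(fit_quadratic_surface(d3, y), condition = identity)
  expect_s3_class(err, "aneuflow_fit_error")
  expect_match(conditionMessage(err), "porosity")
  # standardized effects invariant under affine response rescaling
  f3 <- fit_quadratic_surface(d, 3.5 * y + 11)
  expect_equal(f1$standardized_effects[-1], f3$standardized_effects[-1],
               tolerance = 1e-9)
})

test_that("effects report sorts, signs, and half-normal quantiles", {
  d2 <- ccd_design(list(factor_spec("a", 0, 1), factor_spec("b", 0, 1),
                        factor_spec("c", 0, 1)), n_center = 2)
  X <- d2$coded_matrix
  set.seed(3)
  y <- 2 * X[, 1] - 5 * X[, 2] + 1 * X[, 3] + rnorm(nrow(X), sd = 1e-3)
  rep_ <- effects_report(fit_quadratic_surface(d2, y))
  expect_identical(as.character(rep_$pareto$term[1:3]), c("b", "a", "c"))
  expect_identical(unname(sign(rep_$signs)), c(1, -1, 1))
  m <- nrow(rep_$half_normal)
  expect_equal(rep_$half_normal$quantile,
               qnorm(0.5 + 0.5 * (seq_len(m) - 0.5) / m))
  # single-effect half-normal quantile is the 75th percentile
  expect_equal(qnorm(0.5 + 0.5 * 0.5 / 1), 0.674489750196082, tolerance = 1e-12)
  expect_true(all(diff(rep_$pareto$abs_t) <= 1e-12))
})
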