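# Campaign plumbing on an ultra-coarse two-factor configuration (seconds per
# run); effect-direction physics runs in test-acceptance.R.

micro_config <- function(outdir = NULL, resume = FALSE) {
  campaign_config(
    factors = list(
      porosity = factor_spec("porosity", 0.73, 0.96),
      parent_radius = factor_spec("parent_radius", 1.59, 2.24, "mm")),
    dx = 0.4, lu_widths = 2, ld_widths = 2, n_cycles = 1,
    outdir = outdir, resume = resume, seed = 7)
}

test_that("campaign configuration defaults encode the study factor ranges", {
  cfg <- campaign_config()
  expect_equal(cfg$factors$sac_area$low, 11.65)
  expect_equal(cfg$factors$sac_area$high, 94.57)
  expect_equal(cfg$factors$parent_radius$low, 1.59)
  expect_equal(cfg$factors$parent_radius$high, 2.24)
  expect_equal(cfg$factors$hct$low, 0.35)
  expect_equal(cfg$factors$hct$high, 0.5)
  expect_equal(cfg$factors$porosity$low, 0.73)
  expect_equal(cfg$factors$porosity$high, 0.96)
  expect_identical(cfg$n_cycles, 3L)
  expect_equal(cfg$dx, 0.2)  # coarse preset
  f <- tempfile(fileext = ".json")
  write_campaign_config(cfg, f)
  cfg2 <- read_campaign_config(f)
  expect_equal(cfg2$factors, cfg$factors)
  expect_equal(cfg2$solver$poisson_tol, cfg$solver$poisson_tol)
  expect_equal(cfg2$dx, cfg$dx)
})

test_that("a reduced campaign runs, logs and resumes reproducibly", {
  out1 <- file.path(tempdir(), "camp1")
  res1 <- run_campaign(micro_config(outdir = out1), verbose = FALSE)
  expect_identical(nrow(res1$rows), 9L)  # 2^2 + 4 + 1
  expect_true(all(res1$rows$status == "ok"))
  # the study's convergence criterion holds for every run
  expect_true(all(res1$rows$final_residual < 1e-4))
  expect_true(file.exists(file.path(out1, "results.csv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  csv1 <- readLines(file.path(out1, "results.csv"))

  # determinism: an independent campaign writes byte-identical results
  out2 <- file.path(tempdir(), "camp2")
  res2 <- run_campaign(micro_config(outdir = out2), verbose = FALSE)
  expect_identical(readLines(file.path(out2, "results.csv")), csv1)

  # resume after an interrupted campaign reproduces the same file
  out3 <- file.path(tempdir(), "camp3")
  dir.create(out3, showWarnings = FALSE)
  partial <- read.csv(file.path(out1, "results.csv"))[1:4, ]
  write.csv(partial, file.path(out3, "results.csv"), row.names = FALSE)
  res3 <- run_campaign(micro_config(outdir = out3, resume = TRUE),
                       verbose = FALSE)
  expect_identical(readLines(file.path(out3, "results.csv")), csv1)

  # both response fits exist on the full 9-run design
  expect_s3_class(res1$fit_pressure, "rsm_fit")
  expect_s3_class(res1$fit_velocity, "rsm_fit")
  expect_true(file.exists(file.path(out1, "effects_pressure.csv")))
})

test_that("degenerate contrasts warn and return zero", {
  cfg <- micro_config()
  expect_warning(ct <- two_point_contrast(cfg, "porosity", 0.85, 0.85),
                 "equals")
  expect_identical(ct$relative, 0)
  expect_error(two_point_contrast(cfg, "porosity", 0.5, 0.9),
               class = "aneuflow_spec_error")
  expect_error(two_point_contrast(cfg, "nope", 0.8, 0.9),
               class = "aneuflow_spec_error")
})
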