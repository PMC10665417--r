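test_that("sac area is discretized within tolerance and under refinement", {
  p <- aneurysm_params(36.6, 1.9)
  m2 <- build_idealized_geometry(p, dx = 0.2)
  expect_lt(abs(measured_sac_area(m2) - 36.6) / 36.6, 0.02)

  m1 <- build_idealized_geometry(p, dx = 0.1)
  n1 <- sum(m1$region_label == 3L & m1$cell_label %in% c(1L, 3L))
  n2 <- sum(m2$region_label == 3L & m2$cell_label %in% c(1L, 3L))
  expect_lt(abs(n1 / n2 - 4), 0.05 * 4)
})

test_that("degenerate sac area gives a straight channel", {
  p <- suppressWarnings(aneurysm_params(0, 1.9))
  m <- build_idealized_geometry(p, dx = 0.2)
  expect_identical(sum(m$region_label == 3L), 0L)
  expect_identical(sum(m$cell_label == 3L), 0L)
  expect_error(sac_wall_mean_pressure(init_flow_state(m), m),
               class = "aneuflow_geometry_error")
})

test_that("coil cells fill exactly the sac when coiling is enabled", {
  p <- aneurysm_params(36.6, 1.9, porosity = 0.845)
  m <- build_idealized_geometry(p, dx = 0.2, coiled = TRUE)
  sac <- m$region_label == 3L & m$cell_label %in% c(1L, 3L)
  expect_true(all(m$cell_label[sac] == 3L))
  expect_true(all(m$region_label[m$cell_label == 3L] == 3L))
  m0 <- build_idealized_geometry(p, dx = 0.2, coiled = FALSE)
  expect_identical(sum(m0$cell_label == 3L), 0L)
  expect_identical(sum(sac), sum(m0$region_label == 3L &
                                   m0$cell_label == 1L))
})

test_that("sac cell count increases monotonically with sac area", {
  counts <- vapply(c(20, 36.6, 60, 94.57), function(A) {
    m <- build_idealized_geometry(aneurysm_params(A, 1.9), dx = 0.2)
    sum(m$region_label == 3L & m$cell_label %in% c(1L, 3L))
  }, 0)
  expect_true(all(diff(counts) > 0))
})

test_that("mirrored build equals the mirrored mask", {
  p <- aneurysm_params(36.6, 1.9)
  top <- build_idealized_geometry(p, dx = 0.2, side = "top")
  bot <- build_idealized_geometry(p, dx = 0.2, side = "bottom")
  ny <- top$grid$ny
  expect_identical(bot$cell_label, top$cell_label[, ny:1])
  expect_identical(bot$region_label, top$region_label[, ny:1])
})

test_that("geometry preconditions are enforced", {
  # sac larger than the short domain
  expect_error(
    build_idealized_geometry(aneurysm_params(94.57, 1.59), dx = 0.2,
                             lu_widths = 1, ld_widths = 1),
    class = "aneuflow_geometry_error")
  # neck narrower than 3 cells
  expect_error(
    build_idealized_geometry(suppressWarnings(aneurysm_params(0.3, 1.9)),
                             dx = 0.2),
    class = "aneuflow_resolution_error")
  expect_error(aneurysm_params(-1, 1.9), class = "aneuflow_geometry_error")
  expect_warning(aneurysm_params(36.6, 1.9, hct = 0.6))
})

test_that("mask exports are readable text files", {
  m <- build_idealized_geometry(aneurysm_params(36.6, 1.9), dx = 0.3)
  vtk <- tempfile(fileext = ".vtk"); csvf <- tempfile(fileext = ".csv")
  write_mask_vtk(m, vtk)
  write_mask_csv(m, csvf)
  expect_true(any(grepl("STRUCTURED_POINTS", readLines(vtk, n = 10))))
  df <- read.csv(csvf)
  expect_identical(nrow(df), m$grid$nx * m$grid$ny)
  expect_setequal(unique(df$cell_label), unique(as.vector(m$cell_label)))
})
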