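#' Physical configuration of one aneurysm run
#'
#' Bundles the four study factors (sac section area, parent-vessel mean
#' radius, hematocrit, coiling porosity) with the shape constants that define
#' one simulated configuration. The study factor ranges are sac section area
#' 11.65--94.57 mm^2, parent radius 1.59--2.24 mm, hematocrit 0.35--0.5 and
#' coiling porosity 0.73--0.96; values outside those ranges are accepted with
#' a warning (hard physical bounds are still enforced).
#'
#' @param sac_section_area sac cross-section area in mm^2 (>= 0; 0 degenerates
#'   to a straight channel with no sac).
#' @param parent_radius parent-vessel mean radius in mm; the 2D channel width
#'   is `2 * parent_radius`.
#' @param hct hematocrit, red-cell volume fraction in `[0, 0.67)`.
#' @param porosity coiling porosity (void fraction of the packed coil mass)
#'   in `(0, 1]`; 1 means no coil.
#' @param neck_ratio neck width as a fraction of the sac diameter, in
#'   `(0, 1]`.
#' @param coil_wire_diameter coil wire diameter in mm.
#' @return an object of class `aneurysm_params`.
#' @export
aneurysm_params <- function(sac_section_area, parent_radius,
                            hct = 0.425, porosity = 0.845,
                            neck_ratio = 0.8, coil_wire_diameter = 0.25) {
  if (!is.numeric(sac_section_area) || sac_section_area < 0)
    stop_aneuflow("sac_section_area must be >= 0 (mm^2)", "aneuflow_geometry_error")
  if (!is.numeric(parent_radius) || parent_radius <= 0)
    stop_aneuflow("parent_radius must be > 0 (mm)", "aneuflow_geometry_error")
  if (neck_ratio <= 0 || neck_ratio > 1)
    stop_aneuflow("neck_ratio must be in (0, 1]", "aneuflow_geometry_error")
  if (hct < 0 || hct >= 0.67)
    stop_aneuflow("hct must be in [0, 0.67) (packing limit)", "aneuflow_rheology_error")
  if (porosity <= 0 || porosity > 1)
    stop_aneuflow("porosity must be in (0, 1]", "aneuflow_domain_error")
  if (coil_wire_diameter <= 0)
    stop_aneuflow("coil_wire_diameter must be > 0 (mm)", "aneuflow_domain_error")
  if (sac_section_area > 0 &&
      (sac_section_area < 11.65 || sac_section_area > 94.57))
    warning("sac_section_area outside the study range 11.65-94.57 mm^2")
  if (parent_radius < 1.59 || parent_radius > 2.24)
    warning("parent_radius outside the study range 1.59-2.24 mm")
  if (hct < 0.35 || hct > 0.5)
    warning("hct outside the study range 0.35-0.5")
  if (porosity < 1 && (porosity < 0.73 || porosity > 0.96))
    warning("porosity outside the study range 0.73-0.96")
  structure(list(sac_section_area = sac_section_area,
                 parent_radius = parent_radius,
                 hct = hct, porosity = porosity,
                 neck_ratio = neck_ratio,
                 coil_wire_diameter = coil_wire_diameter),
            class = "aneurysm_params")
}

#' @export
print.aneurysm_params <- function(x, ...) {
  cat("aneurysm_params:\n")
  cat(sprintf("  sac section area : %.3f mm^2\n", x$sac_section_area))
  cat(sprintf("  parent radius    : %.3f mm (channel width %.3f mm)\n",
              x$parent_radius, 2 * x$parent_radius))
  cat(sprintf("  hematocrit       : %.3f\n", x$hct))
  cat(sprintf("  coiling porosity : %.3f\n", x$porosity))
  cat(sprintf("  neck ratio       : %.2f   coil wire: %.3f mm\n",
              x$neck_ratio, x$coil_wire_diameter))
  invisible(x)
}

#' Uniform Cartesian grid specification
#'
#' Square cells only; cell-centered labels, origin at the lower-left cell
#' corner, x along the parent vessel.
#'
#' @param nx,ny cell counts (>= 8).
#' @param dx uniform spacing in mm (> 0).
#' @param origin length-2 numeric, lower-left corner in mm.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(nx, ny, dx, origin = c(0, 0)) {
  if (nx < 8 || ny < 8) stop_aneuflow("nx, ny must be >= 8", "aneuflow_geometry_error")
  if (dx <= 0) stop_aneuflow("dx must be > 0", "aneuflow_geometry_error")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 dx = dx, origin = as.numeric(origin)),
            class = "grid_spec")
}

# Sac circle solved from the requested truncated area. The circle is cut by
# the channel wall line; the cut chord is the neck. The neck width is
# neck_ratio * min(sac diameter, channel width): the ostium is a defect of
# the parent-vessel wall, so across sacs of different size on the same
# parent vessel it is vessel-limited and stays fixed, while for sacs
# smaller than the vessel it scales with the sac diameter.
sac_circle_from_area <- function(area, neck_ratio, channel_width) {
  w <- neck_ratio * channel_width
  amin <- pi * (w / 2)^2 / 2                  # half-disc area at r = w/2
  if (area >= amin) {
    # vessel-limited neck: fixed chord w, radius from the truncated area
    # pi r^2 - r^2 acos(h/r) + h w/2 = area, h = center height above wall
    f <- function(r) {
      h <- sqrt(max(r^2 - (w / 2)^2, 0))
      pi * r^2 - r^2 * acos(min(h / r, 1)) + h * w / 2 - area
    }
    rmax <- sqrt(area / pi) + w
    r <- uniroot(f, c(w / 2, rmax), tol = 1e-12)$root
    h <- sqrt(max(r^2 - (w / 2)^2, 0))
    return(list(r = r, hn = h / r, chord_half = w / 2))
  }
  # sac-limited neck (small sacs): chord = neck_ratio * 2r, closed form
  hn <- sqrt(max(0, 1 - neck_ratio^2))        # center height / r
  seg_below <- acos(hn) - hn * neck_ratio      # area below chord / r^2
  factor <- pi - seg_below                     # truncated area / r^2
  r <- sqrt(area / factor)
  list(r = r, hn = hn, chord_half = neck_ratio * r)
}

#' Build an idealized 2D sidewall-aneurysm geometry mask
#'
#' Discretizes a straight parent channel of width `2 * parent_radius` with a
#' circular sac of the requested section area attached through a neck on one
#' wall. Cells are labelled FLUID / WALL / COIL / EXTERIOR; fluid cells carry
#' a region label (PARENT / NECK / SAC) and the domain ends carry the inlet
#' (left) and outlet (right) pressure boundaries.
#'
#' @param params an [aneurysm_params()] object.
#' @param grid optional [grid_spec()]; when `NULL` a default grid is sized
#'   from the geometry (`lu_widths` channel-widths upstream of the neck
#'   center and `ld_widths` downstream, six-cell exterior margins above and
#'   below).
#' @param dx grid spacing in mm, used when `grid` is `NULL`.
#' @param lu_widths,ld_widths domain length upstream/downstream of the neck
#'   center, in channel widths.
#' @param coiled when `TRUE` and `params$porosity < 1`, sac cells are
#'   labelled COIL (the coil fills the entire sac).
#' @param side `"top"` or `"bottom"`: wall the sac is attached to.
#' @return an object of class `geometry_mask`.
#' @export
build_idealized_geometry <- function(params, grid = NULL, dx = 0.2,
                                     lu_widths = 10, ld_widths = 5,
                                     coiled = TRUE, side = c("top", "bottom")) {
  side <- match.arg(side)
  stopifnot(inherits(params, "aneurysm_params"))
  if (!is.null(grid)) dx <- grid$dx
  # snap the discrete channel width to whole cells so the wall lines lie on
  # cell faces; a wall line through a row of cell centers would otherwise
  # label a spurious solid row that seals the neck
  ny_ch <- max(3L, as.integer(round(2 * params$parent_radius / dx)))
  W <- ny_ch * dx
  L <- (lu_widths + ld_widths) * W
  x_neck <- lu_widths * W

  has_sac <- params$sac_section_area > 0
  if (has_sac) {
    sc <- sac_circle_from_area(params$sac_section_area, params$neck_ratio, W)
    if (2 * sc$chord_half < 3 * dx)
      stop_aneuflow(sprintf(
        "neck width %.3f mm narrower than 3 cells at dx = %.3f mm",
        2 * sc$chord_half, dx), "aneuflow_resolution_error")
  } else sc <- list(r = 0, hn = 0, chord_half = 0)

  margin <- 6L  # exterior + wall margin, cells
  if (is.null(grid)) {
    nx <- max(8L, as.integer(round(L / dx)))
    ny_sac <- if (has_sac) as.integer(ceiling((sc$hn * sc$r + sc$r) / dx)) else 0L
    ny <- margin + ny_ch + ny_sac + margin
    grid <- grid_spec(nx, max(8L, ny), dx, origin = c(0, 0))
  }
  nx <- grid$nx; ny <- grid$ny
  x0 <- grid$origin[1]; y0 <- grid$origin[2]
  L_grid <- nx * dx
  # the channel spans the full x extent; rescale neck position to the grid
  x_neck <- x0 + L_grid * lu_widths / (lu_widths + ld_widths)
  y_ch0 <- y0 + margin * dx
  y_ch1 <- y_ch0 + W
  yc <- y_ch1 + sc$hn * sc$r
  xc <- x_neck

  if (has_sac) {
    if (xc - sc$r < x0 + 4 * dx || xc + sc$r > x0 + L_grid - 4 * dx ||
        yc + sc$r > y0 + (ny - 4) * dx)
      stop_aneuflow("sac does not fit inside the grid with a 4-cell margin",
                    "aneuflow_geometry_error")
  }
  if (y_ch1 > y0 + (ny - 4) * dx)
    stop_aneuflow("channel does not fit inside the grid", "aneuflow_geometry_error")

  xcen <- x0 + (seq_len(nx) - 0.5) * dx
  ycen <- y0 + (seq_len(ny) - 0.5) * dx
  X <- matrix(xcen, nx, ny)
  Y <- matrix(ycen, nx, ny, byrow = TRUE)

  in_channel <- Y > y_ch0 & Y < y_ch1
  in_sac <- if (has_sac)
    ((X - xc)^2 + (Y - yc)^2 < sc$r^2) & Y > y_ch1
  else matrix(FALSE, nx, ny)

  cell <- matrix(CELL_EXTERIOR, nx, ny)
  cell[in_channel] <- CELL_FLUID
  cell[in_sac] <- if (coiled && params$porosity < 1) CELL_COIL else CELL_FLUID

  region <- matrix(REGION_NONE, nx, ny)
  region[in_channel] <- REGION_PARENT
  region[in_sac] <- REGION_SAC
  if (has_sac) {
    in_neck <- in_channel & abs(X - xc) <= sc$chord_half & Y > y_ch1 - dx
    region[in_neck] <- REGION_NECK
  }

  # walls: non-fluid cells 8-adjacent to a fluid/coil cell
  act <- cell == CELL_FLUID | cell == CELL_COIL
  near <- matrix(FALSE, nx, ny)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is <- max(1, 1 + di):min(nx, nx + di)
    js <- max(1, 1 + dj):min(ny, ny + dj)
    near[is - di, js - dj] <- near[is - di, js - dj] | act[is, js]
  }
  cell[!act & near] <- CELL_WALL

  mask <- structure(list(
    grid = grid, cell_label = cell, region_label = region,
    params = params, side = side, coiled = coiled && params$porosity < 1,
    sac = list(center = c(xc, yc), r = sc$r, chord_half = sc$chord_half,
               wall_y = y_ch1),
    channel = list(y0 = y_ch0, y1 = y_ch1, width = W, x_neck = x_neck)
  ), class = "geometry_mask")
  if (side == "bottom") mask <- mirror_mask(mask)
  validate_geometry_mask(mask)
  mask
}

# Mirror a mask about the channel axis (vertical flip of the grid).
mirror_mask <- function(mask) {
  ny <- mask$grid$ny; dx <- mask$grid$dx; y0 <- mask$grid$origin[2]
  flip_y <- function(y) 2 * y0 + ny * dx - y
  mask$cell_label <- mask$cell_label[, ny:1, drop = FALSE]
  mask$region_label <- mask$region_label[, ny:1, drop = FALSE]
  mask$sac$center[2] <- flip_y(mask$sac$center[2])
  mask$sac$wall_y <- flip_y(mask$sac$wall_y)
  ch <- mask$channel
  mask$channel$y0 <- flip_y(ch$y1); mask$channel$y1 <- flip_y(ch$y0)
  mask$side <- if (identical(mask$side, "top")) "bottom" else "top"
  mask
}

#' Structural validity checks for a geometry mask
#'
#' Verifies that every COIL cell lies in the SAC region and that the inlet
#' and outlet faces each form one contiguous segment on opposite domain ends.
#'
#' @param mask a `geometry_mask`.
#' @return `mask`, invisibly; errors on violation.
#' @export
validate_geometry_mask <- function(mask) {
  cell <- mask$cell_label; region <- mask$region_label
  if (any(cell == CELL_COIL & region != REGION_SAC))
    stop_aneuflow("COIL cells outside the SAC region", "aneuflow_geometry_error")
  act <- cell == CELL_FLUID | cell == CELL_COIL
  for (col in c(1L, mask$grid$nx)) {
    open <- which(act[col, ])
    if (length(open) == 0 || !all(diff(open) == 1))
      stop_aneuflow("inlet/outlet faces are empty or non-contiguous",
                    "aneuflow_geometry_error")
  }
  invisible(mask)
}

#' Measured sac area of a mask
#'
#' @param mask a `geometry_mask`.
#' @return SAC cell count times cell area, in mm^2.
#' @export
measured_sac_area <- function(mask) {
  sum(mask$region_label == REGION_SAC &
        (mask$cell_label == CELL_FLUID | mask$cell_label == CELL_COIL)) *
    mask$grid$dx^2
}

sac_cell_count <- function(mask) {
  sum(mask$region_label == REGION_SAC &
        (mask$cell_label == CELL_FLUID | mask$cell_label == CELL_COIL))
}

#' @export
print.geometry_mask <- function(x, ...) {
  tab <- table(factor(x$cell_label, levels = 0:3,
                      labels = c("EXTERIOR", "FLUID", "WALL", "COIL")))
  cat(sprintf("geometry_mask: %d x %d cells, dx = %.3f mm (side: %s)\n",
              x$grid$nx, x$grid$ny, x$grid$dx, x$side))
  cat(sprintf("  channel width %.3f mm, sac area %.3f mm^2 (requested %.3f)\n",
              x$channel$width, measured_sac_area(x),
              x$params$sac_section_area))
  cat("  cells:", paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}

#' Export a geometry mask as a legacy VTK structured-points file
#'
#' Integer cell labels (and region labels as a second array) on the uniform
#' grid, readable by ParaView/VisIt.
#'
#' @param mask a `geometry_mask`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask_vtk <- function(mask, path) {
  g <- mask$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "aneuflow geometry mask", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", g$nx, g$ny),
               sprintf("ORIGIN %g %g 0", g$origin[1] + g$dx / 2,
                       g$origin[2] + g$dx / 2),
               sprintf("SPACING %g %g 1", g$dx, g$dx),
               sprintf("POINT_DATA %d", g$nx * g$ny),
               "SCALARS cell_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.vector(mask$cell_label), collapse = " "), con)
  writeLines(c("SCALARS region_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.vector(mask$region_label), collapse = " "), con)
  invisible(path)
}

#' Export mask labels as CSV (one row per cell) for debugging
#'
#' @param mask a `geometry_mask`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask_csv <- function(mask, path) {
  g <- mask$grid
  idx <- expand.grid(i = seq_len(g$nx), j = seq_len(g$ny))
  df <- data.frame(i = idx$i, j = idx$j,
                   x = g$origin[1] + (idx$i - 0.5) * g$dx,
                   y = g$origin[2] + (idx$j - 0.5) * g$dx,
                   cell_label = as.vector(mask$cell_label),
                   region_label = as.vector(mask$region_label))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
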