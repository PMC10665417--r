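# STL surface morphometrics: measure the sac section area and the parent
# vessel radius from a triangulated surface, the same quantities the
# parametric geometry generator takes as inputs. Both the ASCII
# ("solid ... facet normal ...") and the 80-byte-header binary dialects are
# read; no installed package parses STL, so the reader is local.

#' Read an STL surface (ASCII or binary)
#'
#' @param path STL file path.
#' @return numeric matrix with one row per triangle and nine columns
#'   (x1, y1, z1, x2, y2, z2, x3, y3, z3).
#' @export
read_stl <- function(path) {
  if (!file.exists(path))
    stop_aneuflow(sprintf("STL file not found: %s", path), "aneuflow_format_error")
  size <- file.info(path)$size
  if (is.na(size) || size < 15)
    stop_aneuflow("unreadable or empty STL file", "aneuflow_format_error")
  # binary if the size matches 84 + 50 * ntri
  is_binary <- FALSE
  if (size >= 84) {
    con <- file(path, "rb")
    hdr <- readBin(con, "raw", 80)
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    close(con)
    if (length(ntri) == 1 && !is.na(ntri) && ntri >= 0 &&
        size == 84 + 50 * as.numeric(ntri))
      is_binary <- TRUE
  }
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (ntri == 0)
      stop_aneuflow("STL contains zero triangles", "aneuflow_format_error")
    out <- matrix(NA_real_, ntri, 9)
    for (k in seq_len(ntri)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
      out[k, ] <- rec[4:12]
    }
    return(out)
  }
  lines <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vx) == 0 || length(vx) %% 3 != 0)
    stop_aneuflow("no complete triangles in ASCII STL", "aneuflow_format_error")
  coords <- t(vapply(strsplit(trimws(vx), "\\s+"),
                     function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(coords))
    stop_aneuflow("malformed vertex line in ASCII STL", "aneuflow_format_error")
  matrix(as.vector(t(coords)), ncol = 9, byrow = TRUE)
}

#' Write triangles as ASCII STL
#'
#' @param triangles matrix as returned by [read_stl()] (n x 9).
#' @param path output file path.
#' @param name solid name.
#' @return `path`, invisibly.
#' @export
write_stl_ascii <- function(triangles, path, name = "aneuflow") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (k in seq_len(nrow(triangles))) {
    v <- matrix(triangles[k, ], 3, 3, byrow = TRUE)
    n <- c(crossprod3(v[2, ] - v[1, ], v[3, ] - v[1, ]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Intersect all triangles with the plane axis = pos; return 2D segments in
# the two remaining axes. Rows: (x1, y1, x2, y2).
slice_triangles <- function(tri, axis, pos) {
  oth <- setdiff(1:3, axis)
  segs <- matrix(NA_real_, 0, 4)
  V <- array(t(tri), dim = c(3, 3, nrow(tri)))  # coord x vertex x tri
  d <- V[axis, , ] - pos                         # 3 x ntri
  keep <- which(apply(d, 2, function(z) min(z) < 0 && max(z) > 0))
  for (k in keep) {
    pts <- matrix(NA_real_, 0, 2)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      d1 <- d[e[1], k]; d2 <- d[e[2], k]
      if ((d1 < 0) != (d2 < 0)) {
        f <- d1 / (d1 - d2)
        p <- V[, e[1], k] + f * (V[, e[2], k] - V[, e[1], k])
        pts <- rbind(pts, p[oth])
      }
    }
    if (nrow(pts) == 2) segs <- rbind(segs, c(pts[1, ], pts[2, ]))
  }
  segs
}

# Chain segments into closed contours; returns a list of (n x 2) polygons.
chain_contours <- function(segs, tol) {
  if (nrow(segs) == 0) return(list())
  key <- function(p) paste(round(p[1] / tol), round(p[2] / tol))
  n <- nrow(segs)
  ends <- rbind(segs[, 1:2, drop = FALSE], segs[, 3:4, drop = FALSE])
  keys <- apply(ends, 1, key)
  lookup <- split(rep(seq_len(n), 2), keys)  # segment ids per endpoint key
  used <- logical(n)
  contours <- list()
  for (s0 in seq_len(n)) {
    if (used[s0]) next
    used[s0] <- TRUE
    start <- segs[s0, 1:2]
    cur <- segs[s0, 3:4]
    poly <- rbind(start, cur)
    closed <- FALSE
    repeat {
      cand <- setdiff(lookup[[key(cur)]], which(used))
      if (length(cand) == 0) break
      s <- cand[1]
      used[s] <- TRUE
      a <- segs[s, 1:2]; b <- segs[s, 3:4]
      nxt <- if (sum(abs(a - cur)) <= sum(abs(b - cur))) b else a
      if (sum(abs(nxt - start)) < 2 * tol) { closed <- TRUE; break }
      poly <- rbind(poly, nxt)
      cur <- nxt
    }
    if (closed && nrow(poly) >= 3) contours[[length(contours) + 1]] <- poly
  }
  contours
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Morphometrics of an STL aneurysm surface
#'
#' Slices the surface perpendicular to its dominant (longest-extent) axis:
#' once at `slice_fraction` to measure the sac section area (area of the
#' largest closed cross-section contour) and once near the inlet end (5%
#' along the axis) to measure the parent vessel's equivalent-circle radius
#' `sqrt(A / pi)`. Watertightness is not required, but the cut contours
#' must close.
#'
#' @param stl_path STL file path (ASCII or binary).
#' @param slice_fraction cutting-plane position along the dominant axis, in
#'   `(0, 1)`.
#' @return list with `sac_section_area` (squared model units, mm^2 for
#'   mm-scaled surfaces) and `parent_mean_radius` (model units).
#' @export
measure_stl_morphometrics <- function(stl_path, slice_fraction = 0.5) {
  if (slice_fraction <= 0 || slice_fraction >= 1)
    stop_aneuflow("slice_fraction must be in (0, 1)", "aneuflow_domain_error")
  tri <- read_stl(stl_path)
  if (nrow(tri) == 0)
    stop_aneuflow("STL contains zero triangles", "aneuflow_format_error")
  xyz <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
               tri[, 7:9, drop = FALSE])
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  ext <- hi - lo
  axis <- which.max(ext)
  tol <- max(ext) * 1e-7

  section_area <- function(frac) {
    pos <- lo[axis] + frac * ext[axis]
    # nudge off any mesh ring lying (nearly) in the plane: degenerate sliver
    # segments otherwise defeat the contour chaining
    guard <- 2e-3 * ext[axis]
    for (k in 1:5) {
      if (!any(abs(xyz[, axis] - pos) < guard)) break
      pos <- pos + guard
    }
    segs <- slice_triangles(tri, axis, pos)
    if (nrow(segs) == 0)
      stop_aneuflow(sprintf("slice at fraction %.3f intersects no triangles",
                            frac), "aneuflow_geometry_error")
    contours <- chain_contours(segs, max(ext) * 1e-6)
    if (length(contours) == 0)
      stop_aneuflow("no closed contour in the slice", "aneuflow_geometry_error")
    max(vapply(contours, polygon_area, 0))
  }

  A_sac <- section_area(slice_fraction)
  A_inlet <- section_area(0.05)
  list(sac_section_area = A_sac,
       parent_mean_radius = sqrt(A_inlet / pi))
}
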