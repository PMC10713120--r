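#' Polygonal region of interest
#'
#' A named closed polygon (typically one hemisomite) applied to every slice of
#' a stack. Vertices are `(row, column)` pixel coordinates, 0-based, with
#' pixel centers at integer coordinates; pixels on the polygon boundary count
#' as inside. The polygon must be simple (non-self-intersecting) and
#' non-degenerate.
#'
#' @param name Identifier, e.g. `"hemisomite_1"`.
#' @param vertices Numeric matrix (or list of length-2 vectors) with one
#'   `(row, col)` vertex per row; at least 3 vertices.
#' @return An object of class `nmj_roi`.
#' @examples
#' roi <- roi_region("hs1", rbind(c(0, 0), c(0, 9), c(9, 9), c(9, 0)))
#' @export
roi_region <- function(name, vertices) {
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("'vertices' must be (row, col) pairs")
  storage.mode(vertices) <- "double"
  # drop a closing vertex that duplicates the first
  n <- nrow(vertices)
  if (n >= 2L && all(vertices[n, ] == vertices[1, ])) {
    vertices <- vertices[-n, , drop = FALSE]
  }
  if (nrow(vertices) < 3L) stop("a polygon needs at least 3 vertices")
  if (anyDuplicated(vertices)) stop("polygon has duplicated vertices")
  if (abs(polygon_area(vertices)) < .Machine$double.eps) {
    stop("degenerate polygon: vertices are collinear")
  }
  if (!polygon_is_simple(vertices)) {
    stop("polygon is self-intersecting")
  }
  structure(list(name = as.character(name), vertices = vertices),
            class = "nmj_roi")
}

#' @export
print.nmj_roi <- function(x, ...) {
  cat(sprintf("nmj_roi '%s': %d vertices, rows [%g, %g], cols [%g, %g]\n",
              x$name, nrow(x$vertices),
              min(x$vertices[, 1]), max(x$vertices[, 1]),
              min(x$vertices[, 2]), max(x$vertices[, 2])))
  invisible(x)
}

# Signed shoelace area of a (row, col) polygon.
polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  sum(v[j, 2] * v[, 1] - v[, 2] * v[j, 1]) / 2
}

# Simplicity check: no two non-adjacent edges intersect, and adjacent edges
# meet only at their shared vertex. O(n^2); ROI polygons are small.
polygon_is_simple <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (segments_cross(a[i, ], b[i, ], a[j, ], b[j, ], adjacent)) return(FALSE)
    }
  }
  TRUE
}

cross2 <- function(o, p, q) {
  (p[1] - o[1]) * (q[2] - o[2]) - (p[2] - o[2]) * (q[1] - o[1])
}

on_segment <- function(p, a, b, eps = 1e-9) {
  abs(cross2(a, b, p)) < eps &&
    p[1] >= min(a[1], b[1]) - eps && p[1] <= max(a[1], b[1]) + eps &&
    p[2] >= min(a[2], b[2]) - eps && p[2] <= max(a[2], b[2]) + eps
}

segments_cross <- function(p1, p2, q1, q2, adjacent) {
  d1 <- cross2(q1, q2, p1); d2 <- cross2(q1, q2, p2)
  d3 <- cross2(p1, p2, q1); d4 <- cross2(p1, p2, q2)
  proper <- ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
            ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  if (adjacent) {
    # adjacent edges share one endpoint; only a proper crossing or overlap
    # beyond the shared vertex is a defect
    if (proper) return(TRUE)
    # collinear overlapping adjacent edges (spike) count as non-simple
    if (abs(d1) < 1e-12 && abs(d2) < 1e-12 && abs(d3) < 1e-12 && abs(d4) < 1e-12) {
      shared <- sum(apply(rbind(q1, q2), 1, function(q)
        all(abs(q - p1) < 1e-12) || all(abs(q - p2) < 1e-12)))
      overlap <- on_segment(p1, q1, q2) + on_segment(p2, q1, q2) +
                 on_segment(q1, p1, p2) + on_segment(q2, p1, p2)
      return(overlap > shared * 2L - 1L)
    }
    return(FALSE)
  }
  if (proper) return(TRUE)
  # improper touching between non-adjacent edges is a self-intersection
  on_segment(p1, q1, q2) || on_segment(p2, q1, q2) ||
    on_segment(q1, p1, p2) || on_segment(q2, p1, p2)
}

#' Point-in-polygon membership for pixel coordinates
#'
#' Even-odd ray casting with an explicit boundary test: points lying on a
#' polygon edge or vertex are inside. Vectorised over points.
#'
#' @param rows,cols Numeric vectors of point coordinates (0-based pixel
#'   centers).
#' @param vertices Polygon vertex matrix as in [roi_region()].
#' @return Logical vector.
#' @export
point_in_polygon <- function(rows, cols, vertices) {
  n <- nrow(vertices)
  vr <- vertices[, 1]; vc <- vertices[, 2]
  inside <- rep(FALSE, length(rows))
  boundary <- rep(FALSE, length(rows))
  eps <- 1e-9
  j <- n
  for (i in seq_len(n)) {
    r1 <- vr[j]; c1 <- vc[j]; r2 <- vr[i]; c2 <- vc[i]
    # boundary: point on segment (r1,c1)-(r2,c2)
    crs <- (r2 - r1) * (cols - c1) - (c2 - c1) * (rows - r1)
    seg_len2 <- (r2 - r1)^2 + (c2 - c1)^2
    onb <- abs(crs) < eps * sqrt(seg_len2 + 1) &
      rows >= pmin(r1, r2) - eps & rows <= pmax(r1, r2) + eps &
      cols >= pmin(c1, c2) - eps & cols <= pmax(c1, c2) + eps
    boundary <- boundary | onb
    # ray casting in the row direction (treat col as ordinate)
    hit <- ((c1 > cols) != (c2 > cols))
    if (any(hit)) {
      rint <- r1 + (cols[hit] - c1) * (r2 - r1) / (c2 - c1)
      flip <- rows[hit] < rint
      inside[hit] <- xor(inside[hit], flip)
    }
    j <- i
  }
  inside | boundary
}

#' Rasterize an ROI polygon onto a pixel grid
#'
#' @param roi An [roi_region()].
#' @param shape Integer `(rows, cols)` frame size in pixels.
#' @return Logical matrix of that shape; `TRUE` exactly for pixel centers
#'   inside or on the polygon boundary.
#' @examples
#' m <- rasterize_roi(roi_region("r", rbind(c(0, 0), c(0, 9), c(9, 9), c(9, 0))),
#'                    c(10, 10))
#' sum(m)  # 100
#' @export
rasterize_roi <- function(roi, shape) {
  stopifnot(inherits(roi, "nmj_roi"), length(shape) == 2L)
  v <- roi$vertices
  if (min(v[, 1]) < 0 || min(v[, 2]) < 0 ||
      max(v[, 1]) > shape[1] - 1 || max(v[, 2]) > shape[2] - 1) {
    stop(sprintf("ROI '%s' does not fit within the %d x %d frame",
                 roi$name, shape[1], shape[2]))
  }
  out <- matrix(FALSE, shape[1], shape[2])
  r0 <- floor(min(v[, 1])); r1 <- ceiling(max(v[, 1]))
  c0 <- floor(min(v[, 2])); c1 <- ceiling(max(v[, 2]))
  rr <- r0:r1; cc <- c0:c1
  grid_r <- rep(rr, times = length(cc))
  grid_c <- rep(cc, each = length(rr))
  inside <- point_in_polygon(grid_r, grid_c, v)
  out[cbind(grid_r + 1L, grid_c + 1L)[inside, , drop = FALSE]] <- TRUE
  out
}

#' Read named ROI polygons from a JSON file
#'
#' The schema is a JSON array of objects, each with a `name` and a `vertices`
#' array of `[row, col]` pairs in 0-based pixel coordinates:
#' `[{"name": "hemisomite_1", "vertices": [[r, c], [r, c], ...]}, ...]`.
#'
#' @param path JSON file path.
#' @return List of [roi_region()] objects.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(raw) == 0L) stop("ROI file contains no regions")
  lapply(raw, function(r) {
    if (is.null(r$name) || is.null(r$vertices)) {
      stop("each ROI entry needs 'name' and 'vertices'")
    }
    verts <- do.call(rbind, lapply(r$vertices, function(p) as.numeric(unlist(p))))
    roi_region(r$name, verts)
  })
}

#' Write ROI polygons to the JSON schema understood by [read_rois()]
#'
#' @param rois List of [roi_region()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  payload <- lapply(rois, function(r) {
    list(name = r$name,
         vertices = lapply(seq_len(nrow(r$vertices)),
                           function(i) as.numeric(r$vertices[i, ])))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rectangular ROI covering a whole frame
#'
#' Convenience for fixture and whole-image analyses.
#' @param shape `(rows, cols)` frame size.
#' @param name ROI name.
#' @return An [roi_region()].
#' @export
full_frame_roi <- function(shape, name = "full_frame") {
  roi_region(name, rbind(
    c(0, 0), c(0, shape[2] - 1), c(shape[1] - 1, shape[2] - 1), c(shape[1] - 1, 0)
  ))
}
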