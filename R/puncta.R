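#' Criteria separating single from clustered puncta
#'
#' A detected object is flagged as a *cluster* of fused puncta when any of
#' three shape conditions holds: area strictly above `max_area_um2`,
#' circularity strictly below `min_circularity`, or aspect ratio strictly
#' above `max_aspect_ratio`. The defaults (4 um^2, 0.65, 2.5) are the values
#' tuned for zebrafish NMJ puncta; they can be overridden per channel.
#'
#' @param max_area_um2 Area threshold (um^2).
#' @param min_circularity Circularity threshold, in `[0, 1]`.
#' @param max_aspect_ratio Aspect-ratio threshold, `>= 1`.
#' @return An object of class `nmj_cluster_criteria`.
#' @export
cluster_criteria <- function(max_area_um2 = 4, min_circularity = 0.65,
                             max_aspect_ratio = 2.5) {
  stopifnot(max_area_um2 > 0, min_circularity >= 0, min_circularity <= 1,
            max_aspect_ratio >= 1)
  structure(list(max_area_um2 = max_area_um2,
                 min_circularity = min_circularity,
                 max_aspect_ratio = max_aspect_ratio),
            class = "nmj_cluster_criteria")
}

# Moore boundary trace of one 8-connected component, returning the chain-code
# path length in pixel units (orthogonal step 1, diagonal step sqrt(2)).
# Single pixels have no boundary path; callers treat length 0 specially.
perimeter_chain_px <- function(pixels) {
  n <- nrow(pixels)
  if (n == 1L) return(0)
  r0 <- min(pixels[, 1]) - 2L
  c0 <- min(pixels[, 2]) - 2L
  nr <- max(pixels[, 1]) - r0 + 2L
  nc <- max(pixels[, 2]) - c0 + 2L
  M <- matrix(FALSE, nr, nc)
  lr <- pixels[, 1] - r0
  lc <- pixels[, 2] - c0
  M[cbind(lr, lc)] <- TRUE
  # start at topmost, then leftmost pixel; its W/NW/N/NE neighbors are bg
  sr <- min(lr)
  sc <- min(lc[lr == sr])
  # Moore neighborhood in clockwise order: W, NW, N, NE, E, SE, S, SW
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  p <- c(sr, sc)
  b_dir <- 1L  # backtrack starts at the W neighbor (background)
  path_r <- integer(4L * n + 8L)
  path_c <- integer(4L * n + 8L)
  np <- 0L
  seen <- new.env(hash = TRUE, parent = emptyenv())
  start_key <- paste(sr, sc, b_dir)
  repeat {
    key <- paste(p[1], p[2], b_dir)
    if (!is.null(seen[[key]])) {
      first <- seen[[key]]
      cyc_r <- path_r[first:np]
      cyc_c <- path_c[first:np]
      break
    }
    np <- np + 1L
    if (np > length(path_r)) {
      path_r <- c(path_r, integer(length(path_r)))
      path_c <- c(path_c, integer(length(path_c)))
    }
    seen[[key]] <- np
    path_r[np] <- p[1]; path_c[np] <- p[2]
    # scan clockwise starting just after the backtrack direction
    found <- FALSE
    d <- b_dir
    for (step in 1:8) {
      d <- d %% 8L + 1L
      q <- c(p[1] + dr[d], p[2] + dc[d])
      if (M[q[1], q[2]]) {
        # new backtrack: the position scanned just before q, as a direction
        # index relative to q
        prev <- d - 1L; if (prev == 0L) prev <- 8L
        bq <- c(p[1] + dr[prev], p[2] + dc[prev])
        b_dir <- which(dr == bq[1] - q[1] & dc == bq[2] - q[2])
        p <- q
        found <- TRUE
        break
      }
    }
    if (!found) {  # isolated pixel (cannot occur for n > 1 connected input)
      cyc_r <- path_r[seq_len(np)]
      cyc_c <- path_c[seq_len(np)]
      break
    }
  }
  m <- length(cyc_r)
  if (m < 2L) return(0)
  nxt <- c(2:m, 1L)
  steps <- pmax(abs(cyc_r[nxt] - cyc_r), abs(cyc_c[nxt] - cyc_c))
  diag <- (cyc_r[nxt] != cyc_r) & (cyc_c[nxt] != cyc_c)
  sum(ifelse(diag, sqrt(2), 1) * (steps > 0))
}

#' Shape descriptors of a pixel set
#'
#' Computes the descriptors used to classify puncta:
#' * **area**: pixel count times pixel area;
#' * **perimeter**: Moore boundary-walk (chain-code) length, diagonal steps
#'   weighted `sqrt(2)`, scaled to um;
#' * **circularity**: `4 * pi * area / perimeter^2`, capped at 1 (a single
#'   pixel, having no boundary path, is 1 by convention);
#' * **aspect ratio**: major/minor axis ratio of the best-fit ellipse from
#'   second-order central moments, with each pixel treated as a unit square
#'   (a `1/12` variance term per axis), so a single pixel has ratio 1.
#'
#' Circularity and aspect ratio are computed in pixel units; both are
#' scale-invariant for square pixels.
#'
#' @param pixels Integer matrix of `(row, col)` coordinates, one 8-connected
#'   component.
#' @param cal An [nmj_calibration()].
#' @return List with `area_um2`, `perimeter_um`, `circularity`,
#'   `aspect_ratio`, `centroid` (row, col).
#' @export
shape_metrics <- function(pixels, cal) {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1L,
            inherits(cal, "nmj_calibration"))
  n <- nrow(pixels)
  per_px <- perimeter_chain_px(pixels)
  circ <- if (per_px <= 0) 1 else min(1, 4 * pi * n / per_px^2)
  r <- pixels[, 1]; cc <- pixels[, 2]
  mr <- mean(r); mc <- mean(cc)
  srr <- mean((r - mr)^2) + 1 / 12
  scc <- mean((cc - mc)^2) + 1 / 12
  src <- mean((r - mr) * (cc - mc))
  h <- (srr + scc) / 2
  d <- sqrt(((srr - scc) / 2)^2 + src^2)
  ar <- sqrt((h + d) / (h - d))
  list(area_um2 = pixels_to_area_um2(n, cal),
       perimeter_um = per_px * cal$pixel_size_um,
       circularity = circ,
       aspect_ratio = ar,
       centroid = c(row = mr, col = mc))
}

#' Classify a punctum as single or clustered
#'
#' Clustered if **any** of the three conditions holds (strict comparisons):
#' area `>` the area threshold, circularity `<` the circularity threshold, or
#' aspect ratio `>` the aspect-ratio threshold; otherwise single. A punctum
#' sitting exactly on all three thresholds is single.
#'
#' @param area_um2,circularity,aspect_ratio Shape descriptors, or an
#'   `nmj_punctum` passed as `area_um2` with the others missing.
#' @param criteria A [cluster_criteria()] object.
#' @return `"single"` or `"clustered"`.
#' @export
classify_punctum <- function(area_um2, circularity, aspect_ratio,
                             criteria = cluster_criteria()) {
  if (inherits(area_um2, "nmj_punctum")) {
    p <- area_um2
    area_um2 <- p$area_um2
    circularity <- p$circularity
    aspect_ratio <- p$aspect_ratio
  }
  stopifnot(inherits(criteria, "nmj_cluster_criteria"))
  clustered <- area_um2 > criteria$max_area_um2 |
    circularity < criteria$min_circularity |
    aspect_ratio > criteria$max_aspect_ratio
  ifelse(clustered, "clustered", "single")
}

new_punctum <- function(id, pixels, cal, criteria, roi_clipped = FALSE) {
  m <- shape_metrics(pixels, cal)
  structure(
    list(id = as.character(id),
         pixels = pixels,
         n_px = nrow(pixels),
         area_um2 = m$area_um2,
         perimeter_um = m$perimeter_um,
         circularity = m$circularity,
         aspect_ratio = m$aspect_ratio,
         centroid = m$centroid,
         status = classify_punctum(m$area_um2, m$circularity, m$aspect_ratio,
                                   criteria),
         roi_clipped = roi_clipped),
    class = "nmj_punctum"
  )
}

#' @export
print.nmj_punctum <- function(x, ...) {
  cat(sprintf(
    "punctum %s [%s]: %d px (%.3f um^2), circ %.3f, AR %.2f, centroid (%.1f, %.1f)\n",
    x$id, x$status, x$n_px, x$area_um2, x$circularity, x$aspect_ratio,
    x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Detect puncta in a binary mask
#'
#' One punctum per 8-connected foreground component, with shape metrics
#' populated and an initial single/clustered status. The mask should already
#' be despeckled.
#'
#' @param mask Logical matrix.
#' @param cal An [nmj_calibration()].
#' @param criteria A [cluster_criteria()].
#' @param roi_mask Optional logical ROI matrix; components touching its
#'   boundary are kept but flagged `roi_clipped`.
#' @return List of `nmj_punctum` objects, ids `"1"`, `"2"`, ... in label
#'   order.
#' @export
find_puncta <- function(mask, cal, criteria = cluster_criteria(),
                        roi_mask = NULL) {
  lab <- label_components(mask)
  comps <- component_pixels(lab)
  edge <- NULL
  if (!is.null(roi_mask)) {
    # ROI boundary = ROI pixels with a non-ROI 8-neighbor (or frame edge)
    edge <- roi_mask & !erode_mask(roi_mask)
  }
  lapply(seq_along(comps), function(i) {
    px <- comps[[i]]
    clipped <- !is.null(edge) && any(edge[px])
    new_punctum(i, px, cal, criteria, roi_clipped = clipped)
  })
}

# 8-neighborhood erosion treating out-of-frame as background.
erode_mask <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    out <- out & pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  out
}

#' Summarise a list of puncta as a data frame
#'
#' @param puncta List of `nmj_punctum` objects.
#' @return Data frame with one row per punctum.
#' @export
puncta_table <- function(puncta) {
  if (length(puncta) == 0L) {
    return(data.frame(id = character(), n_px = integer(),
                      area_um2 = numeric(), perimeter_um = numeric(),
                      circularity = numeric(), aspect_ratio = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      status = character(), roi_clipped = logical(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    id = vapply(puncta, `[[`, character(1), "id"),
    n_px = vapply(puncta, `[[`, integer(1), "n_px"),
    area_um2 = vapply(puncta, `[[`, numeric(1), "area_um2"),
    perimeter_um = vapply(puncta, `[[`, numeric(1), "perimeter_um"),
    circularity = vapply(puncta, `[[`, numeric(1), "circularity"),
    aspect_ratio = vapply(puncta, `[[`, numeric(1), "aspect_ratio"),
    centroid_row = vapply(puncta, function(p) p$centroid[[1]], numeric(1)),
    centroid_col = vapply(puncta, function(p) p$centroid[[2]], numeric(1)),
    status = vapply(puncta, `[[`, character(1), "status"),
    roi_clipped = vapply(puncta, `[[`, logical(1), "roi_clipped"),
    stringsAsFactors = FALSE
  )
}
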