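#' Parameters of the declustering (segmentation) stage
#'
#' @param gaussian_sigma Blur (px) applied to the raw slice before seeking
#'   local maxima; default 1.
#' @param maxima_prominence Minimum intensity drop separating two maxima
#'   (the "noise tolerance" of peak seeding). `NULL` (default) means 10% of
#'   the blurred slice's dynamic range, computed at run time; this default is
#'   a package choice and the single most influential free parameter of the
#'   stage.
#' @param max_rounds Recursion cap per punctum lineage (default 10): a
#'   cluster still failing the single-punctum criteria after this many
#'   generations of splitting is marked `unsegmentable`.
#' @return An object of class `nmj_segmentation_params`.
#' @export
segmentation_params <- function(gaussian_sigma = 1.0, maxima_prominence = NULL,
                                max_rounds = 10L) {
  stopifnot(gaussian_sigma >= 0,
            is.null(maxima_prominence) || maxima_prominence >= 0,
            max_rounds >= 1)
  structure(list(gaussian_sigma = gaussian_sigma,
                 maxima_prominence = maxima_prominence,
                 max_rounds = as.integer(max_rounds)),
            class = "nmj_segmentation_params")
}

# Local lookup helpers: map a punctum's (row, col) pixels into a padded
# bounding-box frame so neighbor queries are O(1).
local_frame <- function(pixels) {
  r0 <- min(pixels[, 1]) - 2L
  c0 <- min(pixels[, 2]) - 2L
  nr <- max(pixels[, 1]) - r0 + 2L
  nc <- max(pixels[, 2]) - c0 + 2L
  idx <- matrix(0L, nr, nc)
  idx[cbind(pixels[, 1] - r0, pixels[, 2] - c0)] <- seq_len(nrow(pixels))
  list(r0 = r0, c0 = c0, idx = idx, nr = nr, nc = nc)
}

NEIGH8 <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

#' Find local intensity maxima inside a punctum
#'
#' Detects peaks of the (blurred) slice restricted to the punctum's pixels,
#' suppressing any candidate that can be reached from a higher pixel without
#' descending more than `prominence` intensity units — the noise-tolerance
#' semantics of interactive maxima finding. A plateau of equal-valued maxima
#' contributes one seed, at the plateau pixel nearest its centroid (ties:
#' smallest row, then column). Seeds are labeled `1..k` in decreasing peak
#' intensity (ties in detection order: row, then column).
#'
#' @param img Numeric intensity matrix (blur it first with the stage sigma).
#' @param pixels Integer `(row, col)` matrix: the punctum's pixel set.
#' @param prominence Non-negative intensity drop required between peaks.
#' @return Integer matrix with columns `row`, `col`, `label`; zero rows if
#'   the punctum has no interior structure (never happens: a punctum always
#'   yields at least one seed).
#' @export
find_local_maxima <- function(img, pixels, prominence) {
  stopifnot(is.matrix(img), is.matrix(pixels), prominence >= 0)
  n <- nrow(pixels)
  fr <- local_frame(pixels)
  v <- img[pixels]
  ord <- order(-v, pixels[, 1], pixels[, 2])
  processed <- logical(n)
  seeds <- NULL
  for (i in ord) {
    if (processed[i]) next
    # flood the basin reachable from i without dropping below v[i] - prominence
    thr <- v[i] - prominence
    region <- integer(0)
    stack <- i
    inreg <- logical(n)
    inreg[i] <- TRUE
    is_max <- TRUE
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      region <- c(region, p)
      if (v[p] > v[i]) is_max <- FALSE
      lr <- pixels[p, 1] - fr$r0
      lc <- pixels[p, 2] - fr$c0
      for (k in 1:8) {
        q <- fr$idx[lr + NEIGH8[k, 1], lc + NEIGH8[k, 2]]
        if (q > 0L && !inreg[q] && v[q] >= thr) {
          inreg[q] <- TRUE
          stack <- c(stack, q)
        }
      }
    }
    if (is_max) {
      # plateau: equal-valued pixels of the region connected to i
      plateau <- plateau_of(i, pixels, v, fr)
      ctr <- colMeans(pixels[plateau, , drop = FALSE])
      d2 <- (pixels[plateau, 1] - ctr[1])^2 + (pixels[plateau, 2] - ctr[2])^2
      best <- plateau[order(d2, pixels[plateau, 1], pixels[plateau, 2])[1]]
      seeds <- rbind(seeds, c(pixels[best, 1], pixels[best, 2]))
    }
    processed[region] <- TRUE
  }
  out <- cbind(seeds, seq_len(nrow(seeds)))
  colnames(out) <- c("row", "col", "label")
  out
}

# 8-connected flood of pixels with value exactly v[i], starting at i.
plateau_of <- function(i, pixels, v, fr) {
  n <- nrow(pixels)
  seen <- logical(n)
  seen[i] <- TRUE
  stack <- i
  out <- integer(0)
  while (length(stack)) {
    p <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, p)
    lr <- pixels[p, 1] - fr$r0
    lc <- pixels[p, 2] - fr$c0
    for (k in 1:8) {
      q <- fr$idx[lr + NEIGH8[k, 1], lc + NEIGH8[k, 2]]
      if (q > 0L && !seen[q] && v[q] == v[i]) {
        seen[q] <- TRUE
        stack <- c(stack, q)
      }
    }
  }
  out
}

#' Deterministic seeded expansion of a clustered punctum
#'
#' Partitions a punctum's pixel set among `k >= 2` seeds by simultaneous
#' region growth. Each seed keeps an ordered list of claimed pixels (the seed
#' itself is pixel 0). Growth proceeds over the claimed-pixel index: for each
#' index, for each direction in the fixed order top-left, left, bottom-left,
#' below, bottom-right, right, top-right, above, and for each seed in label
#' order, the neighbor of that seed's pixel at that index is claimed iff it
#' lies in the punctum and is still unclaimed; claimed pixels are appended to
#' the claiming seed's list. The first claim wins, so the partition is a
#' deterministic function of the mask and the seeds. Growth stops when every
#' pixel is claimed; each region is 8-connected and contains its seed.
#'
#' @param pixels Integer `(row, col)` matrix: the punctum's pixel set (one
#'   8-connected component).
#' @param seeds Integer matrix with columns `row`, `col` (and optionally
#'   `label`; row order defines labels otherwise), all inside `pixels`.
#' @return List of `(row, col)` pixel matrices, one per seed, in label order.
#' @examples
#' bar <- cbind(rep(1L, 5), 1:5)
#' parts <- expand_seeds(bar, rbind(c(1L, 1L), c(1L, 5L)))
#' vapply(parts, nrow, integer(1))  # 2 3
#' @export
expand_seeds <- function(pixels, seeds) {
  stopifnot(is.matrix(pixels), is.matrix(seeds), nrow(seeds) >= 2L)
  seeds <- seeds[, 1:2, drop = FALSE]
  n <- nrow(pixels)
  k <- nrow(seeds)
  fr <- local_frame(pixels)
  lr <- seeds[, 1] - fr$r0
  lc <- seeds[, 2] - fr$c0
  if (any(lr < 1L | lr > fr$nr | lc < 1L | lc > fr$nc)) {
    stop("seed lies outside the punctum pixel set")
  }
  seed_idx <- fr$idx[cbind(lr, lc)]
  if (any(seed_idx == 0L)) stop("seed lies outside the punctum pixel set")
  if (anyDuplicated(seed_idx)) stop("duplicate seed positions")

  # fixed direction order: top-left, left, bottom-left, below, bottom-right,
  # right, top-right, above
  ddr <- c(-1L, 0L, 1L, 1L, 1L, 0L, -1L, -1L)
  ddc <- c(-1L, -1L, -1L, 0L, 1L, 1L, 1L, 0L)

  owner <- integer(n)            # 0 = unclaimed
  lists <- vector("list", k)     # claimed pixel indices per seed, in order
  lens <- integer(k)
  for (s in seq_len(k)) {
    lists[[s]] <- integer(max(16L, n %/% k + 8L))
    lists[[s]][1L] <- seed_idx[s]
    lens[s] <- 1L
    owner[seed_idx[s]] <- s
  }
  claimed <- k
  i <- 1L
  while (claimed < n && i <= max(lens)) {
    for (d in 1:8) {
      for (s in seq_len(k)) {
        if (lens[s] < i) next
        p <- lists[[s]][i]
        lr <- pixels[p, 1] - fr$r0 + ddr[d]
        lc <- pixels[p, 2] - fr$c0 + ddc[d]
        q <- fr$idx[lr, lc]
        if (q > 0L && owner[q] == 0L) {
          owner[q] <- s
          lens[s] <- lens[s] + 1L
          if (lens[s] > length(lists[[s]])) {
            lists[[s]] <- c(lists[[s]], integer(length(lists[[s]])))
          }
          lists[[s]][lens[s]] <- q
          claimed <- claimed + 1L
        }
      }
    }
    i <- i + 1L
  }
  out <- lapply(seq_len(k), function(s) {
    px <- pixels[lists[[s]][seq_len(lens[s])], , drop = FALSE]
    dimnames(px) <- list(NULL, c("row", "col"))
    px
  })
  if (claimed < n) {
    # defensive: unreachable pixels (disconnected input mask) become extra
    # regions, one per leftover component
    left <- pixels[owner == 0L, , drop = FALSE]
    sub <- matrix(FALSE, fr$nr, fr$nc)
    sub[cbind(left[, 1] - fr$r0, left[, 2] - fr$c0)] <- TRUE
    lab <- label_components(sub)
    for (px in component_pixels(lab)) {
      px[, 1] <- px[, 1] + fr$r0
      px[, 2] <- px[, 2] + fr$c0
      out <- c(out, list(px))
    }
    warning("expansion left unreachable pixels; input mask was disconnected")
  }
  out
}

#' Recursively split clustered puncta into single puncta
#'
#' Worklist loop over the detected puncta: each punctum flagged `clustered`
#' is searched for local intensity maxima on the blurred slice; with two or
#' more maxima it is replaced by its expansion sub-puncta
#' (see [expand_seeds()]), which are re-measured, re-classified and
#' re-enqueued; with at most one maximum it is marked `unsegmentable` and
#' kept. Lineages deeper than `max_rounds` generations are cut off as
#' `unsegmentable` with a warning. Pixels are conserved exactly: the union of
#' output pixel sets equals the union of input pixel sets.
#'
#' @param puncta List of `nmj_punctum` (from [find_puncta()]).
#' @param slice_img Raw intensity slice (the stage applies its own blur).
#' @param criteria A [cluster_criteria()].
#' @param params A [segmentation_params()].
#' @param cal An [nmj_calibration()].
#' @return List with `puncta` (final list) and `stats` (counts of parents
#'   split, children produced, unsegmentable puncta).
#' @export
segment_all <- function(puncta, slice_img, criteria = cluster_criteria(),
                        params = segmentation_params(), cal = nmj_calibration()) {
  stopifnot(inherits(params, "nmj_segmentation_params"))
  blurred <- gaussian_blur(slice_img, params$gaussian_sigma)
  prom <- params$maxima_prominence
  if (is.null(prom)) prom <- 0.10 * (max(blurred) - min(blurred))

  queue <- lapply(puncta, function(p) list(p = p, depth = 0L))
  out <- list()
  n_parents_split <- 0L
  n_children <- 0L
  n_unseg <- 0L
  capped <- FALSE
  next_id <- length(puncta)
  while (length(queue)) {
    item <- queue[[1]]
    queue <- queue[-1]
    p <- item$p
    if (!identical(p$status, "clustered")) {
      out[[length(out) + 1L]] <- p
      next
    }
    if (item$depth >= params$max_rounds) {
      capped <- TRUE
      p$status <- "unsegmentable"
      n_unseg <- n_unseg + 1L
      out[[length(out) + 1L]] <- p
      next
    }
    seeds <- find_local_maxima(blurred, p$pixels, prom)
    if (nrow(seeds) <= 1L) {
      p$status <- "unsegmentable"
      n_unseg <- n_unseg + 1L
      out[[length(out) + 1L]] <- p
      next
    }
    parts <- expand_seeds(p$pixels, seeds)
    n_parents_split <- n_parents_split + 1L
    for (j in seq_along(parts)) {
      next_id <- next_id + 1L
      child <- new_punctum(paste0(p$id, ".", j), parts[[j]], cal, criteria,
                           roi_clipped = p$roi_clipped)
      n_children <- n_children + 1L
      queue[[length(queue) + 1L]] <- list(p = child, depth = item$depth + 1L)
    }
  }
  if (capped) {
    warning("segmentation recursion cap reached for at least one lineage")
  }
  list(puncta = out,
       stats = list(parents_split = n_parents_split,
                    children = n_children,
                    unsegmentable = n_unseg))
}
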