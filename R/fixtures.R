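#' Generate a synthetic two-channel z-stack with known ground truth
#'
#' Renders fluorescent-punctum-like spots on a dark background, per slice and
#' channel, so that every pipeline stage can be validated without microscopy
#' data. Three fixture styles are supported:
#'
#' * **isolated Gaussian spots** (the default): each spot occupies its own
#'   grid cell, so with zero noise the detected punctum count equals the
#'   planned count exactly;
#' * **fused groups** (`fusion_groups`): listed spots are placed in a row
#'   inside one cell, `fusion_spacing_px` apart, so they merge into a single
#'   clustered component at threshold while keeping distinct intensity peaks
#'   — the declustering test bed;
#' * **exact-overlap rectangles** (`overlap_plan`): each plan entry places a
#'   channel-1 rectangle and a channel-2 rectangle shifted so that the
#'   channel-1 punctum's overlap fraction equals the planned value exactly in
#'   pixel counts (the rectangle width makes tenths representable). Analyse
#'   these with blur and trim disabled so thresholding reproduces the drawn
#'   rectangles.
#'
#' Spot placement shuffles grid cells with the given `seed`; generation is
#' bit-reproducible from the arguments. The default frame (256 x 256, 2
#' slices, 50 spots per channel per slice at 0.21 um/px) keeps the per-slice
#' punctum density of a typical zebrafish hemisomite acquisition at a desk
#'-scale frame size.
#'
#' @param n_spots_per_channel Spots per channel on every slice (ignored when
#'   `overlap_plan` is given, which fixes one pair per entry).
#' @param overlap_plan Numeric vector of planned channel-1 overlap fractions
#'   in `[0, 1]`; switches to rectangle mode.
#' @param fusion_groups List of integer vectors: channel-1 spot indices to
#'   fuse into one clustered component each.
#' @param noise_sd Additive Gaussian noise SD (intensity units), clipped to
#'   the bit range.
#' @param seed Integer seed (sets the RNG).
#' @param shape Frame size `(rows, cols)`.
#' @param n_slices Slices per channel.
#' @param spot_sigma_px Gaussian spot width (px).
#' @param peak_intensity Spot peak above background.
#' @param background Background intensity.
#' @param rect_size Rectangle `(height, width)` in px for rectangle mode;
#'   the width is the denominator of exact overlap fractions.
#' @param paired_fraction Fraction of channel-1 spots given a channel-2
#'   partner at a 1-px diagonal offset (high cross-channel overlap); the
#'   remaining channel-2 spots are placed in free cells.
#' @param fusion_spacing_px Distance between fused spot centers; default
#'   `3 * spot_sigma_px` (merged at threshold, separate peaks).
#' @param pixel_size_um,bit_depth,channel_names Stack metadata.
#' @param out_dir If non-`NULL`, the stack is written there as
#'   `<name>.tif` + `<name>.json` (metadata sidecar) and
#'   `<name>_truth.json` (ground truth).
#' @param name Base file name used with `out_dir`.
#' @return List with `stack` (an [nmj_zstack()]), `truth` (data frame of
#'   planned spots: `slice`, `channel`, `id`, `row`, `col` in 0-based pixel
#'   coordinates, `kind`, `group`, `planned_overlap`, `realized_overlap`)
#'   and, when written, `paths`.
#' @export
make_stack <- function(n_spots_per_channel = 50,
                       overlap_plan = NULL,
                       fusion_groups = NULL,
                       noise_sd = 0,
                       seed = 1,
                       shape = c(256L, 256L),
                       n_slices = 2L,
                       spot_sigma_px = 3.2,
                       peak_intensity = 200,
                       background = 8,
                       rect_size = c(6L, 10L),
                       paired_fraction = 0,
                       fusion_spacing_px = NULL,
                       pixel_size_um = 0.21,
                       bit_depth = 8L,
                       channel_names = c("SV2a", "aBTX"),
                       out_dir = NULL,
                       name = "stack") {
  set.seed(seed)
  top <- 2^bit_depth - 1
  if (background + peak_intensity > top) {
    stop("peak intensity exceeds the bit range")
  }
  rect_mode <- !is.null(overlap_plan)
  if (rect_mode) {
    if (any(overlap_plan < 0 | overlap_plan > 1)) {
      stop("overlap fractions must lie in [0, 1]")
    }
    n_spots_per_channel <- length(overlap_plan)
    if (!is.null(fusion_groups) || paired_fraction > 0) {
      stop("rectangle mode does not combine with fusion or pairing")
    }
  }
  n1 <- n_spots_per_channel
  if (is.null(fusion_spacing_px)) fusion_spacing_px <- 3 * spot_sigma_px
  if (!is.null(fusion_groups)) {
    idx <- unlist(fusion_groups)
    if (anyDuplicated(idx) || any(idx < 1 | idx > n1)) {
      stop("fusion_groups must reference distinct channel-1 spot indices")
    }
  }

  # grid cells sized so that occupants of different cells never merge
  if (rect_mode) {
    h <- rect_size[1]; w <- rect_size[2]
    cell_h <- h + 10L
    cell_w <- 2L * w + 12L
  } else {
    gmax <- if (is.null(fusion_groups)) 1L else max(lengths(fusion_groups))
    span <- (gmax - 1L) * fusion_spacing_px
    cell_h <- cell_w <- as.integer(ceiling(6 * spot_sigma_px + span)) + 2L
  }
  ncr <- (shape[1] - 4L) %/% cell_h
  ncc <- (shape[2] - 4L) %/% cell_w
  n_cells <- ncr * ncc
  centers <- cbind(
    rep(seq_len(ncr), times = ncc) * cell_h - cell_h %/% 2L + 2L,
    rep(seq_len(ncc), each = ncr) * cell_w - cell_w %/% 2L + 2L
  )

  # channel-1 entities: fused groups plus leftover singles
  grouped <- if (is.null(fusion_groups)) integer(0) else unlist(fusion_groups)
  singles1 <- setdiff(seq_len(n1), grouped)
  n_pairs <- if (rect_mode) n1 else min(round(paired_fraction * n1), length(singles1))
  n_entities <- if (rect_mode) {
    n1
  } else {
    length(singles1) + length(fusion_groups) + (n1 - n_pairs)  # + unpaired ch2
  }
  if (n_entities > n_cells) {
    stop(sprintf("infeasible plan: %d placements needed, %d cells available",
                 n_entities, n_cells))
  }

  data <- array(0L, c(2L, n_slices, shape[1], shape[2]))
  truth <- list()
  for (s in seq_len(n_slices)) {
    img <- list(matrix(0, shape[1], shape[2]), matrix(0, shape[1], shape[2]))
    cells <- centers[sample.int(n_cells), , drop = FALSE]
    ci <- 0L
    take_cell <- function() {
      ci <<- ci + 1L
      cells[ci, ]
    }
    add_spot <- function(ch, r, c, kind, id, group = NA_integer_,
                         planned = NA_real_, realized = NA_real_) {
      truth[[length(truth) + 1L]] <<- data.frame(
        slice = s, channel = ch, id = id, row = r - 1, col = c - 1,
        kind = kind, group = group, planned_overlap = planned,
        realized_overlap = realized, stringsAsFactors = FALSE
      )
    }

    if (rect_mode) {
      for (i in seq_len(n1)) {
        ctr <- take_cell()
        f <- overlap_plan[i]
        r0 <- ctr[1] - h %/% 2L
        c0 <- ctr[2] - w - 2L
        img[[1]] <- draw_rect(img[[1]], r0, c0, h, w, peak_intensity)
        ov_cols <- round(f * w)
        shift <- if (ov_cols > 0L) w - ov_cols else w + 4L
        img[[2]] <- draw_rect(img[[2]], r0, c0 + shift, h, w, peak_intensity)
        realized <- if (ov_cols > 0L) ov_cols / w else 0
        add_spot(1L, r0 + (h - 1) / 2, c0 + (w - 1) / 2, "rect", i,
                 planned = f, realized = realized)
        add_spot(2L, r0 + (h - 1) / 2, c0 + shift + (w - 1) / 2, "rect", i,
                 planned = f, realized = realized)
      }
    } else {
      pos1 <- matrix(NA_real_, n1, 2)
      if (!is.null(fusion_groups)) {
        for (gi in seq_along(fusion_groups)) {
          g <- fusion_groups[[gi]]
          ctr <- take_cell()
          offs <- (seq_along(g) - (length(g) + 1) / 2) * fusion_spacing_px
          for (j in seq_along(g)) {
            pos1[g[j], ] <- c(ctr[1], ctr[2] + offs[j])
          }
        }
      }
      for (i in singles1) {
        ctr <- take_cell()
        pos1[i, ] <- ctr
      }
      for (i in seq_len(n1)) {
        img[[1]] <- draw_gauss(img[[1]], pos1[i, 1], pos1[i, 2],
                               spot_sigma_px, peak_intensity)
        grp <- NA_integer_
        if (!is.null(fusion_groups)) {
          hit <- which(vapply(fusion_groups, function(g) i %in% g, logical(1)))
          if (length(hit)) grp <- hit
        }
        add_spot(1L, pos1[i, 1], pos1[i, 2], "gauss", i, group = grp)
      }
      # channel 2: partners first, then independent spots
      paired_with <- if (n_pairs > 0L) singles1[seq_len(n_pairs)] else integer(0)
      id2 <- 0L
      for (i in paired_with) {
        id2 <- id2 + 1L
        r <- pos1[i, 1] + 1; c <- pos1[i, 2] + 1
        img[[2]] <- draw_gauss(img[[2]], r, c, spot_sigma_px, peak_intensity)
        add_spot(2L, r, c, "gauss", id2, planned = 1)
      }
      for (j in seq_len(n1 - n_pairs)) {
        id2 <- id2 + 1L
        ctr <- take_cell()
        img[[2]] <- draw_gauss(img[[2]], ctr[1], ctr[2],
                               spot_sigma_px, peak_intensity)
        add_spot(2L, ctr[1], ctr[2], "gauss", id2)
      }
    }

    for (ch in 1:2) {
      v <- img[[ch]] + background
      if (noise_sd > 0) {
        v <- v + matrix(stats::rnorm(length(v), sd = noise_sd),
                        nrow(v), ncol(v))
      }
      data[ch, s, , ] <- pmin(pmax(round(v), 0), top)
    }
  }

  stack <- nmj_zstack(data, nmj_calibration(pixel_size_um),
                      channel_names = channel_names, bit_depth = bit_depth)
  truth_df <- if (length(truth)) {
    do.call(rbind, c(truth, list(make.row.names = FALSE)))
  } else {
    data.frame(slice = integer(), channel = integer(), id = integer(),
               row = numeric(), col = numeric(), kind = character(),
               group = integer(), planned_overlap = numeric(),
               realized_overlap = numeric(), stringsAsFactors = FALSE)
  }
  out <- list(stack = stack, truth = truth_df)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    tif <- file.path(out_dir, paste0(name, ".tif"))
    write_zstack(stack, tif)
    tf <- file.path(out_dir, paste0(name, "_truth.json"))
    jsonlite::write_json(truth_df, tf, digits = NA)
    out$paths <- c(tiff = tif, sidecar = sidecar_path(tif), truth = tf)
  }
  out
}

draw_gauss <- function(img, r, c, sigma, peak) {
  rad <- ceiling(4 * sigma)
  rr <- max(1L, floor(r - rad)):min(nrow(img), ceiling(r + rad))
  cc <- max(1L, floor(c - rad)):min(ncol(img), ceiling(c + rad))
  d2 <- outer((rr - r)^2, (cc - c)^2, `+`)
  img[rr, cc] <- img[rr, cc] + peak * exp(-d2 / (2 * sigma^2))
  img
}

draw_rect <- function(img, r0, c0, h, w, peak) {
  rr <- r0:(r0 + h - 1L)
  cc <- c0:(c0 + w - 1L)
  if (min(rr) < 1L || min(cc) < 1L || max(rr) > nrow(img) || max(cc) > ncol(img)) {
    stop("infeasible plan: rectangle outside the frame")
  }
  img[rr, cc] <- pmax(img[rr, cc], peak)
  img
}

#' Generate matched "wild-type" and "depleted" fixture sets
#'
#' Emulates, qualitatively, a disease model with fewer synaptic termini: the
#' depleted group has ~28% fewer spots per channel per slice and a lower
#' pairing rate between channels than the wild-type-like group. Used to
#' demonstrate that the pipeline orders group means correctly (depleted
#' counts below wild-type); it makes no claim of reproducing any real
#' biological magnitudes.
#'
#' @param seed Integer seed; stack `i` of each group uses `seed + i`-derived
#'   offsets, so the two groups are independent but reproducible.
#' @param n_stacks Stacks per group (default 10).
#' @param n_spots_wt,n_spots_depleted Spots per channel per slice.
#' @param paired_wt,paired_depleted Cross-channel pairing rates.
#' @param noise_sd Additive noise SD.
#' @param ... Further arguments passed to [make_stack()].
#' @return List with elements `wt` and `depleted`, each a list of
#'   [make_stack()] results.
#' @export
make_disease_contrast <- function(seed, n_stacks = 10L,
                                  n_spots_wt = 50L, n_spots_depleted = 36L,
                                  paired_wt = 0.6, paired_depleted = 0.45,
                                  noise_sd = 2, ...) {
  wt <- lapply(seq_len(n_stacks), function(i) {
    make_stack(n_spots_per_channel = n_spots_wt, paired_fraction = paired_wt,
               noise_sd = noise_sd, seed = seed + i, ...)
  })
  depleted <- lapply(seq_len(n_stacks), function(i) {
    make_stack(n_spots_per_channel = n_spots_depleted,
               paired_fraction = paired_depleted,
               noise_sd = noise_sd, seed = seed + 10000L + i, ...)
  })
  list(wt = wt, depleted = depleted)
}
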