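#' The 11 co-localization thresholds
#'
#' Overlap thresholds in percent: `>0%, >10%, ..., >90%, =100%`.
#' @return Integer vector `c(0, 10, ..., 100)`.
#' @export
coloc_thresholds <- function() seq(0L, 100L, by = 10L)

#' Pixel-wise AND of two binary masks
#'
#' @param mask1,mask2 Logical matrices of identical shape (same slice of the
#'   two channels).
#' @return Logical matrix, `TRUE` exactly where both inputs are `TRUE`.
#' @export
overlap_image <- function(mask1, mask2) {
  stopifnot(is.matrix(mask1), is.matrix(mask2))
  if (!identical(dim(mask1), dim(mask2))) {
    stop("masks must have identical dimensions")
  }
  mask1 & mask2
}

#' Fraction of a punctum's area covered by the other channel
#'
#' @param p An `nmj_punctum` (or a `(row, col)` pixel matrix).
#' @param other_mask Logical foreground mask of the other channel on the
#'   same slice.
#' @return Overlap fraction in `[0, 1]`.
#' @export
punctum_overlap_fraction <- function(p, other_mask) {
  pixels <- if (inherits(p, "nmj_punctum")) p$pixels else p
  stopifnot(is.matrix(pixels), is.matrix(other_mask))
  if (nrow(pixels) == 0L) stop("empty punctum")
  if (max(pixels[, 1]) > nrow(other_mask) || max(pixels[, 2]) > ncol(other_mask) ||
      min(pixels) < 1L) {
    stop("punctum pixels fall outside the mask frame")
  }
  sum(other_mask[pixels]) / nrow(pixels)
}

#' Per-punctum overlap records for one slice
#'
#' @param puncta List of `nmj_punctum` for one channel/slice.
#' @param other_mask The other channel's foreground mask on that slice.
#' @param channel,slice Indices recorded in the output.
#' @param exclude_unsegmentable Drop puncta with status `unsegmentable` from
#'   the tally (default `FALSE`: they are counted like any other punctum).
#' @return Data frame with columns `channel`, `slice`, `punctum_id`,
#'   `status`, `n_px`, `n_overlap`, `overlap_fraction`.
#' @export
overlap_records <- function(puncta, other_mask, channel, slice,
                            exclude_unsegmentable = FALSE) {
  if (exclude_unsegmentable) {
    puncta <- Filter(function(p) p$status != "unsegmentable", puncta)
  }
  if (length(puncta) == 0L) {
    return(data.frame(channel = integer(), slice = integer(),
                      punctum_id = character(), status = character(),
                      n_px = integer(), n_overlap = integer(),
                      overlap_fraction = numeric(), stringsAsFactors = FALSE))
  }
  n_px <- vapply(puncta, `[[`, integer(1), "n_px")
  n_ov <- vapply(puncta, function(p) sum(other_mask[p$pixels]), integer(1))
  data.frame(
    channel = channel,
    slice = slice,
    punctum_id = vapply(puncta, `[[`, character(1), "id"),
    status = vapply(puncta, `[[`, character(1), "status"),
    n_px = n_px,
    n_overlap = n_ov,
    overlap_fraction = n_ov / n_px,
    stringsAsFactors = FALSE
  )
}

#' Tally single and co-localized puncta at the 11 thresholds
#'
#' Accumulates per-punctum overlap records (all slices of one ROI) into the
#' result table: per channel, the total punctum count and, at each threshold
#' `t`, how many puncta are single (overlap not past `t`) and co-localized
#' (overlap past `t`). At every threshold `single + coloc = total`, and the
#' co-localized count is non-increasing in `t`. Both channel directions
#' (channel 1 vs 2 and 2 vs 1) are tallied independently.
#'
#' @param records Data frame from [overlap_records()] (rows from several
#'   slices/channels may be concatenated).
#' @param roi_name Name written into the table.
#' @param channels Channels to report (default: those present, else `1:2`).
#' @return Data frame of class `nmj_coloc_table`: one row per channel with
#'   columns `roi`, `channel`, `total`, then `single_<t>` and `coloc_<t>`
#'   for `t` in `0, 10, ..., 100`.
#' @export
tabulate_coloc <- function(records, roi_name, channels = NULL) {
  th <- coloc_thresholds()
  if (is.null(channels)) {
    channels <- if (nrow(records)) sort(unique(records$channel)) else 1:2
  }
  rows <- lapply(channels, function(ch) {
    rec <- records[records$channel == ch, , drop = FALSE]
    total <- nrow(rec)
    row <- list(roi = roi_name, channel = ch, total = total)
    for (t in th) {
      cc <- if (total) sum(is_colocalized(rec$n_px, rec$n_overlap, t)) else 0L
      row[[paste0("single_", t)]] <- total - cc
      row[[paste0("coloc_", t)]] <- cc
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("nmj_coloc_table", class(out))
  out
}

# Exact threshold decision in integer arithmetic, vectorised over puncta:
# co-localized at threshold t (percent) iff overlap > t% for t < 100, and
# iff full coverage for t = 100.
is_colocalized <- function(n_px, n_overlap, t) {
  if (t >= 100L) n_overlap == n_px else 100 * n_overlap > t * n_px
}
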