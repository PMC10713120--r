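#' Calibrated multi-channel z-stack
#'
#' The unit of input of the pipeline: a 4-D grayscale intensity volume indexed
#' `[channel, slice, row, column]`, together with its spatial calibration and
#' channel labels. Intensities must be non-negative integers of a declared bit
#' depth (8 or 16 bit); all slices share the same frame size.
#'
#' The pipeline entry point requires exactly two channels (presynaptic and
#' postsynaptic markers); the lower-level operations accept any channel count.
#'
#' @param data 4-D numeric array `[channel, slice, row, column]` of
#'   non-negative integer intensities.
#' @param calibration An [nmj_calibration()] object.
#' @param channel_names Character vector of channel labels, one per channel.
#'   Defaults to `"SV2a"` (presynaptic) and `"aBTX"` (postsynaptic) for
#'   two-channel data, otherwise `"ch1"`, `"ch2"`, ...
#' @param bit_depth Integer, 8 or 16. Intensities must fit in this depth.
#'
#' @return An object of class `nmj_zstack`.
#' @export
nmj_zstack <- function(data, calibration = nmj_calibration(),
                       channel_names = NULL, bit_depth = 8L) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    stop("'data' must be a 4-D array [channel, slice, row, column]")
  }
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16")
  if (any(data < 0) || any(data != round(data))) {
    stop("intensities must be non-negative integers")
  }
  if (max(data) > 2^bit_depth - 1) {
    stop("intensities exceed the declared bit depth")
  }
  stopifnot(inherits(calibration, "nmj_calibration"))
  nc <- dim(data)[1]
  if (is.null(channel_names)) {
    channel_names <- if (nc == 2L) c("SV2a", "aBTX") else paste0("ch", seq_len(nc))
  }
  if (length(channel_names) != nc) {
    stop("'channel_names' must have one entry per channel")
  }
  structure(
    list(
      data = data,
      calibration = calibration,
      channel_names = as.character(channel_names),
      bit_depth = as.integer(bit_depth)
    ),
    class = "nmj_zstack"
  )
}

#' @export
print.nmj_zstack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "nmj_zstack: %d channel(s) [%s], %d slice(s), %d x %d px, %d-bit\n",
    d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4],
    x$bit_depth
  ))
  print(x$calibration)
  invisible(x)
}

#' @export
dim.nmj_zstack <- function(x) dim(x$data)

#' Extract one slice of one channel as a plain intensity matrix
#'
#' @param stack An [nmj_zstack()].
#' @param channel,slice 1-based channel and slice indices.
#' @return Numeric matrix `[row, column]`.
#' @export
get_slice <- function(stack, channel, slice) {
  stopifnot(inherits(stack, "nmj_zstack"))
  d <- dim(stack$data)
  if (channel < 1 || channel > d[1]) stop("invalid channel index")
  if (slice < 1 || slice > d[2]) stop("invalid slice index")
  matrix(stack$data[channel, slice, , ], d[3], d[4])
}

#' Z-projection of one channel
#'
#' Collapses the slice axis to a single 2-D image, by default with the
#' pixel-wise maximum (the standard projection for punctate fluorescence,
#' used here only to give users a view on which to draw ROIs; the analysis
#' itself runs per slice).
#'
#' @param stack An [nmj_zstack()].
#' @param channel 1-based channel index.
#' @param method `"max"` (default) or `"mean"`.
#' @return Numeric matrix `[row, column]`.
#' @examples
#' arr <- array(0L, c(1, 2, 4, 4)); arr[1, 1, 1, 1] <- 10L; arr[1, 2, 4, 4] <- 20L
#' zp <- z_project(nmj_zstack(arr), 1)
#' zp[1, 1] == 10 && zp[4, 4] == 20
#' @export
z_project <- function(stack, channel, method = c("max", "mean")) {
  stopifnot(inherits(stack, "nmj_zstack"))
  method <- match.arg(method)
  d <- dim(stack$data)
  slices <- lapply(seq_len(d[2]), function(s) get_slice(stack, channel, s))
  if (method == "max") {
    Reduce(pmax, slices)
  } else {
    Reduce(`+`, slices) / d[2]
  }
}

# ---- TIFF + sidecar I/O ----------------------------------------------------

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path, ignore.case = TRUE)

#' Write a z-stack to a multi-page TIFF with a JSON metadata sidecar
#'
#' Pages are stored channel-fastest (`c1 s1, c2 s1, c1 s2, ...`), matching the
#' XYCZT hyperstack convention. The sidecar (`<name>.json`) records channel
#' count and names, bit depth and calibration, so [read_zstack()] can restore
#' the stack without guessing.
#'
#' @param stack An [nmj_zstack()].
#' @param path Output TIFF path (`.tif`/`.tiff`).
#' @param sidecar Write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path, sidecar = TRUE) {
  stopifnot(inherits(stack, "nmj_zstack"))
  d <- dim(stack$data)
  top <- 2^stack$bit_depth - 1
  pages <- vector("list", d[1] * d[2])
  k <- 0L
  for (s in seq_len(d[2])) {
    for (ch in seq_len(d[1])) {
      k <- k + 1L
      pages[[k]] <- get_slice(stack, ch, s) / top
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  if (sidecar) {
    meta <- list(
      n_channels = d[1],
      channel_names = stack$channel_names,
      bit_depth = stack$bit_depth,
      pixel_size_um = stack$calibration$pixel_size_um,
      z_step_um = stack$calibration$z_step_um
    )
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a calibrated z-stack from a multi-page TIFF
#'
#' Pages are interpreted channel-fastest (see [write_zstack()]). Calibration
#' is resolved in priority order: the `pixel_size_um` argument, then a JSON
#' sidecar next to the file, then TIFF resolution tags, then a hard default of
#' 0.21 um/px with a warning.
#'
#' @param path TIFF path.
#' @param n_channels Channel count; default from the sidecar, else 2.
#' @param pixel_size_um Explicit calibration override (um/px).
#' @param channel_names Optional channel labels.
#' @return An [nmj_zstack()].
#' @export
read_zstack <- function(path, n_channels = NULL, pixel_size_um = NULL,
                        channel_names = NULL) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  bit_depth <- if (!is.null(bits) && bits %in% c(8, 16)) as.integer(bits) else 8L

  if (is.null(n_channels)) {
    n_channels <- if (!is.null(meta$n_channels)) as.integer(meta$n_channels) else 2L
  }
  np <- length(pages)
  if (np %% n_channels != 0L) {
    stop(sprintf("page count (%d) is not a multiple of the channel count (%d)",
                 np, n_channels))
  }
  n_slices <- np %/% n_channels
  dims <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), dims), logical(1)))) {
    stop("all TIFF pages must share the same dimensions")
  }

  if (is.null(pixel_size_um)) {
    if (!is.null(meta$pixel_size_um)) {
      pixel_size_um <- meta$pixel_size_um
    } else {
      pixel_size_um <- pixel_size_from_tags(pages[[1]])
      if (is.null(pixel_size_um)) {
        warning("no calibration found; falling back to 0.21 um/px")
        pixel_size_um <- 0.21
      }
    }
  }
  z_step <- if (!is.null(meta$z_step_um)) meta$z_step_um else 0.44
  if (is.null(channel_names) && !is.null(meta$channel_names)) {
    channel_names <- meta$channel_names
  }

  data <- array(0L, c(n_channels, n_slices, dims[1], dims[2]))
  k <- 0L
  for (s in seq_len(n_slices)) {
    for (ch in seq_len(n_channels)) {
      k <- k + 1L
      data[ch, s, , ] <- pages[[k]]
    }
  }
  nmj_zstack(data, nmj_calibration(pixel_size_um, z_step),
             channel_names = channel_names, bit_depth = bit_depth)
}

# Resolve pixel size (um) from TIFF resolution tags, if present and sane.
pixel_size_from_tags <- function(page) {
  xres <- attr(page, "x.resolution")
  unit <- attr(page, "resolution.unit")
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(NULL)
  if (is.null(unit)) return(NULL)
  if (identical(unit, "cm")) return(1e4 / xres)
  if (identical(unit, "inch")) return(25400 / xres)
  NULL
}
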