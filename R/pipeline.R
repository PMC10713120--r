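#' Analyse one z-stack over a set of ROIs
#'
#' The per-stack engine of the pipeline. For every ROI, channel and slice:
#' Gaussian blur, histogram expansion and Otsu thresholding restricted to the
#' ROI, despeckling, punctum detection and classification, optional recursive
#' declustering, then object-based co-localization of each channel's puncta
#' against the other channel's foreground on the same slice. Counts are
#' accumulated over slices into one result table per ROI. The whole
#' computation is deterministic.
#'
#' @param stack An [nmj_zstack()] with exactly 2 channels.
#' @param rois List of [roi_region()] objects (or a single one).
#' @param preprocess A [preprocess_params()].
#' @param criteria A [cluster_criteria()], or a list of two (one per
#'   channel).
#' @param seg_params A [segmentation_params()].
#' @param segmentation Run the declustering stage (default `TRUE`).
#' @param exclude_unsegmentable Drop unsegmentable clusters from the
#'   co-localization tally (default `FALSE`; totals then exclude them too).
#' @return Object of class `nmj_stack_result`: list with `table`
#'   (rows per ROI x channel, see [tabulate_coloc()]), `records`
#'   (per-punctum overlap records), `counts` (per-stage punctum counts),
#'   `warnings`, and the parameter echo `params`.
#' @export
analyse_stack <- function(stack, rois,
                          preprocess = preprocess_params(),
                          criteria = cluster_criteria(),
                          seg_params = segmentation_params(),
                          segmentation = TRUE,
                          exclude_unsegmentable = FALSE) {
  stopifnot(inherits(stack, "nmj_zstack"))
  d <- dim(stack$data)
  if (d[1] != 2L) stop("the pipeline requires exactly 2 channels")
  if (inherits(rois, "nmj_roi")) rois <- list(rois)
  crit <- if (inherits(criteria, "nmj_cluster_criteria")) {
    list(criteria, criteria)
  } else {
    stopifnot(length(criteria) == 2L)
    criteria
  }
  cal <- stack$calibration
  warnings <- character(0)
  counts <- data.frame()
  tables <- list()
  all_records <- list()

  for (roi in rois) {
    roi_mask <- rasterize_roi(roi, d[3:4])
    roi_records <- list()
    cnt <- list(detected = c(0L, 0L), single = c(0L, 0L),
                clustered = c(0L, 0L), parents_split = c(0L, 0L),
                children = c(0L, 0L), unsegmentable = c(0L, 0L))
    for (s in seq_len(d[2])) {
      slice_puncta <- vector("list", 2L)
      slice_masks <- vector("list", 2L)
      for (ch in 1:2) {
        raw <- get_slice(stack, ch, s)
        step <- preprocess_slice(raw, roi_mask, preprocess, stack$bit_depth, cal)
        if (!is.null(step$warning)) {
          warnings <- c(warnings, sprintf("%s ch%d slice %d: %s",
                                          roi$name, ch, s, step$warning))
        }
        puncta <- find_puncta(step$mask, cal, crit[[ch]], roi_mask = roi_mask)
        cnt$detected[ch] <- cnt$detected[ch] + length(puncta)
        st <- vapply(puncta, `[[`, character(1), "status")
        cnt$clustered[ch] <- cnt$clustered[ch] + sum(st == "clustered")
        if (segmentation && any(st == "clustered")) {
          seg <- segment_all(puncta, raw, crit[[ch]], seg_params, cal)
          puncta <- seg$puncta
          cnt$parents_split[ch] <- cnt$parents_split[ch] + seg$stats$parents_split
          cnt$children[ch] <- cnt$children[ch] + seg$stats$children
          cnt$unsegmentable[ch] <- cnt$unsegmentable[ch] + seg$stats$unsegmentable
        }
        stf <- vapply(puncta, `[[`, character(1), "status")
        cnt$single[ch] <- cnt$single[ch] + sum(stf == "single")
        slice_puncta[[ch]] <- puncta
        slice_masks[[ch]] <- step$mask
      }
      for (ch in 1:2) {
        other <- if (ch == 1L) 2L else 1L
        roi_records[[length(roi_records) + 1L]] <- overlap_records(
          slice_puncta[[ch]], slice_masks[[other]], ch, s,
          exclude_unsegmentable = exclude_unsegmentable
        )
      }
    }
    rec <- do.call(rbind, roi_records)
    tables[[roi$name]] <- tabulate_coloc(rec, roi$name, channels = 1:2)
    all_records[[roi$name]] <- rec
    counts <- rbind(counts, data.frame(
      roi = roi$name, channel = 1:2,
      detected = cnt$detected, single = cnt$single,
      clustered = cnt$clustered, parents_split = cnt$parents_split,
      children = cnt$children, unsegmentable = cnt$unsegmentable,
      stringsAsFactors = FALSE
    ))
  }

  table <- do.call(rbind, unname(tables))
  rownames(table) <- NULL
  structure(
    list(table = table,
         records = do.call(rbind, unname(all_records)),
         counts = counts,
         warnings = warnings,
         channel_names = stack$channel_names,
         params = list(preprocess = preprocess, criteria = crit,
                       segmentation = seg_params,
                       segmentation_enabled = segmentation,
                       exclude_unsegmentable = exclude_unsegmentable,
                       pixel_size_um = cal$pixel_size_um)),
    class = "nmj_stack_result"
  )
}

# One channel-slice: blur -> histogram expansion -> Otsu -> despeckle,
# all restricted to the ROI. A slice that is constant within the ROI (no
# separable classes) yields an empty mask plus a warning string.
preprocess_slice <- function(raw, roi_mask, pp, bit_depth, cal) {
  bl <- gaussian_blur(raw, pp$gaussian_sigma)
  warn <- NULL
  ex <- withCallingHandlers(
    expand_histogram(bl, pp$trim_fraction, bit_depth, mask = roi_mask),
    warning = function(w) {
      warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    }
  )
  ex <- round(ex)
  mask <- tryCatch(
    otsu_threshold(ex, mask = roi_mask)$mask,
    error = function(e) {
      warn <<- conditionMessage(e)
      matrix(FALSE, nrow(raw), ncol(raw))
    }
  )
  list(mask = despeckle(mask, cal, pp$despeckle_area_um2), warning = warn)
}

#' @export
print.nmj_stack_result <- function(x, ...) {
  cat("nmj_stack_result\n")
  tot <- x$table[, c("roi", "channel", "total", "coloc_0")]
  print(tot, row.names = FALSE)
  if (length(x$warnings)) cat(length(x$warnings), "warning(s)\n")
  invisible(x)
}

#' Run configuration for the batch pipeline
#'
#' Collects every tunable of the workflow. All fields mirror the YAML config
#' schema and the command-line flags of the `nmjquant` script; command-line
#' flags override the file.
#'
#' @param input_dir Folder containing the TIFF stacks.
#' @param roi_file JSON ROI file (see [read_rois()]) applied to every stack.
#' @param output_dir Folder for result CSVs (created if missing).
#' @param pixel_size_um Optional calibration override (um/px).
#' @param channel_names Channel labels; channel 1 is presynaptic by
#'   convention.
#' @param preprocess,criteria,seg_params See [analyse_stack()].
#' @param segmentation_enabled,exclude_unsegmentable Stage switches.
#' @param save_masks Also write per-slice foreground masks as TIFFs for QC.
#' @return Object of class `nmj_run_config`.
#' @export
nmj_config <- function(input_dir, roi_file, output_dir,
                       pixel_size_um = NULL,
                       channel_names = c("SV2a", "aBTX"),
                       preprocess = preprocess_params(),
                       criteria = cluster_criteria(),
                       seg_params = segmentation_params(),
                       segmentation_enabled = TRUE,
                       exclude_unsegmentable = FALSE,
                       save_masks = FALSE) {
  if (!dir.exists(input_dir)) stop("input_dir does not exist: ", input_dir)
  if (!file.exists(roi_file)) stop("roi_file does not exist: ", roi_file)
  structure(list(input_dir = input_dir, roi_file = roi_file,
                 output_dir = output_dir, pixel_size_um = pixel_size_um,
                 channel_names = channel_names, preprocess = preprocess,
                 criteria = criteria, seg_params = seg_params,
                 segmentation_enabled = segmentation_enabled,
                 exclude_unsegmentable = exclude_unsegmentable,
                 save_masks = save_masks),
            class = "nmj_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The schema mirrors [nmj_config()]:
#' ```yaml
#' input_dir: stacks/
#' roi_file: rois.json
#' output_dir: results/
#' pixel_size_um: 0.21
#' gaussian_sigma: 1.0
#' trim_fraction: 0.10
#' despeckle_area_um2: 0.043
#' max_area_um2: 4
#' min_circularity: 0.65
#' max_aspect_ratio: 2.5
#' maxima_prominence: ~      # null = 10% of dynamic range
#' segmentation_enabled: true
#' exclude_unsegmentable: false
#' ```
#' @param path YAML file.
#' @param overrides Named list of values taking precedence over the file
#'   (used by the CLI).
#' @return An `nmj_run_config`.
#' @export
read_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  get_or <- function(name, default) if (!is.null(y[[name]])) y[[name]] else default
  nmj_config(
    input_dir = y$input_dir, roi_file = y$roi_file, output_dir = y$output_dir,
    pixel_size_um = y$pixel_size_um,
    channel_names = get_or("channel_names", c("SV2a", "aBTX")),
    preprocess = preprocess_params(
      gaussian_sigma = get_or("gaussian_sigma", 1.0),
      trim_fraction = get_or("trim_fraction", 0.10),
      despeckle_area_um2 = get_or("despeckle_area_um2", 0.043)
    ),
    criteria = cluster_criteria(
      max_area_um2 = get_or("max_area_um2", 4),
      min_circularity = get_or("min_circularity", 0.65),
      max_aspect_ratio = get_or("max_aspect_ratio", 2.5)
    ),
    seg_params = segmentation_params(
      gaussian_sigma = get_or("seg_gaussian_sigma", 1.0),
      maxima_prominence = y$maxima_prominence,
      max_rounds = get_or("max_rounds", 10L)
    ),
    segmentation_enabled = get_or("segmentation_enabled", TRUE),
    exclude_unsegmentable = get_or("exclude_unsegmentable", FALSE),
    save_masks = get_or("save_masks", FALSE)
  )
}

#' Run the full batch pipeline
#'
#' Scans `input_dir` for TIFF stacks (lexicographic order, for stable
#' output), analyses each with [analyse_stack()] over the ROIs of
#' `roi_file`, and writes one CSV result table per stack to `output_dir`
#' (`<stack>_coloc.csv`). Files that fail to read or analyse are recorded in
#' the report and the run continues. Two runs on identical inputs and
#' configuration produce byte-identical CSVs.
#'
#' @param config An [nmj_config()] (or path to a YAML file).
#' @return Object of class `nmj_report`: per-image results, pooled tables,
#'   stage counts, per-file errors and the full parameter echo.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "nmj_run_config"))
  rois <- read_rois(config$roi_file)
  files <- sort(list.files(config$input_dir, pattern = "\\.tiff?$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
  }
  images <- list()
  errors <- character(0)
  for (f in files) {
    name <- sub("\\.tiff?$", "", basename(f), ignore.case = TRUE)
    res <- tryCatch({
      stack <- read_zstack(f, pixel_size_um = config$pixel_size_um,
                           channel_names = config$channel_names)
      out <- analyse_stack(
        stack, rois,
        preprocess = config$preprocess,
        criteria = config$criteria,
        seg_params = config$seg_params,
        segmentation = config$segmentation_enabled,
        exclude_unsegmentable = config$exclude_unsegmentable
      )
      csv <- file.path(config$output_dir, paste0(name, "_coloc.csv"))
      utils::write.csv(out$table, csv, row.names = FALSE)
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("%s: %s", name, conditionMessage(res)))
    } else {
      images[[name]] <- res
    }
  }
  tables <- NULL
  counts <- NULL
  if (length(images)) {
    tables <- do.call(rbind, c(
      lapply(names(images), function(n) cbind(image = n, images[[n]]$table)),
      list(make.row.names = FALSE)
    ))
    counts <- do.call(rbind, c(
      lapply(names(images), function(n) cbind(image = n, images[[n]]$counts)),
      list(make.row.names = FALSE)
    ))
  }
  structure(list(images = images, table = tables, counts = counts,
                 errors = errors, config = config),
            class = "nmj_report")
}

#' @export
print.nmj_report <- function(x, ...) {
  cat(sprintf("nmj_report: %d image(s) analysed, %d error(s)\n",
              length(x$images), length(x$errors)))
  if (!is.null(x$table)) {
    print(x$table[, c("image", "roi", "channel", "total", "coloc_0")],
          row.names = FALSE)
  }
  if (length(x$errors)) cat("errors:\n ", paste(x$errors, collapse = "\n  "), "\n")
  invisible(x)
}

#' @export
summary.nmj_report <- function(object, ...) {
  cat(sprintf("Pipeline run over %d image(s); %d ROI(s) per image\n",
              length(object$images),
              if (length(object$images)) {
                length(unique(object$images[[1]]$table$roi))
              } else 0L))
  if (!is.null(object$counts)) {
    agg <- stats::aggregate(
      cbind(detected, single, clustered, unsegmentable) ~ channel,
      data = object$counts, FUN = sum
    )
    cat("Per-stage punctum counts (summed over images and ROIs):\n")
    print(agg, row.names = FALSE)
  }
  if (!is.null(object$table)) {
    agg2 <- stats::aggregate(cbind(total, coloc_0, coloc_50, coloc_100) ~ channel,
                             data = object$table, FUN = sum)
    cat("Co-localization totals:\n")
    print(agg2, row.names = FALSE)
  }
  invisible(object)
}
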