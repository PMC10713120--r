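cal <- nmj_calibration(0.21)

# two Gaussian peaks of height `peak` with a saddle between them, on a flat
# background; returns the image and the fused pixel set above `thr`
two_peak_image <- function(frame = 40L, sep = 10, sigma = 3, peak = 200,
                           thr = 60) {
  ctr <- c(frame / 2, frame / 2)
  p1 <- c(ctr[1], ctr[2] - sep / 2)
  p2 <- c(ctr[1], ctr[2] + sep / 2)
  rr <- matrix(seq_len(frame), frame, frame)
  cc <- t(rr)
  img <- peak * exp(-((rr - p1[1])^2 + (cc - p1[2])^2) / (2 * sigma^2)) +
         peak * exp(-((rr - p2[1])^2 + (cc - p2[2])^2) / (2 * sigma^2))
  list(img = img, pixels = which(img > thr, arr.ind = TRUE),
       peaks = rbind(p1, p2))
}

test_that("maxima seeding finds plateau centers and separated peaks", {
  # uniform punctum: one plateau, one seed at the centroid-nearest pixel
  img <- matrix(10, 9, 9)
  px <- as.matrix(expand.grid(r = 3:7, c = 3:7))
  s <- find_local_maxima(img, px, prominence = 2)
  expect_equal(nrow(s), 1L)
  expect_equal(unname(s[1, 1:2]), c(5L, 5L))

  # two clear peaks above the prominence floor
  tp <- two_peak_image()
  s2 <- find_local_maxima(tp$img, tp$pixels, prominence = 20)
  expect_equal(nrow(s2), 2L)
  got <- s2[order(s2[, "col"]), 1:2, drop = FALSE]
  expect_lt(max(abs(got - tp$peaks)), 1.0)

  # one peak -> one seed (cluster would be left as is)
  one <- two_peak_image(sep = 0)
  s3 <- find_local_maxima(one$img, one$pixels, prominence = 20)
  expect_equal(nrow(s3), 1L)

  # prominence larger than the dip merges the two peaks into one seed
  s4 <- find_local_maxima(tp$img, tp$pixels, prominence = 250)
  expect_equal(nrow(s4), 1L)
})

test_that("seeded expansion follows the deterministic direction/label order", {
  bar <- cbind(rep(1L, 5), 1:5)
  parts <- expand_seeds(bar, rbind(c(1L, 1L), c(1L, 5L)))
  # hand trace: at index 0 the left-end seed claims rightward once, the
  # right-end seed claims leftward twice (left precedes right in the
  # direction order), leaving a 2 px / 3 px split
  expect_equal(vapply(parts, nrow, integer(1)), c(2L, 3L))
  expect_setequal(parts[[1]][, 2], 1:2)
  expect_setequal(parts[[2]][, 2], 3:5)

  # two 3x3 squares joined by a single-pixel bridge
  m <- matrix(FALSE, 7, 11)
  m[2:4, 2:4] <- TRUE
  m[2:4, 8:10] <- TRUE
  m[3, 5:7] <- TRUE
  px <- which(m, arr.ind = TRUE)
  parts2 <- expand_seeds(px, rbind(c(3L, 3L), c(3L, 9L)))
  sq1 <- as.matrix(expand.grid(row = 2:4, col = 2:4))
  sq2 <- as.matrix(expand.grid(row = 2:4, col = 8:10))
  in_set <- function(a, b) {
    nrow(merge(as.data.frame(a), as.data.frame(b))) == nrow(a)
  }
  expect_true(in_set(sq1, parts2[[1]]))
  expect_true(in_set(sq2, parts2[[2]]))

  expect_error(expand_seeds(bar, rbind(c(1L, 1L), c(2L, 9L))), "outside")
})

test_that("expansion partitions random blobs: conservation, disjointness, connectivity", {
  set.seed(99)
  for (rep in 1:25) {
    px <- random_blob(40)
    if (nrow(px) < 6) next
    k <- sample(2:4, 1)
    seeds <- random_seeds(px, k)
    parts <- expand_seeds(px, seeds)
    all_px <- do.call(rbind, parts)
    expect_equal(nrow(all_px), nrow(px))                 # conservation
    expect_equal(anyDuplicated(all_px), 0L)              # disjoint
    key <- function(m) paste(m[, 1], m[, 2])
    expect_setequal(key(all_px), key(px))                # exact union
    for (j in seq_len(k)) {
      expect_true(key(seeds)[j] %in% key(parts[[j]]))    # seed containment
      sub <- matrix(FALSE, 40, 40)
      sub[parts[[j]]] <- TRUE
      expect_equal(max(oracle_flood_label(sub)), 1L)     # 8-connected region
    }
    # determinism: identical inputs give identical partitions
    expect_identical(parts, expand_seeds(px, seeds))
  }
})

test_that("recursive declustering splits a dumbbell and respects no-op inputs", {
  tp <- two_peak_image(sep = 10, sigma = 3, peak = 200)
  img <- round(tp$img)
  mask <- matrix(FALSE, 40, 40)
  mask[tp$pixels] <- TRUE
  puncta <- find_puncta(mask, cal)
  expect_identical(puncta[[1]]$status, "clustered")
  seg <- segment_all(puncta, img, cal = cal)
  expect_equal(seg$stats$parents_split, 1L)
  st <- vapply(seg$puncta, `[[`, character(1), "status")
  expect_identical(st, c("single", "single"))
  cents <- t(vapply(seg$puncta, `[[`, numeric(2), "centroid"))
  d <- sqrt(rowSums((cents[order(cents[, 2]), ] - tp$peaks)^2))
  expect_lt(max(d), 2)

  # all-single input passes through untouched
  m <- matrix(FALSE, 10, 10)
  m[3:4, 3:4] <- TRUE
  singles <- find_puncta(m, cal)
  out <- segment_all(singles, matrix(50, 10, 10) + diag(10), cal = cal)
  expect_identical(out$puncta, singles)

  # elongated blob with a single maximum cannot be split
  bar_mask <- matrix(FALSE, 12, 30)
  bar_mask[6:7, 3:28] <- TRUE
  ramp <- matrix(rep(seq_len(30), each = 12), 12, 30)  # monotone: one maximum
  bar_puncta <- find_puncta(bar_mask, cal)
  expect_identical(bar_puncta[[1]]$status, "clustered")
  out2 <- segment_all(bar_puncta, ramp, cal = cal)
  expect_length(out2$puncta, 1L)
  expect_identical(out2$puncta[[1]]$status, "unsegmentable")
})

test_that("declustering conserves pixels across arbitrary recursion", {
  set.seed(123)
  for (rep in 1:8) {
    frame <- 48L
    img <- matrix(0, frame, frame)
    for (i in 1:4) {
      ctr <- runif(2, 12, 36)
      rr <- matrix(seq_len(frame), frame, frame)
      img <- img + 180 * exp(-((rr - ctr[1])^2 + (t(rr) - ctr[2])^2) / 18)
    }
    img <- round(img)
    mask <- img > 40
    if (!any(mask)) next
    puncta <- find_puncta(mask, cal)
    seg <- segment_all(puncta, img, cal = cal)
    n_in <- sum(vapply(puncta, `[[`, integer(1), "n_px"))
    n_out <- sum(vapply(seg$puncta, `[[`, integer(1), "n_px"))
    expect_identical(n_out, n_in)
    all_out <- do.call(rbind, lapply(seg$puncta, `[[`, "pixels"))
    expect_equal(anyDuplicated(all_out), 0L)
  }
})

test_that("the recursion cap marks stubborn lineages unsegmentable", {
  tp <- two_peak_image()
  mask <- matrix(FALSE, 40, 40)
  mask[tp$pixels] <- TRUE
  puncta <- find_puncta(mask, cal)
  # max_rounds = 0 is invalid; cap of 1 with an impossible criterion forces
  # children to hit the cap
  strict <- cluster_criteria(max_area_um2 = 1e-6)
  pu <- lapply(puncta, function(p) { p$status <- "clustered"; p })
  expect_warning(
    out <- segment_all(pu, round(tp$img), criteria = strict,
                       params = segmentation_params(max_rounds = 1L), cal = cal),
    "cap"
  )
  st <- vapply(out$puncta, `[[`, character(1), "status")
  expect_true(all(st == "unsegmentable"))
  n_in <- sum(vapply(puncta, `[[`, integer(1), "n_px"))
  expect_identical(sum(vapply(out$puncta, `[[`, integer(1), "n_px")), n_in)
})
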