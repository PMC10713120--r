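cal <- nmj_calibration(0.21)

test_that("component detection matches a flood-fill oracle", {
  expect_identical(find_puncta(matrix(FALSE, 8, 8), cal), list())

  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:3] <- TRUE
  m[7:8, 7:8] <- TRUE
  pu <- find_puncta(m, cal)
  expect_length(pu, 2L)
  expect_equal(vapply(pu, `[[`, numeric(1), "area_um2"),
               rep(4 * cal$pixel_area_um2, 2))

  set.seed(21)
  for (rep in 1:15) {
    m <- matrix(runif(48 * 48) < 0.25, 48, 48)
    lab <- label_components(m)
    ref <- oracle_flood_label(m)
    expect_equal(max(lab), max(ref))
    # identical partitions up to renumbering: canonicalise both by first
    # occurrence along the same pixel ordering
    fg <- which(m)
    canon <- function(l) match(l[fg], unique(l[fg]))
    expect_identical(canon(lab), canon(ref))
  }
})

test_that("shape descriptors behave on reference shapes", {
  # single pixel: both descriptors are 1 by convention
  sp <- shape_metrics(cbind(3L, 3L), cal)
  expect_equal(sp$circularity, 1)
  expect_equal(sp$aspect_ratio, 1)
  expect_equal(sp$area_um2, cal$pixel_area_um2)

  # digital disk of radius 10 px: nearly circular, nearly isotropic
  grid <- expand.grid(r = 1:25, c = 1:25)
  disk <- as.matrix(grid[(grid$r - 13)^2 + (grid$c - 13)^2 <= 100, ])
  dm <- shape_metrics(disk, cal)
  expect_gte(dm$circularity, 0.85)
  expect_lte(dm$circularity, 1.0)
  expect_gte(dm$aspect_ratio, 1.0)
  expect_lte(dm$aspect_ratio, 1.1)

  # 1 x 20 bar: elongated and non-circular
  bar <- shape_metrics(cbind(rep(1L, 20), 1:20), cal)
  expect_gt(bar$aspect_ratio, 2.5)
  expect_lt(bar$circularity, 0.65)
})

test_that("moment-based aspect ratio matches an independent eigen computation", {
  set.seed(33)
  for (rep in 1:10) {
    px <- random_blob(32)
    m <- shape_metrics(px, cal)
    cov <- stats::cov(px) * (nrow(px) - 1) / nrow(px) + diag(2) / 12
    ev <- eigen(cov, symmetric = TRUE)$values
    expect_equal(m$aspect_ratio, sqrt(ev[1] / ev[2]), tolerance = 1e-10)
  }
})

test_that("cluster classification uses strict OR of the three violations", {
  crit <- cluster_criteria()
  expect_identical(classify_punctum(5, 0.8, 1.2, crit), "clustered")   # area
  expect_identical(classify_punctum(3, 0.5, 1.2, crit), "clustered")   # circ
  expect_identical(classify_punctum(3, 0.8, 3.0, crit), "clustered")   # AR
  expect_identical(classify_punctum(3, 0.8, 1.2, crit), "single")
  # exact boundary: all strict inequalities fail -> single
  expect_identical(classify_punctum(4.0, 0.65, 2.5, crit), "single")
  expect_identical(classify_punctum(4.0 + 1e-9, 0.65, 2.5, crit), "clustered")
  expect_identical(classify_punctum(4.0, 0.65 - 1e-9, 2.5, crit), "clustered")
  expect_identical(classify_punctum(4.0, 0.65, 2.5 + 1e-9, crit), "clustered")
})

test_that("classification is monotone in each descriptor", {
  crit <- cluster_criteria()
  set.seed(8)
  for (rep in 1:50) {
    a <- runif(1, 0, 8); ci <- runif(1, 0, 1); ar <- runif(1, 1, 5)
    s <- classify_punctum(a, ci, ar, crit)
    if (s == "clustered") {
      # worsening any descriptor must never flip clustered -> single
      expect_identical(classify_punctum(a + runif(1, 0, 3), ci, ar, crit), "clustered")
      expect_identical(classify_punctum(a, ci * runif(1, 0, 1), ar, crit), "clustered")
      expect_identical(classify_punctum(a, ci, ar + runif(1, 0, 3), crit), "clustered")
    }
  }
})

test_that("small rasterized circles are always single under default criteria", {
  for (rad in c(1.5, 2.5, 3.5, 4.5, 5.2)) {
    grid <- expand.grid(r = 1:25, c = 1:25)
    px <- as.matrix(grid[(grid$r - 13)^2 + (grid$c - 13)^2 <= rad^2, ])
    m <- shape_metrics(px, cal)
    if (m$area_um2 < 4) {
      expect_identical(
        classify_punctum(m$area_um2, m$circularity, m$aspect_ratio),
        "single"
      )
    }
  }
})

test_that("puncta clipped by the ROI boundary are kept and flagged", {
  m <- matrix(FALSE, 12, 12)
  m[1:2, 1:2] <- TRUE     # touches the ROI edge
  m[6:7, 6:7] <- TRUE     # interior
  roi <- matrix(TRUE, 12, 12)
  pu <- find_puncta(m, cal, roi_mask = roi)
  expect_length(pu, 2L)
  expect_true(pu[[1]]$roi_clipped)
  expect_false(pu[[2]]$roi_clipped)
})

test_that("puncta_table summarises a punctum list", {
  m <- matrix(FALSE, 8, 8)
  m[2:3, 2:5] <- TRUE
  tab <- puncta_table(find_puncta(m, cal))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_px, 8L)
  expect_identical(tab$status, "single")
  expect_equal(nrow(puncta_table(list())), 0L)
})
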