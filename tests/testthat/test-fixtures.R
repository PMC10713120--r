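test_that("stack generation is bit-reproducible from the seed", {
  a <- make_stack(n_spots_per_channel = 6, n_slices = 1, noise_sd = 2, seed = 5)
  b <- make_stack(n_spots_per_channel = 6, n_slices = 1, noise_sd = 2, seed = 5)
  d <- make_stack(n_spots_per_channel = 6, n_slices = 1, noise_sd = 2, seed = 6)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$stack$data, d$stack$data))
})

test_that("noise-free well-separated spots are detected exactly", {
  fx <- make_stack(n_spots_per_channel = 12, n_slices = 2, noise_sd = 0, seed = 2)
  res <- analyse_stack(fx$stack, full_frame_roi(dim(fx$stack)[3:4]))
  expect_equal(res$table$total, c(24L, 24L))      # 12 spots x 2 slices
  expect_equal(res$counts$clustered, c(0L, 0L))
})

test_that("fused groups merge into one clustered component before declustering", {
  fx <- make_stack(n_spots_per_channel = 2, fusion_groups = list(1:2),
                   n_slices = 1, noise_sd = 0, seed = 4)
  res_noseg <- analyse_stack(fx$stack, full_frame_roi(dim(fx$stack)[3:4]),
                             segmentation = FALSE)
  expect_equal(res_noseg$counts$detected[1], 1L)
  expect_equal(res_noseg$counts$clustered[1], 1L)
  res_seg <- analyse_stack(fx$stack, full_frame_roi(dim(fx$stack)[3:4]))
  expect_equal(res_seg$table$total[1], 2L)
})

test_that("rectangle overlap fixtures realize their planned fractions exactly", {
  plan <- c(0, 0.2, 0.5, 0.8, 1)
  fx <- make_stack(overlap_plan = plan, n_slices = 1, noise_sd = 0, seed = 9)
  expect_equal(sort(fx$truth$realized_overlap[fx$truth$channel == 1]),
               sort(plan))
  res <- analyse_stack(
    fx$stack, full_frame_roi(dim(fx$stack)[3:4]),
    preprocess = preprocess_params(gaussian_sigma = 0, trim_fraction = 0)
  )
  rec <- res$records[res$records$channel == 1, ]
  expect_equal(sort(rec$overlap_fraction), sort(plan))
})

test_that("infeasible plans are rejected", {
  expect_error(make_stack(n_spots_per_channel = 5000, shape = c(64L, 64L)),
               "infeasible")
  expect_error(make_stack(overlap_plan = c(0.5, 1.2)), "fractions")
  expect_error(make_stack(peak_intensity = 300, background = 10), "bit range")
  expect_error(make_stack(fusion_groups = list(c(1, 1))), "distinct")
})

test_that("an empty plan yields an empty stack and empty tables", {
  fx <- make_stack(n_spots_per_channel = 0, n_slices = 1, noise_sd = 0, seed = 1)
  expect_equal(nrow(fx$truth), 0L)
  res <- analyse_stack(fx$stack, full_frame_roi(dim(fx$stack)[3:4]))
  expect_equal(res$table$total, c(0L, 0L))
  expect_true(all(res$table$coloc_0 == 0L))
  expect_gt(length(res$warnings), 0L)  # constant slices are reported
})

test_that("written fixtures round-trip through the TIFF reader", {
  td <- withr::local_tempdir()
  fx <- make_stack(n_spots_per_channel = 4, n_slices = 2, noise_sd = 1,
                   seed = 10, out_dir = td, name = "fix")
  expect_true(all(file.exists(fx$paths)))
  back <- read_zstack(fx$paths[["tiff"]])
  expect_equal(back$data, fx$stack$data, ignore_attr = TRUE)
  expect_equal(back$calibration$pixel_size_um, 0.21)
})

test_that("zero pairing produces zero co-localization in both groups", {
  for (seed in 1:2) {
    fx <- make_stack(n_spots_per_channel = 8, paired_fraction = 0,
                     n_slices = 1, noise_sd = 0, seed = seed)
    res <- analyse_stack(fx$stack, full_frame_roi(dim(fx$stack)[3:4]))
    expect_true(all(res$table$coloc_0 == 0L))
  }
})

test_that("identical generation rates leave no systematic group ordering", {
  # same parameters and seeds: the two 'groups' are identical by construction
  g1 <- lapply(1:3, function(i) make_stack(n_spots_per_channel = 10,
                                           paired_fraction = 0.5, noise_sd = 2,
                                           n_slices = 1, seed = 100 + i))
  g2 <- lapply(1:3, function(i) make_stack(n_spots_per_channel = 10,
                                           paired_fraction = 0.5, noise_sd = 2,
                                           n_slices = 1, seed = 100 + i))
  t1 <- vapply(g1, function(f) sum(analyse_stack(
    f$stack, full_frame_roi(c(256L, 256L)))$table$total), numeric(1))
  t2 <- vapply(g2, function(f) sum(analyse_stack(
    f$stack, full_frame_roi(c(256L, 256L)))$table$total), numeric(1))
  expect_identical(t1, t2)
})
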