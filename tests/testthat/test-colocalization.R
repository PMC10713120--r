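test_that("the AND image is a pixel-wise conjunction", {
  set.seed(2)
  a <- matrix(runif(100) < 0.4, 10, 10)
  b <- matrix(runif(100) < 0.4, 10, 10)
  expect_identical(overlap_image(a, matrix(FALSE, 10, 10)),
                   matrix(FALSE, 10, 10))
  expect_identical(overlap_image(a, a), a)
  expect_identical(overlap_image(a, b), overlap_image(b, a))
  ref <- matrix(FALSE, 10, 10)
  for (i in 1:10) for (j in 1:10) ref[i, j] <- a[i, j] && b[i, j]
  expect_identical(overlap_image(a, b), ref)
  expect_error(overlap_image(a, matrix(FALSE, 5, 5)), "dimensions")
})

test_that("overlap fractions are exact pixel ratios", {
  px <- cbind(rep(3L, 10), 1:10)
  full <- matrix(TRUE, 6, 12)
  none <- matrix(FALSE, 6, 12)
  half <- none; half[3, 1:5] <- TRUE
  expect_equal(punctum_overlap_fraction(px, full), 1.0)
  expect_equal(punctum_overlap_fraction(px, none), 0.0)
  expect_equal(punctum_overlap_fraction(px, half), 0.5)
  expect_error(punctum_overlap_fraction(px[0, , drop = FALSE], full), "empty")
  expect_error(punctum_overlap_fraction(cbind(9L, 20L), full), "outside")
})

test_that("threshold semantics: strict above below 100%, equality at 100%", {
  rec <- function(n_px, n_ov) {
    data.frame(channel = 1L, slice = 1L, punctum_id = "1", status = "single",
               n_px = n_px, n_overlap = n_ov,
               overlap_fraction = n_ov / n_px, stringsAsFactors = FALSE)
  }
  th <- coloc_thresholds()
  expect_identical(th, seq(0L, 100L, 10L))

  tab_full <- tabulate_coloc(rec(10L, 10L), "roi", channels = 1L)
  expect_true(all(tab_full[paste0("coloc_", th)] == 1L))

  tab_none <- tabulate_coloc(rec(10L, 0L), "roi", channels = 1L)
  expect_true(all(tab_none[paste0("coloc_", th)] == 0L))
  expect_true(all(tab_none[paste0("single_", th)] == 1L))

  tab_half <- tabulate_coloc(rec(10L, 5L), "roi", channels = 1L)
  expect_true(all(tab_half[paste0("coloc_", c(0, 10, 20, 30, 40))] == 1L))
  expect_true(all(tab_half[paste0("coloc_", c(50, 60, 70, 80, 90, 100))] == 0L))

  # 99%-covered punctum: co-localized at >90% but not at =100%
  tab_99 <- tabulate_coloc(rec(100L, 99L), "roi", channels = 1L)
  expect_equal(tab_99$coloc_90, 1L)
  expect_equal(tab_99$coloc_100, 0L)

  # exact boundary is not past the threshold: 3/10 is single at >30%
  tab_30 <- tabulate_coloc(rec(10L, 3L), "roi", channels = 1L)
  expect_equal(tab_30$coloc_20, 1L)
  expect_equal(tab_30$coloc_30, 0L)
})

test_that("tallies are complete and monotone on random records", {
  set.seed(17)
  th <- coloc_thresholds()
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    n_px <- sample(1:50, n, replace = TRUE)
    n_ov <- vapply(n_px, function(k) sample(0:k, 1), integer(1))
    rec <- data.frame(channel = sample(1:2, n, replace = TRUE), slice = 1L,
                      punctum_id = as.character(seq_len(n)), status = "single",
                      n_px = n_px, n_overlap = n_ov,
                      overlap_fraction = n_ov / n_px, stringsAsFactors = FALSE)
    tab <- tabulate_coloc(rec, "roi", channels = 1:2)
    for (i in 1:2) {
      row <- tab[tab$channel == i, ]
      cc <- as.numeric(row[paste0("coloc_", th)])
      ss <- as.numeric(row[paste0("single_", th)])
      expect_true(all(cc + ss == row$total))
      expect_true(all(diff(cc) <= 0))
      # coloc at t=0 counts exactly the puncta with >= 1 overlapping pixel
      expect_equal(cc[1], sum(rec$n_overlap[rec$channel == i] > 0))
    }
  }
})

test_that("channel directions are tallied independently", {
  rec <- data.frame(
    channel = c(1L, 2L, 2L), slice = 1L,
    punctum_id = c("1", "1", "2"), status = "single",
    n_px = c(10L, 10L, 10L), n_overlap = c(10L, 0L, 2L),
    overlap_fraction = c(1, 0, 0.2), stringsAsFactors = FALSE
  )
  tab <- tabulate_coloc(rec, "roi")
  expect_equal(tab$total, c(1L, 2L))
  expect_equal(tab$coloc_0, c(1L, 1L))
  expect_equal(tab$coloc_100, c(1L, 0L))
})
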