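test_that("contrast stretch maps observed range linearly with half-up rounding", {
  m <- matrix(c(0, 500, 1000), 1)
  expect_identical(as.vector(contrast_stretch(m)), c(10L, 128L, 245L))
  # constant image maps to lo
  expect_true(all(contrast_stretch(matrix(7, 3, 3)) == 10L))
  # image already spanning [10, 245] is a fixed point (idempotence)
  img <- matrix(sample(10:245, 64, replace = TRUE), 8, 8)
  img[1] <- 10L; img[64] <- 245L
  expect_identical(contrast_stretch(img), {
    s <- img; storage.mode(s) <- "integer"; s
  })
  expect_identical(contrast_stretch(contrast_stretch(img)),
                   contrast_stretch(img))
  expect_error(contrast_stretch(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(contrast_stretch(m, lo = 100, hi = 50), "lo < hi")
})

test_that("mask stacks load from multi-page TIFF and directories", {
  m1 <- matrix(0L, 4, 4); m1[1:2, 1] <- 1L
  m2 <- matrix(0L, 4, 4)
  m3 <- matrix(0L, 4, 4); m3[2:3, 2:3] <- 1L; m3[1, 4] <- 1L
  st <- mask_stack(list(m1, m2, m3), "p1")

  tf <- tempfile(fileext = ".tif")
  write_mask_stack(st, tf)
  rt <- load_mask_stack(tf)
  expect_length(rt$slices, 3)
  expect_identical(extract_area_signal(rt)$counts, c(2L, 0L, 5L))

  # directory form, lexicographic order
  dir <- tempfile(); dir.create(dir)
  tiff::writeTIFF(m3 * 1.0, file.path(dir, "s000.tif"))
  tiff::writeTIFF(m1 * 1.0, file.path(dir, "s001.tif"))
  png::writePNG(m2 * 1.0, file.path(dir, "s010.png"))
  stack <- load_mask_stack(dir)
  expect_identical(extract_area_signal(stack)$counts, c(5L, 2L, 0L))

  # inconsistent dimensions rejected
  expect_error(mask_stack(list(m1, matrix(0L, 5, 5))), "inconsistent")
  expect_error(load_mask_stack(tempfile()), "cannot read")
})

test_that("area extraction counts 1-pixels and ignores their arrangement", {
  m <- matrix(0L, 6, 6); m[sample(36, 11)] <- 1L
  perm <- matrix(m[sample(36)], 6, 6)
  st <- mask_stack(list(m, perm), "p")
  expect_identical(extract_area_signal(st)$counts, c(11L, 11L))
  # all-zero stack
  zs <- mask_stack(rep(list(matrix(0L, 3, 3)), 10))
  expect_identical(extract_area_signal(zs)$counts, rep(0L, 10))
  # non-binary input binarizes (any nonzero -> 1)
  g <- matrix(c(0, 3, 200, 0), 2, 2)
  expect_identical(extract_area_signal(mask_stack(list(g)))$counts, 2L)
})

test_that("rasterized discs reproduce their target counts exactly", {
  sig <- area_signal(c(0, 12, 812, 97), "disc")
  patient <- list(signal = sig)
  st <- rasterize_patient(patient, side = 40)
  # independent per-pixel enumeration
  brute <- vapply(st$slices, function(m) {
    cnt <- 0L
    for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
      if (m[r, c] == 1L) cnt <- cnt + 1L
    }
    cnt
  }, integer(1))
  expect_identical(brute, c(0L, 12L, 812L, 97L))
  # discs are connected blobs around the center, not scattered pixels:
  # every filled pixel lies within the bounding radius of the count
  m <- st$slices[[3]]
  ctr <- (40 + 1) / 2
  d <- sqrt(outer((seq_len(40) - ctr)^2, (seq_len(40) - ctr)^2, `+`))
  expect_lt(max(d[m == 1L]), sqrt(812 / pi) + 2)
  expect_error(rasterize_patient(patient, side = 5), "exceeds")
})

test_that("generator-written stacks round-trip through load and extract", {
  p <- simulate_patient(cohort_spec(n_patients = 1, n_slices_range = c(30, 30),
                                    base_count_range = c(200, 300),
                                    aneurysm_len_range = c(8, 8),
                                    noise_cv = 0.05, seed = 3))
  tf <- tempfile(fileext = ".tif")
  write_mask_stack(rasterize_patient(p), tf)
  recovered <- extract_area_signal(load_mask_stack(tf))
  expect_identical(recovered$counts, p$signal$counts)
})

test_that("signal tables round-trip and reject malformed input", {
  f <- tempfile(fileext = ".csv")
  s <- area_signal(c(100L, 120L), "t")
  write_signal_table(s, f)
  expect_identical(read_signal_table(f)$counts, c(100L, 120L))

  set.seed(11)
  big <- area_signal(sample(0:2000, 200, replace = TRUE), "rt")
  write_signal_table(big, f)
  expect_identical(read_signal_table(f)$counts, big$counts)

  writeLines(c("slice_index,pixel_count", "0,100", "2,120"), f)
  expect_error(read_signal_table(f), "consecutively")
  writeLines(c("slice_index,pixel_count", "0,100", "1,-5"), f)
  expect_error(read_signal_table(f), "negative|non-negative")
  writeLines(c("a,b", "0,100"), f)
  expect_error(read_signal_table(f), "header")
})
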