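test_that("box counting: closed-form cases and input validation", {
  full8 <- matrix(TRUE, 8, 8)
  expect_equal(box_count(full8, 2)$counts, 16L)
  single <- matrix(FALSE, 32, 32); single[7, 19] <- TRUE
  for (e in c(1, 3, 5, 16, 32))
    expect_equal(box_count(single, e)$counts, 1L)
  expect_error(box_count(matrix(FALSE, 8, 8), 2), "EMPTY_MASK")
  expect_error(box_count(full8, 9), "grid dims")
  # partial edge boxes count: 10x10 full grid at eps = 4 -> ceiling(10/4)^2
  expect_equal(box_count(matrix(TRUE, 10, 10), 4)$counts, 9L)
})

test_that("box counts match the brute-force oracle on random masks", {
  set.seed(99)
  for (i in 1:20) {
    m <- matrix(runif(64^2) < runif(1, 0.02, 0.6), 64, 64)
    if (!any(m)) m[1, 1] <- TRUE
    got <- box_count(m, 1:16)$counts
    expect_identical(got, vapply(1:16, function(e) brute_box_count(m, e), 0L))
  }
})

test_that("known-dimension masks are recovered: line, plane, carpet", {
  sizes3 <- 3^(1:5)
  line <- make_fractal_fixture("line", 729)
  expect_equal(sum(line), 729)
  fit <- fit_dimension(sizes3, box_count(line, sizes3)$counts)
  expect_equal(fit$df, 1.0, tolerance = 0.1)

  square <- make_fractal_fixture("filled_square", 729)
  expect_true(all(square))
  fit <- fit_dimension(sizes3, box_count(square, sizes3)$counts)
  expect_equal(fit$df, 2.0, tolerance = 0.05)

  carpet <- make_fractal_fixture("sierpinski_carpet", 729, depth = 5)
  expect_equal(sum(carpet), 8^5 * 9)      # 8^5 filled 3x3-px cells
  counts <- box_count(carpet, sizes3)$counts
  expect_equal(counts, as.integer(8^(6 - (1:5))))  # exact self-similarity
  fit <- fit_dimension(sizes3, counts)
  expect_equal(fit$df, log(8) / log(3), tolerance = 0.05)
  expect_gt(fit$r2, 0.999)
  expect_error(make_fractal_fixture("sierpinski_carpet", 700, depth = 5),
               "multiple")
})

test_that("dimension fitting validates its inputs", {
  expect_error(fit_dimension(c(2, 4), c(10, 5)), "INSUFFICIENT_SCALES")
  expect_error(fit_dimension(c(2, 4, 8), c(10, 5, 0)), "INSUFFICIENT_SCALES")
  fit <- fit_dimension(c(2, 4, 8, 16), c(256, 64, 16, 4))
  expect_equal(fit$df, 2.0, tolerance = 1e-12)   # exact power law
  expect_equal(fit$r2, 1.0, tolerance = 1e-12)
  expect_gte(fit$df, 0); expect_lte(fit$df, 2)
})

test_that("box counts and fitted Df are monotone in the mask", {
  set.seed(5)
  b <- matrix(runif(128^2) < 0.3, 128, 128)
  a <- b & (matrix(runif(128^2), 128, 128) < 0.5)   # a subset of b
  if (!any(a)) a[which(b)[1]] <- TRUE
  sizes <- box_size_schedule(128)
  ca <- box_count(a, sizes)$counts
  cb <- box_count(b, sizes)$counts
  expect_true(all(ca <= cb))
  expect_lte(fit_dimension(sizes, ca)$df, fit_dimension(sizes, cb)$df + 0.02)
  # counts non-increasing in eps
  expect_true(all(diff(cb) <= 0) || all(diff(rev(cb)) >= 0))
})

test_that("Df is robust to a 2x resolution change on reference fixtures", {
  for (m in list(make_fractal_fixture("sierpinski_carpet", 243, 5),
                 make_fractal_fixture("disk", 200))) {
    up <- kronecker(m * 1L, matrix(1L, 2, 2)) > 0
    d1 <- fit_dimension(box_size_schedule(nrow(m)),
                        box_count(m, box_size_schedule(nrow(m)))$counts)$df
    d2 <- fit_dimension(box_size_schedule(nrow(up)),
                        box_count(up, box_size_schedule(nrow(up)))$counts)$df
    expect_lt(abs(d1 - d2), 0.05)
  }
})

test_that("roi restriction: neutral roi, empty intersection, symmetry", {
  set.seed(8)
  m <- matrix(runif(96^2) < 0.25, 96, 96)
  full <- matrix(TRUE, 96, 96)
  fit_roi <- roi_density(m, full)
  bc <- box_count(m, box_size_schedule(96))
  fit_raw <- fit_dimension(bc$sizes, bc$counts)
  expect_equal(fit_roi$df, fit_raw$df)

  # vessels entirely outside the roi -> flagged, not fatal
  roi <- matrix(FALSE, 96, 96); roi[1:40, 1:40] <- TRUE
  m2 <- matrix(FALSE, 96, 96); m2[60:90, 60:90] <- TRUE
  flagged <- roi_density(m2, roi)
  expect_equal(flagged$status, "EMPTY_MASK")
  expect_true(is.na(flagged$df))

  # a vertically mirror-symmetric pattern has equal S and I densities
  half <- matrix(runif(108 * 216) < 0.3, 108, 216)
  sym <- rbind(half, half[108:1, ])
  rois <- make_etdrs_rois(geom216())
  dS <- roi_density(sym, rois$regions$S)$df
  dI <- roi_density(sym, rois$regions$I)$df
  expect_lt(abs(dS - dI), 0.02)
})

test_that("cohort density assembly is deterministic with zero variance for identical images", {
  syn <- synth_angiogram(seed = 31, subject_id = "HC01")
  # two subjects, same image
  mm1 <- mem_manifest(list(SRL = syn$image), subject_id = "HC01")
  mm2 <- mem_manifest(list(SRL = syn$image), subject_id = "HC02")
  manifest <- octafd:::validate_manifest(rbind(as.data.frame(mm1$manifest),
                                               as.data.frame(mm2$manifest)))
  images <- c(mm1$images, mm2$images)
  tab <- build_density_table(manifest, images = images)
  expect_equal(nrow(tab), 2 * 45)
  v <- tapply(tab$density, paste(tab$mask_kind, tab$scheme, tab$region),
              function(x) diff(range(x)))
  expect_true(all(v == 0, na.rm = TRUE))
  # rerun gives the identical table
  tab2 <- build_density_table(manifest, images = images)
  expect_identical(tab$density, tab2$density)
})
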