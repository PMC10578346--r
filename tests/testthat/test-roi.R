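schemes_for <- function(geom) {
  list(make_etdrs_rois(geom), make_hemi_rois(geom),
       make_annuli_rois(geom), make_global_rois(geom))
}

# support mask a scheme claims to cover, rebuilt independently
annulus_of <- function(geom, r_in, r_out) {
  d <- geom$dim; ctr <- (d - 1) / 2
  x <- matrix((seq_len(d[2]) - 1 - ctr[2]) * geom$mm_per_px, d[1], d[2], byrow = TRUE)
  y <- matrix(-(seq_len(d[1]) - 1 - ctr[1]) * geom$mm_per_px, d[1], d[2])
  r <- sqrt(x^2 + y^2)
  r >= r_in & r < r_out
}

test_that("every scheme is a pairwise-disjoint exact cover of its support", {
  geom <- list(dim = c(600, 600), mm_per_px = 0.01)
  for (rs in schemes_for(geom)) {
    acc <- Reduce(`+`, rs$regions)
    expect_true(all(acc <= 1), info = rs$scheme)      # disjoint
    support <- annulus_of(geom, rs$geometry$r_inner_mm, rs$geometry$r_outer_mm)
    expect_identical(acc == 1, support, label = rs$scheme)  # exact cover
    expect_true(all(vapply(rs$regions, sum, 0L) > 0), info = rs$scheme)
  }
})

# region name(s) containing the pixel at a (row, col) px offset from the
# exact center of an odd-sized grid
member_at <- function(rois, dr, dc, n = 601) {
  ctr0 <- (n - 1) / 2
  names(Filter(function(m) m[ctr0 + dr + 1, ctr0 + dc + 1], rois$regions))
}

test_that("ETDRS quadrants: symmetry, membership, full-disk cover", {
  geom <- list(dim = c(601, 601), mm_per_px = 0.01)
  rois <- make_etdrs_rois(geom, 0.3, 2.9)
  areas <- vapply(rois$regions, sum, 0L)
  expect_true(max(areas) / min(areas) < 1.01)  # equal areas within 1%
  expect_identical(member_at(rois, -100, 0), "S")   # 1.0 mm superior
  expect_identical(member_at(rois, 100, 0), "I")
  expect_identical(member_at(rois, 0, -100), "L")
  expect_identical(member_at(rois, 0, 100), "R")
  # r_inner = 0: sectors cover the full disk
  rois0 <- make_etdrs_rois(geom, 0, 2.9)
  disk_area <- pi * 2.9^2 / 0.01^2
  expect_equal(sum(vapply(rois0$regions, sum, 0L)), disk_area,
               tolerance = 0.01)
})

test_that("hemispheric quadrants are the ETDRS sectors rotated by 45 degrees", {
  geom <- list(dim = c(600, 600), mm_per_px = 0.01)
  hemi <- make_hemi_rois(geom)
  etdrs <- make_etdrs_rois(geom)
  areas <- vapply(hemi$regions, sum, 0L)
  expect_true(max(areas) / min(areas) < 1.01)
  # 1.0 mm superior, 0.5 mm left -> SL only
  hemi601 <- make_hemi_rois(list(dim = c(601, 601), mm_per_px = 0.01))
  expect_identical(member_at(hemi601, -100, -50), "SL")
  # each HEMI region overlaps exactly two ETDRS regions
  for (hn in names(hemi$regions)) {
    ov <- vapply(etdrs$regions, function(em)
      sum(em & hemi$regions[[hn]]) > 0, TRUE)
    expect_equal(sum(ov), 2L, info = hn)
  }
})

test_that("central annuli: default geometry and ring membership", {
  geom <- list(dim = c(601, 601), mm_per_px = 0.01)
  rois <- make_annuli_rois(geom)  # defaults: 0.6 mm FAZ, 2.5 mm outer, 6 rings
  g <- rois$geometry
  expect_equal(g$r_outer_mm, 1.25)                    # C6 outer radius
  expect_equal(g$ring_width_mm, 0.95 / 6)             # ~0.158, rounded 0.16
  expect_equal(g$ring_width_mm * g$n_rings, 0.95)     # total radial band
  expect_identical(member_at(rois, 0, 31), "C1")      # r = 0.31 mm
  expect_identical(member_at(rois, 0, 124), "C6")     # r = 1.24 mm
  expect_length(member_at(rois, 0, 25), 0)   # r = 0.25 mm: inside the FAZ
  # equal widths, strictly increasing pixel counts with ring index
  counts <- vapply(rois$regions, sum, 0L)
  expect_true(all(diff(counts) > 0))
})

test_that("global region matches the area formula and the ETDRS union", {
  geom <- list(dim = c(600, 600), mm_per_px = 0.01)
  glob <- make_global_rois(geom, 0.3, 2.9)
  expect_equal(sum(glob$regions$ALL) * 0.01^2, pi * (2.9^2 - 0.3^2),
               tolerance = 0.01)
  etdrs <- make_etdrs_rois(geom, 0.3, 2.9)
  expect_identical(glob$regions$ALL, Reduce(`|`, etdrs$regions))
  expect_error(make_global_rois(geom, 1, 1), "degenerate")
  expect_error(make_etdrs_rois(geom, 0.3, 4.0), "exceeds")
})

test_that("a 90-degree rotation permutes quadrant labels S->L->I->R->S", {
  geom <- list(dim = c(301, 301), mm_per_px = 0.01)  # odd: exact center pixel
  rois <- make_etdrs_rois(geom, 0.3, 1.4)
  # rotating the image 90 degrees CCW maps pixel (r, c) -> (2*ctr - c, r);
  # a sector at angle a lands at a + 90
  rot <- function(m) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    idx <- which(m, arr.ind = TRUE)
    ctr <- (nrow(m) + 1) / 2  # 1-based center
    out[cbind(2 * ctr - idx[, 2], idx[, 1])] <- TRUE
    out
  }
  expect_identical(rot(rois$regions$R), rois$regions$S)
  expect_identical(rot(rois$regions$S), rois$regions$L)
  expect_identical(rot(rois$regions$L), rois$regions$I)
  expect_identical(rot(rois$regions$I), rois$regions$R)
})
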