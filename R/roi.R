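#' ROI partition schemes about the fovea
#'
#' Builders for the named macular partition schemes, as binary pixel masks in
#' physical (mm) coordinates about the fovea center:
#'
#' * **ETDRS quadrants** `S`, `I`, `L`, `R`: four 90-degree sectors bounded
#'   by the two diagonals (boundary angles at +-45 and +-135 degrees from
#'   +x), restricted to an annulus.
#' * **Hemispheric quadrants** `SL`, `SR`, `IL`, `IR`: four sectors bounded
#'   by the horizontal and vertical axes through the fovea, same annulus.
#' * **Central annuli** `C1`..`Cn`: `n` concentric equal-width rings between
#'   the foveal avascular zone and an outer circle (defaults: 0.6 mm FAZ
#'   diameter, 2.5 mm outer diameter, 6 rings of (2.5-0.6)/2/6 ~ 0.158 mm).
#' * **Global** `ALL`: the whole annulus, for whole-image densities.
#'
#' Angles use +x toward increasing column and +y superior (decreasing row);
#' membership is by pixel-center location, with half-open radial
#' `[r_in, r_out)` and angular intervals (counterclockwise, e.g.
#' `[-45, 45) -> R`, `[45, 135) -> S`) so every scheme is a pixel-exact
#' disjoint cover of its support. `L`/`R` are image left/right; they are not
#' remapped to nasal/temporal (eye laterality travels in the metadata).
#'
#' @param img_geom An [angiogram], [vessel_mask], or
#'   `list(dim = c(nrow, ncol), mm_per_px = , fovea_center_px = )`.
#' @param r_inner_mm,r_outer_mm Annulus radii in mm. Quadrant defaults
#'   exclude the avascular center (0.3 mm) and stop at 2.9 mm, the largest
#'   circle safely inside a 6 mm scan.
#' @return A `roi_set`: list with `scheme`, named `regions` (logical
#'   matrices) and `geometry`.
#' @name roi_partition
NULL

roi_geometry <- function(img_geom) {
  if (inherits(img_geom, "angiogram") || inherits(img_geom, "vessel_mask")) {
    list(dim = dim(img_geom$pixels), mm_per_px = img_geom$mm_per_px,
         fovea_center_px = img_geom$fovea_center_px)
  } else {
    stopifnot(is.list(img_geom), !is.null(img_geom$dim),
              !is.null(img_geom$mm_per_px))
    img_geom$fovea_center_px <- img_geom$fovea_center_px %||%
      ((img_geom$dim - 1) / 2)
    img_geom
  }
}

# polar coordinates (mm, degrees in [-180, 180)) of every pixel center
roi_polar <- function(geom) {
  d <- geom$dim
  ctr <- geom$fovea_center_px
  x_mm <- (seq_len(d[2]) - 1 - ctr[2]) * geom$mm_per_px   # +x = +col
  y_mm <- -(seq_len(d[1]) - 1 - ctr[1]) * geom$mm_per_px  # +y = superior
  X <- matrix(x_mm, d[1], d[2], byrow = TRUE)
  Y <- matrix(y_mm, d[1], d[2])
  theta <- atan2(Y, X) * 180 / pi
  theta[theta >= 180] <- -180
  list(r = sqrt(X^2 + Y^2), theta = theta)
}

check_fits <- function(geom, r_outer_mm) {
  ctr <- geom$fovea_center_px
  d <- geom$dim
  room_px <- min(ctr[1], ctr[2], d[1] - 1 - ctr[1], d[2] - 1 - ctr[2]) + 0.5
  if (r_outer_mm / geom$mm_per_px > room_px)
    stop(sprintf("outer radius %.2f mm exceeds the image bounds (%.2f mm available)",
                 r_outer_mm, room_px * geom$mm_per_px))
}

roi_set <- function(scheme, regions, geometry, check = TRUE) {
  if (check && length(regions) > 1) {
    acc <- matrix(0L, nrow(regions[[1]]), ncol(regions[[1]]))
    for (m in regions) acc <- acc + m
    if (any(acc > 1L)) stop("ROI regions overlap")
  }
  structure(list(scheme = scheme, regions = regions, geometry = geometry),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set:%s> regions: %s\n", x$scheme,
              paste(sprintf("%s(%d px)", names(x$regions),
                            vapply(x$regions, sum, 0L)), collapse = ", ")))
  invisible(x)
}

# angular sector selector on half-open [lo, hi) degree intervals, with wrap
sector <- function(theta, lo, hi) {
  if (lo < hi) theta >= lo & theta < hi else theta >= lo | theta < hi
}

#' @rdname roi_partition
#' @export
make_etdrs_rois <- function(img_geom, r_inner_mm = 0.3, r_outer_mm = 2.9) {
  geom <- roi_geometry(img_geom)
  if (!(r_inner_mm >= 0 && r_inner_mm < r_outer_mm))
    stop("need 0 <= r_inner_mm < r_outer_mm")
  check_fits(geom, r_outer_mm)
  p <- roi_polar(geom)
  ann <- p$r >= r_inner_mm & p$r < r_outer_mm
  regions <- list(S = ann & sector(p$theta,   45,  135),
                  I = ann & sector(p$theta, -135,  -45),
                  L = ann & sector(p$theta,  135, -135),
                  R = ann & sector(p$theta,  -45,   45))
  roi_set("ETDRS", regions,
          list(r_inner_mm = r_inner_mm, r_outer_mm = r_outer_mm,
               quadrant_boundary_angles = c(-135, -45, 45, 135)))
}

#' @rdname roi_partition
#' @export
make_hemi_rois <- function(img_geom, r_inner_mm = 0.3, r_outer_mm = 2.9) {
  geom <- roi_geometry(img_geom)
  if (!(r_inner_mm >= 0 && r_inner_mm < r_outer_mm))
    stop("need 0 <= r_inner_mm < r_outer_mm")
  check_fits(geom, r_outer_mm)
  p <- roi_polar(geom)
  ann <- p$r >= r_inner_mm & p$r < r_outer_mm
  regions <- list(SL = ann & sector(p$theta,   90,  180),
                  SR = ann & sector(p$theta,    0,   90),
                  IL = ann & sector(p$theta, -180,  -90),
                  IR = ann & sector(p$theta,  -90,    0))
  roi_set("HEMI", regions,
          list(r_inner_mm = r_inner_mm, r_outer_mm = r_outer_mm,
               quadrant_boundary_angles = c(-180, -90, 0, 90)))
}

#' @param faz_diameter_mm Diameter of the excluded central avascular zone.
#' @param outer_diameter_mm Outer circle diameter.
#' @param n_rings Number of equal-width concentric rings.
#' @rdname roi_partition
#' @export
make_annuli_rois <- function(img_geom, faz_diameter_mm = 0.6,
                             outer_diameter_mm = 2.5, n_rings = 6) {
  geom <- roi_geometry(img_geom)
  if (!(faz_diameter_mm >= 0 && faz_diameter_mm < outer_diameter_mm))
    stop("need faz_diameter_mm < outer_diameter_mm")
  if (n_rings < 1) stop("need n_rings >= 1")
  check_fits(geom, outer_diameter_mm / 2)
  r0 <- faz_diameter_mm / 2
  width <- (outer_diameter_mm - faz_diameter_mm) / (2 * n_rings)
  p <- roi_polar(geom)
  regions <- lapply(seq_len(n_rings), function(i) {
    p$r >= r0 + (i - 1) * width & p$r < r0 + i * width
  })
  names(regions) <- paste0("C", seq_len(n_rings))
  roi_set("ANNULI", regions,
          list(r_inner_mm = r0, r_outer_mm = outer_diameter_mm / 2,
               ring_width_mm = width, n_rings = n_rings))
}

#' @rdname roi_partition
#' @export
make_global_rois <- function(img_geom, r_inner_mm = 0.3, r_outer_mm = 2.9) {
  geom <- roi_geometry(img_geom)
  if (!(r_inner_mm >= 0 && r_inner_mm < r_outer_mm))
    stop("need 0 <= r_inner_mm < r_outer_mm (degenerate annulus)")
  check_fits(geom, r_outer_mm)
  p <- roi_polar(geom)
  roi_set("GLOBAL", list(ALL = p$r >= r_inner_mm & p$r < r_outer_mm),
          list(r_inner_mm = r_inner_mm, r_outer_mm = r_outer_mm))
}

#' Build every partition scheme for one image geometry
#'
#' @inheritParams roi_partition
#' @param config ROI geometry settings (see [default_config()]`$roi`).
#' @return Named list of `roi_set`s: `GLOBAL`, `ETDRS`, `HEMI`, `ANNULI`.
#' @export
make_all_rois <- function(img_geom, config = default_config()$roi) {
  list(GLOBAL = make_global_rois(img_geom, config$r_inner_mm, config$r_outer_mm),
       ETDRS  = make_etdrs_rois(img_geom, config$r_inner_mm, config$r_outer_mm),
       HEMI   = make_hemi_rois(img_geom, config$r_inner_mm, config$r_outer_mm),
       ANNULI = make_annuli_rois(img_geom, config$faz_diameter_mm,
                                 config$outer_diameter_mm, config$n_rings))
}

#' Serialize an ROI set as a labeled PNG plus JSON legend
#'
#' Writes an 8-bit PNG whose pixel value is the region index (0 =
#' background) and a JSON file mapping indices to region names and geometry.
#'
#' @param rois A `roi_set`.
#' @param path_png,path_json Output paths.
#' @return `path_png`, invisibly.
#' @export
write_roi_set <- function(rois, path_png,
                          path_json = sub("\\.png$", ".json", path_png)) {
  lab <- matrix(0L, nrow(rois$regions[[1]]), ncol(rois$regions[[1]]))
  for (i in seq_along(rois$regions)) lab[rois$regions[[i]]] <- i
  png::writePNG(lab / 255, path_png)
  jsonlite::write_json(
    list(scheme = rois$scheme,
         legend = stats::setNames(as.list(seq_along(rois$regions)),
                                  names(rois$regions)),
         geometry = rois$geometry),
    path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_png)
}
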