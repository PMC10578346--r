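#' En-face angiogram object
#'
#' Container for a single 2-D grayscale en-face OCTA scan with its physical
#' scale and fovea location. Intensities live in \[0, 1\]; pixel coordinates
#' are 0-based `(row, col)` with row 0 at the image top, so "superior" means
#' decreasing row index. Physical coordinates are mm offsets from the fovea
#' center, +y superior and +x toward increasing column.
#'
#' @param pixels Numeric matrix of intensities in \[0, 1\].
#' @param mm_per_px Isotropic physical scale in mm per pixel (> 0).
#' @param fovea_center_px Numeric `(row, col)`, 0-based; defaults to the
#'   image center.
#' @param layer One of `"SRL"`, `"DRL"`, `"CONJ"`.
#' @param eye One of `"OD"`, `"OS"`, `"NA"`.
#' @param subject_id Subject identifier string.
#' @return An object of class `angiogram`.
#' @export
angiogram <- function(pixels, mm_per_px, fovea_center_px = NULL,
                      layer = c("SRL", "DRL", "CONJ"),
                      eye = c("NA", "OD", "OS"), subject_id = "") {
  layer <- match.arg(layer)
  eye <- match.arg(eye)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("angiogram intensities must be finite")
  if (any(pixels < 0 | pixels > 1))
    stop("angiogram intensities must lie in [0, 1]")
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1L || mm_per_px <= 0)
    stop("`mm_per_px` must be a single positive number")
  d <- dim(pixels)
  if (is.null(fovea_center_px)) fovea_center_px <- (d - 1) / 2
  fovea_center_px <- as.numeric(fovea_center_px)
  if (length(fovea_center_px) != 2L ||
      any(fovea_center_px < 0) || fovea_center_px[1] > d[1] - 1 ||
      fovea_center_px[2] > d[2] - 1)
    stop("`fovea_center_px` must be a (row, col) location inside the image")
  fov_mm <- d[1] * mm_per_px
  if (layer %in% c("SRL", "DRL") && (fov_mm < 5 || fov_mm > 7))
    warning(sprintf("field of view %.2f mm outside the 5-7 mm macular range",
                    fov_mm))
  structure(list(pixels = pixels, mm_per_px = mm_per_px,
                 fovea_center_px = fovea_center_px, layer = layer,
                 eye = eye, subject_id = subject_id),
            class = "angiogram")
}

#' @export
print.angiogram <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<angiogram> %s eye=%s layer=%s  %d x %d px, %.4f mm/px (%.2f x %.2f mm)\n",
              x$subject_id, x$eye, x$layer, d[1], d[2], x$mm_per_px,
              d[1] * x$mm_per_px, d[2] * x$mm_per_px))
  cat(sprintf("  fovea at (%.1f, %.1f) px; intensity range [%.3f, %.3f]\n",
              x$fovea_center_px[1], x$fovea_center_px[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read an en-face angiogram from a grayscale PNG or TIFF file
#'
#' Intensities are rescaled to \[0, 1\] by the image bit depth (a constant
#' 8-bit 255 image loads as all 1.0). RGB input is converted to luminance with
#' a warning. A missing `mm_per_px` defaults to 6 mm / image width (the usual
#' macular scan width) with a warning; a missing fovea center defaults to the
#' image center.
#'
#' @param path PNG or TIFF file path.
#' @param mm_per_px Physical scale; `NULL` for the 6 mm default.
#' @param fovea_center_px `(row, col)` 0-based fovea location, or `NULL` for
#'   the image center.
#' @inheritParams angiogram
#' @return An [angiogram] object.
#' @export
read_angiogram <- function(path, mm_per_px = NULL, fovea_center_px = NULL,
                           layer = c("SRL", "DRL", "CONJ"),
                           eye = c("NA", "OD", "OS"), subject_id = "") {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               png = png::readPNG(path),
               tif = ,
               tiff = tiff::readTIFF(path),
               stop("unsupported image format (need PNG or TIFF): ", path))
  if (length(dim(px)) == 3L) {
    nch <- dim(px)[3]
    if (nch >= 3) {
      warning("RGB input converted to luminance: ", path)
      px <- 0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
    } else {
      px <- px[, , 1]
    }
  }
  px <- pmin(pmax(px, 0), 1)
  if (is.null(mm_per_px)) {
    mm_per_px <- 6.0 / ncol(px)
    warning(sprintf("no physical scale given; assuming 6 mm width (%.4f mm/px)",
                    mm_per_px))
  }
  if (is.null(fovea_center_px))
    message("no fovea center given; using the image center")
  angiogram(px, mm_per_px = mm_per_px, fovea_center_px = fovea_center_px,
            layer = layer, eye = eye, subject_id = subject_id)
}

#' Write a binary vessel mask as an 8-bit PNG (0/255)
#'
#' @param mask A [vessel_mask] or logical matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  px <- if (inherits(mask, "vessel_mask")) mask$pixels else mask
  png::writePNG(px * 1.0, path)
  invisible(path)
}

#' Read a binary mask written by [write_mask_png()]
#'
#' @param path PNG path.
#' @return Logical matrix (pixels > 0.5).
#' @export
read_mask_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  px > 0.5
}
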