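#' Box-size schedule for box counting
#'
#' Powers of two from 2 px up to `floor(min_dim / 4)`, the default schedule
#' used throughout the package. At least three scales are required for a
#' stable log-log fit, so `min_dim` must be >= 32.
#'
#' @param min_dim Smaller dimension (px) of the region being counted.
#' @return Integer vector of box sizes (increasing).
#' @export
box_size_schedule <- function(min_dim) {
  emax <- floor(min_dim / 4)
  if (emax < 8)
    stop("INSUFFICIENT_SCALES: region too small for a 3-scale schedule (need min dim >= 32 px)")
  2^(1:floor(log2(emax)))
}

#' Count occupied boxes at a set of box sizes
#'
#' The grid is tiled from the top-left corner into `eps x eps` boxes (the
#' last row/column of boxes may be partial) and, for each size, the number of
#' boxes containing at least one foreground pixel is returned.
#'
#' @param mask Logical matrix (or [vessel_mask]).
#' @param box_sizes_px Integer box sizes, each in `[1, min(dim(mask))]`.
#' @return `list(sizes, counts)`.
#' @export
box_count <- function(mask, box_sizes_px) {
  px <- if (inherits(mask, "vessel_mask")) mask$pixels else mask
  if (!any(px)) stop("EMPTY_MASK: box counting undefined for an empty mask")
  box_sizes_px <- as.integer(box_sizes_px)
  if (any(box_sizes_px < 1) || any(box_sizes_px > min(dim(px))))
    stop("box sizes must lie in [1, min(grid dims)]")
  list(sizes = box_sizes_px, counts = as.integer(cpp_box_count(px, box_sizes_px)))
}

#' Fit the box-counting fractal dimension
#'
#' Df is the ordinary-least-squares slope of `log N` against `log(1/eps)`
#' over the supplied `(eps, N)` pairs; the coefficient of determination of
#' that fit is reported alongside.
#'
#' @param sizes Box sizes eps (px).
#' @param counts Occupied-box counts N(eps), positive.
#' @return A `box_count_fit`: `box_sizes_px`, `counts`, `log_eps`, `log_N`,
#'   `df` (the dimension), `r2`, `n_points`.
#' @export
fit_dimension <- function(sizes, counts) {
  keep <- is.finite(sizes) & is.finite(counts) & counts > 0
  sizes <- sizes[keep]; counts <- counts[keep]
  if (length(sizes) < 3)
    stop("INSUFFICIENT_SCALES: need >= 3 (size, count) pairs with positive counts")
  x <- log(1 / sizes)
  y <- log(counts)
  # closed-form OLS (slope and r^2); equivalent to lm(y ~ x)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
  slope <- sxy / sxx
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 1
  structure(list(box_sizes_px = sizes, counts = counts,
                 log_eps = log(sizes), log_N = y,
                 df = slope, r2 = r2,
                 n_points = length(sizes)),
            class = "box_count_fit")
}

#' @export
print.box_count_fit <- function(x, ...) {
  cat(sprintf("<box_count_fit> Df = %.4f (r2 = %.4f, %d scales: %s)\n",
              x$df, x$r2, x$n_points,
              paste(x$box_sizes_px, collapse = ",")))
  invisible(x)
}

#' Fractal density of a vessel mask restricted to one region
#'
#' Box counting is applied to `mask & roi` over the tight bounding box of the
#' region, with the default size schedule taken from the bounding-box
#' dimensions unless sizes are supplied. An empty intersection is flagged
#' (`status = "EMPTY_MASK"`) rather than raising, so cohort assembly can
#' continue.
#'
#' @param mask A [vessel_mask] or logical matrix.
#' @param roi Logical region matrix of the same dimensions.
#' @param box_sizes_px Optional explicit size schedule.
#' @return A `box_count_fit` with extra fields `status` (`"OK"` or a reason
#'   code) and `pixel_fraction` (conventional area density of the mask inside
#'   the region -- not the Df metric).
#' @export
roi_density <- function(mask, roi, box_sizes_px = NULL) {
  px <- if (inherits(mask, "vessel_mask")) mask$pixels else mask
  if (!identical(dim(px), dim(roi))) stop("mask and roi geometry differ")
  if (!any(roi)) stop("empty roi region")
  rows <- range(which(rowSums(roi) > 0))
  cols <- range(which(colSums(roi) > 0))
  sub_roi <- roi[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  sub <- px[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE] & sub_roi
  pfrac <- sum(sub) / sum(sub_roi)
  if (!any(sub)) {
    out <- structure(list(box_sizes_px = integer(), counts = integer(),
                          log_eps = numeric(), log_N = numeric(),
                          df = NA_real_, r2 = NA_real_, n_points = 0L),
                     class = "box_count_fit")
    out$status <- "EMPTY_MASK"
    out$pixel_fraction <- pfrac
    return(out)
  }
  if (is.null(box_sizes_px)) box_sizes_px <- box_size_schedule(min(dim(sub)))
  bc <- box_count(sub, box_sizes_px)
  out <- fit_dimension(bc$sizes, bc$counts)
  out$status <- "OK"
  out$pixel_fraction <- pfrac
  out
}

density_row <- function(subject_id, group, eye, layer, mask_kind, scheme,
                        region, fit) {
  data.frame(subject_id = subject_id, group = group, eye = eye, layer = layer,
             mask_kind = mask_kind, scheme = scheme, region = region,
             density = fit$df, r2 = fit$r2, n_scales = fit$n_points,
             pixel_fraction = fit$pixel_fraction,
             status = fit$status, stringsAsFactors = FALSE)
}

#' Assemble the per-cohort density table
#'
#' For every manifest eye and available layer, the image is denoised,
#' binarized and caliber-split, and the fractal density of each mask kind
#' (`TMI`, `MIR`, `MAR`) is computed in every region of every partition
#' scheme (1 GLOBAL + 4 ETDRS + 4 HEMI + 6 ANNULI = 15 regions, i.e. 45 rows
#' per eye and layer). Per-image failures are recorded as rows with
#' `status != "OK"` and a missing density; the pipeline continues.
#'
#' @param manifest A `cohort_manifest` (see [read_manifest()]).
#' @param config Run configuration ([default_config()]).
#' @param images Optional named list of in-memory [angiogram]s keyed by the
#'   manifest's image-path entries, bypassing file I/O.
#' @param log Optional function called with one progress line per eye/layer.
#' @return A `density_table` data frame.
#' @export
build_density_table <- function(manifest, config = default_config(),
                                images = NULL, log = NULL) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  if (!nrow(manifest)) stop("empty manifest: nothing to analyze")
  layer_cols <- c(SRL = "image_srl", DRL = "image_drl")
  layer_cols <- layer_cols[layer_cols %in% names(manifest)]
  roi_cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(manifest) * length(layer_cols))
  k <- 0L
  for (i in seq_len(nrow(manifest))) {
    for (ln in names(layer_cols)) {
      ref <- manifest[[layer_cols[[ln]]]][i]
      if (is.na(ref) || !nzchar(ref)) next
      k <- k + 1L
      rows[[k]] <- tryCatch({
        mm <- if ("mm_per_px" %in% names(manifest)) manifest$mm_per_px[i]
              else config$mm_per_px
        img <- if (!is.null(images) && !is.null(images[[ref]])) images[[ref]]
               else read_angiogram(ref, mm_per_px = mm,
                                   layer = ln, eye = manifest$eye[i],
                                   subject_id = manifest$subject_id[i])
        t0 <- proc.time()[["elapsed"]]
        res <- eye_densities(img, config, roi_cache,
                             subject_id = manifest$subject_id[i],
                             group = manifest$group[i],
                             eye = manifest$eye[i], layer = ln)
        if (!is.null(log))
          log(sprintf("density %s/%s/%s: %d rows in %.2fs",
                      manifest$subject_id[i], manifest$eye[i], ln,
                      nrow(res), proc.time()[["elapsed"]] - t0))
        res
      }, error = function(e) {
        if (!is.null(log))
          log(sprintf("FAILED %s/%s/%s: %s", manifest$subject_id[i],
                      manifest$eye[i], ln, conditionMessage(e)))
        data.frame(subject_id = manifest$subject_id[i],
                   group = manifest$group[i], eye = manifest$eye[i],
                   layer = ln, mask_kind = NA_character_,
                   scheme = NA_character_, region = NA_character_,
                   density = NA_real_, r2 = NA_real_, n_scales = 0L,
                   pixel_fraction = NA_real_,
                   status = paste0("ERROR: ", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  structure(out, class = c("density_table", "data.frame"))
}

# precomputed per-region crop windows + size schedules for one geometry
prep_regions <- function(rois) {
  out <- list()
  for (rs in rois) {
    for (rn in names(rs$regions)) {
      roi <- rs$regions[[rn]]
      rows <- range(which(rowSums(roi) > 0))
      cols <- range(which(colSums(roi) > 0))
      sub_roi <- roi[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
      out[[length(out) + 1L]] <- list(
        scheme = rs$scheme, region = rn, rows = rows, cols = cols,
        sub_roi = sub_roi, n_roi = sum(sub_roi),
        sizes = box_size_schedule(min(dim(sub_roi))))
    }
  }
  out
}

# roi_density on a precomputed region window (hot path of cohort assembly)
roi_density_prepped <- function(px, pr) {
  sub <- px[pr$rows[1]:pr$rows[2], pr$cols[1]:pr$cols[2], drop = FALSE] & pr$sub_roi
  pfrac <- sum(sub) / pr$n_roi
  if (!any(sub)) {
    out <- structure(list(box_sizes_px = integer(), counts = integer(),
                          log_eps = numeric(), log_N = numeric(),
                          df = NA_real_, r2 = NA_real_, n_points = 0L),
                     class = "box_count_fit")
    out$status <- "EMPTY_MASK"; out$pixel_fraction <- pfrac
    return(out)
  }
  out <- fit_dimension(pr$sizes, as.integer(cpp_box_count(sub, pr$sizes)))
  out$status <- "OK"; out$pixel_fraction <- pfrac
  out
}

# densities of all masks x all regions for one loaded angiogram
eye_densities <- function(img, config, roi_cache = new.env(),
                          subject_id = img$subject_id, group = NA_character_,
                          eye = img$eye, layer = img$layer) {
  pp <- config$preprocess
  den <- denoise_nlm(img, h = pp$h, patch_px = pp$patch_px,
                     search_px = pp$search_px)
  tmi <- if (identical(pp$binarize, "fixed"))
    binarize(den, "fixed", threshold = pp$threshold)
  else binarize(den, "otsu")
  cal <- separate_calibers(tmi, caliber_cut_mm = pp$caliber_cut_mm)
  masks <- list(TMI = tmi, MIR = cal$mir, MAR = cal$mar)
  key <- paste(paste(dim(img$pixels), collapse = "x"), img$mm_per_px,
               paste(img$fovea_center_px, collapse = ","), sep = "|")
  if (is.null(roi_cache[[key]]))
    roi_cache[[key]] <- prep_regions(make_all_rois(img, config$roi))
  prep <- roi_cache[[key]]
  n <- length(masks) * length(prep)
  res <- data.frame(subject_id = rep(subject_id, n), group = group,
                    eye = eye, layer = layer,
                    mask_kind = rep(names(masks), each = length(prep)),
                    scheme = rep(vapply(prep, `[[`, "", "scheme"), length(masks)),
                    region = rep(vapply(prep, `[[`, "", "region"), length(masks)),
                    density = NA_real_, r2 = NA_real_, n_scales = 0L,
                    pixel_fraction = NA_real_, status = "",
                    stringsAsFactors = FALSE)
  k <- 0L
  for (mk in names(masks)) {
    px <- masks[[mk]]$pixels
    for (pr in prep) {
      fit <- roi_density_prepped(px, pr)
      k <- k + 1L
      res$density[k] <- fit$df; res$r2[k] <- fit$r2
      res$n_scales[k] <- fit$n_points
      res$pixel_fraction[k] <- fit$pixel_fraction
      res$status[k] <- fit$status
    }
  }
  res
}

#' Write / read a density table as CSV
#'
#' Long-format RFC-4180 CSV, one row per subject x eye x layer x mask x
#' region, densities at 4 decimals, stable column order. Writing an empty
#' table is an error.
#'
#' @param table A `density_table`.
#' @param path Output CSV path.
#' @return `path` (write) or a `density_table` (read).
#' @export
write_density_table <- function(table, path) {
  if (is.null(table) || !nrow(table)) stop("refusing to write an empty density table")
  cols <- c("subject_id", "group", "eye", "layer", "mask_kind", "scheme",
            "region", "density", "r2", "n_scales", "pixel_fraction", "status")
  out <- as.data.frame(table)[, cols]
  for (col in c("density", "r2", "pixel_fraction"))
    out[[col]] <- round(out[[col]], 4)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_density_table
#' @export
read_density_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("density_table", "data.frame"))
}
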