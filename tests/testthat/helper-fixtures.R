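# small constructors used across test files

mk_ang <- function(px, mm_per_px = 6 / ncol(px), ...) {
  suppressWarnings(angiogram(px, mm_per_px = mm_per_px, ...))
}

# horizontal bar(s) of given widths on a blank canvas
bar_mask <- function(nr, nc, rows_list) {
  m <- matrix(FALSE, nr, nc)
  for (rows in rows_list) m[rows, ] <- TRUE
  m
}

# geometry helper for ROI construction without an image
geom216 <- function(px = 216) list(dim = c(px, px), mm_per_px = 6 / px)

# a one-eye in-memory cohort (manifest + images list) around given angiograms
mem_manifest <- function(imgs_by_layer, subject_id = "HC01", group = "HC",
                         eye = "OD") {
  row <- data.frame(subject_id = subject_id, group = group, eye = eye,
                    conj_density = 1.6,
                    mm_per_px = imgs_by_layer[[1]]$mm_per_px,
                    image_srl = NA_character_, image_drl = NA_character_,
                    stringsAsFactors = FALSE)
  images <- list()
  for (ln in names(imgs_by_layer)) {
    key <- sprintf("mem://%s/%s/%s", subject_id, eye, ln)
    images[[key]] <- imgs_by_layer[[ln]]
    row[[if (ln == "DRL") "image_drl" else "image_srl"]] <- key
  }
  list(manifest = octafd:::validate_manifest(row), images = images)
}

# one simulated cohort pushed through the full analysis path
run_cohort_comparisons <- function(cfg) {
  coh <- synth_cohort(cfg)
  tab <- build_density_table(coh$manifest, images = coh$images)
  compare_all_regions(tab)
}

# density_table constructed directly (for statistics-layer unit tests)
mk_density_table <- function(df) {
  base <- data.frame(r2 = 0.99, n_scales = 5L, pixel_fraction = 0.3,
                     status = "OK", stringsAsFactors = FALSE)
  out <- cbind(df, base[rep(1, nrow(df)), , drop = FALSE])
  rownames(out) <- NULL
  structure(out, class = c("density_table", "data.frame"))
}
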