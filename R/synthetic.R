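#' Deterministic fractal fixtures with known box-counting dimension
#'
#' Ground-truth binary masks for validating the box-counting estimator:
#' a 1-px `line` (dimension 1), a `filled_square` (dimension 2), a `disk`
#' (dimension 2), and a `sierpinski_carpet` of the given depth (dimension
#' log 8 / log 3 ~ 1.8928, with `8^depth` filled cells).
#'
#' @param kind One of `"line"`, `"filled_square"`, `"sierpinski_carpet"`,
#'   `"disk"`.
#' @param size_px Mask side length. For the carpet, `3^depth` must divide
#'   `size_px`.
#' @param depth Carpet recursion depth.
#' @return Logical `size_px x size_px` matrix.
#' @export
make_fractal_fixture <- function(kind = c("line", "filled_square",
                                          "sierpinski_carpet", "disk"),
                                 size_px = 729, depth = 5) {
  kind <- match.arg(kind)
  switch(kind,
    line = {
      m <- matrix(FALSE, size_px, size_px)
      m[ceiling(size_px / 2), ] <- TRUE
      m
    },
    filled_square = matrix(TRUE, size_px, size_px),
    disk = {
      ctr <- (size_px - 1) / 2
      r <- size_px / 2 - 1
      d2 <- outer((seq_len(size_px) - 1 - ctr)^2,
                  (seq_len(size_px) - 1 - ctr)^2, "+")
      d2 <= r^2
    },
    sierpinski_carpet = {
      cells <- 3^depth
      if (size_px %% cells != 0)
        stop(sprintf("size_px must be a multiple of 3^depth = %d", cells))
      pat <- matrix(c(1, 1, 1, 1, 0, 1, 1, 1, 1), 3, 3)
      m <- matrix(1, 1, 1)
      for (k in seq_len(depth)) m <- kronecker(m, pat)
      kronecker(m, matrix(1, size_px / cells, size_px / cells)) > 0
    })
}

# stochastic branching tree: returns a matrix of segments
# (r0, c0, r1, c1, half_width_px, intensity), grown from one origin
grow_tree <- function(r0, c0, ang0, halfwidth, mm_per_px, dim_px,
                      seg_len_mm = c(0.14, 0.30), branch_prob = 0.38,
                      angle_jitter = 0.35, hw_decay = 0.94, hw_min = 0.55,
                      r_max_px, center, max_depth = 26, max_segs = 130,
                      intensity = c(0.55, 0.8)) {
  segs <- matrix(0, max_segs, 6)
  n <- 0L
  queue <- list(c(r0, c0, ang0, 0, halfwidth))
  while (length(queue) && n < max_segs) {
    st <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    len_px <- stats::runif(1, seg_len_mm[1], seg_len_mm[2]) / mm_per_px
    ang <- st[3] + stats::rnorm(1, 0, angle_jitter)
    r1 <- st[1] - sin(ang) * len_px   # +y superior = decreasing row
    c1 <- st[2] + cos(ang) * len_px
    n <- n + 1L
    segs[n, ] <- c(st[1], st[2], r1, c1, st[5],
                   stats::runif(1, intensity[1], intensity[2]))
    rad <- sqrt((r1 - center[1])^2 + (c1 - center[2])^2)
    depth <- st[4] + 1
    if (depth >= max_depth || rad > r_max_px ||
        r1 < -4 || r1 > dim_px + 3 || c1 < -4 || c1 > dim_px + 3) next
    hw <- max(st[5] * hw_decay, hw_min)
    queue[[length(queue) + 1L]] <- c(r1, c1, ang, depth, hw)
    if (stats::runif(1) < branch_prob) {
      dang <- sample(c(-1, 1), 1) * stats::runif(1, 0.4, 0.95)
      queue[[length(queue) + 1L]] <- c(r1, c1, ang + dang, depth, hw)
    }
  }
  segs[seq_len(n), , drop = FALSE]
}

#' Synthesize one en-face angiogram with controllable vascular structure
#'
#' Stochastic branching trees are grown outward from seeds on the rim of a
#' circular avascular zone: many narrow "micro" trees plus a few wide
#' "macro" trunks. Segments are rasterized as capsules, the avascular zone
#' is cleared, and the grayscale rendering adds Gaussian blur, a background
#' haze and speckle noise. Fully reproducible from `seed`.
#'
#' Branch density can be thinned globally (`keep_prob`) or regionally
#' (`regional_keep`): a micro segment whose midpoint falls in a region mask
#' is retained with the given probability, which is how group-level regional
#' density deficits are imposed.
#'
#' @param image_px Image side length (default 216 px, a 6 mm scan at the
#'   scanner's 216 A-scan sampling).
#' @param mm_per_px Physical scale.
#' @param faz_radius_mm Radius of the central avascular zone.
#' @param n_micro_trees,n_macro_trunks Numbers of narrow/wide trees.
#' @param micro_halfwidth,macro_halfwidth Half-width ranges (px).
#' @param keep_prob Global micro-segment retention probability in (0, 1].
#' @param regional_keep Named list `region mask -> retention probability`.
#' @param noise_sigma Additive Gaussian noise SD on the \[0, 1\] scale.
#' @param blur_sigma_px Gaussian blur SD of the renderer.
#' @param background Background haze intensity.
#' @param seed RNG seed (`NULL` uses the current RNG stream).
#' @param layer,eye,subject_id Metadata labels.
#' @param render If `FALSE`, skip the grayscale rendering (ground-truth mask
#'   only; much faster).
#' @return `list(image, clean_mask, segments)`: the noisy [angiogram] (or
#'   `NULL`), the noise-free TMI [vessel_mask] ground truth, and the segment
#'   table.
#' @export
synth_angiogram <- function(image_px = 216, mm_per_px = 6 / 216,
                            faz_radius_mm = 0.3, n_micro_trees = 18,
                            n_macro_trunks = 4,
                            micro_halfwidth = c(0.7, 1.1),
                            macro_halfwidth = c(2.4, 3.2),
                            keep_prob = 1, regional_keep = NULL,
                            noise_sigma = 0.08, blur_sigma_px = 0.8,
                            background = 0.12, seed = NULL,
                            layer = "SRL", eye = "NA", subject_id = "",
                            render = TRUE) {
  stopifnot(faz_radius_mm >= 0, keep_prob > 0, keep_prob <= 1)
  with_seed(seed, {
    center <- rep((image_px - 1) / 2, 2)
    faz_px <- faz_radius_mm / mm_per_px
    r_max_px <- 3.05 / mm_per_px
    seed_ring <- faz_px + 1.5
    micro <- lapply(seq_len(n_micro_trees), function(i) {
      a <- stats::runif(1, -pi, pi)
      grow_tree(center[1] - sin(a) * seed_ring, center[2] + cos(a) * seed_ring,
                ang0 = a + stats::rnorm(1, 0, 0.3),
                halfwidth = stats::runif(1, micro_halfwidth[1], micro_halfwidth[2]),
                mm_per_px = mm_per_px, dim_px = image_px,
                r_max_px = r_max_px, center = center)
    })
    macro <- lapply(seq_len(n_macro_trunks), function(i) {
      a <- stats::runif(1, -pi, pi)
      grow_tree(center[1] - sin(a) * seed_ring, center[2] + cos(a) * seed_ring,
                ang0 = a + stats::rnorm(1, 0, 0.2),
                halfwidth = stats::runif(1, macro_halfwidth[1], macro_halfwidth[2]),
                mm_per_px = mm_per_px, dim_px = image_px,
                seg_len_mm = c(0.25, 0.45), branch_prob = 0.22,
                angle_jitter = 0.25, hw_decay = 0.90,
                hw_min = macro_halfwidth[1] * 0.75,
                r_max_px = r_max_px, center = center, max_depth = 25,
                max_segs = 120, intensity = c(0.9, 1.0))
    })
    micro <- do.call(rbind, micro)
    macro <- do.call(rbind, macro)
    # thinning: global and regional retention of micro segments
    if (keep_prob < 1 || length(regional_keep)) {
      p <- rep(keep_prob, nrow(micro))
      if (length(regional_keep)) {
        mid_r <- pmin(pmax(round((micro[, 1] + micro[, 3]) / 2), 0), image_px - 1)
        mid_c <- pmin(pmax(round((micro[, 2] + micro[, 4]) / 2), 0), image_px - 1)
        idx <- cbind(mid_r + 1, mid_c + 1)
        for (k in seq_along(regional_keep))
          p <- p * ifelse(regional_keep[[k]]$mask[idx], regional_keep[[k]]$keep, 1)
      }
      micro <- micro[stats::runif(nrow(micro)) < p, , drop = FALSE]
    }
    segs <- rbind(micro, macro)
    if (!nrow(segs)) stop("parameter combination yields empty vasculature")
    canvas <- cpp_draw_capsules(image_px, image_px, segs)
    d2 <- outer((seq_len(image_px) - 1 - center[1])^2,
                (seq_len(image_px) - 1 - center[2])^2, "+")
    canvas[d2 <= faz_px^2] <- 0
    clean <- vessel_mask(canvas > 0, kind = "TMI", mm_per_px = mm_per_px,
                         fovea_center_px = center, layer = layer, eye = eye,
                         subject_id = subject_id)
    img <- NULL
    if (render) {
      blurred <- cpp_gblur(canvas, blur_sigma_px)
      px <- background + (1 - background) * blurred +
        stats::rnorm(length(blurred), 0, noise_sigma)
      img <- angiogram(pmin(pmax(px, 0), 1), mm_per_px = mm_per_px,
                       fovea_center_px = center, layer = layer, eye = eye,
                       subject_id = subject_id)
    }
    colnames(segs) <- c("r0", "c0", "r1", "c1", "half_width_px", "intensity")
    list(image = img, clean_mask = clean, segments = as.data.frame(segs))
  })
}

# design-time calibration curve: target control Df -> micro-segment keep
# probability, measured on the default SRL recipe
density_to_keep <- function(target_df) {
  curve_df <- c(1.614, 1.681, 1.726, 1.757, 1.778, 1.793)
  curve_keep <- c(0.25, 0.40, 0.55, 0.70, 0.85, 1.00)
  stats::approx(curve_df, curve_keep, xout = target_df, rule = 2)$y
}

valid_effect_regions <- function() {
  c("ALL", "S", "I", "L", "R", "SL", "SR", "IL", "IR", paste0("C", 1:6))
}

#' Synthetic cohort configuration
#'
#' Study-design parameters of the synthetic two-group cohort. Defaults
#' mirror the emulated study: 12 subjects with 2 eyes per group, 6 x 6 mm
#' scans at 216 px, and clinical covariates drawn from the published group
#' summaries (age, visual acuity, IOP, ESR, CRP).
#'
#' @param n_per_group Subjects per group.
#' @param eyes_per_subject 1 or 2.
#' @param image_px,mm_per_px Image geometry.
#' @param seed Cohort RNG seed.
#' @param base_density Target control-group global TMI Df.
#' @param regional_effects Named list/vector `region -> multiplicative
#'   branch-density retention` in (0, 1\] applied to the disease group (e.g.
#'   `c(S = 0.6)` = a 40% branch-density deficit in the superior ETDRS
#'   quadrant). Valid names: ALL, S, I, L, R, SL, SR, IL, IR, C1-C6.
#' @param conj_rho Copula correlation between conjunctival density and each
#'   eye's realized superficial TMI Df.
#' @param noise_sigma Speckle noise SD.
#' @param layers Layers to synthesize (`"SRL"`, `"DRL"`).
#' @param groups `c(control, disease)` labels.
#' @return Config list of class `synth_cohort_config`.
#' @export
synth_config <- function(n_per_group = 12, eyes_per_subject = 2,
                         image_px = 216, mm_per_px = 6 / 216, seed = 1,
                         base_density = 1.78, regional_effects = list(),
                         conj_rho = 0.7, noise_sigma = 0.08,
                         layers = c("SRL", "DRL"), groups = c("HC", "RA")) {
  stopifnot(n_per_group >= 2, eyes_per_subject %in% 1:2,
            conj_rho >= -1, conj_rho <= 1)
  regional_effects <- as.list(regional_effects)
  if (length(regional_effects)) {
    bad <- setdiff(names(regional_effects), valid_effect_regions())
    if (length(bad))
      stop("unknown region name(s) in regional_effects: ",
           paste(bad, collapse = ", "), "; valid: ",
           paste(valid_effect_regions(), collapse = ", "))
    eff <- unlist(regional_effects)
    if (any(eff <= 0 | eff > 1)) stop("regional effects must lie in (0, 1]")
  }
  structure(list(n_per_group = n_per_group,
                 eyes_per_subject = eyes_per_subject, image_px = image_px,
                 mm_per_px = mm_per_px, seed = seed,
                 base_density = base_density,
                 regional_effects = regional_effects, conj_rho = conj_rho,
                 noise_sigma = noise_sigma, layers = layers, groups = groups),
            class = "synth_cohort_config")
}

# Table-1-style covariate distributions (mean, sd) per group
covariate_dists <- function() {
  list(control = list(age_y = c(38.8, 5.7), visual_acuity = c(0.89, 0.12),
                      iop_mmHg = c(14.89, 1.06), esr_mm = c(3.84, 1.24),
                      crp = c(1.31, 0.77)),
       disease = list(age_y = c(39.0, 9.85), visual_acuity = c(0.68, 0.23),
                      iop_mmHg = c(15.36, 1.57), esr_mm = c(15.93, 8.43),
                      crp = c(3.27, 2.44)))
}

#' Generate a two-group synthetic cohort
#'
#' Control eyes are drawn at the configured base density; disease eyes have
#' their micro-branch density multiplied by `regional_effects` inside the
#' named regions. Conjunctival densities are generated by a Gaussian copula
#' at `conj_rho` against each eye's realized (noise-free) superficial global
#' TMI Df; clinical covariates come from the configured per-group
#' distributions. Eyes are statistically independent. The per-eye realized
#' regional densities (the generator's ground truth) are returned, and
#' written alongside the images when `dir` is given.
#'
#' @param config A [synth_config()].
#' @param dir Output directory for a self-contained cohort (images/,
#'   `manifest.csv`, `ground_truth.csv`, `config.yaml`), or `NULL` to keep
#'   images in memory.
#' @param render If `FALSE`, only ground-truth masks are produced (no
#'   grayscale images; `manifest` then carries no readable paths).
#' @return `list(manifest, images, ground_truth, config)`; `images` is a
#'   named list of [angiogram]s keyed like the manifest's path columns.
#' @export
synth_cohort <- function(config = synth_config(), dir = NULL, render = TRUE) {
  stopifnot(inherits(config, "synth_cohort_config"))
  geom <- list(dim = rep(config$image_px, 2), mm_per_px = config$mm_per_px)
  rois <- make_all_rois(geom)
  region_masks <- do.call(c, unname(lapply(rois, function(r) r$regions)))
  regional_keep <- NULL
  if (length(config$regional_effects))
    regional_keep <- lapply(names(config$regional_effects), function(rn)
      list(mask = region_masks[[rn]], keep = config$regional_effects[[rn]]))
  keep <- density_to_keep(config$base_density)
  glob <- rois$GLOBAL$regions$ALL
  etdrs <- rois$ETDRS$regions
  dists <- covariate_dists()
  grp_names <- stats::setNames(config$groups, c("control", "disease"))
  if (!is.null(dir)) dir.create(file.path(dir, "images"),
                                recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed, {
    man <- list(); gt <- list(); images <- list()
    stmi <- numeric(0)
    k <- 0L
    for (gi in c("control", "disease")) {
      g <- grp_names[[gi]]
      for (s in seq_len(config$n_per_group)) {
        sid <- sprintf("%s%02d", g, s)
        cov <- lapply(dists[[gi]], function(ms)
          round(max(ms[1] + stats::rnorm(1) * ms[2], 0.05), 3))
        for (e in c("OD", "OS")[seq_len(config$eyes_per_subject)]) {
          k <- k + 1L
          row <- data.frame(subject_id = sid, group = g, eye = e,
                            age_y = cov$age_y, visual_acuity = cov$visual_acuity,
                            iop_mmHg = cov$iop_mmHg, esr_mm = cov$esr_mm,
                            crp = cov$crp, conj_density = NA_real_,
                            mm_per_px = config$mm_per_px,
                            image_srl = NA_character_,
                            image_drl = NA_character_,
                            stringsAsFactors = FALSE)
          for (ln in config$layers) {
            deep <- ln == "DRL"
            syn <- synth_angiogram(
              image_px = config$image_px, mm_per_px = config$mm_per_px,
              n_micro_trees = if (deep) 22 else 18,
              n_macro_trunks = if (deep) 2 else 4,
              macro_halfwidth = if (deep) c(1.9, 2.5) else c(2.4, 3.2),
              keep_prob = keep,
              regional_keep = if (g == grp_names[["disease"]]) regional_keep,
              noise_sigma = config$noise_sigma, layer = ln, eye = e,
              subject_id = sid, render = render)
            ref <- if (!is.null(dir))
              file.path(dir, "images", sprintf("%s_%s_%s.png", sid, e, ln))
            else sprintf("mem://%s/%s/%s", sid, e, ln)
            if (render) {
              if (!is.null(dir)) png::writePNG(syn$image$pixels, ref)
              else images[[ref]] <- syn$image
              row[[if (deep) "image_drl" else "image_srl"]] <- ref
            }
            # realized (noise-free) densities: ground truth for recovery tests
            gfit <- roi_density(syn$clean_mask$pixels, glob)
            rows <- data.frame(subject_id = sid, group = g, eye = e,
                               layer = ln,
                               region = c("GLOBAL", names(etdrs)),
                               realized_df = c(gfit$df,
                                 vapply(etdrs, function(rm)
                                   roi_density(syn$clean_mask$pixels, rm)$df,
                                   0)),
                               stringsAsFactors = FALSE)
            gt[[length(gt) + 1L]] <- rows
            if (ln == "SRL") stmi[k] <- gfit$df
          }
          man[[k]] <- row
        }
      }
    }
    manifest <- do.call(rbind, man)
    # conjunctival density: Gaussian copula against realized superficial Df
    z <- as.numeric(scale(stmi))
    rho <- config$conj_rho
    conj <- 1.60 + 0.12 * (rho * z + sqrt(1 - rho^2) * stats::rnorm(length(z)))
    manifest$conj_density <- round(conj, 4)
    manifest <- validate_manifest(manifest, groups = config$groups)
    ground_truth <- do.call(rbind, gt)
    if (!is.null(dir)) {
      utils::write.csv(as.data.frame(manifest),
                       file.path(dir, "manifest.csv"), row.names = FALSE)
      utils::write.csv(ground_truth, file.path(dir, "ground_truth.csv"),
                       row.names = FALSE)
      cfg <- unclass(config)
      yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
    }
    list(manifest = manifest, images = images, ground_truth = ground_truth,
         config = config)
  })
}
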