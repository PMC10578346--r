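#' Two-sided pooled-variance (Student) t-test
#'
#' Classical independent-samples t with pooled variance and
#' `df = n1 + n2 - 2`. Two identical constant samples give `t = 0, p = 1`;
#' constant samples with unequal means have no defined t and raise
#' `DEGENERATE_VARIANCE`. Set `welch = TRUE` for the unequal-variance
#' variant.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param welch Use Welch's correction instead of pooling.
#' @return `list(t, p, df, mean_a, mean_b, sd_a, sd_b, n_a, n_b)`.
#' @export
independent_t_test <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite values")
  out <- list(mean_a = mean(a), mean_b = mean(b), sd_a = stats::sd(a),
              sd_b = stats::sd(b), n_a = length(a), n_b = length(b))
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(c(list(t = 0, p = 1, df = length(a) + length(b) - 2), out))
    stop("DEGENERATE_VARIANCE: zero variance with unequal means")
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  c(list(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter)), out)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects F test across `k >= 2` groups. With exactly two
#' groups, `F` equals the square of the pooled t statistic. Identical
#' constant groups (zero between- and within-group variance) are reported as
#' `F = 0, p = 1`.
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return `list(F, p, df1, df2)`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, 0L) < 2)) stop("each group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(y))) stop("non-finite values")
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  df1 <- length(groups) - 1L
  df2 <- length(y) - length(groups)
  if (stats::var(y) == 0) return(list(F = 0, p = 1, df1 = df1, df2 = df2))
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ow$statistic), p = ow$p.value, df1 = df1, df2 = df2)
}

#' Pearson product-moment correlation
#'
#' `r` with a two-sided p-value from the t transform on `n - 2` degrees of
#' freedom. Constant input raises `CONSTANT_INPUT`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return `list(r, p, n)`.
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("CONSTANT_INPUT: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pearson chi-square or Fisher's exact test on a 2x2 table
#'
#' Fisher's exact test is used for small samples -- whenever any expected
#' cell count is at most 5 or the total count is below 40 -- otherwise the
#' (uncorrected) Pearson chi-square; the method actually used is reported.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return `list(stat, p, method)` (`stat` is `NA` for Fisher).
#' @export
chi_square_or_fisher <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2) || any(table < 0) || any(table != round(table)))
    stop("need a 2x2 table of nonnegative integer counts")
  n <- sum(table)
  if (n == 0) stop("all-zero table")
  expected <- outer(rowSums(table), colSums(table)) / n
  if (any(expected <= 5) || n < 40) {
    ft <- stats::fisher.test(table)
    list(stat = NA_real_, p = ft$p.value, method = "fisher")
  } else {
    cs <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    list(stat = unname(cs$statistic), p = cs$p.value, method = "chisq")
  }
}

#' ROC analysis of a density marker between two groups
#'
#' AUC by the Mann-Whitney rank construction with tie correction and a 95%
#' DeLong confidence interval. Orientation is fixed so that *lower* density
#' in the disease group maps to AUC > 0.5 (control values are expected to
#' exceed disease values); the orientation is recorded in the result.
#'
#' @param values_by_group Named list of two numeric vectors; names are the
#'   group labels.
#' @param positive_label Name of the disease (case) group.
#' @return A `roc_result`: `auc`, `ci95 = c(lo, hi)`, `thresholds`,
#'   `sensitivity`, `specificity`, `orientation`, group sizes.
#' @export
roc_analysis <- function(values_by_group, positive_label = "RA") {
  stopifnot(is.list(values_by_group), length(values_by_group) == 2,
            positive_label %in% names(values_by_group))
  cases <- as.numeric(values_by_group[[positive_label]])
  controls <- as.numeric(values_by_group[[setdiff(names(values_by_group),
                                                  positive_label)]])
  if (!length(cases) || !length(controls)) stop("both groups must be nonempty")
  r <- pROC::roc(controls = controls, cases = cases, direction = ">",
                 quiet = TRUE)
  ci <- suppressWarnings(pROC::ci.auc(r, method = "delong"))
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci95 = c(max(0, ci[1]), min(1, ci[3])),
                 thresholds = r$thresholds,
                 sensitivity = r$sensitivities,
                 specificity = r$specificities,
                 orientation = "lower density indicates disease",
                 n_cases = length(cases), n_controls = length(controls)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (95%% CI %.3f-%.3f), %d cases vs %d controls; %s\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_cases, x$n_controls,
              x$orientation))
  invisible(x)
}

#' Group comparison and ROC for every region of a density table
#'
#' For each layer, the three caliber masks are compared on the global
#' annulus, and each subregion of the three partition schemes is compared on
#' the `masks_regional` mask(s) (default `TMI`, the structure of the
#' published comparison tables). Each comparison reports group mean/SD, the
#' pooled t-test, an optional multiplicity-adjusted p, a significance flag at
#' `alpha`, and the ROC AUC with its DeLong interval.
#'
#' @param table A `density_table`.
#' @param groups Named `c(control = , disease = )` labels.
#' @param alpha Significance level (default 0.05).
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()]
#'   (default `"none"`, matching the conventional uncorrected reporting).
#' @param unit `"eye"` (each eye is an observation) or `"subject"`
#'   (densities averaged per subject first).
#' @param masks_regional Mask kinds compared within subregions.
#' @param welch Use Welch's t instead of the pooled t.
#' @return A `region_comparison` data frame, one row per comparison, with
#'   attribute `alpha`.
#' @export
compare_all_regions <- function(table, groups = c(control = "HC", disease = "RA"),
                                alpha = 0.05, p_adjust = "none", unit = c("eye", "subject"),
                                masks_regional = "TMI", welch = FALSE) {
  unit <- match.arg(unit)
  df <- as.data.frame(table)
  df <- df[!is.na(df$mask_kind) & df$status == "OK" & is.finite(df$density), ]
  if (!nrow(df)) stop("no usable density rows")
  keep <- (df$scheme == "GLOBAL") |
    (df$scheme != "GLOBAL" & df$mask_kind %in% masks_regional)
  df <- df[keep, ]
  if (unit == "subject") {
    agg <- stats::aggregate(density ~ subject_id + group + layer + mask_kind +
                              scheme + region, data = df, FUN = mean)
    df <- agg
  }
  keys <- unique(df[, c("layer", "mask_kind", "scheme", "region")])
  keys <- keys[order(keys$layer, keys$scheme, keys$mask_kind, keys$region), ]
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sel <- df$layer == k$layer & df$mask_kind == k$mask_kind &
      df$scheme == k$scheme & df$region == k$region
    vc <- df$density[sel & df$group == groups[["control"]]]
    vd <- df$density[sel & df$group == groups[["disease"]]]
    row <- data.frame(layer = k$layer, mask_kind = k$mask_kind,
                      scheme = k$scheme, region = k$region,
                      n_control = length(vc), n_disease = length(vd),
                      mean_control = NA_real_, sd_control = NA_real_,
                      mean_disease = NA_real_, sd_disease = NA_real_,
                      t = NA_real_, p = NA_real_, auc = NA_real_,
                      auc_lo = NA_real_, auc_hi = NA_real_,
                      status = "OK", stringsAsFactors = FALSE)
    if (length(vc) < 2 || length(vd) < 2) {
      row$status <- "MISSING_GROUP"
    } else {
      tt <- tryCatch(independent_t_test(vc, vd, welch = welch),
                     error = function(e) NULL)
      if (is.null(tt)) {
        row$status <- "DEGENERATE_VARIANCE"
      } else {
        row$mean_control <- tt$mean_a; row$sd_control <- tt$sd_a
        row$mean_disease <- tt$mean_b; row$sd_disease <- tt$sd_b
        row$t <- tt$t; row$p <- tt$p
        rr <- stats::setNames(list(vc, vd),
                              c(groups[["control"]], groups[["disease"]]))
        roc <- roc_analysis(rr, positive_label = groups[["disease"]])
        row$auc <- roc$auc; row$auc_lo <- roc$ci95[1]; row$auc_hi <- roc$ci95[2]
      }
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  res$p_adj <- stats::p.adjust(res$p, method = p_adjust)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  attr(res, "alpha") <- alpha
  class(res) <- c("region_comparison", "data.frame")
  res
}

#' Demographics comparison table
#'
#' Per-subject clinical covariates compared between groups with the pooled
#' t-test, in the layout of a conventional cohort "Table 1".
#'
#' @param manifest A `cohort_manifest`.
#' @param groups Named `c(control = , disease = )` labels.
#' @param covariates Covariate columns to compare (present ones are used).
#' @return Data frame with per-group mean/SD, t and p per covariate.
#' @export
demographics_table <- function(manifest, groups = c(control = "HC", disease = "RA"),
                               covariates = c("age_y", "visual_acuity",
                                              "iop_mmHg", "esr_mm", "crp",
                                              "conj_density")) {
  df <- as.data.frame(manifest)
  df <- df[!duplicated(df$subject_id), ]
  covariates <- intersect(covariates, names(df))
  out <- lapply(covariates, function(cv) {
    vc <- df[[cv]][df$group == groups[["control"]]]
    vd <- df[[cv]][df$group == groups[["disease"]]]
    vc <- vc[is.finite(vc)]; vd <- vd[is.finite(vd)]
    tt <- tryCatch(independent_t_test(vc, vd), error = function(e) NULL)
    data.frame(covariate = cv,
               n_control = length(vc), n_disease = length(vd),
               mean_control = mean(vc), sd_control = stats::sd(vc),
               mean_disease = mean(vd), sd_disease = stats::sd(vd),
               t = if (is.null(tt)) NA_real_ else tt$t,
               p = if (is.null(tt)) NA_real_ else tt$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Correlation between conjunctival density and superficial TMI density
#'
#' Pearson correlation, across all eyes of both groups, between the
#' manifest's per-eye conjunctival capillary density and the superficial
#' (SRL) global TMI fractal density from the density table.
#'
#' @param table A `density_table`.
#' @param manifest The matching `cohort_manifest` (with `conj_density`).
#' @return Data frame with `r`, `p`, `n`.
#' @export
correlation_summary <- function(table, manifest) {
  df <- as.data.frame(table)
  stmi <- df[df$layer == "SRL" & df$mask_kind == "TMI" &
               df$scheme == "GLOBAL" & df$status == "OK", ]
  m <- merge(stmi[, c("subject_id", "eye", "density")],
             as.data.frame(manifest)[, c("subject_id", "eye", "conj_density")],
             by = c("subject_id", "eye"))
  m <- m[is.finite(m$density) & is.finite(m$conj_density), ]
  ct <- pearson_correlation(m$conj_density, m$density)
  data.frame(x = "conj_density", y = "STMI_df", r = ct$r, p = ct$p, n = ct$n)
}
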