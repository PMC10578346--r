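#' Read a cohort manifest CSV
#'
#' The manifest lists one row per eye: `subject_id`, `group` (control/disease
#' labels, by default `HC`/`RA`), `eye` (`OD`/`OS`), clinical covariates
#' (`age_y`, `visual_acuity`, `iop_mmHg`, `esr_mm`, `crp`, `conj_density`)
#' and per-layer image paths (`image_srl`, `image_drl`; relative paths are
#' resolved against the manifest's directory). `subject_id` x `eye` must be
#' unique and every group label must be one of `groups`.
#'
#' @param path CSV file with a header row.
#' @param groups Character vector of admissible group labels,
#'   `c(control, disease)`.
#' @param check_paths Verify that referenced image files exist.
#' @return A `cohort_manifest` data frame (possibly 0-row).
#' @export
read_manifest <- function(path, groups = c("HC", "RA"), check_paths = TRUE) {
  if (!file.exists(path)) stop("cannot read manifest: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "eye")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest is missing required columns: ", paste(missing, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df$group <- as.character(df$group)
  df$eye <- as.character(df$eye)
  if (nrow(df)) {
    bad <- setdiff(unique(df$group), groups)
    if (length(bad))
      stop("unknown group label(s): ", paste(bad, collapse = ", "),
           " (expected ", paste(groups, collapse = "/"), ")")
    key <- paste(df$subject_id, df$eye)
    if (anyDuplicated(key))
      stop("duplicate subject x eye rows in manifest: ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    base <- dirname(normalizePath(path))
    for (col in intersect(c("image_srl", "image_drl"), names(df))) {
      p <- df[[col]]
      rel <- !is.na(p) & nzchar(p) & !grepl("^(/|[A-Za-z]:)", p)
      p[rel] <- file.path(base, p[rel])
      df[[col]] <- p
      if (check_paths) {
        have <- !is.na(p) & nzchar(p)
        gone <- have & !file.exists(p)
        if (any(gone))
          stop("manifest references missing image file(s): ",
               paste(utils::head(p[gone], 5), collapse = ", "))
      }
    }
  }
  validate_manifest(df, groups)
}

validate_manifest <- function(df, groups = c("HC", "RA")) {
  structure(df, class = c("cohort_manifest", "data.frame"), groups = groups)
}

#' Write a cohort manifest CSV
#'
#' @param manifest A `cohort_manifest` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat(sprintf("<cohort_manifest> %d eyes, %d subjects; groups: %s\n",
              nrow(x), length(unique(x$subject_id)),
              paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 4))
  invisible(x)
}
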