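## Landmark and metrics file IO. CSV is the canonical interchange format
## (spreadsheet-compatible); JSON mirrors it field-for-field for
## programmatic use, and an XLSX adapter ingests spreadsheet exports with
## the same column layout. Coordinates in files are raw image pixels
## (y-down); all frame conventions are applied only by normalize_eye().

landmark_columns <- function() {
  c("subject_id", "rater_id", "laterality",
    as.vector(t(outer(sprintf("bez_%d", 0:3), c("x_px", "y_px"), paste, sep = "_"))),
    "limbus_a_x_px", "limbus_a_y_px", "limbus_b_x_px", "limbus_b_y_px",
    "pupil_x_px", "pupil_y_px")
}

landmarks_to_df <- function(landmarks) {
  if (inherits(landmarks, "landmark_set")) landmarks <- list(landmarks)
  rows <- lapply(landmarks, function(lm) {
    b <- lm$bezier_px
    vals <- c(as.vector(t(b)), lm$limbus_a_px, lm$limbus_b_px, lm$pupil_px)
    df <- data.frame(subject_id = lm$subject_id, rater_id = lm$rater_id,
                     laterality = lm$laterality, stringsAsFactors = FALSE)
    df[landmark_columns()[-(1:3)]] <- as.list(vals)
    df
  })
  do.call(rbind, rows)
}

df_to_landmarks <- function(df) {
  cols <- landmark_columns()
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_io(sprintf("landmark schema error: missing column(s) %s",
                    paste(missing, collapse = ", ")))
  }
  num_cols <- cols[-(1:3)]
  for (col in num_cols) {
    v <- df[[col]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
    } else {
      vn <- as.numeric(v)
    }
    bad <- which(is.na(vn) | !is.finite(vn))
    if (length(bad)) {
      stop_io(sprintf("landmark parse error: non-numeric value in column %s, row %d",
                      col, bad[1]))
    }
    df[[col]] <- vn
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    bez_cols <- sprintf("bez_%d_%s_px", rep(0:3, each = 2), c("x", "y"))
    bez <- matrix(as.numeric(unlist(row[bez_cols])),
                  nrow = 4, ncol = 2, byrow = TRUE)
    tryCatch(
      landmark_set(
        bez,
        limbus_a_px = c(row$limbus_a_x_px, row$limbus_a_y_px),
        limbus_b_px = c(row$limbus_b_x_px, row$limbus_b_y_px),
        pupil_px = c(row$pupil_x_px, row$pupil_y_px),
        laterality = as.character(row$laterality),
        subject_id = as.character(row$subject_id),
        rater_id = as.character(row$rater_id)),
      bezlid_validation_error = function(e) {
        stop_validation(sprintf("row %d (subject %s): %s",
                                i, as.character(row$subject_id), conditionMessage(e)))
      })
  })
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("csv", "json")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext else "csv"
}

#' Read landmark records
#'
#' Reads per-eye landmark records from CSV or JSON (schema: `subject_id`,
#' `rater_id`, `laterality`, then the 14 numeric pixel columns
#' `bez_{0..3}_{x,y}_px`, `limbus_{a,b}_{x,y}_px`, `pupil_{x,y}_px`) and
#' validates every row. Errors name the offending column, row and subject.
#'
#' @param path Input file path.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   `NULL`.
#' @return A list of [landmark_set()] objects.
#' @export
read_landmarks <- function(path, format = NULL) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  format <- infer_format(path, format)
  df <- switch(format,
               csv = utils::read.csv(path, stringsAsFactors = FALSE,
                                     colClasses = "character"),
               json = as.data.frame(jsonlite::fromJSON(path),
                                    stringsAsFactors = FALSE))
  if (!nrow(df)) stop_io(sprintf("no landmark rows in %s", path))
  df_to_landmarks(df)
}

#' Write landmark records
#'
#' Inverse of [read_landmarks()]: writes a list of [landmark_set()] objects
#' in the raw pixel schema, as CSV or JSON.
#'
#' @param landmarks A [landmark_set()] or list thereof.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   `NULL`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path, format = NULL) {
  format <- infer_format(path, format)
  df <- landmarks_to_df(landmarks)
  switch(format,
         csv = utils::write.csv(df, path, row.names = FALSE),
         json = jsonlite::write_json(df, path, digits = NA, auto_unbox = FALSE))
  invisible(path)
}

#' Read landmark records from a spreadsheet
#'
#' Adapter for XLSX exports that carry the same column layout as the CSV
#' schema (see [read_landmarks()]). Requires the `readxl` package.
#'
#' @param path XLSX file path.
#' @param sheet Sheet name or index (default first sheet).
#' @return A list of [landmark_set()] objects.
#' @export
read_landmarks_xlsx <- function(path, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop_io("reading XLSX requires the readxl package")
  }
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet),
                      stringsAsFactors = FALSE)
  if (!nrow(df)) stop_io(sprintf("no landmark rows in %s", path))
  df_to_landmarks(df)
}

#' Write the metrics tables
#'
#' Writes the wide per-eye metrics CSV (identifiers, scalar metrics, the 13
#' MPLD columns, the six temporal-to-nasal ratios and `ratio_total`) and,
#' optionally, the long-format MPLD table (one row per eye x angle).
#' Values are rounded to 2 decimals for display unless `full_precision`.
#'
#' @param metrics A list of `eyelid_metrics`, a single one, or the
#'   `data.frame` from [metrics_table()].
#' @param path Output path of the wide CSV.
#' @param long_path Optional output path of the long MPLD CSV.
#' @param full_precision Write full double precision instead of 2 decimals.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, long_path = NULL,
                          full_precision = FALSE) {
  df <- if (is.data.frame(metrics)) metrics else metrics_table(metrics)
  if (!nrow(df)) stop_validation("no metrics to write")
  out <- df
  if (!full_precision) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], round, digits = 2)
  }
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop_io(sprintf("directory does not exist: %s", dirname(path)))
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(long_path)) {
    mp_cols <- grep("^mpld_", names(df), value = TRUE)
    angles <- as.numeric(sub("^mpld_", "", mp_cols))
    long <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      data.frame(subject_id = df$subject_id[i], rater_id = df$rater_id[i],
                 laterality = df$laterality[i], angle_deg = angles,
                 mpld_mm = if (full_precision) as.numeric(df[i, mp_cols])
                           else round(as.numeric(df[i, mp_cols]), 2),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(long, long_path, row.names = FALSE)
  }
  invisible(path)
}

#' Measure every eye in a landmark collection
#'
#' Convenience pipeline: [normalize_eye()] then [measure_all()] over a list
#' of landmark sets.
#'
#' @param landmarks A list of [landmark_set()] (or a single one).
#' @param corneal_diameter_mm,mirror_policy Passed to [normalize_eye()].
#' @param angles,ratio_total Passed to [measure_all()].
#' @return A list of `eyelid_metrics`.
#' @export
measure_landmarks <- function(landmarks, corneal_diameter_mm = 12,
                              mirror_policy = "viewer",
                              angles = mpld_angles(),
                              ratio_total = "mean") {
  if (inherits(landmarks, "landmark_set")) landmarks <- list(landmarks)
  lapply(landmarks, function(lm) {
    eye <- normalize_eye(lm, corneal_diameter_mm = corneal_diameter_mm,
                         mirror_policy = mirror_policy)
    measure_all(eye, angles = angles, ratio_total = ratio_total)
  })
}
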