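# Format round-tripping: 8-bit grayscale PNG photographs, landmark CSVs,
# and the ratings spreadsheet (one row per comparison, one column per
# observer; XLSX as deposited, or CSV).

#' Write / read an 8-bit grayscale photograph
#'
#' @param image Numeric matrix, grey levels `[0, 255]`.
#' @param path File path (`.png`).
#' @return `read_photo_png()` returns the image matrix on the `[0, 255]`
#'   scale; `write_photo_png()` returns `path` invisibly.
#' @export
write_photo_png <- function(image, path) {
  png::writePNG(round(pmin(pmax(image, 0), 255)) / 255, path)
  invisible(path)
}

#' @rdname write_photo_png
#' @export
read_photo_png <- function(path) {
  if (!file.exists(path)) stop("photo file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * 255
}

#' Write a binary spot mask as a PNG for inspection
#'
#' Black pixels (spots) render black on a white background.
#'
#' @param binary A `binary_spot_image` or logical matrix.
#' @param path File path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(binary, path) {
  px <- if (inherits(binary, "binary_spot_image")) binary$pixels else binary
  stopifnot(is.logical(px), is.matrix(px))
  png::writePNG(1 - (px * 1), path)
  invisible(path)
}

landmarks_to_row <- function(lm) {
  tibble(eye_x = lm["eye", "x"], eye_y = lm["eye", "y"],
         nose_x = lm["nose_notch", "x"], nose_y = lm["nose_notch", "y"],
         mouth_x = lm["mouth_trailing_edge", "x"],
         mouth_y = lm["mouth_trailing_edge", "y"])
}

row_to_landmarks <- function(row) {
  landmarks(eye = c(row$eye_x, row$eye_y),
            nose_notch = c(row$nose_x, row$nose_y),
            mouth_trailing_edge = c(row$mouth_x, row$mouth_y))
}

#' Write a photo table to a directory
#'
#' Photographs go to `<photo_id>.png`; design and landmarks to
#' `landmarks.csv` with columns `photo_id`, `set_id`, `individual_id`,
#' `side`, `quality`, `eye_x`, `eye_y`, `nose_x`, `nose_y`, `mouth_x`,
#' `mouth_y`.
#'
#' @param photos Tibble from [render_study_photos()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_photos <- function(photos, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(photos))) {
    write_photo_png(photos$image[[i]],
                    file.path(dir, paste0(photos$photo_id[i], ".png")))
  }
  meta <- bind_rows(map(photos$landmarks, landmarks_to_row))
  meta <- dplyr::bind_cols(
    photos[, c("photo_id", "set_id", "individual_id", "side", "quality")],
    meta)
  readr::write_csv(meta, file.path(dir, "landmarks.csv"))
  invisible(dir)
}

#' Read a photo table from a directory
#'
#' Inverse of [write_photos()]: reads `landmarks.csv` and every referenced
#' PNG. Aborts naming any missing file.
#'
#' @param dir Directory written by [write_photos()].
#' @return A photos tibble with list-columns `image`, `landmarks`.
#' @export
read_photos <- function(dir) {
  lm_path <- file.path(dir, "landmarks.csv")
  if (!file.exists(lm_path)) stop("landmark file not found: ", lm_path)
  meta <- readr::read_csv(lm_path, show_col_types = FALSE)
  need <- c("photo_id", "set_id", "individual_id", "side", "quality",
            "eye_x", "eye_y", "nose_x", "nose_y", "mouth_x", "mouth_y")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("landmarks.csv lacks column(s): ", paste(miss, collapse = ", "))
  }
  as_tibble(meta) |>
    mutate(
      usable = .data$quality != "unsuitable",
      image = map(.data$photo_id, function(id) {
        read_photo_png(file.path(dir, paste0(id, ".png")))
      }),
      landmarks = map(row_number(), function(i) row_to_landmarks(meta[i, ]))
    )
}

#' Export a rated comparison table
#'
#' Wide CSV: one row per comparison (`trial_id`, `comparison_id`, `set_a`,
#' `set_b`, `truth`) and one rating column per observer.
#'
#' @param comparisons A [build_comparison_table()] tibble.
#' @param ratings Long ratings tibble (`comparison_id`, `observer_id`,
#'   `rating`).
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
export_ratings <- function(comparisons, ratings, path) {
  wide <- ratings |>
    tidyr::pivot_wider(names_from = "observer_id", values_from = "rating")
  out <- left_join(comparisons, wide, by = "comparison_id")
  readr::write_csv(out, path)
  invisible(path)
}

#' Import a ratings-by-comparison-by-observer table
#'
#' Reads the deposited spreadsheet layout -- one row per pairwise
#' comparison, one rating column per observer -- from XLSX or CSV and
#' validates it: the expected number of comparisons and observers, ratings
#' only in `{"S", "D"}`, no missing cells. Violations are reported in one
#' itemized failure.
#'
#' @param path `.xlsx` or `.csv` file.
#' @param n_comparisons,n_observers Expected dimensions (the study design:
#'   525 comparisons, 10 observers); `NULL` skips the corresponding check.
#' @param observer_cols Names of the observer columns; by default every
#'   column not among the id columns (`trial_id`, `comparison_id`,
#'   `set_a`, `set_b`, `truth`).
#' @return A tibble with the id columns present in the file plus the
#'   observer rating columns; observer column names in attribute
#'   `"observers"`. Pivot with [ratings_long()] for analysis.
#' @export
import_ratings <- function(path, n_comparisons = 525, n_observers = 10,
                           observer_cols = NULL) {
  if (!file.exists(path)) stop("ratings file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  tbl <- switch(ext,
    xlsx = readxl::read_excel(path),
    xls = readxl::read_excel(path),
    csv = readr::read_csv(path, show_col_types = FALSE),
    stop("unsupported ratings format: .", ext)
  )
  tbl <- as_tibble(tbl)
  id_cols <- intersect(c("trial_id", "comparison_id", "set_a", "set_b",
                         "truth"), names(tbl))
  if (!"comparison_id" %in% id_cols) {
    stop("ratings file lacks a comparison_id column")
  }
  if (is.null(observer_cols)) observer_cols <- setdiff(names(tbl), id_cols)
  issues <- character(0)
  if (!is.null(n_comparisons) && nrow(tbl) != n_comparisons) {
    issues <- c(issues, sprintf("expected %d comparisons, found %d",
                                n_comparisons, nrow(tbl)))
  }
  if (!is.null(n_observers) && length(observer_cols) != n_observers) {
    issues <- c(issues, sprintf("expected %d observer columns, found %d (%s)",
                                n_observers, length(observer_cols),
                                paste(observer_cols, collapse = ", ")))
  }
  dup <- tbl$comparison_id[duplicated(tbl$comparison_id)]
  if (length(dup)) {
    issues <- c(issues, paste("duplicated comparison id(s):",
                              paste(unique(dup), collapse = ", ")))
  }
  for (oc in observer_cols) {
    v <- tbl[[oc]]
    bad <- which(is.na(v) | !v %in% c("S", "D"))
    if (length(bad)) {
      issues <- c(issues, sprintf(
        "observer %s: invalid or missing rating at comparison %s", oc,
        paste(head(tbl$comparison_id[bad], 5), collapse = ", ")))
    }
  }
  if ("truth" %in% names(tbl) &&
      !all(tbl$truth %in% c("same", "different"))) {
    issues <- c(issues, "truth column contains values outside same/different")
  }
  if (length(issues)) {
    stop("ratings file failed validation:\n  - ",
         paste(issues, collapse = "\n  - "))
  }
  attr(tbl, "observers") <- observer_cols
  tbl
}

#' Pivot an imported ratings table to long form
#'
#' @param wide A tibble from [import_ratings()].
#' @param observer_cols Observer column names (default: the `"observers"`
#'   attribute).
#' @return Long tibble with `comparison_id`, `observer_id`, `rating` (id
#'   columns carried along).
#' @export
ratings_long <- function(wide, observer_cols = attr(wide, "observers")) {
  stopifnot(!is.null(observer_cols))
  tidyr::pivot_longer(wide, dplyr::all_of(observer_cols),
                      names_to = "observer_id", values_to = "rating")
}
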