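#' Validate a greyscale image matrix
#'
#' Images are plain integer matrices with intensities in 0..255 (8-bit
#' greyscale, the native depth of the analysis; no pre-processing is applied
#' anywhere in the pipeline).
#'
#' @param img object to check.
#' @param what label used in error messages.
#' @return the matrix, invisibly, after validation.
#' @keywords internal
assert_grey_image <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop(sprintf("%s has zero extent (%d x %d)", what, nrow(img), ncol(img)),
         call. = FALSE)
  }
  if (anyNA(img)) stop(sprintf("%s contains missing values", what), call. = FALSE)
  if (any(img < 0) || any(img > 255)) {
    stop(sprintf("%s has intensities outside [0, 255]", what), call. = FALSE)
  }
  if (any(img != round(img))) {
    stop(sprintf("%s has non-integer intensities", what), call. = FALSE)
  }
  invisible(img)
}

#' Read a greyscale ultrasound image
#'
#' Reads a PNG or TIFF image and returns an 8-bit greyscale intensity matrix
#' (values 0-255). RGB(A) input is converted to luminance by the integer-rounded
#' ITU-R BT.601 weights (0.299, 0.587, 0.114); 16-bit input is rescaled to
#' [0, 255] by division by the maximum representable value, then rounded.
#' An alpha channel, if present, is ignored.
#'
#' @param path path to a PNG or TIFF file.
#' @return an integer matrix of intensities in 0..255 (rows x cols).
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' write_grey_image(matrix(c(0, 255, 0, 255), 2, 2), f)
#' img <- read_grey_image(f)
read_grey_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("path must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file not found: %s", path), call. = FALSE)
  }
  lower <- tolower(path)
  raw <- if (grepl("\\.png$", lower)) {
    tryCatch(png::readPNG(path),
             error = function(e) stop(sprintf("unreadable PNG '%s': %s",
                                              path, conditionMessage(e)), call. = FALSE))
  } else if (grepl("\\.(tif|tiff)$", lower)) {
    tryCatch(tiff::readTIFF(path),
             error = function(e) stop(sprintf("unreadable TIFF '%s': %s",
                                              path, conditionMessage(e)), call. = FALSE))
  } else {
    stop(sprintf("unsupported image format (PNG or TIFF expected): %s", path),
         call. = FALSE)
  }
  # readPNG/readTIFF normalise to [0,1] regardless of bit depth, so x*255 is
  # both the identity for 8-bit data and max-value rescaling for 16-bit data.
  if (length(dim(raw)) == 2L) {
    grey255 <- raw * 255
  } else if (length(dim(raw)) == 3L) {
    nch <- dim(raw)[3L]
    chan <- function(k) {                # keep matrix shape for 1-pixel edges
      m <- raw[, , k]
      dim(m) <- dim(raw)[1:2]
      m
    }
    if (nch %in% c(1L, 2L)) {            # grey (+ alpha)
      grey255 <- chan(1L) * 255
    } else {                             # RGB (+ alpha)
      grey255 <- (0.299 * chan(1L) + 0.587 * chan(2L) + 0.114 * chan(3L)) * 255
    }
  } else {
    stop(sprintf("unsupported image array layout in %s", path), call. = FALSE)
  }
  img <- round(grey255)
  storage.mode(img) <- "integer"
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop(sprintf("zero-sized image: %s", path), call. = FALSE)
  }
  assert_grey_image(img, sprintf("image '%s'", path))
  img
}

#' Write a greyscale image to PNG
#'
#' @param img integer intensity matrix (0..255).
#' @param path output path ending in .png.
#' @return `path`, invisibly.
#' @export
write_grey_image <- function(img, path) {
  assert_grey_image(img)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' Rectangular region of interest
#'
#' Coordinates are 0-based and half-open on both axes, so the box covers pixel
#' rows `row_start .. row_end - 1` and its area is
#' `(row_end - row_start) * (col_end - col_start)`.
#'
#' @param row_start,row_end,col_start,col_end integer pixel bounds.
#' @return an object of class `roi_box`.
#' @export
roi_box <- function(row_start, row_end, col_start, col_end) {
  v <- c(row_start = row_start, row_end = row_end,
         col_start = col_start, col_end = col_end)
  if (anyNA(v) || any(v != round(v))) {
    stop("ROI coordinates must be integers", call. = FALSE)
  }
  if (row_start < 0 || col_start < 0 || row_end <= row_start || col_end <= col_start) {
    stop(sprintf(
      "invalid ROI box: rows [%d, %d), cols [%d, %d) (need 0 <= start < end)",
      row_start, row_end, col_start, col_end), call. = FALSE)
  }
  structure(as.list(stats::setNames(as.integer(v), names(v))),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("ROI box: rows [%d, %d), cols [%d, %d), area %d px\n",
              x$row_start, x$row_end, x$col_start, x$col_end, roi_area(x)))
  invisible(x)
}

#' @rdname roi_box
#' @param box an `roi_box`.
#' @export
roi_area <- function(box) {
  (box$row_end - box$row_start) * (box$col_end - box$col_start)
}

#' Crop a rectangular ROI from an image
#'
#' The full rectangle is the pixel population; no masking is applied (the
#' manual ROI of the imaging protocol is a plain rectangle drawn inside the
#' muscle fascia boundaries).
#'
#' @param img greyscale intensity matrix.
#' @param box an [roi_box()].
#' @return the cropped intensity matrix.
#' @export
extract_roi <- function(img, box) {
  assert_grey_image(img)
  if (!inherits(box, "roi_box")) {
    box <- do.call(roi_box, as.list(box)[c("row_start", "row_end",
                                           "col_start", "col_end")])
  }
  if (box$row_end > nrow(img) || box$col_end > ncol(img)) {
    stop(sprintf(
      "ROI box rows [%d, %d), cols [%d, %d) exceeds image extent %d x %d",
      box$row_start, box$row_end, box$col_start, box$col_end,
      nrow(img), ncol(img)), call. = FALSE)
  }
  img[(box$row_start + 1L):box$row_end, (box$col_start + 1L):box$col_end,
      drop = FALSE]
}

cohort_columns <- c("image_id", "row_start", "row_end", "col_start", "col_end",
                    "subject_id", "limb", "grade")

#' Load a cohort ROI/metadata table
#'
#' Reads a CSV with columns `image_id, row_start, row_end, col_start, col_end,
#' subject_id, limb, grade`. The grade column is the modified Heckmatt grade
#' (1 = normal echotexture, 4 = severely affected) and may be empty for an
#' ungraded cohort. ROI boxes must have an area of at least 64 pixels; smaller
#' populations make the texture statistics degenerate.
#'
#' @param path path to the CSV file.
#' @return a data frame with one row per image; `grade` is integer or `NA`.
#' @export
load_cohort_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cohort table not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(cohort_columns, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("cohort table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  tab <- tab[cohort_columns]
  for (col in c("row_start", "row_end", "col_start", "col_end")) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    if (anyNA(v)) {
      stop(sprintf("non-integer value in cohort column '%s'", col), call. = FALSE)
    }
    tab[[col]] <- v
  }
  grade_chr <- trimws(tab$grade)
  grade <- suppressWarnings(as.integer(grade_chr))
  bad <- which(nzchar(grade_chr) & (is.na(grade) | !grade %in% 1:4))
  if (length(bad)) {
    stop(sprintf("invalid grade '%s' in cohort table row %d (must be 1..4 or empty)",
                 grade_chr[bad[1L]], bad[1L]), call. = FALSE)
  }
  tab$grade <- ifelse(nzchar(grade_chr), grade, NA_integer_)
  if (anyDuplicated(tab$image_id)) {
    stop("duplicate image_id values in cohort table", call. = FALSE)
  }
  if (!all(tab$limb %in% c("left", "right"))) {
    stop("limb must be 'left' or 'right' in cohort table", call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    box <- roi_box(tab$row_start[i], tab$row_end[i],
                   tab$col_start[i], tab$col_end[i])
    if (roi_area(box) < 64L) {
      stop(sprintf("ROI for image '%s' (row %d) has area %d < 64 pixels",
                   tab$image_id[i], i, roi_area(box)), call. = FALSE)
    }
  }
  tab
}

#' Write a cohort ROI/metadata table
#'
#' @param tab data frame with the cohort columns (see [load_cohort_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(tab, path) {
  stopifnot(all(cohort_columns %in% names(tab)))
  out <- tab[cohort_columns]
  out$grade <- ifelse(is.na(out$grade), "", as.character(out$grade))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
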