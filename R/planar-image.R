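#' Planar gamma-camera count image
#'
#' A `planar_image` holds a 2-D grid of raw detector counts together with
#' the acquisition metadata needed for quantification: physical pixel
#' spacing, acquisition duration and acquisition start time. Counts are
#' stored row-major with a 0-based, top-left origin convention; pixel
#' `(i, j)` (row `i`, column `j`) has its centre at physical coordinates
#' `x = (j + 0.5) * spacing_x`, `y = (i + 0.5) * spacing_y` in cm.
#'
#' @param counts numeric matrix of non-negative counts. Counts must be
#'   integral unless `check_integer = FALSE` (used for noiseless
#'   expectation images, which carry fractional mean counts).
#' @param pixel_spacing physical pixel size in cm/pixel; a scalar or a
#'   length-2 vector `c(row, col)`.
#' @param acquisition_duration acquisition time in seconds.
#' @param acquisition_start acquisition start, a `POSIXct` timestamp.
#' @param check_integer enforce integral counts (the default).
#'
#' @return an object of class `planar_image`.
#' @seealso [read_grid_image()], [write_grid_image()], [roi_counts()]
#' @export
planar_image <- function(counts, pixel_spacing, acquisition_duration,
                         acquisition_start = as.POSIXct("2000-01-01 00:00:00",
                                                        tz = "UTC"),
                         check_integer = TRUE) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("counts must be a numeric matrix without missing values")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (check_integer && any(counts != round(counts))) {
    stop("counts must be integral")
  }
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0)) {
    stop("pixel_spacing must be one or two positive numbers (cm/pixel)")
  }
  acquisition_duration <- as.numeric(acquisition_duration)
  if (!is.finite(acquisition_duration) || acquisition_duration <= 0) {
    stop("acquisition_duration must be a positive number of seconds")
  }
  if (!inherits(acquisition_start, "POSIXct")) {
    acquisition_start <- as.POSIXct(acquisition_start, tz = "UTC")
  }
  structure(
    list(counts = counts,
         pixel_spacing = pixel_spacing,
         acquisition_duration = acquisition_duration,
         acquisition_start = acquisition_start),
    class = "planar_image"
  )
}

#' @export
print.planar_image <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("planar_image: %d x %d pixels, %.4g x %.4g cm/pixel\n",
              d[1], d[2], x$pixel_spacing[1], x$pixel_spacing[2]))
  cat(sprintf("  total counts %.6g, duration %g s, start %s\n",
              sum(x$counts), x$acquisition_duration,
              format(x$acquisition_start, "%Y-%m-%dT%H:%M:%S", tz = "UTC")))
  invisible(x)
}

#' Physical area of one pixel in cm^2
#' @param image a [planar_image()].
#' @return pixel area in cm^2.
#' @export
pixel_area <- function(image) {
  stopifnot(inherits(image, "planar_image"))
  prod(image$pixel_spacing)
}

# ---- portable grid format -------------------------------------------------
#
# Plain-text, version-controlled image format ("THYROGRID"):
#
#   THYROGRID 1
#   rows <nr>
#   cols <nc>
#   spacing <row cm/px> <col cm/px>
#   duration <seconds>
#   start <ISO 8601 UTC>
#   DATA
#   <nr whitespace-separated rows of nc integers>
#
# The header keys may appear in any order between the magic line and DATA.

#' Write a planar image in the portable grid format
#'
#' A plain-text PGM-like format (magic line `THYROGRID 1`, header
#' key-value lines, a `DATA` sentinel, then the integer count matrix in
#' row-major order). Round-trips counts and metadata losslessly, so
#' fixtures can live in version control.
#'
#' @param image a [planar_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid_image <- function(image, path) {
  stopifnot(inherits(image, "planar_image"))
  d <- dim(image$counts)
  header <- c(
    "THYROGRID 1",
    sprintf("rows %d", d[1]),
    sprintf("cols %d", d[2]),
    sprintf("spacing %.17g %.17g", image$pixel_spacing[1],
            image$pixel_spacing[2]),
    sprintf("duration %.17g", image$acquisition_duration),
    sprintf("start %s", format(image$acquisition_start,
                               "%Y-%m-%dT%H:%M:%S", tz = "UTC")),
    "DATA"
  )
  body <- apply(image$counts, 1L, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a planar image from the portable grid format
#'
#' @param path file path written by [write_grid_image()].
#' @param check_integer enforce integral counts (the default).
#' @return a [planar_image()].
#' @export
read_grid_image <- function(path, check_integer = TRUE) {
  lines <- readLines(path)
  if (length(lines) < 3L || !identical(trimws(lines[1]), "THYROGRID 1")) {
    stop("not a THYROGRID 1 file: ", path)
  }
  data_at <- which(trimws(lines) == "DATA")[1]
  if (is.na(data_at)) stop("malformed grid file: missing DATA sentinel")
  hdr <- list()
  for (ln in lines[2:(data_at - 1L)]) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "[ \t]+")[[1]]
    hdr[[parts[1]]] <- parts[-1]
  }
  need <- c("rows", "cols", "spacing", "duration", "start")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("malformed grid header: missing ", paste(miss, collapse = ", "))
  nr <- as.integer(hdr$rows)
  nc <- as.integer(hdr$cols)
  vals <- scan(text = paste(lines[(data_at + 1L):length(lines)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("grid body has %d values, expected %d x %d = %d",
                 length(vals), nr, nc, nr * nc))
  }
  counts <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (all(counts == round(counts)) && max(counts) <= .Machine$integer.max) {
    storage.mode(counts) <- "integer"
  }
  planar_image(counts,
               pixel_spacing = as.numeric(hdr$spacing),
               acquisition_duration = as.numeric(hdr$duration),
               acquisition_start = as.POSIXct(paste(hdr$start, collapse = " "),
                                              format = "%Y-%m-%dT%H:%M:%S",
                                              tz = "UTC"),
               check_integer = check_integer)
}
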