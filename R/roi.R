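#' Region-of-interest pixel mask
#'
#' A `roi_mask` is the set of pixels belonging to one region (thyroid,
#' background, injection-site leakage ...) of a planar image, stored as
#' linear indices into the count matrix plus the matrix dimensions.
#'
#' @param member either a logical matrix the size of the image (TRUE =
#'   member pixel) or an integer vector of linear (column-major) indices.
#' @param dim the image dimensions `c(rows, cols)`; required when
#'   `member` is an index vector.
#' @return an object of class `roi_mask` with elements `idx` (sorted
#'   linear indices) and `dim`.
#' @export
roi_mask <- function(member, dim = NULL) {
  if (is.matrix(member) && is.logical(member)) {
    dim <- base::dim(member)
    idx <- which(member)
  } else {
    idx <- as.integer(member)
    if (is.null(dim) || length(dim) != 2L) {
      stop("dim = c(rows, cols) is required when member is an index vector")
    }
  }
  dim <- as.integer(dim)
  if (length(idx) == 0L) stop("ROI mask is empty")
  if (any(idx < 1L) || any(idx > prod(dim))) {
    stop("ROI indices outside the image bounds")
  }
  if (anyDuplicated(idx)) idx <- unique(idx)
  structure(list(idx = sort(idx), dim = dim), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: %d pixels in a %d x %d grid\n",
              length(x$idx), x$dim[1], x$dim[2]))
  invisible(x)
}

#' Number of member pixels in a mask
#' @param roi a [roi_mask()].
#' @export
roi_pixel_count <- function(roi) {
  stopifnot(inherits(roi, "roi_mask"))
  length(roi$idx)
}

#' Do two masks share any pixel?
#' @param a,b [roi_mask()] objects on the same grid.
#' @export
roi_overlaps <- function(a, b) {
  stopifnot(inherits(a, "roi_mask"), inherits(b, "roi_mask"))
  if (!identical(a$dim, b$dim)) stop("masks are defined on different grids")
  length(intersect(a$idx, b$idx)) > 0L
}

#' Counts and physical area inside an ROI
#'
#' Sums the raw counts over the member pixels and converts the pixel
#' count to a physical area. These are the `C` (counts) and `S` (cm^2)
#' quantities that enter the uptake ratios: `C_T`/`S_T` for the thyroid
#' ROI and `C_B`/`S_B` for the background ROI.
#'
#' @param image a [planar_image()].
#' @param roi a [roi_mask()] on the same grid.
#' @return a list with `C` (total counts), `S` (area, cm^2) and
#'   `n_pixels`.
#' @export
roi_counts <- function(image, roi) {
  stopifnot(inherits(image, "planar_image"), inherits(roi, "roi_mask"))
  if (!identical(as.integer(dim(image$counts)), roi$dim)) {
    stop("ROI grid does not match the image dimensions")
  }
  list(C = sum(image$counts[roi$idx]),
       S = length(roi$idx) * pixel_area(image),
       n_pixels = length(roi$idx))
}

# ---- polygon rasterization ------------------------------------------------

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
# Half-open convention: a crossing counts when one endpoint is strictly
# above and the other at-or-below the test point, and the edge crossing is
# strictly to the right of the point. Left/top boundary pixels are included,
# right/bottom excluded, so adjacent polygons tile without double counting.
.points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    yi <- vy[i]; yj <- vy[j]
    xi <- vx[i]; xj <- vx[j]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

# Proper-intersection test between non-adjacent edges (O(n^2); ROI polygons
# are small). Shared endpoints between adjacent edges are not intersections.
.polygon_self_intersects <- function(vx, vy) {
  n <- length(vx)
  seg <- cbind(vx, vy, vx[c(2:n, 1)], vy[c(2:n, 1)])
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      o1 <- orient(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      o2 <- orient(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      o3 <- orient(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      o4 <- orient(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0) return(TRUE)
    }
  }
  FALSE
}

#' Rasterize a polygon ROI to a pixel mask
#'
#' Vertices are given in continuous pixel coordinates (0-based, origin at
#' the top-left corner of the image; `x` along columns, `y` along rows).
#' Pixel `(i, j)` is a member when its centre `(j + 0.5, i + 0.5)` falls
#' inside the polygon under the even-odd rule, with a half-open boundary
#' convention (left/top edges included) so the rasterization is
#' deterministic across platforms.
#'
#' @param polygon a two-column matrix (or data frame) of `(x, y)` vertices,
#'   at least 3, describing a closed, non-self-intersecting polygon.
#' @param image the [planar_image()] the ROI lives on (supplies the grid).
#' @return a [roi_mask()].
#' @export
polygon_to_mask <- function(polygon, image) {
  stopifnot(inherits(image, "planar_image"))
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
    stop("polygon must have at least 3 (x, y) vertices")
  }
  vx <- as.numeric(polygon[, 1]); vy <- as.numeric(polygon[, 2])
  if (.polygon_self_intersects(vx, vy)) stop("polygon is self-intersecting")
  # degenerate: zero signed area (all vertices collinear)
  area2 <- sum(vx * vy[c(2:length(vy), 1)] - vx[c(2:length(vx), 1)] * vy)
  if (abs(area2) < .Machine$double.eps * max(1, max(abs(vx)), max(abs(vy)))^2) {
    stop("degenerate polygon: vertices are collinear (zero area)")
  }
  d <- dim(image$counts)
  # restrict the test to the polygon bounding box
  i0 <- max(0L, floor(min(vy) - 0.5)); i1 <- min(d[1] - 1L, ceiling(max(vy)))
  j0 <- max(0L, floor(min(vx) - 0.5)); j1 <- min(d[2] - 1L, ceiling(max(vx)))
  if (i1 < i0 || j1 < j0) stop("polygon lies outside the image")
  ii <- i0:i1; jj <- j0:j1
  px <- rep(jj + 0.5, each = length(ii))
  py <- rep(ii + 0.5, times = length(jj))
  inside <- .points_in_polygon(px, py, vx, vy)
  if (!any(inside)) stop("polygon contains no pixel centres")
  rows <- rep(ii, times = length(jj))[inside] + 1L
  cols <- rep(jj, each = length(ii))[inside] + 1L
  roi_mask(as.integer((cols - 1L) * d[1] + rows), dim = d)
}

# ---- mask / polygon file I/O ---------------------------------------------

#' Write / read an ROI mask as a portable 0/1 grid
#'
#' The mask is stored in the same plain-text grid format as images
#' ([write_grid_image()]) with 1 for member pixels, using unit spacing
#' and duration placeholders (a mask has no acquisition metadata).
#'
#' @param roi a [roi_mask()].
#' @param path file path.
#' @return `path` (write) or a [roi_mask()] (read).
#' @export
write_grid_mask <- function(roi, path) {
  stopifnot(inherits(roi, "roi_mask"))
  m <- matrix(0L, roi$dim[1], roi$dim[2])
  m[roi$idx] <- 1L
  write_grid_image(planar_image(m, pixel_spacing = 1, acquisition_duration = 1),
                   path)
}

#' @rdname write_grid_mask
#' @export
read_grid_mask <- function(path) {
  img <- read_grid_image(path)
  if (any(!img$counts %in% c(0, 1))) stop("mask grid must contain only 0/1")
  roi_mask(img$counts == 1)
}

#' Write / read a polygon ROI as JSON
#'
#' Serializes the vertex list as `{"vertices": [[x, y], ...]}` in pixel
#' coordinates (see [polygon_to_mask()] for the coordinate convention).
#'
#' @param polygon two-column vertex matrix.
#' @param path file path.
#' @export
write_polygon <- function(polygon, path) {
  polygon <- as.matrix(polygon)
  jsonlite::write_json(list(vertices = unname(polygon)), path, digits = NA)
  invisible(path)
}

#' @rdname write_polygon
#' @export
read_polygon <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$vertices)) stop("polygon file has no 'vertices' field")
  as.matrix(obj$vertices)
}
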