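#' Rasterize a contour onto the image grid
#'
#' A pixel belongs to the mask iff its centre lies strictly inside the
#' polygon under the even-odd rule; centres lying exactly on an edge are
#' excluded. Pixel centres sit at integer coordinates, `(x, y) = (col, row)`,
#' 0-based.
#'
#' @param ct a [contour()].
#' @param shape integer length-2, (rows, cols) of the target grid.
#' @return Logical matrix of dimension `shape`.
#' @export
rasterize_contour <- function(ct, shape) {
  stopifnot(inherits(ct, "contour"), length(shape) == 2L)
  pts <- ct$points
  if (any(pts[, 1L] < -0.5 - 1e-9) || any(pts[, 1L] > shape[2L] - 0.5 + 1e-9) ||
      any(pts[, 2L] < -0.5 - 1e-9) || any(pts[, 2L] > shape[1L] - 0.5 + 1e-9))
    stop("contour extends outside the image grid", call. = FALSE)
  mask <- matrix(FALSE, shape[1L], shape[2L])
  # restrict the inside test to the polygon's bounding box
  r0 <- max(0L, floor(min(pts[, 2L]))); r1 <- min(shape[1L] - 1L, ceiling(max(pts[, 2L])))
  c0 <- max(0L, floor(min(pts[, 1L]))); c1 <- min(shape[2L] - 1L, ceiling(max(pts[, 1L])))
  if (r1 < r0 || c1 < c0) return(mask)
  rows <- r0:r1; cols <- c0:c1
  px <- rep(cols, each = length(rows))
  py <- rep(rows, times = length(cols))
  inside <- points_in_polygon(px, py, pts)
  mask[cbind(py + 1L, px + 1L)] <- inside
  mask
}

#' Dice metric of two region masks
#'
#' Area-overlap score `2 |A n B| / (|A| + |B|)`, ranging from 0 (no overlap)
#' to 1 (perfect overlap). Two empty masks count as identical regions
#' (Dice 1); empty versus non-empty gives 0.
#'
#' @param a,b logical matrices of identical dimension.
#' @return Dice metric in `[0, 1]`.
#' @export
dice_metric <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Resample a contour to physical coordinates at a fixed step
#'
#' @param ct a [contour()].
#' @param pixel_spacing_mm (row, col) spacing in mm.
#' @param step_mm maximum spacing between consecutive resampled points
#'   (default 0.25 mm).
#' @return n x 2 matrix of (x, y) positions in mm.
#' @export
contour_points_mm <- function(ct, pixel_spacing_mm, step_mm = 0.25) {
  stopifnot(step_mm > 0)
  mm <- cbind(ct$points[, 1L] * pixel_spacing_mm[2L],
              ct$points[, 2L] * pixel_spacing_mm[1L])
  n <- max(nrow(mm), ceiling(poly_perimeter(mm) / step_mm))
  resample_closed(mm, n)
}

#' Hausdorff distance between two contour point sets
#'
#' The symmetric max-min Euclidean distance
#' `max(max_x min_y d(x,y), max_y min_x d(x,y))` over densely resampled
#' contour points, in mm.
#'
#' @param x,y n x 2 point matrices (mm), e.g. from [contour_points_mm()].
#' @return Hausdorff distance in mm.
#' @export
hausdorff_distance <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!nrow(x) || !nrow(y)) stop("empty point set", call. = FALSE)
  d2 <- outer(x[, 1L], y[, 1L], "-")^2 + outer(x[, 2L], y[, 2L], "-")^2
  max(sqrt(max(apply(d2, 1L, min))), sqrt(max(apply(d2, 2L, min))))
}

#' Per-slice Dice and Hausdorff between two contour sets
#'
#' Pairs contours by (phase, slice), rasterizes each pair on the stated grid
#' for the Dice metric, and resamples the polylines to physical mm for the
#' Hausdorff distance — areas for overlap, boundary points for distance.
#' Keys present in only one set are skipped.
#'
#' @param set_a,set_b [contour_set()] objects sharing spacing metadata.
#' @param shape (rows, cols) of the underlying image grid.
#' @param structure structure to compare (default `"rv_endo"`).
#' @param step_mm Hausdorff resampling step (default 0.25 mm).
#' @return Tibble with columns `phase`, `slice`, `dice`, `hausdorff_mm`.
#' @export
contour_metrics <- function(set_a, set_b, shape, structure = "rv_endo",
                            step_mm = 0.25) {
  keys_a <- lapply(set_a$contours, function(ct) c(ct$phase, ct$slice, ct$structure))
  rows <- list()
  sp <- set_a$pixel_spacing_mm
  for (k in keys_a) {
    if (k[[3L]] != structure) next
    p <- as.integer(k[[1L]]); s <- as.integer(k[[2L]])
    ca <- get_contour(set_a, p, s, structure)
    cb <- get_contour(set_b, p, s, structure)
    if (is.null(cb)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      phase = p, slice = s,
      dice = dice_metric(rasterize_contour(ca, shape),
                         rasterize_contour(cb, shape)),
      hausdorff_mm = hausdorff_distance(
        contour_points_mm(ca, sp, step_mm),
        contour_points_mm(cb, sp, step_mm)))
  }
  if (!length(rows))
    return(tibble::tibble(phase = integer(), slice = integer(),
                          dice = numeric(), hausdorff_mm = numeric()))
  dplyr::bind_rows(rows)
}
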