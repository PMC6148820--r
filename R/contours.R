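#' Closed planar contour bound to a (phase, slice, structure) triple
#'
#' A contour is an ordered, implicitly closed polygon in continuous pixel
#' coordinates, with `x` along image columns and `y` along image rows
#' (0-based: the centre of the top-left pixel is `(0, 0)`). Physical
#' millimetre coordinates are obtained by multiplying `x` by the column
#' spacing and `y` by the row spacing.
#'
#' @param points numeric matrix (or two-column data frame) of at least three
#'   `(x, y)` vertices; a repeated final vertex equal to the first is dropped.
#' @param phase,slice 0-based phase and slice indices.
#' @param structure one of `"rv_endo"`, `"lv_endo"`, `"lv_epi"`.
#' @param check validate simplicity and positive area (default `TRUE`).
#'
#' @return An object of class `contour`: a list with fields `phase`, `slice`,
#'   `structure` and `points` (n x 2 matrix, columns `x`, `y`).
#' @examples
#' sq <- contour(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), 0, 0)
#' contour_area(sq, c(1, 1))
#' @export
contour <- function(points, phase = 0L, slice = 0L, structure = "rv_endo",
                    check = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("contour points must be an n x 2 matrix of (x, y)", call. = FALSE)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (n >= 4L && all(abs(points[n, ] - points[1L, ]) < 1e-12))
    points <- points[-n, , drop = FALSE]
  if (nrow(points) < 3L)
    stop("a contour needs at least 3 distinct points", call. = FALSE)
  if (!all(is.finite(points)))
    stop("contour points must be finite", call. = FALSE)
  structure <- match.arg(structure, c("rv_endo", "lv_endo", "lv_epi"))
  colnames(points) <- c("x", "y")
  obj <- base::structure(
    list(phase = as.integer(phase), slice = as.integer(slice),
         structure = structure, points = points),
    class = "contour")
  if (check) {
    if (abs(poly_signed_area(points)) <= 0)
      stop("contour encloses no area", call. = FALSE)
    if (!poly_is_simple(points))
      stop("contour polygon is self-intersecting", call. = FALSE)
  }
  obj
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %s  phase %d  slice %d  %d points  area %.1f px^2\n",
              x$structure, x$phase, x$slice, nrow(x$points),
              abs(poly_signed_area(x$points))))
  invisible(x)
}

#' @export
format.contour <- function(x, ...) {
  sprintf("%s p%d s%d (%d pts)", x$structure, x$phase, x$slice, nrow(x$points))
}

# ---- low-level polygon geometry (vertices as n x 2 matrices) ----------------

# signed shoelace area in the coordinate units of `pts`
poly_signed_area <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

poly_centroid <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(pts))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

poly_perimeter <- function(pts) {
  d <- pts - pts[c(2:nrow(pts), 1L), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# Even-odd point-in-polygon, strict interior: points lying on an edge are
# excluded. Vectorised over query points; loops over edges.
points_in_polygon <- function(px, py, pts, tol = 1e-9) {
  n <- nrow(pts)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- pts[j, 1L]; y1 <- pts[j, 2L]
    x2 <- pts[i, 1L]; y2 <- pts[i, 2L]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xi <- x1 + (py[crosses] - y1) * (x2 - x1) / (y2 - y1)
      hit <- logical(sum(crosses))
      hit[px[crosses] < xi] <- TRUE
      inside[crosses] <- xor(inside[crosses], hit)
    }
    # on-segment test
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - x1) * dx + (py - y1) * dy) / len2
      perp <- abs((px - x1) * dy - (py - y1) * dx) / sqrt(len2)
      on_edge <- on_edge | (perp < tol & t > -tol & t < 1 + tol)
    }
    j <- i
  }
  inside & !on_edge
}

seg_intersects <- function(p1, p2, p3, p4, tol = 1e-12) {
  o <- function(a, b, c)
    (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
  d1 <- o(p3, p4, p1); d2 <- o(p3, p4, p2)
  d3 <- o(p1, p2, p3); d4 <- o(p1, p2, p4)
  if (((d1 > tol && d2 < -tol) || (d1 < -tol && d2 > tol)) &&
      ((d3 > tol && d4 < -tol) || (d3 < -tol && d4 > tol))) return(TRUE)
  FALSE
}

# simple = no two non-adjacent edges properly intersect
poly_is_simple <- function(pts) {
  n <- nrow(pts)
  idx <- cbind(seq_len(n), c(2:n, 1L))
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (seg_intersects(pts[idx[i, 1L], ], pts[idx[i, 2L], ],
                         pts[idx[j, 1L], ], pts[idx[j, 2L], ])) return(FALSE)
    }
  }
  TRUE
}

# Uniform arc-length resampling of a closed polyline to n points.
resample_closed <- function(pts, n) {
  m <- nrow(pts)
  closed <- rbind(pts, pts[1L, , drop = FALSE])
  seg <- sqrt(rowSums((closed[-1L, , drop = FALSE] -
                         closed[-(m + 1L), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[m + 1L]
  if (total <= 0) stop("degenerate polyline", call. = FALSE)
  target <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  x <- stats::approx(s, closed[, 1L], xout = target, ties = "ordered")$y
  y <- stats::approx(s, closed[, 2L], xout = target, ties = "ordered")$y
  cbind(x = x, y = y)
}

# one pass of a circular 3-point moving average
smooth_closed <- function(pts) {
  n <- nrow(pts)
  (pts[c(n, 1:(n - 1L)), , drop = FALSE] + pts +
      pts[c(2:n, 1L), , drop = FALSE]) / 3
}

#' Tidy a contour into a tibble of vertices
#'
#' @param x a [contour()].
#' @param ... unused.
#' @return A tibble with columns `phase`, `slice`, `structure`, `point`, `x`, `y`.
#' @method tidy contour
#' @export
#' @importFrom generics tidy
tidy.contour <- function(x, ...) {
  tibble::tibble(phase = x$phase, slice = x$slice, structure = x$structure,
                 point = seq_len(nrow(x$points)),
                 x = x$points[, 1L], y = x$points[, 2L])
}

#' @export
generics::tidy

# ---- contour sets -----------------------------------------------------------

#' Collection of contours sharing one stack's spacing metadata
#'
#' @param contours list of [contour()] objects; no two may share the same
#'   (phase, slice, structure) key.
#' @param pixel_spacing_mm numeric length-2, (row, col) spacing in mm.
#' @param slice_thickness_mm,interslice_gap_mm slice geometry in mm.
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(contours = list(), pixel_spacing_mm = c(1, 1),
                        slice_thickness_mm = 8, interslice_gap_mm = 2) {
  stopifnot(length(pixel_spacing_mm) == 2L, all(pixel_spacing_mm > 0),
            slice_thickness_mm > 0, interslice_gap_mm >= 0)
  keys <- vapply(contours, function(ct)
    paste(ct$phase, ct$slice, ct$structure, sep = "/"), character(1))
  if (anyDuplicated(keys))
    stop("duplicate contour key: ", keys[duplicated(keys)][1L], call. = FALSE)
  base::structure(
    list(pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         slice_thickness_mm = as.numeric(slice_thickness_mm),
         interslice_gap_mm = as.numeric(interslice_gap_mm),
         contours = contours),
    class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> %d contours, spacing (%.3g, %.3g) mm, thickness %g + gap %g mm\n",
              length(x$contours), x$pixel_spacing_mm[1L], x$pixel_spacing_mm[2L],
              x$slice_thickness_mm, x$interslice_gap_mm))
  invisible(x)
}

#' @export
length.contour_set <- function(x) length(x$contours)

#' Look up one contour by key
#'
#' @param set a [contour_set()].
#' @param phase,slice,structure key of the contour.
#' @return The matching [contour()], or `NULL` when absent.
#' @export
get_contour <- function(set, phase, slice, structure = "rv_endo") {
  for (ct in set$contours)
    if (ct$phase == phase && ct$slice == slice && ct$structure == structure)
      return(ct)
  NULL
}

#' @rdname get_contour
#' @param contour_obj contour to insert (replaces any existing contour with
#'   the same key).
#' @export
set_contour <- function(set, contour_obj) {
  keep <- vapply(set$contours, function(ct)
    !(ct$phase == contour_obj$phase && ct$slice == contour_obj$slice &&
        ct$structure == contour_obj$structure), logical(1))
  set$contours <- c(set$contours[keep], list(contour_obj))
  set
}

#' @export
as.data.frame.contour_set <- function(x, ...) {
  as.data.frame(tidy.contour_set(x))
}

#' Tidy a contour set into one tibble of vertices
#' @param x a [contour_set()].
#' @param ... unused.
#' @method tidy contour_set
#' @export
tidy.contour_set <- function(x, ...) {
  dplyr::bind_rows(lapply(x$contours, tidy.contour))
}

#' Write / read contour sets as versioned JSON
#'
#' The on-disk document is
#' `{"version":1, "pixel_spacing_mm":[r,c], "slice_thickness_mm":t,
#' "interslice_gap_mm":g, "contours":[{"phase":p,"slice":s,"structure":...,
#' "points":[[x,y],...]}, ...]}`. Contours are stored implicitly closed; a
#' repeated final point is dropped on read. `read_contours(write_contours(s))`
#' reproduces `s` to within floating-point round-trip.
#'
#' @param set a [contour_set()].
#' @param path file path of the JSON document.
#' @return `write_contours()` returns `path` invisibly; `read_contours()`
#'   returns a [contour_set()].
#' @export
write_contours <- function(set, path) {
  stopifnot(inherits(set, "contour_set"))
  doc <- list(
    version = 1L,
    pixel_spacing_mm = set$pixel_spacing_mm,
    slice_thickness_mm = set$slice_thickness_mm,
    interslice_gap_mm = set$interslice_gap_mm,
    contours = lapply(set$contours, function(ct)
      list(phase = ct$phase, slice = ct$slice, structure = ct$structure,
           points = unname(ct$points))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$version) || doc$version != 1L)
    stop("unsupported contour file version", call. = FALSE)
  cts <- doc$contours
  contours <- list()
  if (length(cts) && NROW(cts) > 0) {
    contours <- lapply(seq_len(nrow(cts)), function(i) {
      contour(cts$points[[i]], phase = cts$phase[i], slice = cts$slice[i],
              structure = cts$structure[i])
    })
  }
  contour_set(contours,
              pixel_spacing_mm = doc$pixel_spacing_mm,
              slice_thickness_mm = doc$slice_thickness_mm,
              interslice_gap_mm = doc$interslice_gap_mm)
}
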