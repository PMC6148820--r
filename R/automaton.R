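#' Configuration of the cellular-automaton label evolution
#'
#' The automaton follows the seeded-competition (GrowCut-family) rule: a
#' labelled pixel q attacks its neighbour p with strength
#' `lambda * g(|I_p - I_q|) * theta_q` where `g(d) = 1 - d` on intensities
#' min-max normalized per slice (so any neighbour difference is at most 1),
#' and p is conquered iff the attack exceeds its own strength `theta_p`.
#' `lambda` is a per-step attenuation encoding distance to the seeds: with
#' `lambda < 1` transmitted strength decays with every step even through
#' homogeneous tissue.
#'
#' @param neighborhood 4 or 8 (default 8).
#' @param lambda per-step attenuation in (0, 1], default 1.
#' @param max_iter iteration cap; default `rows * cols` of the slice.
#' @param seed_erosion_px erosion margin applied to the rasterized seed
#'   polygon before foreground seeding (default 2).
#' @param seed_dilation_px dilation margin outside which static pixels are
#'   background-seeded (default 10).
#' @param motion_quantile quantile of the temporal-SD motion map below which
#'   a pixel counts as static tissue (default 0.5).
#' @param contour_points number of points of extracted contours (default 120).
#' @return A list of class `automaton_config`.
#' @export
automaton_config <- function(neighborhood = 8L, lambda = 1.0, max_iter = NULL,
                             seed_erosion_px = 2L, seed_dilation_px = 10L,
                             motion_quantile = 0.5, contour_points = 120L) {
  stopifnot(neighborhood %in% c(4L, 8L), lambda > 0, lambda <= 1,
            seed_erosion_px >= 0, seed_dilation_px >= 0,
            motion_quantile >= 0, motion_quantile <= 1, contour_points >= 8)
  base::structure(
    list(neighborhood = as.integer(neighborhood), lambda = lambda,
         max_iter = max_iter, seed_erosion_px = as.integer(seed_erosion_px),
         seed_dilation_px = as.integer(seed_dilation_px),
         motion_quantile = motion_quantile,
         contour_points = as.integer(contour_points)),
    class = "automaton_config")
}

# fixed neighbour scan order: N, NE, E, SE, S, SW, W, NW as (drow, dcol);
# ties among equal attack strengths resolve to the earliest direction.
neighbor_offsets <- function(neighborhood) {
  all8 <- list(N = c(-1L, 0L), NE = c(-1L, 1L), E = c(0L, 1L), SE = c(1L, 1L),
               S = c(1L, 0L), SW = c(1L, -1L), W = c(0L, -1L), NW = c(-1L, -1L))
  if (neighborhood == 4L) all8[c("N", "E", "S", "W")] else all8
}

# value at p taken from its neighbour at (drow, dcol); outside filled
shift_mat <- function(m, drow, dcol, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L - drow):min(nr, nr - drow)
  cs <- max(1L, 1L - dcol):min(nc, nc - dcol)
  out[rs, cs] <- m[rs + drow, cs + dcol]
  out
}

label_field <- function(labels, theta, feature, phase, slice) {
  base::structure(list(labels = labels, theta = theta, feature = feature,
                       phase = as.integer(phase), slice = as.integer(slice),
                       converged = FALSE, iterations = 0L),
                  class = "label_field")
}

#' @export
print.label_field <- function(x, ...) {
  cat(sprintf("<label_field> %dx%d, fg %d, bg %d, unlabeled %d, %s after %d iterations\n",
              nrow(x$labels), ncol(x$labels), sum(x$labels == 1L),
              sum(x$labels == 2L), sum(x$labels == 0L),
              if (x$converged) "converged" else "not converged", x$iterations))
  invisible(x)
}

binary_morph <- function(mask, radius, op) {
  if (radius <= 0L) return(mask)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  out <- if (op == "erode") EBImage::erode(mask * 1, brush)
  else EBImage::dilate(mask * 1, brush)
  out > 0.5
}

# temporal standard deviation over phases for one slice: (rows x cols)
motion_map <- function(stack, slice) {
  arr <- stack$intensities[, slice + 1L, , , drop = FALSE]
  dim(arr) <- dim(arr)[-2L]                       # (phase, row, col)
  n <- dim(arr)[1L]
  if (n < 2L) return(matrix(0, dim(arr)[2L], dim(arr)[3L]))
  mu <- colMeans(arr)
  mu2 <- colMeans(arr^2)
  v <- (mu2 - mu^2) * n / (n - 1)
  sqrt(pmax(v, 0))
}

#' Seed a label field from a rough endocardial contour
#'
#' Foreground seeds are the pixels inside the seed polygon after erosion by
#' a safety margin. Background seeds combine (a) the one-pixel image border
#' and (b) pixels outside the dilated seed polygon whose temporal intensity
#' standard deviation across the cine phases falls at or below a quantile of
#' that motion map — static tissue away from the moving heart. Seeds get
#' strength 1; everything else starts unlabeled at strength 0. The slice
#' feature image is min-max normalized.
#'
#' @param slice_image 2D (row, col) intensity matrix.
#' @param seed_contour a [contour()] inside the image bounds.
#' @param stack the source [cine_stack()] (for the motion map).
#' @param phase 0-based phase index of `slice_image`.
#' @param config an [automaton_config()].
#' @return A `label_field` (labels: 0 unlabeled, 1 foreground, 2 background).
#' @export
init_labels <- function(slice_image, seed_contour, stack, phase,
                        config = automaton_config()) {
  shape <- dim(slice_image)
  seed_mask <- rasterize_contour(seed_contour, shape)
  fg <- binary_morph(seed_mask, config$seed_erosion_px, "erode")
  if (!any(fg))
    stop("eroded seed region is empty; draw a larger seed contour",
         call. = FALSE)
  mm <- motion_map(stack, seed_contour$slice)
  thr <- stats::quantile(mm, config$motion_quantile, names = FALSE, type = 7)
  static_far <- !binary_morph(seed_mask, config$seed_dilation_px, "dilate") &
    (mm <= thr)
  frame <- matrix(FALSE, shape[1L], shape[2L])
  frame[c(1L, shape[1L]), ] <- TRUE
  frame[, c(1L, shape[2L])] <- TRUE
  bg <- (frame | static_far) & !fg
  labels <- matrix(0L, shape[1L], shape[2L])
  labels[bg] <- 2L
  labels[fg] <- 1L
  theta <- matrix(0, shape[1L], shape[2L])
  theta[labels > 0L] <- 1
  rng <- range(slice_image)
  feat <- if (diff(rng) > 0) (slice_image - rng[1L]) / diff(rng)
  else matrix(0, shape[1L], shape[2L])
  label_field(labels, theta, feat, phase, seed_contour$slice)
}

#' Evolve a label field to its fixpoint
#'
#' Synchronous (Jacobi-style) updates: every attack in one iteration is
#' computed against the previous iteration's labels and strengths, so the
#' result is independent of memory layout. Among simultaneous attackers the
#' maximum attack strength wins, with ties broken by the fixed neighbour
#' scan order N, NE, E, SE, S, SW, W, NW. Iteration stops when a full pass
#' changes nothing (labels and strengths), so a converged field is a true
#' fixpoint: re-running `evolve()` returns it unchanged. Per-pixel strength
#' never decreases.
#'
#' @param field a `label_field` from [init_labels()].
#' @param config an [automaton_config()].
#' @return The evolved `label_field` with `converged` and `iterations` set.
#' @export
evolve <- function(field, config = automaton_config()) {
  labels <- field$labels
  theta <- field$theta
  feat <- field$feature
  if (!any(labels == 1L)) stop("no foreground seeds", call. = FALSE)
  if (!any(labels == 2L)) stop("no background seeds", call. = FALSE)
  offsets <- neighbor_offsets(config$neighborhood)
  lambda <- config$lambda
  max_iter <- if (is.null(config$max_iter)) nrow(labels) * ncol(labels)
  else config$max_iter
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    best_att <- matrix(0, nrow(labels), ncol(labels))
    best_lab <- matrix(0L, nrow(labels), ncol(labels))
    for (off in offsets) {
      thq <- shift_mat(theta, off[1L], off[2L], 0)
      labq <- shift_mat(labels, off[1L], off[2L], 0L)
      fq <- shift_mat(feat, off[1L], off[2L], Inf)
      att <- lambda * pmax(1 - abs(feat - fq), 0) * thq
      att[labq == 0L] <- 0
      upd <- att > best_att
      if (any(upd)) {
        best_att[upd] <- att[upd]
        best_lab[upd] <- labq[upd]
      }
    }
    conquered <- best_att > theta
    if (!any(conquered)) { converged <- TRUE; break }
    labels[conquered] <- best_lab[conquered]
    theta[conquered] <- best_att[conquered]
  }
  field$labels <- labels
  field$theta <- theta
  field$converged <- converged
  field$iterations <- field$iterations + iter
  field
}

# Largest 8-connected component of a logical mask. EBImage::bwlabel is
# 4-connected, so labels touching diagonally are merged with a union-find.
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  nlab <- max(lab)
  if (nlab == 0) return(mask & FALSE)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab
    b <- shift_mat(lab, off[1L], off[2L], 0L)
    touch <- a > 0L & b > 0L & a != b
    if (any(touch)) {
      prs <- unique(cbind(a[touch], b[touch]))
      for (k in seq_len(nrow(prs))) {
        ra <- find(prs[k, 1L]); rb <- find(prs[k, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  lab[lab > 0L] <- root[lab[lab > 0L]]
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

#' Extract the foreground boundary as a closed contour
#'
#' Keeps the largest connected foreground component, fills interior holes,
#' traces the sub-pixel boundary at the 0.5 level of the component's
#' indicator (marching squares), resamples to a fixed number of points and
#' applies one pass of a 3-point moving average.
#'
#' @param field an evolved `label_field`.
#' @param phase,slice indices stamped onto the returned contour; default to
#'   the field's own.
#' @param config an [automaton_config()] (`contour_points` is used).
#' @return A simple closed [contour()] with structure `"rv_endo"`.
#' @export
extract_contour <- function(field, phase = field$phase, slice = field$slice,
                            config = automaton_config()) {
  fg <- field$labels == 1L
  if (!any(fg)) stop("no foreground pixels to contour", call. = FALSE)
  comp <- largest_component(fg)
  comp <- EBImage::fillHull(comp * 1) > 0.5
  nr <- nrow(comp); nc <- ncol(comp)
  cl <- grDevices::contourLines(x = 0:(nr - 1L), y = 0:(nc - 1L),
                                z = comp * 1, levels = 0.5)
  if (!length(cl)) stop("degenerate foreground component", call. = FALSE)
  areas <- vapply(cl, function(l) abs(poly_signed_area(cbind(l$y, l$x))),
                  numeric(1))
  l <- cl[[which.max(areas)]]
  pts <- cbind(x = l$y, y = l$x)           # (col, row) convention
  if (nrow(pts) > 1L && all(abs(pts[nrow(pts), ] - pts[1L, ]) < 1e-12))
    pts <- pts[-nrow(pts), , drop = FALSE]
  pts <- smooth_closed(resample_closed(pts, config$contour_points))
  contour(pts, phase = phase, slice = slice, structure = "rv_endo",
          check = FALSE)
}

#' Refine a rough seed contour on one slice
#'
#' Runs the full single-slice chain — seeding, label evolution, contour
#' extraction — and returns the refined endocardial contour that replaces
#' the rough seed for inter-slice propagation. When the refined area grows
#' beyond 300% of the seed area (or shrinks below a third of it) the contour
#' carries a quality warning in `attr(, "flags")` (a seed dropped into
#' homogeneous tissue far from the ventricle typically triggers it).
#'
#' @param slice_image 2D (row, col) intensity matrix.
#' @param rough_seed rough seed [contour()].
#' @param stack the source [cine_stack()].
#' @param phase 0-based phase index.
#' @param config an [automaton_config()].
#' @return A refined [contour()]; `attr(, "flags")` is a character vector.
#' @export
optimize_seed <- function(slice_image, rough_seed, stack, phase,
                          config = automaton_config()) {
  field <- init_labels(slice_image, rough_seed, stack, phase, config)
  field <- evolve(field, config)
  refined <- extract_contour(field, phase, rough_seed$slice, config)
  flags <- character()
  a0 <- abs(poly_signed_area(rough_seed$points))
  a1 <- abs(poly_signed_area(refined$points))
  if (a0 > 0 && (a1 > 3 * a0 || a1 < a0 / 3))
    flags <- c(flags, "area_change_gt_300pct")
  attr(refined, "flags") <- flags
  refined
}
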