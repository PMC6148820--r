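#' Configuration of inter-slice contour propagation
#'
#' @param align_radius_mm search radius of the integer-pixel misalignment
#'   correction (default 10 mm).
#' @param window_margin_px margin added around the previous contour's
#'   bounding box to form the alignment window (default 10 px).
#' @param apical_decay area factor applied to the transferred seed for each
#'   step toward the apex (default 0.85); base-ward transfer is unscaled.
#'   This is the only geometry prior: the seed shrinks the way the ventricle
#'   does, the automaton then finds the actual border.
#' @param min_area_px results smaller than this area are omitted with a
#'   warning and propagation stops in that direction (default 10 px).
#' @param align enable misalignment correction (default `TRUE`).
#' @return A list of class `propagation_config`.
#' @export
propagation_config <- function(align_radius_mm = 10, window_margin_px = 10L,
                               apical_decay = 0.85, min_area_px = 10,
                               align = TRUE) {
  stopifnot(align_radius_mm >= 0, window_margin_px >= 0,
            apical_decay > 0, apical_decay <= 1, min_area_px >= 0)
  base::structure(
    list(align_radius_mm = align_radius_mm,
         window_margin_px = as.integer(window_margin_px),
         apical_decay = apical_decay, min_area_px = min_area_px,
         align = isTRUE(align)),
    class = "propagation_config")
}

#' Integer-pixel alignment of two adjacent slices
#'
#' Finds the integer translation `(dx, dy)` (columns, rows) maximizing the
#' normalized cross-correlation of a window between two slices: the window
#' content of `slice_a` best matches `slice_b` displaced by `(dx, dy)`.
#' Candidate shifts are visited in order of increasing magnitude (then scan
#' order), so ties resolve to the smallest shift. A constant (degenerate)
#' window yields `(0, 0)` with a `"degenerate_window"` flag.
#'
#' @param slice_a,slice_b 2D (row, col) intensity matrices of equal shape.
#' @param window integer vector `c(row0, row1, col0, col1)`, 0-based
#'   inclusive bounds of the correlation window in `slice_a`.
#' @param radius_px search radius in pixels.
#' @return Integer vector `c(dx, dy)`; `attr(, "flags")` lists warnings.
#' @export
align_adjacent <- function(slice_a, slice_b, window, radius_px = 8L) {
  stopifnot(identical(dim(slice_a), dim(slice_b)))
  r0 <- window[1L] + 1L; r1 <- window[2L] + 1L
  c0 <- window[3L] + 1L; c1 <- window[4L] + 1L
  stopifnot(r0 >= 1L, c0 >= 1L, r1 <= nrow(slice_a), c1 <= ncol(slice_a),
            r0 <= r1, c0 <= c1)
  template <- slice_a[r0:r1, c0:c1]
  flags <- character()
  if (stats::sd(template) == 0) {
    out <- c(dx = 0L, dy = 0L)
    attr(out, "flags") <- "degenerate_window"
    return(out)
  }
  cand <- expand.grid(dy = -radius_px:radius_px, dx = -radius_px:radius_px)
  cand <- cand[order(cand$dx^2 + cand$dy^2, cand$dy, cand$dx), ]
  best <- -Inf; best_dx <- 0L; best_dy <- 0L
  any_valid <- FALSE
  for (i in seq_len(nrow(cand))) {
    dy <- cand$dy[i]; dx <- cand$dx[i]
    rr <- (r0:r1) + dy; cc <- (c0:c1) + dx
    if (rr[1L] < 1L || cc[1L] < 1L ||
        rr[length(rr)] > nrow(slice_b) || cc[length(cc)] > ncol(slice_b))
      next
    region <- slice_b[rr, cc]
    if (stats::sd(region) == 0) next
    ncc <- stats::cor(as.vector(template), as.vector(region))
    if (is.finite(ncc)) {
      any_valid <- TRUE
      if (ncc > best) { best <- ncc; best_dx <- dx; best_dy <- dy }
    }
  }
  if (!any_valid) flags <- c(flags, "degenerate_window")
  out <- c(dx = as.integer(best_dx), dy = as.integer(best_dy))
  attr(out, "flags") <- flags
  out
}

translate_contour <- function(ct, dx, dy) {
  ct$points[, 1L] <- ct$points[, 1L] + dx
  ct$points[, 2L] <- ct$points[, 2L] + dy
  ct
}

scale_contour_area <- function(ct, area_factor) {
  cen <- poly_centroid(ct$points)
  s <- sqrt(area_factor)
  ct$points <- sweep(sweep(ct$points, 2L, cen), 2L, c(s, s), "*") |>
    sweep(2L, cen, "+")
  ct
}

contour_window <- function(ct, shape, margin) {
  r0 <- max(0L, floor(min(ct$points[, 2L])) - margin)
  r1 <- min(shape[1L] - 1L, ceiling(max(ct$points[, 2L])) + margin)
  c0 <- max(0L, floor(min(ct$points[, 1L])) - margin)
  c1 <- min(shape[2L] - 1L, ceiling(max(ct$points[, 1L])) + margin)
  c(r0, r1, c0, c1)
}

#' Attach an RV endocardial contour to the LV epicardium
#'
#' Where the RV contour overlaps the LV epicardial contour, the overlapping
#' region is removed and the freed stretch of boundary is replaced by the
#' epicardial arc between the two junction points, so the two contours share
#' the septum without gap or overlap. Disjoint contours are returned
#' unchanged with a `"no_attachment"` flag; an RV contour fully inside the
#' epicardium is returned unchanged with `"rv_inside_lv"`; more than one
#' overlap region yields the polygon difference with a `"multi_junction"`
#' flag.
#'
#' @param rv RV endocardial [contour()].
#' @param lv_epi LV epicardial [contour()] on the same (phase, slice).
#' @return The attached [contour()]; `attr(, "flags")` lists conditions.
#' @export
attach_to_lv <- function(rv, lv_epi) {
  stopifnot(inherits(rv, "contour"), inherits(lv_epi, "contour"))
  a <- list(list(x = rv$points[, 1L], y = rv$points[, 2L]))
  b <- list(list(x = lv_epi$points[, 1L], y = lv_epi$points[, 2L]))
  flags <- character()
  inter <- polyclip::polyclip(a, b, op = "intersection")
  if (!length(inter)) {
    attr(rv, "flags") <- "no_attachment"
    return(rv)
  }
  if (length(inter) > 1L) flags <- c(flags, "multi_junction")
  dif <- polyclip::polyclip(a, b, op = "minus")
  if (!length(dif)) {
    attr(rv, "flags") <- c(flags, "rv_inside_lv")
    return(rv)
  }
  areas <- vapply(dif, function(pc)
    abs(poly_signed_area(cbind(pc$x, pc$y))), numeric(1))
  pc <- dif[[which.max(areas)]]
  out <- contour(cbind(pc$x, pc$y), rv$phase, rv$slice, rv$structure,
                 check = FALSE)
  attr(out, "flags") <- flags
  out
}

#' Propagate an optimized contour across the annotated slice range
#'
#' Marches from the seeded slice toward the basal and the apical slices.
#' For each next slice the previous slice's contour is translated by the
#' inter-slice alignment (normalized cross-correlation in a window around
#' the contour), shrunk by the apical decay factor when moving apex-ward,
#' and used as the rough seed for [optimize_seed()] on that slice. When LV
#' epicardial contours are supplied, each slice result is attached to the
#' epicardium ([attach_to_lv()]) before being transferred onward. Slices
#' whose refined contour falls below the minimum area are omitted with a
#' warning and stop the march in that direction.
#'
#' @param stack a [cine_stack()].
#' @param phase 0-based phase index (must be the annotated ED or ES phase).
#' @param annotations a [study_annotations()].
#' @param optimized_seed refined contour on the seeded slice, e.g. from
#'   [optimize_seed()].
#' @param seed_slice 0-based slice carrying the seed, within the annotated
#'   range.
#' @param auto_config an [automaton_config()].
#' @param prop_config a [propagation_config()].
#' @param lv_contours optional [contour_set()] with `lv_epi` contours.
#' @return A [contour_set()] with one `rv_endo` contour per segmented slice.
#' @export
propagate_phase <- function(stack, phase, annotations, optimized_seed,
                            seed_slice,
                            auto_config = automaton_config(),
                            prop_config = propagation_config(),
                            lv_contours = NULL) {
  stopifnot(inherits(stack, "cine_stack"),
            inherits(annotations, "study_annotations"))
  phase_tag <- if (phase == annotations$ed_phase) "ed"
  else if (phase == annotations$es_phase) "es"
  else stop("phase ", phase, " is not the annotated ED or ES phase",
            call. = FALSE)
  slices <- phase_slice_range(annotations, phase_tag)   # basal -> apical
  pos <- match(seed_slice, slices)
  if (is.na(pos))
    stop("seed_slice outside the annotated slice range", call. = FALSE)
  shape <- c(stack$n_rows, stack$n_cols)
  radius_px <- max(0L, round(prop_config$align_radius_mm /
                               mean(stack$pixel_spacing_mm)))

  maybe_attach <- function(ct) {
    if (is.null(lv_contours)) return(ct)
    epi <- get_contour(lv_contours, phase, ct$slice, "lv_epi")
    if (is.null(epi)) return(ct)
    attach_to_lv(ct, epi)
  }

  results <- list()
  seed_ct <- maybe_attach(optimized_seed)
  results[[as.character(seed_slice)]] <- seed_ct

  march <- function(index_seq, apexward) {
    prev <- seed_ct
    for (i in index_seq) {
      s <- slices[i]
      prev_img <- stack_slice(stack, phase, prev$slice)
      next_img <- stack_slice(stack, phase, s)
      rough <- prev
      if (prop_config$align && radius_px > 0L) {
        sh <- align_adjacent(prev_img, next_img,
                             contour_window(prev, shape,
                                            prop_config$window_margin_px),
                             radius_px)
        rough <- translate_contour(rough, sh[["dx"]], sh[["dy"]])
      }
      if (apexward) rough <- scale_contour_area(rough, prop_config$apical_decay)
      rough$slice <- as.integer(s)
      refined <- tryCatch(
        optimize_seed(next_img, rough, stack, phase, auto_config),
        error = function(e) NULL)
      if (is.null(refined) ||
          abs(poly_signed_area(refined$points)) < prop_config$min_area_px) {
        warning("slice ", s, " omitted: result below minimum area",
                call. = FALSE)
        break
      }
      refined <- maybe_attach(refined)
      results[[as.character(s)]] <<- refined
      prev <- refined
    }
  }

  if (pos < length(slices)) march((pos + 1L):length(slices), apexward = TRUE)
  if (pos > 1L) march((pos - 1L):1L, apexward = FALSE)

  contour_set(unname(results),
              pixel_spacing_mm = stack$pixel_spacing_mm,
              slice_thickness_mm = stack$slice_thickness_mm,
              interslice_gap_mm = stack$interslice_gap_mm)
}
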