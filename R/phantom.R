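#' Specification of the synthetic short-axis cine phantom
#'
#' The phantom emulates an SSFP-like short-axis acquisition: bright blood
#' pool, darker myocardium, dim background, 8 mm slices with a 2 mm gap,
#' 1.25 mm in-plane pixels and 24 reconstructed phases. The left ventricle
#' is a disc (endocardium) inside an annulus (epicardium); the right
#' ventricle is the crescent (lune) between the LV epicardial circle and a
#' larger off-centre circle, so the two structures share the septum exactly
#' as the segmentation's attachment step assumes. All cross-sections scale
#' per slice by a linear taper toward the apex, which keeps every area in
#' closed form: the analytic ground-truth volume is the lens-formula lune
#' area times the taper-squared sum times the effective slice thickness.
#'
#' The in-plane scale is solved so the analytic end-diastolic RV volume
#' equals `rv_edv_ml`, and the end-systolic in-plane contraction factor is
#' solved (uniroot) so the analytic ES volume equals
#' `(1 - rv_contraction) * rv_edv_ml`; phases in between follow a cosine
#' time course with ES at `es_phase`.
#'
#' @param n_phases,n_slices,n_rows,n_cols stack dimensions.
#' @param pixel_spacing_mm,slice_thickness_mm,interslice_gap_mm acquisition
#'   geometry in mm.
#' @param ed_phase,es_phase 0-based phase indices of ED and ES.
#' @param basal_slice,apical_slice 0-based slice indices bounding the
#'   ventricle (annotations).
#' @param lv_endo_radius_mm,lv_wall_mm LV endocardial radius and wall
#'   thickness at ED, mid-cavity, before EDV scaling.
#' @param rv_outer_radius_mm,rv_center_offset_mm,rv_wall_mm RV outer-circle
#'   radius, distance of its centre from the LV centre, and free-wall
#'   thickness (same units and scaling).
#' @param lv_offset_mm LV centre offset from the image centre along +x.
#' @param rv_edv_ml target analytic end-diastolic RV volume.
#' @param rv_contraction,lv_contraction volumetric ejection fractions (0-1)
#'   of the two ventricles between ED and ES.
#' @param apical_taper in-plane scale factor at the apical slice (basal = 1).
#' @param shift_mm per-slice breath-hold misalignment magnitude; integer
#'   pixel shifts are drawn uniformly within this radius per slice.
#' @param noise_sd SD of i.i.d. Gaussian intensity noise (blood level = 1).
#' @param intensity_blood,intensity_myocardium,intensity_background tissue
#'   intensity levels.
#' @param rng_seed integer seed; the same spec and seed give bit-identical
#'   output.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_phases = 24L, n_slices = 10L,
                         n_rows = 160L, n_cols = 160L,
                         pixel_spacing_mm = c(1.25, 1.25),
                         slice_thickness_mm = 8, interslice_gap_mm = 2,
                         ed_phase = 0L, es_phase = 9L,
                         basal_slice = 1L, apical_slice = 8L,
                         lv_endo_radius_mm = 22, lv_wall_mm = 8,
                         rv_outer_radius_mm = 36, rv_center_offset_mm = 24,
                         rv_wall_mm = 4, lv_offset_mm = 18,
                         rv_edv_ml = 166.2,
                         rv_contraction = 1 - 74.5 / 166.2,
                         lv_contraction = 0.60,
                         apical_taper = 0.45,
                         shift_mm = 2, noise_sd = 0.05,
                         intensity_blood = 1.0, intensity_myocardium = 0.35,
                         intensity_background = 0.1,
                         rng_seed = 1L) {
  spec <- as.list(environment())
  stopifnot(spec$n_phases >= 1, spec$n_slices >= 1,
            all(spec$pixel_spacing_mm > 0), spec$slice_thickness_mm > 0,
            spec$interslice_gap_mm >= 0,
            spec$lv_endo_radius_mm > 0, spec$lv_wall_mm > 0,
            spec$rv_outer_radius_mm > 0, spec$rv_center_offset_mm > 0,
            spec$rv_wall_mm > 0, spec$rv_edv_ml > 0,
            spec$rv_contraction > 0, spec$rv_contraction < 1,
            spec$lv_contraction > 0, spec$lv_contraction < 1,
            spec$apical_taper > 0, spec$apical_taper <= 1,
            spec$shift_mm >= 0, spec$noise_sd >= 0,
            spec$ed_phase >= 0, spec$ed_phase < spec$n_phases,
            spec$es_phase >= 0, spec$es_phase < spec$n_phases,
            spec$ed_phase != spec$es_phase,
            spec$basal_slice >= 0, spec$basal_slice < spec$n_slices,
            spec$apical_slice >= 0, spec$apical_slice < spec$n_slices)
  class(spec) <- "phantom_spec"
  spec
}

# ---- closed-form circle geometry -------------------------------------------

# area of the intersection (lens) of two discs with centre distance d
circle_lens_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  k <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - k
}

# area of disc2 outside disc1 (the RV crescent), centre distance d
lune_area <- function(r1, r2, d) pi * r2^2 - circle_lens_area(r1, r2, d)

# sample an arc of the circle (center, R) from angle a1 to a2 choosing the
# sweep that passes through angle `through`; n points, endpoint excluded
arc_points <- function(center, R, a1, a2, through, n) {
  wrap <- function(a) (a + 2 * pi) %% (2 * pi)
  ccw_dist <- function(from, to) wrap(to - from)
  if (ccw_dist(a1, through) <= ccw_dist(a1, a2)) {
    ang <- a1 + seq(0, ccw_dist(a1, a2), length.out = n + 1L)[-(n + 1L)]
  } else {
    ang <- a1 - seq(0, wrap(a1 - a2), length.out = n + 1L)[-(n + 1L)]
  }
  cbind(center[1L] + R * cos(ang), center[2L] + R * sin(ang))
}

# polygon tracing the lune: outer arc on (c2, r2) outside (o, r1), then the
# arc of (o, r1) inside (c2, r2); coordinates in whatever units o/c2 use
lune_polygon <- function(o, r1, c2, r2, n = 160L) {
  dvec <- c2 - o
  d <- sqrt(sum(dvec^2))
  if (!(d > abs(r1 - r2) && d < r1 + r2))
    stop("circles do not properly intersect", call. = FALSE)
  u <- dvec / d
  a <- (d^2 + r1^2 - r2^2) / (2 * d)
  h <- sqrt(max(r1^2 - a^2, 0))
  pbase <- o + a * u
  nvec <- c(-u[2L], u[1L])
  i1 <- pbase + h * nvec
  i2 <- pbase - h * nvec
  ang <- function(p, c) atan2(p[2L] - c[2L], p[1L] - c[1L])
  far2 <- c2 + r2 * u               # point of circle2 farthest from o
  near1 <- o + r1 * u               # point of circle1 closest to c2
  n_out <- max(24L, round(n * 2 / 3))
  n_in <- max(16L, n - n_out)
  outer_arc <- arc_points(c2, r2, ang(i1, c2), ang(i2, c2), ang(far2, c2), n_out)
  inner_arc <- arc_points(o, r1, ang(i2, o), ang(i1, o), ang(near1, o), n_in)
  rbind(outer_arc, inner_arc)
}

circle_polygon <- function(center, R, n = 96L) {
  ang <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1L] + R * cos(ang), center[2L] + R * sin(ang))
}

# cosine systolic weight: 0 at ED, 1 at ES, periodic, zero slope at both
systole_weight <- function(phase, ed_phase, es_phase, n_phases) {
  tau <- ((phase - ed_phase) %% n_phases) / n_phases
  tau_es <- ((es_phase - ed_phase) %% n_phases) / n_phases
  ifelse(tau <= tau_es,
         (1 - cos(pi * tau / tau_es)) / 2,
         (1 - cos(pi * (1 - tau) / (1 - tau_es))) / 2)
}

# per-slice in-plane taper: 1 at the basal slice, apical_taper at the apical
# slice, linearly extended (and clamped) beyond the annotated range
slice_taper <- function(spec, slice) {
  span <- spec$apical_slice - spec$basal_slice
  u <- if (span == 0) as.numeric(slice == spec$apical_slice)
  else (slice - spec$basal_slice) / span
  pmin(pmax(1 + (spec$apical_taper - 1) * u, 0.1), 1.2)
}

# Phase-resolved mid-cavity geometry in mm, in the LV-centred frame
# (+x toward the LV free wall, RV centre at -x). All lengths already carry
# the global EDV scale `s`.
phantom_geometry <- function(spec, s, beta_es) {
  lv_endo_ed <- spec$lv_endo_radius_mm * s
  lv_epi_ed <- (spec$lv_endo_radius_mm + spec$lv_wall_mm) * s
  wall_area <- pi * (lv_epi_ed^2 - lv_endo_ed^2)
  lv_endo_es <- lv_endo_ed * sqrt(1 - spec$lv_contraction)
  function(phase) {
    w <- systole_weight(phase, spec$ed_phase, spec$es_phase, spec$n_phases)
    lv_endo <- lv_endo_ed + (lv_endo_es - lv_endo_ed) * w
    lv_epi <- sqrt(lv_endo^2 + wall_area / pi)   # incompressible wall
    beta <- 1 + (beta_es - 1) * w
    list(lv_endo = lv_endo, lv_epi = lv_epi,
         rv_r2 = spec$rv_outer_radius_mm * s * beta,
         rv_d = spec$rv_center_offset_mm * s * beta,
         rv_wall = spec$rv_wall_mm * s)
  }
}

phantom_taper_sq_sum <- function(spec) {
  slices <- seq(min(spec$basal_slice, spec$apical_slice),
                max(spec$basal_slice, spec$apical_slice))
  sum(slice_taper(spec, slices)^2)
}

# analytic RV volume (mL) at one phase given geometry closure
phantom_rv_volume <- function(spec, geom, phase) {
  g <- geom(phase)
  a <- lune_area(g$lv_epi, g$rv_r2, g$rv_d)
  a * phantom_taper_sq_sum(spec) *
    (spec$slice_thickness_mm + spec$interslice_gap_mm) / 1000
}

# solve the global in-plane scale and the ES contraction factor so the
# analytic EDV and ESV hit their targets exactly
phantom_calibrate <- function(spec) {
  edv_at <- function(s) {
    geom <- phantom_geometry(spec, s, beta_es = 1)
    phantom_rv_volume(spec, geom, spec$ed_phase)
  }
  s <- sqrt(spec$rv_edv_ml / edv_at(1))
  target_esv <- (1 - spec$rv_contraction) * spec$rv_edv_ml
  esv_at <- function(beta) {
    geom <- phantom_geometry(spec, s, beta_es = beta)
    phantom_rv_volume(spec, geom, spec$es_phase)
  }
  beta_es <- stats::uniroot(function(b) esv_at(b) - target_esv,
                            lower = 0.2, upper = 1, tol = 1e-10)$root
  list(scale = s, beta_es = beta_es)
}

#' Generate a synthetic cine dataset with analytic ground truth
#'
#' Builds the full 4D stack described by the spec, the ground-truth
#' `rv_endo` / `lv_endo` / `lv_epi` contours for every phase and every
#' annotated slice, the study annotations, and the analytic truth volumes.
#' Per-slice integer-pixel in-plane shifts (breath-hold misalignment) are
#' applied to both the image and the truth contours; i.i.d. Gaussian noise
#' is added to the image only. All randomness derives from `spec$rng_seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_dataset` with fields `stack`
#'   ([cine_stack()]), `truth` ([contour_set()]), `annotations`
#'   ([study_annotations()]), `truth_volumes` (analytic `volume_set`),
#'   `shifts` (tibble: slice, dx_px, dy_px) and `calibration`.
#' @examples
#' ds <- generate_phantom(phantom_spec(noise_sd = 0, shift_mm = 0))
#' ds$truth_volumes
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  cal <- phantom_calibrate(spec)
  geom <- phantom_geometry(spec, cal$scale, cal$beta_es)
  sp <- spec$pixel_spacing_mm
  # LV centre in mm image coordinates (x = col * col_mm, y = row * row_mm)
  cx <- (spec$n_cols - 1) / 2 * sp[2L] + spec$lv_offset_mm
  cy <- (spec$n_rows - 1) / 2 * sp[1L]

  # The apical taper scales each slice about the RV long axis (the ED
  # crescent centroid), so narrowing toward the apex does not translate the
  # ventricle across slices the way scaling about the LV centre would.
  g_ed <- geom(spec$ed_phase)
  axis_rel <- poly_centroid(
    lune_polygon(c(0, 0), g_ed$lv_epi, c(-g_ed$rv_d, 0), g_ed$rv_r2))

  withr::with_seed(spec$rng_seed, {
    max_shift <- round(spec$shift_mm / mean(sp))
    shifts <- tibble::tibble(
      slice = 0:(spec$n_slices - 1L),
      dx_px = if (max_shift > 0)
        sample(seq(-max_shift, max_shift), spec$n_slices, replace = TRUE)
      else integer(spec$n_slices),
      dy_px = if (max_shift > 0)
        sample(seq(-max_shift, max_shift), spec$n_slices, replace = TRUE)
      else integer(spec$n_slices))

    xs <- (0:(spec$n_cols - 1L)) * sp[2L]
    ys <- (0:(spec$n_rows - 1L)) * sp[1L]
    gx <- matrix(xs, spec$n_rows, spec$n_cols, byrow = TRUE)
    gy <- matrix(ys, spec$n_rows, spec$n_cols)

    intens <- array(spec$intensity_background,
                    dim = c(spec$n_phases, spec$n_slices,
                            spec$n_rows, spec$n_cols))
    contours <- list()
    ann_slices <- seq(min(spec$basal_slice, spec$apical_slice),
                      max(spec$basal_slice, spec$apical_slice))

    for (p in 0:(spec$n_phases - 1L)) {
      g <- geom(p)
      for (k in 0:(spec$n_slices - 1L)) {
        t <- slice_taper(spec, k)
        dx <- shifts$dx_px[k + 1L] * sp[2L]
        dy <- shifts$dy_px[k + 1L] * sp[1L]
        o <- c(cx + dx, cy + dy) + (1 - t) * axis_rel
        c2 <- o - c(g$rv_d * t, 0)
        in_disc <- function(cen, R)
          (gx - cen[1L])^2 + (gy - cen[2L])^2 <= R^2
        img <- matrix(spec$intensity_background, spec$n_rows, spec$n_cols)
        lv_epi_R <- g$lv_epi * t
        rv_r2 <- g$rv_r2 * t
        outside_lv <- !in_disc(o, lv_epi_R)
        img[in_disc(c2, rv_r2 + g$rv_wall * t) & outside_lv] <-
          spec$intensity_myocardium
        img[in_disc(c2, rv_r2) & outside_lv] <- spec$intensity_blood
        img[!outside_lv] <- spec$intensity_myocardium
        img[in_disc(o, g$lv_endo * t)] <- spec$intensity_blood
        intens[p + 1L, k + 1L, , ] <- img

        if (k %in% ann_slices) {
          to_px <- function(mm) cbind(mm[, 1L] / sp[2L], mm[, 2L] / sp[1L])
          rv_pts <- to_px(lune_polygon(o, lv_epi_R, c2, rv_r2))
          epi_pts <- to_px(circle_polygon(o, lv_epi_R))
          endo_pts <- to_px(circle_polygon(o, g$lv_endo * t))
          bound_ok <- function(pts)
            all(pts[, 1L] > 0.5 & pts[, 1L] < spec$n_cols - 1.5 &
                  pts[, 2L] > 0.5 & pts[, 2L] < spec$n_rows - 1.5)
          if (!bound_ok(rv_pts) || !bound_ok(epi_pts))
            stop("phantom geometry exceeds the field of view", call. = FALSE)
          contours <- c(contours, list(
            contour(rv_pts, p, k, "rv_endo", check = FALSE),
            contour(epi_pts, p, k, "lv_epi", check = FALSE),
            contour(endo_pts, p, k, "lv_endo", check = FALSE)))
        }
      }
    }
    if (spec$noise_sd > 0)
      intens <- pmax(intens + stats::rnorm(length(intens),
                                           sd = spec$noise_sd), 0)
  })

  stack <- cine_stack(intens, pixel_spacing_mm = sp,
                      slice_thickness_mm = spec$slice_thickness_mm,
                      interslice_gap_mm = spec$interslice_gap_mm)
  truth <- contour_set(contours, pixel_spacing_mm = sp,
                       slice_thickness_mm = spec$slice_thickness_mm,
                       interslice_gap_mm = spec$interslice_gap_mm)
  ann <- study_annotations(spec$ed_phase, spec$es_phase,
                           spec$apical_slice, spec$basal_slice,
                           spec$apical_slice, spec$basal_slice,
                           n_phases = spec$n_phases, n_slices = spec$n_slices)
  edv <- spec$rv_edv_ml
  esv <- (1 - spec$rv_contraction) * spec$rv_edv_ml
  base::structure(
    list(stack = stack, truth = truth, annotations = ann,
         truth_volumes = volume_set(edv, esv),
         shifts = shifts, calibration = cal, spec = spec),
    class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat("<phantom_dataset>\n  ")
  print(x$stack)
  cat("  ")
  print(x$truth_volumes)
  invisible(x)
}

#' Analytic RV volume of a phantom at an arbitrary phase
#'
#' @param dataset a `phantom_dataset`.
#' @param phase 0-based phase index.
#' @return Volume in mL, from the closed-form lune area.
#' @export
phantom_analytic_volume <- function(dataset, phase) {
  geom <- phantom_geometry(dataset$spec, dataset$calibration$scale,
                           dataset$calibration$beta_es)
  phantom_rv_volume(dataset$spec, geom, phase)
}

#' Perturb a contour into a reproducible rough seed
#'
#' Emulates a careless human seed: the radius about the centroid is
#' modulated by a low-order random Fourier series (orders 1-4) whose peak
#' amplitude equals `magnitude_mm`, and the polygon is re-checked for
#' simplicity (re-drawn up to 25 times if a draw self-intersects).
#' `magnitude_mm = 0` returns the input unchanged; the same `rng_seed`
#' always gives the same perturbation.
#'
#' @param ct a [contour()] in pixel coordinates.
#' @param magnitude_mm peak radial perturbation in mm.
#' @param rng_seed integer seed.
#' @param pixel_spacing_mm (row, col) spacing used to convert the magnitude
#'   to pixels (default 1 mm pixels).
#' @return A perturbed [contour()] with the same key.
#' @export
perturb_seed <- function(ct, magnitude_mm, rng_seed,
                         pixel_spacing_mm = c(1, 1)) {
  stopifnot(inherits(ct, "contour"), magnitude_mm >= 0)
  if (magnitude_mm == 0) return(ct)
  mag_px <- magnitude_mm / mean(pixel_spacing_mm)
  cen <- poly_centroid(ct$points)
  rel <- sweep(ct$points, 2L, cen)
  phi <- atan2(rel[, 2L], rel[, 1L])
  r <- sqrt(rowSums(rel^2))
  withr::with_seed(rng_seed, {
    for (attempt in 1:25) {
      amp <- stats::runif(4L, 0.2, 1)
      ph <- stats::runif(4L, 0, 2 * pi)
      dr <- rowSums(vapply(1:4, function(k) amp[k] * cos(k * phi + ph[k]),
                           numeric(length(phi))))
      dr <- dr / max(abs(dr)) * mag_px
      rnew <- pmax(r + dr, 0.2 * r)
      pts <- cbind(cen[1L] + rnew * cos(phi), cen[2L] + rnew * sin(phi))
      if (poly_is_simple(pts) && abs(poly_signed_area(pts)) > 0)
        return(contour(pts, ct$phase, ct$slice, ct$structure, check = FALSE))
    }
  })
  stop("could not produce a simple perturbed contour", call. = FALSE)
}
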