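#' Planimetric area of a contour in mm^2
#'
#' Shoelace area of the polygon in pixel^2 scaled by the product of the row
#' and column pixel spacings; orientation-independent.
#'
#' @param ct a [contour()].
#' @param pixel_spacing_mm length-2 numeric, (row, col) spacing in mm, or a
#'   single value used for both.
#' @return Area in mm^2.
#' @examples
#' sq <- contour(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), 0, 0)
#' contour_area(sq, c(1.25, 1.25))  # 156.25
#' @export
contour_area <- function(ct, pixel_spacing_mm) {
  stopifnot(inherits(ct, "contour"))
  if (length(pixel_spacing_mm) == 1L)
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  abs(poly_signed_area(ct$points)) * pixel_spacing_mm[1L] * pixel_spacing_mm[2L]
}

#' Simpson's-rule ventricular volume
#'
#' Clinical Simpson volumetry: the sum over slices of contour area times the
#' effective slice thickness (slice thickness plus interslice gap),
#' converted from mm^3 to mL. Slices without a segmented contour simply do
#' not contribute.
#'
#' @param planimetry data frame with columns `area_mm2` and `thickness_mm`
#'   (one row per segmented slice); may have zero rows.
#' @return Volume in mL.
#' @examples
#' simpson_volume(data.frame(area_mm2 = 100, thickness_mm = 10))  # 1 mL
#' @export
simpson_volume <- function(planimetry) {
  if (NROW(planimetry) == 0L) return(0)
  a <- planimetry$area_mm2
  t <- planimetry$thickness_mm
  if (any(a < 0)) stop("negative slice area", call. = FALSE)
  if (any(t <= 0)) stop("non-positive slice thickness", call. = FALSE)
  sum(a * t) / 1000
}

#' Ejection fraction in percent
#'
#' `EF = (EDV - ESV) / EDV * 100`.
#'
#' @param ed_volume_ml end-diastolic volume in mL (> 0).
#' @param es_volume_ml end-systolic volume in mL.
#' @return EF in percent.
#' @export
ejection_fraction <- function(ed_volume_ml, es_volume_ml) {
  if (any(ed_volume_ml <= 0))
    stop("ed_volume_ml must be > 0", call. = FALSE)
  (ed_volume_ml - es_volume_ml) / ed_volume_ml * 100
}

#' Per-phase Simpson volumes and EF from a contour set
#'
#' Sums `rv_endo` contour areas over the annotated basal-to-apical slice
#' range at the ED and ES phases, applies the effective slice thickness from
#' the set's metadata, and derives the ejection fraction. Annotated slices
#' with no contour contribute zero area and are counted as omitted.
#'
#' @param set a [contour_set()] holding `rv_endo` contours.
#' @param annotations a [study_annotations()].
#' @param structure contour structure to measure (default `"rv_endo"`).
#' @return An object of class `volume_set`: a list with `ed_volume_ml`,
#'   `es_volume_ml`, `ef_percent` and a tibble `per_phase` with columns
#'   `phase_tag`, `phase`, `volume_ml`, `n_slices`, `n_omitted`.
#' @export
measure_volumes <- function(set, annotations, structure = "rv_endo") {
  stopifnot(inherits(set, "contour_set"), inherits(annotations, "study_annotations"))
  thick <- effective_thickness(set)
  one_phase <- function(tag) {
    phase <- if (tag == "ed") annotations$ed_phase else annotations$es_phase
    slices <- phase_slice_range(annotations, tag)
    areas <- vapply(slices, function(s) {
      ct <- get_contour(set, phase, s, structure)
      if (is.null(ct)) NA_real_ else contour_area(ct, set$pixel_spacing_mm)
    }, numeric(1))
    vol <- simpson_volume(data.frame(area_mm2 = areas[!is.na(areas)],
                                     thickness_mm = thick))
    tibble::tibble(phase_tag = tag, phase = phase, volume_ml = vol,
                   n_slices = length(slices), n_omitted = sum(is.na(areas)))
  }
  per_phase <- dplyr::bind_rows(one_phase("ed"), one_phase("es"))
  volume_set(per_phase$volume_ml[1L], per_phase$volume_ml[2L], per_phase)
}

volume_set <- function(ed_volume_ml, es_volume_ml, per_phase = NULL) {
  base::structure(
    list(ed_volume_ml = ed_volume_ml, es_volume_ml = es_volume_ml,
         ef_percent = if (ed_volume_ml > 0)
           ejection_fraction(ed_volume_ml, es_volume_ml) else NA_real_,
         per_phase = per_phase),
    class = "volume_set")
}

#' @export
print.volume_set <- function(x, ...) {
  cat(sprintf("<volume_set> EDV %.1f mL, ESV %.1f mL, EF %.1f%%\n",
              x$ed_volume_ml, x$es_volume_ml, x$ef_percent))
  invisible(x)
}

#' Tidy a volume set
#' @param x a `volume_set`.
#' @param ... unused.
#' @return Tibble with columns `parameter`, `value`, `unit`.
#' @method tidy volume_set
#' @export
tidy.volume_set <- function(x, ...) {
  tibble::tibble(parameter = c("ed_volume", "es_volume", "ef"),
                 value = c(x$ed_volume_ml, x$es_volume_ml, x$ef_percent),
                 unit = c("mL", "mL", "%"))
}
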