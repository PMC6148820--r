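#' 4D short-axis cine stack
#'
#' The image substrate: a 4D intensity array indexed `(phase, slice, row,
#' col)` plus the physical spacing needed for volumetry. Slice thickness and
#' interslice gap are kept separate; the effective per-slice thickness used
#' by Simpson volumetry is their sum.
#'
#' @param intensities 4D numeric array `(phase, slice, row, col)`, finite,
#'   non-negative.
#' @param pixel_spacing_mm length-2 numeric, in-plane (row, col) spacing, mm.
#' @param slice_thickness_mm slice thickness in mm (> 0).
#' @param interslice_gap_mm gap between slices in mm (>= 0).
#' @return An object of class `cine_stack` with fields `intensities`,
#'   `pixel_spacing_mm`, `slice_thickness_mm`, `interslice_gap_mm` and the
#'   dimensions `n_phases`, `n_slices`, `n_rows`, `n_cols`.
#' @export
cine_stack <- function(intensities, pixel_spacing_mm = c(1.25, 1.25),
                       slice_thickness_mm = 8, interslice_gap_mm = 2) {
  if (length(dim(intensities)) != 4L)
    stop("expected 4 dimensions (phase, slice, row, col), got ",
         length(dim(intensities)), call. = FALSE)
  if (!all(is.finite(intensities)))
    stop("intensities must be finite", call. = FALSE)
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0))
    stop("pixel_spacing_mm must be two positive values", call. = FALSE)
  if (slice_thickness_mm <= 0)
    stop("slice_thickness_mm must be > 0", call. = FALSE)
  if (interslice_gap_mm < 0)
    stop("interslice_gap_mm must be >= 0", call. = FALSE)
  d <- dim(intensities)
  base::structure(
    list(intensities = intensities,
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         slice_thickness_mm = as.numeric(slice_thickness_mm),
         interslice_gap_mm = as.numeric(interslice_gap_mm),
         n_phases = d[1L], n_slices = d[2L], n_rows = d[3L], n_cols = d[4L]),
    class = "cine_stack")
}

#' @export
print.cine_stack <- function(x, ...) {
  cat(sprintf(
    "<cine_stack> %d phases x %d slices x %d x %d, %.3g x %.3g mm/px, %g mm + %g mm gap\n",
    x$n_phases, x$n_slices, x$n_rows, x$n_cols,
    x$pixel_spacing_mm[1L], x$pixel_spacing_mm[2L],
    x$slice_thickness_mm, x$interslice_gap_mm))
  invisible(x)
}

# one 2D slice image as a (row, col) matrix
stack_slice <- function(stack, phase, slice) {
  stack$intensities[phase + 1L, slice + 1L, , ]
}

# effective thickness used by Simpson volumetry
effective_thickness <- function(stack_or_set) {
  stack_or_set$slice_thickness_mm + stack_or_set$interslice_gap_mm
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "", path) |> paste0(".json")
}

#' Write / read a cine stack as NIfTI
#'
#' The NIfTI voxel order is `(col, row, slice, phase)` with `pixdim`
#' carrying (col mm, row mm, slice thickness + gap). Because the NIfTI
#' header conflates slice thickness and interslice gap into one z-spacing, a
#' sidecar JSON (`<stem>.json`) stores them separately; `read_cine()` uses
#' the sidecar when present and otherwise interprets the header z-spacing as
#' thickness with zero gap.
#'
#' @param stack a [cine_stack()].
#' @param path a `.nii` or `.nii.gz` file. `read_cine()` also accepts a
#'   directory of per-phase 3D NIfTI files (lexicographic order = phase
#'   order).
#' @return `read_cine()` returns a [cine_stack()]; `write_cine()` returns
#'   `path` invisibly.
#' @export
write_cine <- function(stack, path) {
  stopifnot(inherits(stack, "cine_stack"))
  vol <- aperm(stack$intensities, c(4L, 3L, 2L, 1L))
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(stack$pixel_spacing_mm[2L],
                           stack$pixel_spacing_mm[1L],
                           effective_thickness(stack), 1)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(slice_thickness_mm = stack$slice_thickness_mm,
         interslice_gap_mm = stack$interslice_gap_mm),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cine
#' @export
read_cine <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.nii(\\.gz)?$",
                             full.names = TRUE))
    if (!length(files)) stop("no NIfTI files in directory ", path, call. = FALSE)
    vols <- lapply(files, RNifti::readNifti)
    for (v in vols) if (length(dim(v)) != 3L)
      stop("expected 3 dimensions per phase file, got ", length(dim(v)),
           call. = FALSE)
    pd <- RNifti::pixdim(vols[[1L]])
    arr4 <- simplify2array(lapply(vols, unclass))   # (col,row,slice,phase)
    return(finish_read_cine(arr4, pd, sidecar_path(files[[1L]])))
  }
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop("expected 4 dimensions, got ", length(dim(img)), call. = FALSE)
  finish_read_cine(unclass(img), RNifti::pixdim(img), sidecar_path(path))
}

finish_read_cine <- function(arr4, pd, sidecar) {
  if (any(pd[1:3] <= 0))
    stop("non-positive pixel spacing in NIfTI header (pixdim)", call. = FALSE)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    thickness <- meta$slice_thickness_mm
    gap <- meta$interslice_gap_mm
  } else {
    thickness <- pd[3L]
    gap <- 0
  }
  cine_stack(aperm(arr4, c(4L, 3L, 2L, 1L)),
             pixel_spacing_mm = c(pd[2L], pd[1L]),
             slice_thickness_mm = thickness,
             interslice_gap_mm = gap)
}

# ---- study annotations ------------------------------------------------------

#' Per-study phase and slice-coverage annotations
#'
#' ED/ES phase indices and, for each of the two phases, the apical and basal
#' slice indices bounding the ventricle. All indices 0-based. No ordering of
#' basal vs apical index is assumed; segmentation iterates from basal to
#' apical whatever their numeric order.
#'
#' @param ed_phase,es_phase 0-based cardiac phase indices.
#' @param ed_apical,ed_basal,es_apical,es_basal 0-based slice indices.
#' @param n_phases,n_slices optional stack dimensions for range validation.
#' @return An object of class `study_annotations`.
#' @export
study_annotations <- function(ed_phase, es_phase, ed_apical, ed_basal,
                              es_apical, es_basal,
                              n_phases = NULL, n_slices = NULL) {
  ann <- base::structure(
    list(ed_phase = as.integer(ed_phase), es_phase = as.integer(es_phase),
         ed = list(apical = as.integer(ed_apical), basal = as.integer(ed_basal)),
         es = list(apical = as.integer(es_apical), basal = as.integer(es_basal))),
    class = "study_annotations")
  validate_annotations(ann, n_phases, n_slices)
  ann
}

validate_annotations <- function(ann, n_phases = NULL, n_slices = NULL) {
  idx <- c(ann$ed_phase, ann$es_phase, ann$ed$apical, ann$ed$basal,
           ann$es$apical, ann$es$basal)
  if (anyNA(idx) || any(idx < 0))
    stop("annotation indices must be present and non-negative", call. = FALSE)
  if (!is.null(n_phases) && any(c(ann$ed_phase, ann$es_phase) >= n_phases))
    stop("phase index out of range (n_phases = ", n_phases, ")", call. = FALSE)
  if (!is.null(n_slices) &&
      any(c(ann$ed$apical, ann$ed$basal, ann$es$apical, ann$es$basal) >= n_slices))
    stop("slice index out of range (n_slices = ", n_slices, ")", call. = FALSE)
  invisible(ann)
}

#' @export
print.study_annotations <- function(x, ...) {
  cat(sprintf("<study_annotations> ED phase %d (slices %d..%d), ES phase %d (slices %d..%d)\n",
              x$ed_phase, x$ed$basal, x$ed$apical,
              x$es_phase, x$es$basal, x$es$apical))
  invisible(x)
}

# slice indices from basal to apical for one phase tag ("ed" or "es")
phase_slice_range <- function(ann, phase_tag) {
  ends <- ann[[phase_tag]]
  if (ends$basal <= ends$apical) seq(ends$basal, ends$apical)
  else seq(ends$basal, ends$apical, by = -1L)
}

#' Write / read study annotations as JSON
#'
#' @param ann a [study_annotations()].
#' @param path JSON file path.
#' @param n_phases,n_slices optional dimensions for range validation on read.
#' @return `read_annotations()` returns a [study_annotations()].
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "study_annotations"))
  jsonlite::write_json(unclass(ann), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path, n_phases = NULL, n_slices = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("ed_phase", "es_phase", "ed", "es")
  miss <- setdiff(need, names(doc))
  if (length(miss)) stop("missing annotation field: ", miss[1L], call. = FALSE)
  study_annotations(doc$ed_phase, doc$es_phase,
                    doc$ed$apical, doc$ed$basal,
                    doc$es$apical, doc$es$basal,
                    n_phases = n_phases, n_slices = n_slices)
}

#' Write / read long-format measurement tables
#'
#' Plain CSV with header `subject,parameter,value`, the exchange format for
#' per-subject volume and ejection-fraction measurements.
#'
#' @param df data frame with columns `subject`, `parameter`, `value`.
#' @param path CSV file path.
#' @return `read_measurements()` returns a tibble.
#' @export
write_measurements <- function(df, path) {
  stopifnot(all(c("subject", "parameter", "value") %in% names(df)))
  readr::write_csv(df[, c("subject", "parameter", "value")], path)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject = readr::col_character(),
    parameter = readr::col_character(),
    value = readr::col_double()))
}
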