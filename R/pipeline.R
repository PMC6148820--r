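#' Segment one cardiac phase from a rough seed contour
#'
#' The full semi-automatic chain for one phase: refine the rough seed on its
#' slice with the cellular automaton ([optimize_seed()]), then propagate the
#' refined contour toward the basal and apical slices
#' ([propagate_phase()]), attaching each slice result to the LV epicardium
#' when LV contours are supplied.
#'
#' @param stack a [cine_stack()].
#' @param annotations a [study_annotations()].
#' @param rough_seed rough RV endocardial seed [contour()]; its `phase` and
#'   `slice` fields locate it.
#' @param lv_contours optional [contour_set()] with `lv_epi` contours.
#' @param auto_config an [automaton_config()].
#' @param prop_config a [propagation_config()].
#' @return A [contour_set()] of per-slice `rv_endo` contours.
#' @export
segment_phase <- function(stack, annotations, rough_seed, lv_contours = NULL,
                          auto_config = automaton_config(),
                          prop_config = propagation_config()) {
  phase <- rough_seed$phase
  img <- stack_slice(stack, phase, rough_seed$slice)
  refined <- optimize_seed(img, rough_seed, stack, phase, auto_config)
  propagate_phase(stack, phase, annotations, refined, rough_seed$slice,
                  auto_config, prop_config, lv_contours)
}

#' Segment both annotated phases of a study
#'
#' @inheritParams segment_phase
#' @param ed_seed,es_seed rough seed contours at the ED and ES phases.
#' @return A [contour_set()] covering both phases.
#' @export
segment_study <- function(stack, annotations, ed_seed, es_seed,
                          lv_contours = NULL,
                          auto_config = automaton_config(),
                          prop_config = propagation_config()) {
  ed <- segment_phase(stack, annotations, ed_seed, lv_contours,
                      auto_config, prop_config)
  es <- segment_phase(stack, annotations, es_seed, lv_contours,
                      auto_config, prop_config)
  contour_set(c(ed$contours, es$contours),
              pixel_spacing_mm = stack$pixel_spacing_mm,
              slice_thickness_mm = stack$slice_thickness_mm,
              interslice_gap_mm = stack$interslice_gap_mm)
}

# Deterministic sub-seed derivation (splitmix-style integer mixing) so one
# global seed reproducibly fans out to per-subject / per-run streams.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in seq_along(idx)) {
    s <- (s * 48271 + (idx[k] + 1) * 1299721 + k * 95279) %% 2147483647
  }
  as.integer(s)
}

# rough mid-slice seed for one phantom phase: the truth contour at the
# middle annotated slice, perturbed to emulate a careless user
phantom_rough_seed <- function(dataset, phase_tag, magnitude_mm, rng_seed) {
  ann <- dataset$annotations
  phase <- if (phase_tag == "ed") ann$ed_phase else ann$es_phase
  slices <- phase_slice_range(ann, phase_tag)
  mid <- slices[ceiling(length(slices) / 2)]
  truth_ct <- get_contour(dataset$truth, phase, mid, "rv_endo")
  perturb_seed(truth_ct, magnitude_mm, rng_seed,
               dataset$stack$pixel_spacing_mm)
}

#' Segment a phantom dataset end-to-end with perturbed seeds
#'
#' Draws a rough seed for each annotated phase by perturbing the mid-slice
#' truth contour, then runs [segment_study()] with the phantom's own LV
#' epicardial contours for attachment.
#'
#' @param dataset a `phantom_dataset` from [generate_phantom()].
#' @param seed_magnitude_mm radial seed perturbation (default 2 mm).
#' @param rng_seed integer seed for the perturbation draws.
#' @param auto_config,prop_config stage configurations.
#' @return A [contour_set()] of segmented `rv_endo` contours at ED and ES.
#' @export
segment_phantom <- function(dataset, seed_magnitude_mm = 2, rng_seed = 1L,
                            auto_config = automaton_config(),
                            prop_config = propagation_config()) {
  ed_seed <- phantom_rough_seed(dataset, "ed", seed_magnitude_mm,
                                derive_seed(rng_seed, 101))
  es_seed <- phantom_rough_seed(dataset, "es", seed_magnitude_mm,
                                derive_seed(rng_seed, 202))
  segment_study(dataset$stack, dataset$annotations, ed_seed, es_seed,
                lv_contours = dataset$truth,
                auto_config = auto_config, prop_config = prop_config)
}

#' Run a synthetic validation cohort
#'
#' Generates `n_subjects` phantom datasets (each with its own derived seed),
#' segments the ED and ES phases `n_runs` times per subject with
#' independently perturbed rough seeds, and collects per-slice validity
#' metrics against ground truth plus per-run Simpson volumes and EF.
#'
#' @param n_subjects number of phantom subjects (default 10).
#' @param seed global integer seed; every random draw derives from it.
#' @param n_runs segmentations per subject (2 enables reproducibility
#'   analysis between independently seeded runs).
#' @param spec base [phantom_spec()]; each subject gets a derived
#'   `rng_seed`.
#' @param seed_magnitude_mm rough-seed perturbation magnitude (default 2 mm).
#' @param auto_config,prop_config stage configurations.
#' @return A list of class `cohort_result`: `metrics` (tibble: subject,
#'   run, phase_tag, phase, slice, dice, hausdorff_mm), `volumes` (tibble:
#'   subject, run, ed_volume_ml, es_volume_ml, ef_percent) and
#'   `truth_volumes` (tibble: subject, ed_volume_ml, es_volume_ml,
#'   ef_percent).
#' @export
run_cohort <- function(n_subjects = 10L, seed = 1L, n_runs = 1L,
                       spec = phantom_spec(), seed_magnitude_mm = 2,
                       auto_config = automaton_config(),
                       prop_config = propagation_config()) {
  metrics <- list(); volumes <- list(); truthv <- list()
  for (subj in seq_len(n_subjects)) {
    sp <- spec
    sp$rng_seed <- derive_seed(seed, subj)
    ds <- generate_phantom(sp)
    shape <- c(ds$stack$n_rows, ds$stack$n_cols)
    truthv[[subj]] <- tibble::tibble(
      subject = subj, ed_volume_ml = ds$truth_volumes$ed_volume_ml,
      es_volume_ml = ds$truth_volumes$es_volume_ml,
      ef_percent = ds$truth_volumes$ef_percent)
    for (run in seq_len(n_runs)) {
      segd <- segment_phantom(ds, seed_magnitude_mm,
                              rng_seed = derive_seed(seed, subj, run),
                              auto_config = auto_config,
                              prop_config = prop_config)
      met <- contour_metrics(segd, ds$truth, shape)
      met$phase_tag <- ifelse(met$phase == ds$annotations$ed_phase,
                              "ed", "es")
      met$subject <- subj
      met$run <- run
      metrics[[length(metrics) + 1L]] <- met
      vs <- measure_volumes(segd, ds$annotations)
      volumes[[length(volumes) + 1L]] <- tibble::tibble(
        subject = subj, run = run,
        ed_volume_ml = vs$ed_volume_ml, es_volume_ml = vs$es_volume_ml,
        ef_percent = vs$ef_percent)
    }
  }
  base::structure(
    list(metrics = dplyr::bind_rows(metrics),
         volumes = dplyr::bind_rows(volumes),
         truth_volumes = dplyr::bind_rows(truthv)),
    class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  med <- x$metrics |>
    dplyr::group_by(.data$phase_tag) |>
    dplyr::summarise(median_dice = stats::median(.data$dice),
                     median_hd_mm = stats::median(.data$hausdorff_mm))
  cat(sprintf("<cohort_result> %d subjects x %d runs\n",
              dplyr::n_distinct(x$volumes$subject),
              dplyr::n_distinct(x$volumes$run)))
  print(as.data.frame(med))
  invisible(x)
}

#' Summarise a cohort: pooled medians and run-to-run reproducibility
#'
#' @param object a `cohort_result`.
#' @param ... unused.
#' @return A list with `validity` (tibble of pooled median/IQR Dice and
#'   Hausdorff per phase) and, when the cohort has two or more runs,
#'   `reproducibility` (tibble of per-parameter median percentage
#'   differences between runs 1 and 2, pair-mean denominator).
#' @export
summary.cohort_result <- function(object, ...) {
  validity <- object$metrics |>
    dplyr::group_by(.data$phase_tag) |>
    dplyr::summarise(
      n_slices = dplyr::n(),
      median_dice = stats::median(.data$dice),
      q25_dice = stats::quantile(.data$dice, 0.25, names = FALSE),
      q75_dice = stats::quantile(.data$dice, 0.75, names = FALSE),
      median_hd_mm = stats::median(.data$hausdorff_mm),
      q25_hd_mm = stats::quantile(.data$hausdorff_mm, 0.25, names = FALSE),
      q75_hd_mm = stats::quantile(.data$hausdorff_mm, 0.75, names = FALSE))
  out <- list(validity = validity)
  if (dplyr::n_distinct(object$volumes$run) >= 2L) {
    v1 <- dplyr::filter(object$volumes, .data$run == 1L)
    v2 <- dplyr::filter(object$volumes, .data$run == 2L)
    v2 <- v2[match(v1$subject, v2$subject), ]
    reproducibility <- purrr::map_dfr(
      c("ed_volume_ml", "es_volume_ml", "ef_percent"),
      function(par) {
        pct <- 100 * (v1[[par]] - v2[[par]]) /
          ((v1[[par]] + v2[[par]]) / 2)
        tibble::tibble(parameter = par,
                       median_pct_diff = stats::median(pct),
                       median_abs_pct_diff = stats::median(abs(pct)))
      })
    out$reproducibility <- reproducibility
  }
  out
}
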