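test_that("alignment recovers a constructed integer shift", {
  ds <- tiny_phantom()
  a <- rvseg:::stack_slice(ds$stack, 0L, 2L)
  # displace content by (dx, dy) = (3, -2): b[r-2, c+3] = a[r, c]
  b <- matrix(0.1, nrow(a), ncol(a))
  b[1:(nrow(a) - 2), 4:ncol(a)] <- a[3:nrow(a), 1:(ncol(a) - 3)]
  truth <- get_contour(ds$truth, 0L, 2L, "rv_endo")
  win <- rvseg:::contour_window(truth, dim(a), 10L)
  sh <- align_adjacent(a, b, win, radius_px = 6L)
  expect_equal(as.vector(sh), c(3L, -2L))
  # identical slices prefer the zero shift
  expect_equal(as.vector(align_adjacent(a, a, win, 6L)), c(0L, 0L))
  # constant window is flagged
  flat <- matrix(1, 64, 64)
  sh0 <- align_adjacent(flat, flat, c(10L, 30L, 10L, 30L), 4L)
  expect_equal(as.vector(sh0), c(0L, 0L))
  expect_true("degenerate_window" %in% attr(sh0, "flags"))
})

test_that("attachment removes the epicardial overlap and keeps the area of the difference", {
  skip_if_not_installed("mgcv")
  ds <- tiny_phantom()
  rv <- get_contour(ds$truth, 0L, 2L, "rv_endo")
  epi <- get_contour(ds$truth, 0L, 2L, "lv_epi")
  # inflate the RV contour toward the LV so it overlaps the epicardium
  cen <- rvseg:::poly_centroid(epi$points)
  inflated <- rv
  inflated$points <- sweep(sweep(rv$points, 2, cen), 2, c(1.08, 1.08), "*") |>
    sweep(2, cen, "+")
  out <- attach_to_lv(inflated, epi)
  # fine-grid pixel-count oracle for area(rv \ epi)
  h <- 0.2
  xs <- seq(min(inflated$points[, 1]) - 1, max(inflated$points[, 1]) + 1, by = h)
  ys <- seq(min(inflated$points[, 2]) - 1, max(inflated$points[, 2]) + 1, by = h)
  grid <- cbind(rep(xs, each = length(ys)), rep(ys, times = length(xs)))
  in_rv <- mgcv::in.out(rbind(inflated$points, inflated$points[1, ]), grid)
  in_epi <- mgcv::in.out(rbind(epi$points, epi$points[1, ]), grid)
  oracle_area <- sum(in_rv & !in_epi) * h^2
  got_area <- abs(rvseg:::poly_signed_area(out$points))
  expect_equal(got_area, oracle_area, tolerance = 0.01)
  # the result must not enter the epicardial interior
  out_pts <- rvseg:::resample_closed(out$points, 400)
  inside_epi <- rvseg:::points_in_polygon(
    out_pts[, 1], out_pts[, 2],
    sweep(sweep(epi$points, 2, cen), 2, c(0.995, 0.995), "*") |>
      sweep(2, cen, "+"))
  expect_equal(sum(inside_epi), 0)
})

test_that("attachment is a no-op for disjoint or already-attached contours", {
  ds <- tiny_phantom()
  rv <- get_contour(ds$truth, 0L, 2L, "rv_endo")
  epi <- get_contour(ds$truth, 0L, 2L, "lv_epi")
  far <- rv
  far$points[, 2] <- far$points[, 2] + 60
  out <- attach_to_lv(far, epi)
  expect_identical(out$points, far$points)
  expect_true("no_attachment" %in% attr(out, "flags"))
  # truth RV already shares the septal arc: area change below 1%
  a0 <- abs(rvseg:::poly_signed_area(rv$points))
  at <- attach_to_lv(rv, epi)
  expect_equal(abs(rvseg:::poly_signed_area(at$points)), a0,
               tolerance = 0.01)
  # idempotence within 0.5% area
  twice <- attach_to_lv(at, epi)
  expect_equal(abs(rvseg:::poly_signed_area(twice$points)),
               abs(rvseg:::poly_signed_area(at$points)), tolerance = 0.005)
})

test_that("a degenerate slice range returns exactly the optimized seed", {
  ds <- tiny_phantom()
  ann <- study_annotations(ds$annotations$ed_phase, ds$annotations$es_phase,
                           2, 2, 2, 2)
  truth <- get_contour(ds$truth, ann$ed_phase, 2L, "rv_endo")
  img <- rvseg:::stack_slice(ds$stack, ann$ed_phase, 2L)
  refined <- optimize_seed(img, truth, ds$stack, ann$ed_phase)
  res <- propagate_phase(ds$stack, ann$ed_phase, ann, refined, 2L)
  expect_equal(length(res), 1L)
  expect_equal(get_contour(res, ann$ed_phase, 2L)$points, refined$points)
  expect_error(propagate_phase(ds$stack, ann$ed_phase, ann, refined, 4L),
               "outside the annotated")
  expect_error(propagate_phase(ds$stack, 5L, ann, refined, 2L),
               "not the annotated")
})

test_that("noise-free propagation recovers every slice at high Dice", {
  ds <- tiny_phantom()
  ann <- ds$annotations
  truth_mid <- get_contour(ds$truth, ann$ed_phase, 2L, "rv_endo")
  rough <- perturb_seed(truth_mid, 2, 3L, ds$stack$pixel_spacing_mm)
  segd <- segment_phase(ds$stack, ann, rough, lv_contours = ds$truth)
  met <- contour_metrics(segd, ds$truth, c(ds$stack$n_rows, ds$stack$n_cols))
  expect_equal(nrow(met), 4L)   # slices 1..4, none omitted
  expect_true(all(met$dice >= 0.95))
})

test_that("alignment has no effect when slices are not misaligned", {
  ds <- tiny_phantom()
  ann <- ds$annotations
  truth_mid <- get_contour(ds$truth, ann$ed_phase, 2L, "rv_endo")
  img <- rvseg:::stack_slice(ds$stack, ann$ed_phase, 2L)
  refined <- optimize_seed(img, truth_mid, ds$stack, ann$ed_phase)
  on <- propagate_phase(ds$stack, ann$ed_phase, ann, refined, 2L,
                        prop_config = propagation_config(align = TRUE))
  off <- propagate_phase(ds$stack, ann$ed_phase, ann, refined, 2L,
                         prop_config = propagation_config(align = FALSE))
  expect_equal(lapply(on$contours, `[[`, "points"),
               lapply(off$contours, `[[`, "points"))
})

test_that("alignment improves propagation across misaligned slices", {
  ds <- generate_phantom(tiny_spec(noise_sd = 0, shift_mm = 5,
                                   rng_seed = 4L))
  ann <- ds$annotations
  shape <- c(ds$stack$n_rows, ds$stack$n_cols)
  truth_mid <- get_contour(ds$truth, ann$ed_phase, 2L, "rv_endo")
  img <- rvseg:::stack_slice(ds$stack, ann$ed_phase, 2L)
  refined <- optimize_seed(img, truth_mid, ds$stack, ann$ed_phase)
  res_on <- propagate_phase(ds$stack, ann$ed_phase, ann, refined, 2L,
                            prop_config = propagation_config(align = TRUE),
                            lv_contours = ds$truth)
  res_off <- suppressWarnings(
    propagate_phase(ds$stack, ann$ed_phase, ann, refined, 2L,
                    prop_config = propagation_config(align = FALSE),
                    lv_contours = ds$truth))
  d_on <- mean(contour_metrics(res_on, ds$truth, shape)$dice)
  d_off <- mean(contour_metrics(res_off, ds$truth, shape)$dice)
  expect_gt(d_on, d_off)
})
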