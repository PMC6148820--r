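test_that("foreground seeding equals an independent erosion of the seed polygon", {
  ds <- tiny_phantom()
  ann <- ds$annotations
  truth <- get_contour(ds$truth, ann$ed_phase, 2L, "rv_endo")
  img <- rvseg:::stack_slice(ds$stack, ann$ed_phase, 2L)
  cfg <- automaton_config(seed_erosion_px = 2L)
  field <- init_labels(img, truth, ds$stack, ann$ed_phase, cfg)

  mask <- rasterize_contour(truth, dim(img))
  brush <- EBImage::makeBrush(5L, shape = "disc")
  offs <- which(brush == 1, arr.ind = TRUE) - 3L
  eroded <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
    rr <- r + offs[, 1L]; c2 <- cc + offs[, 2L]
    ok <- all(rr >= 1 & rr <= nrow(mask) & c2 >= 1 & c2 <= ncol(mask))
    eroded[r, cc] <- ok && all(mask[cbind(rr, c2)])
  }
  expect_equal(sum(field$labels == 1L), sum(eroded))
  expect_identical(field$labels == 1L, eroded)
})

test_that("image border is always background-seeded and seeds carry strength 1", {
  ds <- tiny_phantom()
  truth <- get_contour(ds$truth, 0L, 2L, "rv_endo")
  img <- rvseg:::stack_slice(ds$stack, 0L, 2L)
  field <- init_labels(img, truth, ds$stack, 0L)
  border <- rbind(cbind(1L, seq_len(ncol(img))),
                  cbind(nrow(img), seq_len(ncol(img))),
                  cbind(seq_len(nrow(img)), 1L),
                  cbind(seq_len(nrow(img)), ncol(img)))
  expect_true(all(field$labels[border] == 2L))
  expect_true(all(field$theta[field$labels > 0L] == 1))
  expect_true(all(field$theta[field$labels == 0L] == 0))
})

test_that("a static cine makes everything outside the dilated seed background", {
  img <- matrix(rep(seq(0, 1, length.out = 24), 24), 24, 24)
  arr <- array(0, dim = c(3, 1, 24, 24))
  for (p in 1:3) arr[p, 1, , ] <- img    # no motion at all
  stack <- cine_stack(arr)
  seed <- square_contour(8, 8, 8)
  field <- init_labels(img, seed, stack, 0L,
                       automaton_config(seed_dilation_px = 4L))
  dilated <- rvseg:::binary_morph(rasterize_contour(seed, dim(img)), 4L,
                                  "dilate")
  expect_true(all(field$labels[!dilated] == 2L))
})

test_that("an empty eroded seed asks for a larger contour", {
  ds <- tiny_phantom()
  small <- contour(cbind(c(30, 32, 32, 30), c(30, 30, 32, 32)), 0L, 2L)
  img <- rvseg:::stack_slice(ds$stack, 0L, 2L)
  expect_error(init_labels(img, small, ds$stack, 0L,
                           automaton_config(seed_erosion_px = 3L)),
               "larger seed")
})

make_field <- function(labels, theta, feat)
  rvseg:::label_field(labels, theta, feat, 0L, 0L)

test_that("a zero-similarity boundary splits the image exactly at the step", {
  feat <- cbind(matrix(0, 10, 5), matrix(1, 10, 5))
  labels <- matrix(0L, 10, 10); theta <- matrix(0, 10, 10)
  labels[5, 2] <- 1L; labels[5, 9] <- 2L; theta[labels > 0] <- 1
  out <- evolve(make_field(labels, theta, feat))
  expect_true(out$converged)
  expect_true(all(out$labels[, 1:5] == 1L))
  expect_true(all(out$labels[, 6:10] == 2L))
})

test_that("evolution matches the brute-force synchronous simulator", {
  withr::local_seed(42)
  for (i in 1:12) {
    nr <- sample(5:12, 1); nc <- sample(5:12, 1)
    nbr <- sample(c(4L, 8L), 1)
    lambda <- sample(c(1, 0.9), 1)
    feat <- matrix(round(stats::runif(nr * nc), 2), nr, nc)
    labels <- matrix(0L, nr, nc); theta <- matrix(0, nr, nc)
    nseed <- sample(2:3, 1)
    idx <- sample(nr * nc, nseed)
    labels[idx] <- c(1L, 2L, sample(1:2, 1))[seq_len(nseed)]
    theta[idx] <- 1
    cfg <- automaton_config(neighborhood = nbr, lambda = lambda)
    got <- evolve(make_field(labels, theta, feat), cfg)
    want <- oracle_growcut(labels, theta, feat, lambda, nbr)
    expect_identical(got$labels, want$labels)
    expect_equal(got$theta, want$theta, tolerance = 1e-12)
    expect_true(got$converged)
    expect_lte(got$iterations, nr * nc)
  }
})

test_that("strengths are non-decreasing and the fixpoint is idempotent", {
  withr::local_seed(7)
  feat <- matrix(stats::runif(100), 10, 10)
  labels <- matrix(0L, 10, 10); theta <- matrix(0, 10, 10)
  labels[3, 3] <- 1L; labels[8, 8] <- 2L; theta[labels > 0] <- 1
  field <- make_field(labels, theta, feat)
  step_cfg <- automaton_config(max_iter = 1L)
  repeat {
    nxt <- evolve(field, step_cfg)
    expect_true(all(nxt$theta >= field$theta - 1e-15))
    expect_true(all(nxt$theta <= 1 + 1e-12))
    if (identical(nxt$labels, field$labels) &&
        identical(nxt$theta, field$theta)) break
    field <- nxt
  }
  fix <- evolve(field)
  expect_identical(fix$labels, field$labels)
  expect_identical(fix$theta, field$theta)
  expect_true(fix$converged)
})

test_that("evolve requires both seed classes", {
  feat <- matrix(0.5, 5, 5)
  labels <- matrix(0L, 5, 5); theta <- matrix(0, 5, 5)
  labels[2, 2] <- 1L; theta[2, 2] <- 1
  expect_error(evolve(make_field(labels, theta, feat)), "background seed")
})

test_that("contour extraction keeps the largest filled component", {
  labels <- matrix(2L, 32, 32)
  labels[6:25, 6:25] <- 1L                       # 20x20 square
  field <- make_field(labels, matrix(1, 32, 32), matrix(0.5, 32, 32))
  ct <- extract_contour(field)
  expect_equal(abs(rvseg:::poly_signed_area(ct$points)), 400,
               tolerance = 0.05 * 400)
  expect_equal(nrow(ct$points), 120L)

  # a second small component must be ignored
  labels2 <- matrix(2L, 32, 32)
  labels2[4:23, 4:18] <- 1L                      # 300 px
  labels2[28:29, 26:30] <- 1L                    # 10 px
  f2 <- make_field(labels2, matrix(1, 32, 32), matrix(0.5, 32, 32))
  ct2 <- extract_contour(f2)
  m2 <- rasterize_contour(ct2, c(32, 32))
  expect_equal(sum(m2[28:29, 26:30]), 0L)

  # interior holes are filled
  labels3 <- matrix(2L, 32, 32)
  labels3[6:15, 6:15] <- 1L
  labels3[10:11, 10:11] <- 2L                    # 2x2 hole
  f3 <- make_field(labels3, matrix(1, 32, 32), matrix(0.5, 32, 32))
  ct3 <- extract_contour(f3)
  expect_equal(abs(rvseg:::poly_signed_area(ct3$points)), 100,
               tolerance = 0.05 * 100)
  expect_error(extract_contour(make_field(matrix(2L, 5, 5), matrix(1, 5, 5),
                                          matrix(0, 5, 5))),
               "no foreground")
})

test_that("seed optimization recovers the truth border on noise-free slices", {
  ds <- tiny_phantom()
  ann <- ds$annotations
  shape <- c(ds$stack$n_rows, ds$stack$n_cols)
  sp <- ds$stack$pixel_spacing_mm
  truth <- get_contour(ds$truth, ann$ed_phase, 2L, "rv_endo")
  img <- rvseg:::stack_slice(ds$stack, ann$ed_phase, 2L)
  tmask <- rasterize_contour(truth, shape)

  refined <- optimize_seed(img, truth, ds$stack, ann$ed_phase)
  expect_gte(dice_metric(rasterize_contour(refined, shape), tmask), 0.98)

  rough <- perturb_seed(truth, 3, 21L, sp)
  refined2 <- optimize_seed(img, rough, ds$stack, ann$ed_phase)
  d_rough <- dice_metric(rasterize_contour(rough, shape), tmask)
  d_ref <- dice_metric(rasterize_contour(refined2, shape), tmask)
  expect_gt(d_ref, d_rough)
})

test_that("a seed dropped into background raises the area-change flag", {
  ds <- tiny_phantom()
  img <- rvseg:::stack_slice(ds$stack, 0L, 2L)
  stray <- contour(cbind(c(20, 26, 26, 20), c(100, 100, 106, 106)), 0L, 2L)
  refined <- optimize_seed(img, stray, ds$stack, 0L)
  expect_true("area_change_gt_300pct" %in% attr(refined, "flags"))
})
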