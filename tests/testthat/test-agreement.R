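pm_of <- function(x, y) paired_measurements(seq_along(x), x, y)

test_that("paired difference statistics follow the stated formulas", {
  rep <- paired_diff_stats(pm_of(c(2, 4, 6), c(1, 2, 3)))  # d = 1, 2, 3
  expect_equal(rep$value$median, 2)
  expect_equal(rep$value$mean, 2)
  expect_equal(rep$value$sd, 1)
  expect_equal(rep$value$loa_lower, 2 - 1.96)
  expect_equal(rep$value$loa_upper, 2 + 1.96)
  # x == y: everything collapses to zero
  rep0 <- paired_diff_stats(pm_of(c(5, 7), c(5, 7)))
  expect_equal(rep0$value$mean, 0)
  expect_equal(rep0$value$loa_lower, 0)
  expect_equal(rep0$value$loa_upper, 0)
  # percentage uses the pair mean by default
  rep1 <- paired_diff_stats(pm_of(110, 90))
  expect_equal(rep1$percentage$median, 100 * 20 / 100)
  # reference-denominator mode
  rep2 <- paired_diff_stats(pm_of(110, 90), pct_denominator = "y")
  expect_equal(rep2$percentage$median, 100 * 20 / 90)
  # zero denominators are excluded and counted
  rep3 <- paired_diff_stats(pm_of(c(1, 2), c(-1, 1)))
  expect_equal(rep3$n_pct_excluded, 1L)
})

test_that("difference statistics negate when the pair order is swapped", {
  withr::local_seed(3)
  x <- rnorm(15, 100, 10); y <- rnorm(15, 100, 10)
  a <- paired_diff_stats(pm_of(x, y))
  b <- paired_diff_stats(pm_of(y, x))
  expect_equal(a$value$mean, -b$value$mean)
  expect_equal(a$value$median, -b$value$median)
  expect_equal(a$value$sd, b$value$sd)
  expect_equal(a$value$loa_lower, -b$value$loa_upper)
  expect_equal(a$value$q25, -b$value$q75)
})

test_that("limits of agreement capture about 95% of normal differences", {
  withr::local_seed(123)
  n <- 1e5
  x <- rnorm(n, 100, 5); y <- x - rnorm(n, 2, 3)   # d ~ N(2, 3)
  rep <- paired_diff_stats(pm_of(x, y))
  d <- x - y
  frac <- mean(d >= rep$value$loa_lower & d <= rep$value$loa_upper)
  expect_equal(frac, 0.95, tolerance = 0.02 / 0.95)
})

test_that("wilcoxon p-values match the stated conventions", {
  # all differences zero
  expect_equal(wilcoxon_signed_rank(pm_of(c(1, 2, 3), c(1, 2, 3))), 1.0)
  # five positive differences: 2/32 two-sided
  expect_equal(wilcoxon_signed_rank(pm_of(c(2, 4, 6, 8, 10),
                                          c(1, 2, 3, 4, 5))), 0.0625)
  # symmetry under swapping
  withr::local_seed(8)
  x <- rnorm(9); y <- rnorm(9)
  expect_equal(wilcoxon_signed_rank(pm_of(x, y)),
               wilcoxon_signed_rank(pm_of(y, x)))
})

test_that("exact wilcoxon equals independent oracles on random instances", {
  withr::local_seed(17)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    x <- round(rnorm(n, 0, 2), 1)
    y <- round(rnorm(n, 0, 2), 1)
    p <- wilcoxon_signed_rank(pm_of(x, y))
    expect_equal(p, oracle_wilcoxon_p(x, y), info = paste("case", i))
    # tie-free cases also agree with stats::wilcox.test's exact branch
    d <- x - y
    if (!any(d == 0) && !any(duplicated(abs(d)))) {
      ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
      expect_equal(p, ref, tolerance = 1e-12)
    }
  }
})

test_that("the large-sample normal approximation stays close to exact", {
  withr::local_seed(31)
  x <- rnorm(20, 0.5); y <- rnorm(20)
  p_approx <- wilcoxon_signed_rank(pm_of(x, y))
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(p_approx, ref, tolerance = 1e-9)
})

test_that("linear fits reproduce closed-form lines and a normal-equations solve", {
  x <- c(1, 2, 3, 4, 5)
  fit <- linear_fit(pm_of(2 * x + 1, x))
  # note: fit is of y on x with x = first member of the pair
  fit2 <- linear_fit(paired_measurements(1:5, x, 2 * x + 1))
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$intercept, 1)
  expect_equal(fit2$r_squared, 1)
  cns <- linear_fit(paired_measurements(1:5, x, c(5, 5, 5, 5, 5)))
  expect_equal(cns$slope, 0)
  expect_equal(cns$r_squared, 0)
  expect_error(linear_fit(paired_measurements(1:3, c(2, 2, 2), 1:3)),
               "constant")
  # independent normal-equations oracle
  withr::local_seed(4)
  xx <- rnorm(5); yy <- rnorm(5)
  f <- linear_fit(paired_measurements(1:5, xx, yy))
  A <- cbind(1, xx)
  beta <- solve(t(A) %*% A, t(A) %*% yy)
  expect_equal(f$intercept, beta[1L], tolerance = 1e-9)
  expect_equal(f$slope, beta[2L], tolerance = 1e-9)
})

test_that("the observer protocol emits five comparisons by three parameters", {
  withr::local_seed(12)
  mk <- function(noise) tibble::tibble(
    subject = paste0("s", 1:8),
    ed_volume_ml = 160 + rnorm(8, 0, noise),
    es_volume_ml = 70 + rnorm(8, 0, noise),
    ef_percent = 55 + rnorm(8, 0, noise))
  base <- mk(0)
  tables <- list(M1 = base, M2a = base, M2b = base,
                 A1 = base, A2a = base, A2b = base)
  res <- run_protocol(tables)
  expect_equal(nrow(res), 15L)
  expect_true(all(res$median_diff == 0))
  expect_true(all(res$p_value == 1))

  # a constant 2 mL offset appears as the validity median difference
  shifted <- base
  shifted$ed_volume_ml <- shifted$ed_volume_ml + 2
  res2 <- run_protocol(modifyList(tables, list(A1 = shifted)))
  v <- res2[res2$comparison == "validity" & res2$parameter == "ed_volume", ]
  expect_equal(v$median_diff, 2)

  # distinct noisy tables still yield the full report grid
  tables3 <- list(M1 = mk(2), M2a = mk(2), M2b = mk(2),
                  A1 = mk(1), A2a = mk(1), A2b = mk(1))
  res3 <- run_protocol(tables3)
  expect_equal(nrow(res3), 15L)
  expect_true(all(is.finite(res3$p_value)))
  expect_error(run_protocol(tables3[-1]), "missing measurement table")
  bad <- tables3
  bad$M2a$subject[1] <- "zz"
  expect_error(run_protocol(bad), "subject mismatch")
})

test_that("agreement reports tidy, glance and plot", {
  withr::local_seed(2)
  pm <- paired_measurements(1:10, rnorm(10, 100, 5), rnorm(10, 100, 5),
                            parameter = "ed_volume", unit = "mL")
  rep <- agreement_analysis(pm)
  td <- tidy(rep)
  expect_equal(nrow(td), 2L)
  expect_equal(td$scale, c("value", "percentage"))
  gl <- glance(rep)
  expect_equal(gl$n, 10L)
  expect_true(is.finite(gl$r_squared))
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
})
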