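#' Paired measurements of one parameter by two methods or observers
#'
#' @param subject vector of subject identifiers.
#' @param x,y paired numeric measurements, aligned by subject.
#' @param parameter,unit optional labels.
#' @return A tibble of class `paired_measurements`.
#' @export
paired_measurements <- function(subject, x, y, parameter = "value",
                                unit = "") {
  stopifnot(length(x) == length(y), length(subject) == length(x),
            length(x) >= 1)
  out <- tibble::tibble(subject = subject, x = as.numeric(x),
                        y = as.numeric(y))
  attr(out, "parameter") <- parameter
  attr(out, "unit") <- unit
  class(out) <- c("paired_measurements", class(out))
  out
}

#' Paired-difference agreement statistics
#'
#' Computes, for differences `d = x - y`: median and interquartile range
#' (25th-75th percentile, linear interpolation between closest ranks), mean
#' and sample SD, and 95% limits of agreement `mean +/- 1.96 * SD`; and the
#' same four statistics for the percentage differences
#' `100 * d / denominator`. The default percentage denominator is the pair
#' mean `(x + y) / 2`; `pct_denominator = "y"` divides by the reference
#' measurement instead (useful when `y` is a manual reference). Pairs whose
#' denominator is zero are excluded from the percentage statistics and
#' counted in `n_pct_excluded`.
#'
#' @param pm a [paired_measurements()] (or data frame with `x`, `y`).
#' @param pct_denominator `"pair_mean"` (default) or `"y"`.
#' @return An object of class `agreement_report`.
#' @export
paired_diff_stats <- function(pm, pct_denominator = c("pair_mean", "y")) {
  pct_denominator <- match.arg(pct_denominator)
  if (NROW(pm) == 0L) stop("no measurement pairs", call. = FALSE)
  d <- pm$x - pm$y
  denom <- if (pct_denominator == "pair_mean") (pm$x + pm$y) / 2 else pm$y
  ok <- denom != 0
  pct <- 100 * d[ok] / denom[ok]
  one <- function(v) {
    if (!length(v))
      return(list(median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                  mean = NA_real_, sd = NA_real_,
                  loa_lower = NA_real_, loa_upper = NA_real_))
    m <- mean(v)
    s <- if (length(v) >= 2L) stats::sd(v) else NA_real_
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    list(median = q[2L], q25 = q[1L], q75 = q[3L], mean = m, sd = s,
         loa_lower = if (is.na(s)) NA_real_ else m - 1.96 * s,
         loa_upper = if (is.na(s)) NA_real_ else m + 1.96 * s)
  }
  base::structure(
    list(value = one(d), percentage = one(pct),
         n = length(d), n_pct_excluded = sum(!ok),
         pct_denominator = pct_denominator,
         parameter = attr(pm, "parameter") %||% "value",
         unit = attr(pm, "unit") %||% "",
         pairs = tibble::tibble(subject = pm$subject,
                                pair_mean = (pm$x + pm$y) / 2,
                                difference = d),
         p_value = NA_real_, regression = NULL),
    class = "agreement_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-tailed Wilcoxon signed-rank test
#'
#' Zero differences are dropped (signed-rank convention) and ties are
#' mid-ranked. For 12 or fewer non-zero differences the two-sided p-value
#' is exact, by enumeration of all sign assignments; beyond that a normal
#' approximation with tie and continuity corrections is used. All-zero
#' differences give p = 1.
#'
#' @param pm a [paired_measurements()] (or data frame with `x`, `y`).
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(pm) {
  d <- pm$x - pm$y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1.0)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 12L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wdist <- as.vector(signs %*% r)
    p <- 2 * min(mean(wdist <= w), mean(wdist >= w))
    return(min(1, p))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- sign(w - mu) * 0.5
  z <- (w - mu - cc) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Ordinary least-squares fit of y on x
#'
#' @param pm a [paired_measurements()] (or data frame with `x`, `y`).
#' @return List with `slope`, `intercept`, `r_squared` (squared Pearson
#'   correlation).
#' @export
linear_fit <- function(pm) {
  if (NROW(pm) < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (stats::sd(pm$x) == 0) stop("x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x, data = pm)
  r2 <- if (stats::sd(pm$y) == 0) 0 else stats::cor(pm$x, pm$y)^2
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2)
}

#' Full agreement analysis of one paired comparison
#'
#' Bundles [paired_diff_stats()], [wilcoxon_signed_rank()] and (when `x`
#' varies) [linear_fit()] into one report.
#'
#' @inheritParams paired_diff_stats
#' @return An `agreement_report` with `p_value` and `regression` filled in.
#' @export
agreement_analysis <- function(pm, pct_denominator = c("pair_mean", "y")) {
  rep <- paired_diff_stats(pm, pct_denominator)
  rep$p_value <- wilcoxon_signed_rank(pm)
  if (NROW(pm) >= 2L && stats::sd(pm$x) > 0)
    rep$regression <- linear_fit(pm)
  rep
}

#' @export
print.agreement_report <- function(x, ...) {
  v <- x$value; p <- x$percentage
  cat(sprintf("<agreement_report> %s (n = %d)\n", x$parameter, x$n))
  cat(sprintf("  value:  median %.3g (%.3g to %.3g), mean %.3g +/- %.3g (LoA %.3g to %.3g) %s\n",
              v$median, v$q25, v$q75, v$mean, v$sd, v$loa_lower, v$loa_upper,
              x$unit))
  cat(sprintf("  pct:    median %.3g%% (%.3g to %.3g%%), mean %.3g +/- %.3g%%\n",
              p$median, p$q25, p$q75, p$mean, p$sd))
  if (!is.na(x$p_value)) cat(sprintf("  Wilcoxon p = %.4f\n", x$p_value))
  if (!is.null(x$regression))
    cat(sprintf("  regression: y = %.4g * x + %.4g, R^2 = %.3f\n",
                x$regression$slope, x$regression$intercept,
                x$regression$r_squared))
  invisible(x)
}

#' Tidy an agreement report
#' @param x an `agreement_report`.
#' @param ... unused.
#' @return One-row tibble per scale (`value`, `percentage`) with the
#'   difference statistics.
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) {
  row <- function(scale, st) tibble::tibble(
    parameter = x$parameter, scale = scale, n = x$n,
    median = st$median, q25 = st$q25, q75 = st$q75,
    mean = st$mean, sd = st$sd,
    loa_lower = st$loa_lower, loa_upper = st$loa_upper,
    p_value = x$p_value)
  dplyr::bind_rows(row("value", x$value), row("percentage", x$percentage))
}

#' Glance at an agreement report
#' @param x an `agreement_report`.
#' @param ... unused.
#' @return One-row tibble with headline statistics.
#' @method glance agreement_report
#' @export
#' @importFrom generics glance
glance.agreement_report <- function(x, ...) {
  tibble::tibble(parameter = x$parameter, n = x$n,
                 median_diff = x$value$median, mean_diff = x$value$mean,
                 sd_diff = x$value$sd, p_value = x$p_value,
                 slope = x$regression$slope %||% NA_real_,
                 intercept = x$regression$intercept %||% NA_real_,
                 r_squared = x$regression$r_squared %||% NA_real_)
}

#' @export
generics::glance

#' Bland-Altman plot of an agreement report
#'
#' Scatter of per-subject differences against pair means with the mean
#' difference and the 95% limits of agreement as horizontal lines.
#'
#' @param object an `agreement_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot agreement_report
#' @export
#' @importFrom ggplot2 autoplot
autoplot.agreement_report <- function(object, ...) {
  v <- object$value
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$pair_mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = v$mean, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(v$loa_lower, v$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(
      x = paste0("Mean of pair", if (nzchar(object$unit))
        paste0(" (", object$unit, ")") else ""),
      y = paste0("Difference", if (nzchar(object$unit))
        paste0(" (", object$unit, ")") else ""),
      title = paste("Bland-Altman:", object$parameter)) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' Run the full observer-variability protocol
#'
#' Takes the six measurement tables of the study design — manual
#' segmentations M1, M2a, M2b and semi-automatic segmentations A1, A2a, A2b
#' — and emits the five standard comparisons (manual inter-observer
#' M1 vs M2a, manual intra-observer M2a vs M2b, semi-automatic
#' inter-observer A1 vs A2a, semi-automatic intra-observer A2a vs A2b, and
#' validity A1 vs M1) for each of ED volume, ES volume and EF.
#'
#' @param measurements named list of data frames (names among M1, M2a, M2b,
#'   A1, A2a, A2b), each with columns `subject`, `ed_volume_ml`,
#'   `es_volume_ml`, `ef_percent`.
#' @param pct_denominator passed to [paired_diff_stats()].
#' @return A tibble with one row per comparison x parameter and a
#'   list-column `report` of `agreement_report` objects, plus unnested
#'   headline statistics.
#' @export
run_protocol <- function(measurements,
                         pct_denominator = c("pair_mean", "y")) {
  pct_denominator <- match.arg(pct_denominator)
  comparisons <- list(
    manual_inter = c("M1", "M2a"), manual_intra = c("M2a", "M2b"),
    auto_inter = c("A1", "A2a"), auto_intra = c("A2a", "A2b"),
    validity = c("A1", "M1"))
  params <- c(ed_volume = "ed_volume_ml", es_volume = "es_volume_ml",
              ef = "ef_percent")
  units <- c(ed_volume = "mL", es_volume = "mL", ef = "%")
  rows <- list()
  for (cmp in names(comparisons)) {
    ab <- comparisons[[cmp]]
    miss <- setdiff(ab, names(measurements))
    if (length(miss))
      stop("missing measurement table: ", miss[1L], call. = FALSE)
    ta <- measurements[[ab[1L]]]; tb <- measurements[[ab[2L]]]
    if (!setequal(ta$subject, tb$subject))
      stop("subject mismatch between ", ab[1L], " and ", ab[2L],
           call. = FALSE)
    tb <- tb[match(ta$subject, tb$subject), ]
    for (par in names(params)) {
      pm <- paired_measurements(ta$subject, ta[[params[[par]]]],
                                tb[[params[[par]]]],
                                parameter = par, unit = units[[par]])
      rep <- agreement_analysis(pm, pct_denominator)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        comparison = cmp, parameter = par,
        median_diff = rep$value$median, q25 = rep$value$q25,
        q75 = rep$value$q75, mean_diff = rep$value$mean,
        sd_diff = rep$value$sd,
        loa_lower = rep$value$loa_lower, loa_upper = rep$value$loa_upper,
        median_pct = rep$percentage$median, mean_pct = rep$percentage$mean,
        p_value = rep$p_value, report = list(rep))
    }
  }
  dplyr::bind_rows(rows)
}
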