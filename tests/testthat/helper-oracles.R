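# Independent oracles, written separately from the package internals.

# Straightforward double-loop synchronous cellular-automaton simulator with
# the same attack rule and tie order (N, NE, E, SE, S, SW, W, NW).
oracle_growcut <- function(labels, theta, feat, lambda = 1,
                           neighborhood = 8L, max_iter = 10000L) {
  nr <- nrow(labels); nc <- ncol(labels)
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  if (neighborhood == 4L) offs <- offs[c(1, 3, 5, 7)]
  it <- 0L
  repeat {
    it <- it + 1L
    new_lab <- labels; new_th <- theta; changed <- FALSE
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      best <- theta[r, cc]; bl <- labels[r, cc]
      for (o in offs) {
        rr <- r + o[1L]; c2 <- cc + o[2L]
        if (rr < 1L || rr > nr || c2 < 1L || c2 > nc) next
        if (labels[rr, c2] == 0L) next
        att <- lambda * max(0, 1 - abs(feat[r, cc] - feat[rr, c2])) *
          theta[rr, c2]
        if (att > best) { best <- att; bl <- labels[rr, c2] }
      }
      if (best > theta[r, cc]) {
        new_lab[r, cc] <- bl; new_th[r, cc] <- best; changed <- TRUE
      }
    }
    labels <- new_lab; theta <- new_th
    if (!changed || it >= max_iter) break
  }
  list(labels = labels, theta = theta, iterations = it)
}

# Exact Wilcoxon signed-rank two-sided p by generating-function counting
# (convolution over doubled midranks), independent of sign enumeration.
oracle_wilcoxon_p <- function(x, y) {
  d <- x - y; d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r2 <- as.integer(round(2 * rank(abs(d))))
  w2 <- sum(r2[d > 0])
  coef <- c(1, rep(0, sum(r2)))
  for (r in r2) {
    shifted <- c(rep(0, r), coef[seq_len(length(coef) - r)])
    coef <- coef + shifted
  }
  tot <- sum(coef)
  ple <- sum(coef[seq_len(w2 + 1L)]) / tot
  pge <- sum(coef[(w2 + 1L):length(coef)]) / tot
  min(1, 2 * min(ple, pge))
}

# Random star-shaped (hence simple) polygon around a centre.
random_polygon <- function(n = 12L, cx = 0, cy = 0, rmin = 2, rmax = 8) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

# Pixel-count mask of a polygon using mgcv's point-in-polygon test.
oracle_mask <- function(pts, shape) {
  bnd <- rbind(pts, pts[1L, ])
  px <- rep(0:(shape[2L] - 1L), each = shape[1L])
  py <- rep(0:(shape[1L] - 1L), times = shape[2L])
  inside <- mgcv::in.out(bnd, cbind(px, py))
  matrix(inside, shape[1L], shape[2L])
}

oracle_dice <- function(mask_a, mask_b) {
  if (sum(mask_a) + sum(mask_b) == 0) return(1)
  2 * sum(mask_a & mask_b) / (sum(mask_a) + sum(mask_b))
}

# Brute-force all-pairs directed/symmetric Hausdorff distance.
oracle_hausdorff <- function(p, q) {
  dmin_pq <- apply(p, 1L, function(v) min(sqrt((q[, 1L] - v[1L])^2 +
                                                 (q[, 2L] - v[2L])^2)))
  dmin_qp <- apply(q, 1L, function(v) min(sqrt((p[, 1L] - v[1L])^2 +
                                                 (p[, 2L] - v[2L])^2)))
  max(max(dmin_pq), max(dmin_qp))
}
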