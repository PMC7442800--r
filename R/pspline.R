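# Penalized cubic B-spline smoother used for pseudotime expression profiles.
#
# Basis: cubic B-splines with interior knots at pseudotime quantiles.
# Penalty: gamma * integral of squared second derivative (O'Sullivan
# penalty, computed exactly by 3-point Gauss-Legendre per inter-knot
# interval) plus a small gamma * 1e-6 * first-derivative penalty so that
# the infinite-penalty limit is the constant fit at the mean rather than
# an arbitrary straight line. Linear trends are essentially unpenalized at
# moderate gamma.

.pspline_knots <- function(t, n_interior) {
  r <- range(t)
  if (n_interior > 0) {
    qs <- stats::quantile(t, probs = seq_len(n_interior) / (n_interior + 1),
                          names = FALSE)
    qs <- qs[qs > r[1] & qs < r[2]]
    qs <- unique(qs)
  } else qs <- numeric(0)
  c(rep(r[1], 4), qs, rep(r[2], 4))
}

.gauss3 <- list(nodes = c(-sqrt(3 / 5), 0, sqrt(3 / 5)),
                weights = c(5 / 9, 8 / 9, 5 / 9))

# integral of B^{(d)} outer products over the knot span
.pspline_penalty <- function(knots, d) {
  brk <- unique(knots)
  p <- length(knots) - 4
  omega <- matrix(0, p, p)
  for (i in seq_len(length(brk) - 1)) {
    a <- brk[i]; b <- brk[i + 1]
    if (b <= a) next
    qx <- (a + b) / 2 + (b - a) / 2 * .gauss3$nodes
    qw <- (b - a) / 2 * .gauss3$weights
    bb <- splines::splineDesign(knots, qx, ord = 4, derivs = rep(d, 3),
                                outer.ok = TRUE)
    omega <- omega + t(bb) %*% (bb * qw)
  }
  omega
}

# smoother matrices for a fixed set of pseudotimes; reused across genes
.pspline_smoother <- function(t, gamma = 5, n_interior = NULL) {
  n <- length(t)
  if (n < 4) stop("pspline: need at least 4 observations")
  if (diff(range(t)) == 0) stop("pspline: degenerate pseudotime range")
  if (is.null(n_interior)) n_interior <- max(0L, min(6L, floor(n / 10)))
  knots <- .pspline_knots(t, n_interior)
  b <- splines::splineDesign(knots, t, ord = 4, outer.ok = TRUE)
  pen <- gamma * (.pspline_penalty(knots, 2) +
                    1e-6 * .pspline_penalty(knots, 1))
  btb <- crossprod(b)
  v <- solve(btb + pen + diag(1e-10, ncol(b)), t(b))
  list(b = b, v = v, edf = sum(b * t(v)), knots = knots,
       range = range(t), gamma = gamma)
}

# fit; returns coefficients, effective df, rss and everything needed to
# evaluate the profile on new pseudotimes
.pspline_fit <- function(t, y, gamma = 5, n_interior = NULL) {
  stopifnot(length(y) == length(t))
  sm <- .pspline_smoother(t, gamma, n_interior)
  coef <- sm$v %*% y
  fitted <- as.vector(sm$b %*% coef)
  list(coef = as.vector(coef), knots = sm$knots, range = sm$range,
       fitted = fitted, edf = sm$edf, rss = sum((y - fitted)^2),
       gamma = gamma)
}

.pspline_predict <- function(fit, newt) {
  newt <- pmin(fit$range[2], pmax(fit$range[1], newt))
  b <- splines::splineDesign(fit$knots, newt, ord = 4, outer.ok = TRUE)
  as.vector(b %*% fit$coef)
}
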