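# Statistics layer: Gaussian KDE, exact two-tailed Mann-Whitney U,
# in-circle region probability, spin-angle collective variable, and work
# integration.

#' Gaussian kernel density estimate
#'
#' Silverman's bandwidth `1.06 * min(sd, IQR/1.34) * n^(-1/5)` unless a
#' fixed bandwidth is supplied; the evaluation grid spans the data range
#' extended by four bandwidths on each side, so the trapezoidal integral
#' of the density is 1 to within 1%.
#'
#' @param samples numeric vector (>= 2 values with nonzero spread).
#' @param bandwidth_rule `"silverman"` or `"fixed"`.
#' @param bandwidth bandwidth when `bandwidth_rule = "fixed"`.
#' @param grid_size number of evaluation points.
#' @return a `density_estimate` list: `grid`, `density`, `bandwidth`.
#' @export
#' @examples
#' d <- gaussian_kde(rnorm(1000))
#' sum(diff(d$grid) * (head(d$density, -1) + tail(d$density, -1)) / 2)
gaussian_kde <- function(samples, bandwidth_rule = c("silverman", "fixed"),
                         bandwidth = NULL, grid_size = 512L) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2L) abort_param("need at least 2 finite samples")
  spread <- min(sd(samples),
                diff(quantile(samples, c(0.25, 0.75), names = FALSE)) / 1.34)
  if (bandwidth_rule == "silverman") {
    if (spread <= 0) abort_param("degenerate sample: zero spread")
    h <- 1.06 * spread * n^(-1 / 5)
  } else {
    if (is.null(bandwidth)) abort_param("fixed rule requires a bandwidth")
    check_scalar(bandwidth, "bandwidth", lower = 0)
    h <- bandwidth
  }
  grid <- seq(min(samples) - 4 * h, max(samples) + 4 * h,
              length.out = grid_size)
  dens <- rowMeans(dnorm(outer(grid, samples, "-"), sd = h))
  structure(list(grid = grid, density = dens, bandwidth = h),
            class = "density_estimate")
}

# U statistic of x against y with midranks for ties
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Two-tailed Mann-Whitney U test
#'
#' U from rank sums with midranks for ties. For `n1 + n2 <= 14` the
#' two-tailed p-value is exact, from full enumeration of the
#' `choose(n1+n2, n1)` group assignments of the pooled values (which
#' handles ties correctly); the two-tailed p doubles the smaller tail and
#' is capped at 1. Larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y numeric samples (each nonempty).
#' @return a `rank_test_result` list: `u_statistic` (U of `x`),
#'   `p_value_two_tailed`, `method`, `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value_two_tailed  # 0.1
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) abort_param("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y)
  u <- u_statistic(x, y)
  if (n1 + n2 <= 14L) {
    pooled <- c(x, y)
    r <- rank(pooled)
    idx <- combn(n1 + n2, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    tail_lo <- mean(us <= u + eps)
    tail_hi <- mean(us >= u - eps)
    p <- min(1, 2 * min(tail_lo, tail_hi))
    method <- "exact"
  } else {
    n <- n1 + n2
    r <- rank(c(x, y))
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    mu <- n1 * n2 / 2
    if (sigma2 <= 0) {
      p <- 1; method <- "normal_approx"
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
      method <- "normal_approx"
    }
  }
  structure(list(u_statistic = u, p_value_two_tailed = p, method = method,
                 n1 = n1, n2 = n2),
            class = "rank_test_result")
}

#' Fraction of points inside a circular region
#'
#' Boundary-inclusive count of points within `radius` of `center`, divided
#' by the number of points.
#'
#' @param points two-column matrix or data.frame of 2D coordinates.
#' @param center length-2 numeric center.
#' @param radius positive radius.
#' @return probability in `[0, 1]`.
#' @export
fraction_in_region <- function(points, center, radius) {
  points <- as.matrix(points)
  if (!nrow(points) || ncol(points) != 2L)
    abort_param("points must be a nonempty 2-column matrix")
  check_scalar(radius, "radius", lower = 0)
  d2 <- (points[, 1] - center[1])^2 + (points[, 2] - center[2])^2
  mean(d2 <= radius^2)
}

#' Spin angle about a fixed axis
#'
#' Closed-form optimal in-plane rotation mapping `reference_coords` onto
#' `current_coords` about `axis`: both point sets are centered on their
#' centroids, projected onto the plane perpendicular to the axis, and the
#' angle is `atan2(sum(axis . (u x v)), sum(u . v))` over matched pairs.
#' The residual is the RMS misfit of the projections after applying the
#' rotation.
#'
#' @param reference_coords,current_coords `n x 3` matrices of matched
#'   points (n >= 2).
#' @param axis length-3 axis vector (normalized internally).
#' @return a `spin_angle_result` list: `angle_rad` in `(-pi, pi]`,
#'   `residual`.
#' @export
#' @examples
#' X <- cbind(c(1, 0, -1), c(0, 1, 0), c(0, 0, 0))
#' R <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
#' spin_angle(X, X %*% t(R(pi / 5)), c(0, 0, 1))$angle_rad  # ~ pi/5
spin_angle <- function(reference_coords, current_coords, axis) {
  A <- as.matrix(reference_coords); B <- as.matrix(current_coords)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3L || nrow(A) < 2L)
    abort_param("coordinate sets must be matched n x 3 matrices, n >= 2")
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm < 1e-12) abort_param("axis has near-zero norm")
  a <- axis / nrm
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  proj <- function(M) M - outer(drop(M %*% a), a)
  U <- proj(A); V <- proj(B)
  if (sum(U^2) < 1e-20 || sum(V^2) < 1e-20)
    abort_param("undefined angle: all points lie on the axis")
  crossd <- U[, 1] * V[, 2] - U[, 2] * V[, 1]
  cross3 <- cbind(U[, 2] * V[, 3] - U[, 3] * V[, 2],
                  U[, 3] * V[, 1] - U[, 1] * V[, 3],
                  crossd)
  num <- sum(cross3 %*% a)
  den <- sum(U * V)
  ang <- atan2(num, den)
  ca <- cos(ang); sa <- sin(ang)
  # Rodrigues rotation of U by ang about a
  Ur <- U * ca + cbind(a[2] * U[, 3] - a[3] * U[, 2],
                       a[3] * U[, 1] - a[1] * U[, 3],
                       a[1] * U[, 2] - a[2] * U[, 1]) * sa +
    outer(drop(U %*% a), a) * (1 - ca)
  structure(list(angle_rad = ang,
                 residual = sqrt(mean(rowSums((Ur - V)^2)))),
            class = "spin_angle_result")
}

#' Integrate work along a steered rotation
#'
#' Rectangle-rule running sum of per-step generalized force times angular
#' displacement.
#'
#' @param forces per-step generalized forces (energy / angle units).
#' @param displacements per-step angular displacements.
#' @return a `work_profile` list: `cumulative_work`, `total`.
#' @export
#' @examples
#' integrate_work(rep(2, 10), rep(2 * pi / 10, 10))$total  # 4*pi
integrate_work <- function(forces, displacements) {
  if (length(forces) != length(displacements))
    abort_param("forces and displacements must have equal length")
  cw <- cumsum(forces * displacements)
  structure(list(cumulative_work = cw, total = cw[length(cw)]),
            class = "work_profile")
}
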