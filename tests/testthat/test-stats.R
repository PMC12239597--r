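# Statistics layer: KDE, Mann-Whitney, region probability, spin angle,
# work integration.

test_that("gaussian_kde matches closed forms and integrates to one", {
  set.seed(51)
  d <- gaussian_kde(rnorm(10000))
  at0 <- approx(d$grid, d$density, 0)$y
  expect_equal(at0, 1 / sqrt(2 * pi), tolerance = 0.02 / 0.399)

  # two-point sample with fixed bandwidth: mixture of two kernels
  h <- 0.4
  d2 <- gaussian_kde(c(-1, 1), bandwidth_rule = "fixed", bandwidth = h)
  expect_equal(approx(d2$grid, d2$density, 0)$y, dnorm(1, sd = h),
               tolerance = 1e-3)   # grid interpolation error only

  # translation equivariance
  set.seed(52)
  x <- rgamma(500, 3)
  da <- gaussian_kde(x); db <- gaussian_kde(x + 10)
  expect_equal(db$grid, da$grid + 10, tolerance = 1e-9)
  expect_equal(db$density, da$density, tolerance = 1e-12)

  # integral ~ 1 for assorted samples
  set.seed(53)
  for (smp in list(rnorm(50), rexp(200), runif(1000, -3, 7))) {
    dd <- gaussian_kde(smp)
    integral <- sum(diff(dd$grid) *
                      (head(dd$density, -1) + tail(dd$density, -1)) / 2)
    expect_equal(integral, 1, tolerance = 0.01)
  }

  expect_error(gaussian_kde(rep(3, 10)), class = "gearbelt_param_error")
  expect_error(gaussian_kde(2), class = "gearbelt_param_error")
})

test_that("mann_whitney_u handles the documented exact cases", {
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value_two_tailed, 1)
  expect_identical(same$method, "exact")

  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$u_statistic, 0)
  expect_equal(sep$p_value_two_tailed, 0.1)

  # fully separated n1 = n2 = 6: p = 2 / choose(12, 6)
  sep6 <- mann_whitney_u(1:6, 101:106)
  expect_identical(sep6$method, "exact")
  expect_equal(sep6$p_value_two_tailed, 2 / choose(12, 6))

  big <- mann_whitney_u(rnorm(10), rnorm(10))
  expect_identical(big$method, "normal_approx")
  expect_error(mann_whitney_u(numeric(0), 1), class = "gearbelt_param_error")
})

test_that("exact p equals the full-enumeration oracle on random instances", {
  set.seed(54)
  for (rep in 1:40) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
    # small integer pools produce plenty of ties
    x <- sample(1:4, n1, replace = TRUE)
    y <- sample(1:4, n2, replace = TRUE)
    res <- mann_whitney_u(x, y)
    expect_identical(res$method, "exact")
    expect_equal(res$u_statistic, brute_u(x, y))
    expect_equal(res$p_value_two_tailed, brute_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("tie-free exact p agrees with stats::wilcox.test", {
  set.seed(55)
  for (rep in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    ours <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(ours$u_statistic, unname(ref$statistic))
    expect_equal(ours$p_value_two_tailed, ref$p.value, tolerance = 1e-9)
  }
})

test_that("fraction_in_region computes boundary-inclusive probabilities", {
  pts <- matrix(rep(c(2, 3), 5), ncol = 2, byrow = TRUE)
  expect_equal(fraction_in_region(pts, c(2, 3), 0.1), 1)

  set.seed(56)
  sq <- cbind(runif(10000, -1, 1), runif(10000, -1, 1))
  expect_equal(fraction_in_region(sq, c(0, 0), 1), pi / 4, tolerance = 0.02)

  # mixture with 82% of its mass inside the circle (measured occupancy)
  set.seed(57)
  n_in <- 8200; n_out <- 1800
  r_in <- sqrt(runif(n_in)); th <- runif(n_in, 0, 2 * pi)
  r_out <- sqrt(runif(n_out, 1.0001, 4)); th2 <- runif(n_out, 0, 2 * pi)
  mix <- rbind(cbind(r_in * cos(th), r_in * sin(th)),
               cbind(r_out * cos(th2), r_out * sin(th2)))
  expect_equal(fraction_in_region(mix, c(0, 0), 1), 0.82, tolerance = 0.001)

  # boundary point is inside
  expect_equal(fraction_in_region(rbind(c(1, 0)), c(0, 0), 1), 1)
  expect_error(fraction_in_region(rbind(c(1, 0)), c(0, 0), 0),
               class = "gearbelt_param_error")
})

rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1),
                            3, 3)

test_that("spin_angle recovers rotations about an axis", {
  set.seed(58)
  X <- cbind(rnorm(20), rnorm(20), rnorm(20))
  a36 <- 36 * pi / 180
  res <- spin_angle(X, X %*% t(rot_z(a36)), c(0, 0, 1))
  expect_equal(res$angle_rad, a36, tolerance = 1e-9)
  expect_lt(res$residual, 1e-9)

  expect_equal(spin_angle(X, X, c(0, 0, 1))$angle_rad, 0)

  # jittered rotation: agree with a brute-force 0.01-degree grid search
  Y <- X %*% t(rot_z(-0.9)) + matrix(rnorm(60, 0, 0.02), 20)
  res2 <- spin_angle(X, Y, c(0, 0, 1))
  grid <- seq(-pi, pi, by = 0.01 * pi / 180)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  Xp <- Xc; Xp[, 3] <- 0; Yp <- Yc; Yp[, 3] <- 0
  rms <- vapply(grid, function(a)
    sqrt(mean(rowSums((Xp %*% t(rot_z(a)) - Yp)^2))), numeric(1))
  expect_equal(res2$angle_rad, grid[which.min(rms)], tolerance = 2e-4)

  # antisymmetry
  expect_equal(spin_angle(X, Y, c(0, 0, 1))$angle_rad,
               -spin_angle(Y, X, c(0, 0, 1))$angle_rad, tolerance = 1e-9)

  expect_error(spin_angle(X, X, c(0, 0, 0)), class = "gearbelt_param_error")
  Z <- cbind(0, 0, 1:5)
  expect_error(spin_angle(Z, Z, c(0, 0, 1)), class = "gearbelt_param_error")
})

test_that("integrate_work sums torque times displacement", {
  n <- 100
  w <- integrate_work(rep(3, n), rep(2 * pi / n, n))
  expect_equal(w$total, 6 * pi)
  expect_equal(w$cumulative_work[1], 3 * 2 * pi / n)

  # equal and opposite passes negate
  set.seed(59)
  f <- rnorm(50)
  fwd <- integrate_work(f, rep(0.1, 50))
  bwd <- integrate_work(f, rep(-0.1, 50))
  expect_equal(fwd$total, -bwd$total)

  # tilted periodic torque landscape favoring CW: the restraint force
  # needed for a full CW turn is smaller on average, so the CW pass
  # accumulates less work (the qualitative ordering of the two passes)
  theta <- seq(0, 2 * pi, length.out = 51)[-51]
  dth <- 2 * pi / 50
  f_ccw <- 1.5 + 0.5 * sin(theta)   # against the tilt
  f_cw <- 1.0 + 0.5 * sin(theta)    # with the tilt
  w_ccw <- integrate_work(f_ccw, rep(dth, 50))$total
  w_cw <- integrate_work(f_cw, rep(dth, 50))$total
  expect_equal(w_ccw, 2 * pi * 1.5, tolerance = 1e-9)
  expect_equal(w_cw, 2 * pi * 1.0, tolerance = 1e-9)
  expect_lt(w_cw, w_ccw)

  expect_error(integrate_work(1:3, 1:4), class = "gearbelt_param_error")
})
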