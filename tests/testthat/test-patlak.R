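test_that("self-comparison gives the unit line: ki = 0, v = 1", {
  sch <- paper_scheme()
  set.seed(41)
  ref <- random_positive_tac(sch)
  pts <- patlak_transform(ref, ref)
  expect_equal(pts$y, rep(1, 41))
  fit <- fit_patlak(pts, c(10, 60))
  expect_equal(fit$ki, 0, tolerance = 1e-12)
  expect_equal(fit$v, 1, tolerance = 1e-12)
})

test_that("normalized time of a constant reference follows the
          triangle-plus-trapezoid closed form", {
  sch <- paper_scheme()
  cref <- tac(sch, rep(7, 41), decay_corrected = TRUE)
  t <- mid_times_min(sch)
  # with activity taken as zero at injection, the running integral of a
  # constant c is c*(t - t1/2) past the first frame and c*t1/2 at it
  expect_equal(patlak_transform(cref, cref)$x,
               c(t[1] / 2, t[-1] - t[1] / 2), tolerance = 1e-12)
})

test_that("normalized time matches a dense-grid quadrature oracle", {
  sch <- paper_scheme()
  pl <- simulate_input_function(mid_times_min(sch))
  ref <- simulate_tissue_tac(pl, kinetic_params(0.4, 0.4, 0), sch)
  pts <- patlak_transform(ref, ref)
  # oracle: integrate a fine linear interpolation of the curve anchored
  # at (0, 0)
  t <- mid_times_min(sch)
  fine <- seq(0, max(t), by = 1e-3)
  v_fine <- approx(c(0, t), c(0, ref$values), xout = fine)$y
  cum_fine <- c(0, cumsum((v_fine[-1] + v_fine[-length(v_fine)]) / 2 *
                            diff(fine)))
  x_oracle <- approx(fine, cum_fine, xout = t)$y / ref$values
  late <- t > 10
  expect_lt(max(abs(pts$x[late] - x_oracle[late]) / x_oracle[late]),
            0.005)
})

test_that("points on an exact line are recovered perfectly", {
  sch <- paper_scheme()
  set.seed(43)
  ref <- random_positive_tac(sch)
  # slope from the printed contralateral range
  target <- construct_patlak_exact_tac(ref, 0.0157, 1)
  fit <- fit_patlak(patlak_transform(target, ref), c(10, 60))
  expect_equal(fit$ki, 0.0157, tolerance = 1e-10)
  expect_equal(fit$v, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("identity round trip holds for any window and random curves", {
  sch <- paper_scheme()
  set.seed(44)
  for (i in 1:25) {
    ref <- random_positive_tac(sch)
    ki <- runif(1, 1e-3, 0.05)
    v <- runif(1, 0.3, 2)
    target <- construct_patlak_exact_tac(ref, ki, v)
    fit <- fit_patlak(patlak_transform(target, ref), random_window())
    expect_lt(abs(fit$ki - ki) / ki, 1e-8)
    expect_lt(abs(fit$v - v) / v, 1e-8)
  }
})

test_that("OLS slope and intercept equal the normal-equations oracle", {
  sch <- paper_scheme()
  set.seed(45)
  ref <- random_positive_tac(sch)
  target <- tac(sch, ref$values * runif(41, 0.5, 3),
                decay_corrected = TRUE)
  pts <- patlak_transform(target, ref)
  fit <- fit_patlak(pts, c(10, 60))
  sel <- pts$mid_min >= 10 & pts$mid_min <= 60
  want <- ols_oracle(pts$x[sel], pts$y[sel])
  expect_equal(fit$ki, want$slope, tolerance = 1e-10)
  expect_equal(fit$v, want$intercept, tolerance = 1e-10)
})

test_that("two in-window points give an exact line with R^2 = 1", {
  sch <- build_framing("2x600")  # mid-times 5 and 15 min
  ref <- tac(sch, c(4, 5), decay_corrected = TRUE)
  target <- tac(sch, c(6, 11), decay_corrected = TRUE)
  fit <- fit_patlak(patlak_transform(target, ref), c(0, 60))
  expect_equal(fit$n_points, 2L)
  expect_equal(fit$r_squared, 1)
})

test_that("degenerate inputs fail with informative errors", {
  sch <- paper_scheme()
  set.seed(46)
  ref <- random_positive_tac(sch)
  bad <- ref; bad$values[17] <- 0
  expect_error(patlak_transform(ref, bad), "frame 17")
  pts <- patlak_transform(ref, ref)
  expect_error(fit_patlak(pts, c(89, 95)), "fewer than 2")
  expect_error(fit_patlak(pts, c(60, 10)), "precede")
})

test_that("ki and v are invariant to common scaling and equivariant to
          target scaling", {
  sch <- paper_scheme()
  set.seed(47)
  ref <- random_positive_tac(sch)
  target <- construct_patlak_exact_tac(ref, 0.012, 0.8)
  f0 <- fit_patlak(patlak_transform(target, ref), c(10, 60))
  scale_tac <- function(x, c) { x$values <- x$values * c; x }
  f_common <- fit_patlak(patlak_transform(scale_tac(target, 3.7),
                                          scale_tac(ref, 3.7)), c(10, 60))
  expect_equal(f_common$ki, f0$ki, tolerance = 1e-12)
  expect_equal(f_common$v, f0$v, tolerance = 1e-12)
  f_target <- fit_patlak(patlak_transform(scale_tac(target, 2.5), ref),
                         c(10, 60))
  expect_equal(f_target$ki, 2.5 * f0$ki, tolerance = 1e-10)
  expect_equal(f_target$v, 2.5 * f0$v, tolerance = 1e-10)
})

test_that("normalized time is non-decreasing once the reference has
          peaked", {
  sch <- paper_scheme()
  set.seed(48)
  for (i in 1:5) {
    # smooth curves: past the peak the reference declines, so the
    # running integral grows while the denominator shrinks
    ref <- random_positive_tac(sch, jitter = FALSE)
    pts <- patlak_transform(ref, ref)
    past_peak <- seq(which.max(ref$values), 41)
    expect_true(all(diff(pts$x[past_peak]) >= 0))
  }
})

test_that("later fit windows converge faster for faster equilibration", {
  sch <- paper_scheme()
  pl <- simulate_input_function(mid_times_min(sch))
  ref <- simulate_tissue_tac(pl, kinetic_params(0.4, 0.4, 0), sch)
  gap <- function(k2, k3) {
    target <- simulate_tissue_tac(pl, kinetic_params(0.08, k2, k3), sch)
    pts <- patlak_transform(target, ref)
    abs(fit_patlak(pts, c(10, 60))$ki - fit_patlak(pts, c(20, 60))$ki)
  }
  # fast: k2+k3 = 1.12 (equilibration well before 10 min); slow:
  # k2+k3 = 0.12 (half-time ~ 6 min, linearity not yet reached at 10)
  expect_lt(gap(0.9, 0.22), gap(0.1, 0.02))
})

test_that("the asymmetry ratio is the plain Ki percentage", {
  expect_equal(ki_ratio(0.016, 0.016), 100)
  expect_equal(ki_ratio(0, 0.016), 0)
  expect_equal(ki_ratio(4e-3, 16e-3), 25)
  expect_error(ki_ratio(0.01, 0), "positive")
  f <- structure(list(ki = 5e-3), class = "patlak_fit")
  g <- structure(list(ki = 20e-3), class = "patlak_fit")
  expect_equal(ki_ratio(f, g), 25)
})
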