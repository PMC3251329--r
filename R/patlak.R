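# Cumulative integral of a TAC on frame mid-times.
# The curve is taken as zero at injection (t = 0), so the first segment is
# the triangle from (0, 0) to (t_1, v_1); later segments are trapezoids.
# construct_patlak_exact_tac() shares this rule, making round trips exact.
cumtrapz_from_zero <- function(t_min, values) {
  n <- length(t_min)
  stopifnot(length(values) == n, n >= 1L, all(diff(t_min) > 0), t_min[1] > 0)
  seg <- c(t_min[1] * values[1] / 2,
           if (n > 1L) diff(t_min) * (values[-1] + values[-n]) / 2)
  cumsum(seg)
}

#' Patlak transform of a target TAC against a reference TAC
#'
#' Maps a (target, reference) pair of regional TACs to graphical-analysis
#' coordinates: normalized time
#' `x(t) = integral_0^t C_ref(u) du / C_ref(t)` (minutes) and uptake ratio
#' `y(t) = C_target(t) / C_ref(t)`. For an irreversibly trapped tracer the
#' plot becomes linear once the free compartment has equilibrated; the
#' slope is the influx constant Ki and the intercept the initial
#' distribution volume V (see [fit_patlak()]).
#'
#' The running integral uses the trapezoidal rule on frame mid-times with
#' an initial triangle from the origin (activity is zero at injection).
#'
#' @param target,reference [tac] objects on identical framing schemes;
#'   the reference (a region devoid of trapping, here cerebellum) stands in
#'   for the arterial input.
#' @return A `patlak_points` data frame with columns `mid_min`, `x`, `y`.
#' @export
patlak_transform <- function(target, reference) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  if (!same_scheme(target$scheme, reference$scheme))
    stop("target and reference TACs must share the framing scheme")
  bad <- which(reference$values <= 0)
  if (length(bad))
    stop("reference TAC is non-positive at frame ", bad[1L],
         " (mid-time ", signif(reference$scheme$mid_min[bad[1L]], 4),
         " min); Patlak transform undefined")
  t_min <- reference$scheme$mid_min
  cumint <- cumtrapz_from_zero(t_min, reference$values)
  out <- data.frame(mid_min = t_min,
                    x = cumint / reference$values,
                    y = target$values / reference$values)
  class(out) <- c("patlak_points", "data.frame")
  out
}

#' Fit the Patlak plot over a time window
#'
#' Ordinary least squares of `y` on `x` restricted to frames whose
#' mid-times fall in the closed window (the analysis convention here uses
#' the 10-60 min post-injection window). The slope is the influx constant
#' Ki (1/min relative to the reference) and the intercept the initial
#' distribution volume V.
#'
#' @param points A `patlak_points` object from [patlak_transform()].
#' @param window_min Length-2 numeric `(start, end)` in minutes; frames
#'   with `start <= mid_min <= end` enter the fit.
#' @return A `patlak_fit` list: `ki`, `v`, `r_squared`, `n_points`,
#'   `window`.
#' @export
fit_patlak <- function(points, window_min = c(10, 60)) {
  stopifnot(inherits(points, "patlak_points"),
            is.numeric(window_min), length(window_min) == 2L)
  if (window_min[1] >= window_min[2])
    stop("window start must precede window end")
  sel <- points$mid_min >= window_min[1] & points$mid_min <= window_min[2]
  if (sum(sel) < 2L)
    stop("fewer than 2 frame mid-times inside the fit window [",
         window_min[1], ", ", window_min[2], "] min")
  fit <- lm(y ~ x, data = points[sel, ])
  cf <- coef(fit)
  yw <- points$y[sel]
  ss_tot <- sum((yw - mean(yw))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  structure(
    list(ki = unname(cf[2L]), v = unname(cf[1L]), r_squared = r2,
         n_points = sum(sel), window = window_min),
    class = "patlak_fit"
  )
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf(
    "Patlak fit [%g-%g min, n = %d]: Ki = %.4g /min, V = %.4g, R^2 = %.4f\n",
    x$window[1], x$window[2], x$n_points, x$ki, x$v, x$r_squared))
  invisible(x)
}

#' Ipsilateral/contralateral influx-constant ratio
#'
#' The lesion-severity index: `100 * Ki_ipsi / Ki_contra` (percent). In the
#' unilateral 6-OHDA model the ipsilateral (right, lesioned) striatum is
#' referenced to the intact contralateral (left) side.
#'
#' @param ipsi,contra `patlak_fit` objects or bare Ki values (1/min).
#' @return Ratio in percent.
#' @examples
#' ki_ratio(4e-3, 16e-3)  # 25
#' @export
ki_ratio <- function(ipsi, contra) {
  ki_of <- function(z) if (inherits(z, "patlak_fit")) z$ki else as.numeric(z)
  ki_i <- ki_of(ipsi)
  ki_c <- ki_of(contra)
  if (!is.finite(ki_c) || ki_c <= 0)
    stop("contralateral Ki must be positive")
  100 * ki_i / ki_c
}
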