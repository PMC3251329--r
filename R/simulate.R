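#' Simulate a bolus plasma input function
#'
#' Analytic bolus shape `Cp(t) = A t e^(-lambda1 t) +
#' B (e^(-lambda2 t) - e^(-lambda1 t))`: a fast rise from zero at
#' injection, an early peak, and slow multi-exponential clearance. The
#' reference-tissue analysis never uses the plasma curve; it exists to
#' drive the forward compartmental simulation (and to let the
#' reference-tissue approximation itself be characterized).
#'
#' @param times Numeric vector of sample times, minutes post-injection,
#'   non-negative and strictly increasing.
#' @param A Peak-amplitude coefficient of the bolus term, kBq/mL per min.
#' @param lambda1 Bolus washout rate, 1/min.
#' @param B Amplitude of the slow clearance component, kBq/mL.
#' @param lambda2 Slow clearance rate, 1/min. The small default mimics a
#'   tracer left nearly intact in plasma over a 90-min scan.
#' @return A `plasma_curve`: list with `times` (min), `values` (kBq/mL)
#'   and the shape parameters (kept so downstream simulation can evaluate
#'   the curve continuously).
#' @export
simulate_input_function <- function(times, A = 800, lambda1 = 2.5,
                                    B = 25, lambda2 = 0.01) {
  stopifnot(is.numeric(times), length(times) >= 1L)
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  pars <- c(A = A, lambda1 = lambda1, B = B, lambda2 = lambda2)
  if (any(!is.finite(pars)) || any(pars < 0))
    stop("plasma shape parameters must be non-negative")
  structure(
    list(times = times, values = eval_plasma(times, pars), params = pars),
    class = "plasma_curve"
  )
}

eval_plasma <- function(t, p) {
  p[["A"]] * t * exp(-p[["lambda1"]] * t) +
    p[["B"]] * (exp(-p[["lambda2"]] * t) - exp(-p[["lambda1"]] * t))
}

plasma_fun <- function(plasma) {
  stopifnot(inherits(plasma, "plasma_curve"))
  if (!is.null(plasma$params)) {
    p <- plasma$params
    function(t) eval_plasma(t, p)
  } else {
    # sampled curve: linear interpolation, zero at injection
    tt <- c(0, plasma$times)
    vv <- c(0, plasma$values)
    function(t) approx(tt, vv, xout = t, rule = 2)$y
  }
}

#' Kinetic parameters of the irreversible two-tissue model
#'
#' @param K1 Plasma-to-tissue transfer, mL/min/g.
#' @param k2 Tissue-to-plasma efflux, 1/min.
#' @param k3 Irreversible trapping rate, 1/min (0 for a reference tissue).
#' @return A `kinetic_params` list with the derived macro-parameter
#'   `ki_true = K1 k3 / (k2 + k3)` (0 when `k2 + k3 = 0`), the net influx
#'   constant the Patlak slope estimates.
#' @export
kinetic_params <- function(K1, k2, k3) {
  v <- c(K1 = K1, k2 = k2, k3 = k3)
  if (any(!is.finite(v)) || any(v < 0))
    stop("rate constants must be finite and non-negative")
  ki_true <- if (k2 + k3 > 0) K1 * k3 / (k2 + k3) else 0
  structure(list(K1 = K1, k2 = k2, k3 = k3, ki_true = ki_true),
            class = "kinetic_params")
}

#' Simulate a tissue TAC from the irreversible two-tissue model
#'
#' Integrates `C_free' = K1 Cp - (k2 + k3) C_free; C_trap' = k3 C_free`
#' driven by a plasma input, and returns for each frame the
#' duration-averaged total concentration (what a scanner histogram
#' measures), not a midpoint sample. With `k3 = 0` this reduces to the
#' one-tissue model used for the cerebellar reference region.
#'
#' @param plasma A [plasma_curve][simulate_input_function].
#' @param params A [kinetic_params] object.
#' @param scheme A [framing_scheme][build_framing].
#' @param region Region label for the returned TAC.
#' @return A decay-corrected [tac] (the model carries no physical decay).
#' @export
simulate_tissue_tac <- function(plasma, params, scheme, region = "") {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(scheme, "framing_scheme"))
  cp <- plasma_fun(plasma)
  beta <- params$k2 + params$k3
  k3 <- params$k3
  K1 <- params$K1
  bounds_min <- c(scheme$start_s, sum(scheme$duration_s)) / 60
  if (K1 == 0)
    return(tac(scheme, rep(0, nrow(scheme)), region = region,
               decay_corrected = TRUE))
  rhs <- function(t, y, parms) {
    dfree <- K1 * cp(t) - beta * y[1L]
    list(c(dfree, k3 * y[1L], y[1L] + y[2L]))
  }
  sol <- deSolve::lsoda(c(free = 0, trap = 0, cum = 0), bounds_min, rhs,
                        rtol = 1e-10, atol = 1e-12)
  frame_means <- diff(sol[, "cum"]) / (scheme$duration_s / 60)
  tac(scheme, frame_means, region = region, decay_corrected = TRUE)
}

#' Construct a target TAC satisfying the Patlak identity exactly
#'
#' Builds `C_tissue(t) = ki * integral_0^t C_ref(u) du + v * C_ref(t)` on
#' the frame mid-times, using the same trapezoid-with-initial-triangle
#' rule as [patlak_transform()]. Feeding the result and the reference into
#' [fit_patlak()] therefore recovers `(ki, v)` to numerical precision over
#' any window — the exact-identity oracle for the graphical analysis.
#'
#' @param reference A [tac] with strictly positive values.
#' @param ki Influx constant, 1/min.
#' @param v Intercept (initial distribution volume), unitless.
#' @param region Region label for the constructed TAC.
#' @return A [tac] on the reference's scheme.
#' @export
construct_patlak_exact_tac <- function(reference, ki, v, region = "") {
  stopifnot(inherits(reference, "tac"), is.numeric(ki), is.numeric(v))
  if (any(reference$values <= 0))
    stop("reference TAC must be strictly positive on every frame")
  cumint <- cumtrapz_from_zero(reference$scheme$mid_min, reference$values)
  tac(reference$scheme, ki * cumint + v * reference$values,
      region = region, decay_corrected = reference$decay_corrected)
}
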