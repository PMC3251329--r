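#' Build a dynamic framing scheme from a compact specification
#'
#' Expands a `"count x seconds"` list such as
#' `"6x10,6x30,11x60,15x180,3x600"` (the 41-frame, 90-min acquisition used
#' throughout this package) into an ordered table of contiguous frames.
#'
#' @param spec Single string: comma-separated `COUNTxSECONDS` groups.
#'   Whitespace is ignored; durations may be fractional seconds.
#'
#' @return A `framing_scheme`: a data frame with columns `frame`,
#'   `start_s`, `duration_s` and `mid_min` (frame mid-time in minutes),
#'   frames contiguous from time zero.
#' @examples
#' sch <- build_framing("6x10,6x30,11x60,15x180,3x600")
#' nrow(sch)              # 41
#' total_duration_s(sch)  # 5400
#' @export
build_framing <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L || !nzchar(spec))
    stop("framing spec must be a single non-empty string")
  parts <- strsplit(gsub("[[:space:]]", "", spec), ",", fixed = TRUE)[[1L]]
  if (!length(parts)) stop("framing spec is empty")
  m <- regmatches(parts, regexec("^([0-9]+)[xX]([0-9]*\\.?[0-9]+)$", parts))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop("malformed framing spec element: '", parts[bad][1L], "'")
  counts <- as.integer(vapply(m, `[[`, character(1L), 2L))
  durs <- as.numeric(vapply(m, `[[`, character(1L), 3L))
  if (any(counts < 1L)) stop("frame counts must be >= 1")
  if (any(durs <= 0)) stop("frame durations must be > 0")
  duration_s <- rep(durs, counts)
  new_framing_scheme(duration_s)
}

new_framing_scheme <- function(duration_s) {
  start_s <- c(0, cumsum(duration_s))[seq_along(duration_s)]
  out <- data.frame(
    frame = seq_along(duration_s),
    start_s = start_s,
    duration_s = duration_s,
    mid_min = (start_s + duration_s / 2) / 60
  )
  class(out) <- c("framing_scheme", "data.frame")
  out
}

#' Total duration of a framing scheme
#' @param scheme A `framing_scheme`.
#' @return Total scan length in seconds.
#' @export
total_duration_s <- function(scheme) {
  stopifnot(inherits(scheme, "framing_scheme"))
  sum(scheme$duration_s)
}

#' Frame mid-times in minutes
#' @param scheme A `framing_scheme`.
#' @return Numeric vector of frame mid-times (minutes post-injection).
#' @export
mid_times_min <- function(scheme) {
  stopifnot(inherits(scheme, "framing_scheme"))
  scheme$mid_min
}

#' @export
print.framing_scheme <- function(x, ...) {
  cat(sprintf("Dynamic framing scheme: %d frames, %.1f min total\n",
              nrow(x), sum(x$duration_s) / 60))
  NextMethod()
}

same_scheme <- function(a, b, tol = 1e-9) {
  nrow(a) == nrow(b) &&
    max(abs(a$start_s - b$start_s), abs(a$duration_s - b$duration_s)) <= tol
}
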