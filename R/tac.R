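#' Construct a regional time-activity curve
#'
#' A TAC holds the frame-mean activity concentration of one region across a
#' dynamic acquisition, together with its decay-correction state. Kinetic
#' routines ([patlak_transform()], [fit_patlak()]) represent each frame by
#' its mid-time.
#'
#' @param scheme A [framing_scheme][build_framing] describing the frames.
#' @param values Numeric vector, one value per frame. Units `kBq/mL` unless
#'   `unit` says otherwise.
#' @param region Region label (e.g. `"striatum_L"`, `"cerebellum"`).
#' @param decay_corrected Logical; whether values are already corrected to
#'   a common reference time.
#' @param unit Concentration unit string; `"suv"` marks a dimensionless
#'   SUV curve.
#' @return An object of class `tac`.
#' @export
tac <- function(scheme, values, region = "", decay_corrected = FALSE,
                unit = "kBq/mL") {
  stopifnot(inherits(scheme, "framing_scheme"))
  values <- as.numeric(values)
  if (length(values) != nrow(scheme))
    stop("TAC has ", length(values), " values for ", nrow(scheme), " frames")
  if (anyNA(values)) stop("TAC values contain NA")
  structure(
    list(scheme = scheme, values = values, region = region,
         decay_corrected = isTRUE(decay_corrected), unit = unit),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC [%s]: %d frames, %s, decay-corrected: %s\n",
              x$region, length(x$values), x$unit,
              x$decay_corrected))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  cbind(as.data.frame(unclass(x$scheme)),
        value = x$values, region = x$region)
}

#' Decay-correct a time-activity curve
#'
#' Corrects frame values to a common reference time using the physical
#' half-life, i.e. multiplies frame `k` by
#' `exp(ln 2 * (t_mid_k - reference_time) / half_life)`. The inverse
#' operation is [decay_uncorrect()].
#'
#' @param x A [tac] that is not yet decay-corrected.
#' @param half_life_min Physical half-life in minutes; defaults to the
#'   109.77-min half-life of fluorine-18.
#' @param reference_time_min Time the activity is referenced to, minutes
#'   post-injection. The default 0 (injection = scan start) matches a bolus
#'   given at the start of the emission scan.
#' @return The corrected `tac` with `decay_corrected = TRUE`.
#' @export
decay_correct <- function(x, half_life_min = F18_HALF_LIFE_MIN,
                          reference_time_min = 0) {
  stopifnot(inherits(x, "tac"))
  if (x$decay_corrected) stop("TAC is already decay-corrected")
  if (!is.numeric(half_life_min) || half_life_min <= 0)
    stop("half-life must be positive")
  f <- exp(log(2) * (x$scheme$mid_min - reference_time_min) / half_life_min)
  x$values <- x$values * f
  x$decay_corrected <- TRUE
  x
}

#' Undo decay correction
#'
#' @inheritParams decay_correct
#' @param x A decay-corrected [tac].
#' @return The uncorrected `tac`.
#' @export
decay_uncorrect <- function(x, half_life_min = F18_HALF_LIFE_MIN,
                            reference_time_min = 0) {
  stopifnot(inherits(x, "tac"))
  if (!x$decay_corrected) stop("TAC is not decay-corrected")
  if (!is.numeric(half_life_min) || half_life_min <= 0)
    stop("half-life must be positive")
  f <- exp(log(2) * (x$scheme$mid_min - reference_time_min) / half_life_min)
  x$values <- x$values / f
  x$decay_corrected <- FALSE
  x
}

#' Normalize a decay-corrected TAC to standardized uptake value
#'
#' `SUV(t) = C(t) [kBq/mL] * body weight [g] / injected activity [kBq]`,
#' assuming 1 g/mL tissue density, so a uniform whole-body distribution of
#' the dose gives SUV 1 at every frame.
#'
#' @param x A decay-corrected [tac] in kBq/mL.
#' @param dose_mbq Injected activity at injection time, MBq.
#' @param weight_g Body weight, grams.
#' @return A `tac` with `unit = "suv"`.
#' @examples
#' sch <- build_framing("1x60")
#' x <- tac(sch, 100, decay_corrected = TRUE)
#' to_suv(x, dose_mbq = 50, weight_g = 400)$values  # 0.8
#' @export
to_suv <- function(x, dose_mbq, weight_g) {
  stopifnot(inherits(x, "tac"))
  if (!x$decay_corrected)
    stop("SUV conversion requires a decay-corrected TAC")
  if (!is.numeric(dose_mbq) || dose_mbq <= 0) stop("dose must be positive")
  if (!is.numeric(weight_g) || weight_g <= 0) stop("weight must be positive")
  x$values <- x$values * weight_g / (dose_mbq * 1000)
  x$unit <- "suv"
  x
}

#' Extract the VOI-mean time-activity curve for one label
#'
#' Per-frame unweighted arithmetic mean over all voxels carrying `label`
#' in the phantom's mask, mirroring plain VOI-mean ROI analysis.
#'
#' @param phantom A [phantom_4d][generate_phantom] (or object returned by
#'   [read_phantom()]).
#' @param label Integer mask code (e.g. 1 = left striatum, 2 = right
#'   striatum, 3 = cerebellum).
#' @param region Optional region name for the returned TAC; defaults to
#'   `"label_<label>"`.
#' @return A [tac] of the VOI mean per frame.
#' @export
extract_voi_tac <- function(phantom, label, region = NULL) {
  stopifnot(inherits(phantom, "phantom_4d"))
  label <- as.integer(label)
  idx <- which(phantom$mask == label)
  if (!length(idx))
    stop("label ", label, " is absent from the mask")
  nf <- nrow(phantom$scheme)
  nvox <- prod(dim(phantom$mask))
  img <- matrix(phantom$image, nrow = nvox, ncol = nf)
  vals <- colMeans(img[idx, , drop = FALSE])
  tac(phantom$scheme, vals,
      region = if (is.null(region)) paste0("label_", label) else region,
      decay_corrected = phantom$decay_corrected)
}

#' Write TACs to a long-format TSV
#'
#' Columns: `frame_index, start_s, duration_s, mid_min, value, unit,
#' region`; one row per frame per region.
#'
#' @param tacs A `tac` or list of `tac` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tacs <- function(tacs, path) {
  if (inherits(tacs, "tac")) tacs <- list(tacs)
  rows <- do.call(rbind, lapply(tacs, function(x) {
    data.frame(frame_index = x$scheme$frame, start_s = x$scheme$start_s,
               duration_s = x$scheme$duration_s, mid_min = x$scheme$mid_min,
               value = x$values, unit = x$unit, region = x$region)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read TACs from a long-format TSV written by [write_tacs()]
#'
#' @param path File path.
#' @param decay_corrected Decay-correction state to record on the curves.
#' @return Named list of [tac] objects (one per region).
#' @export
read_tacs <- function(path, decay_corrected = TRUE) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("frame_index", "start_s", "duration_s", "value", "region")
  if (!all(need %in% names(d)))
    stop("TAC table must contain columns: ", paste(need, collapse = ", "))
  out <- lapply(split(d, d$region), function(g) {
    g <- g[order(g$frame_index), ]
    tac(new_framing_scheme(g$duration_s), g$value, region = g$region[1L],
        decay_corrected = decay_corrected,
        unit = if ("unit" %in% names(g)) g$unit[1L] else "kBq/mL")
  })
  out
}
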