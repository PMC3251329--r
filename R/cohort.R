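#' Configuration of the synthetic lesion cohort
#'
#' Defines the generative model for a unilaterally 6-OHDA-lesioned rat
#' cohort: per-dose group sizes, the contralateral influx-constant
#' distribution, the dose-dependent lesion-severity distribution, and the
#' two links tying lesion severity to striatal monoamine content and to
#' methamphetamine-induced rotation counts.
#'
#' Lesion severity `s` is the residual ipsilateral fraction of the influx
#' constant (`ki_ipsi = s * ki_contra`), drawn per animal from a normal
#' distribution truncated to `(0, 1]` with dose-specific mean and SD. The
#' DA link maps Ki R/L percent (`100 s`) linearly to DA+metabolites R/L
#' percent; the rotation link maps it linearly to log10 rotation counts
#' per 90 min. Controls rotate negligibly, so their counts come from a
#' low-mean Poisson instead of the log-linear link (set
#' `control_rotation_lambda = NULL` to apply the link to controls too).
#'
#' Defaults emulate the study conditions this package targets: groups of
#' 3/6/6/6 animals at 0/7/14/28 ug 6-OHDA; contralateral Ki ~ 16.2e-3
#' 1/min with small spread; mean residual fractions 1.0/0.70/0.55/0.30
#' with wide scatter at the intermediate doses; a DA link with non-zero
#' intercept; and rotation counts rising to the hundreds in severely
#' lesioned animals.
#'
#' @param group_sizes Named integer vector, dose (ug) -> animals.
#' @param ki_contra_mean,ki_contra_sd Contralateral Ki distribution, 1/min.
#' @param severity_mean,severity_sd Named numeric vectors (same names as
#'   `group_sizes`): per-dose mean and SD of the residual ipsilateral
#'   fraction `s` in `(0, 1]`.
#' @param da_link `c(slope, intercept, sd)`: DA R/L percent =
#'   `slope * KiRL + intercept + N(0, sd)`, clipped to `(0.1, 100]`.
#' @param rot_link `c(slope, intercept, sd)`: log10 rotations =
#'   `slope * KiRL + intercept + N(0, sd)`.
#' @param da_contra_mean,da_contra_sd Contralateral DA+metabolites level,
#'   nmol/g tissue.
#' @param control_rotation_lambda Poisson mean of control rotation counts,
#'   or `NULL` to use the log-linear link for controls.
#' @param seed Integer seed; a fixed seed makes [simulate_cohort()] output
#'   bit-reproducible.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(group_sizes = c(`0` = 3L, `7` = 6L, `14` = 6L,
                                          `28` = 6L),
                          ki_contra_mean = 16.2e-3, ki_contra_sd = 0.25e-3,
                          severity_mean = c(`0` = 1.0, `7` = 0.70,
                                            `14` = 0.55, `28` = 0.30),
                          severity_sd = c(`0` = 0.03, `7` = 0.20,
                                          `14` = 0.20, `28` = 0.06),
                          da_link = c(slope = 1.25, intercept = -25, sd = 10),
                          rot_link = c(slope = -0.032, intercept = 3.7,
                                       sd = 0.5),
                          da_contra_mean = 60, da_contra_sd = 8,
                          control_rotation_lambda = 5,
                          seed = 1L) {
  group_sizes <- setNames(as.integer(group_sizes), names(group_sizes))
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("group_sizes must be named by 6-OHDA dose (ug)")
  if (any(group_sizes < 1L)) stop("group sizes must be >= 1")
  doses <- names(group_sizes)
  if (!all(doses %in% names(severity_mean)) ||
      !all(doses %in% names(severity_sd)))
    stop("severity_mean/severity_sd must cover every dose in group_sizes")
  if (any(severity_mean[doses] <= 0) || any(severity_mean[doses] > 1))
    stop("severity means must lie in (0, 1]")
  if (any(severity_sd[doses] < 0) || ki_contra_sd < 0 ||
      da_link[["sd"]] < 0 || rot_link[["sd"]] < 0 || da_contra_sd < 0)
    stop("SDs must be non-negative")
  if (ki_contra_mean <= 0 || da_contra_mean <= 0)
    stop("contralateral means must be positive")
  structure(
    list(group_sizes = group_sizes,
         ki_contra_mean = ki_contra_mean, ki_contra_sd = ki_contra_sd,
         severity_mean = severity_mean[doses],
         severity_sd = severity_sd[doses],
         da_link = da_link, rot_link = rot_link,
         da_contra_mean = da_contra_mean, da_contra_sd = da_contra_sd,
         control_rotation_lambda = control_rotation_lambda,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# normal truncated to (lo, hi]; sd = 0 degenerates to the mean
rnorm_trunc <- function(n, mean, sd, lo = 0, hi = 1) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  for (i in seq_len(1000L)) {
    bad <- out <= lo | out > hi
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(out, lo + 1e-12), hi)
}

#' Simulate a lesion cohort with known ground truth
#'
#' Draws one [animal record][assemble_cohort] per animal under the
#' generative model of [cohort_config()]: contralateral Ki, residual
#' ipsilateral fraction `s` (truncated normal per dose group), ipsilateral
#' Ki = `s * ki_contra`, DA+metabolites on both sides via the DA link, and
#' a rotation count via the rotation link (controls: low-mean Poisson).
#' The configured seed fixes the entire table.
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `animal_id, dose_ug, ki_ipsi, ki_contra,
#'   da_ipsi, da_contra, rotations` (one row per animal).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  doses <- names(config$group_sizes)
  rows <- vector("list", length(doses))
  counter <- 0L
  for (d in doses) {
    n <- config$group_sizes[[d]]
    s <- rnorm_trunc(n, config$severity_mean[[d]], config$severity_sd[[d]])
    ki_contra <- rnorm_trunc(n, config$ki_contra_mean, config$ki_contra_sd,
                             lo = 0, hi = Inf)
    ki_rl <- 100 * s
    da_contra <- rnorm_trunc(n, config$da_contra_mean, config$da_contra_sd,
                             lo = 0, hi = Inf)
    da_rl <- config$da_link[["slope"]] * ki_rl +
      config$da_link[["intercept"]] +
      rnorm(n, 0, config$da_link[["sd"]])
    da_rl <- pmin(pmax(da_rl, 0.1), 100)
    log_rot <- config$rot_link[["slope"]] * ki_rl +
      config$rot_link[["intercept"]] + rnorm(n, 0, config$rot_link[["sd"]])
    rotations <- pmax(0L, as.integer(round(10^log_rot)))
    if (d == "0" && !is.null(config$control_rotation_lambda))
      rotations <- rpois(n, config$control_rotation_lambda)
    rows[[d]] <- data.frame(
      animal_id = sprintf("R%03d", counter + seq_len(n)),
      dose_ug = as.numeric(d),
      ki_ipsi = s * ki_contra,
      ki_contra = ki_contra,
      da_ipsi = da_rl / 100 * da_contra,
      da_contra = da_contra,
      rotations = rotations
    )
    counter <- counter + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a cohort table as TSV
#'
#' Plain UTF-8 TSV with a header row and `.` decimal separator; columns
#' `animal_id, dose_ug, ki_ipsi, ki_contra, da_ipsi, da_contra, rotations`.
#'
#' @param cohort Data frame as returned by [simulate_cohort()].
#' @param path File path.
#' @return `write_cohort`: `path` invisibly; `read_cohort`: the data frame.
#' @export
write_cohort <- function(cohort, path) {
  need <- c("animal_id", "dose_ug", "ki_ipsi", "ki_contra",
            "da_ipsi", "da_contra", "rotations")
  stopifnot(all(need %in% names(cohort)))
  write.table(cohort[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE, comment.char = "#")
  need <- c("animal_id", "dose_ug", "ki_ipsi", "ki_contra",
            "da_ipsi", "da_contra", "rotations")
  if (!all(need %in% names(d)))
    stop("cohort table must contain columns: ", paste(need, collapse = ", "))
  d
}
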