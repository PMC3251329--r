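#' Configuration of an end-to-end pipeline run
#'
#' @param framing Compact framing spec string (see [build_framing()]).
#' @param window_min Patlak fit window, minutes (closed on frame
#'   mid-times).
#' @param half_life_min Physical half-life used wherever decay handling
#'   applies.
#' @param cohort A [cohort_config()]; its `seed` is overridden by `seed`.
#' @param striatum_params,reference_params [kinetic_params] for the
#'   forward model. The reference (trapping-free, unit distribution
#'   volume) drives the cerebellar TAC from which each animal's striatal
#'   TACs are built with that animal's ground-truth Ki.
#' @param v Patlak intercept used when constructing per-animal striatal
#'   TACs.
#' @param dunnett_nsim Monte Carlo draws for Dunnett adjusted p.
#' @param seed Integer master seed for the whole run.
#' @return A `run_config` list.
#' @export
run_config <- function(framing = "6x10,6x30,11x60,15x180,3x600",
                       window_min = c(10, 60),
                       half_life_min = F18_HALF_LIFE_MIN,
                       cohort = cohort_config(),
                       striatum_params = kinetic_params(0.08, 0.45, 0.11),
                       reference_params = kinetic_params(0.4, 0.4, 0),
                       v = 1,
                       dunnett_nsim = 1e5,
                       seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(striatum_params, "kinetic_params"),
            inherits(reference_params, "kinetic_params"),
            is.numeric(window_min), length(window_min) == 2L,
            window_min[1] < window_min[2],
            half_life_min > 0, dunnett_nsim >= 1e4)
  build_framing(framing)  # validate early
  cohort$seed <- as.integer(seed)
  structure(
    list(framing = framing, window_min = window_min,
         half_life_min = half_life_min, cohort = cohort,
         striatum_params = striatum_params,
         reference_params = reference_params, v = v,
         dunnett_nsim = as.integer(dunnett_nsim), seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Assemble the per-animal cohort table from the three measurements
#'
#' Inner join by `animal_id` of the bilateral Patlak results, the striatal
#' monoamine levels, and the rotation counts, enforcing the complete-case
#' rule: animals missing any of the three measures are excluded from the
#' correlation analyses and reported in the `excluded` attribute (and via
#' a message). Derived columns `ki_rl_percent`, `da_rl_percent`,
#' `log_rotations` are recomputable from the base columns.
#'
#' @param patlak Data frame: `animal_id, dose_ug, ki_ipsi, ki_contra`.
#' @param monoamines Data frame: `animal_id, da_ipsi, da_contra`
#'   (DA+metabolites, nmol/g).
#' @param rotations Data frame: `animal_id, rotations`.
#' @return A `cohort_table` data frame (one row per complete-case animal)
#'   with attribute `excluded` listing dropped animal ids.
#' @export
assemble_cohort <- function(patlak, monoamines, rotations) {
  check_tab <- function(d, need, what) {
    if (!all(need %in% names(d)))
      stop(what, " table must contain columns: ",
           paste(need, collapse = ", "))
    d <- d[stats::complete.cases(d[, need]), need, drop = FALSE]
    if (anyDuplicated(d$animal_id))
      stop("duplicate animal_id in ", what, " table")
    d
  }
  patlak <- check_tab(patlak, c("animal_id", "dose_ug", "ki_ipsi",
                                "ki_contra"), "patlak")
  monoamines <- check_tab(monoamines, c("animal_id", "da_ipsi",
                                        "da_contra"), "monoamine")
  rotations <- check_tab(rotations, c("animal_id", "rotations"),
                         "rotation")
  all_ids <- unique(c(patlak$animal_id, monoamines$animal_id,
                      rotations$animal_id))
  out <- merge(merge(patlak, monoamines, by = "animal_id"),
               rotations, by = "animal_id")
  if (!nrow(out))
    stop("no animal has all three measures; nothing to assemble")
  excluded <- setdiff(all_ids, out$animal_id)
  if (length(excluded))
    message("complete-case rule excluded ", length(excluded),
            " animal(s): ", paste(excluded, collapse = ", "))
  if (any(out$ki_contra <= 0)) stop("non-positive contralateral Ki")
  out$ki_rl_percent <- 100 * out$ki_ipsi / out$ki_contra
  out$da_rl_percent <- 100 * out$da_ipsi / out$da_contra
  out$log_rotations <- log_rotations(out$rotations)
  out <- out[order(out$dose_ug, out$animal_id), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("cohort_table", "data.frame")
  out
}

# The statistical battery over an assembled cohort table: paired t per
# dose group, ANOVA + Dunnett per measure, and the three pairwise
# regressions with and without controls.
cohort_battery <- function(cohort, dunnett_nsim = 1e5) {
  by_dose <- split(cohort, cohort$dose_ug)
  doses <- names(by_dose)

  paired <- list()
  for (d in doses) {
    g <- by_dose[[d]]
    if (nrow(g) >= 2L) {
      paired[[d]] <- list(
        ki = try_or_null(paired_t_test(g$ki_ipsi, g$ki_contra)),
        da = try_or_null(paired_t_test(g$da_ipsi, g$da_contra))
      )
    }
  }

  grp <- function(col) lapply(by_dose, `[[`, col)
  control_dose <- doses[1L]
  # single-group or degenerate cohorts yield NULL entries rather than
  # aborting the whole battery
  anova_dunnett <- lapply(
    c(ki_ipsi = "ki_ipsi", ki_contra = "ki_contra",
      da_ipsi = "da_ipsi", da_contra = "da_contra"),
    function(col) {
      g <- grp(col)
      list(anova = try_or_null(one_way_anova(g)),
           dunnett = if (length(g) >= 2L)
             try_or_null(dunnett_test(g[[control_dose]], g[-1L],
                                      nsim = dunnett_nsim)))
    })

  lesioned <- cohort[cohort$dose_ug > 0, ]
  reg_pair <- function(d, xcol, ycol)
    try_or_null(linear_regression(d[[xcol]], d[[ycol]]))
  regressions <- list(
    ki_vs_da = list(
      all = reg_pair(cohort, "ki_rl_percent", "da_rl_percent"),
      lesioned = reg_pair(lesioned, "ki_rl_percent", "da_rl_percent")),
    ki_vs_logrot = list(
      all = reg_pair(cohort, "ki_rl_percent", "log_rotations"),
      lesioned = reg_pair(lesioned, "ki_rl_percent", "log_rotations")),
    da_vs_logrot = list(
      all = reg_pair(cohort, "da_rl_percent", "log_rotations"),
      lesioned = reg_pair(lesioned, "da_rl_percent", "log_rotations"))
  )

  list(paired_t = paired, anova_dunnett = anova_dunnett,
       regressions = regressions)
}

try_or_null <- function(expr) tryCatch(expr, error = function(e) NULL)

#' Run the full quantitation chain end to end
#'
#' Simulates a lesion cohort, builds per-animal bilateral striatal TACs on
#' a simulated cerebellar reference curve (via the exact Patlak identity,
#' so the graphical analysis is exercised on every animal), fits the
#' Patlak plot over the configured window, assembles the cohort table,
#' runs the statistical battery, and (optionally) writes a TSV report
#' set. Deterministic for a fixed seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory for the report files, or `NULL` to
#'   skip writing. Created if absent. On any stage failure, files already
#'   written there by this run are removed before the error propagates.
#' @return Invisibly, a list: `cohort` (assembled table), `patlak`
#'   (per-animal fit table), `stats` (battery), `config`, `files`.
#' @export
run_all <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  scheme <- build_framing(config$framing)
  cohort_raw <- simulate_cohort(config$cohort)  # seeds the RNG stream

  plasma <- simulate_input_function(mid_times_min(scheme))
  ref_tac <- simulate_tissue_tac(plasma, config$reference_params, scheme,
                                 region = "cerebellum")

  fits <- lapply(seq_len(nrow(cohort_raw)), function(i) {
    row <- cohort_raw[i, ]
    fit_side <- function(ki, side) {
      target <- construct_patlak_exact_tac(ref_tac, ki, config$v,
                                           region = side)
      fit_patlak(patlak_transform(target, ref_tac), config$window_min)
    }
    ipsi <- fit_side(row$ki_ipsi, "striatum_R")
    contra <- fit_side(row$ki_contra, "striatum_L")
    data.frame(animal_id = row$animal_id, dose_ug = row$dose_ug,
               ki_ipsi = ipsi$ki, v_ipsi = ipsi$v,
               r2_ipsi = ipsi$r_squared,
               ki_contra = contra$ki, v_contra = contra$v,
               r2_contra = contra$r_squared,
               n_points = ipsi$n_points)
  })
  patlak_tab <- do.call(rbind, fits)

  cohort <- assemble_cohort(
    patlak_tab[, c("animal_id", "dose_ug", "ki_ipsi", "ki_contra")],
    cohort_raw[, c("animal_id", "da_ipsi", "da_contra")],
    cohort_raw[, c("animal_id", "rotations")]
  )

  battery <- cohort_battery(cohort, dunnett_nsim = config$dunnett_nsim)

  files <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    files <- tryCatch(
      write_report(out_dir, config, cohort, patlak_tab, battery),
      error = function(e) {
        written <- list.files(out_dir, full.names = TRUE,
                              pattern = "^fdopar_")
        unlink(written)
        stop("report writing failed (partial outputs removed): ",
             conditionMessage(e), call. = FALSE)
      })
  }
  invisible(list(cohort = cohort, patlak = patlak_tab, stats = battery,
                 config = config, files = files))
}

config_provenance <- function(config) {
  ser <- paste(deparse(unclass(config), control = "all"), collapse = " ")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(ser, tf)
  c(sprintf("# fdopar run"),
    sprintf("# seed: %d", config$seed),
    sprintf("# config_md5: %s", unname(md5sum(tf))),
    sprintf("# log_rotation_offset: 1"),
    sprintf("# patlak_window_min: [%g, %g] closed on frame mid-times",
            config$window_min[1], config$window_min[2]),
    sprintf("# config: %s", ser))
}

write_tsv_report <- function(d, path, header) {
  if (is.null(d)) d <- data.frame(note = "not computed (degenerate input)")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_report <- function(out_dir, config, cohort, patlak_tab, battery) {
  hdr <- config_provenance(config)
  f <- function(name) file.path(out_dir, paste0("fdopar_", name))

  files <- c(
    write_tsv_report(as.data.frame(cohort), f("cohort.tsv"), hdr),
    write_tsv_report(patlak_tab, f("patlak.tsv"), hdr)
  )

  pt_rows <- do.call(rbind, lapply(names(battery$paired_t), function(d) {
    do.call(rbind, lapply(c("ki", "da"), function(m) {
      r <- battery$paired_t[[d]][[m]]
      if (is.null(r)) return(NULL)
      data.frame(dose_ug = d, measure = m, t = r$statistic, df = r$df,
                 p_value = r$p_value, mean_diff = r$mean_diff, n = r$n)
    }))
  }))
  files <- c(files, write_tsv_report(pt_rows, f("paired_t.tsv"), hdr))

  ad_rows <- do.call(rbind, lapply(names(battery$anova_dunnett),
                                   function(m) {
    r <- battery$anova_dunnett[[m]]
    if (is.null(r$anova) || is.null(r$dunnett)) return(NULL)
    cbind(data.frame(measure = m, F = r$anova$statistic,
                     df1 = r$anova$df[1], df2 = r$anova$df[2],
                     p_anova = r$anova$p_value),
          r$dunnett$table)
  }))
  files <- c(files, write_tsv_report(ad_rows, f("anova_dunnett.tsv"), hdr))

  reg_rows <- do.call(rbind, lapply(names(battery$regressions),
                                    function(pair) {
    do.call(rbind, lapply(c("all", "lesioned"), function(subset) {
      r <- battery$regressions[[pair]][[subset]]
      if (is.null(r)) return(NULL)
      data.frame(pair = pair, subset = subset, slope = r$slope,
                 intercept = r$intercept, pearson_r = r$pearson_r,
                 p_value = r$p_value, n = r$n)
    }))
  }))
  files <- c(files, write_tsv_report(reg_rows, f("regressions.tsv"), hdr))

  line_if <- function(obj, fmt, ...) if (is.null(obj)) character(0)
    else sprintf(fmt, ...)
  an <- battery$anova_dunnett$ki_ipsi$anova
  summ <- c(
    hdr,
    sprintf("animals: %d (complete-case)", nrow(cohort)),
    sprintf("mean contralateral Ki: %.4g /min", mean(cohort$ki_contra)),
    line_if(an, "ANOVA on ipsilateral Ki: F = %.2f, p = %.3g",
            an$statistic, an$p_value),
    line_if(battery$regressions$ki_vs_da$all,
            "Ki R/L vs DA R/L: r = %.3f",
            battery$regressions$ki_vs_da$all$pearson_r),
    line_if(battery$regressions$ki_vs_logrot$all,
            "Ki R/L vs log rotations: r = %.3f",
            battery$regressions$ki_vs_logrot$all$pearson_r),
    line_if(battery$regressions$da_vs_logrot$all,
            "DA R/L vs log rotations: r = %.3f",
            battery$regressions$da_vs_logrot$all$pearson_r)
  )
  sf <- f("summary.txt")
  writeLines(summ, sf)
  c(files, sf)
}
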