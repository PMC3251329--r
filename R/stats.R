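#' Paired Student's t test on within-animal (ipsi, contra) values
#'
#' Two-sided paired t on the within-animal differences (df = n - 1), the
#' comparison used for lesioned vs contralateral sides within a dose
#' group. Inputs with zero difference variance fail loudly rather than
#' returning NaN.
#'
#' @param x,y Numeric vectors of equal length (>= 2 pairs): ipsilateral
#'   and contralateral values per animal.
#' @return A `test_result` list: `statistic` (t), `df`, `p_value`,
#'   `mean_diff`, `n`, `method`.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must pair up")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (sd(d) == 0)
    stop("all within-pair differences identical; t statistic undefined")
  ht <- t.test(x, y, paired = TRUE)
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, mean_diff = mean(d), n = length(x),
         method = "paired t"),
    class = "test_result"
  )
}

as_group_list <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list")
  lapply(groups, function(g) {
    g <- as.numeric(g)
    if (length(g) < 1L || anyNA(g)) stop("each group needs >= 1 finite value")
    g
  })
}

#' One-way (one-factor) analysis of variance
#'
#' `F = MS_between / MS_within` with `(k - 1, N - k)` degrees of freedom,
#' fitted via [stats::aov()]. Zero within-group variance with unequal
#' means is reported explicitly as an infinite F (p = 0); zero variance
#' with equal means is an error.
#'
#' @param groups Named list, group label (e.g. dose in ug) -> numeric
#'   values.
#' @return A `test_result` list: `statistic` (F), `df` (`c(df1, df2)`),
#'   `p_value`, `group_means`, `method`.
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  N <- sum(lengths(groups))
  k <- length(groups)
  if (N - k < 1L) stop("need at least 1 within-group degree of freedom")
  means <- vapply(groups, mean, numeric(1L))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1L)))
  if (ss_within == 0) {
    if (max(means) - min(means) == 0)
      stop("no variance anywhere; F undefined")
    return(structure(
      list(statistic = Inf, df = c(k - 1, N - k), p_value = 0,
           group_means = means, method = "one-way ANOVA"),
      class = "test_result"))
  }
  dat <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  tab <- summary(aov(y ~ g, data = dat))[[1L]]
  structure(
    list(statistic = tab[1L, "F value"],
         df = c(tab[1L, "Df"], tab[2L, "Df"]),
         p_value = tab[1L, "Pr(>F)"],
         group_means = means, method = "one-way ANOVA"),
    class = "test_result"
  )
}

#' Dunnett's many-to-one comparisons against a shared control
#'
#' Per treatment group `i`, `t_i = (mean_i - mean_ctrl) / SE_i` with the
#' pooled within-group variance across all groups (df = N - k - 1 for k
#' treatment groups). The family-wise adjusted p-value is the tail
#' probability of `max_j |T_j|` under the null correlated multivariate-t
#' distribution (correlation induced by the shared control), evaluated by
#' Monte Carlo. This handles the unbalanced designs typical of lesion
#' studies (e.g. 3 controls vs 6 per dose group), where exact tabulated
#' critical values do not apply. Adjusted p-values are never allowed below
#' the corresponding unadjusted two-sample p.
#'
#' Draws use the current RNG stream; seed beforehand for reproducibility.
#'
#' @param control Numeric vector of control values.
#' @param treatments Named list of treatment-group numeric vectors.
#' @param nsim Monte Carlo draws for the max-|t| null (>= 1e4; default
#'   1e5).
#' @return A `dunnett_result` list: `table` (data frame with `group`,
#'   `mean_diff`, `statistic`, `p_unadjusted`, `p_adjusted`), `df`,
#'   `pooled_sd`, `nsim`, `alpha`.
#' @export
dunnett_test <- function(control, treatments, nsim = 1e5) {
  control <- as.numeric(control)
  if (!length(control)) stop("control group is empty")
  stopifnot(is.list(treatments), length(treatments) >= 1L)
  if (is.null(names(treatments)) || any(!nzchar(names(treatments))))
    stop("treatments must be a named list")
  treatments <- lapply(treatments, as.numeric)
  nsim <- as.integer(nsim)
  if (nsim < 1e4) stop("nsim must be at least 1e4")
  n0 <- length(control)
  ni <- lengths(treatments)
  k <- length(treatments)
  N <- n0 + sum(ni)
  df <- N - (k + 1L)
  if (df < 1L) stop("no residual degrees of freedom")
  ss <- sum((control - mean(control))^2) +
    sum(vapply(treatments, function(g) sum((g - mean(g))^2), numeric(1L)))
  s2 <- ss / df
  if (s2 == 0) stop("pooled within-group variance is zero")
  se <- sqrt(s2 * (1 / ni + 1 / n0))
  diffs <- vapply(treatments, mean, numeric(1L)) - mean(control)
  tstat <- diffs / se
  p_unadj <- 2 * pt(-abs(tstat), df)

  # null max-|T|: T_j = (Z_j/sqrt(n_j) - Z_0/sqrt(n_0)) / (S sqrt(1/n_j + 1/n_0)),
  # S^2 ~ chi^2_df / df shared across contrasts
  z0 <- rnorm(nsim) / sqrt(n0)
  s_draw <- sqrt(rchisq(nsim, df) / df)
  maxT <- rep(0, nsim)
  for (j in seq_len(k)) {
    tj <- abs((rnorm(nsim) / sqrt(ni[j]) - z0) /
                (s_draw * sqrt(1 / ni[j] + 1 / n0)))
    maxT <- pmax(maxT, tj)
  }
  p_adj <- vapply(abs(tstat), function(t0) mean(maxT >= t0), numeric(1L))
  p_adj <- pmax(p_adj, p_unadj)

  structure(
    list(table = data.frame(group = names(treatments),
                            mean_diff = unname(diffs),
                            statistic = unname(tstat),
                            p_unadjusted = unname(p_unadj),
                            p_adjusted = unname(p_adj),
                            row.names = NULL),
         df = df, pooled_sd = sqrt(s2), nsim = nsim, alpha = 0.05),
    class = "dunnett_result"
  )
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf("Dunnett many-to-one comparisons (df = %d, %d MC draws)\n",
              x$df, x$nsim))
  print(x$table, ...)
  invisible(x)
}

#' Simple linear regression with Pearson correlation
#'
#' OLS of `y` on `x` plus Pearson's r and the two-sided p-value from
#' `t = r sqrt((n - 2) / (1 - r^2))`, the analysis used for the pairwise
#' relations between Ki R/L, DA-metabolites R/L, and log rotation counts.
#'
#' @param x,y Numeric vectors (n >= 3 complete pairs, `var(x) > 0`).
#' @return A `regression_result` list: `slope`, `intercept`, `pearson_r`,
#'   `p_value`, `n`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must pair up")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (var(x) == 0) stop("x is constant; regression undefined")
  fit <- lm(y ~ x)
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), n - 2)
  }
  structure(
    list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         pearson_r = r, p_value = p, n = n),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: y = %.4g x + %.4g, r = %.3f, p = %.3g, n = %d\n",
              x$slope, x$intercept, x$pearson_r, x$p_value, x$n))
  invisible(x)
}

#' Common logarithm of a rotation count
#'
#' `log10(count + offset)`; the default offset 1 maps the zero-rotation
#' counts of unlesioned controls to 0 instead of -Inf. The offset used is
#' recorded in pipeline output metadata.
#'
#' @param count Non-negative integer rotation count(s) per session.
#' @param offset Pseudo-count added before the logarithm.
#' @return `log10(count + offset)`.
#' @examples
#' log_rotations(c(0, 99, 999))  # 0, 2, 3
#' @export
log_rotations <- function(count, offset = 1) {
  if (any(!is.finite(count)) || any(count < 0))
    stop("rotation counts must be non-negative")
  log10(count + offset)
}
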