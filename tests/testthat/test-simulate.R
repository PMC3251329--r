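test_that("plasma input is a bolus: zero at injection, peak where a dense
          grid says", {
  t <- mid_times_min(paper_scheme())
  expect_equal(simulate_input_function(c(0, t))$values[1], 0)
  expect_equal(simulate_input_function(t, A = 0, B = 0)$values,
               rep(0, length(t)))

  pl <- simulate_input_function(t)
  # brute-force grid search for the continuous peak
  grid <- seq(0, 5, by = 1e-4)
  dense <- fdopar:::eval_plasma(grid, pl$params)
  t_peak_oracle <- grid[which.max(dense)]
  coarse_peak <- t[which.max(pl$values)]
  # sampled argmax must be the sampled time closest to the true peak
  expect_equal(coarse_peak, t[which.min(abs(t - t_peak_oracle))])

  expect_error(simulate_input_function(t, A = -1), "non-negative")
  expect_error(simulate_input_function(c(1, 0.5)), "increasing")
})

test_that("two-tissue simulation matches a fine-step RK4 oracle", {
  sch <- paper_scheme()
  pl <- simulate_input_function(mid_times_min(sch))
  cp <- fdopar:::plasma_fun(pl)
  cases <- list(c(0.08, 0.45, 0.11), c(0.4, 0.4, 0), c(0.05, 0.12, 0.03))
  for (cs in cases) {
    got <- simulate_tissue_tac(pl, kinetic_params(cs[1], cs[2], cs[3]),
                               sch)$values
    want <- rk4_tissue_oracle(cp, cs[1], cs[2], cs[3], sch, h = 0.01)
    expect_lt(max(abs(got - want) / pmax(abs(want), 1e-9)), 1e-3)
  }
})

test_that("degenerate kinetics behave as closed forms dictate", {
  sch <- paper_scheme()
  pl <- simulate_input_function(mid_times_min(sch))
  # no uptake
  expect_equal(
    simulate_tissue_tac(pl, kinetic_params(0, 0.5, 0.1), sch)$values,
    rep(0, 41))
  # 1-tissue steady state: constant plasma level B, tissue -> K1/k2 * B
  pl_const <- simulate_input_function(mid_times_min(sch),
                                      A = 0, lambda1 = 3, B = 40,
                                      lambda2 = 0)
  x <- simulate_tissue_tac(pl_const, kinetic_params(0.3, 0.6, 0), sch)
  ratio <- x$values[41] / 40
  expect_equal(ratio, 0.3 / 0.6, tolerance = 1e-3)
  # macro-parameter of a reference tissue is zero
  expect_equal(kinetic_params(0.3, 0.6, 0)$ki_true, 0)
  expect_equal(kinetic_params(0, 0, 0)$ki_true, 0)
  expect_equal(kinetic_params(0.08, 0.45, 0.11)$ki_true,
               0.08 * 0.11 / 0.56)
})

test_that("exact-identity TAC construction honors its closed forms", {
  sch <- paper_scheme()
  set.seed(21)
  ref <- random_positive_tac(sch)
  # ki = 0, v = 1 reproduces the reference identically
  expect_equal(construct_patlak_exact_tac(ref, 0, 1)$values, ref$values)
  # constant reference c: output is (ki * cum(t) + v) * c with the shared
  # triangle-plus-trapezoid integral, i.e. linear in integrated time
  cc <- 12
  cref <- tac(sch, rep(cc, 41), decay_corrected = TRUE)
  t <- mid_times_min(sch)
  cum <- c(t[1] / 2, t[-1] - t[1] / 2)  # integral of a constant 1
  expect_equal(construct_patlak_exact_tac(cref, 0.02, 1.1)$values,
               (0.02 * cum + 1.1) * cc, tolerance = 1e-12)
  bad <- tac(sch, c(0, rep(1, 40)))
  expect_error(construct_patlak_exact_tac(bad, 0.01, 1), "positive")
})

test_that("cohort generator respects degenerate-noise and control cases", {
  cfg <- cohort_config(
    severity_sd = c(`0` = 0, `7` = 0, `14` = 0, `28` = 0),
    ki_contra_sd = 0, da_contra_sd = 0,
    da_link = c(slope = 1.25, intercept = -25, sd = 0),
    rot_link = c(slope = -0.032, intercept = 3.7, sd = 0),
    control_rotation_lambda = NULL, seed = 42)
  coh <- simulate_cohort(cfg)
  # zero noise: all animals within a dose group identical
  for (d in unique(coh$dose_ug)) {
    g <- coh[coh$dose_ug == d, -1]
    expect_true(all(vapply(g, function(col) length(unique(col)) == 1,
                           logical(1))))
  }
  # unlesioned controls with severity mean 1 are symmetric
  ctrl <- coh[coh$dose_ug == 0, ]
  expect_equal(ctrl$ki_ipsi, ctrl$ki_contra, tolerance = 1e-12)
  expect_equal(ctrl$da_ipsi, ctrl$da_contra, tolerance = 1e-12)
})

test_that("cohort generator is bit-reproducible and dose-monotone", {
  cfg <- cohort_config(seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)

  # non-increasing severity means give non-increasing mean Ki R/L
  big <- cohort_config(group_sizes = c(`0` = 80L, `7` = 80L, `14` = 80L,
                                       `28` = 80L), seed = 7)
  coh <- simulate_cohort(big)
  rl <- tapply(100 * coh$ki_ipsi / coh$ki_contra, coh$dose_ug, mean)
  expect_true(all(diff(rl[order(as.numeric(names(rl)))]) <= 0))

  expect_error(cohort_config(group_sizes = c(`0` = 0L, `7` = 6L)),
               ">= 1")
})

test_that("regression on a large cohort recovers the configured DA link", {
  # severities low enough that this steep link stays inside the
  # generator's (0.1, 100] percent clip range (linear regime)
  slope <- 2.5; intercept <- -20
  cfg <- cohort_config(
    group_sizes = c(`0` = 200L, `7` = 200L, `14` = 200L, `28` = 200L),
    severity_mean = c(`0` = 0.32, `7` = 0.28, `14` = 0.24, `28` = 0.20),
    severity_sd = c(`0` = 0.03, `7` = 0.03, `14` = 0.03, `28` = 0.03),
    da_link = c(slope = slope, intercept = intercept, sd = 4),
    seed = 123)
  coh <- simulate_cohort(cfg)
  ki_rl <- 100 * coh$ki_ipsi / coh$ki_contra
  da_rl <- 100 * coh$da_ipsi / coh$da_contra
  fit <- lm(da_rl ~ ki_rl)
  se <- coef(summary(fit))[, "Std. Error"]
  expect_lt(abs(coef(fit)[2] - slope), 3 * se[2])
  expect_lt(abs(coef(fit)[1] - intercept), 3 * se[1])
})
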