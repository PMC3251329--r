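# Independent oracles and small fixture builders shared across tests.
# Every oracle here is a brute-force or closed-form route kept deliberately
# separate from the package implementation it checks.

paper_scheme <- function() build_framing("6x10,6x30,11x60,15x180,3x600")

# a strictly positive, decay-corrected reference-like TAC: random
# rise-and-clearance shape, optionally with multiplicative jitter
random_positive_tac <- function(scheme, region = "ref", jitter = TRUE) {
  t <- mid_times_min(scheme)
  base <- 50 * (1 - exp(-t / runif(1, 0.5, 3))) *
    exp(-t * runif(1, 0, 0.004)) + runif(1, 1, 5)
  if (jitter) base <- base * runif(length(t), 0.9, 1.1)
  tac(scheme, base, region = region, decay_corrected = TRUE)
}

# a random Patlak fit window guaranteed to contain at least two frame
# mid-times of the 41-frame scheme (dense frames end near 58.5 min)
random_window <- function() {
  start <- runif(1, 1, 55)
  c(start, start + runif(1, 10, 30))
}

# fixed-step RK4 integration of the irreversible two-tissue model driven
# by a continuous plasma function. The running integral of the total
# concentration is carried as a third RK4 state, and steps subdivide each
# frame exactly, so frame averages come straight from the state vector at
# the frame boundaries.
rk4_tissue_oracle <- function(cp_fun, K1, k2, k3, scheme, h = 0.01) {
  beta <- k2 + k3
  deriv <- function(t, y) c(K1 * cp_fun(t) - beta * y[1],
                            k3 * y[1],
                            y[1] + y[2])
  y <- c(0, 0, 0)
  out <- numeric(nrow(scheme))
  for (f in seq_len(nrow(scheme))) {
    t0 <- scheme$start_s[f] / 60
    dur <- scheme$duration_s[f] / 60
    nstep <- ceiling(dur / h)
    hf <- dur / nstep
    cum0 <- y[3]
    for (i in seq_len(nstep)) {
      tt <- t0 + (i - 1) * hf
      k_1 <- deriv(tt, y)
      k_2 <- deriv(tt + hf / 2, y + hf / 2 * k_1)
      k_3 <- deriv(tt + hf / 2, y + hf / 2 * k_2)
      k_4 <- deriv(tt + hf, y + hf * k_3)
      y <- y + hf / 6 * (k_1 + 2 * k_2 + 2 * k_3 + k_4)
    }
    out[f] <- (y[3] - cum0) / dur
  }
  out
}

# closed-form OLS from raw sums (normal equations)
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * sum(y^2) - sy^2))
  list(slope = slope, intercept = intercept, r = r)
}

# one-way ANOVA F from the explicit sums-of-squares decomposition
anova_ss_oracle <- function(groups) {
  y <- unlist(groups, use.names = FALSE)
  N <- length(y); k <- length(groups)
  gm <- mean(y)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - gm)^2, numeric(1)))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  (ss_between / (k - 1)) / (ss_within / (N - k))
}

# one-sample t on the pairwise differences, from first principles
paired_t_oracle <- function(x, y) {
  d <- x - y
  n <- length(d)
  mean(d) / (sd(d) / sqrt(n))
}

# Dunnett null max-|t| distribution by brute force: simulate raw normal
# data for control + treatment groups, compute the many-to-one t
# statistics with the pooled SD estimated from the simulated data, and
# return the adjusted p for each observed |t|
dunnett_raw_oracle <- function(t_obs, n0, ni, ndraw = 1e6,
                               chunk = 2.5e5) {
  k <- length(ni)
  df <- n0 + sum(ni) - (k + 1)
  exceed <- numeric(length(t_obs))
  done <- 0
  while (done < ndraw) {
    m <- min(chunk, ndraw - done)
    grp_stats <- function(n) {
      X <- matrix(rnorm(m * n), m, n)
      mu <- rowMeans(X)
      list(mu = mu, ss = rowSums((X - mu)^2))
    }
    ctrl <- grp_stats(n0)
    trt <- lapply(ni, grp_stats)
    ss <- ctrl$ss + Reduce(`+`, lapply(trt, `[[`, "ss"))
    s <- sqrt(ss / df)
    maxT <- rep(0, m)
    for (j in seq_len(k)) {
      tj <- abs((trt[[j]]$mu - ctrl$mu) /
                  (s * sqrt(1 / ni[j] + 1 / n0)))
      maxT <- pmax(maxT, tj)
    }
    for (i in seq_along(t_obs))
      exceed[i] <- exceed[i] + sum(maxT >= abs(t_obs[i]))
    done <- done + m
  }
  exceed / ndraw
}
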