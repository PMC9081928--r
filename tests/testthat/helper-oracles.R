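# Independent oracles, deliberately naive: straightforward loops and
# textbook formulas, sharing no code with the implementation.

# rectangle-sum AUC: interval * sum of positive exceedances below threshold
oracle_auc <- function(temps, threshold, interval = 5) {
  total <- 0
  for (t in temps) if (t < threshold) total <- total + (threshold - t)
  interval * total
}

# Welch's t from first principles
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

# Pearson r via explicit sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# type-7 quantile by hand: h = (n-1)p + 1, interpolate order statistics
oracle_quantile7 <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# argmin of a + b x + c x^2 over a fine grid
oracle_grid_argmin <- function(a, b, c, lo, hi, n_grid = 200001) {
  g <- seq(lo, hi, length.out = n_grid)
  g[which.min(a + b * g + c * g^2)]
}

# constant-temperature series over the full 3-h window
const_series <- function(temp, id = "p1", group = "control", n = 37) {
  temperature_series(id, group, seq(0, by = 5, length.out = n), rep(temp, n))
}

# baseline until t_step, then constant low temperature
step_series <- function(t_step = 40, low = 24, base = 37, id = "p1") {
  times <- seq(0, 180, 5)
  temperature_series(id, "hypothermia", times, ifelse(times < t_step, base, low))
}
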