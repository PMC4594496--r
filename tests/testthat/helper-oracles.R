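# Independent oracles used to cross-check the implementation.

# Brute-force count of complete cycles: strict local maxima of the raw
# (noiseless) vertical signal, scanned sample by sample.
oracle_cycle_count <- function(y) {
  peaks <- 0L
  for (i in 2:(length(y) - 1L))
    if (y[i] >= y[i - 1L] && y[i] > y[i + 1L]) peaks <- peaks + 1L
  max(0L, peaks - 1L)
}

# Expected OI of a noiseless ellipse with lateral/vertical semi-axes (a, b),
# by numerical integration of sd(x) over one period (population SD of
# a*cos(2*pi*t) on [0, 1]) against the vertical semi-extent b.
oracle_ellipse_oi <- function(a, b) {
  mean_x <- stats::integrate(function(t) a * cos(2 * pi * t), 0, 1)$value
  var_x <- stats::integrate(function(t) (a * cos(2 * pi * t) - mean_x)^2,
                            0, 1)$value
  100 * sqrt(var_x) / (b / sqrt(2))
}

# Straightforward per-cycle OI, written independently of the package
# internals: the same 0.1 s centered moving average (edge windows shrink at
# the boundaries) applied sample by sample, population SD by explicit sums.
oracle_per_cycle_oi <- function(traj, cycles, window_s = 0.1) {
  n <- nrow(traj)
  half <- (max(1L, round(window_s / stats::median(diff(traj$time_s)))) -
             1L) %/% 2L
  smooth1 <- function(v) vapply(seq_len(n), function(i)
    mean(v[max(1L, i - half):min(n, i + half)]), numeric(1))
  xs <- smooth1(traj$x_mm)
  ys <- smooth1(traj$y_mm)
  vapply(seq_len(nrow(cycles)), function(k) {
    idx <- cycles$start[k]:(cycles$end[k] - 1L)
    x <- xs[idx]
    m <- sum(x) / length(x)
    sdx <- sqrt(sum((x - m)^2) / length(x))
    h <- (max(ys[idx]) - min(ys[idx])) / 2
    100 * sdx / (h / sqrt(2))
  }, numeric(1))
}

# Closed-form unstandardized difference test.
oracle_udt <- function(x, y, mx, sx, my, sy, r, n) {
  ((x - y) - (mx - my)) / (sqrt(sx^2 + sy^2 - 2 * r * sx * sy) *
                             sqrt((n + 1) / n))
}

# Large-n asymptotic form of the standardized-difference statistic.
oracle_rsdt_asymptotic <- function(zx, zy, r, n) {
  (zx - zy) / sqrt(2 - 2 * r) * sqrt(n / (n + 1))
}

printed_norm <- function() normative_summary(5.5, 1.5, 13.4, 8.4,
                                             r = 0.8, n = 12)

# Evaluate `code` under set.seed(seed), restoring the caller's RNG stream.
with_seed_restore <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}
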