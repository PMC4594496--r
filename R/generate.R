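#' Generate one hand's stroke series
#'
#' Simulates continuous drawing of either vertical lines or circles as
#' harmonic motion, uniformly sampled. A line is vertical harmonic motion in
#' y with lateral displacement `ovalization_ratio * amplitude` times the
#' circular-phase x-component; a circle is uniform circular motion of radius
#' `amplitude`. Isotropic Gaussian jitter of SD `noise_sd` is added to both
#' coordinates.
#'
#' @param params A [trajectory_params()] object.
#' @param shape `"line"` or `"circle"`.
#' @param duration Stroke series length in seconds (> 0). The sample count is
#'   `floor(duration * sampling_rate)`.
#' @param phase Starting phase in radians (default 0).
#' @param t_offset Time of the first sample, in seconds from session start.
#'
#' @return A data frame with columns `time_s`, `x_mm`, `y_mm`.
#' @examples
#' p <- trajectory_params(amplitude = 50, frequency = 1, noise_sd = 0)
#' circ <- generate_stroke_series(p, "circle", duration = 15)
#' range(sqrt(circ$x_mm^2 + circ$y_mm^2))  # all samples at radius 50
#' @export
generate_stroke_series <- function(params, shape = c("line", "circle"),
                                   duration, phase = 0, t_offset = 0) {
  shape <- match.arg(shape)
  if (!inherits(params, "trajectory_params"))
    params <- do.call(trajectory_params, as.list(params))
  if (!is.numeric(duration) || length(duration) != 1L ||
      !is.finite(duration) || duration <= 0)
    stop_invalid_parameter("`duration` must be a positive number of seconds")
  n <- floor(duration * params$sampling_rate)
  t_rel <- (seq_len(n) - 1L) / params$sampling_rate
  ang <- 2 * pi * params$frequency * t_rel + phase
  if (shape == "circle") {
    x <- params$amplitude * cos(ang)
    y <- params$amplitude * sin(ang)
  } else {
    x <- params$ovalization_ratio * params$amplitude * cos(ang)
    y <- params$amplitude * sin(ang)
  }
  if (params$noise_sd > 0) {
    noise <- with_preserved_seed(params$seed,
                                 stats::rnorm(2L * n, 0, params$noise_sd))
    x <- x + noise[seq_len(n)]
    y <- y + noise[n + seq_len(n)]
  }
  data.frame(time_s = t_offset + t_rel, x_mm = x, y_mm = y)
}

#' Generate a full two-hand drawing session
#'
#' Realizes a [session_spec()] timeline with both hands: condition L is
#' right-hand lines alone, C left-hand circles alone, LL both hands drawing
#' lines (congruent), CL left-hand circles with right-hand lines
#' (non-congruent). In CL blocks the right hand's lateral coordinate receives
#' additive contamination equal to `coupling` times the left hand's noiseless
#' circular x-component — the bimanual coupling/interference effect.
#' `coupling = 0` models a patient whose line hand is immune to the circling
#' hand; positive values model the normal interference seen in controls.
#' Rest periods contain no samples.
#'
#' @param spec A [session_spec()].
#' @param left_params,right_params [trajectory_params()] for each hand.
#' @param coupling Fraction in \eqn{[0, 1]}: lateral contamination of the
#'   right (line) hand by the left (circle) hand in CL blocks. A noiseless
#'   session with line `ovalization_ratio = 0` yields right-hand
#'   OI(CL) − OI(LL) of about `100 * coupling`.
#' @param seed Integer seed governing all per-block noise draws (takes
#'   precedence over the per-hand `seed` fields).
#'
#' @return A data frame (one row per sample) with columns
#'   `time_s`, `x_mm`, `y_mm`, `hand` ("L"/"R"), `block_id`, `condition`.
#' @examples
#' spec <- session_spec(seed = 7)
#' ses <- generate_session(spec, trajectory_params(), trajectory_params(),
#'                         coupling = 0.25, seed = 7)
#' table(unique(ses[c("block_id", "condition")])$condition)
#' @export
generate_session <- function(spec, left_params = trajectory_params(),
                             right_params = trajectory_params(),
                             coupling = 0, seed = NULL) {
  if (!inherits(spec, "session_spec"))
    stop_invalid_parameter("`spec` must be a session_spec")
  if (!is.numeric(coupling) || coupling < 0 || coupling > 1)
    stop_invalid_parameter("`coupling` must lie in [0, 1]")
  blocks <- spec$blocks
  seeds <- block_noise_seeds(seed, nrow(blocks))
  pieces <- vector("list", 2L * nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    right <- left <- NULL
    lp <- left_params;  lp$seed <- seeds[[i]][1L]
    rp <- right_params; rp$seed <- seeds[[i]][2L]
    if (b$condition %in% c("C", "LL", "CL")) {
      lshape <- if (b$condition == "LL") "line" else "circle"
      left <- generate_stroke_series(lp, lshape, b$duration,
                                     t_offset = b$onset)
      left$hand <- "L"
    }
    if (b$condition %in% c("L", "LL", "CL")) {
      right <- generate_stroke_series(rp, "line", b$duration,
                                      t_offset = b$onset)
      if (b$condition == "CL" && coupling > 0) {
        # contamination from the circling hand's noiseless lateral component
        ang <- 2 * pi * lp$frequency *
          (right$time_s - b$onset)
        right$x_mm <- right$x_mm + coupling * lp$amplitude * cos(ang)
      }
      right$hand <- "R"
    }
    for (traj in list(left, right)) {
      if (is.null(traj)) next
      traj$block_id <- b$block_id
      traj$condition <- b$condition
      pieces[[2L * i - as.integer(traj$hand[1L] == "L")]] <- traj
    }
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  rownames(out) <- NULL
  out[order(out$time_s, out$hand), ,
      drop = FALSE][, c("time_s", "x_mm", "y_mm", "hand",
                        "block_id", "condition")]
}

# Deterministic per-(block, hand) noise seeds derived from a master seed.
block_noise_seeds <- function(seed, n_blocks) {
  if (is.null(seed)) return(rep(list(c(NULL, NULL)), n_blocks))
  base <- as.integer(seed) %% 1000003L
  lapply(seq_len(n_blocks),
         function(i) c((base * 131L + 2L * i) %% 2147483562L,
                       (base * 131L + 2L * i + 1L) %% 2147483562L))
}

#' Simulate a normative control cohort
#'
#' Draws `n` control subjects' paired task scores (task x, e.g. LL; task y,
#' e.g. CL) from a bivariate normal with the requested population means, SDs
#' and inter-task correlation, as used to anchor the single-case tests.
#'
#' @param n Number of controls (>= 2).
#' @param mean_x,sd_x Task-x population mean and SD (SD > 0).
#' @param mean_y,sd_y Task-y population mean and SD (SD > 0).
#' @param r Population inter-task correlation, strictly inside (−1, 1).
#' @param seed Integer seed.
#' @param task_x,task_y Task labels carried into the realized summary.
#'
#' @return A list with `scores` (data frame `x`, `y`) and `summary`, a
#'   [normative_summary()] of the realized sample statistics.
#' @examples
#' coh <- generate_normative_cohort(12, 5.5, 1.5, 13.4, 8.4, r = 0.8, seed = 1)
#' coh$summary
#' @export
generate_normative_cohort <- function(n, mean_x, sd_x, mean_y, sd_y, r,
                                      seed = NULL, task_x = "LL",
                                      task_y = "CL") {
  if (!is.numeric(n) || n < 2)
    stop_invalid_parameter("`n` must be >= 2 to form a control sample")
  if (sd_x <= 0 || sd_y <= 0)
    stop_invalid_parameter("target SDs must be positive")
  if (!is.finite(r) || abs(r) >= 1)
    stop_invalid_parameter("`r` must lie strictly inside (-1, 1)")
  sigma <- matrix(c(sd_x^2, r * sd_x * sd_y, r * sd_x * sd_y, sd_y^2), 2L)
  draws <- with_preserved_seed(seed,
    MASS::mvrnorm(n, mu = c(mean_x, mean_y), Sigma = sigma))
  scores <- data.frame(x = draws[, 1L], y = draws[, 2L])
  summ <- normative_summary(
    mean_x = mean(scores$x), sd_x = stats::sd(scores$x),
    mean_y = mean(scores$y), sd_y = stats::sd(scores$y),
    r = stats::cor(scores$x, scores$y), n = as.integer(n),
    task_x = task_x, task_y = task_y)
  list(scores = scores, summary = summ)
}
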