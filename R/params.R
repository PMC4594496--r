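#' Trajectory generator parameters
#'
#' Bundles the kinematic parameters of one hand's drawing behaviour for the
#' synthetic trajectory generator. Lines are vertical harmonic motion;
#' `ovalization_ratio` sets the lateral-to-vertical semi-axis ratio of the
#' drawn path (0 = perfectly straight vertical stroke, 1 = circular).
#'
#' @param amplitude Vertical semi-extent of a stroke, in mm (> 0).
#' @param frequency Drawing cycles per second, in Hz (> 0).
#' @param ovalization_ratio Target lateral/vertical semi-axis ratio, in
#'   \eqn{[0, 1]}. A noiseless line generated with ratio \eqn{\alpha} has
#'   Ovalization Index \eqn{100\alpha}.
#' @param noise_sd Isotropic positional jitter SD, in mm (>= 0).
#' @param sampling_rate Samples per second, in Hz (>= 20; cycle segmentation
#'   needs several samples per cycle).
#' @param seed Optional integer seed; a fixed seed makes generated
#'   trajectories bitwise reproducible.
#'
#' @return An object of class `trajectory_params` (a validated list).
#' @examples
#' trajectory_params(amplitude = 50, frequency = 1, ovalization_ratio = 0.3)
#' @export
trajectory_params <- function(amplitude = 50, frequency = 1,
                              ovalization_ratio = 0, noise_sd = 0,
                              sampling_rate = 100, seed = NULL) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L,
            is.numeric(frequency), length(frequency) == 1L,
            is.numeric(ovalization_ratio), length(ovalization_ratio) == 1L,
            is.numeric(noise_sd), length(noise_sd) == 1L,
            is.numeric(sampling_rate), length(sampling_rate) == 1L)
  if (!is.finite(amplitude) || amplitude <= 0)
    stop_invalid_parameter("`amplitude` must be a positive number (mm)")
  if (!is.finite(frequency) || frequency <= 0)
    stop_invalid_parameter("`frequency` must be a positive number (Hz)")
  if (!is.finite(ovalization_ratio) ||
      ovalization_ratio < 0 || ovalization_ratio > 1)
    stop_invalid_parameter("`ovalization_ratio` must lie in [0, 1]")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop_invalid_parameter("`noise_sd` must be >= 0 (mm)")
  if (!is.finite(sampling_rate) || sampling_rate < 20)
    stop_invalid_parameter("`sampling_rate` must be >= 20 Hz")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(amplitude = amplitude, frequency = frequency,
                 ovalization_ratio = ovalization_ratio, noise_sd = noise_sd,
                 sampling_rate = sampling_rate, seed = seed),
            class = "trajectory_params")
}

#' Block-design session specification
#'
#' Builds the paradigm's block timeline: an initial rest, experimental blocks
#' (conditions L, C, LL, CL) alternating with equal-length rest blocks, and a
#' final rest. The condition order is a seeded pseudo-random shuffle
#' constrained to at most three consecutive identical conditions.
#'
#' @param n_reps Repetitions per condition (default 6, giving 24 blocks).
#' @param block_duration Experimental block length in seconds (default 15).
#' @param rest_duration Interleaved rest length in seconds (default 15).
#' @param initial_rest,final_rest Leading/trailing rest in seconds (default 30).
#' @param conditions Character vector of condition labels.
#' @param seed Integer seed for the block-order shuffle.
#'
#' @return An object of class `session_spec`: a list with a `blocks`
#'   data frame (`block_id`, `condition`, `onset`, `duration`) and the timing
#'   fields, plus `total_duration`.
#' @examples
#' spec <- session_spec(seed = 1)
#' table(spec$blocks$condition)
#' spec$total_duration  # 765 s under the defaults
#' @export
session_spec <- function(n_reps = 6, block_duration = 15, rest_duration = 15,
                         initial_rest = 30, final_rest = 30,
                         conditions = c("L", "C", "LL", "CL"), seed = 1L) {
  stopifnot(n_reps >= 1, block_duration > 0, rest_duration >= 0,
            initial_rest >= 0, final_rest >= 0)
  if (!all(conditions %in% c("L", "C", "LL", "CL")))
    stop_invalid_parameter("conditions must be drawn from {L, C, LL, CL}")
  order <- shuffle_conditions(rep(conditions, each = n_reps), seed = seed,
                              max_run = 3L)
  n_blocks <- length(order)
  onset <- initial_rest + (seq_len(n_blocks) - 1L) *
    (block_duration + rest_duration)
  blocks <- data.frame(block_id = seq_len(n_blocks), condition = order,
                       onset = onset, duration = block_duration,
                       stringsAsFactors = FALSE)
  total <- initial_rest + n_blocks * block_duration +
    (n_blocks - 1L) * rest_duration + final_rest
  structure(list(blocks = blocks, n_reps = n_reps,
                 block_duration = block_duration,
                 rest_duration = rest_duration,
                 initial_rest = initial_rest, final_rest = final_rest,
                 seed = as.integer(seed), total_duration = total),
            class = "session_spec")
}

# Seeded shuffle with a cap on consecutive identical labels (rejection
# sampling; deterministic given the seed).
shuffle_conditions <- function(labels, seed, max_run = 3L) {
  with_preserved_seed(seed, {
    repeat {
      cand <- sample(labels)
      runs <- rle(cand)$lengths
      if (max(runs) <= max_run) return(cand)
    }
  })
}

# Run `expr` under set.seed(seed) without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_invalid_parameter <- function(msg) {
  stop(errorCondition(msg, class = c("cl_invalid_parameter", "error")))
}

stop_no_cycle <- function(msg = "no complete drawing cycle in trajectory") {
  stop(errorCondition(msg, class = c("cl_no_cycle", "error")))
}

#' @export
print.session_spec <- function(x, ...) {
  cat("Circles-Lines session spec:", nrow(x$blocks), "experimental blocks (",
      paste(names(table(x$blocks$condition)), table(x$blocks$condition),
            sep = "=", collapse = ", "),
      "),", x$block_duration, "s each;", "total", x$total_duration, "s\n")
  invisible(x)
}

#' @export
print.trajectory_params <- function(x, ...) {
  cat(sprintf(
    "trajectory_params: amplitude %g mm, frequency %g Hz, ovalization %g, noise SD %g mm, %g Hz sampling\n",
    x$amplitude, x$frequency, x$ovalization_ratio, x$noise_sd,
    x$sampling_rate))
  invisible(x)
}
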