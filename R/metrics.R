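#' Segment a trajectory into drawing cycles
#'
#' A cycle is the half-open sample interval between two successive qualifying
#' maxima of the (smoothed) vertical coordinate: `[max_i, max_{i+1})`. The
#' vertical signal is smoothed with a moving average over `smooth_window`
#' seconds, and extrema must drop by at least `min_prominence` times the
#' block's vertical range on both sides to qualify, which excludes jitter
#' extrema. On a plateau the first sample is taken as the extremum. Only
#' complete cycles are returned.
#'
#' @param traj Data frame with strictly increasing `time_s` and columns
#'   `x_mm`, `y_mm` for a single hand within a single block.
#' @param smooth_window Moving-average window in seconds (default 0.1).
#' @param min_prominence Minimum extremum prominence as a fraction of the
#'   block's vertical range (default 0.05).
#'
#' @return A data frame with one row per complete cycle: `start`, `end`
#'   (sample indices, half-open `[start, end)`), `t_start`, `t_end`,
#'   `duration`. Zero rows when fewer than two qualifying maxima exist.
#' @examples
#' p <- trajectory_params(frequency = 1.3, noise_sd = 0)
#' cyc <- segment_cycles(generate_stroke_series(p, "circle", 15))
#' nrow(cyc)  # floor(19.5) = 19 complete cycles
#' @export
segment_cycles <- function(traj, smooth_window = 0.1, min_prominence = 0.05) {
  validate_trajectory(traj)
  y <- traj$y_mm
  dt <- stats::median(diff(traj$time_s))
  w <- max(1L, round(smooth_window / dt))
  ys <- moving_average(y, w)
  rng <- diff(range(ys))
  if (rng <= 0) return(empty_cycles())
  peaks <- find_prominent_maxima(ys, min_prominence * rng)
  if (length(peaks) < 2L) return(empty_cycles())
  starts <- peaks[-length(peaks)]
  ends <- peaks[-1L]
  data.frame(start = starts, end = ends,
             t_start = traj$time_s[starts], t_end = traj$time_s[ends],
             duration = traj$time_s[ends] - traj$time_s[starts])
}

empty_cycles <- function() {
  data.frame(start = integer(), end = integer(), t_start = numeric(),
             t_end = numeric(), duration = numeric())
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(y, w) {
  if (w <= 1L) return(y)
  n <- length(y)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Local maxima of a smoothed oscillatory signal, filtered by topographic
# prominence: each kept peak must rise at least `thr` above its key saddles,
# the minima separating it from the nearest strictly higher sample on each
# side (or the record boundary). Plateau -> first sample.
find_prominent_maxima <- function(y, thr) {
  n <- length(y)
  if (n < 3L) return(integer())
  d <- diff(y)
  # collapse plateaus: sign of the next non-zero difference
  s <- sign(d)
  for (i in rev(seq_len(length(s) - 1L)))
    if (s[i] == 0) s[i] <- s[i + 1L]
  cand <- which(s[-length(s)] > 0 & s[-1L] < 0) + 1L
  # shift plateau maxima to the first sample of the plateau
  for (k in seq_along(cand)) {
    i <- cand[k]
    while (i > 1L && y[i - 1L] == y[i]) i <- i - 1L
    cand[k] <- i
  }
  if (length(cand) == 0L) return(integer())
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    j <- i
    while (j > 1L && y[j - 1L] <= y[i]) j <- j - 1L
    left_saddle <- min(y[j:i])
    j <- i
    while (j < n && y[j + 1L] <= y[i]) j <- j + 1L
    right_saddle <- min(y[i:j])
    keep[k] <- (y[i] - max(left_saddle, right_saddle)) >= thr
  }
  cand[keep]
}

#' Ovalization Index of a drawn trajectory
#'
#' Quantifies the lateral deviation of a nominally vertical stroke. Per
#' cycle, \eqn{OI = 100 \, sd(x - \bar x) / (h/\sqrt 2)}, where `h` is the
#' cycle's vertical semi-extent (half the y-range) and `sd` is the
#' population standard deviation over the cycle's samples. Both coordinates
#' are first smoothed with the same moving average used for cycle
#' segmentation: the filter attenuates the lateral and vertical harmonics
#' of the drawing frequency by an identical factor, so the index is
#' untouched for clean strokes while high-frequency jitter is suppressed.
#' Under this normalization a straight vertical line scores 0, a circle
#' scores exactly 100, and an ellipse with lateral/vertical semi-axis ratio
#' a/b scores 100·a/b. The block value is the mean over complete cycles,
#' clipped to \eqn{[0, 100]} (noise can push sd(x) above the circular
#' bound).
#'
#' @inheritParams segment_cycles
#' @return An object of class `oi_result`: list with `oi`, `n_cycles`,
#'   `frequency_hz`, `per_cycle_oi`.
#' @examples
#' p <- trajectory_params(ovalization_ratio = 0.3, noise_sd = 0)
#' ovalization_index(generate_stroke_series(p, "line", 15))$oi  # ~30
#' @export
ovalization_index <- function(traj, smooth_window = 0.1,
                              min_prominence = 0.05) {
  cyc <- segment_cycles(traj, smooth_window, min_prominence)
  if (nrow(cyc) == 0L) stop_no_cycle()
  dt <- stats::median(diff(traj$time_s))
  w <- max(1L, round(smooth_window / dt))
  xs <- moving_average(traj$x_mm, w)
  ys <- moving_average(traj$y_mm, w)
  per <- rep(NA_real_, nrow(cyc))
  for (k in seq_len(nrow(cyc))) {
    idx <- seq.int(cyc$start[k], cyc$end[k] - 1L)
    h <- diff(range(ys[idx])) / 2
    if (h <= 0) next
    per[k] <- 100 * sd_pop(xs[idx]) / (h / sqrt(2))
  }
  if (all(is.na(per)))
    stop_invalid_parameter("all cycles degenerate (zero vertical extent)")
  if (anyNA(per))
    warning("skipping ", sum(is.na(per)), " degenerate cycle(s)")
  per <- per[!is.na(per)]
  structure(list(oi = min(100, max(0, mean(per))),
                 n_cycles = nrow(cyc),
                 frequency_hz = nrow(cyc) /
                   (cyc$t_end[nrow(cyc)] - cyc$t_start[1L]),
                 per_cycle_oi = per),
            class = "oi_result")
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.oi_result <- function(x, ...) {
  cat(sprintf("OI %.2f over %d cycles (%.3f Hz)\n",
              x$oi, x$n_cycles, x$frequency_hz))
  invisible(x)
}

#' Average drawing frequency of a trajectory
#'
#' Number of complete drawing cycles per second: the cycle count divided by
#' the time spanned by complete cycles, equivalently the inverse of the mean
#' cycle duration.
#'
#' @inheritParams segment_cycles
#' @return Frequency in Hz.
#' @export
drawing_frequency <- function(traj, smooth_window = 0.1,
                              min_prominence = 0.05) {
  cyc <- segment_cycles(traj, smooth_window, min_prominence)
  if (nrow(cyc) == 0L) stop_no_cycle()
  nrow(cyc) / (cyc$t_end[nrow(cyc)] - cyc$t_start[1L])
}

#' Bimanual coupling effect
#'
#' The interference of the circling hand on the line-drawing hand: the
#' increase of the Ovalization Index in the non-congruent (CL) condition
#' over the congruent (LL) condition.
#'
#' @param oi_cl,oi_ll Condition-level OI means, each in \eqn{[0, 100]}.
#' @return `oi_cl - oi_ll`.
#' @examples
#' coupling_effect(11.5, 10.4)  # 1.1
#' @export
coupling_effect <- function(oi_cl, oi_ll) {
  stopifnot(is.numeric(oi_cl), is.numeric(oi_ll))
  if (any(c(oi_cl, oi_ll) < 0) || any(c(oi_cl, oi_ll) > 100))
    stop_invalid_parameter("OI values must lie in [0, 100]")
  oi_cl - oi_ll
}

validate_trajectory <- function(traj) {
  if (!is.data.frame(traj) ||
      !all(c("time_s", "x_mm", "y_mm") %in% names(traj)))
    stop_invalid_parameter(
      "trajectory must be a data frame with time_s, x_mm, y_mm")
  if (nrow(traj) < 2L)
    stop_invalid_parameter("trajectory needs at least 2 samples")
  if (!all(is.finite(traj$x_mm)) || !all(is.finite(traj$y_mm)) ||
      !all(is.finite(traj$time_s)))
    stop_invalid_parameter("trajectory coordinates must be finite")
  if (any(diff(traj$time_s) <= 0))
    stop_invalid_parameter("trajectory times must be strictly increasing")
  invisible(traj)
}

#' Per-block trajectory metrics for one hand
#'
#' Applies [ovalization_index()] to every (block, hand) trajectory of a
#' session and tabulates the results; blocks without a complete cycle are
#' dropped and recorded in the `skipped` attribute rather than silently lost.
#'
#' @param session Long data frame as produced by [generate_session()] or
#'   [read_trajectory_csv()].
#' @param hand Which hand to analyze, `"R"` (default, the line hand) or `"L"`.
#' @inheritParams segment_cycles
#' @return Data frame `block_id`, `condition`, `hand`, `oi`, `n_cycles`,
#'   `frequency_hz`; skipped blocks in `attr(, "skipped")`.
#' @export
block_metrics <- function(session, hand = "R", smooth_window = 0.1,
                          min_prominence = 0.05) {
  stopifnot(hand %in% c("L", "R"))
  sub <- session[session$hand == hand, , drop = FALSE]
  ids <- unique(sub$block_id)
  rows <- vector("list", length(ids))
  skipped <- character()
  for (i in seq_along(ids)) {
    blk <- sub[sub$block_id == ids[i], , drop = FALSE]
    res <- tryCatch(
      ovalization_index(blk, smooth_window, min_prominence),
      cl_no_cycle = function(e) NULL)
    if (is.null(res)) {
      skipped <- c(skipped, sprintf("block %s (%s): no complete cycle",
                                    ids[i], blk$condition[1L]))
      next
    }
    rows[[i]] <- data.frame(block_id = ids[i],
                            condition = blk$condition[1L], hand = hand,
                            oi = res$oi, n_cycles = res$n_cycles,
                            frequency_hz = res$frequency_hz)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(
    block_id = integer(), condition = character(), hand = character(),
    oi = numeric(), n_cycles = integer(), frequency_hz = numeric())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Condition-level OI and frequency scores
#'
#' Averages [block_metrics()] within condition: the condition-level score is
#' the mean over that condition's blocks (six under the default paradigm).
#'
#' @inheritParams block_metrics
#' @param conditions Conditions to keep (default the bimanual pair LL, CL).
#' @return Data frame `condition`, `oi`, `frequency_hz`, `n_blocks`.
#' @export
condition_scores <- function(session, hand = "R",
                             conditions = c("LL", "CL"), ...) {
  bm <- block_metrics(session, hand = hand, ...)
  bm <- bm[bm$condition %in% conditions, , drop = FALSE]
  missing <- setdiff(conditions, bm$condition)
  if (length(missing))
    stop(errorCondition(
      paste0("no analyzable blocks for condition(s) ",
             paste(missing, collapse = ", "), " on hand ", hand),
      class = c("cl_missing_condition", "error")))
  agg <- lapply(split(bm, factor(bm$condition, levels = conditions)),
                function(d) data.frame(condition = d$condition[1L],
                                       oi = mean(d$oi),
                                       frequency_hz = mean(d$frequency_hz),
                                       n_blocks = nrow(d)))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
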