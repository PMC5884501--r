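#' I-VT fixation/saccade segmentation
#'
#' Velocity-threshold segmentation of a gaze recording: per-sample angular
#' velocity is computed by central finite differences (one-sided at the
#' ends), samples below `velocity_threshold_deg_s` are fixation samples and
#' samples above are saccade samples. Contiguous runs form events; fixation
#' runs shorter than `min_fixation_s` are relabelled as saccade samples and
#' merged into their neighbours, the usual guard against drift/tremor
#' flicker. Every valid sample belongs to exactly one event.
#'
#' @param rec a [gaze_recording()] (invalid samples are ignored).
#' @param velocity_threshold_deg_s threshold in deg/s (default 30, the
#'   community default for remote trackers).
#' @param geometry a [screen_geometry()].
#' @param min_fixation_s minimum fixation duration in seconds (default
#'   0.06).
#' @return A list with data frames `fixations` (`start_t`, `end_t`,
#'   `centroid_x`, `centroid_y`, `duration`) and `saccades` (`start_t`,
#'   `end_t`, `amplitude_deg`, `mean_velocity_deg_s`,
#'   `peak_velocity_deg_s`), plus `velocity` (per-sample deg/s) and
#'   `sample_event` (event index per valid sample).
#' @export
ivt_segment <- function(rec, velocity_threshold_deg_s = 30,
                        geometry = screen_geometry(),
                        min_fixation_s = 0.06) {
  stopifnot(inherits(rec, "gaze_recording"))
  s <- rec$samples[rec$samples$valid, , drop = FALSE]
  n <- nrow(s)
  if (n < 2) stop("recording has fewer than 2 valid samples")
  v <- sample_velocity(s$t, s$x, s$y, geometry)
  is_fix <- v < velocity_threshold_deg_s

  run <- rle(is_fix)
  # relabel too-short fixation runs as saccade, then re-run rle to merge
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  for (i in seq_along(run$values)) {
    if (run$values[i] && (s$t[ends[i]] - s$t[starts[i]]) < min_fixation_s)
      is_fix[starts[i]:ends[i]] <- FALSE
  }
  run <- rle(is_fix)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1

  fix_rows <- list(); sac_rows <- list()
  sample_event <- integer(n)
  for (i in seq_along(run$values)) {
    idx <- starts[i]:ends[i]
    sample_event[idx] <- i
    if (run$values[i]) {
      fix_rows[[length(fix_rows) + 1L]] <- data.frame(
        start_t = s$t[starts[i]], end_t = s$t[ends[i]],
        centroid_x = mean(s$x[idx]), centroid_y = mean(s$y[idx]),
        duration = s$t[ends[i]] - s$t[starts[i]])
    } else {
      amp_px <- sqrt((s$x[ends[i]] - s$x[starts[i]])^2 +
                       (s$y[ends[i]] - s$y[starts[i]])^2)
      sac_rows[[length(sac_rows) + 1L]] <- data.frame(
        start_t = s$t[starts[i]], end_t = s$t[ends[i]],
        amplitude_deg = pixels_to_degrees(geometry, amp_px),
        mean_velocity_deg_s = mean(v[idx]),
        peak_velocity_deg_s = max(v[idx]))
    }
  }
  empty_fix <- data.frame(start_t = numeric(0), end_t = numeric(0),
                          centroid_x = numeric(0), centroid_y = numeric(0),
                          duration = numeric(0))
  empty_sac <- data.frame(start_t = numeric(0), end_t = numeric(0),
                          amplitude_deg = numeric(0),
                          mean_velocity_deg_s = numeric(0),
                          peak_velocity_deg_s = numeric(0))
  list(fixations = if (length(fix_rows)) do.call(rbind, fix_rows) else empty_fix,
       saccades = if (length(sac_rows)) do.call(rbind, sac_rows) else empty_sac,
       velocity = v, sample_event = sample_event)
}

# Angular velocity (deg/s) per sample: central difference in the interior,
# one-sided at the two ends.
sample_velocity <- function(t, x, y, geometry) {
  n <- length(t)
  v <- numeric(n)
  if (n >= 3) {
    i <- 2:(n - 1)
    d_px <- sqrt((x[i + 1] - x[i - 1])^2 + (y[i + 1] - y[i - 1])^2)
    v[i] <- pixels_to_degrees(geometry, d_px) / (t[i + 1] - t[i - 1])
  }
  d1 <- sqrt((x[2] - x[1])^2 + (y[2] - y[1])^2)
  v[1] <- pixels_to_degrees(geometry, d1) / (t[2] - t[1])
  dn <- sqrt((x[n] - x[n - 1])^2 + (y[n] - y[n - 1])^2)
  v[n] <- pixels_to_degrees(geometry, dn) / (t[n] - t[n - 1])
  v
}

#' Complex eye-movement (CEM) statistics of one recording
#'
#' Eleven fixation/saccade summary scalars: fixation count, mean/sd
#' fixation duration, mean/sd saccade amplitude, duration, mean velocity
#' and peak velocity (population sd; sd is 0 for a single event). An empty
#' event class yields zeros and is flagged.
#'
#' @param fixations,saccades event data frames from [ivt_segment()].
#' @return Named numeric vector of length 11 with attribute `flags`
#'   (`no_fixations`, `no_saccades`).
#' @export
cem_features <- function(fixations, saccades) {
  pop_sd <- function(v) if (length(v) <= 1) 0 else sqrt(mean((v - mean(v))^2))
  mz <- function(v) if (length(v) == 0) 0 else mean(v)
  sac_dur <- saccades$end_t - saccades$start_t
  out <- c(fixation_count = nrow(fixations),
           fix_duration_mean = mz(fixations$duration),
           fix_duration_sd = pop_sd(fixations$duration),
           sacc_amplitude_mean = mz(saccades$amplitude_deg),
           sacc_amplitude_sd = pop_sd(saccades$amplitude_deg),
           sacc_duration_mean = mz(sac_dur),
           sacc_duration_sd = pop_sd(sac_dur),
           sacc_mean_velocity_mean = mz(saccades$mean_velocity_deg_s),
           sacc_mean_velocity_sd = pop_sd(saccades$mean_velocity_deg_s),
           sacc_peak_velocity_mean = mz(saccades$peak_velocity_deg_s),
           sacc_peak_velocity_sd = pop_sd(saccades$peak_velocity_deg_s))
  attr(out, "flags") <- c(no_fixations = nrow(fixations) == 0,
                          no_saccades = nrow(saccades) == 0)
  out
}
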