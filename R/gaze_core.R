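#' Construct a gaze recording
#'
#' A gaze recording is an ordered sequence of timestamped gaze samples for
#' one subject answering one question. Coordinates follow the common
#' eye-tracker export convention: origin at the top-left of the screen,
#' x rightward, y downward, 0-based pixels. Binocular data are assumed to
#' be pre-averaged into a single gaze stream.
#'
#' @param t numeric vector of timestamps in seconds, strictly increasing,
#'   all >= 0.
#' @param x,y numeric gaze position in screen pixels.
#' @param valid logical validity flags (tracker-reported sample quality).
#' @param rate_hz nominal sampling rate in Hz.
#' @param subject_id,question_id opaque labels.
#' @param trial trial index (1 or 2 in a two-visit study design).
#' @return An object of class `gaze_recording`: a list with a `samples`
#'   data frame (`t`, `x`, `y`, `valid`) plus metadata fields.
#' @export
gaze_recording <- function(t, x, y, valid = rep(TRUE, length(t)),
                           rate_hz = 300, subject_id = "s1",
                           question_id = "q1", trial = 1L) {
  n <- length(t)
  stopifnot(length(x) == n, length(y) == n, length(valid) == n, n >= 1)
  if (any(t < 0)) stop("timestamps must be >= 0")
  if (n > 1 && any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  structure(
    list(samples = data.frame(t = as.numeric(t), x = as.numeric(x),
                              y = as.numeric(y), valid = as.logical(valid)),
         rate_hz = rate_hz, subject_id = as.character(subject_id),
         question_id = as.character(question_id), trial = as.integer(trial)),
    class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> subject %s, trial %d, question %s: %d samples @ %g Hz (%.1f%% valid)\n",
              x$subject_id, x$trial, x$question_id, nrow(x$samples),
              x$rate_hz, 100 * mean(x$samples$valid)))
  invisible(x)
}

n_valid_samples <- function(rec) sum(rec$samples$valid)

#' Write gaze recordings to CSV
#'
#' Emits the package's gaze CSV dialect: comma-separated, UTF-8, '.'
#' decimal, header `subject,trial,question,t,x,y,valid,rate_hz`. The
#' `rate_hz` column is repeated per row so the file round-trips without
#' side information.
#'
#' @param recordings a list of [gaze_recording()] objects (non-empty).
#' @param path output file path.
#' @return `invisible(path)`.
#' @seealso [read_gaze_csv()]
#' @export
write_gaze_csv <- function(recordings, path) {
  if (inherits(recordings, "gaze_recording")) recordings <- list(recordings)
  if (length(recordings) == 0) stop("no recordings to write")
  num <- function(v) sprintf("%.17g", v)  # bit-exact round trip
  rows <- lapply(recordings, function(r) {
    data.frame(subject = r$subject_id, trial = r$trial,
               question = r$question_id, t = num(r$samples$t),
               x = num(r$samples$x), y = num(r$samples$y),
               valid = r$samples$valid, rate_hz = num(r$rate_hz))
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gaze recordings from CSV
#'
#' Reads the dialect written by [write_gaze_csv()] and returns one
#' recording per (subject, trial, question) group, samples sorted by
#' timestamp. Rows duplicating a timestamp within a group are rejected
#' with a warning.
#'
#' @param path input file path.
#' @param default_rate_hz sampling rate assumed when the file has no
#'   `rate_hz` column.
#' @return A list of [gaze_recording()] objects.
#' @export
read_gaze_csv <- function(path, default_rate_hz = 300) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject", "trial", "question", "t", "x", "y", "valid")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("gaze CSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0) stop("empty gaze file: ", path)
  if (!"rate_hz" %in% names(df)) df$rate_hz <- default_rate_hz
  key <- interaction(df$subject, df$trial, df$question, drop = TRUE)
  groups <- split(df, key)
  out <- lapply(groups, function(g) {
    g <- g[order(g$t), , drop = FALSE]
    dup <- duplicated(g$t)
    if (any(dup)) {
      warning(sprintf("dropped %d duplicated-timestamp row(s) in group %s/%s/%s",
                      sum(dup), g$subject[1], g$trial[1], g$question[1]))
      g <- g[!dup, , drop = FALSE]
    }
    gaze_recording(g$t, g$x, g$y, as.logical(g$valid),
                   rate_hz = g$rate_hz[1], subject_id = g$subject[1],
                   question_id = g$question[1], trial = g$trial[1])
  })
  names(out) <- NULL
  out
}

#' Drop invalid samples and report validity
#'
#' @param rec a [gaze_recording()].
#' @return A list with `recording` (valid samples only) and `report`, a
#'   list with `fraction_valid`, `n_total` and `n_valid`.
#' @export
filter_validity <- function(rec) {
  stopifnot(inherits(rec, "gaze_recording"))
  n_total <- nrow(rec$samples)
  keep <- rec$samples$valid
  n_valid <- sum(keep)
  if (n_valid == 0) stop("recording has no valid samples")
  out <- rec
  out$samples <- rec$samples[keep, , drop = FALSE]
  rownames(out$samples) <- NULL
  list(recording = out,
       report = list(fraction_valid = n_valid / n_total,
                     n_total = n_total, n_valid = n_valid))
}

#' Temporally downsample a recording by decimation
#'
#' Keeps every k-th sample starting from the first, where
#' `k = rate_hz / target_hz` must be an integer. Pure decimation (no
#' anti-alias filtering) is used, the conservative reading of generating a
#' lower-rate tracker from a higher-rate one.
#'
#' @param rec a [gaze_recording()].
#' @param target_hz target sampling rate; must divide `rec$rate_hz`.
#' @return The decimated [gaze_recording()] with `rate_hz` updated.
#' @export
downsample_gaze <- function(rec, target_hz) {
  stopifnot(inherits(rec, "gaze_recording"), target_hz > 0)
  k <- rec$rate_hz / target_hz
  if (abs(k - round(k)) > 1e-9)
    stop(sprintf("unsupported rate: %g Hz is not an integer decimation of %g Hz",
                 target_hz, rec$rate_hz))
  k <- as.integer(round(k))
  out <- rec
  out$samples <- rec$samples[seq(1, nrow(rec$samples), by = k), , drop = FALSE]
  rownames(out$samples) <- NULL
  out$rate_hz <- target_hz
  out
}

#' Add Gaussian spatial noise to a recording
#'
#' Adds independent zero-mean Gaussian noise to the x and y coordinates of
#' every valid sample, with per-axis standard deviation `sd_deg` converted
#' to pixels via [degrees_to_pixels()]. Emulates a tracker with degraded
#' spatial accuracy. Noised samples are not clamped to the screen bounds
#' (rendering clips instead), so the noise distribution is preserved.
#'
#' @param rec a [gaze_recording()].
#' @param sd_deg noise standard deviation in degrees of visual angle (>= 0).
#' @param geometry a [screen_geometry()].
#' @param seed integer seed; the same seed reproduces the same noise.
#' @return The noised [gaze_recording()]; timestamps and validity flags are
#'   unchanged.
#' @export
add_spatial_noise <- function(rec, sd_deg, geometry, seed = 1L) {
  stopifnot(inherits(rec, "gaze_recording"))
  if (sd_deg < 0) stop("sd_deg must be >= 0")
  if (sd_deg == 0) return(rec)
  sd_px <- degrees_to_pixels(geometry, sd_deg)
  out <- rec
  idx <- which(rec$samples$valid)
  with_seed(seed, {
    out$samples$x[idx] <- rec$samples$x[idx] + rnorm(length(idx), 0, sd_px)
    out$samples$y[idx] <- rec$samples$y[idx] + rnorm(length(idx), 0, sd_px)
  })
  out
}
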