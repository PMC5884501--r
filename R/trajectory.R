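#' Render gaze recordings as a square grayscale trajectory image
#'
#' Maps the full screen rectangle onto an `size_px` x `size_px` canvas
#' (anisotropically: x scaled by `size_px / width_px`, y by
#' `size_px / height_px`) and connects consecutive valid samples with
#' 1-pixel Bresenham lines. Each traversal adds `increment` to every pixel
#' on the line, and intensities are clipped at 1, producing the multi-level
#' gray trace that texture extraction operates on. Samples falling outside
#' the screen are clipped (they break the line chain, as do invalid
#' samples; gaps are never bridged).
#'
#' @param recs a [gaze_recording()] or list of recordings rendered onto one
#'   canvas.
#' @param size_px canvas side length N (>= 32; 64/128/256 are the usual
#'   working sizes).
#' @param geometry a [screen_geometry()].
#' @param increment intensity added per traversal of a pixel (default 0.25).
#' @return An object of class `trajectory_image`: list with `pixels`
#'   (N x N matrix in `[0, 1]`, rows = y), `size_px` and `provenance`.
#' @export
render_trajectory <- function(recs, size_px = 128,
                              geometry = screen_geometry(),
                              increment = 0.25) {
  if (inherits(recs, "gaze_recording")) recs <- list(recs)
  stopifnot(size_px >= 32, increment > 0)
  n_ok <- sum(vapply(recs, n_valid_samples, numeric(1)))
  if (n_ok < 2) stop("need at least 2 valid samples to render a trajectory")
  sx <- size_px / geometry$width_px
  sy <- size_px / geometry$height_px
  seg <- list(x0 = integer(0), y0 = integer(0),
              x1 = integer(0), y1 = integer(0))
  for (r in recs) {
    s <- r$samples
    on_screen <- s$valid & s$x >= 0 & s$x < geometry$width_px &
      s$y >= 0 & s$y < geometry$height_px
    cx <- floor(s$x * sx); cy <- floor(s$y * sy)
    ok <- on_screen[-nrow(s)] & on_screen[-1]   # both endpoints usable
    if (!any(ok)) next
    i <- which(ok)
    seg$x0 <- c(seg$x0, cx[i]);     seg$y0 <- c(seg$y0, cy[i])
    seg$x1 <- c(seg$x1, cx[i + 1]); seg$y1 <- c(seg$y1, cy[i + 1])
  }
  if (length(seg$x0) == 0) stop("no drawable segments (all samples off-screen?)")
  px <- render_accumulate_cpp(as.integer(seg$x0), as.integer(seg$y0),
                              as.integer(seg$x1), as.integer(seg$y1),
                              as.integer(size_px), increment)
  structure(list(pixels = px, size_px = as.integer(size_px),
                 provenance = vapply(recs, function(r)
                   paste(r$subject_id, r$trial, r$question_id, sep = "/"),
                   character(1))),
            class = "trajectory_image")
}

#' @export
print.trajectory_image <- function(x, ...) {
  cat(sprintf("<trajectory_image> %dx%d, %d nonzero px, mean gray %.4f\n",
              x$size_px, x$size_px, sum(x$pixels > 0), mean(x$pixels)))
  invisible(x)
}

#' Gray-image (GI) control features
#'
#' The mean and population standard deviation of all pixel intensities of a
#' trajectory image. These two numbers summarize only the gross amount and
#' spread of "ink" and serve as a control feature set: a matcher driven by
#' them should perform near chance if the texture features carry the real
#' biometric signal.
#'
#' @param img a [render_trajectory()] image.
#' @return Named numeric vector `c(mean_gray, std_gray)`.
#' @export
gi_features <- function(img) {
  stopifnot(inherits(img, "trajectory_image"))
  v <- as.numeric(img$pixels)
  m <- mean(v)
  c(mean_gray = m, std_gray = sqrt(mean((v - m)^2)))
}

#' Export a trajectory image as 8-bit grayscale PNG
#'
#' Pixel values are `round(255 * intensity)` rescaled to PNG's unit range.
#'
#' @param img a [render_trajectory()] image.
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_trajectory_png <- function(img, path) {
  stopifnot(inherits(img, "trajectory_image"))
  png::writePNG(round(255 * img$pixels) / 255, target = path)
  invisible(path)
}
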