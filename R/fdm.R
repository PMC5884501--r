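#' Build a fixation density map
#'
#' Duration-weighted 2-D histogram of fixation centroids on a
#' `grid_size` x `grid_size` grid covering the full screen, optionally
#' Gaussian-smoothed (separable kernel, sd in grid cells), renormalized to
#' sum 1. A probabilistic representation of where (and for how long) a
#' subject fixated.
#'
#' @param fixations fixation data frame from [ivt_segment()] (>= 1 row).
#' @param grid_size grid side length (default 64).
#' @param smoothing_sigma cells of Gaussian smoothing; 0 disables.
#' @param geometry a [screen_geometry()].
#' @return A `fixation_density_map`: list with `weights` (grid matrix,
#'   rows = y, summing to 1), `grid_size`, `smoothing_sigma`.
#' @export
fdm_build <- function(fixations, grid_size = 64, smoothing_sigma = 1,
                      geometry = screen_geometry()) {
  if (nrow(fixations) == 0) stop("need at least one fixation")
  if (sum(fixations$duration) <= 0) stop("total fixation duration is zero")
  gx <- pmin(pmax(floor(fixations$centroid_x * grid_size / geometry$width_px),
                  0), grid_size - 1) + 1
  gy <- pmin(pmax(floor(fixations$centroid_y * grid_size / geometry$height_px),
                  0), grid_size - 1) + 1
  w <- matrix(0, grid_size, grid_size)
  for (i in seq_len(nrow(fixations)))
    w[gy[i], gx[i]] <- w[gy[i], gx[i]] + fixations$duration[i]
  if (smoothing_sigma > 0) {
    hw <- ceiling(3 * smoothing_sigma)
    k <- dnorm(seq(-hw, hw), sd = smoothing_sigma)
    k <- k / sum(k)
    w <- apply(w, 2, conv1d_zero, k = k)      # smooth columns (y)
    w <- t(apply(w, 1, conv1d_zero, k = k))   # smooth rows (x)
  }
  structure(list(weights = w / sum(w), grid_size = as.integer(grid_size),
                 smoothing_sigma = smoothing_sigma),
            class = "fixation_density_map")
}

# 1-D zero-padded convolution with a centered odd kernel.
conv1d_zero <- function(v, k) {
  hw <- (length(k) - 1) / 2
  padded <- c(rep(0, hw), v, rep(0, hw))
  vapply(seq_along(v), function(i) sum(padded[i:(i + 2 * hw)] * rev(k)),
         numeric(1))
}

#' Similarity between two fixation density maps
#'
#' Three metrics, all oriented so larger = more similar:
#' `SIM = sum(min(p, q))` (histogram intersection, in `[0, 1]`), `PCC`
#' (Pearson correlation over flattened cells), and `KLD` (symmetrized
#' Kullback-Leibler divergence with an epsilon floor, returned negated).
#'
#' @param p,q `fixation_density_map`s on the same grid.
#' @param metric `"SIM"` (default), `"PCC"` or `"KLD"`.
#' @param eps probability floor for KLD.
#' @return Scalar similarity.
#' @export
fdm_similarity <- function(p, q, metric = c("SIM", "PCC", "KLD"),
                           eps = 1e-12) {
  stopifnot(inherits(p, "fixation_density_map"),
            inherits(q, "fixation_density_map"))
  if (p$grid_size != q$grid_size) stop("density maps are on different grids")
  metric <- match.arg(metric)
  a <- as.numeric(p$weights); b <- as.numeric(q$weights)
  switch(metric,
    SIM = sum(pmin(a, b)),
    PCC = cor(a, b),
    KLD = {
      a2 <- pmax(a, eps); a2 <- a2 / sum(a2)
      b2 <- pmax(b, eps); b2 <- b2 / sum(b2)
      -(0.5 * sum(a2 * log(a2 / b2)) + 0.5 * sum(b2 * log(b2 / a2)))
    })
}
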