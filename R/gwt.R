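#' Gabor filter-bank configuration
#'
#' The texture extractor uses a bank of complex Gabor wavelets on a
#' half-octave frequency ladder `f_i = f_max / spacing^(i-1)` (default
#' `f_max = 0.5` cycles/pixel, `spacing = sqrt(2)`, 11 scales) crossed with
#' 8 orientations `theta_j = pi * (j-1) / 8`, i.e. 88 kernels. With the
#' defaults the lowest frequency is `0.5 / sqrt(2)^10 = 1/64 = 4/256`
#' cycles/pixel, the classical lower design bound `f >= 4/N` for images up
#' to `N = 256`. The envelope parameters are `gamma = 1`, `eta = 2`,
#' `sigma = 1/f`, phase `phi = 0`.
#'
#' Two envelope variants are supported. `"as-printed"` follows the kernel
#' equation with `eta` only in the amplitude prefactor and `gamma` only in
#' the exponent,
#' `G(x,y) = f^2/(pi*gamma*eta) * exp(-(x'^2 + gamma^2 y'^2)/(2 sigma^2)) *
#' exp(i(2 pi f x' + phi))`; `"standard"` uses the conventional
#' anisotropic form `exp(-(f^2/gamma^2) x'^2 - (f^2/eta^2) y'^2)` with the
#' same prefactor. `x', y'` are the coordinates rotated by `theta`.
#'
#' @param n_scales,n_orientations bank dimensions (defaults 11 and 8).
#' @param f_max highest frequency in cycles/pixel (must be in (0, 0.5]).
#' @param spacing frequency ratio between adjacent scales.
#' @param gamma,eta,phi envelope/phase parameters.
#' @param variant `"as-printed"` (default) or `"standard"`.
#' @return A `gabor_bank_config` list.
#' @export
gabor_bank_config <- function(n_scales = 11, n_orientations = 8,
                              f_max = 0.5, spacing = sqrt(2),
                              gamma = 1, eta = 2, phi = 0,
                              variant = c("as-printed", "standard")) {
  stopifnot(n_scales >= 1, n_orientations >= 1, f_max > 0, f_max <= 0.5,
            spacing > 1, gamma > 0, eta > 0)
  structure(list(n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 f_max = f_max, spacing = spacing, gamma = gamma, eta = eta,
                 phi = phi, variant = match.arg(variant)),
            class = "gabor_bank_config")
}

bank_frequencies <- function(cfg) {
  cfg$f_max / cfg$spacing^(seq_len(cfg$n_scales) - 1)
}

#' Sample one complex Gabor kernel
#'
#' Evaluates the configured Gabor wavelet at frequency `f` and orientation
#' `theta` on an odd-sized grid of half-width `ceil(3 * sigma)` with
#' `sigma = 1/f` (the envelope has decayed to ~1% of its peak at the grid
#' edge). Grid x runs along matrix columns, y along rows, so the kernel
#' matrix convolves directly with a trajectory-image matrix.
#'
#' @param f spatial frequency in cycles/pixel, in (0, 0.5].
#' @param theta orientation in radians.
#' @param cfg a [gabor_bank_config()].
#' @return A `gabor_kernel`: list with `f`, `theta`, `sigma`, half-width
#'   `hw` and the complex `values` matrix.
#' @export
gabor_kernel <- function(f, theta, cfg = gabor_bank_config()) {
  if (f <= 0 || f > 0.5) stop("frequency must be in (0, 0.5] cycles/pixel")
  sigma <- 1 / f
  hw <- as.integer(ceiling(3 * sigma))
  g <- seq(-hw, hw)
  x <- matrix(g, 2 * hw + 1, 2 * hw + 1, byrow = TRUE)  # columns
  y <- matrix(g, 2 * hw + 1, 2 * hw + 1)                # rows
  xp <- x * cos(theta) + y * sin(theta)
  yp <- -x * sin(theta) + y * cos(theta)
  env <- if (cfg$variant == "as-printed") {
    exp(-(xp^2 + cfg$gamma^2 * yp^2) / (2 * sigma^2))
  } else {
    exp(-(f^2 / cfg$gamma^2) * xp^2 - (f^2 / cfg$eta^2) * yp^2)
  }
  amp <- f^2 / (pi * cfg$gamma * cfg$eta)
  structure(list(f = f, theta = theta, sigma = sigma, hw = hw,
                 values = amp * env * exp(1i * (2 * pi * f * xp + cfg$phi))),
            class = "gabor_kernel")
}

#' Build the full Gabor wavelet bank
#'
#' @param cfg a [gabor_bank_config()].
#' @return A `gabor_bank`: list of [gabor_kernel()]s ordered scale-major
#'   (all orientations of scale 1, then scale 2, ...), with the config
#'   attached as an attribute.
#' @examples
#' bank <- build_bank()
#' length(bank)  # 88
#' @export
build_bank <- function(cfg = gabor_bank_config()) {
  freqs <- bank_frequencies(cfg)
  thetas <- pi * (seq_len(cfg$n_orientations) - 1) / cfg$n_orientations
  kernels <- list()
  for (f in freqs) for (th in thetas)
    kernels[[length(kernels) + 1L]] <- gabor_kernel(f, th, cfg)
  structure(kernels, config = cfg, class = "gabor_bank")
}

img_matrix <- function(img) {
  if (inherits(img, "trajectory_image")) img$pixels
  else if (is.matrix(img)) img
  else stop("expected a trajectory_image or a numeric matrix")
}

#' Filter an image with one Gabor kernel
#'
#' Linear convolution via zero-padded frequency-domain multiplication; the
#' result is the magnitude of the complex response, cropped to the input
#' size. Padding always covers the full linear convolution, so kernels
#' larger than the image are handled without wrap-around.
#'
#' @param img a [render_trajectory()] image or a numeric matrix.
#' @param kernel a [gabor_kernel()].
#' @return Numeric matrix of magnitude responses, same size as the input.
#' @export
filter_image <- function(img, kernel) {
  stopifnot(inherits(kernel, "gabor_kernel"))
  m <- img_matrix(img)
  stopifnot(nrow(m) == ncol(m))
  pad <- nextn(nrow(m) + 2 * kernel$hw, 2)
  gabor_response_cpp(m, kernel$values, kernel$hw, pad)
}

feature_names <- function(cfg) {
  nm <- character(0)
  for (i in seq_len(cfg$n_scales)) for (j in seq_len(cfg$n_orientations))
    nm <- c(nm, sprintf("s%02d_o%d_mean", i, j), sprintf("s%02d_o%d_sd", i, j))
  nm
}

#' Extract the Gabor texture feature vector(s)
#'
#' For each kernel of the bank, convolves the image and records the mean
#' and population standard deviation of the magnitude response, giving
#' `2 * n_scales * n_orientations` features per image (176 for the default
#' bank). Features are ordered scale-major, orientation inner, with the
#' (mean, sd) pair adjacent per channel.
#'
#' @param imgs one [render_trajectory()] image / matrix, or a list of them
#'   (all the same size; batching shares the kernel FFTs and is much
#'   faster).
#' @param bank a [build_bank()] Gabor bank.
#' @return For a single image a named numeric vector; for a list, a matrix
#'   with one row per image.
#' @export
extract_features <- function(imgs, bank = build_bank()) {
  stopifnot(inherits(bank, "gabor_bank"))
  single <- inherits(imgs, "trajectory_image") || is.matrix(imgs)
  if (single) imgs <- list(imgs)
  mats <- lapply(imgs, img_matrix)
  N <- nrow(mats[[1]])
  stopifnot(all(vapply(mats, nrow, 1L) == N),
            all(vapply(mats, ncol, 1L) == N))
  hw <- vapply(bank, function(k) k$hw, integer(1))
  pad <- vapply(hw, function(h) nextn(N + 2 * h, 2), numeric(1))
  vals <- lapply(bank, function(k) k$values)
  out <- gabor_features_cpp(mats, vals, as.integer(hw), as.integer(pad))
  colnames(out) <- feature_names(attr(bank, "config"))
  if (single) out[1, ] else out
}
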