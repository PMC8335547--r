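#' V1-like Gabor filter bank
#'
#' Builds a bank of even-symmetric (cosine-phase), zero-mean Gabor kernels
#' covering `n_frequencies` spatial frequencies in descending octave steps
#' from `base_frequency`, crossed with `n_orientations` orientations. Each
#' (frequency, orientation) pair yields two sign channels at encode time
#' (positive- and negative-rectified), modelling ON/OFF simple cells, so the
#' bank has `n_frequencies * n_orientations * 2` channels.
#'
#' The Gaussian envelope width is set from the frequency bandwidth:
#' `sigma = sqrt(log(2)/2) / (pi * f) * (2^b + 1) / (2^b - 1)` with
#' `b = bandwidth` octaves. Kernels are truncated at `trunc_sigma` standard
#' deviations (odd pixel extent, so the filter is centred) and mean-subtracted
#' so they are DC-free: a uniform image produces zero response.
#'
#' @param n_frequencies Number of spatial frequency bands (>= 1).
#' @param n_orientations Number of orientations (>= 1), evenly spaced over
#'   pi radians starting at 0. Orientation 0 oscillates along x, i.e. it
#'   responds maximally to vertical bars/edges.
#' @param base_frequency Highest spatial frequency, cycles/pixel, in (0, 0.5].
#' @param bandwidth Frequency half-amplitude bandwidth in octaves.
#' @param gamma Spatial aspect ratio of the envelope (1 = circular).
#' @param trunc_sigma Kernel truncation radius in units of sigma.
#' @return An object of class `gabor_bank` with fields `frequencies`,
#'   `orientations`, `kernels` (one per frequency x orientation),
#'   `kernel_sizes`, `channel_index` (one row per output channel:
#'   frequency, orientation, sign) and `n_channels`.
#' @examples
#' bank <- gabor_bank(4, 4)
#' bank$n_channels  # 32
#' @export
gabor_bank <- function(n_frequencies = 4, n_orientations = 4,
                       base_frequency = 0.25, bandwidth = 1.5,
                       gamma = 1, trunc_sigma = 2.4) {
  stopifnot(n_frequencies >= 1, n_orientations >= 1)
  if (base_frequency <= 0 || base_frequency > 0.5)
    stop("base_frequency must be in (0, 0.5] cycles/pixel", call. = FALSE)
  freqs <- base_frequency / 2^(seq_len(n_frequencies) - 1)
  thetas <- (seq_len(n_orientations) - 1) * pi / n_orientations
  kernels <- list()
  sizes <- integer(n_frequencies)
  for (fi in seq_along(freqs)) {
    for (oi in seq_along(thetas)) {
      k <- .gabor_kernel(freqs[fi], thetas[oi], bandwidth, gamma, trunc_sigma)
      kernels[[length(kernels) + 1L]] <- k
      sizes[fi] <- nrow(k)
    }
  }
  ci <- expand.grid(orientation = thetas, frequency = freqs,
                    KEEP.OUT.ATTRS = FALSE)[, c("frequency", "orientation")]
  ci <- ci[rep(seq_len(nrow(ci)), each = 2L), ]
  ci$sign <- rep(c(1, -1), n_frequencies * n_orientations)
  rownames(ci) <- NULL
  structure(list(
    frequencies = freqs, orientations = thetas,
    n_signs = 2L, kernels = kernels, kernel_sizes = sizes,
    channel_index = ci, n_channels = 2L * n_frequencies * n_orientations,
    bandwidth = bandwidth, gamma = gamma, trunc_sigma = trunc_sigma
  ), class = "gabor_bank")
}

# Even-phase Gabor on an odd-sized grid, mean-subtracted to kill DC.
.gabor_kernel <- function(freq, theta, bandwidth, gamma, trunc_sigma) {
  sigma <- sqrt(log(2) / 2) / (pi * freq) *
    (2^bandwidth + 1) / (2^bandwidth - 1)
  r <- max(1L, ceiling(trunc_sigma * sigma))
  ax <- seq(-r, r)
  x <- matrix(ax, 2 * r + 1, 2 * r + 1, byrow = TRUE)   # column coordinate
  y <- matrix(ax, 2 * r + 1, 2 * r + 1)                 # row coordinate
  xp <- x * cos(theta) + y * sin(theta)
  yp <- -x * sin(theta) + y * cos(theta)
  g <- exp(-(xp^2 + (gamma * yp)^2) / (2 * sigma^2)) * cos(2 * pi * freq * xp)
  g <- g - mean(g)
  g / sqrt(sum(g^2))  # unit energy, so bands drive Layer 1 comparably
}

#' Validate a retinal image
#'
#' A retinal image is a numeric matrix of luminances in \[0, 1\].
#'
#' @param pixels Numeric matrix.
#' @return The matrix, invisibly classed as `retinal_image`.
#' @export
retinal_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("retinal image must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop("retinal image contains NaN/Inf", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("retinal image values must lie in [0, 1]", call. = FALSE)
  class(pixels) <- c("retinal_image", class(pixels))
  pixels
}

#' Encode a retinal image through the Gabor bank
#'
#' Convolves the image with every kernel (zero-padded, 'same' output), splits
#' each linear response r into half-rectified sign channels max(r, 0) and
#' max(-r, 0), and (by default) contrast-normalises the whole response volume
#' to unit L2 norm so input drive is comparable across stimuli.
#'
#' @param image Numeric matrix in \[0,1\] (or `retinal_image`).
#' @param bank A [gabor_bank()].
#' @param normalize Divide the response volume by its L2 norm (default TRUE).
#' @return Object of class `input_rep`: list with `rates` (height x width x
#'   channels array, all >= 0) and `channel_index`.
#' @export
encode_image <- function(image, bank, normalize = TRUE) {
  image <- retinal_image(unclass(as.matrix(image)))
  h <- nrow(image); w <- ncol(image)
  ks <- max(bank$kernel_sizes)
  if (ks > h || ks > w)
    stop(sprintf(
      "largest kernel (%d px) does not fit the %dx%d image; reduce the number of frequency octaves or trunc_sigma",
      ks, h, w), call. = FALSE)
  rates <- array(0, dim = c(h, w, bank$n_channels))
  ch <- 1L
  for (ki in seq_along(bank$kernels)) {
    r <- .conv2_same(image, bank$kernels[[ki]])
    rates[, , ch] <- pmax(r, 0)
    rates[, , ch + 1L] <- pmax(-r, 0)
    ch <- ch + 2L
  }
  if (normalize) {
    nrm <- sqrt(sum(rates^2))
    if (nrm > 0) rates <- rates / nrm
  }
  structure(list(rates = rates, channel_index = bank$channel_index),
            class = "input_rep")
}

# FFT correlation with 'same' centred output. The image border is replicate-
# padded so a DC-free kernel responds with exactly zero to a uniform image
# even at the edges. Kernels here are point-symmetric so correlation equals
# convolution, but we flip anyway.
.conv2_same <- function(img, kern) {
  kern <- kern[rev(seq_len(nrow(kern))), rev(seq_len(ncol(kern))), drop = FALSE]
  hk <- nrow(kern); wk <- ncol(kern)
  rk <- (hk - 1L) %/% 2L; ck <- (wk - 1L) %/% 2L
  h0 <- nrow(img); w0 <- ncol(img)
  ri <- c(rep(1L, rk), seq_len(h0), rep(h0, rk))
  ci <- c(rep(1L, ck), seq_len(w0), rep(w0, ck))
  padded <- img[ri, ci, drop = FALSE]
  hi <- nrow(padded); wi <- ncol(padded)
  hp <- hi + hk - 1L; wp <- wi + wk - 1L
  pi_ <- matrix(0, hp, wp); pi_[1:hi, 1:wi] <- padded
  pk <- matrix(0, hp, wp); pk[1:hk, 1:wk] <- kern
  full <- Re(stats::fft(stats::fft(pi_) * stats::fft(pk), inverse = TRUE)) / (hp * wp)
  # 'same' window of the padded image, then strip the padding
  same <- full[(rk + 1L):(rk + hi), (ck + 1L):(ck + wi), drop = FALSE]
  same[(rk + 1L):(rk + h0), (ck + 1L):(ck + w0), drop = FALSE]
}

#' Encode an optic-flow field as direction-tuned V1 motion channels
#'
#' The dorsal-stream input variant: each retinal position carries a 2D flow
#' vector; each of `n_directions` channels responds with half-rectified
#' cosine direction tuning scaled by flow speed,
#' `rate = max(0, cos(theta_channel - theta_flow)) * |flow|`.
#'
#' @param flow Numeric array height x width x 2 (dx, dy components).
#' @param n_directions Number of direction channels (>= 2), preferred
#'   directions evenly spaced over 2*pi starting at 0 (rightward).
#' @return An `input_rep` whose `channel_index` holds the preferred direction
#'   of each channel (radians).
#' @export
encode_flow_field <- function(flow, n_directions = 8) {
  if (n_directions < 2) stop("n_directions must be >= 2", call. = FALSE)
  stopifnot(length(dim(flow)) == 3, dim(flow)[3] == 2)
  if (any(!is.finite(flow))) stop("flow field contains NaN/Inf", call. = FALSE)
  h <- dim(flow)[1]; w <- dim(flow)[2]
  speed <- sqrt(flow[, , 1]^2 + flow[, , 2]^2)
  ang <- atan2(flow[, , 2], flow[, , 1])
  dirs <- (seq_len(n_directions) - 1) * 2 * pi / n_directions
  rates <- array(0, dim = c(h, w, n_directions))
  for (d in seq_len(n_directions)) {
    rates[, , d] <- pmax(0, cos(dirs[d] - ang)) * speed
  }
  structure(list(rates = rates,
                 channel_index = data.frame(direction = dirs)),
            class = "input_rep")
}

#' Read an 8-bit grayscale PNG as a retinal image
#' @param path PNG file path.
#' @return `retinal_image` matrix in \[0,1\].
#' @export
read_retina_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]  # first channel of RGB(A)
  retinal_image(px)
}

#' Write a retinal image to PNG
#' @param image Matrix in \[0,1\].
#' @param path Output path.
#' @export
write_retina_png <- function(image, path) {
  png::writePNG(pmin(pmax(unclass(as.matrix(image)), 0), 1), path)
  invisible(path)
}
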