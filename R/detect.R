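#' @title Spot detection and intensity measurement
#' @name detect
#' @description Difference-of-Gaussian detection with a 3x3 median prefilter,
#'   subpixel localization by least-squares 2-D Gaussian fitting, and
#'   Gaussian-weighted intensity measurement in photon units.
NULL

# vectorised 3x3 median filter (replicate padding); sorting network over the
# nine shifted copies avoids per-pixel apply() calls
median3x3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  pad[1, ] <- pad[2, ]; pad[h + 2, ] <- pad[h + 1, ]
  pad[, 1] <- pad[, 2]; pad[, w + 2] <- pad[, w + 1]
  cols <- matrix(0, h * w, 9L)
  idx <- 1L
  for (dy in 0:2) for (dx in 0:2) {
    cols[, idx] <- as.numeric(pad[(1 + dy):(h + dy), (1 + dx):(w + dx)])
    idx <- idx + 1L
  }
  for (i in 1:8) for (j in 1:(9 - i)) {
    a <- cols[, j]; b <- cols[, j + 1]
    lo <- pmin(a, b)
    cols[, j] <- lo
    cols[, j + 1] <- a + b - lo
  }
  matrix(cols[, 5], h, w)
}

# separable Gaussian blur with replicate-like edge handling via kernel
# renormalisation (band matrices applied left and right)
blur_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(4 * sigma)
  K <- matrix(0, n, n)
  offs <- -r:r
  kern <- stats::dnorm(offs, sd = sigma)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- kern[ok] / sum(kern[ok])
  }
  K
}

gaussian_blur <- function(m, sigma) {
  blur_matrix(nrow(m), sigma) %*% m %*% t(blur_matrix(ncol(m), sigma))
}

counts_to_photons <- function(counts, camera) {
  (counts - camera$offset) / (camera$ecf * camera$qe)
}

# pixel-integrated unit-volume Gaussian on a window of pixel indices
psf_weights <- function(ix, iy, cx, cy, sigma_px) {
  wx <- stats::pnorm(ix, cx, sigma_px) - stats::pnorm(ix - 1, cx, sigma_px)
  wy <- stats::pnorm(iy, cy, sigma_px) - stats::pnorm(iy - 1, cy, sigma_px)
  outer(wy, wx)
}

#' Measure spot intensity by Gaussian-weighted summation
#'
#' The local background is a robust annulus estimate around the spot (the
#' mean of annulus pixels no more than 4 MAD above their median, which is
#' insensitive to bright neighbours yet unbiased on skewed EMCCD count
#' distributions) and is subtracted; the intensity estimate is
#' sum(w * (pixel - bg)) / sum(w^2)
#' with weights w the pixel-integrated unit-volume PSF, so a noise-free
#' Gaussian spot of volume N returns N photons. The signal-to-noise ratio is
#' 20 * log10(peak amplitude / sigma_background) in dB.
#'
#' @param frame Matrix of camera counts (or photons, see `camera`).
#' @param x,y Spot center in pixel units (0-based, pixel (0,0) spans
#'   `[0,1)^2`).
#' @param sigma_px PSF standard deviation in pixels.
#' @param camera A [camera_model()] used to convert counts to photons;
#'   `NULL` if `frame` is already in photons.
#' @param annulus Inner/outer annulus radii in multiples of `sigma_px`
#'   (default `c(3, 5)`).
#' @return List with `photons`, `background` (photons/pixel), `snr_db` and
#'   `bg_fallback` (TRUE when the annulus fell outside the image and the
#'   frame median was used).
#' @export
measure_intensity <- function(frame, x, y, sigma_px, camera = NULL,
                              annulus = c(3, 5)) {
  if (!is.null(camera)) frame <- counts_to_photons(frame, camera)
  h <- nrow(frame); w <- ncol(frame)
  cx <- x; cy <- y   # 0-based continuous coords; pixel j spans [j-1, j)
  r_in <- annulus[1] * sigma_px
  r_out <- annulus[2] * sigma_px

  jx <- max(1L, floor(cx - r_out) + 1L):min(w, ceiling(cx + r_out))
  iy <- max(1L, floor(cy - r_out) + 1L):min(h, ceiling(cy + r_out))
  px <- outer(rep(1, length(iy)), jx - 0.5)
  py <- outer(iy - 0.5, rep(1, length(jx)))
  rr <- sqrt((px - cx)^2 + (py - cy)^2)
  ann <- frame[iy, jx][rr >= r_in & rr <= r_out]
  bg_fallback <- length(ann) < 8
  if (bg_fallback) ann <- as.numeric(frame)
  # median-anchored, upward-clipped mean: keeps the median's robustness to
  # bright neighbours but avoids its downward bias on skewed, lumpy EMCCD
  # count distributions at few-photon backgrounds
  md <- stats::median(ann)
  sig_bg <- stats::mad(ann)
  bg <- mean(ann[ann <= md + 4 * sig_bg])

  jx2 <- max(1L, floor(cx - r_in) + 1L):min(w, ceiling(cx + r_in))
  iy2 <- max(1L, floor(cy - r_in) + 1L):min(h, ceiling(cy + r_in))
  wts <- psf_weights(jx2, iy2, cx, cy, sigma_px)
  vals <- frame[iy2, jx2] - bg
  photons <- sum(wts * vals) / sum(wts^2)
  amp <- photons * max(wts)      # expected peak pixel value above background
  snr_db <- if (sig_bg > 0 && amp > 0) 20 * log10(amp / sig_bg) else -Inf
  list(photons = photons, background = bg, snr_db = snr_db,
       bg_fallback = bg_fallback)
}

# least-squares 2-D Gaussian (fixed sigma) refinement on a pixel window;
# returns refined 0-based center or NULL on failure
refine_subpixel <- function(frame, cx0, cy0, sigma_px, half) {
  h <- nrow(frame); w <- ncol(frame)
  jx <- max(1L, floor(cx0 - half) + 1L):min(w, ceiling(cx0 + half))
  iy <- max(1L, floor(cy0 - half) + 1L):min(h, ceiling(cy0 + half))
  if (length(jx) < 4 || length(iy) < 4) return(NULL)
  d <- data.frame(v = as.numeric(frame[iy, jx]),
                  px = as.numeric(outer(rep(1, length(iy)), jx - 0.5)),
                  py = as.numeric(outer(iy - 0.5, rep(1, length(jx)))))
  a0 <- max(d$v) - stats::median(d$v)
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(
      v ~ b + a * exp(-((px - x0)^2 + (py - y0)^2) / (2 * sigma_px^2)),
      data = d,
      start = list(b = stats::median(d$v), a = a0, x0 = cx0, y0 = cy0),
      control = minpack.lm::nls.lm.control(maxiter = 50))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  out <- c(x = unname(cf["x0"]), y = unname(cf["y0"]))
  if (any(!is.finite(out))) return(NULL)
  out
}

#' Detect and localize spots in one frame
#'
#' A 3x3 median prefilter is followed by a difference-of-Gaussian band-pass
#' matched to the expected spot radius; local maxima above the quality
#' threshold are refined to subpixel accuracy by a least-squares 2-D
#' Gaussian fit and measured with [measure_intensity()].
#'
#' @param frame Matrix of camera counts.
#' @param camera A [camera_model()] (counts-to-photon conversion).
#' @param pixel_size Pixel size in nm.
#' @param expected_radius Expected spot radius in nm (approximately
#'   2 * sigma_PSF).
#' @param quality_threshold Minimum DoG response (in photons) for a local
#'   maximum to be kept.
#' @param frame_index Frame number stored in the output rows.
#' @param truncation_radius Fit/measurement window half-width in multiples of
#'   sigma (default 5; the fit window spans 2x this radius across).
#' @param keep_edge Keep localizations whose window is clipped at the image
#'   border (default FALSE).
#' @return Data frame with columns frame, x, y (nm, subpixel), intensity
#'   (photons), background (photons/pixel), snr_db, quality, edge.
#' @export
detect_spots <- function(frame, camera, pixel_size, expected_radius,
                         quality_threshold, frame_index = 1L,
                         truncation_radius = 5, keep_edge = FALSE) {
  photons <- counts_to_photons(frame, camera)
  sigma_px <- (expected_radius / 2) / pixel_size
  med <- median3x3(photons)
  dog <- gaussian_blur(med, sigma_px) - gaussian_blur(med, 1.6 * sigma_px)

  h <- nrow(dog); w <- ncol(dog)
  empty <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      intensity = numeric(0), background = numeric(0),
                      snr_db = numeric(0), quality = numeric(0),
                      edge = logical(0))
  if (h < 5 || w < 5) return(empty)
  # local maxima over the 3x3 neighbourhood, excluding a 1-px border
  ctr <- dog[2:(h - 1), 2:(w - 1)]
  ismax <- ctr >= quality_threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ismax <- ismax & ctr >= dog[(2 + dy):(h - 1 + dy), (2 + dx):(w - 1 + dx)]
  }
  hits <- which(ismax, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty)

  half <- truncation_radius * sigma_px
  rows <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ri <- unname(hits[i, 1]) + 1L    # row/col in full image
    ci <- unname(hits[i, 2]) + 1L
    cx0 <- ci - 0.5
    cy0 <- ri - 0.5
    edge <- (cx0 - half < 0) || (cx0 + half > w) ||
            (cy0 - half < 0) || (cy0 + half > h)
    pos <- refine_subpixel(photons, cx0, cy0, sigma_px, half)
    if (is.null(pos)) next
    # reject fits that wandered out of the local neighbourhood
    if (abs(pos["x"] - cx0) > 2 || abs(pos["y"] - cy0) > 2) next
    m <- measure_intensity(photons, pos["x"], pos["y"], sigma_px)
    rows[[i]] <- data.frame(frame = frame_index,
                            x = unname(pos["x"]) * pixel_size,
                            y = unname(pos["y"]) * pixel_size,
                            intensity = m$photons, background = m$background,
                            snr_db = m$snr_db,
                            quality = dog[ri, ci], edge = edge)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  if (!keep_edge) out <- out[!out$edge, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect spots in every frame of a stack
#'
#' @param stack A `synthetic_stack` (or list with `frames` array and
#'   `config` carrying the camera model).
#' @param expected_radius Expected spot radius in nm; defaults to
#'   2 * sigma_PSF from the stack's PSF model.
#' @param quality_threshold Minimum DoG response in photons.
#' @param ... Passed to [detect_spots()].
#' @return A localization table (rows from all frames).
#' @export
detect_stack <- function(stack, expected_radius = NULL, quality_threshold,
                         ...) {
  cfg <- stack$config
  if (is.null(expected_radius))
    expected_radius <- 2 * psf_sigma(cfg$psf)
  nf <- dim(stack$frames)[3]
  do.call(rbind, lapply(seq_len(nf), function(f) {
    detect_spots(stack$frames[, , f], cfg$camera, cfg$imaging$pixel_size,
                 expected_radius, quality_threshold, frame_index = f, ...)
  }))
}

#' Predicted variance of the Gaussian-weighted intensity estimate
#'
#' Propagates the camera model (shot noise inflated by the EM excess factor,
#' plus Gaussian readout noise) through the weighted-sum estimator of
#' [measure_intensity()] for a spot of known mean photon count.
#'
#' @param photons Mean spot photons.
#' @param background Mean background photons per pixel.
#' @param sigma_px PSF standard deviation in pixels.
#' @param camera A [camera_model()].
#' @param annulus Annulus radii in multiples of sigma (matches the default
#'   of [measure_intensity()]; the inner radius is also the measurement
#'   window radius).
#' @return Variance of the measured photon count.
#' @export
intensity_measurement_variance <- function(photons, background, sigma_px,
                                           camera, annulus = c(3, 5)) {
  r <- annulus[1] * sigma_px
  n <- 2 * ceiling(r) + 1
  ix <- seq_len(n)
  ctr <- n / 2
  wts <- psf_weights(ix, ix, ctr, ctr, sigma_px)
  f2 <- camera$excess_factor^2
  # per-pixel photon-unit variance: F^2 * mu_e / QE^2 + (read / (ecf*QE))^2
  read_var <- (camera$read_sigma / (camera$ecf * camera$qe))^2
  mu_px <- photons * wts + background
  var_px <- f2 * mu_px / camera$qe + read_var
  var_spot <- sum(wts^2 * var_px) / sum(wts^2)^2
  # background subtraction: var(clipped annulus mean) ~ var_px / m,
  # amplified by (sum w / sum w^2)^2 through the estimator
  m_ann <- pi * ((annulus[2] * sigma_px)^2 - (annulus[1] * sigma_px)^2)
  var_bg_px <- f2 * background / camera$qe + read_var
  var_bg <- var_bg_px / m_ann * (sum(wts) / sum(wts^2))^2
  var_spot + var_bg
}
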