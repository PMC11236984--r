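# shared fixtures: small simulation configs and rendered single spots

test_camera <- function() camera_model(qe = 0.9, ecf = 12, offset = 100,
                                       read_sigma = 6)

test_psf <- function() psf_model(lambda_em = 680, na = 1.49)

# single stationary emitter rendered as photon means (no camera noise)
render_single_spot <- function(x_um, y_um, photons = 400, background = 0,
                               width_px = 32, pixel_size = 100) {
  im <- imaging_config(width_px = width_px, height_px = width_px,
                       pixel_size = pixel_size, n_frames = 1)
  tr <- structure(list(list(id = 1L, oligomer_size = 1L, first_frame = 1L,
                            frames = 1L, x = x_um, y = y_um, z = 0,
                            photons = photons)),
                  class = "trajectory_set")
  render_photon_frames(tr, im, test_psf(), illumination_model(),
                       background = background)
}

# monomer/dimer mixture movie in the live-cell imaging regime
mixture_config <- function(n_frames = 50, density = 0.1,
                           fractions = c("1" = 0.8, "2" = 0.2),
                           background = 10) {
  simulation_config(
    imaging = imaging_config(width_px = 160, height_px = 160,
                             pixel_size = 100, n_frames = n_frames,
                             frame_interval = 0.025),
    emitter = emitter_model(mean_photons = 400, lifetime = Inf,
                            density = density,
                            oligomer_fractions = fractions,
                            D_by_size = c("1" = 0, "2" = 0)),
    evanescent = evanescent_model(sigma_z = 0),
    psf = test_psf(),
    camera = test_camera(),
    background = background, mode = "tracking")
}

# band-limited white-noise image with a sharp cutoff in normalized frequency
band_limited_image <- function(n = 256, cutoff = 0.5, seed = 3) {
  set.seed(seed)
  white <- matrix(stats::rnorm(n * n), n, n)
  Fw <- stats::fft(white)
  f1 <- (seq_len(n) - 1)
  f1 <- ifelse(f1 < n / 2, f1, f1 - n) / (n / 2)
  rr <- sqrt(outer(f1^2, f1^2, "+"))
  Fw[rr > cutoff] <- 0
  Re(stats::fft(Fw, inverse = TRUE)) / n^2
}
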