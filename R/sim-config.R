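#' @title Simulation configuration objects
#' @name sim-config
#' @description Constructors for the parameter groups of the single-molecule
#'   TIRF simulator. Each constructor validates its arguments and returns a
#'   classed list; [simulation_config()] bundles them into a complete,
#'   validated configuration that [run_simulation()] consumes.
#'
#'   Unless a field name carries a `_um` suffix, lengths are in nanometres,
#'   times in seconds, diffusion constants in µm²/s and densities in
#'   emitters/µm².
NULL

stop_config <- function(...) stop(..., call. = FALSE)

check_num <- function(x, name, lower = -Inf, upper = Inf, allow_inf = FALSE,
                      len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x))
    stop_config(sprintf("'%s' must be a numeric of length %d", name, len))
  if (!allow_inf && any(!is.finite(x)))
    stop_config(sprintf("'%s' must be finite", name))
  if (any(x < lower) || any(x > upper))
    stop_config(sprintf("'%s' must be in [%s, %s]", name, lower, upper))
  x
}

#' Imaging geometry and timing
#'
#' @param width_px,height_px Field of view in camera pixels.
#' @param pixel_size Camera pixel size in nm; must be an integer multiple of
#'   `supersample_pitch`.
#' @param n_frames Number of frames to simulate.
#' @param frame_interval Frame interval (Delta t) in seconds.
#' @param supersample_pitch Pitch of the fine rendering grid in nm
#'   (default 5 nm).
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(width_px = 64L, height_px = 64L, pixel_size = 100,
                           n_frames = 100L, frame_interval = 0.025,
                           supersample_pitch = 5) {
  width_px  <- as.integer(check_num(width_px, "width_px", 1))
  height_px <- as.integer(check_num(height_px, "height_px", 1))
  n_frames  <- as.integer(check_num(n_frames, "n_frames", 1))
  check_num(pixel_size, "pixel_size", .Machine$double.eps)
  check_num(frame_interval, "frame_interval", .Machine$double.eps)
  check_num(supersample_pitch, "supersample_pitch", .Machine$double.eps)
  if (abs(pixel_size / supersample_pitch -
          round(pixel_size / supersample_pitch)) > 1e-9)
    stop_config("'pixel_size' must be an integer multiple of 'supersample_pitch'")
  structure(list(width_px = width_px, height_px = height_px,
                 pixel_size = pixel_size, n_frames = n_frames,
                 frame_interval = frame_interval,
                 supersample_pitch = supersample_pitch),
            class = "imaging_config")
}

#' Emitter photophysics and mobility
#'
#' @param mean_photons Mean emitted photons per monomer per frame (S_e) at the
#'   reference axial position.
#' @param lifetime Mean on-lifetime tau in seconds (single-exponential
#'   bleaching/unbinding); `Inf` disables bleaching.
#' @param density Emitters per µm² of field of view.
#' @param oligomer_fractions Named numeric vector mapping oligomer size to its
#'   fraction; must sum to 1.
#' @param D_by_size Named numeric vector mapping oligomer size to its
#'   diffusion constant in µm²/s.
#' @return An object of class `emitter_model`.
#' @export
emitter_model <- function(mean_photons = 400, lifetime = Inf, density = 0.5,
                          oligomer_fractions = c("1" = 1),
                          D_by_size = c("1" = 0)) {
  check_num(mean_photons, "mean_photons", .Machine$double.eps)
  check_num(lifetime, "lifetime", .Machine$double.eps, allow_inf = TRUE)
  check_num(density, "density", 0)
  if (is.null(names(oligomer_fractions)) || any(oligomer_fractions < 0) ||
      abs(sum(oligomer_fractions) - 1) > 1e-8)
    stop_config("'oligomer_fractions' must be named, non-negative and sum to 1")
  sizes <- names(oligomer_fractions)
  if (!all(sizes %in% names(D_by_size)))
    stop_config("'D_by_size' must name every oligomer size in 'oligomer_fractions'")
  if (any(D_by_size < 0)) stop_config("all diffusion constants must be >= 0")
  structure(list(mean_photons = mean_photons, lifetime = lifetime,
                 density = density, oligomer_fractions = oligomer_fractions,
                 D_by_size = D_by_size),
            class = "emitter_model")
}

#' Lateral illumination profile
#'
#' @param profile `"flat"` (flat-field, unit intensity everywhere) or
#'   `"gaussian"` (single-beam profile).
#' @param beam_sigma Gaussian beam sigma in µm (required for
#'   `profile = "gaussian"`).
#' @param bleach_exponent Exponent alpha of the local bleaching hazard,
#'   hazard proportional to (local excitation)^alpha. The default 1 is the
#'   plain single-exponential model; larger values emulate locally enhanced
#'   non-linear photobleaching under over-illumination.
#' @return An object of class `illumination_model`.
#' @export
illumination_model <- function(profile = c("flat", "gaussian"),
                               beam_sigma = NULL, bleach_exponent = 1) {
  profile <- match.arg(profile)
  if (profile == "gaussian") {
    if (is.null(beam_sigma)) stop_config("'beam_sigma' required for gaussian profile")
    check_num(beam_sigma, "beam_sigma", .Machine$double.eps)
  }
  check_num(bleach_exponent, "bleach_exponent", 1)
  structure(list(profile = profile, beam_sigma = beam_sigma,
                 bleach_exponent = bleach_exponent),
            class = "illumination_model")
}

#' Evanescent excitation field and axial emitter motion
#'
#' @param penetration_depth 1/e decay length d_p of the evanescent field (nm).
#' @param z0 Mean axial emitter position (nm); the reference position at which
#'   an emitter emits exactly its configured mean photon count.
#' @param sigma_z Standard deviation of the axial ripple (nm); 0 pins every
#'   emitter to `z0`.
#' @param node_spacing Frame spacing of the random axial nodes between which
#'   z positions are spline-interpolated; must be >= 2.
#' @return An object of class `evanescent_model`.
#' @export
evanescent_model <- function(penetration_depth = 200, z0 = 0, sigma_z = 0,
                             node_spacing = 10L) {
  check_num(penetration_depth, "penetration_depth", .Machine$double.eps)
  check_num(z0, "z0")
  check_num(sigma_z, "sigma_z", 0)
  node_spacing <- as.integer(check_num(node_spacing, "node_spacing", 2))
  structure(list(penetration_depth = penetration_depth, z0 = z0,
                 sigma_z = sigma_z, node_spacing = node_spacing),
            class = "evanescent_model")
}

#' Gaussian point-spread-function model
#'
#' The PSF standard deviation is derived from the Abbe limit
#' d_Abbe = lambda_em / (2 NA) as sigma_PSF = prefactor * d_Abbe / 2.355,
#' i.e. 0.276 * lambda_em / NA with the default prefactor of 1.3 that
#' corrects for effective numerical aperture and resolution.
#'
#' @param lambda_em Emission wavelength in nm.
#' @param na Numerical aperture of the objective.
#' @param prefactor Empirical width correction (default 1.3).
#' @param truncation_radius Rendering support radius in multiples of
#'   sigma_PSF (default 5).
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(lambda_em = 680, na = 1.49, prefactor = 1.3,
                      truncation_radius = 5) {
  check_num(lambda_em, "lambda_em", .Machine$double.eps)
  check_num(na, "na", .Machine$double.eps)
  check_num(prefactor, "prefactor", .Machine$double.eps)
  check_num(truncation_radius, "truncation_radius", 1)
  structure(list(lambda_em = lambda_em, na = na, prefactor = prefactor,
                 truncation_radius = truncation_radius),
            class = "psf_model")
}

#' EMCCD camera model
#'
#' @param qe Quantum efficiency in (0, 1].
#' @param ecf Electron conversion factor, digital counts per photoelectron.
#' @param offset Camera offset in counts.
#' @param read_sigma Gaussian readout noise in counts.
#' @param excess_factor Excess noise factor F of the EM register; the electron
#'   variance is F² times the shot-noise variance (default sqrt(2), F² = 2).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(qe = 0.9, ecf = 1, offset = 100, read_sigma = 1,
                         excess_factor = sqrt(2)) {
  check_num(qe, "qe", .Machine$double.eps, 1)
  check_num(ecf, "ecf", .Machine$double.eps)
  check_num(offset, "offset", 0)
  check_num(read_sigma, "read_sigma", 0)
  check_num(excess_factor, "excess_factor", 1)
  structure(list(qe = qe, ecf = ecf, offset = offset, read_sigma = read_sigma,
                 excess_factor = excess_factor),
            class = "camera_model")
}

#' Complete simulation configuration
#'
#' @param imaging An [imaging_config()].
#' @param emitter An [emitter_model()].
#' @param illumination An [illumination_model()].
#' @param evanescent An [evanescent_model()].
#' @param psf A [psf_model()].
#' @param camera A [camera_model()].
#' @param background Mean background in photons per camera pixel per frame.
#' @param mode `"tracking"` (all emitters present from frame 1, mobile) or
#'   `"paint"` (stationary emitters, binding events start uniformly in time).
#' @param max_emitters Refusal cap on the expected emitter count.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(imaging = imaging_config(),
                              emitter = emitter_model(),
                              illumination = illumination_model(),
                              evanescent = evanescent_model(),
                              psf = psf_model(),
                              camera = camera_model(),
                              background = 10,
                              mode = c("tracking", "paint"),
                              max_emitters = 50000L) {
  mode <- match.arg(mode)
  bad <- character(0)
  if (!inherits(imaging, "imaging_config")) bad <- c(bad, "imaging")
  if (!inherits(emitter, "emitter_model")) bad <- c(bad, "emitter")
  if (!inherits(illumination, "illumination_model")) bad <- c(bad, "illumination")
  if (!inherits(evanescent, "evanescent_model")) bad <- c(bad, "evanescent")
  if (!inherits(psf, "psf_model")) bad <- c(bad, "psf")
  if (!inherits(camera, "camera_model")) bad <- c(bad, "camera")
  if (length(bad))
    stop_config("invalid configuration section(s): ", paste(bad, collapse = ", "))
  check_num(background, "background", 0)
  structure(list(imaging = imaging, emitter = emitter,
                 illumination = illumination, evanescent = evanescent,
                 psf = psf, camera = camera, background = background,
                 mode = mode, max_emitters = as.integer(max_emitters)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  im <- x$imaging
  cat(sprintf("simulation_config: %d x %d px @ %g nm, %d frames @ %g s (%s mode)\n",
              im$width_px, im$height_px, im$pixel_size, im$n_frames,
              im$frame_interval, x$mode))
  cat(sprintf("  emitters: S_e = %g photons, tau = %g s, density = %g /um^2\n",
              x$emitter$mean_photons, x$emitter$lifetime, x$emitter$density))
  cat(sprintf("  illumination: %s; evanescent d_p = %g nm, sigma_z = %g nm\n",
              x$illumination$profile, x$evanescent$penetration_depth,
              x$evanescent$sigma_z))
  invisible(x)
}

# serialize a config (recursively unclass) for JSON snapshots
config_to_list <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (!is.null(names(x))) as.list(x)   # keep names (JSON object)
    else x
  }
  strip(cfg)
}

#' Restore a simulation configuration from a parsed JSON snapshot
#'
#' @param lst A named list as produced by parsing the JSON snapshot written
#'   alongside simulator output.
#' @return A validated [simulation_config()].
#' @export
config_from_list <- function(lst) {
  req <- c("imaging", "emitter", "illumination", "evanescent", "psf",
           "camera", "background", "mode")
  miss <- setdiff(req, names(lst))
  if (length(miss))
    stop_config("config snapshot missing section(s): ", paste(miss, collapse = ", "))
  simulation_config(
    imaging = do.call(imaging_config, lst$imaging),
    emitter = {
      e <- lst$emitter
      e$oligomer_fractions <- unlist(e$oligomer_fractions)
      e$D_by_size <- unlist(e$D_by_size)
      e$lifetime <- as.numeric(e$lifetime)   # JSON carries Inf as a string
      do.call(emitter_model, e)
    },
    illumination = {
      il <- lst$illumination
      if (length(il$beam_sigma) == 0) il$beam_sigma <- NULL  # JSON null/{}
      do.call(illumination_model, il)
    },
    evanescent = do.call(evanescent_model, lst$evanescent),
    psf = do.call(psf_model, lst$psf),
    camera = do.call(camera_model, lst$camera),
    background = lst$background,
    mode = lst$mode,
    max_emitters = if (is.null(lst$max_emitters)) 50000L else lst$max_emitters)
}
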