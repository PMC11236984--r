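test_that("mean displacement follows sqrt(2 D dt)", {
  expect_equal(mean_displacement(0, 0.04), 0)
  expect_equal(mean_displacement(0.25, 0.02), 0.1)
  expect_equal(mean_displacement(0.1, 0.04), 0.0894, tolerance = 1e-3)
  expect_error(mean_displacement(-1, 0.1), "D")
  expect_error(mean_displacement(0.1, 0), "dt")
})

test_that("PSF sigma derives from the Abbe limit with the 0.276 coefficient", {
  p <- psf_model(680, 1.49)
  expect_equal(psf_sigma(p) / (680 / 1.49), 1.3 / (2 * 2.355),
               tolerance = 1e-12)
  expect_equal(psf_sigma(p), 125.96, tolerance = 1e-4)
  expect_equal(psf_sigma(psf_model(525, 1.33)), 108.96, tolerance = 1e-4)
})

test_that("trajectory simulation reproduces the random-walk statistics", {
  im <- imaging_config(width_px = 40, height_px = 40, pixel_size = 100,
                       n_frames = 10, frame_interval = 0.02)
  ev <- evanescent_model()

  # zero density -> no trajectories
  empty <- simulate_trajectories(im, emitter_model(density = 0), ev, seed = 1)
  expect_length(empty, 0)

  # immortal, immobile emitters stay put and alive
  em0 <- emitter_model(density = 1, lifetime = Inf, D_by_size = c("1" = 0))
  trs <- simulate_trajectories(im, em0, ev, seed = 2)
  expect_true(all(vapply(trs, function(t) length(t$frames) == 10, TRUE)))
  expect_true(all(vapply(trs, function(t) stats::sd(t$x) == 0, TRUE)))

  # ensemble one-frame MSD = 4 D dt within 5%
  emD <- emitter_model(density = 65, lifetime = Inf, D_by_size = c("1" = 0.1))
  trs <- simulate_trajectories(im, emD, ev, seed = 3)
  expect_gt(length(trs), 900)
  d2 <- unlist(lapply(trs, function(t) diff(t$x)^2 + diff(t$y)^2))
  expect_equal(mean(d2), 4 * 0.1 * 0.02, tolerance = 0.05)

  # emitter-count cap refusal
  expect_error(simulate_trajectories(im, emitter_model(density = 1e5), ev,
                                     seed = 1, max_emitters = 1000),
               "cap")
})

test_that("survival fraction decays exponentially with the configured lifetime", {
  im <- imaging_config(width_px = 40, height_px = 40, pixel_size = 100,
                       n_frames = 40, frame_interval = 0.025)
  tau <- 0.25   # 10 frames
  em <- emitter_model(density = 125, lifetime = tau, D_by_size = c("1" = 0))
  trs <- simulate_trajectories(im, em, evanescent_model(), seed = 4)
  n <- length(trs)
  len <- vapply(trs, function(t) length(t$frames), 1L)
  for (k in c(5, 10, 20)) {
    surv <- mean(len > k)
    p <- exp(-k * 0.025 / tau)
    expect_lt(abs(surv - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("evanescent intensity decays with z and normalizes at z0", {
  ev <- evanescent_model(penetration_depth = 100, z0 = 50, sigma_z = 0)
  tr <- list(oligomer_size = 1L, z = rep(50, 5))
  expect_equal(emitter_intensity_series(tr, 400, ev), rep(400, 5))
  tr$z <- rep(75, 5)   # z - z0 = +25 nm
  expect_equal(emitter_intensity_series(tr, 400, ev)[1], 400 * exp(-0.25))
  # dimers emit twice the monomer mean
  tr$oligomer_size <- 2L
  tr$z <- rep(50, 5)
  expect_equal(emitter_intensity_series(tr, 400, ev), rep(800, 5))
  # literal printed form S_e * exp(z / d_p)
  tr$oligomer_size <- 1L
  tr$z <- 100
  expect_equal(emitter_intensity_series(tr, 400, ev,
                                        literal_formula = TRUE),
               400 * exp(1))
})

test_that("rendering conserves photons and applies the illumination profile", {
  img <- render_single_spot(1.63, 1.57, photons = 400)
  expect_equal(sum(img), 400, tolerance = 0.01)

  # background only
  im <- imaging_config(width_px = 16, height_px = 16, pixel_size = 100,
                       n_frames = 2)
  bg <- render_photon_frames(structure(list(), class = "trajectory_set"),
                             im, test_psf(), illumination_model(),
                             background = 7)
  expect_true(all(bg == 7))

  # gaussian profile: center vs one beam sigma off-center, ratio e^-0.5
  im <- imaging_config(width_px = 64, height_px = 64, pixel_size = 100,
                       n_frames = 1)
  illum <- illumination_model("gaussian", beam_sigma = 2)
  mk <- function(x_um) structure(list(list(
    id = 1L, oligomer_size = 1L, first_frame = 1L, frames = 1L,
    x = x_um, y = 3.2, z = 0, photons = 400)), class = "trajectory_set")
  at_center <- sum(render_photon_frames(mk(3.2), im, test_psf(), illum))
  at_sigma <- sum(render_photon_frames(mk(5.2), im, test_psf(), illum))
  expect_equal(at_sigma / at_center, exp(-0.5), tolerance = 0.01)
})

test_that("camera model reproduces offset, gain and excess-noise statistics", {
  cam0 <- camera_model(qe = 0.9, ecf = 1, offset = 100, read_sigma = 0)
  out <- apply_camera_model(matrix(0, 10, 10), cam0, seed = 1)
  expect_true(all(out == 100))

  # mean counts ~ QE * photons (offset 0, ecf 1)
  cam1 <- camera_model(qe = 0.9, ecf = 1, offset = 0, read_sigma = 0)
  draws <- apply_camera_model(matrix(100, 1e5, 1), cam1, seed = 2)
  expect_equal(mean(draws), 0.9 * 100, tolerance = 0.01)

  # electron-domain variance/mean = F^2 = 2 within 5% at mu_e = 100
  cam2 <- camera_model(qe = 1, ecf = 1, offset = 0, read_sigma = 0)
  e <- as.numeric(apply_camera_model(matrix(100, 1e5, 1), cam2, seed = 3))
  expect_equal(var(e) / mean(e), 2, tolerance = 0.05)

  expect_error(apply_camera_model(matrix(-1, 2, 2), cam0), ">= 0")
})

test_that("gaussian illumination broadens the intensity distribution", {
  base <- list(
    imaging = imaging_config(width_px = 96, height_px = 96, pixel_size = 100,
                             n_frames = 8, frame_interval = 0.025),
    emitter = emitter_model(mean_photons = 400, lifetime = Inf,
                            density = 0.35, D_by_size = c("1" = 0)),
    evanescent = evanescent_model(sigma_z = 0), psf = test_psf(),
    camera = test_camera(), background = 10)
  run_cv <- function(illum, seed) {
    cfg <- do.call(simulation_config, c(base, list(illumination = illum)))
    sim <- run_simulation(cfg, seed = seed)
    locs <- detect_stack(sim$stack, quality_threshold = 3)
    stats::sd(locs$intensity) / mean(locs$intensity)
  }
  cv_flat <- run_cv(illumination_model("flat"), seed = 21)
  cv_gauss <- run_cv(illumination_model("gaussian", beam_sigma = 4), seed = 21)
  expect_gt(cv_gauss, cv_flat)
})

test_that("full runs are seed-deterministic and write their outputs", {
  cfg <- simulation_config(
    imaging = imaging_config(width_px = 24, height_px = 24, pixel_size = 100,
                             n_frames = 3, frame_interval = 0.02),
    emitter = emitter_model(density = 1, lifetime = 0.1,
                            D_by_size = c("1" = 0.05)),
    evanescent = evanescent_model(sigma_z = 25, node_spacing = 2),
    psf = test_psf(), camera = test_camera(), background = 5)
  a <- run_simulation(cfg, seed = 9)
  b <- run_simulation(cfg, seed = 9)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth, b$truth)

  # empty field gives background-only frames and an empty table
  cfg0 <- simulation_config(
    imaging = imaging_config(width_px = 16, height_px = 16, pixel_size = 100,
                             n_frames = 1),
    emitter = emitter_model(density = 0), background = 5,
    camera = test_camera())
  z <- run_simulation(cfg0, seed = 1)
  expect_equal(nrow(z$truth), 0)
  expect_equal(dim(z$stack$frames), c(16L, 16L, 1L))

  # file outputs round-trip
  pref <- file.path(withr::local_tempdir(), "sim")
  run_simulation(cfg, seed = 9, out_prefix = pref)
  expect_true(file.exists(paste0(pref, ".tif")))
  back <- read_stack(paste0(pref, ".tif"))
  expect_identical(back$frames, a$stack$frames)
  expect_equal(back$config, cfg)
  truth <- utils::read.csv(paste0(pref, "_truth.csv"))
  expect_equal(nrow(truth), nrow(a$truth))
})
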