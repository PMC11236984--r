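#' @title Single-molecule TIRF movie simulator
#' @name sim-engine
#' @description Core operations of the simulator: random-walk trajectories
#'   with exponential on-times, evanescent-field intensity modulation, PSF
#'   rendering on a supersampled grid and the EMCCD camera model.
NULL

#' Mean per-axis displacement of a free diffuser
#'
#' For 2-D Brownian motion each per-axis step is a standard normal draw
#' multiplied by this value, sqrt(2 * D * dt).
#'
#' @param D Diffusion constant in µm²/s.
#' @param dt Frame interval in seconds.
#' @return Mean displacement in µm.
#' @export
mean_displacement <- function(D, dt) {
  if (!is.numeric(D) || any(D < 0)) stop("'D' must be >= 0", call. = FALSE)
  if (!is.numeric(dt) || any(dt <= 0)) stop("'dt' must be > 0", call. = FALSE)
  sqrt(2 * D * dt)
}

#' Gaussian PSF standard deviation
#'
#' sigma_PSF = prefactor * d_Abbe / 2.355 with d_Abbe = lambda_em / (2 NA);
#' the default prefactor 1.3 gives sigma_PSF = 0.276 * lambda_em / NA.
#'
#' @param psf A [psf_model()].
#' @return PSF standard deviation in nm.
#' @export
psf_sigma <- function(psf) {
  stopifnot(inherits(psf, "psf_model"))
  d_abbe <- psf$lambda_em / (2 * psf$na)
  psf$prefactor * d_abbe / 2.355
}

# illumination profile value at lateral positions (µm), normalized so the
# mean over the camera pixel grid is 1; flat profile is identically 1
illumination_scale <- function(illum, imaging) {
  if (illum$profile == "flat") {
    return(function(x_um, y_um) rep(1, length(x_um)))
  }
  w_um <- imaging$width_px * imaging$pixel_size / 1000
  h_um <- imaging$height_px * imaging$pixel_size / 1000
  cx <- w_um / 2
  cy <- h_um / 2
  bs <- illum$beam_sigma
  px_um <- imaging$pixel_size / 1000
  xs <- (seq_len(imaging$width_px) - 0.5) * px_um
  ys <- (seq_len(imaging$height_px) - 0.5) * px_um
  prof <- outer(exp(-(ys - cy)^2 / (2 * bs^2)),
                exp(-(xs - cx)^2 / (2 * bs^2)))
  norm <- mean(prof)
  function(x_um, y_um) {
    exp(-((x_um - cx)^2 + (y_um - cy)^2) / (2 * bs^2)) / norm
  }
}

#' Simulate single-molecule trajectories
#'
#' Emitters are placed uniformly at random at the configured density, their
#' oligomer sizes drawn from the configured fractions, and they perform 2-D
#' random walks with per-axis steps `rnorm() * mean_displacement(D, dt)`.
#' On-times are single-exponential with mean `emitter$lifetime`. Axial
#' positions are drawn at equidistant node frames from
#' Normal(z0, sigma_z) and spline-interpolated between nodes.
#'
#' @param imaging An [imaging_config()].
#' @param emitter An [emitter_model()].
#' @param evanescent An [evanescent_model()].
#' @param seed Optional integer seed for reproducibility.
#' @param mode `"tracking"` (all emitters start at frame 1) or `"paint"`
#'   (stationary binding events starting uniformly in time).
#' @param illumination Optional [illumination_model()]; when given with a
#'   gaussian profile or `bleach_exponent > 1`, the bleaching hazard of each
#'   emitter is proportional to (local excitation)^alpha.
#' @param max_emitters Refuse to simulate more than this many emitters.
#' @return A list of trajectories (class `trajectory_set`); each trajectory
#'   holds `id`, `oligomer_size`, `first_frame`, `frames`, `x`, `y` (µm),
#'   `z` (nm) and diffusion constant `D`.
#' @export
simulate_trajectories <- function(imaging, emitter, evanescent, seed = NULL,
                                  mode = c("tracking", "paint"),
                                  illumination = NULL,
                                  max_emitters = 50000L) {
  stopifnot(inherits(imaging, "imaging_config"),
            inherits(emitter, "emitter_model"),
            inherits(evanescent, "evanescent_model"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)

  w_um <- imaging$width_px * imaging$pixel_size / 1000
  h_um <- imaging$height_px * imaging$pixel_size / 1000
  n <- round(emitter$density * w_um * h_um)
  if (n > max_emitters)
    stop(sprintf("density implies %d emitters, exceeding the cap of %d",
                 n, max_emitters), call. = FALSE)
  if (n == 0) {
    return(structure(list(), class = "trajectory_set", imaging = imaging))
  }

  dt <- imaging$frame_interval
  nf <- imaging$n_frames
  # positions are drawn before the oligomer sizes: the first uniforms after
  # seeding are the least well mixed across nearby seeds, and a uniform
  # position is insensitive to that while a categorical size draw is not
  x0 <- runif(n, 0, w_um)
  y0 <- runif(n, 0, h_um)
  sizes <- as.integer(sample(names(emitter$oligomer_fractions), n,
                             replace = TRUE,
                             prob = emitter$oligomer_fractions))
  D <- unname(emitter$D_by_size[as.character(sizes)])
  if (mode == "paint") D <- rep(0, n)
  first <- if (mode == "paint") sample.int(nf, n, replace = TRUE) else rep(1L, n)

  tau <- emitter$lifetime
  nonlinear <- !is.null(illumination) &&
    (illumination$profile == "gaussian" || illumination$bleach_exponent > 1)
  scale_fun <- if (nonlinear) illumination_scale(illumination, imaging) else NULL
  alpha <- if (nonlinear) illumination$bleach_exponent else 1

  # simple case: position-independent exponential on-times
  if (!nonlinear) {
    len <- if (is.infinite(tau)) nf - first + 1L
           else pmin(nf - first + 1L, pmax(1L, ceiling(stats::rexp(n, 1 / tau) / dt)))
  }

  trajs <- vector("list", n)
  for (i in seq_len(n)) {
    li <- if (nonlinear) nf - first[i] + 1L else len[i]
    step <- mean_displacement(D[i], dt)
    if (li > 1L && step > 0) {
      xi <- x0[i] + c(0, cumsum(stats::rnorm(li - 1L) * step))
      yi <- y0[i] + c(0, cumsum(stats::rnorm(li - 1L) * step))
    } else {
      xi <- rep(x0[i], li)
      yi <- rep(y0[i], li)
    }
    if (nonlinear && is.finite(tau)) {
      p <- scale_fun(xi, yi)^alpha
      surv <- cumprod(exp(-dt * p / tau))
      death <- which(surv < stats::runif(1))
      if (length(death)) {
        li <- max(1L, death[1L])
        xi <- xi[seq_len(li)]
        yi <- yi[seq_len(li)]
      }
    }
    if (evanescent$sigma_z == 0) {
      zi <- rep(evanescent$z0, li)
    } else {
      nodes <- unique(c(seq(1L, li, by = evanescent$node_spacing), li))
      zn <- stats::rnorm(length(nodes), evanescent$z0, evanescent$sigma_z)
      zi <- if (length(nodes) == 1L) rep(zn, li)
            else stats::spline(nodes, zn, xout = seq_len(li))$y
    }
    trajs[[i]] <- list(id = i, oligomer_size = sizes[i], D = D[i],
                       first_frame = first[i],
                       frames = seq(first[i], length.out = li),
                       x = xi, y = yi, z = zi)
  }
  structure(trajs, class = "trajectory_set", imaging = imaging)
}

#' Per-frame mean emitted photons of a trajectory
#'
#' The evanescent excitation decays as exp(-(z - z0) / d_p) with z increasing
#' away from the coverslip, normalized so that an emitter at the reference
#' position z0 emits exactly `oligomer_size * mean_photons`; a size-k
#' oligomer emits k monomer-equivalent photon streams.
#'
#' @param traj One trajectory from [simulate_trajectories()].
#' @param mean_photons Monomer mean photons per frame (S_e).
#' @param evanescent An [evanescent_model()].
#' @param literal_formula If `TRUE`, use the unnormalized exponential
#'   S_e * exp(z / d_p) instead of the decay normalized at z0.
#' @return Numeric vector of mean photons, one per alive frame.
#' @export
emitter_intensity_series <- function(traj, mean_photons, evanescent,
                                     literal_formula = FALSE) {
  stopifnot(inherits(evanescent, "evanescent_model"))
  z <- traj$z
  if (literal_formula) {
    traj$oligomer_size * mean_photons * exp(z / evanescent$penetration_depth)
  } else {
    traj$oligomer_size * mean_photons *
      exp(-(z - evanescent$z0) / evanescent$penetration_depth)
  }
}

# block-sum a (h*k) x (w*k) matrix down to h x w
block_sum <- function(m, k) {
  if (k == 1L) return(m)
  h <- nrow(m) / k
  w <- ncol(m) / k
  m <- rowsum(m, rep(seq_len(h), each = k))
  t(rowsum(t(m), rep(seq_len(w), each = k)))
}

#' Render trajectories into photon-mean frames
#'
#' Each alive emitter is rendered as a symmetric 2-D Gaussian of total volume
#' equal to its per-frame mean photons (scaled by the illumination profile at
#' its lateral position) on the supersampled grid, truncated at
#' `truncation_radius * sigma_PSF`, block-summed down to camera pixels;
#' background is added to every camera pixel.
#'
#' @param trajs A `trajectory_set`; each trajectory must carry a `photons`
#'   vector (see [emitter_intensity_series()]).
#' @param imaging An [imaging_config()].
#' @param psf A [psf_model()].
#' @param illumination An [illumination_model()].
#' @param background Mean background photons per camera pixel.
#' @return Array of photon means, dim `(height_px, width_px, n_frames)`.
#' @export
render_photon_frames <- function(trajs, imaging, psf, illumination,
                                 background = 0) {
  stopifnot(inherits(imaging, "imaging_config"), inherits(psf, "psf_model"),
            inherits(illumination, "illumination_model"))
  k <- as.integer(round(imaging$pixel_size / imaging$supersample_pitch))
  H <- imaging$height_px * k
  W <- imaging$width_px * k
  pitch <- imaging$supersample_pitch
  sig_ss <- psf_sigma(psf) / pitch
  R <- psf$truncation_radius * sig_ss
  scale_fun <- illumination_scale(illumination, imaging)

  # per-frame list of (cx, cy in supersample units, photons)
  nf <- imaging$n_frames
  out <- array(0, dim = c(imaging$height_px, imaging$width_px, nf))
  per_frame <- vector("list", nf)
  for (tr in trajs) {
    if (is.null(tr$photons))
      stop("trajectories must carry a 'photons' vector; see emitter_intensity_series()",
           call. = FALSE)
    amp <- tr$photons * scale_fun(tr$x, tr$y)
    for (j in seq_along(tr$frames)) {
      f <- tr$frames[j]
      if (f < 1L || f > nf) next
      per_frame[[f]] <- c(per_frame[[f]],
                          list(c(tr$x[j] * 1000 / pitch,
                                 tr$y[j] * 1000 / pitch, amp[j])))
    }
  }

  for (f in seq_len(nf)) {
    ems <- per_frame[[f]]
    if (length(ems)) {
      canvas <- matrix(0, H, W)
      for (e in ems) {
        cx <- e[1]; cy <- e[2]; photons <- e[3]
        jx <- max(1L, ceiling(cx - R)):min(W, floor(cx + R) + 1L)
        iy <- max(1L, ceiling(cy - R)):min(H, floor(cy + R) + 1L)
        if (jx[1] > jx[length(jx)] || iy[1] > iy[length(iy)]) next
        if (cx + R < 1 || cx - R > W || cy + R < 1 || cy - R > H) next
        gx <- stats::dnorm(jx - 0.5, mean = cx, sd = sig_ss)
        gy <- stats::dnorm(iy - 0.5, mean = cy, sd = sig_ss)
        canvas[iy, jx] <- canvas[iy, jx] + photons * outer(gy, gx)
      }
      out[, , f] <- block_sum(canvas, k) + background
    } else {
      out[, , f] <- background
    }
  }
  out
}

#' Apply the EMCCD camera model to photon-mean frames
#'
#' Per pixel: mu_e = QE * photons; stochastic electrons are drawn with mean
#' mu_e and variance F² mu_e (implemented as F² * Poisson(mu_e / F²), a
#' mean-preserving inflation of the shot-noise variance by the EM excess
#' factor); counts = electrons * ecf + offset + Normal(0, read_sigma),
#' rounded and clipped to the 16-bit range.
#'
#' @param photon_means Numeric array/matrix of mean photons per pixel.
#' @param camera A [camera_model()].
#' @param seed Optional seed; omit to continue the current RNG stream.
#' @return Integer array of camera counts with the same dimensions.
#' @export
apply_camera_model <- function(photon_means, camera, seed = NULL) {
  stopifnot(inherits(camera, "camera_model"))
  if (any(photon_means < 0)) stop("photon means must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  f2 <- camera$excess_factor^2
  mu_e <- camera$qe * as.numeric(photon_means)
  electrons <- f2 * stats::rpois(length(mu_e), mu_e / f2)
  counts <- electrons * camera$ecf + camera$offset
  if (camera$read_sigma > 0)
    counts <- counts + stats::rnorm(length(counts), 0, camera$read_sigma)
  counts <- pmin(pmax(round(counts), 0), 65535)
  out <- as.integer(counts)
  dim(out) <- dim(photon_means)
  out
}

#' Run a complete simulation
#'
#' Deterministic for a fixed seed. Returns the synthetic camera stack plus a
#' ground-truth table with one row per alive emitter per frame. In
#' `"paint"` mode trajectories are stationary with exponential on-times
#' starting uniformly in time.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>.tif` (16-bit multi-page), `<prefix>_truth.csv` and
#'   `<prefix>_config.json` (config snapshot including the seed).
#' @return A list with `stack` (class `synthetic_stack`: `frames`, `config`,
#'   `seed`) and `truth` (data.frame with columns frame, id, x_um, y_um,
#'   z_nm, photons, oligomer_size, in_field).
#' @export
run_simulation <- function(config, seed = 1L, out_prefix = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  trajs <- simulate_trajectories(config$imaging, config$emitter,
                                 config$evanescent, seed = NULL,
                                 mode = config$mode,
                                 illumination = config$illumination,
                                 max_emitters = config$max_emitters)
  for (i in seq_along(trajs)) {
    trajs[[i]]$photons <- emitter_intensity_series(
      trajs[[i]], config$emitter$mean_photons, config$evanescent)
  }
  photon_means <- render_photon_frames(trajs, config$imaging, config$psf,
                                       config$illumination,
                                       background = config$background)
  frames <- apply_camera_model(photon_means, config$camera)

  w_um <- config$imaging$width_px * config$imaging$pixel_size / 1000
  h_um <- config$imaging$height_px * config$imaging$pixel_size / 1000
  if (length(trajs)) {
    truth <- do.call(rbind, lapply(trajs, function(tr) {
      data.frame(frame = tr$frames, id = tr$id, x_um = tr$x, y_um = tr$y,
                 z_nm = tr$z, photons = tr$photons,
                 oligomer_size = tr$oligomer_size,
                 in_field = tr$x >= 0 & tr$x <= w_um &
                            tr$y >= 0 & tr$y <= h_um)
    }))
    truth <- truth[truth$frame >= 1 & truth$frame <= config$imaging$n_frames, ]
    truth <- truth[order(truth$frame, truth$id), ]
    rownames(truth) <- NULL
  } else {
    truth <- data.frame(frame = integer(0), id = integer(0),
                        x_um = numeric(0), y_um = numeric(0),
                        z_nm = numeric(0), photons = numeric(0),
                        oligomer_size = integer(0), in_field = logical(0))
  }

  stack <- structure(list(frames = frames, config = config, seed = seed),
                     class = "synthetic_stack")
  if (!is.null(out_prefix)) {
    write_stack(stack, paste0(out_prefix, ".tif"))
    utils::write.csv(truth, paste0(out_prefix, "_truth.csv"),
                     row.names = FALSE)
    snap <- config_to_list(config)
    snap$seed <- seed
    jsonlite::write_json(snap, paste0(out_prefix, "_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(stack = stack, truth = truth)
}

#' @export
print.synthetic_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("synthetic_stack: %d frames of %d x %d px (seed %s)\n",
              d[3], d[1], d[2], format(x$seed)))
  invisible(x)
}
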