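test_that("static well-separated emitters give one full track each", {
  locs <- data.frame(frame = rep(1:10, 3),
                     x = rep(c(1000, 5000, 9000), each = 10),
                     y = rep(c(1000, 5000, 1000), each = 10))
  tr <- link_tracks(locs, max_link = 500)
  expect_equal(length(unique(tr$track_id)), 3)
  expect_true(all(table(tr$track_id) == 10))
  # frames strictly increasing within tracks
  by_tr <- split(tr$frame, tr$track_id)
  expect_true(all(vapply(by_tr, function(f) all(diff(f) > 0), TRUE)))
})

test_that("gap closing bridges up to two missed frames within 500 nm", {
  locs <- data.frame(frame = c(1:3, 6:10), x = 1000, y = 1000)
  tr <- link_tracks(locs, max_link = 500, max_gap_frames = 2,
                    max_gap_distance = 500)
  expect_equal(length(unique(tr$track_id)), 1)

  # three missed frames exceed the gap limit
  locs3 <- data.frame(frame = c(1:3, 7:10), x = 1000, y = 1000)
  tr3 <- link_tracks(locs3, max_link = 500, max_gap_frames = 2)
  expect_equal(length(unique(tr3$track_id)), 2)

  # displacement above max_link terminates the track
  jump <- data.frame(frame = 1:6, x = c(rep(1000, 3), rep(3000, 3)),
                     y = 1000)
  trj <- link_tracks(jump, max_link = 500)
  expect_equal(length(unique(trj$track_id)), 2)
})

test_that("linking is invariant to input row order", {
  set.seed(12)
  base <- do.call(rbind, lapply(1:6, function(i)
    data.frame(frame = 1:15,
               x = 2500 * i + cumsum(stats::rnorm(15, 0, 60)),
               y = 2500 * i + cumsum(stats::rnorm(15, 0, 60)))))
  t1 <- link_tracks(base, max_link = 500)
  t2 <- link_tracks(base[sample(nrow(base)), ], max_link = 500)
  key <- function(tt) {
    sets <- lapply(split(paste(tt$frame, round(tt$x, 6), round(tt$y, 6)),
                         tt$track_id), sort)
    sort(vapply(sets, paste, "", collapse = "|"))
  }
  expect_identical(key(t1), key(t2))
})

test_that("confinement ratio is 1 for directed motion and small for confined", {
  directed <- link_tracks(data.frame(frame = 1:20, x = (1:20) * 100, y = 0),
                          max_link = 500)
  expect_equal(track_stats(directed)$confinement_ratio, 1)
  set.seed(4)
  confined <- link_tracks(data.frame(frame = 1:200,
                                     x = stats::rnorm(200, 0, 30),
                                     y = stats::rnorm(200, 0, 30)),
                          max_link = 500)
  st <- track_stats(confined)
  expect_equal(st$length, 200)
  expect_lt(st$confinement_ratio, 0.1)
})

test_that("immobile filter separates fixed emitters from diffusers", {
  set.seed(9)
  imm <- data.frame(frame = 1:100, x = stats::rnorm(100, 0, 20),
                    y = stats::rnorm(100, 0, 20))
  step <- sqrt(2 * 0.1 * 0.025) * 1000
  mob <- data.frame(frame = 1:100,
                    x = 5e4 + cumsum(stats::rnorm(100)) * step,
                    y = cumsum(stats::rnorm(100)) * step)
  fi <- filter_immobile(rbind(imm, mob), radius = 100, obs_prob = 0.5)
  # the fixed emitter is fully immobile; the diffuser mostly mobile
  expect_true(all(fi$immobile$x < 1000))
  expect_gt(sum(fi$mobile$x > 1000), 50)

  e <- filter_immobile(data.frame(frame = integer(0), x = numeric(0),
                                  y = numeric(0)))
  expect_equal(nrow(e$immobile), 0)
  expect_equal(nrow(e$mobile), 0)
})

test_that("channel transforms recover known mappings exactly", {
  set.seed(7)
  a <- matrix(stats::runif(24, 0, 2e4), 12, 2)
  # identity
  ident <- fit_channel_transform(a, a, "affine")
  expect_equal(ident$matrix, diag(3), tolerance = 1e-9)
  expect_lt(ident$rms, 1e-9)
  # known affine
  M <- rbind(c(1.02, 0.03, 50), c(-0.01, 0.98, -30), c(0, 0, 1))
  b <- tirfsmt:::apply_transform_matrix(M, a)
  fa <- fit_channel_transform(a, b, "affine")
  expect_lt(max(abs(fa$matrix - M)) / max(abs(M)), 1e-9)
  # exact projective correspondences
  H <- rbind(c(1.1, 0.05, 20), c(0.02, 0.95, 10), c(1e-5, -2e-5, 1))
  bh <- tirfsmt:::apply_transform_matrix(H, a[1:4, ])
  fp <- fit_channel_transform(a[1:4, ], bh, "projective")
  expect_lt(fp$rms, 1e-6)
  # apply/invert round-trip
  back <- apply_transform(fa, apply_transform(fa, a), inverse = TRUE)
  expect_equal(unname(back), unname(a), tolerance = 1e-9)
  # degenerate configurations
  col <- cbind(1:5, 2 * (1:5))
  expect_error(fit_channel_transform(col, col, "affine"), "degenerate")
  expect_error(fit_channel_transform(a[1:2, ], a[1:2, ], "affine"), ">= 3")
})

test_that("transform residual scales linearly with coordinate noise", {
  set.seed(15)
  a <- matrix(stats::runif(40, 0, 2e4), 20, 2)
  rms_at <- vapply(c(5, 10, 20), function(s) {
    b <- a + stats::rnorm(40, 0, s)
    fit_channel_transform(a, b, "affine")$rms
  }, 1.0)
  expect_equal(rms_at[2] / rms_at[1], 2, tolerance = 0.5)
  expect_equal(rms_at[3] / rms_at[1], 4, tolerance = 1.0)
})

test_that("MSD curves and diffusion fits behave as the theory dictates", {
  # stationary
  still <- data.frame(frame = 1:10, x = 5, y = 5)
  expect_true(all(msd_curve(still, dt = 1)$msd == 0))
  expect_error(msd_curve(still[1, , drop = FALSE]), ">= 2")

  # constant velocity: MSD = v^2 t^2
  v <- 200   # nm per frame interval of 0.5 s
  cv <- data.frame(frame = 1:20, x = (1:20) * v, y = 0)
  m <- msd_curve(cv, dt = 0.5)
  expect_equal(m$msd, (v / 0.5)^2 * m$lag_s^2, tolerance = 1e-12)

  # exact linear MSD: D = slope / 4, intercept absorbed
  msd_lin <- structure(data.frame(lag_s = 1:8, msd = 4 * 0.1 * (1:8) + 0.3),
                       class = c("msd_curve", "data.frame"))
  est <- diffusion_from_msd(msd_lin)
  expect_equal(est$D, 0.1, tolerance = 1e-12)
  expect_equal(est$intercept, 0.3, tolerance = 1e-12)
  expect_equal(est$n_points, 5)

  # lags beyond the fifth are ignored
  msd_bad <- msd_lin
  msd_bad$msd[6:8] <- 99
  expect_equal(diffusion_from_msd(msd_bad)$D, 0.1, tolerance = 1e-12)

  # ensemble of random walks recovers D within 5%
  set.seed(22)
  step <- sqrt(2 * 0.1 * 0.02)   # um
  Ds <- replicate(400, {
    tr <- data.frame(frame = 1:15,
                     x = cumsum(stats::rnorm(15)) * step,
                     y = cumsum(stats::rnorm(15)) * step)
    diffusion_from_msd(msd_curve(tr, dt = 0.02))$D
  })
  expect_equal(mean(Ds), 0.1, tolerance = 0.05)
})
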