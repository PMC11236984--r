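#' @title Intensity-based stoichiometry
#' @name stoichiometry
#' @description Gaussian-mixture fitting of single-molecule intensity
#'   histograms, dimerization levels from peak integrals and
#'   threshold-based monomer/dimer classification.
NULL

freedman_diaconis <- function(x) {
  iqr <- stats::IQR(x)
  if (iqr == 0) return(NA_real_)
  2 * iqr / length(x)^(1 / 3)
}

#' Fit a Gaussian mixture to an intensity histogram
#'
#' Builds a histogram with the given bin width and fits a k-component sum of
#' Gaussians A_j * exp(-(x - mu_j)^2 / (2 sigma_j^2)) to the bin counts by
#' nonlinear least squares. Components are initialized from a k-quantile
#' split of the samples and reported sorted by ascending mean, with standard
#' errors from the fit covariance.
#'
#' @param intensities Numeric vector of intensities in photons (>= 100
#'   samples recommended).
#' @param k Number of components (1, 2 or 3).
#' @param bin_width Histogram bin width in photons; default is the
#'   Freedman-Diaconis choice.
#' @param constrain_double If `TRUE` (k = 2 only), constrain the second mean
#'   to twice the first (mu_2 = 2 mu_1).
#' @param init_means Optional numeric vector of length k of starting
#'   component means, overriding the k-means initialization (used e.g. to
#'   target a known dim spur population).
#' @return A `mixture_fit`: list with `mean`, `sigma`, `amplitude`, their
#'   standard errors (`se_*`), `k`, `bin_width` and the fitted histogram.
#' @export
fit_intensity_mixture <- function(intensities, k = 1L, bin_width = NULL,
                                  constrain_double = FALSE,
                                  init_means = NULL) {
  stopifnot(k %in% 1:3)
  x <- intensities[is.finite(intensities)]
  if (length(x) < 10) stop("too few intensity samples", call. = FALSE)
  if (is.null(bin_width)) bin_width <- freedman_diaconis(x)
  if (!is.finite(bin_width) || bin_width <= 0 || diff(range(x)) < bin_width)
    stop("degenerate intensity histogram (no spread at this bin width)",
         call. = FALSE)
  breaks <- seq(min(x) - bin_width, max(x) + bin_width, by = bin_width)
  hh <- graphics::hist(x, breaks = breaks, plot = FALSE)
  d <- data.frame(mid = hh$mids, counts = hh$counts)

  # k-quantile split initialization, refined by one k-means pass; explicit
  # init_means assign samples to the nearest requested mean instead
  if (!is.null(init_means)) {
    stopifnot(length(init_means) == k)
    grp <- apply(abs(outer(x, init_means, "-")), 1, which.min)
  } else {
    qs <- stats::quantile(x, probs = seq(0, 1, length.out = k + 2)[-c(1, k + 2)])
    grp <- if (k == 1) rep(1L, length(x)) else
      tryCatch(stats::kmeans(x, centers = unique(qs))$cluster,
               error = function(e) cut(x, breaks = k, labels = FALSE))
  }
  mu0 <- unname(tapply(x, grp, mean))
  ord0 <- order(mu0)
  mu0 <- mu0[ord0]
  sd0 <- unname(pmax(tapply(x, grp, stats::sd), bin_width))[ord0]
  sd0[is.na(sd0)] <- bin_width
  a0 <- unname(tapply(x, grp, length))[ord0] * bin_width /
    (sd0 * sqrt(2 * pi))
  if (length(mu0) < k) stop("initialization failed: fewer groups than k",
                            call. = FALSE)

  if (k == 1) {
    form <- counts ~ a1 * exp(-(mid - m1)^2 / (2 * s1^2))
    start <- list(a1 = a0[1], m1 = mu0[1], s1 = sd0[1])
  } else if (k == 2 && constrain_double) {
    form <- counts ~ a1 * exp(-(mid - m1)^2 / (2 * s1^2)) +
      a2 * exp(-(mid - 2 * m1)^2 / (2 * s2^2))
    start <- list(a1 = a0[1], m1 = mu0[1], s1 = sd0[1],
                  a2 = a0[2], s2 = sd0[2])
  } else if (k == 2) {
    form <- counts ~ a1 * exp(-(mid - m1)^2 / (2 * s1^2)) +
      a2 * exp(-(mid - m2)^2 / (2 * s2^2))
    start <- list(a1 = a0[1], m1 = mu0[1], s1 = sd0[1],
                  a2 = a0[2], m2 = mu0[2], s2 = sd0[2])
  } else {
    form <- counts ~ a1 * exp(-(mid - m1)^2 / (2 * s1^2)) +
      a2 * exp(-(mid - m2)^2 / (2 * s2^2)) +
      a3 * exp(-(mid - m3)^2 / (2 * s3^2))
    start <- list(a1 = a0[1], m1 = mu0[1], s1 = sd0[1],
                  a2 = a0[2], m2 = mu0[2], s2 = sd0[2],
                  a3 = a0[3], m3 = mu0[3], s3 = sd0[3])
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = d, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf(
        "mixture fit did not converge (%s); initial values: %s",
        conditionMessage(e),
        paste(sprintf("%s=%.3g", names(start), unlist(start)),
              collapse = ", ")), call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  if (k == 2 && constrain_double) {
    cf <- c(cf, m2 = unname(2 * cf["m1"]))
    se <- c(se, m2 = unname(2 * se["m1"]))
  }
  mu <- abs(cf[paste0("m", 1:k)])
  sg <- abs(cf[paste0("s", 1:k)])
  am <- cf[paste0("a", 1:k)]
  ord <- order(mu)
  res <- list(mean = unname(mu[ord]), sigma = unname(sg[ord]),
              amplitude = unname(am[ord]),
              se_mean = unname(se[paste0("m", 1:k)][ord]),
              se_sigma = unname(se[paste0("s", 1:k)][ord]),
              se_amplitude = unname(se[paste0("a", 1:k)][ord]),
              k = k, bin_width = bin_width,
              histogram = d, fitted = stats::fitted(fit))
  class(res) <- "mixture_fit"
  res
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("%d-component Gaussian mixture (bin width %.3g):\n",
              x$k, x$bin_width))
  for (j in seq_len(x$k))
    cat(sprintf("  component %d: mean = %.4g +/- %.2g, sigma = %.4g +/- %.2g, amplitude = %.4g\n",
                j, x$mean[j], x$se_mean[j], x$sigma[j], x$se_sigma[j],
                x$amplitude[j]))
  invisible(x)
}

#' Gaussian areas of a mixture fit
#'
#' Area of each unnormalized component, amplitude * sigma (the sqrt(2*pi)
#' factor cancels in any area ratio).
#'
#' @param fit A `mixture_fit`.
#' @return Numeric vector of component areas.
#' @export
mixture_areas <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  fit$amplitude * fit$sigma
}

#' Dimerization level from the peak integrals of a bimodal fit
#'
#' Fraction of particles in the high-intensity peak,
#' A2 * sigma2 / (A1 * sigma1 + A2 * sigma2).
#'
#' @param fit A two-component `mixture_fit`.
#' @return Dimer fraction in \[0, 1\].
#' @export
dimer_level_from_integrals <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (fit$k != 2) stop("dimer level requires a k = 2 fit", call. = FALSE)
  ar <- mixture_areas(fit)
  ar[2] / sum(ar)
}

#' Classify particles by an intensity threshold
#'
#' Particles at or below the threshold are classified low (monomers), above
#' it high (dimers); values exactly at the threshold are assigned low.
#'
#' @param x Numeric intensities in photons, or a data frame with an
#'   `intensity` column.
#' @param threshold Classification threshold in photons (e.g. 625 for the
#'   ~400/~800-photon monomer/dimer regime, or 165 at lower signal levels).
#' @return List with `low` and `high` partitions (same type as the input)
#'   and a `label` factor.
#' @export
classify_particles <- function(x, threshold) {
  vals <- if (is.data.frame(x)) x$intensity else x
  lab <- factor(ifelse(vals <= threshold, "low", "high"),
                levels = c("low", "high"))
  if (is.data.frame(x)) {
    list(low = x[lab == "low", , drop = FALSE],
         high = x[lab == "high", , drop = FALSE], label = lab)
  } else {
    list(low = vals[lab == "low"], high = vals[lab == "high"], label = lab)
  }
}
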