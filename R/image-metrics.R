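#' @title Image resolution and meshwork metrics
#' @name image-metrics
#' @description Parameter-free resolution estimation by decorrelation
#'   analysis of the Fourier phase correlation, automatic thresholding, and
#'   corral-size statistics on binary meshwork masks.
NULL

# raised-cosine edge taper of the given width (px)
apodize <- function(img, width = 20) {
  h <- nrow(img); w <- ncol(img)
  taper <- function(n) {
    t <- rep(1, n)
    k <- min(width, floor(n / 2))
    if (k > 0) {
      ramp <- 0.5 * (1 - cos(pi * (seq_len(k) - 0.5) / k))
      t[seq_len(k)] <- ramp
      t[n + 1 - seq_len(k)] <- ramp
    }
    t
  }
  img * outer(taper(h), taper(w))
}

fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c((floor(h / 2) + 1):h, 1:floor(h / 2)),
    c((floor(w / 2) + 1):w, 1:floor(w / 2))]
}

#' Decorrelation parameters
#'
#' @param n_radii Number of mask radii sampled in (0, 1] (default 50).
#' @param n_filters Number of Gaussian high-pass filters, log-spaced in
#'   width (default 10).
#' @param apod_width Edge apodization taper width in px (default 20).
#' @return An object of class `decorr_params`.
#' @export
decorr_params <- function(n_radii = 50L, n_filters = 10L, apod_width = 20) {
  stopifnot(n_radii >= 10, n_filters >= 1)
  structure(list(n_radii = as.integer(n_radii),
                 n_filters = as.integer(n_filters),
                 apod_width = apod_width),
            class = "decorr_params")
}

# decorrelation curve d(r): Pearson-type correlation in Fourier space of
# I(k) with its unit-modulus normalization masked at radius r; since
# I(k) conj(I_n(k)) = |I(k)| this reduces to cumulative |I| sums
decorr_curve <- function(modI, rnorm_sorted, ord, radii) {
  mod_sorted <- modI[ord]
  cum <- cumsum(mod_sorted)
  cnt <- seq_along(mod_sorted)
  total <- sqrt(sum(mod_sorted^2))
  idx <- findInterval(radii, rnorm_sorted)
  d <- ifelse(idx > 0, cum[pmax(idx, 1)] / (total * sqrt(cnt[pmax(idx, 1)])), 0)
  d[idx == 0] <- 0
  d
}

# highest local maximum of a lightly smoothed curve; NA if no interior peak
curve_peak <- function(radii, d) {
  if (length(d) >= 5) {
    ker <- c(1, 2, 3, 2, 1) / 9
    ds <- stats::filter(d, ker, sides = 2)
    ds[is.na(ds)] <- d[is.na(ds)]
  } else ds <- d
  n <- length(ds)
  if (n < 3) return(NA_real_)
  ismax <- which(ds[2:(n - 1)] > ds[1:(n - 2)] & ds[2:(n - 1)] >= ds[3:n]) + 1
  if (!length(ismax)) return(NA_real_)
  radii[ismax[which.max(ds[ismax])]]
}

#' Image resolution by decorrelation analysis
#'
#' The apodized image is Fourier transformed; the decorrelation function
#' d(r) is the Pearson correlation of I(k) with its unit-modulus
#' normalization masked by a binary circle of normalized radius r (r = 1 at
#' Nyquist). The analysis is repeated after each of `n_filters` Gaussian
#' high-pass filters of log-spaced width; the cut-off k_c is the maximum of
#' the per-curve peak positions and the resolution is 2 * pixel_size / k_c.
#'
#' @param image 2-D numeric matrix.
#' @param pixel_size Pixel size (any length unit; the resolution is returned
#'   in the same unit).
#' @param params A [decorr_params()].
#' @return A `decorr_result`: list with `kc`, `resolution`, `peaks` (one per
#'   curve) and `curves` (matrix of d(r) values, one column per filter).
#' @export
decorrelation_resolution <- function(image, pixel_size,
                                     params = decorr_params()) {
  stopifnot(is.matrix(image))
  img <- apodize(image - mean(image), params$apod_width)
  if (all(img == 0))
    stop("featureless input: no decorrelation peak", call. = FALSE)
  Fk <- fftshift2(stats::fft(img))
  h <- nrow(Fk); w <- ncol(Fk)
  fy <- ((seq_len(h) - 1) - floor(h / 2)) / (h / 2)
  fx <- ((seq_len(w) - 1) - floor(w / 2)) / (w / 2)
  rr <- sqrt(outer(fy^2, fx^2, "+"))
  inside <- rr <= 1
  rvec <- rr[inside]
  ord <- order(rvec)
  rsorted <- rvec[ord]
  radii <- seq(1 / params$n_radii, 1, length.out = params$n_radii)

  # log-spaced high-pass widths in normalized frequency
  sig_k <- exp(seq(log(0.05), log(1), length.out = params$n_filters))
  modI0 <- Mod(Fk)[inside]
  curves <- matrix(0, params$n_radii, params$n_filters + 1)
  peaks <- rep(NA_real_, params$n_filters + 1)
  curves[, 1] <- decorr_curve(modI0, rsorted, ord, radii)
  peaks[1] <- curve_peak(radii, curves[, 1])
  for (g in seq_len(params$n_filters)) {
    hp <- 1 - exp(-rvec^2 / (2 * sig_k[g]^2))
    curves[, g + 1] <- decorr_curve(modI0 * hp, rsorted, ord, radii)
    peaks[g + 1] <- curve_peak(radii, curves[, g + 1])
  }
  if (all(is.na(peaks)))
    stop("featureless input: no decorrelation peak", call. = FALSE)
  kc <- max(peaks, na.rm = TRUE)
  structure(list(kc = kc, resolution = 2 * pixel_size / kc, peaks = peaks,
                 radii = radii, curves = curves),
            class = "decorr_result")
}

#' @export
print.decorr_result <- function(x, ...) {
  cat(sprintf("decorrelation analysis: k_c = %.3f, resolution = %.4g\n",
              x$kc, x$resolution))
  invisible(x)
}

#' Automatic image threshold
#'
#' @param image Numeric matrix.
#' @param method `"isodata"` (iterative intermeans, the classic default of
#'   histogram-based particle analysis) or `"otsu"`.
#' @return Threshold value; foreground is `image > threshold`.
#' @export
auto_threshold <- function(image, method = c("isodata", "otsu")) {
  method <- match.arg(method)
  v <- as.numeric(image)
  if (method == "isodata") {
    t0 <- mean(range(v))
    repeat {
      lo <- v[v <= t0]; hi <- v[v > t0]
      if (!length(lo) || !length(hi)) return(t0)
      t1 <- (mean(lo) + mean(hi)) / 2
      if (abs(t1 - t0) < 1e-9 * diff(range(v))) return(t1)
      t0 <- t1
    }
  } else {
    brk <- seq(min(v), max(v), length.out = 257)
    hcnt <- graphics::hist(v, breaks = brk, plot = FALSE)
    p <- hcnt$counts / sum(hcnt$counts)
    mids <- hcnt$mids
    w0 <- cumsum(p)
    mu <- cumsum(p * mids)
    mu_t <- mu[length(mu)]
    sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
    sigma_b[!is.finite(sigma_b)] <- 0
    mids[which.max(sigma_b)]
  }
}

# 4-connected component labelling via the pixel adjacency graph
label_components4 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask)
  if (!length(fg)) return(matrix(0L, h, w))
  pos <- integer(h * w)
  pos[fg] <- seq_along(fg)
  ri <- ((fg - 1) %% h) + 1
  ci <- ((fg - 1) %/% h) + 1
  down <- fg[ri < h]
  down <- down[mask[down + 1]]
  right <- fg[ci < w]
  right <- right[mask[right + h]]
  el <- rbind(cbind(pos[down], pos[down + 1]),
              cbind(pos[right], pos[right + h]))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab <- matrix(0L, h, w)
  lab[fg] <- comp[seq_along(fg)]
  lab
}

#' Corral-size statistics of a binary meshwork mask
#'
#' Labels the 4-connected foreground components (corral interiors), drops
#' components touching the image border, filters by maximum area and
#' reports areas and equivalent-circle diameters.
#'
#' @param mask Logical (or 0/1) matrix; foreground = corral interiors.
#'   Callers segmenting a skeletonized meshwork should invert it first (see
#'   [auto_threshold()]).
#' @param pixel_size Pixel size in nm.
#' @param max_area Maximum corral area kept, in µm² (default 0.25).
#' @return A `corral_stats`: data frame of per-corral `area_um2` and
#'   `diameter_nm`, with attributes `mean_area_um2` and `count`.
#' @export
corral_stats <- function(mask, pixel_size, max_area = 0.25) {
  mask <- mask > 0
  lab <- label_components4(mask)
  empty <- structure(data.frame(area_um2 = numeric(0),
                                diameter_nm = numeric(0)),
                     mean_area_um2 = NA_real_, count = 0L,
                     class = c("corral_stats", "data.frame"))
  if (!any(lab > 0)) return(empty)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  counts <- table(lab[lab > 0 & !(lab %in% border)])
  if (!length(counts)) return(empty)
  px_um2 <- (pixel_size / 1000)^2
  areas <- as.numeric(counts) * px_um2
  keep <- areas <= max_area
  areas <- areas[keep]
  out <- data.frame(area_um2 = areas,
                    diameter_nm = 2 * sqrt(areas / pi) * 1000)
  structure(out, mean_area_um2 = if (length(areas)) mean(areas) else NA_real_,
            count = length(areas),
            class = c("corral_stats", "data.frame"))
}
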