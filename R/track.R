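#' @title Trajectory linking, immobile filtering, registration and diffusion
#' @name track
#' @description Frame-to-frame linking with gap closing, a density-based
#'   (DBSCAN) immobile-particle filter, bead-based channel registration and
#'   mean-squared-displacement diffusion estimation.
NULL

# greedy globally-sorted assignment between two point sets: candidate pairs
# within max_dist are taken in order of increasing distance, each point used
# at most once; returns two-column index matrix
greedy_assign <- function(ax, ay, bx, by, max_dist) {
  na <- length(ax); nb <- length(bx)
  if (na == 0 || nb == 0) return(matrix(integer(0), 0, 2))
  d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
  cand <- which(d2 <= max_dist^2, arr.ind = TRUE)
  if (nrow(cand) == 0) return(matrix(integer(0), 0, 2))
  cand <- cand[order(d2[cand]), , drop = FALSE]
  used_a <- logical(na); used_b <- logical(nb)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, 1]; b <- cand[i, 2]
    if (!used_a[a] && !used_b[b]) {
      keep[i] <- TRUE
      used_a[a] <- TRUE
      used_b[b] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Link localizations into trajectories
#'
#' Frame-to-frame assignment minimizing squared displacement (greedy,
#' globally sorted by distance, each localization used once), followed by
#' greedy gap closing: a track end may be joined to a track start up to
#' `max_gap_frames` later and within `max_gap_distance`.
#'
#' @param locs Localization table with columns `frame`, `x`, `y` (nm); other
#'   columns are carried through.
#' @param max_link Maximum frame-to-frame linking distance in nm.
#' @param max_gap_frames Maximum number of missed frames bridged by gap
#'   closing (default 2).
#' @param max_gap_distance Maximum gap-closing distance in nm (default 500).
#' @return The input rows with a `track_id` column, ordered by track and
#'   frame (class `track_table`).
#' @export
link_tracks <- function(locs, max_link = 500, max_gap_frames = 2,
                        max_gap_distance = 500) {
  stopifnot(all(c("frame", "x", "y") %in% names(locs)))
  if (nrow(locs) == 0) {
    locs$track_id <- integer(0)
    class(locs) <- c("track_table", class(locs))
    return(locs)
  }
  locs <- locs[order(locs$frame, locs$x, locs$y), , drop = FALSE]
  rownames(locs) <- NULL
  track_of <- integer(nrow(locs))
  frames <- sort(unique(locs$frame))
  idx_by_frame <- split(seq_len(nrow(locs)), locs$frame)
  next_id <- 0L

  prev_idx <- idx_by_frame[[as.character(frames[1])]]
  track_of[prev_idx] <- next_id + seq_along(prev_idx)
  next_id <- next_id + length(prev_idx)
  if (length(frames) > 1) for (fi in 2:length(frames)) {
    cur_idx <- idx_by_frame[[as.character(frames[fi])]]
    contiguous <- frames[fi] - frames[fi - 1] == 1
    if (contiguous && length(prev_idx)) {
      m <- greedy_assign(locs$x[prev_idx], locs$y[prev_idx],
                         locs$x[cur_idx], locs$y[cur_idx], max_link)
    } else m <- matrix(integer(0), 0, 2)
    linked_cur <- logical(length(cur_idx))
    if (nrow(m)) {
      track_of[cur_idx[m[, 2]]] <- track_of[prev_idx[m[, 1]]]
      linked_cur[m[, 2]] <- TRUE
    }
    nnew <- sum(!linked_cur)
    if (nnew) {
      track_of[cur_idx[!linked_cur]] <- next_id + seq_len(nnew)
      next_id <- next_id + nnew
    }
    prev_idx <- cur_idx
  }

  # gap closing: join track ends to later track starts
  if (max_gap_frames > 0) {
    ends <- vapply(split(seq_len(nrow(locs)), track_of),
                   function(ii) ii[which.max(locs$frame[ii])], 1L)
    starts <- vapply(split(seq_len(nrow(locs)), track_of),
                     function(ii) ii[which.min(locs$frame[ii])], 1L)
    cand <- list()
    for (e in seq_along(ends)) {
      fe <- locs$frame[ends[e]]
      ok <- which(locs$frame[starts] - fe >= 2 &
                  locs$frame[starts] - fe <= max_gap_frames + 1)
      for (s in ok) {
        d <- sqrt((locs$x[ends[e]] - locs$x[starts[s]])^2 +
                  (locs$y[ends[e]] - locs$y[starts[s]])^2)
        if (d <= max_gap_distance)
          cand[[length(cand) + 1L]] <- c(e, s, d)
      }
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand[, 3]), , drop = FALSE]
      ids <- as.integer(names(ends))
      merged_from <- logical(length(ends))
      merged_into <- logical(length(starts))
      for (i in seq_len(nrow(cand))) {
        e <- cand[i, 1]; s <- cand[i, 2]
        if (merged_from[e] || merged_into[s] || ids[e] == ids[s]) next
        track_of[track_of == ids[s]] <- ids[e]
        ids[ids == ids[s]] <- ids[e]
        merged_from[e] <- TRUE
        merged_into[s] <- TRUE
      }
    }
  }

  locs$track_id <- match(track_of, unique(track_of[order(locs$frame)]))
  locs <- locs[order(locs$track_id, locs$frame), , drop = FALSE]
  rownames(locs) <- NULL
  class(locs) <- c("track_table", class(locs))
  locs
}

#' Per-track summary statistics
#'
#' @param tracks A `track_table` from [link_tracks()].
#' @return Data frame with one row per track: `track_id`, `length` (number
#'   of localizations), `net_nm` (net displacement), `path_nm` (total path
#'   length) and `confinement_ratio` = net / path (1 for straight directed
#'   motion, near 0 for confined tracks).
#' @export
track_stats <- function(tracks) {
  do.call(rbind, lapply(split(tracks, tracks$track_id), function(tr) {
    n <- nrow(tr)
    dx <- diff(tr$x); dy <- diff(tr$y)
    path <- sum(sqrt(dx^2 + dy^2))
    net <- sqrt((tr$x[n] - tr$x[1])^2 + (tr$y[n] - tr$y[1])^2)
    data.frame(track_id = tr$track_id[1], length = n, net_nm = net,
               path_nm = path,
               confinement_ratio = if (path > 0) net / path else 0)
  }))
}

# exact epsilon-neighbourhood DBSCAN with a grid accelerator
dbscan_cluster <- function(x, y, eps, min_pts = 10L) {
  n <- length(x)
  if (n == 0) return(integer(0))
  gx <- floor(x / eps); gy <- floor(y / eps)
  cell <- paste(gx, gy)
  cell_idx <- split(seq_len(n), cell)
  neighbours <- function(i) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      key <- paste(gx[i] + dx, gy[i] + dy)
      ci <- cell_idx[[key]]
      if (!is.null(ci)) cand <- c(cand, ci)
    }
    cand[(x[cand] - x[i])^2 + (y[cand] - y[i])^2 <= eps^2]
  }
  labels <- rep(0L, n)   # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    nb <- neighbours(i)
    if (length(nb) < min_pts) { labels[i] <- -1L; next }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[1L]
      queue <- queue[-1L]
      if (labels[j] == -1L) labels[j] <- cl
      if (labels[j] != 0L) next
      labels[j] <- cl
      nbj <- neighbours(j)
      if (length(nbj) >= min_pts)
        queue <- c(queue, nbj[labels[nbj] == 0L])
    }
  }
  labels
}

#' Separate immobile from mobile localizations
#'
#' Density-based clustering (DBSCAN) over all frames with search radius
#' `radius`; a cluster is classified immobile when it contains localizations
#' in at least `obs_prob` of the frames it spans.
#'
#' @param locs Localization table with columns `frame`, `x`, `y` (nm).
#' @param radius DBSCAN search radius in nm (default 100).
#' @param obs_prob Minimum fraction of spanned frames containing a cluster
#'   member (default 0.5).
#' @param min_pts DBSCAN core-point threshold (default 10): an immobile
#'   emitter keeps essentially all its localizations inside the search
#'   radius, while a free diffuser at typical membrane mobility spends only
#'   a few frames there, so a threshold of ~10 separates the two without a
#'   spatial-extent heuristic.
#' @return List with `immobile` and `mobile` localization tables; both carry
#'   a `cluster` column (NA for noise points).
#' @export
filter_immobile <- function(locs, radius = 100, obs_prob = 0.5,
                            min_pts = 10L) {
  if (nrow(locs) == 0) {
    locs$cluster <- integer(0)
    return(list(immobile = locs, mobile = locs))
  }
  labels <- dbscan_cluster(locs$x, locs$y, eps = radius, min_pts = min_pts)
  locs$cluster <- ifelse(labels > 0, labels, NA_integer_)
  immobile_cl <- integer(0)
  for (cl in setdiff(unique(labels), c(-1L, 0L))) {
    ii <- which(labels == cl)
    span <- diff(range(locs$frame[ii])) + 1
    covered <- length(unique(locs$frame[ii])) >= obs_prob * span
    # an immobile particle stays within the search radius of its centroid;
    # density-connected chains left by slow diffusers do not
    rmsd <- sqrt(mean((locs$x[ii] - mean(locs$x[ii]))^2 +
                      (locs$y[ii] - mean(locs$y[ii]))^2))
    if (covered && rmsd <= radius)
      immobile_cl <- c(immobile_cl, cl)
  }
  is_imm <- labels %in% immobile_cl
  list(immobile = locs[is_imm, , drop = FALSE],
       mobile = locs[!is_imm, , drop = FALSE])
}

#' Fit a channel registration transform from matched bead coordinates
#'
#' Least-squares affine or projective (homography, via the normalized direct
#' linear transform) mapping points in channel a onto channel b.
#'
#' @param points_a,points_b Two-column matrices or data frames (x, y in nm)
#'   of matched coordinates; at least 3 pairs for affine, 4 for projective.
#' @param kind `"affine"` or `"projective"`.
#' @return A `transform_model`: 3x3 `matrix`, `kind`, `rms` residual in nm.
#' @export
fit_channel_transform <- function(points_a, points_b,
                                  kind = c("affine", "projective")) {
  kind <- match.arg(kind)
  a <- as.matrix(points_a)[, 1:2, drop = FALSE]
  b <- as.matrix(points_b)[, 1:2, drop = FALSE]
  stopifnot(nrow(a) == nrow(b))
  n <- nrow(a)
  if (kind == "affine") {
    if (n < 3) stop("affine fit needs >= 3 point pairs", call. = FALSE)
    X <- cbind(a, 1)
    if (qr(X)$rank < 3)
      stop("degenerate (collinear) bead configuration", call. = FALSE)
    beta <- qr.solve(X, b)                    # 3 x 2
    M <- rbind(t(beta), c(0, 0, 1))
  } else {
    if (n < 4) stop("projective fit needs >= 4 point pairs", call. = FALSE)
    norm_pts <- function(p) {
      ctr <- colMeans(p)
      sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, ctr)^2)))
      T <- rbind(c(sc, 0, -sc * ctr[1]), c(0, sc, -sc * ctr[2]), c(0, 0, 1))
      list(T = T, p = cbind(p, 1) %*% t(T))
    }
    na <- norm_pts(a); nb <- norm_pts(b)
    A <- matrix(0, 2 * n, 9)
    for (i in seq_len(n)) {
      p <- na$p[i, ]; q <- nb$p[i, ]
      A[2 * i - 1, ] <- c(-p, 0, 0, 0, q[1] * p)
      A[2 * i, ]     <- c(0, 0, 0, -p, q[2] * p)
    }
    sv <- svd(A, nu = 0, nv = 9)
    if (sv$d[8] < 1e-10 * sv$d[1])
      stop("degenerate bead configuration", call. = FALSE)
    Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
    M <- solve(nb$T) %*% Hn %*% na$T
    M <- M / M[3, 3]
  }
  pred <- apply_transform_matrix(M, a)
  rms <- sqrt(mean(rowSums((pred - b)^2)))
  structure(list(kind = kind, matrix = M, rms = rms),
            class = "transform_model")
}

apply_transform_matrix <- function(M, pts) {
  p <- cbind(as.matrix(pts)[, 1:2, drop = FALSE], 1) %*% t(M)
  p[, 1:2] / p[, 3]
}

#' Apply (or invert) a channel registration transform
#'
#' @param model A `transform_model` from [fit_channel_transform()].
#' @param pts Two-column matrix/data frame of coordinates.
#' @param inverse Map from channel b back to channel a.
#' @return Transformed coordinates (matrix with columns x, y).
#' @export
apply_transform <- function(model, pts, inverse = FALSE) {
  M <- if (inverse) solve(model$matrix) else model$matrix
  apply_transform_matrix(M, pts)
}

#' @export
print.transform_model <- function(x, ...) {
  cat(sprintf("%s transform, rms residual %.3g nm\n", x$kind, x$rms))
  print(x$matrix)
  invisible(x)
}

#' Time-averaged mean squared displacement of one track
#'
#' MSD at lag L frames is the average of squared displacements over all
#' localization pairs L frames apart.
#'
#' @param track Data frame with columns `frame`, `x`, `y`; positions in nm
#'   or µm (the MSD is returned in the square of the input unit).
#' @param dt Frame interval in seconds.
#' @param max_lag Largest lag (frames) to evaluate; defaults to track span
#'   minus one.
#' @return An `msd_curve`: data frame with `lag_s`, `msd`, `n`.
#' @export
msd_curve <- function(track, dt = 1, max_lag = NULL) {
  if (nrow(track) < 2) stop("track must have >= 2 localizations", call. = FALSE)
  f <- track$frame
  span <- diff(range(f))
  if (is.null(max_lag)) max_lag <- span
  msd <- numeric(0); nn <- integer(0); lags <- integer(0)
  for (L in seq_len(max_lag)) {
    j <- match(f + L, f)
    ok <- !is.na(j)
    if (!any(ok)) next
    d2 <- (track$x[j[ok]] - track$x[ok])^2 + (track$y[j[ok]] - track$y[ok])^2
    lags <- c(lags, L); msd <- c(msd, mean(d2)); nn <- c(nn, sum(ok))
  }
  structure(data.frame(lag_s = lags * dt, msd = msd, n = nn),
            class = c("msd_curve", "data.frame"))
}

#' Diffusion coefficient from an MSD curve
#'
#' Ordinary least squares on the first `n_points` lags (default 5, or all
#' available if fewer); for 2-D free diffusion MSD = 4 D t + c, so
#' D = slope / 4 and the intercept absorbs the localization-error offset.
#'
#' @param msd An `msd_curve` (or data frame with `lag_s` and `msd`).
#' @param n_points Number of initial MSD points used (default 5).
#' @return List with `D` (slope / 4, units of msd per second / 4),
#'   `intercept` and `n_points` actually used.
#' @export
diffusion_from_msd <- function(msd, n_points = 5L) {
  if (nrow(msd) < 2) stop("need >= 2 MSD lags", call. = FALSE)
  k <- min(n_points, nrow(msd))
  fit <- stats::lm(msd ~ lag_s, data = msd[seq_len(k), ])
  list(D = unname(stats::coef(fit)[2]) / 4,
       intercept = unname(stats::coef(fit)[1]),
       n_points = k)
}
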