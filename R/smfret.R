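#' @title ALEX single-molecule FRET quantification
#' @name smfret
#' @description Donor/acceptor co-localization, correction-factor estimation
#'   (leakage, direct excitation, gamma), accurate FRET efficiencies and
#'   stoichiometries, efficiency-distance conversion and the
#'   labeling-ratio-corrected dimerization fraction.
NULL

#' FRET correction coefficients
#'
#' @param leakage Donor leakage fraction l into the acceptor emission channel
#'   (in \[0, 1)).
#' @param dir_coeff Direct-excitation fraction of the acceptor by the donor
#'   laser; the subtracted term is `dir_coeff * I_Aex_Aem` (proportional
#'   mode) or the constant `dir_const` when given.
#' @param gamma Detection/quantum-yield correction factor (> 0).
#' @param r0 Foerster radius in nm (default 6.441, the Cy3B/ATTO 643 pair).
#' @param dir_const Optional constant direct-excitation offset in photons;
#'   overrides the proportional mode.
#' @return An object of class `fret_corrections`.
#' @export
fret_corrections <- function(leakage = 0.11, dir_coeff = 0.01, gamma = 0.8755,
                             r0 = 6.441, dir_const = NULL) {
  stopifnot(leakage >= 0, leakage < 1, gamma > 0, r0 > 0, dir_coeff >= 0)
  structure(list(leakage = leakage, dir_coeff = dir_coeff, gamma = gamma,
                 r0 = r0, dir_const = dir_const),
            class = "fret_corrections")
}

#' Frame-wise mutual-nearest-neighbor co-localization
#'
#' Within each frame, points of set a are matched to points of set b by
#' mutual nearest neighbors within `radius`; each point is matched at most
#' once.
#'
#' @param set_a,set_b Data frames with columns `frame`, `x`, `y` (nm,
#'   registered coordinates).
#' @param radius Co-localization radius in nm (default 150).
#' @return Data frame with columns `frame`, `idx_a`, `idx_b` (row indices
#'   into the inputs) and `dist_nm`.
#' @export
colocalize <- function(set_a, set_b, radius = 150) {
  out <- list()
  frames <- intersect(unique(set_a$frame), unique(set_b$frame))
  for (f in frames) {
    ia <- which(set_a$frame == f)
    ib <- which(set_b$frame == f)
    m <- greedy_assign(set_a$x[ia], set_a$y[ia],
                       set_b$x[ib], set_b$y[ib], radius)
    if (nrow(m)) {
      d <- sqrt((set_a$x[ia[m[, 1]]] - set_b$x[ib[m[, 2]]])^2 +
                (set_a$y[ia[m[, 1]]] - set_b$y[ib[m[, 2]]])^2)
      out[[length(out) + 1L]] <- data.frame(frame = f, idx_a = ia[m[, 1]],
                                            idx_b = ib[m[, 2]], dist_nm = d)
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), idx_a = integer(0),
                      idx_b = integer(0), dist_nm = numeric(0)))
  do.call(rbind, out)
}

#' Filter spurious dim acceptor signals
#'
#' Fits a bimodal Gaussian to the directly-excited acceptor intensity
#' histogram; when the lower-mean component carries less than `max_share` of
#' the total area it is treated as a spurious dim population and the values
#' assigned to it (below the component crossing point) are dropped.
#'
#' @param intensities I_Aex_Aem values in photons (>= 100 recommended).
#' @param max_share Maximum area share of the low peak for removal
#'   (default 0.05).
#' @return List with `retained` values, `keep` logical index and the `fit`
#'   (NULL if fitting failed, in which case everything is retained with a
#'   warning).
#' @export
filter_acceptor_population <- function(intensities, max_share = 0.05) {
  # seed the low component in the dim tail so a small spur is not missed
  init <- c(stats::quantile(intensities, 0.02), stats::median(intensities))
  fit <- tryCatch(
    fit_intensity_mixture(intensities, k = 2, init_means = unname(init)),
    error = function(e) NULL)
  keep <- rep(TRUE, length(intensities))
  if (is.null(fit)) {
    warning("acceptor-population fit failed; all signals retained")
    return(list(retained = intensities, keep = keep, fit = NULL))
  }
  share <- mixture_areas(fit)[1] / sum(mixture_areas(fit))
  # a genuine spur is both small and well separated from the main peak
  separated <- diff(fit$mean) > 2 * sum(fit$sigma)
  if (share < max_share && separated) {
    # crossing point of the two components between the means
    g <- function(x)
      fit$amplitude[1] * exp(-(x - fit$mean[1])^2 / (2 * fit$sigma[1]^2)) -
      fit$amplitude[2] * exp(-(x - fit$mean[2])^2 / (2 * fit$sigma[2]^2))
    cross <- tryCatch(
      stats::uniroot(g, lower = fit$mean[1], upper = fit$mean[2])$root,
      error = function(e) mean(fit$mean))
    keep <- intensities > cross
  }
  list(retained = intensities[keep], keep = keep, fit = fit)
}

#' Donor leakage coefficient from donor-only records
#'
#' l = mean over records of I_Dex_Aem / I_Dex_Dem.
#'
#' @param records Data frame with columns `I_Dex_Dem` and `I_Dex_Aem`
#'   pre-filtered to donor-only molecules.
#' @return The leakage fraction l.
#' @export
estimate_leakage <- function(records) {
  if (nrow(records) == 0) stop("no donor-only records", call. = FALSE)
  ok <- records$I_Dex_Dem > 0
  if (!any(ok)) stop("no records with positive donor signal", call. = FALSE)
  mean(records$I_Dex_Aem[ok] / records$I_Dex_Dem[ok])
}

#' Theoretical gamma factor
#'
#' gamma = phi_A * eta_A / (phi_D * eta_D), the ratio of acceptor to donor
#' quantum-yield x detection-efficiency products.
#'
#' @param phi_d,phi_a Donor/acceptor quantum yields in (0, 1].
#' @param eta_d,eta_a Donor/acceptor detection efficiencies (> 0), e.g.
#'   integrated from emission-spectrum x filter-transmission tables.
#' @return The gamma factor.
#' @export
gamma_theoretical <- function(phi_d, phi_a, eta_d, eta_a) {
  stopifnot(phi_d > 0, phi_d <= 1, phi_a > 0, phi_a <= 1,
            eta_d > 0, eta_a > 0)
  (phi_a * eta_a) / (phi_d * eta_d)
}

#' FRET efficiencies and stoichiometry for ALEX records
#'
#' Computes, per record: the apparent efficiency
#' E_raw = I_Dex_Aem / (I_Dex_Dem + I_Dex_Aem); the crosstalk-corrected
#' sensitized intensity I* = I_Dex_Aem - l * I_Dex_Dem - Dir (Dir
#' proportional to I_Aex_Aem by default, negative values retained); the
#' proximity ratio E_PR = I* / (I_Dex_Dem + I*); the accurate efficiency
#' E = E_PR / (gamma - (gamma - 1) * E_PR); and the apparent stoichiometry
#' S_raw = (I_Dex_Dem + I_Dex_Aem) / (I_Dex_Dem + I_Dex_Aem + I_Aex_Aem).
#'
#' @param records Data frame with columns `I_Dex_Dem`, `I_Dex_Aem`,
#'   `I_Aex_Aem` (photons); other columns are carried through.
#' @param corrections A [fret_corrections()].
#' @return The input with columns `I_star`, `E_raw`, `E_PR`, `E`, `S_raw`
#'   and `skipped` (TRUE where the total donor-excitation signal was zero).
#' @export
fret_efficiencies <- function(records, corrections = fret_corrections()) {
  stopifnot(inherits(corrections, "fret_corrections"))
  dd <- records$I_Dex_Dem
  da <- records$I_Dex_Aem
  aa <- records$I_Aex_Aem
  dir_term <- if (is.null(corrections$dir_const))
    corrections$dir_coeff * aa else corrections$dir_const
  istar <- da - corrections$leakage * dd - dir_term
  g <- corrections$gamma
  records$I_star <- istar
  records$E_raw <- da / (dd + da)
  records$E_PR <- istar / (dd + istar)
  records$E <- records$E_PR / (g - (g - 1) * records$E_PR)
  records$S_raw <- (dd + da) / (dd + da + aa)
  records$skipped <- (dd + da) == 0
  records$E_raw[records$skipped] <- NA_real_
  records$E_PR[records$skipped] <- NA_real_
  records$E[records$skipped] <- NA_real_
  records
}

#' Donor-acceptor distance from FRET efficiency
#'
#' Inverts E = 1 / (1 + (r / R0)^6): r = R0 * ((1 - E) / E)^(1/6).
#'
#' @param E FRET efficiency, strictly inside (0, 1).
#' @param r0 Foerster radius in nm.
#' @return Distance in nm.
#' @export
distance_from_efficiency <- function(E, r0 = 6.441) {
  if (any(E <= 0 | E >= 1)) stop("E must be in (0, 1)", call. = FALSE)
  r0 * ((1 - E) / E)^(1 / 6)
}

#' FRET efficiency at a donor-acceptor distance
#'
#' @param r Distance in nm (>= 0).
#' @param r0 Foerster radius in nm.
#' @return Efficiency E = 1 / (1 + (r / R0)^6).
#' @export
efficiency_from_distance <- function(r, r0 = 6.441) {
  if (any(r < 0)) stop("r must be >= 0", call. = FALSE)
  1 / (1 + (r / r0)^6)
}

#' Labeling-ratio-corrected relative dimerization fraction
#'
#' From mean per-frame localization counts in the two direct-excitation
#' channels (n1*, n2*) and the mean per-frame count of sensitized-FRET
#' co-localizations (nd12*): the labeling ratio r_l = n1* / (n1* + n2*),
#' the correction factor c_l = r_l (1 - r_l), the dimer receptor count
#' N_d = 2 nd12* / (2 r_l (1 - r_l)), the monomer count
#' N_m = n1* + n2* - nd12* / c_l, and the relative dimer fraction
#' f_rel_D = nd12* / (c_l (n1* + n2*)), which equals N_d / (N_m + N_d)
#' exactly (asserted to 1e-12). A mixed-label dimer is observed with
#' probability 2 r_l (1 - r_l), so at r_l = 0.5 the count correction factor
#' is 2.
#'
#' @param n_m1_star,n_m2_star Mean per-frame localization counts in
#'   channels 1 and 2.
#' @param n_d12_star Mean per-frame sensitized-FRET co-localization count.
#' @param cell_area Cell area in µm² for density reporting (optional).
#' @return List with `r_l`, `c_l`, `N_m`, `N_d`, `f_rel_D` (clipped to
#'   \[0, 1\]; `out_of_range` flags clipping), `density_1`, `density_2`
#'   (per µm², NA without `cell_area`).
#' @export
dimer_fraction <- function(n_m1_star, n_m2_star, n_d12_star,
                           cell_area = NA_real_) {
  stopifnot(n_m1_star >= 0, n_m2_star >= 0, n_d12_star >= 0)
  total <- n_m1_star + n_m2_star
  if (total == 0) stop("no localizations in either channel", call. = FALSE)
  r_l <- n_m1_star / total
  c_l <- r_l * (1 - r_l)
  if (c_l == 0)
    stop("single-channel labeling (r_l = 0 or 1): mixed-label dimers unobservable",
         call. = FALSE)
  if (n_d12_star > min(n_m1_star, n_m2_star))
    warning("n_d12* exceeds the smaller channel count; counts may be inconsistent")
  N_d <- 2 * n_d12_star / (2 * r_l * (1 - r_l))
  N_m <- total - n_d12_star / c_l
  f <- n_d12_star / (c_l * total)
  stopifnot(abs(f - N_d / (N_m + N_d)) < 1e-12)
  out_of_range <- f < 0 || f > 1
  list(r_l = r_l, c_l = c_l, N_m = N_m, N_d = N_d,
       f_rel_D = min(max(f, 0), 1), out_of_range = out_of_range,
       density_1 = n_m1_star / cell_area,
       density_2 = n_m2_star / cell_area)
}
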