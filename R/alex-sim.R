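#' @title Synthetic ALEX-smFRET experiments
#' @name alex-sim
#' @description Generates two-channel alternating-laser-excitation data for
#'   a partially dimerized receptor population with binomial dual-color
#'   labeling, and runs the full quantification chain (co-localization,
#'   correction-factor estimation, efficiency calculation, dimer counting)
#'   on it.
NULL

# Poisson draw with EMCCD excess-noise inflation (variance F^2 * mu)
noisy_photons <- function(mu, excess_factor = sqrt(2)) {
  f2 <- excess_factor^2
  f2 * stats::rpois(length(mu), pmax(mu, 0) / f2)
}

#' Simulate a two-channel ALEX-smFRET experiment
#'
#' Receptors are placed uniformly on a square membrane patch; a fraction
#' `f_true` of them pair up into dimers, and every receptor independently
#' carries label 1 (donor) with probability `r_l`, otherwise label 2
#' (acceptor). Per frame, three detection channels are emitted with photon
#' shot noise inflated by the EMCCD excess factor: directly excited donor,
#' directly excited acceptor, and the sensitized channel containing real
#' FRET transfer (efficiency `E_true`, detection-corrected by `gamma`) plus
#' donor leakage and acceptor direct excitation. Localizations carry
#' Gaussian position noise. Label-homozygous dimers appear as a single
#' spot in their channel.
#'
#' @param n_receptors Number of receptors on the patch.
#' @param f_true True fraction of receptors residing in dimers.
#' @param r_l Labeling ratio (probability of label 1).
#' @param E_true True FRET efficiency of donor-acceptor dimers.
#' @param field_um Side length of the square patch in µm.
#' @param n_frames Number of ALEX frame pairs.
#' @param mean_photons Mean detected photons per fluorophore per frame.
#' @param leakage Donor leakage fraction into the acceptor emission channel.
#' @param dir_coeff Acceptor direct-excitation fraction under donor
#'   excitation.
#' @param gamma Detection correction factor applied to transferred photons.
#' @param loc_sigma Localization noise (nm, per axis).
#' @param D Diffusion constant of all entities in µm²/s.
#' @param frame_interval Frame interval in seconds.
#' @param excess_factor EMCCD excess noise factor.
#' @param seed Optional RNG seed.
#' @return List of per-frame tables: `donor` and `acceptor` (directly
#'   excited localizations: frame, x, y in nm, intensity in photons) and
#'   `records` (one row per donor-channel spot with the three channel
#'   intensities `I_Dex_Dem`, `I_Dex_Aem`, `I_Aex_Aem` of the nearest
#'   acceptor if any, plus the ground-truth `kind`), and `params`.
#' @export
simulate_alex_experiment <- function(n_receptors = 1000, f_true = 0.2,
                                     r_l = 0.5, E_true = 0.18,
                                     field_um = 20, n_frames = 40,
                                     mean_photons = 400, leakage = 0.11,
                                     dir_coeff = 0.01, gamma = 0.8755,
                                     loc_sigma = 20, D = 0.1,
                                     frame_interval = 0.05,
                                     excess_factor = sqrt(2),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_dimer_rec <- 2L * floor(round(f_true * n_receptors) / 2)
  n_dim <- n_dimer_rec / 2L
  n_mono <- n_receptors - n_dimer_rec

  # entities: monomers and dimers; dimers carry two labels
  lab_mono <- ifelse(stats::runif(n_mono) < r_l, 1L, 2L)
  lab_d1 <- ifelse(stats::runif(n_dim) < r_l, 1L, 2L)
  lab_d2 <- ifelse(stats::runif(n_dim) < r_l, 1L, 2L)
  n_ent <- n_mono + n_dim
  x <- stats::runif(n_ent, 0, field_um * 1000)
  y <- stats::runif(n_ent, 0, field_um * 1000)
  is_dimer <- c(rep(FALSE, n_mono), rep(TRUE, n_dim))
  # dimer kind: DD / AA / DA
  kind <- c(ifelse(lab_mono == 1L, "D", "A"),
            ifelse(lab_d1 == 1L & lab_d2 == 1L, "DD",
                   ifelse(lab_d1 == 2L & lab_d2 == 2L, "AA", "DA")))
  n_donor_labels <- c(as.integer(lab_mono == 1L),
                      (lab_d1 == 1L) + (lab_d2 == 1L))
  n_acceptor_labels <- c(as.integer(lab_mono == 2L),
                         (lab_d1 == 2L) + (lab_d2 == 2L))

  step_nm <- mean_displacement(D, frame_interval) * 1000
  donor <- list(); acceptor <- list(); records <- list()
  for (f in seq_len(n_frames)) {
    if (f > 1 && step_nm > 0) {
      x <- x + stats::rnorm(n_ent) * step_nm
      y <- y + stats::rnorm(n_ent) * step_nm
    }
    # expected photon means per entity
    mu_dd <- numeric(n_ent)   # donor-excited donor emission
    mu_sens <- numeric(n_ent) # sensitized (true transfer) photons
    mu_aa <- numeric(n_ent)   # acceptor-excited acceptor emission
    has_fret <- kind == "DA"
    mu_dd <- n_donor_labels * mean_photons
    mu_dd[has_fret] <- mean_photons * (1 - E_true)
    mu_sens[has_fret] <- mean_photons * E_true * gamma
    mu_aa <- n_acceptor_labels * mean_photons

    I_dd <- noisy_photons(mu_dd, excess_factor)
    I_sens <- noisy_photons(mu_sens, excess_factor)
    I_aa <- noisy_photons(mu_aa, excess_factor)
    # measured sensitized channel adds leakage + direct excitation
    I_da <- I_sens + leakage * I_dd + dir_coeff * I_aa

    in_d <- n_donor_labels > 0
    in_a <- n_acceptor_labels > 0
    jit <- function(n) stats::rnorm(n, 0, loc_sigma)
    donor[[f]] <- data.frame(frame = f, entity = which(in_d),
                             x = x[in_d] + jit(sum(in_d)),
                             y = y[in_d] + jit(sum(in_d)),
                             intensity = I_dd[in_d])
    acceptor[[f]] <- data.frame(frame = f, entity = which(in_a),
                                x = x[in_a] + jit(sum(in_a)),
                                y = y[in_a] + jit(sum(in_a)),
                                intensity = I_aa[in_a])
    records[[f]] <- data.frame(frame = f, entity = which(in_d),
                               x = x[in_d] + jit(sum(in_d)),
                               y = y[in_d] + jit(sum(in_d)),
                               I_Dex_Dem = I_dd[in_d],
                               I_Dex_Aem = I_da[in_d],
                               I_Aex_Aem = I_aa[in_d],
                               kind = kind[in_d])
  }
  list(donor = do.call(rbind, donor), acceptor = do.call(rbind, acceptor),
       records = do.call(rbind, records),
       params = list(n_receptors = n_receptors, f_true = f_true, r_l = r_l,
                     E_true = E_true, field_um = field_um,
                     n_frames = n_frames, mean_photons = mean_photons,
                     leakage = leakage, dir_coeff = dir_coeff,
                     gamma = gamma))
}

#' Quantify a two-channel ALEX-smFRET dataset
#'
#' Runs the analysis chain on per-frame donor/acceptor localization tables:
#' (1) co-localize donor-channel spots with directly excited acceptor spots
#' (mutual nearest neighbors within `radius`); (2) estimate the donor
#' leakage from non-co-localized (donor-only) spots unless a value is
#' supplied; (3) compute corrected FRET efficiencies for the co-localized
#' records; (4) gate sensitized-FRET detections on the corrected sensitized
#' intensity I* exceeding `min_sensitized` (by default 5x a robust noise
#' scale estimated from the donor-only I* distribution); (5) form per-frame
#' mean counts and the labeling-ratio-corrected dimer fraction.
#'
#' @param sim Output of [simulate_alex_experiment()], or a compatible list
#'   with `donor`, `acceptor` and `records` tables.
#' @param radius Co-localization radius in nm (default 150).
#' @param corrections A [fret_corrections()]; its `leakage` entry is
#'   replaced by the data-driven estimate when `leakage = "auto"`.
#' @param leakage `"auto"` (estimate from donor-only records) or a numeric
#'   value.
#' @param min_sensitized FRET gate on I* in photons; `NULL` for the
#'   noise-scale default.
#' @param cell_area Area in µm² for density reporting; defaults to the
#'   bounding box of all localizations.
#' @return List with `dimer` (output of [dimer_fraction()]), `counts`
#'   (n1*, n2*, nd12*, plus the uncorrected co-localization count
#'   `n_coloc`), `leakage`, `E_peak` (mean of the FRET population from a
#'   bimodal fit of E, falling back to the gated-record mean), `records`
#'   (co-localized records with efficiencies) and `coloc_fraction`
#'   (co-localization-based dimer fraction estimate, for comparison with
#'   the FRET-gated one).
#' @export
analyze_alex_experiment <- function(sim, radius = 150,
                                    corrections = fret_corrections(),
                                    leakage = "auto",
                                    min_sensitized = NULL,
                                    cell_area = NULL) {
  donor <- sim$donor
  acceptor <- sim$acceptor
  records <- sim$records
  n_frames <- length(unique(donor$frame))

  # acceptor-population filter on the directly excited acceptor intensities
  acc_keep <- filter_acceptor_population(acceptor$intensity)$keep
  acceptor <- acceptor[acc_keep, , drop = FALSE]

  pairs <- colocalize(records, acceptor, radius = radius)
  rec <- records[pairs$idx_a, , drop = FALSE]
  rec$I_Aex_Aem <- acceptor$intensity[pairs$idx_b]

  donor_only <- if (nrow(pairs) > 0)
    records[-pairs$idx_a, , drop = FALSE] else records
  if (identical(leakage, "auto")) {
    leak <- if (nrow(donor_only) > 0) estimate_leakage(donor_only)
            else corrections$leakage
  } else leak <- leakage
  corrections$leakage <- leak

  rec <- fret_efficiencies(rec, corrections)

  if (is.null(min_sensitized)) {
    dir_term <- if (is.null(corrections$dir_const))
      corrections$dir_coeff * 0 else corrections$dir_const
    istar_null <- donor_only$I_Dex_Aem - leak * donor_only$I_Dex_Dem - dir_term
    scale <- stats::mad(istar_null)
    if (!is.finite(scale) || scale == 0) scale <- stats::sd(istar_null)
    min_sensitized <- 5 * scale
  }
  fret_gated <- !rec$skipped & rec$I_star > min_sensitized

  n1 <- nrow(records) / n_frames
  n2 <- nrow(acceptor) / n_frames
  nd12 <- sum(fret_gated) / n_frames
  n_coloc <- nrow(pairs) / n_frames
  if (is.null(cell_area)) {
    cell_area <- diff(range(donor$x)) * diff(range(donor$y)) / 1e6
  }
  dim_res <- dimer_fraction(n1, n2, nd12, cell_area = cell_area)
  r_l <- dim_res$r_l
  coloc_fraction <- min(1, n_coloc / (dim_res$c_l * (n1 + n2)))

  # E peak of the FRET population: bimodal fit separating the null peak
  e_vals <- rec$E[!rec$skipped & is.finite(rec$E)]
  E_peak <- NA_real_
  if (length(e_vals) >= 30) {
    fit <- tryCatch(fit_intensity_mixture(e_vals, k = 2, bin_width = 0.02),
                    error = function(e) NULL)
    if (!is.null(fit)) E_peak <- fit$mean[which.max(fit$mean)]
  }
  if (!is.finite(E_peak) && any(fret_gated))
    E_peak <- mean(rec$E[fret_gated], na.rm = TRUE)

  list(dimer = dim_res,
       counts = list(n_m1_star = n1, n_m2_star = n2, n_d12_star = nd12,
                     n_coloc = n_coloc),
       leakage = leak, E_peak = E_peak, records = rec,
       coloc_fraction = coloc_fraction,
       min_sensitized = min_sensitized)
}
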