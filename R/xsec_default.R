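## Packaged default liquid-water cross-section set and synthetic fixtures.

## Bethe-like inelastic shape: threshold rise, peak a few times above
## threshold, ln(E)/E fall-off. A is the overall magnitude (nm^2).
.s_bethe <- function(E, thr, A, nu = 1.5) {
  out <- numeric(length(E))
  ok <- E > thr
  x <- E[ok] / thr
  out[ok] <- A * log(x) / x * (1 - 1 / x)^nu
  out
}

#' Default channel-resolved cross sections for liquid water
#'
#' A synthetic parametrisation of the channel-resolved electron cross
#' sections of liquid water on 0.001 eV - 100 keV, assembled from standard
#' literature magnitudes: Bethe-shaped electronic channels (one valence
#' ionisation shell at 10.9 eV binding, three discrete excitation bands, and
#' the collective excitation around 21.4 eV that carries the largest
#' inelastic cross section in the liquid phase), two vibrational modes
#' (bend 0.198 eV, stretch 0.453 eV), quasi-elastic phonon scattering that
#' dominates subexcitation transport, elastic scattering, and an attachment
#' (DEA) channel that is present in the taxonomy but carries zero cross
#' section: DEA is taken to be suppressed in the liquid phase.
#'
#' The parametrisation is a smooth stand-in, not a digitised data file; its
#' magnitudes are chosen to reproduce liquid-water observables (inelastic
#' mean free paths at keV energies, subexcitation thermalisation distances,
#' and picosecond hydrated-electron yields) rather than any specific
#' published table.
#'
#' @return an `aq_xsec` table (`phase = "liquid"`).
#' @export
default_xsec_table <- function() {
  E <- 10^seq(log10(0.001), log10(1e5), length.out = 177)
  chans <- list(
    xsec_channel("elastic", "elastic", 0, "none"),
    xsec_channel("phonon", "phonon", 0, "fixed_quantum", transfer = 0.02),
    xsec_channel("vib_bend", "vibrational", 0.198),
    xsec_channel("vib_stretch", "vibrational", 0.453),
    xsec_channel("exc_a1b1", "excitation_discrete", 8.4),
    xsec_channel("exc_b1a1", "excitation_discrete", 10.1),
    xsec_channel("exc_ryd", "excitation_discrete", 11.5),
    xsec_channel("exc_coll", "excitation_collective", 12.4,
                 transfer = 21.4),
    xsec_channel("ion_val", "ionisation", 10.9, lorentz_a = 8),
    xsec_channel("dea", "attachment", 5.0)
  )
  sig <- cbind(
    elastic     = 0.12 / (1 + (E / 6)^1.0),
    phonon      = 0.22 / (1 + (E / 0.3)^1.3),
    vib_bend    = ifelse(E > 0.198,
                         0.0035 * sqrt(pmax(0, 1 - 0.198 / E)) /
                           (1 + (E / 3)^2), 0),
    vib_stretch = ifelse(E > 0.453,
                         0.0060 * sqrt(pmax(0, 1 - 0.453 / E)) /
                           (1 + (E / 3)^2), 0),
    exc_a1b1    = .s_bethe(E, 8.4, 0.042),
    exc_b1a1    = .s_bethe(E, 10.1, 0.032),
    exc_ryd     = .s_bethe(E, 11.5, 0.024),
    exc_coll    = .s_bethe(E, 21.4, 0.120),
    ion_val     = .s_bethe(E, 10.9, 0.118),
    dea         = 0 * E
  )
  xsec_table(E, sig, chans,
             provenance = "aquadmc synthetic liquid-water parametrisation v1")
}

#' Generate a synthetic fixture cross-section table
#'
#' Deterministic (seeded) generator of small, valid cross-section tables for
#' tests and examples. The generated table always contains at least one
#' elastic, one ionisation, one discrete-excitation and one vibrational
#' channel with plausible eV-scale thresholds; an attachment channel, when
#' requested, carries zero cross section unless `dea_sigma` is overridden.
#'
#' @param n_grid number of (log-spaced) grid points.
#' @param E_min,E_max grid span, eV.
#' @param extra_ionisation,extra_excitation additional random channels.
#' @param attachment include a (zero) DEA channel.
#' @param dea_sigma override the DEA cross section (nm^2, scalar); leaving it
#'   at 0 keeps the default-physics invariant.
#' @param seed integer seed; the same seed yields an identical table.
#' @return an `aq_xsec` table.
#' @export
generate_fixture <- function(n_grid = 25, E_min = 0.01, E_max = 1000,
                             extra_ionisation = 0, extra_excitation = 0,
                             attachment = FALSE, dea_sigma = 0, seed = 1) {
  stopifnot(n_grid >= 4, E_max > E_min)
  rng <- .lcg_stream(seed)
  E <- 10^seq(log10(E_min), log10(E_max), length.out = n_grid)
  chans <- list(xsec_channel("elastic", "elastic", 0, "none"),
                xsec_channel("vib", "vibrational", 0.2),
                xsec_channel("exc", "excitation_discrete",
                             8 + 2 * rng()),
                xsec_channel("ion", "ionisation", 10 + 2 * rng()))
  sig <- cbind(0.05 + 0.05 * rng() / (1 + E / 20),
               ifelse(E > 0.2, 0.004 * (1 + rng()) / (1 + (E / 3)^2), 0),
               .s_bethe(E, chans[[3]]$threshold_energy, 0.01 * (1 + rng())),
               .s_bethe(E, chans[[4]]$threshold_energy, 0.05 * (1 + rng())))
  k <- 4L
  for (i in seq_len(extra_ionisation)) {
    k <- k + 1L
    chans[[k]] <- xsec_channel(paste0("ion", i + 1), "ionisation",
                               12 + 20 * rng())
    sig <- cbind(sig, .s_bethe(E, chans[[k]]$threshold_energy,
                               0.02 * (1 + rng())))
  }
  for (i in seq_len(extra_excitation)) {
    k <- k + 1L
    chans[[k]] <- xsec_channel(paste0("exc", i + 1), "excitation_discrete",
                               8 + 4 * rng())
    sig <- cbind(sig, .s_bethe(E, chans[[k]]$threshold_energy,
                               0.01 * (1 + rng())))
  }
  if (attachment) {
    k <- k + 1L
    chans[[k]] <- xsec_channel("dea", "attachment", 5)
    sig <- cbind(sig, ifelse(E > 5 & E < 12, dea_sigma, 0))
  }
  xsec_table(E, sig, chans, dea_zero = FALSE,
             provenance = paste0("aquadmc fixture seed=", seed))
}

## tiny deterministic uniform stream independent of R's RNG, so fixture
## generation never perturbs a caller's random state
.lcg_stream <- function(seed) {
  state <- (as.numeric(seed) %% 2147483647) + 1
  function() {
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
}
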