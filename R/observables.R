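## Classification by the charge-separation radius and all reported summary
## quantities: G_total(t), P_ion/P_exc, G_hyd(1 ps), W values, penetration
## range, spectra and component decompositions.

.event_kinds_counted <- c(1L, 2L, 3L)  # ionisation, discrete and collective
                                       # electronic excitation

#' Total yield of ionisation plus electronic excitation at time t0
#'
#' \eqn{G_{total}(t_0) = \langle N_{total}(t_0)\rangle / E_0 \times 100}
#' (per 100 eV), where `N_total(t0)` is the number of ionisation and
#' electronic-excitation events induced up to global time `t0`.
#'
#' @param result an `aq_result`.
#' @param t0 global time, fs (vectorised).
#' @return data frame with `t0`, `G` (per 100 eV) and the Monte Carlo
#'   standard error `se` over histories.
#' @export
g_total <- function(result, t0 = result$config$t_horizon) {
  if (any(t0 > result$config$t_horizon))
    stop("t0 beyond the simulated horizon", call. = FALSE)
  nh <- result$config$n_histories
  E0 <- result$config$E0
  ev <- result$events
  ev <- ev[ev$kind %in% .event_kinds_counted, , drop = FALSE]
  G <- se <- numeric(length(t0))
  for (k in seq_along(t0)) {
    counts <- vapply(seq_len(nh), function(h)
      sum(ev$history == h & ev$t0 <= t0[k]), numeric(1))
    g <- counts / E0 * 100
    G[k] <- mean(g)
    se[k] <- if (nh > 1) stats::sd(g) / sqrt(nh) else NA_real_
  }
  data.frame(t0 = t0, G = G, se = se)
}

#' Classify final electron positions against the charge-separation radius
#'
#' Every spawned secondary electron is judged by its final distance to its
#' own parent cation at the horizon: `delocalised` at or beyond `r_sep`
#' (ionisation in the physicochemical sense, the nascent hydrated
#' electron), `localised` within `r_sep` for excitation-channel electrons,
#' and `relocalised` within `r_sep` for ionisation-channel electrons pulled
#' back by the parent field. Ties at exactly `r_sep` count as delocalised.
#' The sub-cutoff primary remnant is not channel-born and is excluded.
#'
#' @param result an `aq_result` from [run_simulation()].
#' @param r_sep charge-separation radius, nm (default from the run config).
#' @return object of class `aq_classcounts`: list with the three counts,
#'   `N_e`, and the per-electron class factor.
#' @export
classify_final <- function(result, r_sep = result$config$r_sep) {
  el <- result$electrons
  el <- el[el$remnant == 0, , drop = FALSE]
  if (is.null(el) || nrow(el) == 0)
    stop("no secondary electrons to classify", call. = FALSE)
  if (any(el$status < 0))
    stop("classification before horizon: active electrons remain",
         call. = FALSE)
  cls <- ifelse(el$dist_parent >= r_sep, "delocalised",
                ifelse(el$origin == 2L, "localised", "relocalised"))
  structure(list(n_delocalised = sum(cls == "delocalised"),
                 n_localised = sum(cls == "localised"),
                 n_relocalised = sum(cls == "relocalised"),
                 N_e = nrow(el),
                 class = cls, r_sep = r_sep),
            class = "aq_classcounts")
}

#' @export
print.aq_classcounts <- function(x, ...) {
  cat(sprintf(paste0("<aq_classcounts> N_e=%d  delocalised=%d  ",
                     "localised=%d  relocalised=%d (r_sep=%g nm)\n"),
              x$N_e, x$n_delocalised, x$n_localised, x$n_relocalised,
              x$r_sep))
  invisible(x)
}

#' Initial hydrated-electron yield G_hyd(1 ps)
#'
#' \eqn{G_{hyd} = G_{total}(1\,ps) \times P_{ion}} with
#' \eqn{P_{ion} = n_{delocalised}/N_e}: the fraction of secondary electrons
#' that ended beyond the charge-separation radius, i.e. the events that are
#' ultimately judged as ionisation and yield a hydrated electron.
#'
#' @inheritParams classify_final
#' @return list with `G_hyd`, `se`, `P_ion`, `G_total` and the class
#'   counts.
#' @export
g_hyd <- function(result, r_sep = result$config$r_sep) {
  counts <- classify_final(result, r_sep)
  gt <- g_total(result, result$config$t_horizon)
  p_ion <- counts$n_delocalised / counts$N_e
  G <- gt$G * p_ion
  ## binomial error on P_ion plus MC error on G_total, propagated
  se_p <- sqrt(p_ion * (1 - p_ion) / counts$N_e)
  se <- sqrt((gt$G * se_p)^2 +
               (p_ion * ifelse(is.na(gt$se), 0, gt$se))^2)
  list(G_hyd = G, se = se, P_ion = p_ion, P_exc = 1 - p_ion,
       G_total = gt$G, counts = counts)
}

#' Convert between W values and G values
#'
#' `W` (eV) is the mean energy expended per ionisation;
#' `G` (per 100 eV) the ionisation yield: `W = 100 / G` and vice versa.
#'
#' @param G yield per 100 eV (> 0).
#' @param W mean energy per ionisation, eV (> 0).
#' @return the converted value.
#' @export
w_from_g <- function(G) {
  if (any(G <= 0)) stop("G must be > 0", call. = FALSE)
  100 / G
}

#' @rdname w_from_g
#' @export
g_from_w <- function(W) {
  if (any(W <= 0)) stop("W must be > 0", call. = FALSE)
  100 / W
}

#' Final ionisation-to-excitation ratio
#'
#' Ratio of total ionisations (delocalised electrons) to total electronic
#' excitations (localised plus relocalised electrons), judged from final
#' positions, not from the colliding channel.
#'
#' @param counts an `aq_classcounts`.
#' @return dimensionless ratio; `NaN` with a warning when no electron ended
#'   inside the separation radius.
#' @export
ratio_ion_exc <- function(counts) {
  den <- counts$n_localised + counts$n_relocalised
  if (den == 0) {
    warning("no localised/relocalised electrons: ratio undefined")
    return(NaN)
  }
  counts$n_delocalised / den
}

#' Penetration range of the primary electron
#'
#' Mean (over histories) straight-line distance from the irradiation origin
#' to the primary electron position at global time `t0`, interpolated along
#' the recorded track.
#'
#' @param result an `aq_result`.
#' @param t0 global times, fs.
#' @return data frame with `t0`, `range_nm`, `se`.
#' @export
penetration_range <- function(result, t0) {
  if (any(t0 > result$config$t_horizon))
    stop("t0 beyond the simulated horizon", call. = FALSE)
  nh <- result$config$n_histories
  pp <- result$primary_path
  ## the retired primary continues as the remnant electron; append its
  ## final position so late times read its stopped location
  rem <- result$electrons
  rem <- if (!is.null(rem)) rem[rem$remnant == 1, , drop = FALSE] else NULL
  r_of <- function(h, t) {
    d <- pp[pp$history == h, , drop = FALSE]
    tt <- d$t0; xx <- d$x; yy <- d$y; zz <- d$z
    if (!is.null(rem) && any(rem$history == h)) {
      rr <- rem[rem$history == h, ][1, ]
      tt <- c(tt, rr$birth_t0 + rr$t_local)
      xx <- c(xx, rr$x); yy <- c(yy, rr$y); zz <- c(zz, rr$z)
    }
    f <- function(w) stats::approx(tt, w, xout = pmin(t, max(tt)),
                                   rule = 2)$y
    sqrt(f(xx)^2 + f(yy)^2 + f(zz)^2)
  }
  out <- vapply(t0, function(t) {
    r <- vapply(seq_len(nh), function(h) r_of(h, t), numeric(1))
    c(mean(r), if (nh > 1) stats::sd(r) / sqrt(nh) else NA_real_)
  }, numeric(2))
  data.frame(t0 = t0, range_nm = out[1, ], se = out[2, ])
}

#' Maxwell-Boltzmann kinetic-energy density
#'
#' \eqn{f(E) = \frac{2}{\sqrt\pi} (k_B T)^{-3/2} \sqrt{E}\, e^{-E/k_B T}},
#' the equilibrium energy distribution of non-relativistic classical
#' particles; thermalised secondary electrons asymptote to it.
#'
#' @param E kinetic energy, eV (>= 0, vectorised).
#' @param temperature K.
#' @return density per eV.
#' @export
maxwellian_pdf <- function(E, temperature = 300) {
  if (any(E < 0)) stop("E must be >= 0", call. = FALSE)
  kT <- aq_constants$k_B * temperature
  2 / sqrt(pi) * kT^(-1.5) * sqrt(E) * exp(-E / kT)
}

.snapshot_at <- function(result, t) {
  sn <- result$snapshots
  if (is.null(sn)) stop("result carries no snapshots", call. = FALSE)
  tt <- result$config$snapshot_times
  if (!any(abs(tt - t) < 1e-9))
    stop("t must be one of the recorded snapshot times: ",
         paste(tt, collapse = ", "), call. = FALSE)
  sn[abs(sn$time - t) < 1e-9, , drop = FALSE]
}

#' Kinetic-energy spectrum of secondary electrons at time t
#'
#' Density-normalised histogram of the kinetic energies of all secondary
#' electrons alive or frozen at global time `t` (one of the configured
#' snapshot times).
#'
#' @param result an `aq_result`.
#' @param t snapshot time, fs.
#' @param bin_edges histogram bin edges, eV; default log-spaced from 1 meV.
#' @return data frame with `lower`, `upper`, `density` (per eV), `count`.
#' @export
energy_spectrum <- function(result, t = result$config$t_horizon,
                            bin_edges = NULL) {
  sn <- .snapshot_at(result, t)
  if (nrow(sn) == 0) stop("no electrons recorded at t = ", t, call. = FALSE)
  ke <- sn$KE
  if (is.null(bin_edges))
    bin_edges <- 10^seq(log10(1e-3), log10(max(result$config$E0, 1)),
                        length.out = 61)
  ke <- pmin(pmax(ke, bin_edges[1]), bin_edges[length(bin_edges)])
  h <- graphics::hist(ke, breaks = bin_edges, plot = FALSE)
  data.frame(lower = utils::head(bin_edges, -1),
             upper = bin_edges[-1],
             density = h$density, count = h$counts)
}

#' Radial distribution of electron-parent distances at time t
#'
#' Count histogram of the distance of every secondary electron to its own
#' parent cation at global time `t`; the total count equals the number of
#' parented secondary electrons.
#'
#' @inheritParams energy_spectrum
#' @param bin_edges bin edges, nm; default 0.05 nm linear bins.
#' @return data frame with `lower`, `upper`, `count`, `density`.
#' @export
spatial_distribution <- function(result, t = result$config$t_horizon,
                                 bin_edges = NULL) {
  sn <- .snapshot_at(result, t)
  sn <- sn[sn$dist >= 0, , drop = FALSE]
  if (nrow(sn) == 0) stop("no parented electrons at t = ", t, call. = FALSE)
  if (is.null(bin_edges))
    bin_edges <- seq(0, max(sn$dist) + 0.05, by = 0.05)
  d <- pmin(sn$dist, bin_edges[length(bin_edges)])
  h <- graphics::hist(d, breaks = bin_edges, plot = FALSE)
  data.frame(lower = utils::head(bin_edges, -1), upper = bin_edges[-1],
             count = h$counts, density = h$density)
}

#' Full yield report
#'
#' Assembles the quantities reported per run: the `G_total(t)` series on
#' the snapshot grid, the final-position class counts, `P_ion`/`P_exc`,
#' `G_hyd(1 ps)`, the `W` value, the ionisation/excitation ratio, and the
#' per-class G values.
#'
#' @inheritParams classify_final
#' @return object of class `aq_greport`.
#' @export
g_report <- function(result, r_sep = result$config$r_sep) {
  gh <- g_hyd(result, r_sep)
  counts <- gh$counts
  gt_series <- g_total(result, result$config$snapshot_times)
  gclass <- gh$G_total / counts$N_e *
    c(counts$n_delocalised, counts$n_localised, counts$n_relocalised)
  names(gclass) <- c("delocalised", "localised", "relocalised")
  structure(list(E0 = result$config$E0,
                 r_sep = r_sep,
                 G_total_series = gt_series,
                 G_total = gh$G_total,
                 P_ion = gh$P_ion, P_exc = gh$P_exc,
                 G_hyd = gh$G_hyd, G_hyd_se = gh$se,
                 W = w_from_g(gh$G_hyd),
                 ratio_ion_exc = ratio_ion_exc(counts),
                 G_class = gclass,
                 counts = counts[c("n_delocalised", "n_localised",
                                   "n_relocalised", "N_e")],
                 n_histories = result$config$n_histories),
            class = "aq_greport")
}

#' @export
print.aq_greport <- function(x, ...) {
  cat(sprintf("<aq_greport> E0 = %g eV (%d histories, r_sep = %g nm)\n",
              x$E0, x$n_histories, x$r_sep))
  cat(sprintf("  G_total(1 ps) = %.3f /100 eV\n", x$G_total))
  cat(sprintf("  P_ion = %.3f  P_exc = %.3f\n", x$P_ion, x$P_exc))
  cat(sprintf("  G_hyd(1 ps)  = %.3f +/- %.3f /100 eV   (W = %.2f eV)\n",
              x$G_hyd, x$G_hyd_se, x$W))
  cat(sprintf("  ion/exc ratio = %.2f\n", x$ratio_ion_exc))
  cat(sprintf("  G delocalised/localised/relocalised = %.3f / %.3f / %.3f\n",
              x$G_class[1], x$G_class[2], x$G_class[3]))
  invisible(x)
}
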