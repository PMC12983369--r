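## The dynamic Monte Carlo engine: run configuration, track generation,
## per-electron femtosecond propagation, and the full simulation driver.

#' Simulation run configuration
#'
#' @param E0 primary electron kinetic energy, eV (supported regime
#'   20 eV - 30 keV).
#' @param n_histories number of independent histories.
#' @param seed master integer seed; every history and every electron derives
#'   its own counter-based substream from it, so results are reproducible
#'   and independent of execution order.
#' @param t_horizon global time horizon of the physical stage, fs (default
#'   1000 = 1 ps, where classification is read).
#' @param t_cut_secondary per-electron cutoff time `t_cut,i`, fs: each
#'   secondary electron is propagated on its own clock for at most this long
#'   (each is essentially thermal by 500 fs).
#' @param r_sep charge-separation radius, nm: electrons ending at least this
#'   far from their parent cation at the horizon count as ionisation
#'   (default 0.75 nm, the hydrated-electron / hydronium reaction radius).
#' @param temperature bath temperature, K.
#' @param dt_max integrator time-step cap, fs.
#' @param tracking_cutoff eV; the primary is retired below this energy and
#'   its remainder handed to the secondary propagator (default 8.4 eV, the
#'   lowest electronic threshold of the default table).
#' @param dea_enabled enable dissociative-attachment channels (default
#'   `FALSE`; the default table carries zero DEA cross section regardless).
#' @param snapshot_times global times (fs) at which per-electron kinetic
#'   energies and parent distances are recorded for spectra.
#' @param disp_cap,disp_cap_far per-step displacement caps (nm) near
#'   (within `far_dist`) and far from the parent cation.
#' @param far_dist nm; distance beyond which the far displacement cap and
#'   larger steps apply.
#' @param r_soft Plummer softening radius of the parent field, nm.
#' @param r_birth nm; radius at which a freed electron enters classical
#'   transport, displaced radially from the event position. The channel
#'   threshold (binding or transition energy) already accounts for escaping
#'   the molecular region, so the macroscopic screened field acts only
#'   beyond the molecular cavity scale.
#' @param r_birth_tail nm; mean of the exponential tail added to `r_birth`
#'   when sampling the entry radius, reflecting the spatial extent of the
#'   vacated or excited orbital (diffuse Rydberg-like states reach toward a
#'   nanometre).
#' @param lambda_th thermal-bath coupling per sub-thermal collision (0-1);
#'   the stationary velocity distribution is Maxwellian at `temperature`.
#' @param eta0 screening parameter scale of the screened-Rutherford elastic
#'   angular distribution (eta = eta0 / E).
#' @param therm_dwell consecutive sub-`therm_band` collisions required to
#'   declare thermalisation.
#' @param therm_enter,therm_band thermal-regime entry and dwell band, in
#'   multiples of k_B T.
#' @param coulomb_on master switch for the parent-cation force (diagnostics
#'   only).
#' @return an object of class `aq_config`.
#' @export
sim_config <- function(E0, n_histories = 1L, seed = 1L,
                       t_horizon = 1000, t_cut_secondary = 500,
                       r_sep = 0.75, temperature = 300,
                       dt_max = 0.5, tracking_cutoff = 8.4,
                       dea_enabled = FALSE,
                       snapshot_times = c(50, 100, 200, 500, 1000),
                       disp_cap = 0.05, disp_cap_far = 0.5, far_dist = 2,
                       r_soft = 0.05, r_birth = 0.30, r_birth_tail = 0.25,
                       lambda_th = 0.25,
                       eta0 = 0.5,
                       therm_dwell = 30L, therm_enter = 10, therm_band = 5,
                       coulomb_on = TRUE) {
  if (E0 < 20 || E0 > 30000)
    stop("E0 must lie in the supported regime [20, 30000] eV", call. = FALSE)
  if (t_cut_secondary > t_horizon)
    stop("t_cut_secondary must be <= t_horizon", call. = FALSE)
  if (r_sep <= 0) stop("r_sep must be > 0", call. = FALSE)
  snapshot_times <- sort(unique(c(snapshot_times, t_horizon)))
  structure(list(E0 = E0, n_histories = as.integer(n_histories),
                 seed = as.integer(seed), t_horizon = t_horizon,
                 t_cut_secondary = t_cut_secondary, r_sep = r_sep,
                 temperature = temperature, dt_max = dt_max,
                 tracking_cutoff = tracking_cutoff,
                 dea_enabled = dea_enabled,
                 snapshot_times = snapshot_times,
                 disp_cap = disp_cap, disp_cap_far = disp_cap_far,
                 far_dist = far_dist, r_soft = r_soft, r_birth = r_birth,
                 r_birth_tail = r_birth_tail,
                 lambda_th = lambda_th, eta0 = eta0,
                 therm_dwell = as.integer(therm_dwell),
                 therm_enter = therm_enter, therm_band = therm_band,
                 coulomb_on = coulomb_on),
            class = "aq_config")
}

.cfg_compact <- function(config) unclass(config)

.check_table_covers <- function(table, E0) {
  if (E0 > max(table$energy_eV))
    stop("cross-section table ends at ", max(table$energy_eV),
         " eV; cannot transport a ", E0, " eV electron (no extrapolation)",
         call. = FALSE)
}

#' Generate one primary electron track
#'
#' Runs only the track-generation stage for `n_histories` histories: the
#' primary starts at the origin moving along +z, alternating exponential
#' free flights with sampled collisions. Ionisation and excitation events
#' spawn secondary electrons (recorded, not propagated here); the primary
#' is retired below `tracking_cutoff` and its remainder recorded as one
#' final electron (`remnant = 1`).
#'
#' @param config an `aq_config`.
#' @param table an `aq_xsec` covering `E0`.
#' @return list with data frames `events`, `electrons` (initial states of
#'   spawned electrons), `primary_path`, and per-history `bookkeeping`.
#' @export
generate_primary_track <- function(config, table = default_xsec_table()) {
  .check_table_covers(table, config$E0)
  params <- dielectric_params()
  .run_histories(config, table, params, primary_only = TRUE)
}

#' Run the full dynamic Monte Carlo simulation
#'
#' For each history: the primary track is generated event by event; every
#' spawned electron (including electrons freed by electronic excitation and
#' delta-ray cascades) is propagated on its own femtosecond clock in the
#' time-dependent screened Coulomb field of its parent cation, undergoing
#' elastic, phonon, vibrational and - while energetically possible -
#' further ionising/exciting collisions, until thermalisation, its cutoff
#' time, or the global horizon. Thermalised electrons freeze at their
#' stopping position.
#'
#' @inheritParams generate_primary_track
#' @param params an `aq_dielectric`.
#' @return an object of class `aq_result`: list with `config`, data frames
#'   `events`, `electrons`, `snapshots`, `primary_path` (all carrying a
#'   `history` column) and `bookkeeping`.
#' @export
run_simulation <- function(config, table = default_xsec_table(),
                           params = dielectric_params()) {
  .check_table_covers(table, config$E0)
  .run_histories(config, table, params, primary_only = FALSE)
}

.run_histories <- function(config, table, params, primary_only) {
  xs <- .xsec_compact(table)
  dl <- .diel_compact(params)
  cf <- .cfg_compact(config)
  out <- vector("list", config$n_histories)
  for (h in seq_len(config$n_histories)) {
    out[[h]] <- cpp_run_history(xs, dl, cf, config$E0, config$seed, h,
                                primary_only)
  }
  bind <- function(field) {
    dfs <- lapply(seq_along(out), function(h) {
      d <- out[[h]][[field]]
      if (nrow(d) > 0) d$history <- h
      d
    })
    dfs <- dfs[vapply(dfs, nrow, 0L) > 0]
    if (length(dfs) == 0) return(NULL)
    do.call(rbind, dfs)
  }
  paths <- lapply(seq_along(out), function(h) {
    m <- out[[h]]$primary_path
    data.frame(t0 = m[, 1], x = m[, 2], y = m[, 3], z = m[, 4], KE = m[, 5],
               history = h)
  })
  book <- do.call(rbind, lapply(seq_along(out), function(h)
    as.data.frame(c(out[[h]]$bookkeeping, history = h))))
  structure(list(config = config,
                 events = bind("events"),
                 electrons = bind("electrons"),
                 snapshots = if (!primary_only) bind("snapshots") else NULL,
                 primary_path = do.call(rbind, paths),
                 bookkeeping = book,
                 provenance = list(seed = config$seed,
                                   table = table$provenance)),
            class = "aq_result")
}

#' @export
print.aq_result <- function(x, ...) {
  cat("<aq_result> E0 =", x$config$E0, "eV,", x$config$n_histories,
      "histories,", if (is.null(x$events)) 0 else nrow(x$events),
      "events,", if (is.null(x$electrons)) 0 else nrow(x$electrons),
      "electrons\n")
  invisible(x)
}

#' Construct an explicit electron state
#'
#' @param position,velocity nm / nm/fs 3-vectors. Alternatively give
#'   `kinetic_energy` (eV) and `direction` (unit 3-vector) instead of
#'   `velocity`.
#' @param parent_position cation anchor, nm, or `NULL` for a free electron.
#' @param birth_time fs on the global clock.
#' @param origin `"ionisation"` or `"excitation"` channel origin.
#' @param kinetic_energy,direction alternative velocity specification.
#' @return list of class `aq_electron`.
#' @export
electron_state <- function(position = c(0, 0, 0), velocity = NULL,
                           parent_position = NULL, birth_time = 0,
                           origin = c("ionisation", "excitation"),
                           kinetic_energy = NULL, direction = c(0, 0, 1)) {
  origin <- match.arg(origin)
  if (is.null(velocity)) {
    if (is.null(kinetic_energy))
      stop("give velocity or kinetic_energy", call. = FALSE)
    direction <- direction / sqrt(sum(direction^2))
    velocity <- electron_speed(kinetic_energy) * direction
  }
  structure(list(position = as.numeric(position),
                 velocity = as.numeric(velocity),
                 has_parent = !is.null(parent_position),
                 parent = if (is.null(parent_position)) c(0, 0, 0)
                          else as.numeric(parent_position),
                 birth_t0 = birth_time,
                 origin = if (origin == "ionisation") 1L else 2L),
            class = "aq_electron")
}

#' Propagate a single secondary electron
#'
#' Integrates Newtonian motion in the time-dependent screened field of the
#' electron's parent cation (evaluated on the electron's own clock),
#' interleaved with sampled collisions, until thermalisation or the cutoff
#' time. Electrons spawned by any ionising/exciting collisions along the way
#' are reported but not propagated.
#'
#' @param state an [electron_state()].
#' @param params an `aq_dielectric`.
#' @param table an `aq_xsec`.
#' @param config an `aq_config`.
#' @param seed integer seed for this electron's substream.
#' @return list with one-row data frame `electron` (final state), plus
#'   `spawned`, `events`, `snapshots` and `bookkeeping`.
#' @export
propagate_secondary <- function(state, params, table, config, seed = 1L) {
  stopifnot(inherits(state, "aq_electron"))
  cpp_propagate(.xsec_compact(table), .diel_compact(params),
                .cfg_compact(config), unclass(state), as.integer(seed))
}

#' Thermalisation-distance experiment
#'
#' Injects `n` force-free electrons isotropically at kinetic energy
#' `E_inject` and returns the straight-line distance from the injection
#' point to the thermalisation point. Subexcitation electrons of
#' 0.1 - 4.0 eV thermalise within roughly 1 - 8.5 nm in liquid water; this
#' experiment reproduces that validation benchmark.
#'
#' @param E_inject injection kinetic energy, eV (0 < E <= 10).
#' @param n number of electrons.
#' @param seed integer seed.
#' @param table an `aq_xsec`.
#' @param params an `aq_dielectric`.
#' @param temperature K.
#' @param t_max maximum per-electron time, fs.
#' @return list with `mean` (nm), `se`, `distances`, `final_KE`, `status`.
#' @export
thermalisation_distance_experiment <- function(E_inject, n = 1000, seed = 1L,
                                               table = default_xsec_table(),
                                               params = dielectric_params(),
                                               temperature = 300,
                                               t_max = 20000) {
  if (E_inject <= 0 || E_inject > 10)
    stop("E_inject must be in (0, 10] eV", call. = FALSE)
  cfg <- sim_config(E0 = 100, seed = seed, temperature = temperature,
                    t_horizon = t_max, t_cut_secondary = t_max,
                    snapshot_times = t_max)
  res <- cpp_therm_experiment(.xsec_compact(table), .diel_compact(params),
                              .cfg_compact(cfg), E_inject, as.integer(n),
                              as.integer(seed))
  list(mean = mean(res$distance),
       se = stats::sd(res$distance) / sqrt(n),
       distances = res$distance, final_KE = res$KE, status = res$status)
}
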