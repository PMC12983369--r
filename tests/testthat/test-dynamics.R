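test_that("primary track generation conserves energy exactly", {
  cfg <- sim_config(E0 = 1000, n_histories = 4, seed = 7)
  pt <- generate_primary_track(cfg, default_xsec_table())
  ## E0 = all deposits + all retained kinetic energies, per history
  for (h in 1:4) {
    bk <- pt$bookkeeping[pt$bookkeeping$history == h, ]
    expect_equal(bk$deposits + bk$residual, 1000, tolerance = 1e-9)
    expect_equal(bk$field_work, 0)
    expect_equal(bk$bath_net, 0)
  }
  ## events carry non-decreasing times and spawned indices
  for (h in 1:4) {
    ev <- pt$events[pt$events$history == h, ]
    expect_true(all(diff(ev$t0) >= 0))
  }
  ## one spawned electron per ionisation/excitation event (plus a remnant)
  expect_equal(nrow(pt$events) + 4L, nrow(pt$electrons))
})

test_that("event induction finishes within tens of fs at 100 eV", {
  cfg <- sim_config(E0 = 100, n_histories = 20, seed = 3)
  pt <- generate_primary_track(cfg, default_xsec_table())
  expect_lt(max(pt$events$t0), 50)
})

test_that("full runs are reproducible and count every spawned electron", {
  cfg <- sim_config(E0 = 300, n_histories = 5, seed = 11)
  tab <- default_xsec_table()
  r1 <- run_simulation(cfg, tab)
  r2 <- run_simulation(cfg, tab)
  expect_identical(r1$electrons, r2$electrons)
  expect_identical(r1$events, r2$events)
  ## N_e equals the number of counted events
  ne <- sum(r1$electrons$remnant == 0)
  expect_equal(ne, nrow(r1$events))
  ## a 20 eV primary with open channels still induces at least one event
  r20 <- run_simulation(sim_config(E0 = 20, n_histories = 5, seed = 2), tab)
  expect_gt(nrow(r20$events), 0)
})

test_that("full-run energy ledger closes including bath and field terms", {
  cfg <- sim_config(E0 = 300, n_histories = 5, seed = 11)
  res <- run_simulation(cfg, default_xsec_table())
  bk <- res$bookkeeping
  expect_equal(bk$deposits + bk$bath_net + bk$residual - bk$field_work,
               rep(300, 5), tolerance = 1e-8)
})

test_that("a free electron with no interactions moves ballistically", {
  st <- electron_state(position = c(0, 0, 0), kinetic_energy = 2,
                       direction = c(0, 0, 1))
  out <- propagate_secondary(st, dielectric_params(), zero_table(),
                             sim_config(E0 = 100, seed = 1), seed = 5)
  v <- sqrt(2 * 2 / aq_constants$m_e)
  ## halted at the 500 fs per-electron cutoff, exactly on the line z = v t
  expect_equal(out$electron$z, v * 500, tolerance = 1e-9)
  expect_equal(out$electron$x, 0)
  expect_equal(out$electron$KE, 2, tolerance = 1e-12)
})

test_that("pure-Coulomb orbits conserve energy and angular momentum", {
  pc <- constant_eps_params(1.78)
  cfg <- sim_config(E0 = 100, seed = 1, t_horizon = 1000,
                    t_cut_secondary = 1000, dt_max = 0.005,
                    disp_cap = 0.005, disp_cap_far = 0.005, r_soft = 1e-4,
                    snapshot_times = 1000)
  st <- electron_state(position = c(0.5, 0, 0), kinetic_energy = 1,
                       direction = c(0, 1, 0),
                       parent_position = c(0, 0, 0))
  out <- propagate_secondary(st, pc, zero_table(), cfg, seed = 3)
  el <- out$electron
  r0 <- 0.5; r1 <- sqrt(el$x^2 + el$y^2 + el$z^2)
  E0 <- 1 - screened_potential(pc, r0, 0)
  E1 <- el$KE - screened_potential(pc, r1, 0)
  expect_lt(abs(E1 - E0), 1e-4)
  ## circular-orbit closed form: v^2 = k /(eps m r) stays on r = const
  k_eff <- aq_constants$k_coulomb / 1.78
  v_circ <- sqrt(k_eff / (aq_constants$m_e * 0.5))
  stc <- electron_state(position = c(0.5, 0, 0),
                        velocity = c(0, v_circ, 0),
                        parent_position = c(0, 0, 0))
  outc <- propagate_secondary(stc, pc, zero_table(), cfg, seed = 4)
  rc <- sqrt(outc$electron$x^2 + outc$electron$y^2 + outc$electron$z^2)
  expect_equal(rc, 0.5, tolerance = 1e-3)
})

test_that("thermalised electrons asymptote to a Maxwellian at 300 K", {
  ex <- thermalisation_distance_experiment(1.0, n = 3000, seed = 21)
  ke <- ex$final_KE[ex$status == 1]
  expect_gt(length(ke), 2500)
  ks <- suppressWarnings(stats::ks.test(ke, maxwell_cdf(300)))
  expect_lt(unname(ks$statistic), 0.05)
  expect_equal(mean(ke), 1.5 * kT300, tolerance = 0.1)
})

test_that("thermalisation distance grows with injection energy", {
  d01 <- thermalisation_distance_experiment(0.1, n = 400, seed = 5)
  d1 <- thermalisation_distance_experiment(1.0, n = 400, seed = 5)
  d4 <- thermalisation_distance_experiment(4.0, n = 400, seed = 5)
  expect_lt(d01$mean, d1$mean)
  expect_lt(d1$mean, d4$mean)
  ## near-thermal injection stops essentially in place
  d0 <- thermalisation_distance_experiment(0.04, n = 400, seed = 5)
  expect_lt(d0$mean, d01$mean + 0.5)
  expect_error(thermalisation_distance_experiment(50), "10")
})

test_that("penetration range ordering and magnitudes follow primary energy", {
  tab <- default_xsec_table()
  r100 <- penetration_range(
    run_simulation(sim_config(E0 = 100, n_histories = 8, seed = 2), tab), 1000)
  r1k <- penetration_range(
    run_simulation(sim_config(E0 = 1000, n_histories = 8, seed = 2), tab), 1000)
  r30k <- penetration_range(
    run_simulation(sim_config(E0 = 30000, n_histories = 2, seed = 2), tab), 1000)
  expect_lt(r100$range_nm, r1k$range_nm)
  expect_lt(r1k$range_nm, r30k$range_nm)
  ## ~10 nm, several 10 nm, ~10 um
  expect_gt(r100$range_nm, 2); expect_lt(r100$range_nm, 30)
  expect_gt(r1k$range_nm, 20); expect_lt(r1k$range_nm, 150)
  expect_gt(r30k$range_nm, 3e3); expect_lt(r30k$range_nm, 3e4)
})

test_that("Monte-Carlo error of P_ion shrinks with the history count", {
  tab <- default_xsec_table()
  p_of <- function(n, seed) {
    res <- run_simulation(sim_config(E0 = 300, n_histories = n, seed = seed),
                          tab)
    counts <- classify_final(res)
    counts$n_delocalised / counts$N_e
  }
  ## binomial error: se ~ sqrt(p(1-p)/N_e); with 4x the electrons the
  ## spread of independent estimates halves
  p_small <- vapply(1:12, function(s) p_of(4, s), numeric(1))
  p_big <- vapply(1:12, function(s) p_of(16, s + 100), numeric(1))
  expect_lt(stats::sd(p_big), stats::sd(p_small))
})

test_that("run configuration enforces the supported regime", {
  expect_error(sim_config(E0 = 5), "20")
  expect_error(sim_config(E0 = 1e6), "30000")
  expect_error(sim_config(E0 = 100, t_cut_secondary = 2000), "t_horizon")
  expect_error(sim_config(E0 = 100, r_sep = -1), "r_sep")
  expect_error(run_simulation(sim_config(E0 = 1000),
                              generate_fixture(E_max = 500)),
               "extrapolation|cannot transport")
})
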