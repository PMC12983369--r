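## A small shared run for the classification/observable checks
obs_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_simulation(sim_config(E0 = 500, n_histories = 30,
                                          seed = 17), default_xsec_table())
    cache
  }
})

test_that("G_total implements N_total/E0 x 100 and is non-decreasing", {
  res <- obs_result()
  ## direct formula check on one history
  ev1 <- res$events[res$events$history == 1, ]
  g1 <- nrow(ev1) / 500 * 100
  counts <- vapply(1:30, function(h)
    sum(res$events$history == h), numeric(1))
  expect_equal(g_total(res, 1000)$G, mean(counts / 500 * 100))
  expect_equal(g_total(res, 0)$G, 0)
  tgrid <- c(0, 5, 10, 20, 50, 100, 200, 500, 1000)
  expect_true(all(diff(g_total(res, tgrid)$G) >= 0))
  expect_gt(g1, 0)
  expect_error(g_total(res, 2000), "horizon")
})

test_that("classification matches an independent brute-force distance scan", {
  res <- obs_result()
  counts <- classify_final(res, 0.75)
  ## independent recomputation straight from the final-state table
  el <- res$electrons[res$electrons$remnant == 0, ]
  d <- sqrt((el$x - el$parent_x)^2 + (el$y - el$parent_y)^2 +
            (el$z - el$parent_z)^2)
  deloc <- sum(d >= 0.75)
  loc <- sum(d < 0.75 & el$origin == 2)
  reloc <- sum(d < 0.75 & el$origin == 1)
  expect_identical(counts$n_delocalised, deloc)
  expect_identical(counts$n_localised, loc)
  expect_identical(counts$n_relocalised, reloc)
  expect_identical(counts$n_delocalised + counts$n_localised +
                   counts$n_relocalised, counts$N_e)
})

test_that("classification is invariant under global rotation", {
  res <- obs_result()
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- res
  xyz <- as.matrix(res$electrons[, c("x", "y", "z")]) %*% R
  pxyz <- as.matrix(res$electrons[, c("parent_x", "parent_y",
                                      "parent_z")]) %*% R
  rot$electrons$x <- xyz[, 1]; rot$electrons$y <- xyz[, 2]
  rot$electrons$z <- xyz[, 3]
  rot$electrons$parent_x <- pxyz[, 1]; rot$electrons$parent_y <- pxyz[, 2]
  rot$electrons$parent_z <- pxyz[, 3]
  rot$electrons$dist_parent <- sqrt(rowSums((xyz - pxyz)^2))
  a <- classify_final(res); b <- classify_final(rot)
  expect_equal(a$n_delocalised, b$n_delocalised)
  expect_equal(a$n_localised, b$n_localised)
  expect_equal(a$n_relocalised, b$n_relocalised)
})

test_that("limiting separation radii give the degenerate yields", {
  res <- obs_result()
  far <- classify_final(res, 1e9)
  expect_equal(far$n_delocalised, 0)
  near <- classify_final(res, 1e-12)
  expect_equal(near$n_delocalised, near$N_e)
  expect_equal(g_hyd(res, 1e9)$G_hyd, 0)
})

test_that("P_ion and P_exc always sum to one", {
  res <- obs_result()
  for (r in c(0.2, 0.75, 1.0, 3)) {
    gh <- g_hyd(res, r)
    expect_equal(gh$P_ion + gh$P_exc, 1, tolerance = 1e-15)
    expect_lte(gh$G_hyd, gh$G_total)
  }
})

test_that("W and G conversions are exact inverses", {
  expect_equal(g_from_w(29.6), 3.378, tolerance = 1e-3)
  expect_equal(round(g_from_w(29.6), 1), 3.4)
  expect_equal(w_from_g(4.30), 23.26, tolerance = 1e-2)
  x <- c(0.3, 2.2, 4.30, 7)
  expect_equal(g_from_w(w_from_g(x)), x)
  expect_error(w_from_g(0), "> 0")
  expect_error(g_from_w(-3), "> 0")
})

test_that("ion/exc ratio handles counts and degenerate denominators", {
  fake <- structure(list(n_delocalised = 2L, n_localised = 1L,
                         n_relocalised = 0L, N_e = 3L), class = "aq_classcounts")
  expect_equal(ratio_ion_exc(fake), 2)
  fake0 <- structure(list(n_delocalised = 3L, n_localised = 0L,
                          n_relocalised = 0L, N_e = 3L),
                     class = "aq_classcounts")
  expect_warning(r <- ratio_ion_exc(fake0), "undefined")
  expect_true(is.nan(r))
})

test_that("Maxwellian density has the closed-form moments", {
  expect_equal(stats::integrate(maxwellian_pdf, 0, Inf,
                                temperature = 300)$value, 1,
               tolerance = 1e-6)
  E <- seq(0, 2, length.out = 40001)
  f <- maxwellian_pdf(E, 300)
  dx <- diff(E)[1]
  expect_equal(sum(f * E) * dx, 1.5 * kT300, tolerance = 1e-4)
  expect_equal(E[which.max(f)], kT300 / 2, tolerance = 5e-3)
  expect_error(maxwellian_pdf(-1), ">= 0")
})

test_that("spectra and radial distributions are consistent histograms", {
  res <- obs_result()
  sp <- energy_spectrum(res, 1000)
  expect_equal(sum(sp$density * (sp$upper - sp$lower)), 1, tolerance = 1e-9)
  sd_ <- spatial_distribution(res, 1000)
  n_parented <- sum(res$snapshots$time == 1000 & res$snapshots$dist >= 0)
  expect_equal(sum(sd_$count), n_parented)
  expect_error(energy_spectrum(res, 333), "snapshot")
  ## the sub-100 meV population grows with time as electrons thermalise
  frac_cold <- function(t) {
    sn <- res$snapshots[res$snapshots$time == t, ]
    mean(sn$KE < 0.1)
  }
  expect_gt(frac_cold(1000), frac_cold(50))
})

test_that("late-time spectra are stationary once induction has ceased", {
  res <- obs_result()
  s500 <- res$snapshots[res$snapshots$time == 500, ]
  s1000 <- res$snapshots[res$snapshots$time == 1000, ]
  ks <- suppressWarnings(stats::ks.test(s500$KE, s1000$KE))
  expect_lt(unname(ks$statistic), 0.05)
  ks_d <- suppressWarnings(stats::ks.test(s500$dist[s500$dist >= 0],
                                          s1000$dist[s1000$dist >= 0]))
  expect_lt(unname(ks_d$statistic), 0.05)
})

test_that("g_report assembles a coherent yield summary", {
  res <- obs_result()
  rep <- g_report(res)
  expect_equal(rep$G_hyd, rep$G_total * rep$P_ion)
  expect_equal(rep$W, 100 / rep$G_hyd)
  expect_equal(sum(rep$G_class), rep$G_total, tolerance = 1e-9)
  expect_equal(unname(rep$G_class["delocalised"]), rep$G_hyd)
  expect_output(print(rep), "G_hyd")
})
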