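test_that("TSV round-trip preserves tables bit-exactly", {
  tab <- two_channel_table()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_xsec(tab, f)
  back <- read_xsec(f)
  expect_identical(back$energy_eV, tab$energy_eV)
  expect_identical(unname(back$sigma), unname(tab$sigma))
  expect_equal(back$number_density, tab$number_density)
  expect_equal(length(back$channels), 2L)
  ## a second cycle is byte-identical
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_xsec(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("table validation rejects malformed input", {
  expect_error(
    xsec_table(c(10, 10, 20), matrix(0.01, 3, 2),
               list(xsec_channel("elastic", "elastic", 0),
                    xsec_channel("ion", "ionisation", 10.9))),
    "strictly increasing")
  expect_error(
    xsec_table(c(10, 20), cbind(c(0.01, -0.01), c(0, 0)),
               list(xsec_channel("elastic", "elastic", 0),
                    xsec_channel("ion", "ionisation", 10.9))),
    "negative")
  ## missing mandatory channels
  expect_error(
    xsec_table(c(10, 20), cbind(c(0.01, 0.01)),
               list(xsec_channel("elastic", "elastic", 0))),
    "ionisation")
  ## sigma > 0 below threshold
  expect_error(
    xsec_table(c(5, 20), cbind(c(0.01, 0.01), c(0.01, 0.01)),
               list(xsec_channel("elastic", "elastic", 0),
                    xsec_channel("ion", "ionisation", 10.9))),
    "below its threshold")
  ## non-zero DEA in default mode
  expect_error(
    xsec_table(c(12, 20), cbind(0.01, c(0.01, 0.01), c(0.002, 0.002)),
               list(xsec_channel("elastic", "elastic", 0),
                    xsec_channel("ion", "ionisation", 10.9),
                    xsec_channel("dea", "attachment", 5))),
    "zero cross section")
})

test_that("sigma_at interpolates log-log, honours nodes and thresholds", {
  tab <- two_channel_table()
  ## node identity
  expect_equal(sigma_at(tab, "ion", 100), 0.02)
  ## below threshold -> 0
  expect_equal(sigma_at(tab, "ion", 9), 0)
  ## hand log-log value: sigma = 1.0 nm2 at 10 eV and 4.0 nm2 at 40 eV
  ## interpolates to exactly 2.0 nm2 at 20 eV
  hand <- xsec_table(c(10, 40), cbind(el = c(1, 4), ion = c(0, 0)),
                     list(xsec_channel("el", "elastic", 0),
                          xsec_channel("ion", "ionisation", 10.9)))
  expect_equal(sigma_at(hand, "el", 20), 2.0, tolerance = 1e-12)
  ## zero bracketing node falls back to linear (threshold region)
  expect_equal(sigma_at(tab, "ion", 20), 0.01 / 3, tolerance = 1e-12)
  ## no extrapolation above the grid
  expect_error(sigma_at(tab, "ion", 2000), "extrapolation")
  ## refinement invariance where log-log applies: inserting the
  ## interpolated value as a new node leaves all queries unchanged
  E2 <- c(5, 10, 20, 40, 100, 1000)
  s2 <- cbind(elastic = sigma_at(tab, "elastic", E2),
              ion = sigma_at(tab, "ion", E2))
  tab2 <- xsec_table(E2, s2, tab$channels)
  q <- c(12, 47, 77, 400)
  expect_equal(sigma_at(tab2, "elastic", q), sigma_at(tab, "elastic", q),
               tolerance = 1e-12)
  expect_equal(sigma_at(tab2, "ion", c(47, 77, 400)),
               sigma_at(tab, "ion", c(47, 77, 400)), tolerance = 1e-12)
})

test_that("inverse mean free path is density times summed sigma", {
  expect_equal(inverse_mfp(flat_table(0.01), 50), 33.43 * 0.01)
  ## additivity: two channels of 0.01 and 0.03 give 4x the single channel
  E <- c(1, 10, 100)
  tab4 <- xsec_table(E, cbind(rep(0.01, 3), rep(0.03, 3), rep(0, 3)),
                     list(xsec_channel("elastic", "elastic", 0),
                          xsec_channel("el2", "elastic", 0),
                          xsec_channel("ion", "ionisation", 10.9)))
  expect_equal(inverse_mfp(tab4, 10), 4 * 33.43 * 0.01)
  expect_equal(inverse_mfp(zero_table(), 10), 0)
})

test_that("free flights are exponential with the table's rate", {
  tab <- flat_table(0.01)  # Lambda = 0.3343 / nm, mean 2.991 nm
  set.seed(42)
  x <- sample_flight(tab, 50, n = 1e5)
  expect_equal(mean(x), 1 / 0.3343, tolerance = 0.01)
  ks <- suppressWarnings(stats::ks.test(x, stats::pexp, rate = 0.3343))
  expect_gt(ks$p.value, 0.01)
  ## determinism under a fixed seed
  set.seed(7); a <- sample_flight(tab, 50, n = 5)
  set.seed(7); b <- sample_flight(tab, 50, n = 5)
  expect_identical(a, b)
  expect_error(sample_flight(zero_table(), 10), "no interaction")
})

test_that("channel branching follows the cross-section ratio", {
  E <- c(1, 10, 100)
  tab <- xsec_table(E, cbind(rep(0.03, 3), c(0, 0, 0.01)),
                    list(xsec_channel("elastic", "elastic", 0),
                         xsec_channel("ion", "ionisation", 10.9)))
  set.seed(1)
  draws <- sample_channel(tab, 100, n = 1e5)
  p_el <- mean(draws == "elastic")
  se <- sqrt(0.75 * 0.25 / 1e5)
  expect_lt(abs(p_el - 0.75), 3 * se)
  ## below all inelastic thresholds the elastic channel is certain
  expect_true(all(sample_channel(tab, 5, n = 100) == "elastic"))
})

test_that("energy partition follows the per-kind transfer rules", {
  exc <- xsec_channel("exc", "excitation_discrete", 8.4)
  p <- sample_energy_partition(exc, 50)
  expect_equal(p$energy_transfer, 8.4)
  expect_equal(p$secondary_KE, 0)
  vib <- xsec_channel("vib", "vibrational", 0.20)
  p <- sample_energy_partition(vib, 5)
  expect_equal(p$energy_transfer, 0.20)
  expect_false(p$spawns_electron)
  coll <- xsec_channel("coll", "excitation_collective", 12.4,
                       transfer = 21.4)
  p <- sample_energy_partition(coll, 100)
  expect_equal(p$energy_transfer, 21.4)
  expect_equal(p$secondary_KE, 9.0)
  ## ionisation: equal-sharing cap 0 <= W <= (E - B)/2, transfer = B + W
  ion <- xsec_channel("ion", "ionisation", 10.9)
  set.seed(3)
  for (i in 1:200) {
    p <- sample_energy_partition(ion, 100)
    expect_gte(p$secondary_KE, 0)
    expect_lte(p$secondary_KE, (100 - 10.9) / 2)
    expect_equal(p$energy_transfer, 10.9 + p$secondary_KE)
    expect_lte(p$energy_transfer, 100)
  }
  expect_error(sample_energy_partition(ion, 10), "threshold")
})

test_that("fixture generator is deterministic and valid", {
  a <- generate_fixture(seed = 5)
  b <- generate_fixture(seed = 5)
  expect_identical(a$sigma, b$sigma)
  expect_s3_class(validate_xsec(a), "aq_xsec")
  kinds <- vapply(a$channels, `[[`, "", "kind")
  expect_true(all(c("elastic", "ionisation", "excitation_discrete",
                    "vibrational") %in% kinds))
  ## attachment column present but zero unless explicitly overridden
  d <- generate_fixture(seed = 5, attachment = TRUE)
  expect_true(all(d$sigma[, "dea"] == 0))
  d2 <- generate_fixture(seed = 5, attachment = TRUE, dea_sigma = 0.01)
  expect_gt(max(d2$sigma[, "dea"]), 0)
})

test_that("the packaged default table satisfies its declared structure", {
  tab <- default_xsec_table()
  expect_s3_class(validate_xsec(tab), "aq_xsec")
  expect_equal(tab$phase, "liquid")
  expect_gte(max(tab$energy_eV), 30000)
  kinds <- vapply(tab$channels, `[[`, "", "kind")
  ## the collective excitation carries the largest single inelastic cross
  ## section anywhere on the grid
  inel <- which(!(kinds %in% c("elastic", "phonon", "attachment")))
  peaks <- apply(tab$sigma[, inel, drop = FALSE], 2, max)
  expect_equal(kinds[inel][which.max(peaks)], "excitation_collective")
})
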