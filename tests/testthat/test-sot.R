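sys3 <- spin_system_preset("threeSpin")
sys4 <- spin_system_preset("fourSpin")

test_that("total sequence durations follow the timing formulas", {
  expect_equal(sot_sequence("phINEPT+", 0.011, 0.009)$t_tot, 0.040)
  expect_equal(sot_sequence("ESOTHERIC", 0.007, 0.006)$t_tot, 0.040)
  expect_equal(sot_sequence("ESOTHERIC", 0, 0)$t_tot, 0)
  # the event list durations are consistent with t_tot
  for (nm in c("phINEPT+", "ESOTHERIC")) {
    sq <- sot_sequence(nm, 0.013, 0.004)
    expect_equal(sum(sq$events$duration), sq$t_tot)
  }
  expect_error(sot_sequence("nope", 1e-3, 1e-3), "unknown")
  expect_error(sot_sequence("phINEPT+", -1e-3, 1e-3), "non-negative")
})

test_that("zero delays give zero transfer", {
  expect_equal(run_sot(sys3, sot_sequence("phINEPT+", 0, 0)), 0,
               tolerance = 1e-10)
  expect_equal(run_sot(sys3, sot_sequence("ESOTHERIC", 0, 0)), 0,
               tolerance = 1e-10)
})

test_that("targets must be 15N and maps agree with run_sot", {
  expect_error(run_sot(sys3, sot_sequence("phINEPT+", 0.01, 0.01),
                       targets = 1), "N channel")
  m <- sot_map(sys3, "phINEPT+", c(0.008, 0.012), c(0.01), k_d = 0)
  expect_equal(nrow(m), 2)
  expect_equal(m$polarization[2],
               run_sot(sys3, sot_sequence("phINEPT+", 0.012, 0.01)),
               tolerance = 1e-10)
  # k_d = 0 leaves the map undamped
  expect_equal(m$polarization, m$undamped)
})

test_that("damping is multiplicative and monotone in k_d", {
  taus <- seq(0.004, 0.02, by = 0.004)
  m0 <- sot_map(sys3, "phINEPT+", taus, taus, k_d = 0)
  m1 <- sot_map(sys3, "phINEPT+", taus, taus, k_d = 2.7)
  m2 <- sot_map(sys3, "phINEPT+", taus, taus, k_d = 5)
  expect_true(all(m1$polarization <= m0$polarization + 1e-12))
  expect_true(all(m2$polarization <= m1$polarization + 1e-12))
  ttot <- 2 * (m1$tau1_s + m1$tau2_s)
  expect_equal(m1$polarization, m0$polarization * exp(-2.7 * ttot),
               tolerance = 1e-12)
  expect_error(sot_map(sys3, "phINEPT+", taus, taus, k_d = -1),
               "non-negative")
})

test_that("all map polarizations are physical", {
  taus <- seq(0.002, 0.03, by = 0.007)
  for (nm in c("phINEPT+", "ESOTHERIC")) {
    m <- sot_map(sys4, nm, taus, taus)
    expect_true(all(m$polarization >= -1e-12 & m$polarization <= 1 + 1e-12))
  }
})

test_that("the mirror-symmetric four-spin system polarizes both 15N equally", {
  sq <- sot_sequence("ESOTHERIC", 0.009, 0.013)
  p1 <- run_sot(sys4, sq, targets = 3)
  p2 <- run_sot(sys4, sq, targets = 4)
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("optimization refines the grid optimum and handles edge cases", {
  # single-point grid equals the map value there
  one <- optimize_sot(sys3, "phINEPT+", bounds = c(0.0099, 0.0101),
                      grid_step = 0.001, k_d = 2.7)
  direct <- run_sot(sys3, sot_sequence("phINEPT+", one$tau1_s, one$tau2_s))
  expect_equal(one$undamped, direct, tolerance = 1e-10)

  coarse <- sot_map(sys3, "phINEPT+", seq(0.004, 0.02, 0.004),
                    seq(0.004, 0.02, 0.004), k_d = 2.7)
  opt <- optimize_sot(sys3, "phINEPT+", bounds = c(0.004, 0.02),
                      grid_step = 0.004, k_d = 2.7)
  expect_gte(opt$polarization, max(coarse$polarization) - 1e-12)
  expect_error(optimize_sot(sys3, "phINEPT+", bounds = c(0.02, 0.01)),
               "bounds")
})

test_that("SABRE store/filter/read variant preserves the in-phase signal", {
  # at tau_e = 0 the bound 15N polarization survives the store + gradient
  # filter + read chain, while coherences are purged
  p_sot <- run_sot(sys3, sot_sequence("phINEPT+", 0.012, 0.012))
  p_sabre <- run_sot(sys3, sot_sequence("SABRE-INEPT", 0.012, 0.012))
  expect_equal(p_sabre, p_sot, tolerance = 1e-8)
})

test_that("singlet initial order is available and differs from zz order", {
  p_zz <- run_sot(sys3, sot_sequence("phINEPT+", 0.012, 0.012), init = "zz")
  p_si <- run_sot(sys3, sot_sequence("phINEPT+", 0.012, 0.012),
                  init = "singlet")
  expect_gt(p_si, p_zz)
})
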