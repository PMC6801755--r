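dmk <- motor_preset("DmK")
hsk <- motor_preset("HsK")
hsk6 <- motor_preset("HsK-6AA")
cl6 <- motor_preset("HsK-CL-6AA")
kif <- motor_preset("KIF17")

test_that("reduced ratio is r0 at zero force, 1 at FS, and decreasing", {
  expect_equal(kin_reduced_ratio(0, dmk), 890)
  expect_equal(kin_reduced_ratio(8, dmk), 1)
  expect_equal(kin_reduced_ratio(4, dmk), sqrt(890))
  expect_equal(kin_reduced_ratio(4, dmk), 29.833, tolerance = 1e-4)
  f <- seq(-5, 10, by = 0.25)
  expect_true(all(diff(kin_reduced_ratio(f, dmk)) < 0))
})

test_that("escape probability is 1 for wild type and rises with |force|", {
  expect_equal(kin_p_escape(c(-4, 0, 3, 8), hsk), rep(1, 4))
  expect_equal(kin_p_escape(0, hsk6), 0.33)
  expect_equal(kin_p_escape(2, hsk6), 0.58794, tolerance = 1e-4)
  # symmetric in the sign of the force, bounded by [P0(0), 1]
  f <- seq(-6, 6, by = 0.5)
  p <- kin_p_escape(f, cl6)
  expect_equal(p, kin_p_escape(-f, cl6))
  expect_true(all(p >= 0.33 & p <= 1))
})

test_that("forward-rebinding probability matches its closed form", {
  expect_equal(kin_p_forward(0, dmk), 890 / (890 + 95 / 3))
  expect_equal(kin_p_forward(8, dmk), 3 / 98)
  expect_lt(kin_p_forward(50, dmk), 1e-10)
  p_nokm <- make_motor_params(r0 = 100, FS = 7, k_plus = 95, k_minus = 0)
  expect_equal(kin_p_forward(c(0, 3), p_nokm), c(1, 1))
})

test_that("stepping ratio matches printed zero-force values and stall", {
  expect_equal(kin_stepping_ratio(0, dmk), 890)
  expect_equal(kin_stepping_ratio(8, dmk), 1)      # wild type stalls at FS
  expect_equal(kin_stepping_ratio(2, hsk6), 72.336, tolerance = 1e-4)
  expect_equal(kin_stepping_ratio(0, cl6), 600)    # r0 at F = 0 in all cases
})

test_that("velocity matches direct evaluation and vanishes at stall", {
  expect_equal(kin_velocity(0, dmk), 751.390, tolerance = 1e-6)
  expect_equal(kin_velocity(0, cl6), 276.722, tolerance = 1e-6)
  expect_equal(kin_velocity(8, dmk), 0)
  expect_lt(kin_velocity(9, dmk), 0)  # net backward beyond stall
})

test_that("dwell time matches the closed form and its limits", {
  expect_equal(kin_dwell_time(0, motor_preset("Bovine")),
               (220 + 46) / (220 + 1) / 138)
  expect_equal(kin_dwell_time(8, dmk), (1 + 95 / 3) / (2 * 95))
  big <- make_motor_params(r0 = 1e4, FS = 50, k_plus = 95, k_minus = 3)
  expect_equal(kin_dwell_time(0, big), 1 / 95, tolerance = 1e-2)
})

test_that("diffusion constant and randomness match direct evaluation", {
  expect_equal(kin_diffusion(0, dmk), 891 / (890 + 95 / 3) * 95 * 8.2^2 / 2)
  expect_equal(kin_diffusion(0, dmk), 3087.63, tolerance = 1e-4)
  expect_true(all(kin_diffusion(seq(-5, 10, 0.5), cl6) > 0))
  expect_equal(kin_randomness(0, dmk), 891 / 889)
  expect_equal(kin_randomness(0, cl6), 1.003339, tolerance = 1e-5)
  expect_error(kin_randomness(8, dmk), "stall")
})

test_that("ATP per step counts reproduce the loose-coupling numbers", {
  expect_equal(kin_atp_per_forward_step(0, cl6), 3.284, tolerance = 1e-3)
  expect_equal(kin_atp_per_forward_step(0, dmk), 1.0683, tolerance = 1e-4)
  expect_equal(kin_atp_per_step(0, kif), 1.8054, tolerance = 1e-4)
  expect_equal(kin_atp_per_step(0, dmk), 1.0671, tolerance = 1e-4)
  f <- seq(-4, 4, by = 0.5)
  for (nm in PRESET_NAMES) {
    p <- motor_preset(nm)
    expect_true(all(kin_atp_per_step(f, p) <=
                      kin_atp_per_forward_step(f, p) + 1e-12), label = nm)
    expect_true(all(kin_atp_per_step(f, p) >= 1 - 1e-12), label = nm)
  }
})

test_that("power is zero at no load and at stall, positive between", {
  expect_equal(kin_power(0, cl6), 0)
  expect_equal(kin_power(8, dmk), 0)
  expect_equal(kin_power(2, cl6), 85.88, tolerance = 1e-3)
  f <- seq(0.25, 7.75, by = 0.25)
  expect_true(all(kin_power(f, dmk) > 0))
})

test_that("efficiency matches the HsK benchmark and scales as 1/deltaG", {
  expect_equal(kin_efficiency(2, hsk), 0.1611, tolerance = 1e-3)
  expect_equal(kin_efficiency(0, hsk), 0)
  expect_equal(kin_efficiency(2, hsk, deltaG = 40),
               kin_efficiency(2, hsk) / 2)
})

test_that("stall force equals FS for wild type and shifts below for mutants", {
  expect_identical(kin_stall_force(hsk), 7)
  expect_identical(kin_stall_force(dmk), 8)
  expect_equal(kin_stall_force(hsk6), 6.032, tolerance = 1e-3)
  s_kif <- kin_stall_force(kif)
  expect_gt(s_kif, 7.3)
  expect_lt(s_kif, 7.5)
  expect_equal(kin_velocity(kin_stall_force(cl6), cl6), 0,
               tolerance = 1e-4)
})

test_that("neck-linker docking energy inverts the zero-force ratio", {
  ed <- kin_docking_energy(dmk)
  expect_equal(ed$ED_kBT, 3.336, tolerance = 1e-3)
  expect_equal(ed$ED_err_kBT, 120 / 890 + 0.4 / 3 + 1 / 95)
  expect_equal(kin_docking_energy(motor_preset("HsK-CL"))$ED_kBT,
               log(600 * 4 / 107))
  # round trip: r0 = (k+/k-) exp(ED)
  for (nm in PRESET_NAMES) {
    p <- motor_preset(nm)
    ed <- kin_docking_energy(p)$ED_kBT
    expect_equal(p$k_plus / p$k_minus * exp(ed), p$r0, label = nm)
  }
  p0 <- make_motor_params(r0 = 100, FS = 7, k_plus = 95, k_minus = 0)
  expect_error(kin_docking_energy(p0), "k_minus")
})

test_that("characteristic distance is about half a step for kinesin-1", {
  p <- make_motor_params(r0 = 900, FS = 7, k_plus = 90.5, k_minus = 4)
  expect_equal(kin_characteristic_distance(p), 4.0, tolerance = 0.01)
  expect_equal(kin_characteristic_distance(motor_preset("Bovine")),
               2.920, tolerance = 1e-3)
  near1 <- make_motor_params(r0 = 1 + 1e-9, FS = 7, k_plus = 95,
                             k_minus = 3)
  expect_equal(kin_characteristic_distance(near1), 0, tolerance = 1e-8)
})

test_that("scan gathers all observables consistently on a tidy grid", {
  f <- seq(0, 6, by = 0.5)
  sc <- kin_scan(cl6, f)
  expect_identical(nrow(sc), length(f))
  expect_equal(sc$velocity_nm_s, kin_velocity(f, cl6))
  expect_equal(sc$ratio, kin_stepping_ratio(f, cl6))
  expect_equal(sc$D_nm2_s, kin_diffusion(f, cl6))
  expect_equal(sc$power_kBT_s, kin_power(f, cl6))
  expect_equal(sc$N, kin_atp_per_step(f, cl6))
  # divergences are reported as Inf in the tabular surface, not errors
  sc_stall <- kin_scan(dmk, 8)
  expect_identical(sc_stall$randomness, Inf)
})
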