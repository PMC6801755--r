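test_that("traces are bit-reproducible given the seed", {
  a <- exact_trace("KIF17", conditions(force = 2), t_max = 2, seed = 5)
  b <- exact_trace("KIF17", conditions(force = 2), t_max = 2, seed = 5)
  expect_identical(a$events, b$events)
  expect_identical(a$com_samples, b$com_samples)
  e1 <- simulate_ensemble("HsK-CL-6AA", conditions(force = 0), t_max = 1,
                          n_traces = 5, base_seed = 9)
  e2 <- simulate_ensemble("HsK-CL-6AA", conditions(force = 0), t_max = 1,
                          n_traces = 5, base_seed = 9)
  expect_identical(e1$per_trace, e2$per_trace)
  expect_identical(e1$com, e2$com)
  # a single-trace ensemble reproduces simulate/exact_trace counts
  tr <- exact_trace("HsK-CL-6AA", conditions(force = 0), t_max = 1,
                    seed = 10)
  expect_identical(e1$per_trace$n_hyd[1], tr$counts$n_hyd)
})

test_that("without ATP nothing happens", {
  tr <- exact_trace("DmK", conditions(force = 0, atp = 0), t_max = 5,
                    seed = 1)
  expect_identical(nrow(tr$events), 0L)
  expect_identical(tr$counts$com_end, 0)
  trf <- simulate_trace("DmK", conditions(force = 0, atp = 0), t_max = 1,
                        seed = 1)
  expect_identical(nrow(trf$events), 0L)
})

test_that("the fixed-timestep engine refuses unstable rate * dt and points to the exact engine", {
  expect_error(simulate_trace("KIF17", conditions(force = 0), t_max = 1,
                              seed = 1),
               "exact")
  expect_error(simulate_trace("HsK", conditions(force = 0, atp = 2000),
                              t_max = 1, seed = 1),
               "binding")
  # permissible at low ATP for moderate rates
  expect_s3_class(simulate_trace("HsK", conditions(force = 0, atp = 10),
                                 t_max = 1, seed = 1), "kin_trace")
  expect_error(simulate_trace("HsK", conditions(), t_max = -1, seed = 1),
               "t_max")
})

test_that("saturating-ATP ensembles reproduce the closed-form dynamics", {
  for (nm in c("DmK", "HsK-CL-6AA")) {
    p <- motor_preset(nm)
    ts <- simulate_ensemble(p, conditions(force = 2), t_max = 10,
                            n_traces = 250, base_seed = 77)
    s <- summarize_traces(ts)
    expect_lt(abs(s$velocity_nm_s - kin_velocity(2, p)),
              3 * s$velocity_sem, label = nm)
    expect_lt(abs(s$ratio - kin_stepping_ratio(2, p)), 3 * s$ratio_sem,
              label = nm)
    expect_lt(abs(s$N - kin_atp_per_step(2, p)), 3 * s$N_sem, label = nm)
    # total ATPase rate is k+ + k-, independent of load and coupling
    expect_lt(abs(s$hydrolysis_rate_s - (p$k_plus + p$k_minus)),
              3.5 * s$hydrolysis_rate_sem, label = nm)
  }
})

test_that("forward/backward event counts converge to the stepping ratio", {
  p <- motor_preset("Bovine")
  ts <- simulate_ensemble(p, conditions(force = 3), t_max = 10,
                          n_traces = 300, base_seed = 21)
  nf <- sum(ts$per_trace$n_fwd)
  nb <- sum(ts$per_trace$n_back)
  r_hat <- nf / nb
  se <- r_hat * sqrt(1 / nf + 1 / nb)
  expect_lt(abs(r_hat - kin_stepping_ratio(3, p)), 3 * se)
})

test_that("fixed-timestep and exact engines agree at non-saturating ATP", {
  cond <- conditions(force = 1, atp = 10)
  f <- summarize_traces(simulate_ensemble("HsK", cond, t_max = 10,
                                          n_traces = 200, base_seed = 3,
                                          engine = "fixed"))
  e <- summarize_traces(simulate_ensemble("HsK", cond, t_max = 10,
                                          n_traces = 200, base_seed = 1003,
                                          engine = "exact"))
  z <- abs(f$velocity_nm_s - e$velocity_nm_s) /
    sqrt(f$velocity_sem^2 + e$velocity_sem^2)
  expect_lt(z, 3)
  zh <- abs(f$hydrolysis_rate_s - e$hydrolysis_rate_s) /
    sqrt(f$hydrolysis_rate_sem^2 + e$hydrolysis_rate_sem^2)
  expect_lt(zh, 3)
})

test_that("halving the timestep leaves ensemble means unchanged within error", {
  cond <- conditions(force = 0, atp = 10)
  a <- summarize_traces(simulate_ensemble("DmK", cond, t_max = 10,
                                          n_traces = 150, base_seed = 11,
                                          engine = "fixed", dt = 1e-4))
  b <- summarize_traces(simulate_ensemble("DmK", cond, t_max = 10,
                                          n_traces = 150, base_seed = 511,
                                          engine = "fixed", dt = 5e-5))
  z <- abs(a$velocity_nm_s - b$velocity_nm_s) /
    sqrt(a$velocity_sem^2 + b$velocity_sem^2)
  expect_lt(z, 3)
})

test_that("velocity versus ATP follows Michaelis-Menten kinetics", {
  atps <- c(5, 10, 20, 50, 100, 500, 2000)
  v <- vapply(atps, function(a) {
    ts <- simulate_ensemble("HsK-CL-6AA", conditions(force = 0, atp = a),
                            t_max = 20, n_traces = 120,
                            base_seed = round(a * 7))
    mean(ts$per_trace$velocity_nm_s)
  }, numeric(1))
  expect_true(all(diff(v) > 0))  # monotone in [ATP]
  fit <- stats::nls(v ~ vmax * atps / (km + atps),
                    start = list(vmax = 280, km = 30), weights = 1 / v^2)
  rel <- abs(v - stats::predict(fit)) / v
  expect_lt(max(rel), 0.05)
  # a 10 uM ensemble is slower than the saturating branch
  expect_lt(v[2], kin_velocity(0, "HsK-CL-6AA"))
})
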