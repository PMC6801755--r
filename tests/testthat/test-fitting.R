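test_that("the synthetic generator is exact at zero noise and seed-reproducible", {
  f <- seq(-5, 7.5, length.out = 15)
  d0 <- generate_synthetic_fv("DmK", f)
  expect_equal(d0$velocity_nm_s, kin_velocity(f, motor_preset("DmK")))
  expect_false("sigma_nm_s" %in% names(d0))
  d1 <- generate_synthetic_fv("DmK", f, noise_cv = 0.02, seed = 42)
  d2 <- generate_synthetic_fv("DmK", f, noise_cv = 0.02, seed = 42)
  expect_identical(d1, d2)
  # realised noise CV is close to the requested one
  big <- generate_synthetic_fv("DmK", rep(f, 20), noise_cv = 0.02,
                               seed = 7)
  rel <- big$velocity_nm_s / kin_velocity(rep(f, 20), "DmK") - 1
  expect_equal(stats::sd(rel), 0.02, tolerance = 0.15)
})

test_that("noiseless velocity fits recover the generating parameters exactly", {
  f <- seq(-5, 7.5, length.out = 15)
  for (nm in WT_NAMES) {
    p <- motor_preset(nm)
    d <- generate_synthetic_fv(p, seq(-5, p$FS - 0.5, length.out = 15))
    fit <- suppressWarnings(fit_force_velocity(d))
    for (par in c("r0", "FS", "k_plus", "k_minus")) {
      expect_equal(fit$estimates[[par]], p[[par]], tolerance = 1e-3,
                   label = paste(nm, par))
    }
    expect_true(fit$converged)
    expect_lt(glance(fit)$rss, 1e-10)
  }
})

test_that("the joint wild-type/mutant protocol recovers the shared parameters and P0", {
  wt <- generate_synthetic_fv("HsK", seq(-4, 6.5, length.out = 15))
  mut <- generate_synthetic_fv("HsK-6AA", seq(-4, 5.5, length.out = 15))
  fit <- suppressWarnings(fit_force_velocity(
    wt, mutant_data = mut,
    free_params = c("r0", "FS", "k_plus", "k_minus", "P0_zero")))
  truth <- c(r0 = 900, FS = 7, k_plus = 90.5, k_minus = 4, P0_zero = 0.33)
  for (par in names(truth)) {
    expect_equal(fit$estimates[[par]], truth[[par]], tolerance = 1e-3,
                 label = par)
  }
})

test_that("noisy velocity fits recover the dominant rates within a few percent", {
  truth <- c(FS = 8, k_plus = 95)
  est <- sapply(1:10, function(i) {
    d <- generate_synthetic_fv("DmK", seq(-5, 7.5, length.out = 15),
                               noise_cv = 0.02, seed = 100 + i)
    fit <- suppressWarnings(fit_force_velocity(d))
    c(fit$estimates[["FS"]], fit$estimates[["k_plus"]])
  })
  err <- abs(est - truth) / truth * 100
  expect_lt(stats::median(err[1, ]), 5)  # FS within 5%
  expect_lt(stats::median(err[2, ]), 5)  # k+ within 5%
})

test_that("reported standard errors shrink as 1/sqrt(n)", {
  se_k <- vapply(c(10, 40, 160), function(n) {
    d <- generate_synthetic_fv("DmK",
                               rep(seq(-5, 7.5, length.out = 10), n / 10),
                               noise_cv = 0.02, seed = n)
    fit <- suppressWarnings(fit_force_velocity(d))
    fit$std_errors[["k_plus"]]
  }, numeric(1))
  expect_true(all(diff(se_k) < 0))
  expect_gt(se_k[1] / se_k[3], 2.5)  # expect about 4 for a 16x larger n
  expect_lt(se_k[1] / se_k[3], 6.5)
})

test_that("stepping-ratio fits are exact on noiseless data and linear in log space", {
  p <- make_motor_params(r0 = 900, FS = 7, k_plus = 90.5, k_minus = 4)
  f <- seq(-3, 6.5, length.out = 20)
  d <- tibble::tibble(force_pN = f, ratio = kin_stepping_ratio(f, p))
  fit <- suppressWarnings(fit_stepping_ratio(
    d, free_params = c("r0", "FS"),
    fixed_params = list(k_plus = 90.5, k_minus = 4)))
  expect_equal(fit$estimates[["r0"]], 900, tolerance = 1e-4)
  expect_equal(fit$estimates[["FS"]], 7, tolerance = 1e-4)
  # wild type: ln r is linear in F with slope -ln(r0)/FS
  slope <- stats::coef(stats::lm(log(d$ratio) ~ d$force_pN))[[2]]
  expect_equal(slope, -log(900) / 7)
  expect_error(fit_stepping_ratio(
    tibble::tibble(force_pN = 1:3, ratio = c(2, -1, 3))), "positive")
})

test_that("noisy stepping-ratio fits recover r0 within the log-scale spread", {
  err <- vapply(1:10, function(i) {
    p <- make_motor_params(r0 = 900, FS = 7, k_plus = 90.5, k_minus = 4)
    f <- seq(-3, 6.5, length.out = 20)
    set.seed(4000 + i)
    d <- tibble::tibble(force_pN = f,
                        ratio = kin_stepping_ratio(f, p) *
                          exp(stats::rnorm(20, sd = 0.05)))
    fit <- suppressWarnings(fit_stepping_ratio(
      d, free_params = c("r0", "FS"),
      fixed_params = list(k_plus = 90.5, k_minus = 4)))
    abs(fit$estimates[["r0"]] - 900) / 900 * 100
  }, numeric(1))
  expect_lt(stats::median(err), 15)
})

test_that("degenerate fit requests fail loudly", {
  d <- generate_synthetic_fv("DmK", c(0, 2, 4))
  expect_error(suppressWarnings(fit_force_velocity(d)), "Under-determined")
  d15 <- generate_synthetic_fv("DmK", seq(-5, 7.5, length.out = 15))
  expect_error(fit_force_velocity(d15, free_params = c("r0", "FS"),
                                  fixed_params = list(r0 = 890)),
               "both free and fixed")
  expect_error(fit_force_velocity(d15, free_params = c("r0", "FS")),
               "neither free nor fixed")
})

test_that("tidy and glance expose broom-style summaries", {
  d <- generate_synthetic_fv("DmK", seq(-5, 7.5, length.out = 15),
                             noise_cv = 0.02, seed = 8)
  fit <- suppressWarnings(fit_force_velocity(d))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_identical(td$term, c("r0", "FS", "k_plus", "k_minus"))
  expect_true(all(td$std.error >= 0))
  gl <- glance(fit)
  expect_named(gl, c("rss", "sigma", "df.residual", "nobs", "converged"))
  expect_identical(gl$nobs, 15L)
})
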