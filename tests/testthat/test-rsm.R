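# Central composite designs, quadratic surface fitting, pure-error /
# lack-of-fit ANOVA and stationary-point analysis.

ref_coef <- c(-186.5841, 48.6774, -3.4315, 2.9364, -0.0500, -0.0173)

test_that("the 11-run CCD hits the stated ranges with 5 levels per factor", {
  d <- generate_ccd(c(4.2, 9.8), c(16, 50), center_reps = 3, alpha = sqrt(2))
  expect_equal(nrow(d), 11)
  expect_equal(sort(unique(round(d$pH, 2))), c(4.2, 5.02, 7.0, 8.98, 9.8),
               tolerance = 0.01)
  expect_equal(sort(unique(round(d$temp_C, 2))), c(16, 20.98, 33, 45.02, 50),
               tolerance = 0.01)
  expect_equal(length(unique(d$coded_x)), 5)
  expect_equal(length(unique(d$coded_y)), 5)
  # coded/natural consistency under the center/step mapping
  expect_equal(d$pH, 7 + d$coded_x * (9.8 - 7) / sqrt(2))
  expect_equal(nrow(generate_ccd(c(4.2, 9.8), c(16, 50), center_reps = 1)), 9)
  expect_warning(d1 <- generate_ccd(c(0, 1), c(0, 1), alpha = 1), "face-centred")
  expect_equal(length(unique(d1$coded_x)), 3)
  expect_error(generate_ccd(c(1, 1), c(0, 1)), "degenerate")
  expect_error(generate_ccd(c(0, 1), c(0, 1), alpha = -1), "positive")
})

test_that("noiseless responses from a known quadratic are recovered exactly", {
  d <- generate_ccd(c(4.2, 9.8), c(16, 50))
  d$activity <- quad_surface(ref_coef, d$pH, d$temp_C)
  m <- fit_quadratic(d)
  expect_equal(unname(m$coefficients), ref_coef, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  an <- rsm_anova(m)
  expect_lt(an$ss[an$term == "Lack of Fit"], 1e-9)
})

test_that("degenerate fits are handled: constant response, rank deficiency", {
  d <- generate_ccd(c(4.2, 9.8), c(16, 50))
  d$activity <- 5
  expect_warning(m <- fit_quadratic(d), "zero-variance")
  expect_equal(m$r_squared, 0)
  expect_equal(unname(m$coefficients[-1]), rep(0, 5), tolerance = 1e-12)
  # perfectly collinear factors cannot support the 6-term model
  d2 <- data.frame(pH = c(1, 2, 3, 4, 5, 6, 7, 1),
                   temp_C = 2 * c(1, 2, 3, 4, 5, 6, 7, 1))
  d2$activity <- stats::rnorm(8)
  expect_error(fit_quadratic(d2), "rank-deficient")
  expect_error(fit_quadratic(d[1:5, ]), "at least 6 runs")
})

test_that("ANOVA decomposition identities hold on noisy replicated designs", {
  truth <- do.call(surface_model, as.list(stats::setNames(
    ref_coef, c("b0", "b1", "b11", "b2", "b22", "b12"))))
  for (seed in 1:5) {
    d <- sim_ccd(generate_ccd(c(4.2, 9.8), c(16, 50)), truth,
                 noise_sd = 0.9, seed = seed)
    m <- fit_quadratic(d)
    an <- rsm_anova(m)
    ss_lof <- an$ss[an$term == "Lack of Fit"]
    ss_pe <- an$ss[an$term == "Pure Error"]
    expect_equal(ss_lof + ss_pe, m$sse, tolerance = 1e-9)
    expect_equal(m$r_squared, 1 - (ss_lof + ss_pe) / m$sst, tolerance = 1e-9)
    expect_equal(an$df[an$term == "Lack of Fit"] + an$df[an$term == "Pure Error"],
                 11 - 6)
    # every F is the term MS over the pure-error MS
    mspe <- attr(an, "ms_pure_error")
    expect_equal(an$f[1:5], an$ms[1:5] / mspe, tolerance = 1e-12)
  }
  # no replicates -> pure error undefined
  d <- generate_ccd(c(4.2, 9.8), c(16, 50), center_reps = 1)
  d$activity <- quad_surface(ref_coef, d$pH, d$temp_C) + stats::rnorm(9)
  expect_error(rsm_anova(fit_quadratic(d)), "no replicated points")
})

test_that("coefficient error shrinks with the noise level", {
  truth <- do.call(surface_model, as.list(stats::setNames(
    ref_coef, c("b0", "b1", "b11", "b2", "b22", "b12"))))
  design <- generate_ccd(c(4.2, 9.8), c(16, 50))
  rmse_at <- function(sd) {
    errs <- vapply(1:200, function(s) {
      d <- sim_ccd(design, truth, noise_sd = sd, seed = s)
      sqrt(mean((fit_quadratic(d)$coefficients - truth$coefficients)^2))
    }, 0)
    mean(errs)
  }
  r_small <- rmse_at(0.2); r_big <- rmse_at(1.0)
  expect_lt(r_small, r_big)
  # exact at zero noise
  d0 <- sim_ccd(design, truth, noise_sd = 0, seed = 1)
  expect_equal(unname(fit_quadratic(d0)$coefficients), ref_coef, tolerance = 1e-9)
})

test_that("F survival function matches its closed form at df (1, 2)", {
  expect_equal(f_survival(0, 1, 2), 1)
  expect_equal(f_survival(0, 3, 10), 1)
  for (f in c(0.01, 0.04031, 0.5, 2.38026, 10, 57.74358, 500))
    expect_equal(f_survival(f, 1, 2), 1 - sqrt(f / (f + 2)), tolerance = 1e-9)
  expect_error(f_survival(-1, 1, 2), "non-negative")
  expect_error(f_survival(1, 0, 2), "degrees of freedom")
})

test_that("the reference LipJ surface has its maximum near pH 7, 28 C", {
  sp <- stationary_point(lipj_surface_model())
  expect_identical(sp$nature, "maximum")
  expect_equal(sp$x_star, 7.02, tolerance = 0.01)
  expect_equal(sp$y_star, 28.15, tolerance = 0.01)
})

test_that("stationary points are classified by Hessian definiteness", {
  # z = -(x-1)^2 - (y-2)^2: maximum at (1, 2)
  m1 <- surface_model(b0 = -5, b1 = 2, b11 = -1, b2 = 4, b22 = -1, b12 = 0)
  s1 <- stationary_point(m1)
  expect_equal(c(s1$x_star, s1$y_star), c(1, 2), tolerance = 1e-12)
  expect_identical(s1$nature, "maximum")
  # z = x^2 - y^2: saddle at origin
  s2 <- stationary_point(surface_model(0, 0, 1, 0, -1, 0))
  expect_equal(c(s2$x_star, s2$y_star), c(0, 0))
  expect_identical(s2$nature, "saddle")
  expect_identical(stationary_point(surface_model(0, 0, 1, 0, 1, 0))$nature,
                   "minimum")
  expect_error(stationary_point(surface_model(0, 1, 0, 1, 0, 0)),
               "ridge/degenerate")
  # extrapolation flag
  s3 <- stationary_point(m1, x_range = c(2, 3), y_range = c(0, 1))
  expect_true(s3$extrapolated)
})

test_that("the gradient vanishes at fitted-surface stationary points", {
  truth <- do.call(surface_model, as.list(stats::setNames(
    ref_coef, c("b0", "b1", "b11", "b2", "b22", "b12"))))
  for (seed in 1:5) {
    d <- sim_ccd(generate_ccd(c(4.2, 9.8), c(16, 50)), truth,
                 noise_sd = 0.9, seed = seed)
    m <- fit_quadratic(d)
    sp <- stationary_point(m)
    b <- m$coefficients
    gx <- b[["b1"]] + 2 * b[["b11"]] * sp$x_star + b[["b12"]] * sp$y_star
    gy <- b[["b2"]] + 2 * b[["b22"]] * sp$y_star + b[["b12"]] * sp$x_star
    expect_lt(sqrt(gx^2 + gy^2), 1e-8)
  }
})

test_that("full simulation round-trip reproduces the reference optimum", {
  truth <- lipj_surface_model()
  d <- sim_ccd(generate_ccd(c(4.2, 9.8), c(16, 50)), truth,
               noise_sd = 0.9, seed = 42)
  m <- fit_quadratic(d)
  an <- rsm_anova(m)
  expect_s3_class(an, "rsm_anova")
  sp <- stationary_point(m, x_range = c(4.2, 9.8), y_range = c(16, 50))
  expect_identical(sp$nature, "maximum")
  expect_equal(sp$x_star, 7.02, tolerance = 0.3)
  expect_equal(sp$y_star, 28.15, tolerance = 2)
})
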