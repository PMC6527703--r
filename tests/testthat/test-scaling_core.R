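test_that("correct_areas rescales by 4*pi/I_G and preserves g exactly", {
  p <- data.frame(partition = c("full", "half", "octant"),
                  A_t = c(15, 30, pi / 2),
                  A_e = c(5, 10, pi / 2),
                  T = c(2, 3, 1),
                  I_G = c(4 * pi, 2 * pi, pi / 2))
  out <- correct_areas(p)
  expect_equal(out$A_e_prime, c(5, 20, 4 * pi))
  expect_equal(out$A_t_prime, c(15, 60, 4 * pi))
  expect_equal(out$A_t_prime / out$A_e_prime, p$A_t / p$A_e)
  expect_equal(out$T, p$T)
  # displacement along the slope-1 contour: x' - x = y' - y = log10(4pi/I_G)
  expect_equal(out$x_prime - log10(p$A_e), log10(4 * pi / p$I_G))
  expect_equal(out$y_prime - log10(p$A_t * sqrt(p$T)),
               log10(4 * pi / p$I_G))

  bad <- p; bad$I_G[2] <- -0.1
  expect_error(correct_areas(bad), "non-positive integrated curvature")
})

test_that("offset K evaluates the fixed-slope-5/4 offset", {
  expect_equal(offset_k(1e4, 1e5, 1), 0)
  expect_equal(offset_k(1e4, 1e5, 100), 1)
  expect_equal(offset_k(1e4, 5e4, 4), 0)  # log10(1e5) - 5 = 0
  expect_error(offset_k(-1, 1, 1), "positive")
  # scaling Ae by f and At by f^(5/4) leaves K unchanged
  f <- 3.7
  expect_equal(offset_k(f * 1e4, f^1.25 * 1e5, 2.5),
               offset_k(1e4, 1e5, 2.5))
})

test_that("ols_slope matches hand-computed least squares", {
  f <- ols_slope(0:3, c(0, 1.25, 2.5, 3.75))
  expect_equal(f$slope, 1.25)
  expect_equal(f$intercept, 0)
  expect_equal(ols_slope(0:2, c(1, 1, 1))$slope, 0)
  expect_equal(ols_slope(0:3, c(0, 1, 0, 1))$slope, 0.2)
  expect_error(ols_slope(c(1, 1, 1), 1:3), "all x equal")
})

test_that("corrected slope recovers exact collinear slopes in closed form", {
  # collinear slope-a data: s22 = a^2 s11, s12 = a s11 -> alpha = a
  for (a in c(0.5, 1, 1.25, 2)) {
    s11 <- 2.3
    expect_equal(corrected_slope(s11, a^2 * s11, a * s11, 0), a,
                 tolerance = 1e-15)
  }
  expect_equal(corrected_slope(1, 1.5625, 1.25, 0), 1.25)
  expect_equal(corrected_slope(1, 1, 0.5, 0), 1)      # gamma = 0
  expect_equal(corrected_slope(1, 1, 0.5, 0.5), 1)    # gamma still 0
  expect_error(corrected_slope(1, 2, 0.25, 0.5), "degenerate covariance")
})

test_that("fit_hemisphere works on collinear, synthetic and 3-lobe data", {
  x <- c(4.0, 4.2, 4.35, 4.6)
  d <- data.frame(partition = c("frontal", "parietal", "temporal",
                                "occipital"),
                  x_prime = x, y_prime = 0.3 + 1.25 * x)
  expect_equal(fit_hemisphere(d, "ols")$alpha, 1.25)
  expect_equal(fit_hemisphere(d, "corrected")$alpha, 1.25)

  sim <- simulate_lobe_table(lobe_table_spec(n_subjects = 3, noise_sd_y = 0,
                                             seed = 42))
  cor <- correct_areas(sim$raw)
  for (key in unique(paste(cor$subject, cor$hemisphere))) {
    h <- cor[paste(cor$subject, cor$hemisphere) == key, ]
    expect_equal(fit_hemisphere(h)$alpha, 1.25, tolerance = 1e-12)
  }

  fit3 <- fit_hemisphere(d[1:3, ])
  expect_identical(fit3$n_partitions, 3L)
  expect_error(fit_hemisphere(d[1:2, ]), "occipital")  # names missing lobes
})

test_that("fit_group pools hemispheres with a 95% CI", {
  x <- c(4.0, 4.3, 4.5, 4.8)
  g <- fit_group(x, 1.25 * x - 0.6)
  expect_equal(g$alpha, 1.25)
  expect_equal(unname(diff(g$ci95)), 0, tolerance = 1e-9)
  expect_error(fit_group(c(4, 4.5), c(5, 5.6)), "3 hemispheres")

  # noisy synthetic cohort: generating exponent inside the CI
  sim <- simulate_lobe_table(lobe_table_spec(n_subjects = 100,
                                             noise_sd_y = 0.01, seed = 1))
  cor <- correct_areas(sim$raw)
  hemi <- do.call(rbind, lapply(split(cor,
                                      paste(cor$subject, cor$hemisphere)),
    function(h) data.frame(x = mean(h$x_prime), y = mean(h$y_prime))))
  gf <- fit_group(hemi$x, hemi$y)
  expect_gt(1.25, gf$ci95[1])
  expect_lt(1.25, gf$ci95[2])
})

test_that("validity filter excludes near-zero curvature partitions", {
  eps <- 0.01 * 4 * pi
  p <- data.frame(partition = c("a", "b", "c", "d"),
                  I_G = c(-0.1, 4 * pi, eps, eps * 1.01))
  flt <- validity_filter(p)
  expect_identical(flt$retained$partition, c("b", "d"))
  expect_identical(flt$excluded$partition, c("a", "c"))  # threshold strict
  expect_true(all(flt$excluded$reason == "near-zero curvature"))
})

test_that("implied fractal dimension is twice the exponent", {
  expect_equal(implied_fractal_dimension(1.25), 2.5)
  expect_equal(implied_fractal_dimension(1), 2)
  expect_equal(implied_fractal_dimension(1.5), 3)
  expect_error(implied_fractal_dimension(0), "positive")
})

test_that("raw partitions of a uniform cortex are collinear with slope 1", {
  # equal gyrification index and thickness across lobes: the only per-lobe
  # difference is the curvature fraction, which displaces raw points along
  # the slope-1 contour of constant g
  spec <- lobe_table_spec(n_subjects = 3, noise_sd_y = 0, T_sd = 0,
                          subject_sd_x = 0,
                          lobe_gi_multipliers = c(1, 1, 1, 1), seed = 5)
  sim <- simulate_lobe_table(spec)
  for (key in unique(paste(sim$raw$subject, sim$raw$hemisphere))) {
    d <- sim$raw[paste(sim$raw$subject, sim$raw$hemisphere) == key, ]
    f <- ols_slope(log10(d$A_e), log10(d$A_t * sqrt(d$T)))
    expect_equal(f$slope, 1, tolerance = 1e-9)
  }
})

test_that("sigma2_logIG estimator matches the sample variance of log10 I_G", {
  reps <- c(0.5, 0.52, 0.48, 0.51) * 4 * pi
  expect_equal(estimate_sigma2_logIG(reps), stats::var(log10(reps)))
  expect_error(estimate_sigma2_logIG(c(1, -1)), "positive")
})
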