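opt <- optical_config()

test_that("zero-lag limit returns the coherence factor", {
  d <- size_distribution(c(5, 50), c(0.3, 0.7))
  tr <- acf_forward(d, optical_config(beta = 0.85), c(1e-9, 1e-6, 1e-3))
  expect_equal(tr$g2m1[1], 0.85, tolerance = 1e-4)
})

test_that("decay rates match an independent Stokes-Einstein calculation", {
  # hand-computed: q = 4 pi n / lambda * sin(angle/2), D = kB T / (6 pi eta R)
  q <- 4 * pi * 1.33 / 633e-9 * sin(173 / 2 * pi / 180)
  D <- 1.380649e-23 * 298.15 / (6 * pi * 8.9e-4 * 15e-9)
  expect_equal(decay_rates(15, opt), D * q^2, tolerance = 1e-6)
  expect_equal(scattering_vector(opt), q, tolerance = 1e-9)
})

test_that("g1 is linear in the component weights", {
  lags <- 10^seq(-7, 0, length.out = 40)
  g_a <- acf_forward(size_distribution(15, 1), opt, lags)$g2m1
  g_b <- acf_forward(size_distribution(150, 1), opt, lags)$g2m1
  g_mix <- acf_forward(size_distribution(c(15, 150), c(0.5, 0.5)), opt, lags)$g2m1
  # with beta = 1, g2-1 = g1^2, so mix g1 is the average of component g1s
  expect_equal(sqrt(g_mix), (sqrt(g_a) + sqrt(g_b)) / 2, tolerance = 1e-10)
})

test_that("decay rates scale as 1/R and as q squared", {
  expect_equal(decay_rates(30, opt), decay_rates(15, opt) / 2, tolerance = 1e-12)
  opt90 <- optical_config(angle_deg = 90)
  ratio <- sin(173 / 2 * pi / 180)^2 / sin(45 * pi / 180)^2
  expect_equal(decay_rates(15, opt) / decay_rates(15, opt90), ratio,
               tolerance = 1e-12)
})

test_that("a noiseless monodisperse trace inverts to the right bin", {
  lags <- 10^seq(-7, 0, length.out = 60)
  tr <- acf_forward(size_distribution(15, 1), opt, lags)
  inv <- invert_acf(tr, opt)
  peak <- inv$radius_nm[which.max(inv$weight)]
  grid_step <- inv$radius_nm[2] / inv$radius_nm[1]
  expect_lt(abs(log(peak / 15)), 1.01 * log(grid_step))
  expect_true(all(inv$weight >= 0))
  expect_equal(sum(inv$weight), 1)
})

test_that("a noiseless bimodal trace recovers both modes within one bin", {
  lags <- 10^seq(-7, 0, length.out = 80)
  tr <- acf_forward(size_distribution(c(15, 150), c(0.5, 0.5)), opt, lags)
  inv <- invert_acf(tr, opt)
  w <- inv$weight
  peaks <- aggrekin:::local_maxima(w)
  peaks <- peaks[w[peaks] >= 0.05 * max(w)]  # ignore numerical specks
  expect_equal(length(peaks), 2L)
  grid_step <- inv$radius_nm[2] / inv$radius_nm[1]
  expect_lt(abs(log(inv$radius_nm[peaks[1]] / 15)), 1.01 * log(grid_step))
  expect_lt(abs(log(inv$radius_nm[peaks[2]] / 150)), 1.01 * log(grid_step))
})

test_that("an exactly representable decay fits to machine residuals", {
  lags <- 10^seq(-7, 0, length.out = 60)
  grid <- aggrekin:::default_radius_grid()
  tr <- acf_forward(size_distribution(grid[30], 1), opt, lags)
  inv <- invert_acf(tr, opt, grid = grid, reg_lambda = 1e-12)
  expect_lt(attr(inv, "residual_norm"), 1e-6)
})

test_that("the smoothness penalty is monotone in the regularization weight", {
  lags <- 10^seq(-7, 0, length.out = 60)
  tr <- acf_forward(size_distribution(c(15, 150), c(0.5, 0.5)), opt, lags)
  grid <- aggrekin:::default_radius_grid(40)
  L <- aggrekin:::second_difference_operator(40)
  pen <- vapply(10^seq(-6, 1, length.out = 8), function(lam) {
    w <- invert_acf(tr, opt, grid = grid, reg_lambda = lam)$weight
    sqrt(sum((L %*% w)^2))
  }, numeric(1))
  expect_true(all(diff(pen) <= 1e-10))
})

test_that("an all-zero trace is flagged empty", {
  tr <- data.frame(lag_s = 10^seq(-7, 0, length.out = 40), g2m1 = 0)
  inv <- invert_acf(tr, opt)
  expect_true(attr(inv, "empty"))
})

test_that("the coherence factor is estimated from the smallest lags", {
  lags <- 10^seq(-8, 0, length.out = 60)
  tr <- acf_forward(size_distribution(15, 1), optical_config(beta = 0.7), lags)
  inv <- invert_acf(tr, optical_config(beta = NA))
  expect_equal(attr(inv, "beta"), 0.7, tolerance = 0.02)
})

test_that("lag-grid preconditions are enforced", {
  expect_error(invert_acf(data.frame(lag_s = 1:10, g2m1 = 0.5), opt), "lags")
  expect_error(
    invert_acf(data.frame(lag_s = seq(1, 2, length.out = 40), g2m1 = 0.5), opt),
    "decades")
})

test_that("a distribution series tracks the monomer-to-aggregate shift", {
  spec <- generator_spec(seed = 8, dls_snr = 1000,
                         design = list(control = kin_params(
                           kn_dmu0 = 12.3e-5, k2_dmu0 = 0.14,
                           r2 = 15, r1 = 150)))
  sr <- generate_dls_series(spec)
  ts <- track_distribution_series(sr$traces, optical_config())
  expect_length(ts$distributions, 6L)
  expect_equal(nrow(ts$modes), 6L)
  # monomer-dominated at t = 0, aggregate-dominated at late times
  expect_lt(ts$modes$mode_radius_nm[1], 6)
  expect_gt(ts$modes$mode_radius_nm[6], 50)
  # determinism: identical traces give identical distributions
  ts2 <- track_distribution_series(sr$traces, optical_config())
  expect_identical(ts$modes, ts2$modes)
  expect_error(track_distribution_series(sr$traces[1], optical_config()),
               ">= 2")
})
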