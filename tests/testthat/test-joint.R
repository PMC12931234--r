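test_that("noiseless data return the generating parameters", {
  p <- table1_params(1)  # wild-type control: kn, k2 > 0, kplus = 0
  ds <- generate_joint_dataset(p, noise_sigma = 0, dls_snr = 1e9, seed = 1)
  fit <- fit_joint(ds$data, seed = 1)
  k <- coef(fit)
  expect_lt(abs(k["kn_dmu0"] - p$kn_dmu0) / p$kn_dmu0, 0.01)
  expect_lt(abs(k["k2_dmu0"] - p$k2_dmu0) / p$k2_dmu0, 0.01)
  expect_identical(unname(k["kplus_dmu0"]), 0)  # bound hit reported as 0
  expect_true(fit$convergence$converged)
})

test_that("the fit is invariant to the fluorescence scale by construction", {
  p <- table1_params(1)
  ds <- generate_joint_dataset(p, noise_sigma = 0.02, seed = 9)
  f1 <- fit_joint(ds$data, seed = 2)
  scaled <- ds$data
  scaled$tht$fluorescence <- 12 * scaled$tht$fluorescence - 700
  f2 <- fit_joint(scaled, seed = 2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("flat datasets raise the non-identifiability flag", {
  set.seed(1)
  t <- seq(0, 30, 0.5)
  tht <- data.frame(well_id = "w1", time_h = t,
                    fluorescence = 100 + rnorm(length(t), 0, 2))
  dls <- data.frame(time_h = 0, monomer = 1, small = 0, large = 0)
  ds <- joint_dataset(tht, dls)
  expect_warning(fit <- fit_joint(ds, seed = 1), "non-identifiable")
  expect_true(fit$non_identifiable)
})

test_that("regime classification follows the dominance ordering", {
  lab <- function(kn, kp, k2)
    classify_regime(kin_params(kn_dmu0 = kn, kplus_dmu0 = kp, k2_dmu0 = k2))$label
  expect_equal(lab(12.3e-5, 0, 0.14), "secondary-nucleation-dominated")
  expect_equal(lab(0.25e-5, 8.7e-2, 3.0e-6), "elongation-dominated")
  expect_equal(lab(0.1, 0, 6.1e-4), "primary-only")
  expect_equal(lab(0.01, 0.01, 0.01), "mixed")
})

test_that("half-time consistency holds on self-consistent synthetic data", {
  p <- table1_params(1)
  ds <- generate_joint_dataset(p, noise_sigma = 0, dls_snr = 1e9, seed = 3)
  fit <- fit_joint(ds$data, seed = 3)
  curves <- split(ds$data$tht, ds$data$tht$well_id)
  tht_fits <- lapply(curves, function(cv)
    fit_progress_curve(cv[, c("time_h", "fluorescence")]))
  rep <- check_halftime_consistency(fit, tht_fits)
  expect_lte(rep$max_rel_dev, 0.02)

  # a model with doubled secondary nucleation misses the half-times
  wrong <- fit
  wrong$params$k2_dmu0 <- 2 * wrong$params$k2_dmu0
  rep2 <- check_halftime_consistency(wrong, tht_fits)
  expect_gt(rep2$max_rel_dev, 0.10)

  # all-zero rates never reach the half-time: refused
  none <- fit
  none$params$kn_dmu0 <- 0; none$params$k2_dmu0 <- 0; none$params$kplus_dmu0 <- 0
  expect_error(check_halftime_consistency(none, tht_fits), "transition|0.5")
})

test_that("standard errors are approximately calibrated for k2", {
  p <- table1_params(1)
  hits <- 0L; n_ok <- 0L
  for (s in 1:10) {
    ds <- generate_joint_dataset(p, noise_sigma = 0.02, dls_snr = 100,
                                 dls_times = c(0, 16, 24, 48, 72), seed = 100 + s)
    fit <- fit_joint(ds$data, seed = s)
    k2 <- coef(fit)["k2_dmu0"]; se <- fit$se["k2_dmu0"]
    if (!is.finite(se) || k2 == 0 || se / k2 > 0.5) next  # ill-conditioned
    n_ok <- n_ok + 1L
    if (abs(k2 - p$k2_dmu0) <= 2 * se) hits <- hits + 1L
  }
  expect_gte(n_ok, 3L)
  expect_gte(hits / n_ok, 0.7)
})

test_that("joint model methods expose the usual interface", {
  p <- table1_params(1)
  ds <- generate_joint_dataset(p, noise_sigma = 0.02, seed = 4)
  fit <- fit_joint(ds$data, seed = 4)
  expect_s3_class(fit, "joint_fit")
  expect_named(coef(fit), c("kn_dmu0", "kplus_dmu0", "k2_dmu0"))
  s <- summary(fit)
  expect_s3_class(s, "summary.joint_fit")
  tr <- predict(fit, times = seq(0, 60, 1))
  expect_s3_class(tr, "kin_trajectory")
  shares <- predict(fit, times = c(0, 30, 60), type = "intensity")
  expect_equal(rowSums(shares[, c("monomer", "small", "large")]), rep(1, 3))
  r <- residuals(fit, type = "tht")
  expect_length(r, nrow(ds$data$tht))
  sim <- simulate(fit, nsim = 1, seed = 5)
  expect_s3_class(sim[[1]]$data, "joint_dataset")
  pf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(pf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(pf))
})
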