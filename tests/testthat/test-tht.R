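test_that("normalization maps baseline and plateau to 0 and 1", {
  expect_equal(as.numeric(normalize_curve(100, f0 = 100, df = 400)), 0)
  expect_equal(as.numeric(normalize_curve(500, f0 = 100, df = 400)), 1)
  expect_equal(as.numeric(normalize_curve(300, f0 = 100, df = 400)), 0.5)
  expect_error(normalize_curve(1, f0 = 0, df = 0), "df")
})

test_that("normalization clamps excursions and reports them", {
  expect_message(out <- normalize_curve(c(100, 700), f0 = 100, df = 400),
                 "clamped")
  expect_equal(attr(out, "n_clamped"), 1L)
  expect_equal(as.numeric(out), c(0, 1))
})

test_that("the exponential limit yields the analytic t50 and v50", {
  t <- seq(0, 10, 0.1)
  curve <- data.frame(time_h = t,
                      fluorescence = 100 + 400 * (1 - exp(-log(2) * t)))
  fit <- fit_progress_curve(curve)
  expect_equal(fit$flag, "ok")
  expect_equal(fit$t50, 1.0, tolerance = 1e-3)
  expect_equal(fit$v50, log(2) / 2, tolerance = 1e-3)
  expect_equal(fit$f0, 100, tolerance = 1e-2)
  expect_equal(fit$df, 400, tolerance = 1e-2)
})

test_that("fitted t50 matches a bisection root of the forward model", {
  ka <- 0.01; kb <- 0.5
  t <- seq(0, 40, 0.2)
  curve <- data.frame(
    time_h = t,
    fluorescence = 50 + 300 * aggrekin:::alpha_autocatalytic(t, ka, kb))
  fit <- fit_progress_curve(curve)
  # independent bisection on the forward closed form
  f <- function(x) aggrekin:::alpha_autocatalytic(x, ka, kb) - 0.5
  lo <- 0; hi <- 40
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  expect_equal(fit$t50, (lo + hi) / 2, tolerance = 1e-3)
  expect_equal(fit$v50, (ka + kb / 2) / 2, tolerance = 1e-4)
})

test_that("v50 recovery is unbiased under 2% amplitude noise", {
  ka <- 0.01; kb <- 0.5
  t <- seq(0, 40, 0.2)
  a <- aggrekin:::alpha_autocatalytic(t, ka, kb)
  v_true <- (ka + kb / 2) / 2
  set.seed(7)
  v50s <- replicate(50, {
    y <- 50 + 300 * a + rnorm(length(t), 0, 0.02 * 300)
    fit_progress_curve(data.frame(time_h = t, fluorescence = y))$v50
  })
  expect_lt(abs(median(v50s) - v_true) / v_true, 0.05)
})

test_that("descriptors are invariant to affine rescaling of fluorescence", {
  t <- seq(0, 40, 0.25)
  a <- aggrekin:::alpha_autocatalytic(t, 0.02, 0.3)
  set.seed(11)
  noise <- rnorm(length(t))
  f1 <- fit_progress_curve(data.frame(time_h = t,
                                      fluorescence = 100 + 400 * a + 4 * noise))
  f2 <- fit_progress_curve(data.frame(time_h = t,
                                      fluorescence = -50 + 2000 * a + 20 * noise))
  expect_equal(f1$t50, f2$t50, tolerance = 1e-6)
  expect_equal(f1$v50, f2$v50, tolerance = 1e-6)
})

test_that("t50 is recovered within 10% across its physiological range", {
  set.seed(3)
  n <- 100
  t50s <- 10^runif(n, 1, 2)  # 10-100 h
  ok <- logical(n)
  for (i in seq_len(n)) {
    kb <- 10^runif(1, -1.3, -0.4)
    # choose ka so the autocatalytic half-time hits the target
    la <- uniroot(function(la)
      aggrekin:::t50_autocatalytic(10^la, kb) - t50s[i], c(-40, 0))$root
    ka <- 10^la
    t <- seq(0, 2.2 * t50s[i], length.out = 250)
    y <- 100 + 400 * aggrekin:::alpha_autocatalytic(t, ka, kb) +
      rnorm(length(t), 0, 0.02 * 400)
    fit <- fit_progress_curve(data.frame(time_h = t, fluorescence = y))
    ok[i] <- is.finite(fit$t50) && abs(fit$t50 - t50s[i]) / t50s[i] <= 0.10
  }
  expect_gte(mean(ok), 0.95)
})

test_that("flat curves are flagged instead of fitted", {
  t <- seq(0, 30, 0.5)
  set.seed(5)
  flat <- data.frame(time_h = t, fluorescence = 100 + rnorm(length(t), 0, 3))
  fit <- fit_progress_curve(flat)
  expect_equal(fit$flag, "no-transition")
  expect_true(is.na(fit$t50))
})

test_that("progress-curve preconditions are enforced", {
  expect_error(fit_progress_curve(
    data.frame(time_h = c(0, 1), fluorescence = c(1, 2))), ">= 20")
  expect_error(fit_progress_curve(
    data.frame(time_h = c(seq(0, 8, 0.5), 8), fluorescence = rnorm(18))),
    "increasing")
})

test_that("condition summaries average technical replicates first", {
  fits <- data.frame(
    condition = rep(c("control", "treated"), each = 6),
    bio_rep = rep(rep(1:2, each = 3), 2),
    t50 = c(1, 1, 1, 3, 3, 3, 2, 2, 2, 4, 4, 4),
    v50 = rep(0.5, 12))
  s <- summarize_conditions(fits)
  ctl <- s[s$condition == "control", ]
  expect_equal(ctl$t50_mean, 2)
  expect_equal(ctl$t50_sem, 1)
  expect_equal(ctl$n, 2)
  # identical v50 in both groups: fold change 1
  expect_equal(s$v50_fold_reduction, c(1, 1))
  expect_error(summarize_conditions(fits, control = "absent"), "control")
})

test_that("a threefold v50 reduction is recovered from a synthetic plate", {
  ctl <- kin_params(kn_dmu0 = 12.3e-5, k2_dmu0 = 0.14)
  trt <- kin_params(kn_dmu0 = 12.3e-5 / 3, k2_dmu0 = 0.14 / 3)
  spec <- generator_spec(seed = 21,
                         design = list(control = ctl, treated = trt),
                         n_bio_reps = 4, n_tech_reps = 3,
                         duration = NA)  # run each condition to alpha = 0.9
  plate <- generate_tht_plate(spec)$plate
  fits <- do.call(rbind, lapply(split(plate, plate$well_id), function(cv) {
    f <- fit_progress_curve(cv[, c("time_h", "fluorescence")])
    data.frame(condition = cv$condition[1], bio_rep = cv$bio_rep[1],
               t50 = f$t50, v50 = f$v50)
  }))
  s <- summarize_conditions(fits)
  fold <- s$v50_fold_reduction[s$condition == "treated"]
  expect_gte(fold, 2.5)
  expect_lte(fold, 3.5)
})
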