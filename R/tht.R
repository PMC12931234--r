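#' Normalize a ThT progress curve to a fractional signal
#'
#' Converts raw fluorescence to the fractional aggregation signal
#' `theta = (F - f0) / df`. Values are clipped to `[-0.05, 1.05]` before a
#' final clamp to `[0, 1]`; the number of clamped points is attached as
#' attribute `n_clamped` (and reported via a message when non-zero) so that
#' pathological baselines are visible rather than silently absorbed.
#'
#' @param fluorescence Raw fluorescence values, arbitrary units.
#' @param f0 Baseline fluorescence, a.u.
#' @param df Amplitude, a.u.; must be > 0.
#' @return Numeric vector of normalized signal in `[0, 1]`.
#' @examples
#' normalize_curve(c(100, 300, 500), f0 = 100, df = 400)
#' @export
normalize_curve <- function(fluorescence, f0, df) {
  if (!is.finite(df) || df <= 0) stop("df must be > 0", call. = FALSE)
  theta <- (fluorescence - f0) / df
  clipped <- pmin(pmax(theta, -0.05), 1.05)
  out <- pmin(pmax(clipped, 0), 1)
  n_clamped <- sum(out != theta)
  if (n_clamped > 0)
    message(sprintf("normalize_curve: clamped %d point(s) outside [0, 1]", n_clamped))
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Fit a ThT progress curve with the autocatalytic sigmoid
#'
#' Fits `F(t) = f0 + df * alpha(t; k_a, k_b)` where `alpha` solves the
#' autocatalytic rate law `dalpha/dt = (k_a + k_b * alpha) (1 - alpha)`
#' (primary nucleation `k_a` plus aggregate-catalysed growth `k_b`; the
#' closed-form Finke-Watzky-type sigmoid). Baseline `f0` and amplitude `df`
#' are fitted jointly with the kinetic parameters, so the extracted
#' descriptors are invariant to the arbitrary fluorescence scale. The
#' descriptors are
#' \deqn{t_{50} = \log((k_b + 2 k_a)/k_a) / (k_a + k_b), \qquad
#'       v_{50} = (k_a + k_b/2)/2,}
#' the half-time of the growth phase and the normalized assembly rate at
#' the half-time.
#'
#' Levenberg-Marquardt refinement is run from a log-spaced multistart grid
#' on `(k_a, k_b)`; the lowest residual sum of squares wins. Curves that
#' never leave the lag phase (maximum normalized signal < 0.3) are flagged
#' `"no-transition"` instead of fitted; fits that fail from every start are
#' flagged `"fit-failure"`. Neither flag raises an error.
#'
#' @param curve Data frame with columns `time_h` (strictly increasing,
#'   at least 20 points) and `fluorescence`.
#' @param starts Number of multistart grid points per parameter (default 6).
#' @return Object of class `tht_fit`: list with `f0`, `df`, `ka`, `kb`,
#'   `t50`, `v50`, `se_t50`, `se_v50`, `rss`, `flag` (`"ok"`,
#'   `"no-transition"` or `"fit-failure"`) and the data.
#' @examples
#' t <- seq(0, 10, 0.1)
#' curve <- data.frame(time_h = t,
#'                     fluorescence = 100 + 400 * (1 - exp(-log(2) * t)))
#' fit <- fit_progress_curve(curve)
#' c(fit$t50, fit$v50)  # 1.0 h, log(2)/2 per h
#' @export
fit_progress_curve <- function(curve, starts = 6L) {
  stopifnot(is.data.frame(curve), all(c("time_h", "fluorescence") %in% names(curve)))
  t <- as.numeric(curve$time_h); y <- as.numeric(curve$fluorescence)
  if (any(diff(t) <= 0)) stop("time_h must be strictly increasing", call. = FALSE)
  if (length(t) < 20L) stop("need >= 20 time points for fitting", call. = FALSE)
  if (any(!is.finite(y))) stop("fluorescence must be finite", call. = FALSE)

  res <- list(f0 = NA_real_, df = NA_real_, ka = NA_real_, kb = NA_real_,
              t50 = NA_real_, v50 = NA_real_, se_t50 = NA_real_,
              se_v50 = NA_real_, rss = NA_real_, flag = "ok",
              data = data.frame(time_h = t, fluorescence = y))
  class(res) <- "tht_fit"

  rng <- diff(range(y))
  if (rng == 0) { res$flag <- "no-transition"; return(res) }

  t_scale <- max(t)
  k_grid <- exp(seq(log(0.05 / t_scale), log(50 / t_scale), length.out = starts))
  model_y <- function(ka, kb) alpha_autocatalytic(t, ka, kb)

  best <- NULL
  for (ka0 in k_grid) for (kb0 in c(0, k_grid)) {
    fit <- tryCatch({
      a0 <- model_y(ka0, kb0)
      lf <- lm(y ~ a0)
      start <- list(f0 = coef(lf)[[1L]], df = max(coef(lf)[[2L]], rng * 0.1),
                    lka = log(ka0), lkb = log(max(kb0, 1e-8 / t_scale)))
      minpack.lm::nlsLM(
        y ~ f0 + df * alpha_autocatalytic(t, exp(lka), exp(lkb)),
        start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12 * rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) { res$flag <- "fit-failure"; return(res) }

  cf <- coef(best$fit)
  ka <- exp(cf[["lka"]]); kb <- exp(cf[["lkb"]])
  f0 <- cf[["f0"]]; df <- cf[["df"]]
  # lag-phase check: the fitted transition must clear the lag threshold
  # and the amplitude must stand clear of the residual noise
  resid_sd <- sqrt(best$rss / max(length(y) - 4L, 1L))
  if (df <= 0 || df < 5 * resid_sd ||
      max(alpha_autocatalytic(t, ka, kb)) < 0.3) {
    res$flag <- "no-transition"
    res$f0 <- f0; res$df <- df; res$rss <- best$rss
    return(res)
  }
  t50 <- t50_autocatalytic(ka, kb)
  v50 <- (ka + kb / 2) / 2

  # delta-method standard errors from the (lka, lkb) covariance
  se_t50 <- se_v50 <- NA_real_
  vc <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  if (!is.null(vc)) {
    g_t50 <- numeric(2L); g_v50 <- numeric(2L)
    h <- 1e-5
    for (i in 1:2) {
      d <- c(0, 0); d[i] <- h
      up <- c(log(ka), log(kb)) + d; dn <- c(log(ka), log(kb)) - d
      g_t50[i] <- (t50_autocatalytic(exp(up[1L]), exp(up[2L])) -
                   t50_autocatalytic(exp(dn[1L]), exp(dn[2L]))) / (2 * h)
      g_v50[i] <- ((exp(up[1L]) + exp(up[2L]) / 2) / 2 -
                   (exp(dn[1L]) + exp(dn[2L]) / 2) / 2) / (2 * h)
    }
    vk <- vc[c("lka", "lkb"), c("lka", "lkb")]
    se_t50 <- sqrt(max(drop(t(g_t50) %*% vk %*% g_t50), 0))
    se_v50 <- sqrt(max(drop(t(g_v50) %*% vk %*% g_v50), 0))
  }

  res$f0 <- f0; res$df <- df; res$ka <- ka; res$kb <- kb
  res$t50 <- t50; res$v50 <- v50
  res$se_t50 <- se_t50; res$se_v50 <- se_v50; res$rss <- best$rss
  res
}

#' @export
print.tht_fit <- function(x, ...) {
  cat("ThT progress-curve fit (autocatalytic sigmoid)\n")
  if (x$flag != "ok") {
    cat("  flag:", x$flag, "\n")
  } else {
    cat(sprintf("  t50 = %.3f h (se %.3g)   v50 = %.4f h^-1 (se %.3g)\n",
                x$t50, x$se_t50, x$v50, x$se_v50))
    cat(sprintf("  f0 = %.3g a.u.  df = %.3g a.u.  rss = %.4g\n", x$f0, x$df, x$rss))
  }
  invisible(x)
}

#' @export
coef.tht_fit <- function(object, ...) {
  c(f0 = object$f0, df = object$df, ka = object$ka, kb = object$kb,
    t50 = object$t50, v50 = object$v50)
}

#' Aggregate per-curve fits into condition-level kinetics
#'
#' Averages technical replicates within each biological replicate first
#' (technical wells are not independent), then reports per-condition mean,
#' SEM and n over biological replicates for `t50` and `v50`, together with
#' the fold change `v50(control) / v50(condition)` and its uncertainty
#' propagated from the two SEMs.
#'
#' @param fits Data frame with columns `condition`, `bio_rep`, `t50`,
#'   `v50` (one row per fitted curve, e.g. assembled from
#'   [fit_progress_curve()] results). Rows with missing `t50` are dropped.
#' @param control Label of the control condition (default `"control"`).
#' @return Data frame with one row per condition: `condition`, `n`,
#'   `t50_mean`, `t50_sem`, `v50_mean`, `v50_sem`, `v50_fold_reduction`,
#'   `v50_fold_se`.
#' @export
summarize_conditions <- function(fits, control = "control") {
  stopifnot(all(c("condition", "bio_rep", "t50", "v50") %in% names(fits)))
  fits <- fits[is.finite(fits$t50) & is.finite(fits$v50), , drop = FALSE]
  if (!control %in% fits$condition)
    stop("missing control group '", control, "'", call. = FALSE)
  # technical -> biological means
  key <- interaction(fits$condition, fits$bio_rep, drop = TRUE)
  bio <- data.frame(condition = tapply(as.character(fits$condition), key, `[`, 1L),
                    t50 = as.numeric(tapply(fits$t50, key, mean)),
                    v50 = as.numeric(tapply(fits$v50, key, mean)))
  sem <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  agg <- do.call(rbind, lapply(split(bio, bio$condition), function(d) {
    data.frame(condition = d$condition[1L], n = nrow(d),
               t50_mean = mean(d$t50), t50_sem = sem(d$t50),
               v50_mean = mean(d$v50), v50_sem = sem(d$v50))
  }))
  rownames(agg) <- NULL
  ctl <- agg[agg$condition == control, ]
  agg$v50_fold_reduction <- ctl$v50_mean / agg$v50_mean
  # first-order error propagation for a ratio of independent means
  rel <- function(s, m) ifelse(is.na(s), 0, (s / m)^2)
  agg$v50_fold_se <- agg$v50_fold_reduction *
    sqrt(rel(ctl$v50_sem, ctl$v50_mean) + rel(agg$v50_sem, agg$v50_mean))
  agg
}
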