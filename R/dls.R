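#' Optical configuration of a DLS measurement
#'
#' Instrument and solvent parameters needed to map hydrodynamic radii to
#' autocorrelation decay rates. Defaults correspond to a backscattering
#' instrument (633 nm laser, 173 degrees) measuring aqueous samples at
#' 25 degrees C.
#'
#' @param wavelength_nm Laser vacuum wavelength, nm.
#' @param angle_deg Scattering angle, degrees in (0, 180).
#' @param refractive_index Solvent refractive index.
#' @param temperature_k Temperature, K.
#' @param viscosity_pa_s Solvent viscosity, Pa s.
#' @param beta Siegert coherence factor in (0, 1]; `NA` to estimate it
#'   from the smallest lags when inverting measured data.
#' @return Object of class `optical_config`.
#' @examples
#' optical_config()
#' @export
optical_config <- function(wavelength_nm = 633, angle_deg = 173,
                           refractive_index = 1.33, temperature_k = 298.15,
                           viscosity_pa_s = 8.9e-4, beta = 1) {
  if (angle_deg <= 0 || angle_deg >= 180) stop("angle must be in (0, 180)", call. = FALSE)
  vals <- c(wavelength_nm, refractive_index, temperature_k, viscosity_pa_s)
  if (any(vals <= 0)) stop("optical parameters must be positive", call. = FALSE)
  if (!is.na(beta) && (beta <= 0 || beta > 1)) stop("beta must be in (0, 1]", call. = FALSE)
  structure(list(wavelength_nm = wavelength_nm, angle_deg = angle_deg,
                 refractive_index = refractive_index, temperature_k = temperature_k,
                 viscosity_pa_s = viscosity_pa_s, beta = beta),
            class = "optical_config")
}

kB <- 1.380649e-23  # Boltzmann constant, J/K

#' Scattering vector magnitude
#'
#' `q = (4 pi n / lambda) sin(theta / 2)` in inverse metres.
#'
#' @param optics An [optical_config()].
#' @return q in m^-1.
#' @export
scattering_vector <- function(optics) {
  4 * pi * optics$refractive_index / (optics$wavelength_nm * 1e-9) *
    sin(optics$angle_deg * pi / 360)
}

#' Autocorrelation decay rates for a set of radii
#'
#' Stokes-Einstein diffusion `D = kB T / (6 pi eta R)` and decay rate
#' `Gamma = D q^2` for each hydrodynamic radius.
#'
#' @param radii_nm Hydrodynamic radii, nm.
#' @param optics An [optical_config()].
#' @return Decay rates in s^-1.
#' @export
decay_rates <- function(radii_nm, optics) {
  if (any(radii_nm <= 0)) stop("radii must be positive", call. = FALSE)
  d <- kB * optics$temperature_k /
    (6 * pi * optics$viscosity_pa_s * radii_nm * 1e-9)
  d * scattering_vector(optics)^2
}

#' Intensity-weighted size distribution
#'
#' @param radii_nm Strictly increasing radius grid, nm.
#' @param weights Non-negative intensity weights; normalized to sum to 1.
#' @return Object of class `size_distribution` (data frame `radius_nm`,
#'   `weight`).
#' @export
size_distribution <- function(radii_nm, weights) {
  if (any(diff(radii_nm) <= 0)) stop("radii must be strictly increasing", call. = FALSE)
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  s <- sum(weights)
  if (s <= 0) stop("weights must not be all zero", call. = FALSE)
  structure(data.frame(radius_nm = radii_nm, weight = weights / s),
            class = c("size_distribution", "data.frame"))
}

## Default log-spaced inversion grid: monomers through large clusters.
default_radius_grid <- function(n = 60L, r_min = 0.5, r_max = 1000) {
  exp(seq(log(r_min), log(r_max), length.out = n))
}

#' Forward-model a DLS autocorrelation function
#'
#' Computes `g1(tau) = sum_i w_i exp(-Gamma_i tau)` from an
#' intensity-weighted size distribution via Stokes-Einstein decay rates,
#' then the measurable `g2(tau) - 1 = beta g1(tau)^2` (Siegert relation).
#'
#' @param dist A [size_distribution()].
#' @param optics An [optical_config()]; `beta` must be set.
#' @param lags Lag times, s, strictly increasing.
#' @return Data frame of class `acf_trace`: `lag_s`, `g2m1`.
#' @examples
#' d <- size_distribution(15, 1)
#' acf_forward(d, optical_config(), 10^seq(-7, 0, length.out = 50))
#' @export
acf_forward <- function(dist, optics, lags) {
  stopifnot(inherits(dist, "size_distribution"))
  if (is.na(optics$beta)) stop("optics$beta must be set for the forward model", call. = FALSE)
  g <- decay_rates(dist$radius_nm, optics)
  g1 <- as.vector(exp(-outer(lags, g)) %*% dist$weight)
  structure(data.frame(lag_s = lags, g2m1 = optics$beta * g1^2),
            class = c("acf_trace", "data.frame"))
}

## Second-difference (curvature) penalty operator on an n-point grid.
second_difference_operator <- function(n) {
  if (n < 3L) return(matrix(0, 0, n))
  L <- matrix(0, n - 2L, n)
  for (i in seq_len(n - 2L)) L[i, i:(i + 2L)] <- c(1, -2, 1)
  L
}

## Non-negative Tikhonov solve: min ||A w - g||^2 + lambda ||L w||^2, w >= 0.
nn_tikhonov <- function(A, g, L, lambda) {
  Aa <- rbind(A, sqrt(lambda) * L)
  ga <- c(g, rep(0, nrow(L)))
  pracma::lsqnonneg(Aa, ga)$x
}

#' Invert a DLS autocorrelation function into a size distribution
#'
#' CONTIN-style regularized inverse Laplace transform: recovers
#' non-negative intensity weights `w` on a log-spaced radius grid by
#' solving
#' \deqn{\min_w \|A w - g_1\|^2 + \lambda \|L w\|^2, \quad w \ge 0,}
#' with `A_ij = exp(-Gamma_j tau_i)` and `L` the second-difference
#' (curvature) operator. The solution is initialized from the signed
#' square root of `g2m1 / beta` and refined by Gauss-Newton iterations
#' that fit the measured `g2 - 1` directly through the Siegert relation,
#' which removes the downward bias the square-root transform puts on
#' weakly decayed lags. When `reg_lambda` is not supplied it is chosen by
#' a residual-plateau rule: the largest lambda whose g2-space residual
#' norm stays within 1% of the unregularized plateau (the flat arm of the
#' L-curve). When `optics$beta` is `NA` it is estimated as the mean
#' `g2m1` over the smallest lags.
#'
#' @param trace Data frame with `lag_s` (>= 30 lags spanning >= 3 decades)
#'   and `g2m1`.
#' @param optics An [optical_config()].
#' @param grid Radius grid, nm (default 60 log-spaced points, 0.5-1000 nm).
#' @param reg_lambda Regularization weight; `NULL` for automatic selection.
#' @return A [size_distribution()] with attributes `reg_lambda`, `beta`,
#'   `residual_norm`, `empty` (TRUE when the trace carries no signal).
#' @examples
#' opt <- optical_config()
#' tr <- acf_forward(size_distribution(15, 1), opt, 10^seq(-7, 0, len = 60))
#' inv <- invert_acf(tr, opt)
#' inv$radius_nm[which.max(inv$weight)]  # ~15 nm
#' @export
invert_acf <- function(trace, optics, grid = default_radius_grid(),
                       reg_lambda = NULL) {
  lags <- trace$lag_s; g2m1 <- trace$g2m1
  if (length(lags) < 30L) stop("need >= 30 lags", call. = FALSE)
  if (log10(max(lags) / min(lags)) < 3) stop("lags must span >= 3 decades", call. = FALSE)

  beta <- optics$beta
  if (is.na(beta)) beta <- max(mean(head(g2m1[order(lags)], 5L)), 1e-6)

  # noise floor from the long-lag tail, where g1 has fully decayed
  tail_idx <- order(lags, decreasing = TRUE)[seq_len(max(5L, length(lags) %/% 10L))]
  noise_floor <- 5 * max(sd(g2m1[tail_idx]), 0.005 * max(abs(g2m1), 1e-12))
  if (any(g2m1 < -noise_floor))
    warning("negative g2-1 values beyond the noise floor; clipped")
  if (all(abs(g2m1) < 1e-12)) {
    out <- size_distribution(grid, rep(1 / length(grid), length(grid)))
    attr(out, "empty") <- TRUE
    attr(out, "reg_lambda") <- NA_real_; attr(out, "beta") <- beta
    attr(out, "residual_norm") <- 0
    return(out)
  }

  # initialization: signed square root keeps the fully-decayed tail
  # zero-mean instead of rectifying its noise into a spurious slow decay
  g1 <- sign(g2m1) * sqrt(abs(g2m1) / beta)
  A <- exp(-outer(lags, decay_rates(grid, optics)))
  L <- second_difference_operator(length(grid))

  # Gauss-Newton refinement fits the measured g2-1 directly (model
  # beta (A w)^2), avoiding the downward bias the square-root transform
  # puts on weakly decayed lags; each linearized subproblem is a
  # non-negative Tikhonov solve with weights 2 beta g1_model
  gn_fit <- function(lam, w0) {
    w <- w0
    for (it in 1:8) {
      g1m <- pmax(as.vector(A %*% w), 1e-3)
      z <- g1m + (g2m1 / beta - g1m^2) / (2 * g1m)
      u <- 2 * beta * g1m
      u <- u / max(u)
      w <- nn_tikhonov(A * u, z * u, L, lam)
    }
    w
  }
  g2_rho <- function(w) sqrt(sum((g2m1 - beta * as.vector(A %*% w)^2)^2))

  if (is.null(reg_lambda)) {
    # residual-plateau rule: the largest lambda whose g2-space residual
    # stays within 1% of the unregularized plateau
    lambdas <- 10^seq(2, -8, by = -1)
    sols <- vector("list", length(lambdas))
    rhos <- numeric(length(lambdas))
    w_prev <- nn_tikhonov(A, g1, L, lambdas[1L])
    for (i in seq_along(lambdas)) {
      sols[[i]] <- gn_fit(lambdas[i], w_prev)
      w_prev <- sols[[i]]
      rhos[i] <- g2_rho(sols[[i]])
    }
    pick <- which(rhos <= 1.01 * min(rhos) + 1e-12)[1L]
    reg_lambda <- lambdas[pick]
    w <- sols[[pick]]
  } else {
    w <- gn_fit(reg_lambda, nn_tikhonov(A, g1, L, reg_lambda))
  }
  if (sum(w) <= 0) {
    out <- size_distribution(grid, rep(1 / length(grid), length(grid)))
    attr(out, "empty") <- TRUE
  } else {
    out <- size_distribution(grid, w)
    attr(out, "empty") <- FALSE
  }
  attr(out, "reg_lambda") <- reg_lambda
  attr(out, "beta") <- beta
  attr(out, "residual_norm") <- sqrt(sum((A %*% w - g1)^2))
  out
}

#' Invert a time series of autocorrelation traces
#'
#' Applies [invert_acf()] to traces collected at successive incubation
#' times with a shared radius grid and a shared regularization weight (the
#' median of the per-trace automatic choices), and summarises the modal
#' hydrodynamic radius and intensity share of each detected mode.
#'
#' @param traces Named list (or list with `incubation_h` attributes) of
#'   data frames with `lag_s`, `g2m1`; at least 2 incubation times.
#' @param optics An [optical_config()] shared by all traces.
#' @param grid Shared radius grid, nm.
#' @param incubation_h Numeric vector of incubation times, h (defaults to
#'   `names(traces)` coerced to numeric).
#' @return List with `distributions` (list of [size_distribution()]),
#'   `modes` (data frame `incubation_h`, `mode_radius_nm`, `mode_share`),
#'   `reg_lambda`.
#' @export
track_distribution_series <- function(traces, optics, grid = default_radius_grid(),
                                      incubation_h = NULL) {
  if (length(traces) < 2L) stop("need >= 2 incubation times", call. = FALSE)
  if (is.null(incubation_h)) incubation_h <- as.numeric(names(traces))
  if (any(is.na(incubation_h))) stop("incubation times must be numeric", call. = FALSE)
  # per-trace automatic selection, then one shared lambda for comparability
  lam <- vapply(traces, function(tr)
    attr(invert_acf(tr, optics, grid), "reg_lambda"), numeric(1L))
  shared <- median(lam, na.rm = TRUE)
  dists <- lapply(traces, invert_acf, optics = optics, grid = grid,
                  reg_lambda = shared)
  modes <- do.call(rbind, Map(function(d, h) {
    peaks <- local_maxima(d$weight)
    main <- peaks[which.max(d$weight[peaks])]
    data.frame(incubation_h = h, mode_radius_nm = d$radius_nm[main],
               mode_share = mode_mass(d$weight, main))
  }, dists, incubation_h))
  rownames(modes) <- NULL
  list(distributions = dists, modes = modes, reg_lambda = shared)
}

## Indices of strict-or-plateau local maxima of a non-negative vector.
local_maxima <- function(w) {
  n <- length(w)
  up <- c(TRUE, diff(w) >= 0); down <- c(diff(w) <= 0, TRUE)
  idx <- which(up & down & w > 0)
  if (length(idx) == 0L) idx <- which.max(w)
  idx
}

## Mass of the mode containing index i (descend to the flanking minima).
mode_mass <- function(w, i) {
  lo <- i; while (lo > 1L && w[lo - 1L] <= w[lo] && w[lo - 1L] > 0) lo <- lo - 1L
  hi <- i; while (hi < length(w) && w[hi + 1L] <= w[hi] && w[hi + 1L] > 0) hi <- hi + 1L
  sum(w[lo:hi])
}
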