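#' Kinetic parameters of the nucleation-and-growth model
#'
#' Bundles the three fitted rate products and the population radii of the
#' two-population nucleation-and-growth model. Rates are only identifiable
#' as products with the initial supersaturation level, so all three carry
#' units of h^-1:
#'
#' * `kn_dmu0` — primary nucleation (monomer-only creation of aggregates),
#' * `kplus_dmu0` — elongation (monomer addition to existing aggregate ends),
#' * `k2_dmu0` — secondary nucleation (aggregate-surface-catalysed creation
#'   of new aggregates).
#'
#' Aggregate mass is split between a large population of hydrodynamic
#' radius `r1` and a small population of radius `r2`; `small_fraction` is
#' the fraction of newly created aggregate mass assigned to the `r2`
#' population (1 when small oligomers dominate, as under tweezer
#' treatment; 0.5 as an agnostic default otherwise).
#'
#' @param kn_dmu0,kplus_dmu0,k2_dmu0 Non-negative rate products, h^-1.
#' @param r_monomer Monomer hydrodynamic radius, nm.
#' @param r1,r2 Large and small aggregate population radii, nm
#'   (`r1 >= r2 > r_monomer`).
#' @param small_fraction Fraction of new aggregate mass entering the `r2`
#'   population, in `[0, 1]`.
#' @return An object of class `kin_params` (a named list).
#' @examples
#' kin_params(kn_dmu0 = 12.3e-5, k2_dmu0 = 0.14, r1 = 150, r2 = 15)
#' @export
kin_params <- function(kn_dmu0 = 0, kplus_dmu0 = 0, k2_dmu0 = 0,
                       r_monomer = 3, r1 = 150, r2 = 15,
                       small_fraction = 0.5) {
  p <- list(kn_dmu0 = as.numeric(kn_dmu0),
            kplus_dmu0 = as.numeric(kplus_dmu0),
            k2_dmu0 = as.numeric(k2_dmu0),
            r_monomer = as.numeric(r_monomer),
            r1 = as.numeric(r1), r2 = as.numeric(r2),
            small_fraction = as.numeric(small_fraction))
  class(p) <- "kin_params"
  validate_kin_params(p)
  p
}

validate_kin_params <- function(p) {
  rates <- c(p$kn_dmu0, p$kplus_dmu0, p$k2_dmu0)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rate products must be finite and >= 0", call. = FALSE)
  if (any(c(p$r_monomer, p$r1, p$r2) <= 0))
    stop("radii must be > 0", call. = FALSE)
  if (!(p$r1 >= p$r2 && p$r2 > p$r_monomer))
    stop("radii must satisfy r1 >= r2 > r_monomer", call. = FALSE)
  if (p$small_fraction < 0 || p$small_fraction > 1)
    stop("small_fraction must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

#' @export
print.kin_params <- function(x, ...) {
  cat("Nucleation-and-growth rate products [h^-1]\n")
  cat(sprintf("  kn*dmu0    = %.4g\n  kplus*dmu0 = %.4g\n  k2*dmu0    = %.4g\n",
              x$kn_dmu0, x$kplus_dmu0, x$k2_dmu0))
  cat(sprintf("Populations: r_monomer = %g nm, r2 = %g nm, r1 = %g nm, small_fraction = %g\n",
              x$r_monomer, x$r2, x$r1, x$small_fraction))
  invisible(x)
}

## RHS of the moment system:
##   dalpha/dt = (kn + k2*alpha)*(1-alpha) + kplus*p*(1-alpha)
##   dp/dt     = (kn + k2*alpha)*(1-alpha)
## with p the normalized particle number (nucleation flux integral).
kin_rhs <- function(t, y, parms) {
  nuc <- (parms[1L] + parms[3L] * y[1L]) * (1 - y[1L])
  list(c(nuc + parms[2L] * y[2L] * (1 - y[1L]), nuc))
}

## Solve on a coarse internal grid and spline back to `times`; the states
## are smooth so the interpolation error (~1e-10) is far below rtol.
solve_alpha <- function(params, times, initial_alpha = 0, initial_p = 0,
                        rtol = 1e-10, n_internal = 400L) {
  t_end <- times[length(times)]
  if (t_end == 0)
    return(cbind(alpha = rep(initial_alpha, length(times)),
                 p = rep(initial_p, length(times))))
  grid <- unique(sort(c(0, seq(0, t_end, length.out = n_internal), times)))
  if (length(times) <= n_internal) {
    out <- deSolve::lsoda(c(initial_alpha, initial_p), grid, kin_rhs,
                          c(params$kn_dmu0, params$kplus_dmu0, params$k2_dmu0),
                          rtol = rtol, atol = rtol * 1e-2)
    idx <- match(times, out[, 1L])
    return(cbind(alpha = pmin(pmax(out[idx, 2L], 0), 1), p = pmax(out[idx, 3L], 0)))
  }
  grid <- unique(c(seq(0, t_end, length.out = n_internal), t_end))
  out <- deSolve::lsoda(c(initial_alpha, initial_p), grid, kin_rhs,
                        c(params$kn_dmu0, params$kplus_dmu0, params$k2_dmu0),
                        rtol = rtol, atol = rtol * 1e-2)
  alpha <- splinefun(out[, 1L], out[, 2L], method = "monoH.FC")(times)
  p <- splinefun(out[, 1L], out[, 3L], method = "monoH.FC")(times)
  cbind(alpha = pmin(pmax(alpha, 0), 1), p = pmax(p, 0))
}

#' Simulate the nucleation-and-growth kinetic model
#'
#' Integrates the dimensionless two-population moment system
#' \deqn{d\alpha/dt = (k_n\Delta\mu_0 + k_2\Delta\mu_0\,\alpha)(1-\alpha) +
#'       k_+\Delta\mu_0\, p\,(1-\alpha)}
#' \deqn{dp/dt = (k_n\Delta\mu_0 + k_2\Delta\mu_0\,\alpha)(1-\alpha)}
#' where \eqn{\alpha} is the aggregate mass fraction, \eqn{m = 1-\alpha}
#' the monomer mass fraction and \eqn{p} a normalized particle number.
#' New aggregate mass is split between the small (`alpha2`) and large
#' (`alpha1`) populations according to `small_fraction`.
#'
#' @param params A [kin_params()] object.
#' @param times Strictly increasing time grid in hours, first entry 0.
#' @param initial_alpha Initial aggregate mass fraction in `[0, 1)`
#'   (non-zero for seeded reactions).
#' @param rtol Relative integration tolerance (default 1e-10).
#' @return A data frame of class `kin_trajectory` with columns
#'   `time_h, m, alpha, alpha1, alpha2, p`.
#' @examples
#' tr <- simulate_kinetics(kin_params(kn_dmu0 = 0.1), seq(0, 10, 0.5))
#' all.equal(tr$alpha, 1 - exp(-0.1 * tr$time_h), tolerance = 1e-7)
#' @export
simulate_kinetics <- function(params, times, initial_alpha = 0, rtol = 1e-10) {
  validate_kin_params(params)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (times[1L] != 0)
    stop("time grid must start at 0", call. = FALSE)
  if (initial_alpha < 0 || initial_alpha >= 1)
    stop("initial_alpha must lie in [0, 1)", call. = FALSE)
  st <- solve_alpha(params, times, initial_alpha = initial_alpha, rtol = rtol,
                    n_internal = length(times) + 1L)
  new_mass <- pmax(st[, "alpha"] - initial_alpha, 0)
  alpha2 <- initial_alpha * params$small_fraction + params$small_fraction * new_mass
  # seeded mass is split with the same rule as newly created mass
  alpha1 <- st[, "alpha"] - alpha2
  tr <- data.frame(time_h = times, m = 1 - st[, "alpha"], alpha = st[, "alpha"],
                   alpha1 = alpha1, alpha2 = alpha2, p = st[, "p"])
  class(tr) <- c("kin_trajectory", "data.frame")
  tr
}

#' Predicted scattering intensity shares of a kinetic state
#'
#' Maps kinetic states (monomer, small-population and large-population mass
#' fractions) to relative scattered intensities under Rayleigh weighting,
#' where each population scatters proportionally to its mass times the cube
#' of its hydrodynamic radius. These are the model-predicted DLS intensity
#' shares used in the joint fit.
#'
#' @param state A `kin_trajectory` (all rows are converted) or any data
#'   frame/list with elements `m`, `alpha2`, `alpha1`.
#' @param params A [kin_params()] object supplying the radii.
#' @return A matrix with columns `monomer`, `small`, `large`; rows sum to 1.
#' @examples
#' predict_intensity_fractions(list(m = 0.5, alpha2 = 0.5, alpha1 = 0),
#'                             kin_params(r2 = 15))
#' @export
predict_intensity_fractions <- function(state, params) {
  validate_kin_params(params)
  m <- state$m; a2 <- state$alpha2; a1 <- state$alpha1
  w <- cbind(monomer = m * params$r_monomer^3,
             small = a2 * params$r2^3,
             large = a1 * params$r1^3)
  tot <- rowSums(w)
  if (any(tot <= 0))
    stop("degenerate state: all population masses are zero", call. = FALSE)
  w / tot
}

## Closed-form autocatalytic (Finke-Watzky type) solution for
## dalpha/dt = (a + b*alpha)(1-alpha), alpha(0) = 0.
alpha_autocatalytic <- function(t, a, b) {
  if (b == 0) return(1 - exp(-a * t))
  e <- exp((a + b) * t)
  a * (e - 1) / (a * e + b)
}

## Half-time of the autocatalytic solution (alpha = 1/2).
t50_autocatalytic <- function(a, b) log((b + 2 * a) / a) / (a + b)

#' Rate products and radii fitted to the ataxin-3 DLS/ThT experiments
#'
#' Published parameter table for wild-type (13Q) and polyQ-expanded (77Q)
#' ataxin-3 aggregating alone (control) or with a five-fold excess of the
#' lysine-binding molecular tweezer CLR01 or its inactive control CLR03.
#' Useful as realistic inputs to the simulator and the synthetic-data
#' generators. Units: radii in nm, rate products in h^-1.
#'
#' @return Data frame with columns `variant`, `condition`, `r1`, `r2`,
#'   `kn_dmu0`, `kplus_dmu0`, `k2_dmu0`.
#' @examples
#' atx3_rate_table()
#' @export
atx3_rate_table <- function() {
  data.frame(
    variant = rep(c("13Q", "77Q"), each = 3L),
    condition = rep(c("control", "CLR01", "CLR03"), 2L),
    r1 = c(150, 150, 100, 150, 150, 40),
    r2 = c(15, 10, 15, 20, 20, 20),
    kn_dmu0 = c(12.3e-5, 0.25e-5, 100e-5, 1.9e-4, 2.6e-6, 0.10),
    kplus_dmu0 = c(0, 8.7e-2, 0, 0, 9.49e-2, 0),
    k2_dmu0 = c(0.14, 3.0e-6, 0.058, 0.13, 5.6e-6, 6.1e-4),
    stringsAsFactors = FALSE)
}

## kin_params from a row of atx3_rate_table (or any compatible row).
row_to_params <- function(row, r_monomer = 3, small_fraction = NULL) {
  if (is.null(small_fraction))
    small_fraction <- if (row$kplus_dmu0 > row$k2_dmu0) 1 else 0.5
  kin_params(kn_dmu0 = row$kn_dmu0, kplus_dmu0 = row$kplus_dmu0,
             k2_dmu0 = row$k2_dmu0, r_monomer = r_monomer,
             r1 = row$r1, r2 = row$r2, small_fraction = small_fraction)
}

## Time at which alpha reaches `level`, found by doubling + uniroot on the
## integrated model. Returns NA if the level is never reached numerically.
time_to_alpha <- function(params, level = 0.5, t_max_cap = 1e7) {
  t_hi <- 10
  repeat {
    a <- solve_alpha(params, c(0, t_hi))[2L, "alpha"]
    if (a >= level || t_hi >= t_max_cap) break
    t_hi <- t_hi * 2
  }
  if (a < level) return(NA_real_)
  f <- function(t) solve_alpha(params, c(0, t))[2L, "alpha"] - level
  uniroot(f, c(1e-9, t_hi), tol = 1e-7 * t_hi)$root
}
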