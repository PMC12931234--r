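## Run code with a temporary RNG state seeded by `seed`, restoring the
## caller's stream afterwards; all generators are pure functions of seed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Design of a synthetic aggregation study
#'
#' Collects the experimental-design knobs the generators emulate: a ThT
#' microplate sampled every 30 min, 4 biological x 3 technical replicates,
#' 2% amplitude noise, and a DLS schedule of 0/16/24/48/72/120 h.
#' Biological-replicate heterogeneity is modelled as a lognormal
#' multiplier on all three rate products, reflecting that half-times vary
#' across protein preparations while technical replicates are consistent.
#'
#' @param seed Integer seed.
#' @param design Named list mapping condition labels to [kin_params()].
#' @param n_bio_reps,n_tech_reps Replicate counts (defaults 4 and 3).
#' @param tht_noise_sigma Gaussian noise as a fraction of the curve
#'   amplitude (default 0.02).
#' @param sampling_interval Sampling interval, h (default 0.5).
#' @param duration Assay duration, h (default 72); `NA` to auto-extend
#'   per condition until `alpha >= 0.9`.
#' @param dls_times DLS schedule, h (default `c(0,16,24,48,72,120)`).
#' @param dls_snr DLS signal-to-noise ratio (default 100).
#' @param bio_jitter_sigma Lognormal sigma of the per-biological-replicate
#'   rate multiplier (default 0.15); 0 disables jitter.
#' @param f0,df Nominal baseline and amplitude, a.u.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L,
                           design = NULL,
                           n_bio_reps = 4L, n_tech_reps = 3L,
                           tht_noise_sigma = 0.02, sampling_interval = 0.5,
                           duration = 72, dls_times = c(0, 16, 24, 48, 72, 120),
                           dls_snr = 100, bio_jitter_sigma = 0.15,
                           f0 = 100, df = 400) {
  if (is.null(design)) {
    tab <- atx3_rate_table()
    design <- list(control = row_to_params(tab[1L, ]),
                   CLR01 = row_to_params(tab[2L, ]))
  }
  stopifnot(n_bio_reps >= 1L, n_tech_reps >= 1L, tht_noise_sigma >= 0,
            is.na(duration) || duration > 0, dls_snr > 0)
  structure(list(seed = as.integer(seed), design = design,
                 n_bio_reps = as.integer(n_bio_reps),
                 n_tech_reps = as.integer(n_tech_reps),
                 tht_noise_sigma = tht_noise_sigma,
                 sampling_interval = sampling_interval, duration = duration,
                 dls_times = dls_times, dls_snr = dls_snr,
                 bio_jitter_sigma = bio_jitter_sigma, f0 = f0, df = df),
            class = "generator_spec")
}

jitter_params <- function(params, mult) {
  kin_params(kn_dmu0 = params$kn_dmu0 * mult,
             kplus_dmu0 = params$kplus_dmu0 * mult,
             k2_dmu0 = params$k2_dmu0 * mult,
             r_monomer = params$r_monomer, r1 = params$r1, r2 = params$r2,
             small_fraction = params$small_fraction)
}

condition_duration <- function(params, spec) {
  if (!is.na(spec$duration)) return(spec$duration)
  t90 <- time_to_alpha(params, 0.9)
  ceiling(t90 / spec$sampling_interval) * spec$sampling_interval
}

#' Generate a synthetic ThT microplate
#'
#' Simulates `alpha(t)` per condition with [simulate_kinetics()], applies
#' a per-biological-replicate lognormal rate multiplier and affine
#' fluorescence scale, and adds Gaussian noise per technical replicate.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec A [generator_spec()].
#' @return List with `plate` (long data frame: `well_id`, `condition`,
#'   `bio_rep`, `tech_rep`, `time_h`, `fluorescence`) and `truth`
#'   (per condition x biological replicate: rate products after jitter,
#'   analytic `t50` and `v50`, `f0`, `df`).
#' @export
generate_tht_plate <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    plate <- list(); truth <- list()
    for (cond in names(spec$design)) {
      base <- spec$design[[cond]]
      dur <- condition_duration(base, spec)
      times <- seq(0, dur, by = spec$sampling_interval)
      for (b in seq_len(spec$n_bio_reps)) {
        mult <- if (spec$bio_jitter_sigma > 0)
          rlnorm(1L, 0, spec$bio_jitter_sigma) else 1
        pj <- jitter_params(base, mult)
        tr <- simulate_kinetics(pj, times)
        f0b <- spec$f0 * runif(1L, 0.8, 1.2)
        dfb <- spec$df * runif(1L, 0.8, 1.2)
        t50 <- time_to_alpha(pj, 0.5)
        v50 <- if (is.na(t50)) NA_real_ else {
          h <- max(t50 * 1e-4, 1e-6)
          st <- solve_alpha(pj, c(0, t50 - h, t50 + h))
          (st[3L, "alpha"] - st[2L, "alpha"]) / (2 * h)
        }
        truth[[length(truth) + 1L]] <- data.frame(
          condition = cond, bio_rep = b, rate_mult = mult,
          kn_dmu0 = pj$kn_dmu0, kplus_dmu0 = pj$kplus_dmu0,
          k2_dmu0 = pj$k2_dmu0, t50 = t50, v50 = v50, f0 = f0b, df = dfb)
        for (r in seq_len(spec$n_tech_reps)) {
          y <- f0b + dfb * tr$alpha +
            rnorm(length(times), 0, spec$tht_noise_sigma * dfb)
          plate[[length(plate) + 1L]] <- data.frame(
            well_id = sprintf("%s_b%d_t%d", cond, b, r),
            condition = cond, bio_rep = b, tech_rep = r,
            time_h = times, fluorescence = y)
        }
      }
    }
    list(plate = do.call(rbind, plate), truth = do.call(rbind, truth))
  })
}

#' Generate a synthetic DLS autocorrelation time series
#'
#' Simulates the kinetic trajectory at the DLS schedule, converts each
#' state to a three-population intensity-weighted size distribution
#' (monomer, small, large), forward-models `g2(tau) - 1` with
#' [acf_forward()] and adds Gaussian noise of standard deviation
#' `beta / dls_snr`.
#'
#' @param spec A [generator_spec()] (`dls_times`, `dls_snr`, `seed` used).
#' @param optics An [optical_config()].
#' @param params A [kin_params()]; default: first condition in the design.
#' @param lags Lag grid in seconds (default 120 log-spaced points,
#'   1e-7 to 1 s).
#' @return List with `traces` (named list of `lag_s`/`g2m1` data frames,
#'   names = incubation times), `truth` (trajectory + true shares).
#' @export
generate_dls_series <- function(spec, optics = optical_config(), params = NULL,
                                lags = 10^seq(-7, 0, length.out = 120L)) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.null(params)) params <- spec$design[[1L]]
  with_seed(spec$seed + 1L, {
    tt <- sort(unique(c(0, spec$dls_times)))
    tr <- simulate_kinetics(params, tt)
    shares <- predict_intensity_fractions(tr, params)
    radii <- c(params$r_monomer, params$r2, params$r1)
    traces <- lapply(seq_along(spec$dls_times), function(i) {
      j <- match(spec$dls_times[i], tt)
      w <- pmax(shares[j, ], 1e-12)
      d <- size_distribution(radii, w)
      trc <- acf_forward(d, optics, lags)
      trc$g2m1 <- trc$g2m1 + rnorm(length(lags), 0, optics$beta / spec$dls_snr)
      trc
    })
    names(traces) <- spec$dls_times
    list(traces = traces,
         truth = list(trajectory = tr, shares = cbind(time_h = tt, shares)))
  })
}

#' Generate one synthetic joint ThT + DLS dataset
#'
#' Produces the input of [fit_joint()] from known rate products: technical
#' ThT replicates sampled every `sampling_interval` hours with Gaussian
#' noise `noise_sigma * amplitude`, and noisy DLS intensity shares at the
#' scheduled incubation times (share noise sd `1 / dls_snr`, renormalized).
#' The duration auto-extends until `alpha >= 0.9` when not given, and the
#' DLS schedule scales with the duration when not given (the canonical
#' 0/16/24/48/72/120 h schedule stretched to the assay length).
#'
#' @param params True [kin_params()].
#' @param n_curves Number of ThT technical replicates (default 3).
#' @param noise_sigma ThT noise as a fraction of amplitude (default 0.02).
#' @param dls_snr DLS signal-to-noise ratio (default 100).
#' @param dls_times DLS schedule, h; `NULL` to scale the canonical
#'   schedule to the duration.
#' @param sampling_interval ThT sampling interval, h (default 0.5).
#' @param duration Assay length, h; `NULL` to extend until `alpha >= 0.9`.
#' @param f0,df ThT baseline and amplitude, a.u.
#' @param seed Integer seed.
#' @return List with `data` (a [joint_dataset()]) and `truth`
#'   (the generating parameters and the noiseless shares).
#' @export
generate_joint_dataset <- function(params, n_curves = 3L, noise_sigma = 0.02,
                                   dls_snr = 100, dls_times = NULL,
                                   sampling_interval = 0.5, duration = NULL,
                                   f0 = 100, df = 400, seed = 1L) {
  validate_kin_params(params)
  if (is.null(duration)) {
    t90 <- time_to_alpha(params, 0.9)
    if (is.na(t90)) stop("model never reaches alpha = 0.9; give a duration",
                         call. = FALSE)
    duration <- ceiling(t90 / sampling_interval) * sampling_interval
  }
  if (is.null(dls_times)) {
    sched <- c(0, 16, 24, 48, 72, 120) / 120
    dls_times <- round(sched * duration / sampling_interval) * sampling_interval
    dls_times <- unique(dls_times)
  }
  with_seed(seed, {
    times <- seq(0, duration, by = sampling_interval)
    tt <- sort(unique(c(times, dls_times)))
    tr <- simulate_kinetics(params, tt)
    alpha <- tr$alpha[match(times, tt)]
    tht <- do.call(rbind, lapply(seq_len(n_curves), function(r) {
      data.frame(well_id = sprintf("tech%d", r), time_h = times,
                 fluorescence = f0 + df * alpha +
                   rnorm(length(times), 0, noise_sigma * df))
    }))
    shares <- predict_intensity_fractions(tr, params)[match(dls_times, tt), ,
                                                      drop = FALSE]
    noisy <- shares + matrix(rnorm(length(shares), 0, 1 / dls_snr),
                             nrow = nrow(shares))
    noisy <- pmax(noisy, 0)
    noisy <- noisy / rowSums(noisy)
    dls <- data.frame(time_h = dls_times, monomer = noisy[, "monomer"],
                      small = noisy[, "small"], large = noisy[, "large"])
    list(data = joint_dataset(tht, dls, r_monomer = params$r_monomer,
                              r2 = params$r2, r1 = params$r1,
                              small_fraction = params$small_fraction),
         truth = list(params = params, shares = cbind(time_h = dls_times, shares),
                      duration = duration))
  })
}

#' Render a synthetic TEM field with known particles
#'
#' Draws anti-aliased dark disks (spherical oligomers, lognormal
#' diameters) and constant-width curvilinear ribbons (protofibrils with
#' random-walk spines) on a noisy bright background, emulating a
#' negative-stain micrograph at a known nm-per-pixel calibration.
#'
#' @param n_oligomers,n_fibrils Particle counts (>= 0).
#' @param nm_per_px Calibration, nm per pixel.
#' @param img_size Image side, px.
#' @param oligomer_meanlog,oligomer_sdlog Lognormal parameters of the
#'   oligomer diameter in nm (defaults give a ~20 nm median).
#' @param fibril_length_nm,fibril_width_nm Ribbon spine length and width, nm.
#' @param background,contrast Background grey level and particle contrast
#'   (8-bit scale).
#' @param noise_sd Gaussian background noise sd (8-bit scale).
#' @param seed Integer seed.
#' @return List with `image` (a `calibrated_image`: 8-bit matrix +
#'   `nm_per_px`) and `truth` (data frame: `class`, `x_px`, `y_px`,
#'   `area_nm2`, `max_feret_nm`).
#' @export
generate_tem_field <- function(n_oligomers = 50L, n_fibrils = 10L,
                               nm_per_px = 1, img_size = 512L,
                               oligomer_meanlog = log(20),
                               oligomer_sdlog = 0.25,
                               fibril_length_nm = 80, fibril_width_nm = 8,
                               background = 180, contrast = 120,
                               noise_sd = 6, seed = 1L) {
  stopifnot(n_oligomers >= 0L, n_fibrils >= 0L, nm_per_px > 0)
  with_seed(seed, {
    cover <- matrix(0, img_size, img_size)  # particle coverage in [0,1]
    truth <- list()
    placed <- matrix(numeric(0), 0, 2)  # centres, for overlap avoidance
    min_gap <- 6
    radii_placed <- numeric(0)
    place <- function(rad_px) {
      for (i in 1:300) {
        xy <- runif(2L, rad_px + 4, img_size - rad_px - 3)
        if (nrow(placed) == 0L ||
            min(sqrt(rowSums((placed - matrix(xy, nrow(placed), 2,
                                              byrow = TRUE))^2)) -
                radii_placed) > rad_px + min_gap)
          return(xy)
      }
      NULL
    }
    # larger particles (ribbons) are placed first so they find room
    for (i in seq_len(n_fibrils)) {
      len_px <- fibril_length_nm / nm_per_px
      w_px <- fibril_width_nm / nm_per_px
      xy <- place(len_px / 2)
      if (is.null(xy)) next
      placed <- rbind(placed, xy)
      radii_placed <- c(radii_placed, len_px / 2)
      step <- 3
      nseg <- max(ceiling(len_px / step), 2L)
      heading <- runif(1L, 0, 2 * pi)
      pts <- matrix(0, nseg + 1L, 2L)
      for (s in seq_len(nseg)) {
        heading <- heading + rnorm(1L, 0, 0.18)
        pts[s + 1L, ] <- pts[s, ] + step * c(cos(heading), sin(heading))
      }
      # centre the spine's bounding box on the placement point
      ctr <- (apply(pts, 2L, max) + apply(pts, 2L, min)) / 2
      pts <- pts + matrix(xy - ctr, nseg + 1L, 2L, byrow = TRUE)
      pts <- pmin(pmax(pts, w_px + 3), img_size - w_px - 2)
      bx <- pmax(1L, floor(min(pts[, 1L]) - w_px)):pmin(img_size, ceiling(max(pts[, 1L]) + w_px))
      by <- pmax(1L, floor(min(pts[, 2L]) - w_px)):pmin(img_size, ceiling(max(pts[, 2L]) + w_px))
      dd <- matrix(Inf, length(bx), length(by))
      for (s in seq_len(nseg)) {
        dd <- pmin(dd, dist_to_segment(bx, by, pts[s, ], pts[s + 1L, ]))
      }
      cover[bx, by] <- pmax(cover[bx, by], pmin(pmax(w_px / 2 - dd + 0.5, 0), 1))
      spine_len <- sum(sqrt(rowSums(diff(pts)^2)))
      ends <- sqrt(sum((pts[nseg + 1L, ] - pts[1L, ])^2))
      truth[[length(truth) + 1L]] <- data.frame(
        class = "fibril", x_px = mean(pts[, 1L]), y_px = mean(pts[, 2L]),
        area_nm2 = spine_len * w_px * nm_per_px^2,
        max_feret_nm = (ends + w_px) * nm_per_px)
    }
    for (i in seq_len(n_oligomers)) {
      d_nm <- rlnorm(1L, oligomer_meanlog, oligomer_sdlog)
      r_px <- d_nm / 2 / nm_per_px
      xy <- place(r_px)
      if (is.null(xy)) next
      placed <- rbind(placed, xy)
      radii_placed <- c(radii_placed, r_px)
      bx <- pmax(1L, floor(xy[1L] - r_px - 2)):pmin(img_size, ceiling(xy[1L] + r_px + 2))
      by <- pmax(1L, floor(xy[2L] - r_px - 2)):pmin(img_size, ceiling(xy[2L] + r_px + 2))
      dd <- sqrt(outer((bx - xy[1L])^2, (by - xy[2L])^2, `+`))
      cover[bx, by] <- pmax(cover[bx, by], pmin(pmax(r_px - dd + 0.5, 0), 1))
      truth[[length(truth) + 1L]] <- data.frame(
        class = "oligomer", x_px = xy[1L], y_px = xy[2L],
        area_nm2 = pi * (d_nm / 2)^2, max_feret_nm = d_nm)
    }
    img <- background - contrast * cover +
      matrix(rnorm(img_size^2, 0, noise_sd), img_size)
    img <- round(pmin(pmax(img, 0), 255))
    list(image = calibrated_image(img, nm_per_px),
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(class = character(), x_px = numeric(), y_px = numeric(),
                      area_nm2 = numeric(), max_feret_nm = numeric()))
  })
}

## Distance from grid points (bx x by) to segment p1-p2.
dist_to_segment <- function(bx, by, p1, p2) {
  v <- p2 - p1
  l2 <- sum(v^2)
  px <- matrix(bx, length(bx), length(by)) - p1[1L]
  py <- matrix(by, length(bx), length(by), byrow = TRUE) - p1[2L]
  t <- if (l2 > 0) pmin(pmax((px * v[1L] + py * v[2L]) / l2, 0), 1) else 0
  sqrt((px - t * v[1L])^2 + (py - t * v[2L])^2)
}

#' Generate noisy 1:1 binding observations over a K_D grid
#'
#' Solves the exact binding equilibrium for each dissociation constant and
#' applies multiplicative lognormal noise to the species abundances.
#'
#' @param kd_grid True dissociation constants, uM.
#' @param p_total,l_total Total concentrations, uM.
#' @param noise Lognormal sigma of the multiplicative noise (0 = exact).
#' @param seed Integer seed.
#' @return Data frame: `kd_true`, `p_free`, `l_free`, `pl`.
#' @export
generate_binding_data <- function(kd_grid, p_total = 10, l_total = 10,
                                  noise = 0, seed = 1L) {
  stopifnot(all(kd_grid > 0), p_total > 0, l_total > 0, noise >= 0)
  with_seed(seed, {
    do.call(rbind, lapply(kd_grid, function(kd) {
      eq <- equilibrium_abundances(p_total, l_total, kd)
      nz <- if (noise > 0) rlnorm(3L, 0, noise) else rep(1, 3L)
      data.frame(kd_true = kd, p_free = eq$p_free * nz[1L],
                 l_free = eq$l_free * nz[2L], pl = eq$pl * nz[3L])
    }))
  })
}
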