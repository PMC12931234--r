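# shared fixtures and oracles for the test suite

# brute-force fixed-step explicit Euler integration of the kinetic model;
# intentionally independent of the package's adaptive solver
euler_alpha <- function(params, times, dt = 0.001) {
  t_end <- max(times)
  n <- ceiling(t_end / dt)
  alpha <- 0; p <- 0
  out_t <- times
  out <- numeric(length(times))
  out[times == 0] <- 0
  ti <- 0
  next_out <- 1L
  for (i in seq_len(n)) {
    nuc <- (params$kn_dmu0 + params$k2_dmu0 * alpha) * (1 - alpha)
    dal <- nuc + params$kplus_dmu0 * p * (1 - alpha)
    alpha <- alpha + dt * dal
    p <- p + dt * nuc
    ti <- ti + dt
    while (next_out <= length(out_t) && out_t[next_out] <= ti + 1e-9) {
      out[next_out] <- alpha
      next_out <- next_out + 1L
    }
  }
  while (next_out <= length(out_t)) {  # guard against float drift at t_end
    out[next_out] <- alpha
    next_out <- next_out + 1L
  }
  out[out_t == 0] <- 0
  out
}

# rasterized disk mask
disk_mask <- function(r, pad = 10L) {
  n <- 2L * (r + pad) + 1L
  c0 <- r + pad + 1L
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) m[i, ] <- (i - c0)^2 + (seq_len(n) - c0)^2 <= r^2
  m
}

# match detected particles to generator ground truth by centroid distance
match_particles <- function(pt, truth, tol_px = 15) {
  vapply(seq_len(nrow(truth)), function(i) {
    d <- sqrt((pt$x_px - truth$x_px[i])^2 + (pt$y_px - truth$y_px[i])^2)
    j <- which.min(d)
    if (length(j) && d[j] < tol_px) pt$class[j] else NA_character_
  }, character(1L))
}

table1_params <- function(i, ...) aggrekin:::row_to_params(atx3_rate_table()[i, ], ...)
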