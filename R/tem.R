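#' A calibrated 8-bit TEM image
#'
#' @param pixels Numeric matrix of grey values in 0-255.
#' @param nm_per_px Calibration, nm per pixel (> 0).
#' @return Object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, nm_per_px) {
  stopifnot(is.matrix(pixels), length(pixels) > 0, nm_per_px > 0)
  structure(list(pixels = pixels, nm_per_px = nm_per_px),
            class = "calibrated_image")
}

#' Preprocess a TEM image into a binary particle mask
#'
#' Reimplements the standard micrograph segmentation recipe: Gaussian
#' blur (sigma in px; 0 skips smoothing), 3x3 Sobel gradient magnitude
#' ("find edges"), linear rescale of the edge image to 0-255, an inclusive
#' threshold band, and hole filling so particle outlines become solid
#' regions.
#'
#' @param image A [calibrated_image()] or a plain matrix.
#' @param sigma Gaussian blur sigma, px (default 1.5).
#' @param threshold_low,threshold_high Inclusive 8-bit threshold band,
#'   `0 <= low < high <= 255` (default 80-255).
#' @param edge_halfwidth Erosion radius in px applied after hole filling,
#'   compensating the half-width of the gradient ridge that the
#'   blur + Sobel steps paint around each particle (default 2 px for
#'   `sigma = 1.5`; 0 disables the compensation).
#' @return Logical matrix mask (same dimensions).
#' @export
tem_preprocess <- function(image, sigma = 1.5, threshold_low = 80,
                           threshold_high = 255, edge_halfwidth = 2L) {
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  if (threshold_low < 0 || threshold_high > 255 || threshold_low >= threshold_high)
    stop("threshold band must satisfy 0 <= low < high <= 255", call. = FALSE)
  img <- EBImage::Image(px / 255)
  if (sigma > 0) img <- EBImage::gblur(img, sigma = sigma)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::filter2(img, kx)
  gy <- EBImage::filter2(img, t(kx))
  # gradient magnitude on the 8-bit scale, clipped (not rescaled) so a
  # featureless image stays below the threshold band
  mag <- pmin(sqrt(EBImage::imageData(gx)^2 + EBImage::imageData(gy)^2) * 255,
              255)
  mask <- mag >= threshold_low & mag <= threshold_high
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  if (edge_halfwidth > 0)
    filled <- EBImage::erode(filled,
                             EBImage::makeBrush(2L * edge_halfwidth + 1L,
                                                shape = "disc"))
  EBImage::imageData(filled) > 0
}

## 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
## touch only diagonally are merged with a union-find pass.
label_components <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  n <- max(lab)
  if (n < 2L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  idx <- which(a > 0 & b > 0 & a != b)
  for (i in idx) union(a[i], b[i])
  a <- lab[-nr, -1]; b <- lab[-1, -nc]
  idx <- which(a > 0 & b > 0 & a != b)
  for (i in idx) union(a[i], b[i])
  roots <- vapply(seq_len(n), find, 1L)
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

## Moore-neighbour boundary trace of a single component (logical matrix).
## Returns the closed boundary path as a two-column matrix of (row, col).
trace_boundary <- function(comp) {
  idx <- which(comp, arr.ind = TRUE)
  if (nrow(idx) == 1L) return(idx)
  # start at the topmost pixel of the leftmost occupied column; its west
  # neighbour is guaranteed background and serves as the backtrack point
  start <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE][1L, ]
  # clockwise Moore neighbourhood offsets starting from W
  offs <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L,
                   1L, 0L, 1L, -1L), ncol = 2L, byrow = TRUE)
  inside <- function(p) p[1L] >= 1L && p[1L] <= nrow(comp) &&
    p[2L] >= 1L && p[2L] <= ncol(comp) && comp[p[1L], p[2L]]
  cur <- start
  b <- start + offs[1L, ]  # backtrack (background) point
  path <- matrix(0L, 0L, 2L)
  cap <- 4L * 8L * nrow(idx)
  repeat {
    path <- rbind(path, cur)
    d0 <- which(offs[, 1L] == b[1L] - cur[1L] & offs[, 2L] == b[2L] - cur[2L])
    found <- FALSE
    for (k in 0:7) {
      j <- ((d0 - 1L + k) %% 8L) + 1L
      cand <- cur + offs[j, ]
      if (inside(cand)) {
        b <- cur + offs[((j - 2L) %% 8L) + 1L, ]  # last background scanned
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (all(cur == start)) break  # boundary loop closed
    if (nrow(path) >= cap) break  # safety
  }
  path
}

## Chain-code perimeter: unit steps for 4-neighbour moves, sqrt(2) for
## diagonal moves, over the closed boundary path.
chain_perimeter <- function(path) {
  if (nrow(path) == 1L) return(4)  # single pixel: unit-square perimeter
  closed <- rbind(path, path[1L, ])
  steps <- abs(diff(closed))
  sum(ifelse(rowSums(steps) == 2L, sqrt(2), 1))
}

## Maximum Feret diameter from the convex hull of the boundary pixel
## centres, plus one pixel for the pixel extent.
max_feret <- function(path) {
  if (nrow(path) == 1L) return(1)
  h <- unique(path[chull(path[, 1L], path[, 2L]), , drop = FALSE])
  if (nrow(h) == 1L) return(1)
  d <- as.matrix(dist(h))
  max(d) + 1
}

## Major/minor axis lengths of the moment-equivalent ellipse.
ellipse_axes <- function(idx) {
  if (nrow(idx) < 2L) return(c(major = 1, minor = 1))
  cc <- scale(idx, scale = FALSE)
  # add the pixel's own second moment (uniform unit square: 1/12)
  S <- crossprod(cc) / nrow(cc) + diag(1 / 12, 2L)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  c(major = 4 * sqrt(ev[1L]), minor = 4 * sqrt(max(ev[2L], 1e-12)))
}

#' Measure particles in a binary mask
#'
#' Labels connected components (8-connectivity) and computes per-particle
#' morphometrics: area, boundary-chain perimeter (sqrt(2)-weighted
#' diagonals), circularity `4 pi A / P^2`, aspect ratio (major/minor axis
#' of the moment-equivalent ellipse) and maximum Feret diameter (longest
#' distance between boundary points, convex-hull based). All lengths are
#' calibrated to nm via `scale_nm_per_px`.
#'
#' @param mask Logical matrix from [tem_preprocess()].
#' @param scale_nm_per_px Calibration, nm per pixel.
#' @param exclude_edge Drop particles touching the image border
#'   (default TRUE).
#' @param min_px Minimum component size in pixels (default 2; single-pixel
#'   specks are kept only when `min_px = 1`).
#' @return Data frame of class `particle_table`: `particle`, `area_nm2`,
#'   `perimeter_nm`, `circularity`, `aspect_ratio`, `max_feret_nm`,
#'   `class` (all `"unclassified"`; see [classify_particles()]).
#' @export
measure_particles <- function(mask, scale_nm_per_px = 1, exclude_edge = TRUE,
                              min_px = 2L) {
  empty <- data.frame(particle = integer(), area_nm2 = numeric(),
                      perimeter_nm = numeric(), circularity = numeric(),
                      aspect_ratio = numeric(), max_feret_nm = numeric(),
                      x_px = numeric(), y_px = numeric(),
                      class = character(), stringsAsFactors = FALSE)
  class(empty) <- c("particle_table", "data.frame")
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  rows <- list()
  for (id in seq_len(max(lab))) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < min_px) next
    if (exclude_edge &&
        (min(idx) == 1L || max(idx[, 1L]) == nrow(mask) ||
         max(idx[, 2L]) == ncol(mask))) next
    comp <- matrix(FALSE, nrow(mask), ncol(mask))
    comp[idx] <- TRUE
    path <- trace_boundary(comp)
    per_px <- chain_perimeter(path)
    area_px <- nrow(idx)
    axes <- ellipse_axes(idx)
    rows[[length(rows) + 1L]] <- data.frame(
      particle = id,
      area_nm2 = area_px * scale_nm_per_px^2,
      perimeter_nm = per_px * scale_nm_per_px,
      circularity = 4 * pi * area_px / per_px^2,
      aspect_ratio = max(axes["major"] / axes["minor"], 1),
      max_feret_nm = max_feret(path) * scale_nm_per_px,
      x_px = mean(idx[, 1L]), y_px = mean(idx[, 2L]),
      class = "unclassified", stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  class(out) <- c("particle_table", "data.frame")
  out
}

#' Classify particles as oligomers or fibrils by shape
#'
#' Applies the morphometric gating rules: a particle is an
#' oligomer when its area is at least `oligomer_min_area_nm2` and its
#' circularity at least `oligomer_min_circ`; a fibril when its
#' circularity is at most `fibril_circ_max` and its aspect ratio at least
#' `fibril_min_ar`; otherwise it stays unclassified.
#'
#' @param table A `particle_table` from [measure_particles()].
#' @param oligomer_min_area_nm2 Minimum oligomer area (default 40 nm^2).
#' @param oligomer_min_circ Minimum oligomer circularity (default 0.90).
#' @param fibril_circ_max Maximum fibril circularity (default 0.40;
#'   commonly tightened to 0.20).
#' @param fibril_min_ar Minimum fibril aspect ratio (default 2.7).
#' @return The table with the `class` column filled in.
#' @export
classify_particles <- function(table, oligomer_min_area_nm2 = 40,
                               oligomer_min_circ = 0.90,
                               fibril_circ_max = 0.40, fibril_min_ar = 2.7) {
  if (fibril_circ_max >= oligomer_min_circ)
    warning("oligomer and fibril circularity criteria overlap")
  cls <- rep("unclassified", nrow(table))
  cls[table$area_nm2 >= oligomer_min_area_nm2 &
        table$circularity >= oligomer_min_circ] <- "oligomer"
  cls[table$circularity <= fibril_circ_max &
        table$aspect_ratio >= fibril_min_ar] <- "fibril"
  table$class <- cls
  table
}

#' Size statistics per particle class
#'
#' Per-class histogram of the maximum Feret diameter, its median and a
#' bootstrap 95% confidence interval of the median (seeded, 10,000
#' resamples by default). Empty classes are omitted with a notice.
#'
#' @param table A classified `particle_table`.
#' @param bin_width_nm Histogram bin width (default 10 nm).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed for the bootstrap.
#' @return Named list per class: `n`, `median_nm`, `ci95` (length 2),
#'   `histogram` (data frame `bin_mid_nm`, `count`).
#' @export
summarize_sizes <- function(table, bin_width_nm = 10, n_boot = 10000L,
                            seed = 1L) {
  classes <- setdiff(unique(table$class), NA)
  if (nrow(table) == 0L || length(classes) == 0L)
    stop("need at least one classified particle", call. = FALSE)
  out <- list()
  for (cl in classes) {
    x <- table$max_feret_nm[table$class == cl]
    if (length(x) == 0L) { message("class '", cl, "' is empty; omitted"); next }
    med <- median(x)
    ci <- with_seed(seed, {
      bm <- vapply(seq_len(n_boot),
                   function(i) median(sample(x, replace = TRUE)), numeric(1L))
      quantile(bm, c(0.025, 0.975), names = FALSE)
    })
    breaks <- seq(0, max(x) + bin_width_nm, by = bin_width_nm)
    counts <- tabulate(findInterval(x, breaks), nbins = length(breaks) - 1L)
    out[[cl]] <- list(n = length(x), median_nm = med, ci95 = ci,
                      histogram = data.frame(
                        bin_mid_nm = breaks[-length(breaks)] + bin_width_nm / 2,
                        count = counts))
  }
  out
}
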