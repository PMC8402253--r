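# SRS measurement sensitivity: detection-weighted mean partial path
# lengths per voxel/slab, their between-detector difference, depth
# profiles, summary metrics, peak-depth maps and regressions.

#' Mean partial path length per voxel or depth slab
#'
#' The detection-weighted mean path length `L = sum(L_i I_i) / sum(I_i)`
#' for one detector ring: `L_i` is the path the i-th detected photon
#' spent in the voxel and `I_i` its detected weight.
#'
#' @param tallies An `srs_tallies` object.
#' @param ring Ring index (1-based), or a nominal center radius if
#'   `by_center = TRUE`.
#' @param by_center Interpret `ring` as a center radius.
#' @return In depth-profile mode, a numeric vector over depth slabs
#'   (mm); in full_3d mode (for gridded rings) a 3-D array over voxels.
#'   Zero where no path weight was recorded.
#' @export
mean_path_grid <- function(tallies, ring, by_center = FALSE) {
  stopifnot(inherits(tallies, "srs_tallies"))
  k <- if (by_center) ring_index(tallies$annuli, ring) else as.integer(ring)
  nr <- length(tallies$detected_weight_by_ring)
  if (k < 1 || k > nr) stop("ring index out of range", call. = FALSE)
  w <- tallies$detected_weight_by_ring[k]
  if (w <= 0)
    stop(sprintf("ring %d (center %.2f mm) detected no weight; increase n_photons",
                 k, tallies$annuli$centers[k]), call. = FALSE)
  if (!is.null(tallies$grid3d_by_ring) && k %in% tallies$grid3d_rings) {
    g <- tallies$grid3d_by_ring[[match(k, tallies$grid3d_rings)]]
    out <- g / w
    attr(out, "origin") <- tallies$grid3d_origin
    attr(out, "voxel_size") <- tallies$config$voxel_size
    out
  } else {
    tallies$path_weight_by_ring[, k] / w
  }
}

#' SRS sensitivity grid: far-detector minus near-detector mean path
#'
#' The SRS measurement sensitivity of a voxel is
#' `L_B(x,y,z) - L_A(x,y,z)` (mm), where A is the detector near the
#' source (distance rho1) and B the far one (rho2): a positive value
#' means an absorption increase in that voxel increases the measured
#' spatial slope.
#'
#' @param L_near Mean-path grid for the near ring (rho1).
#' @param L_far Mean-path grid for the far ring (rho2), same geometry.
#' @param pair Numeric `c(rho1, rho2)` recorded on the result.
#' @param voxel_size Voxel/slab size, mm (carried through for profiles).
#' @return An object of class `sensitivity_grid` wrapping `values`
#'   (vector over depth slabs, or 3-D array over voxels).
#' @export
sensitivity_grid <- function(L_near, L_far, pair = c(NA_real_, NA_real_),
                             voxel_size = NULL) {
  if (!identical(dim(L_near), dim(L_far)) ||
      length(L_near) != length(L_far))
    stop("near and far grids do not share geometry", call. = FALSE)
  if (is.null(voxel_size)) voxel_size <- attr(L_near, "voxel_size")
  structure(list(values = L_far - L_near, pair = as.numeric(pair),
                 voxel_size = voxel_size,
                 mode = if (is.null(dim(L_near))) "depth_profile" else "full_3d",
                 origin = attr(L_near, "origin")),
            class = "sensitivity_grid")
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf("SRS sensitivity grid (%s), pair %g-%g mm, total %.4g mm\n",
              x$mode, x$pair[1], x$pair[2], sum(x$values)))
  invisible(x)
}

#' Depth profile of the SRS measurement sensitivity
#'
#' The sensitivity at depth z is the sum of the sensitivities of all
#' voxels at that depth; the total over depths equals the grid total
#' exactly.
#'
#' @param x A `sensitivity_grid`, or an `srs_tallies` object together
#'   with `pair`.
#' @param pair When `x` is a tallies object: `c(rho1, rho2)` nominal
#'   ring centers, mm.
#' @return An object of class `depth_profile` with fields
#'   `depth_centers` (mm) and `sensitivity` (mm).
#' @export
depth_profile <- function(x, pair = NULL) {
  if (inherits(x, "srs_tallies")) {
    stopifnot(!is.null(pair), length(pair) == 2L)
    ln <- mean_path_grid(x, pair[1], by_center = TRUE)
    lf <- mean_path_grid(x, pair[2], by_center = TRUE)
    if (!is.null(dim(ln))) {  # gridded rings: sum laterally
      g <- sensitivity_grid(ln, lf, pair)
      return(depth_profile(g))
    }
    g <- sensitivity_grid(ln, lf, pair, voxel_size = x$config$voxel_size)
    return(structure(list(depth_centers = x$depth_centers,
                          sensitivity = g$values, pair = g$pair),
                     class = "depth_profile"))
  }
  stopifnot(inherits(x, "sensitivity_grid"))
  v <- x$values
  if (is.null(dim(v))) {
    sens <- as.numeric(v)
  } else {
    sens <- apply(v, 3, sum)
  }
  vox <- if (is.null(x$voxel_size)) NA_real_ else x$voxel_size
  structure(list(depth_centers = (seq_along(sens) - 0.5) * vox,
                 sensitivity = sens, pair = x$pair),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("SRS sensitivity depth profile, pair %g-%g mm, %d slabs, peak %.3g mm at %.2f mm\n",
              x$pair[1], x$pair[2], length(x$sensitivity),
              max(x$sensitivity), x$depth_centers[which.max(x$sensitivity)]))
  invisible(x)
}

#' @export
as.data.frame.depth_profile <- function(x, ...) {
  data.frame(depth = x$depth_centers, sensitivity = x$sensitivity)
}

#' @export
plot.depth_profile <- function(x, ...) {
  graphics::plot(x$depth_centers, x$sensitivity, type = "l",
                 xlab = "depth (mm)", ylab = "SRS sensitivity (mm)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

# Optional 3-point moving average (half-weighted ends), applied before
# peak finding when Monte Carlo noise dominates the profile.
.smooth3 <- function(ys) {
  n <- length(ys)
  if (n < 3) return(ys)
  out <- ys
  out[2:(n - 1)] <- (ys[1:(n - 2)] + ys[2:(n - 1)] + ys[3:n]) / 3
  out[1] <- (2 * ys[1] + ys[2]) / 3
  out[n] <- (ys[n - 1] + 2 * ys[n]) / 3
  out
}

# Parabolic refinement of a discrete argmax through the three samples
# around it; falls back to the raw argmax at the profile ends.
.refine_peak <- function(xs, ys) {
  i <- which.max(ys)
  if (i == 1L || i == length(ys)) return(xs[i])
  y1 <- ys[i - 1]; y2 <- ys[i]; y3 <- ys[i + 1]
  den <- y1 - 2 * y2 + y3
  if (den >= 0) return(xs[i])  # not locally concave; keep the sample
  delta <- 0.5 * (y1 - y3) / den
  delta <- max(-0.5, min(0.5, delta))
  xs[i] + delta * (xs[i] - xs[i - 1])
}

# Linearly interpolated crossing of `level` between samples j and j+1.
.cross_at <- function(xs, ys, j, level) {
  xs[j] + (level - ys[j]) * (xs[j + 1] - xs[j]) / (ys[j + 1] - ys[j])
}

#' Summary metrics of a sensitivity depth profile
#'
#' Reports the peak depth (parabolic refinement through the three
#' samples around the argmax), the depth range where the sensitivity
#' halves the maximum (outermost linearly interpolated crossings of
#' 0.5 x max bracketing the peak), and the first depth beyond the peak
#' where it falls to 10% of the maximum (linear interpolation).
#'
#' @param profile A `depth_profile`.
#' @return An object of class `profile_metrics` with fields
#'   `peak_depth`, `half_range_low`, `half_range_high`, `depth_10pct`
#'   (all mm; the 10% depth is `NA` if the profile never falls that far).
#' @export
profile_metrics <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  xs <- profile$depth_centers
  ys <- profile$sensitivity
  m <- max(ys)
  if (!is.finite(m) || m <= 0)
    stop("profile has no positive maximum", call. = FALSE)
  ipk <- which.max(ys)
  peak <- .refine_peak(xs, ys)

  half <- 0.5 * m
  above <- which(ys >= half)
  k1 <- min(above)  # outermost (shallowest) crossing bracketing the peak
  lo <- if (k1 == 1L) xs[1] else .cross_at(xs, ys, k1 - 1L, half)
  k2 <- max(above)  # outermost (deepest) crossing
  hi <- if (k2 == length(ys)) xs[length(xs)] else .cross_at(xs, ys, k2, half)

  ten <- 0.10 * m
  d10 <- NA_real_
  after10 <- which(ys < ten & seq_along(ys) > ipk)
  if (length(after10)) {
    j <- min(after10) - 1L
    d10 <- .cross_at(xs, ys, j, ten)
  }
  structure(list(peak_depth = peak, half_range_low = lo,
                 half_range_high = hi, depth_10pct = d10,
                 pair = profile$pair),
            class = "profile_metrics")
}

#' @export
print.profile_metrics <- function(x, ...) {
  cat(sprintf("pair %g-%g mm: peak %.2f mm, 50%% range %.2f-%.2f mm, 10%% depth %.2f mm\n",
              x$pair[1], x$pair[2], x$peak_depth, x$half_range_low,
              x$half_range_high, x$depth_10pct))
  invisible(x)
}

#' Normalized sensitivity-vs-depth map over near-detector positions
#'
#' For a fixed far distance rho2, sweeps the near distance rho1 from
#' `rho1_step` to `rho2 - rho1_step` on a regular grid, builds the
#' sensitivity depth profile of every (rho1, rho2) pair, normalizes each
#' curve to maximum 1, and records the peak measurement depth D_p per
#' curve. All pairs are read from a single simulation with fine annuli.
#'
#' @param model A [tissue_model()] (ignored when `tallies` is given).
#' @param rho2 Far source-detector distance, mm (>= 1).
#' @param config A [run_config()] (voxel 0.5 mm recommended).
#' @param tallies Optional precomputed `srs_tallies` from a run with
#'   [fine_annuli()] of width `rho1_step`; one run can serve every rho2.
#' @param rho1_step Near-distance grid step and ring width, mm.
#' @param wavelength Wavelength label (defaults as in [run_simulation()]).
#' @return An object of class `depth_map`: `rho2`, `rho1_values`,
#'   `depth_centers`, `normalized_curves` (rows = rho1 values),
#'   `peak_depths`.
#' @export
sweep_depth_map <- function(model = NULL, rho2, config = NULL, tallies = NULL,
                            rho1_step = 0.5, wavelength = NULL) {
  stopifnot(rho2 >= 1.0)
  if (is.null(tallies)) {
    stopifnot(inherits(model, "tissue_model"), inherits(config, "run_config"))
    ann <- fine_annuli(rho2, width = rho1_step)
    tallies <- run_simulation(model, config, ann, wavelength = wavelength)
  }
  rho1s <- seq(rho1_step, rho2 - rho1_step + 1e-9, by = rho1_step)
  lf <- mean_path_grid(tallies, rho2, by_center = TRUE)
  nz <- length(lf)
  curves <- matrix(NA_real_, nrow = length(rho1s), ncol = nz)
  peaks <- numeric(length(rho1s))
  for (i in seq_along(rho1s)) {
    ln <- mean_path_grid(tallies, rho1s[i], by_center = TRUE)
    prof <- structure(list(depth_centers = tallies$depth_centers,
                           sensitivity = lf - ln,
                           pair = c(rho1s[i], rho2)),
                      class = "depth_profile")
    m <- max(prof$sensitivity)
    if (m <= 0)
      stop(sprintf("pair %g-%g mm has no positive sensitivity", rho1s[i], rho2),
           call. = FALSE)
    curves[i, ] <- prof$sensitivity / m
    peaks[i] <- .refine_peak(prof$depth_centers, prof$sensitivity)
  }
  structure(list(rho2 = rho2, rho1_values = rho1s,
                 depth_centers = tallies$depth_centers,
                 normalized_curves = curves, peak_depths = peaks,
                 model_label = tallies$model_label),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("depth map, rho2 = %g mm, %d rho1 values (%g..%g mm), D_p %.2f..%.2f mm\n",
              x$rho2, length(x$rho1_values), min(x$rho1_values),
              max(x$rho1_values), min(x$peak_depths), max(x$peak_depths)))
  invisible(x)
}

#' @export
as.data.frame.depth_map <- function(x, ...) {
  data.frame(rho1 = x$rho1_values, rho2 = x$rho2, peak_depth = x$peak_depths)
}

#' Regression of the peak measurement depth on the two detector distances
#'
#' Pools the (rho1, rho2, D_p) points of one or more depth maps and fits
#' ordinary least squares `D_p ~ rho1 + rho2` with intercept, the model
#' behind the linear peak-depth calibration of the probe family.
#'
#' @param maps A `depth_map`, a list of them, or a data frame with
#'   columns `rho1`, `rho2`, `peak_depth`.
#' @return An object of class `dp_regression` wrapping the `lm` fit,
#'   with `coef`, `print`, `summary`, `predict` and `residuals` methods.
#' @export
fit_dp_regression <- function(maps) {
  if (inherits(maps, "depth_map")) maps <- list(maps)
  if (is.data.frame(maps)) {
    pts <- maps
  } else {
    stopifnot(is.list(maps), length(maps) >= 1L)
    pts <- do.call(rbind, lapply(maps, as.data.frame))
  }
  stopifnot(all(c("rho1", "rho2", "peak_depth") %in% names(pts)))
  if (nrow(pts) < 3L)
    stop("need at least 3 (rho1, rho2, D_p) points", call. = FALSE)
  if (length(unique(pts$rho1)) < 2L || length(unique(pts$rho2)) < 2L)
    stop("design is rank deficient: points must span both rho1 and rho2",
         call. = FALSE)
  fit <- stats::lm(peak_depth ~ rho1 + rho2, data = pts)
  structure(list(
    coef_rho1 = unname(coef(fit)["rho1"]),
    coef_rho2 = unname(coef(fit)["rho2"]),
    intercept = unname(coef(fit)["(Intercept)"]),
    rmse = sqrt(mean(residuals(fit)^2)),
    n_points = nrow(pts),
    fit = fit, points = pts
  ), class = "dp_regression")
}

#' @export
print.dp_regression <- function(x, ...) {
  cat(sprintf("D_p = %.3f rho1 + %.3f rho2 + %.2f  (mm; %d points, RMSE %.3f mm)\n",
              x$coef_rho1, x$coef_rho2, x$intercept, x$n_points, x$rmse))
  invisible(x)
}

#' @export
coef.dp_regression <- function(object, ...) {
  c(intercept = object$intercept, rho1 = object$coef_rho1,
    rho2 = object$coef_rho2)
}

#' @export
summary.dp_regression <- function(object, ...) summary(object$fit, ...)

#' @export
predict.dp_regression <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$points
  predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.dp_regression <- function(object, ...) residuals(object$fit, ...)
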