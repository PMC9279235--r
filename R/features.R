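# 3D binary morphology helpers on logical arrays (face connectivity).

shift3 <- function(arr, dx, dy, dz, fill = FALSE) {
  dims <- dim(arr)
  out <- array(fill, dims)
  sx <- seq_len(dims[1]); sy <- seq_len(dims[2]); sz <- seq_len(dims[3])
  fx <- sx - dx; fy <- sy - dy; fz <- sz - dz
  okx <- fx >= 1 & fx <= dims[1]
  oky <- fy >= 1 & fy <= dims[2]
  okz <- fz >= 1 & fz <= dims[3]
  out[sx[okx], sy[oky], sz[okz]] <- arr[fx[okx], fy[oky], fz[okz]]
  out
}

erode6 <- function(arr) {
  out <- arr
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    out <- out & shift3(arr, o[1], o[2], o[3], fill = FALSE)
  }
  out
}

dilate6 <- function(arr) {
  out <- arr
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    out <- out | shift3(arr, o[1], o[2], o[3], fill = FALSE)
  }
  out
}

# 3x3x3 box mean filter (separable, edge-renormalised). The surrogate
# smooths its input before measuring intensities, the fixed-feature analog
# of the local averaging a convolutional model's early layers learn, so
# acquisition noise does not degrade the intensity readout of unablated
# windows relative to noise-free ablated ones.
box3 <- function(v) {
  ones <- array(1, dim(v))
  axis_mean <- function(a, axis) {
    o1 <- c(0, 0, 0); o1[axis] <- 1
    num <- a + shift3(a, o1[1], o1[2], o1[3], fill = 0) +
      shift3(a, -o1[1], -o1[2], -o1[3], fill = 0)
    den <- ones + shift3(ones, o1[1], o1[2], o1[3], fill = 0) +
      shift3(ones, -o1[1], -o1[2], -o1[3], fill = 0)
    num / den
  }
  axis_mean(axis_mean(axis_mean(v, 1), 2), 3)
}

#' Fixed image features of a classifier window
#'
#' Deterministic feature vector standing in for learned CNN features. The
#' window is first smoothed with a 3x3x3 mean filter; the smoothed signal
#' provides intensity moments and histogram quantiles, low-density tail
#' fractions (emphysema-pocket burden), gradient-magnitude statistics, a
#' radial mean-intensity profile, and shape descriptors of the largest
#' above-threshold connected component (volume proxy, maximal per-slice
#' extent, surface-to-volume ratio, compactness, sphericity, convex
#' deficiency of the largest axial slice, spike count and residue fraction
#' of a one-step morphological opening, component mean density). The
#' smoothing residual provides texture features (global and
#' within-component SD). The function sees only the HU values of the
#' window; it has no access to the ground-truth mask or the label.
#'
#' @param patch A cubic `ct_volume` window.
#' @param threshold_hu Foreground threshold separating nodule-like tissue
#'   from aerated lung; the default -600 HU sits between ground-glass and
#'   parenchyma densities.
#' @return Named numeric feature vector.
#' @export
featurize <- function(patch, threshold_hu = -600) {
  stopifnot(inherits(patch, "ct_volume"))
  dims <- dim(patch$values)
  ext <- dims * patch$spacing
  if (max(ext) - min(ext) > max(patch$spacing)) {
    abort("`patch` must be (physically) cubic.")
  }
  raw <- patch$values
  v <- box3(raw)
  resid <- raw - v
  mu <- mean(v)
  s <- stats::sd(as.vector(v))
  skew <- if (s > 0) mean((v - mu)^3) / s^3 else 0
  qs <- quantile(v, c(.01, .05, .10, .25, .50, .75, .90, .95, .99), names = FALSE)

  # gradient magnitude by central differences on the smoothed interior
  gmag <- 0
  if (all(dims >= 3)) {
    ix <- 2:(dims[1] - 1); iy <- 2:(dims[2] - 1); iz <- 2:(dims[3] - 1)
    gx <- (v[ix + 1, iy, iz] - v[ix - 1, iy, iz]) / (2 * patch$spacing[1])
    gy <- (v[ix, iy + 1, iz] - v[ix, iy - 1, iz]) / (2 * patch$spacing[2])
    gz <- (v[ix, iy, iz + 1] - v[ix, iy, iz - 1]) / (2 * patch$spacing[3])
    gmag <- sqrt(gx^2 + gy^2 + gz^2)
  }
  g_mean <- mean(gmag)
  g_sd <- if (length(gmag) > 1) stats::sd(as.vector(gmag)) else 0
  g_p90 <- as.numeric(quantile(gmag, 0.9, names = FALSE))

  # largest above-threshold component of the raw window: parenchyma noise
  # never crosses the nodule/lung threshold, and raw segmentation keeps
  # thin spiculation spikes that smoothing would erase
  fg <- raw > threshold_hu
  comp_feats <- c(comp_volume_mm3 = 0, comp_esd_mm = 0, comp_max_extent_mm = 0,
                  comp_surface_to_volume = 0, comp_compactness = 0,
                  comp_sphericity = 0, comp_residue_fraction = 0,
                  comp_convex_deficiency = 0,
                  comp_spike_count = 0, comp_mean_hu = -1024, comp_sd_hu = 0)
  if (any(fg)) {
    lab <- label_components(fg)
    comp_full <- lab == 1L
    comp <- comp_full
    # morphology and per-slice shape work on the component's padded
    # bounding box; results are identical, allocations much smaller
    cix <- which(comp, arr.ind = TRUE)
    lo <- pmax(apply(cix, 2, min) - 1L, 1L)
    hi <- pmin(apply(cix, 2, max) + 1L, dims)
    comp <- comp[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    cdims <- dim(comp)
    nvx <- sum(comp)
    voxvol <- prod(patch$spacing)
    vol_mm3 <- nvx * voxvol
    esd <- (6 * vol_mm3 / pi)^(1 / 3)
    # maximal per-slice bounding-box diagonal
    ext_best <- 0
    slice_areas <- numeric(cdims[3])
    for (k in seq_len(cdims[3])) {
      sl <- matrix(comp[, , k], cdims[1], cdims[2])
      slice_areas[k] <- sum(sl)
      if (!any(sl)) next
      ij <- which(sl, arr.ind = TRUE)
      dx <- (diff(range(ij[, 1])) + 1) * patch$spacing[1]
      dy <- (diff(range(ij[, 2])) + 1) * patch$spacing[2]
      ext_best <- max(ext_best, sqrt(dx^2 + dy^2))
    }
    boundary <- comp & !erode6(comp)
    opened <- dilate6(erode6(comp))
    residue <- comp & !opened
    spike_count <- 0
    if (any(residue)) {
      rl <- label_components(residue)
      if (max(rl) > 0) {
        sizes <- tabulate(rl[rl > 0])
        spike_count <- sum(sizes >= 2)
      }
    }
    compact <- vol_mm3 / (pi / 6 * max(ext_best, patch$spacing[1])^3)
    # dimensionless margin-irregularity descriptors (size-decorrelated):
    # sphericity compares exposed surface area with the volume-matched
    # sphere; the residue fraction measures how much of the component a
    # one-step opening removes; convex deficiency is evaluated on the
    # largest axial slice
    area <- 0
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      exposed <- comp & !shift3(comp, o[1], o[2], o[3], fill = FALSE)
      face <- prod(patch$spacing) / patch$spacing[which(o != 0)]
      area <- area + sum(exposed) * face
    }
    sphericity <- (pi^(1 / 3) * (6 * vol_mm3)^(2 / 3)) / max(area, 1e-9)
    residue_fraction <- sum(residue) / nvx
    kbest <- which.max(slice_areas)
    convex_deficiency <- 0
    ij <- which(matrix(comp[, , kbest], cdims[1], cdims[2]), arr.ind = TRUE)
    if (nrow(ij) >= 3) {
      pts <- cbind(ij[, 1] * patch$spacing[1], ij[, 2] * patch$spacing[2])
      hull <- grDevices::chull(pts)
      hp <- pts[hull, , drop = FALSE]
      hull_area <- abs(sum(hp[, 1] * c(hp[-1, 2], hp[1, 2]) -
                             c(hp[-1, 1], hp[1, 1]) * hp[, 2])) / 2
      slice_area <- slice_areas[kbest] * patch$spacing[1] * patch$spacing[2]
      if (hull_area > 0) {
        convex_deficiency <- max(0, 1 - slice_area / hull_area)
      }
    }
    comp_feats <- c(comp_volume_mm3 = vol_mm3, comp_esd_mm = esd,
                    comp_max_extent_mm = ext_best,
                    comp_surface_to_volume = sum(boundary) / nvx,
                    comp_compactness = compact,
                    comp_sphericity = sphericity,
                    comp_residue_fraction = residue_fraction,
                    comp_convex_deficiency = convex_deficiency,
                    comp_spike_count = spike_count,
                    comp_mean_hu = mean(raw[comp_full]),
                    comp_sd_hu = if (nvx > 1) stats::sd(raw[comp_full]) else 0)
  }

  # radial mean-intensity profile around the window centre
  ctr <- index_to_world(patch, (dims + 1) / 2)
  xs <- axis_coords(patch, 1) - ctr[1]
  ys <- axis_coords(patch, 2) - ctr[2]
  zs <- axis_coords(patch, 3) - ctr[3]
  r <- sqrt(outer(outer(xs^2, ys^2, "+"), zs^2, "+"))
  rmax <- min(ext) / 2
  shell <- findInterval(r / rmax, c(0.25, 0.5, 0.75, 1)) + 1
  prof <- vapply(1:4, function(b) {
    sel <- shell == b
    if (any(sel)) mean(v[sel]) else -1024
  }, numeric(1))

  c(hu_mean = mu, hu_sd = s, hu_skew = skew,
    stats::setNames(qs, paste0("hu_q", c("01", "05", "10", "25", "50", "75",
                                         "90", "95", "99"))),
    frac_below_m880 = mean(v < -880),
    frac_below_m860 = mean(v < -860),
    texture_sd = stats::sd(as.vector(resid)),
    grad_mean = g_mean, grad_sd = g_sd, grad_p90 = g_p90,
    comp_feats,
    stats::setNames(prof, paste0("radial_mean_hu_", 1:4)))
}
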