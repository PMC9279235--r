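#' Nodule volume from a binary mask
#'
#' Volume is the number of foreground voxels times the physical voxel
#' volume `dx * dy * dz`.
#'
#' @param mask A `nodule_mask`, or a binary 3D array (then `spacing` is
#'   required).
#' @param spacing Voxel spacing in mm when `mask` is a bare array.
#' @return Volume in mm^3.
#' @export
nodule_volume <- function(mask, spacing = NULL) {
  m <- resolve_mask(mask, spacing)
  n <- sum(m$arr)
  if (n == 0) abort("Mask is empty; volume is undefined.")
  n * prod(m$spacing)
}

#' Equivalent spherical diameter
#'
#' Diameter of the sphere whose volume equals the nodule's:
#' `ESD = (6 V / pi)^(1/3)`.
#'
#' @param volume_mm3 Volume in mm^3, strictly positive.
#' @return Diameter in mm.
#' @export
equivalent_spherical_diameter <- function(volume_mm3) {
  if (any(!is.finite(volume_mm3)) || any(volume_mm3 <= 0)) {
    abort("`volume_mm3` must be strictly positive.")
  }
  (6 * volume_mm3 / pi)^(1 / 3)
}

# Footprint corners (mm, in-plane) of set voxels on one axial slice.
# Each voxel's physical footprint is a dx-by-dy rectangle centred on the
# voxel centre; its 4 corners define the rendered boundary, so a single
# voxel has a positive (diagonal) diameter.
slice_corners <- function(slice, spacing, origin = c(0, 0)) {
  # only boundary voxels can contribute hull corners; interior-voxel
  # corners lie strictly inside the footprint polygon
  if (any(slice)) {
    nr <- nrow(slice); nc <- ncol(slice)
    pad <- matrix(FALSE, nr + 2, nc + 2)
    pad[2:(nr + 1), 2:(nc + 1)] <- slice
    interior <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
      pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
    slice <- slice & !interior
  }
  ij <- which(slice, arr.ind = TRUE)
  if (nrow(ij) == 0) return(matrix(numeric(0), ncol = 2))
  cx <- origin[1] + (ij[, 1] - 1) * spacing[1]
  cy <- origin[2] + (ij[, 2] - 1) * spacing[2]
  hx <- spacing[1] / 2
  hy <- spacing[2] / 2
  pts <- cbind(x = c(cx - hx, cx - hx, cx + hx, cx + hx),
               y = c(cy - hy, cy + hy, cy - hy, cy + hy))
  unique(pts)
}

max_pairwise_points <- function(pts) {
  if (nrow(pts) == 1) return(0)
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  d2 <- outer(hp[, 1], hp[, 1], "-")^2 + outer(hp[, 2], hp[, 2], "-")^2
  sqrt(max(d2))
}

#' Maximal axial diameter, pairwise method
#'
#' On every axial (constant-z) slice the boundary is taken as the set of
#' voxel-footprint corners of the slice's foreground voxels; the slice
#' diameter is the largest pairwise distance between corners (computed on
#' the convex hull), and the returned value is the maximum over slices, in
#' mm. This is the "calliper" reading of maximal axial diameter; it is
#' sensitive to spiculation because spike tips enter the boundary.
#'
#' @inheritParams nodule_volume
#' @return Diameter in mm.
#' @export
max_pairwise_axial_diameter <- function(mask, spacing = NULL) {
  m <- resolve_mask(mask, spacing)
  if (!any(m$arr)) abort("Mask is empty; diameter is undefined.")
  best <- 0
  for (k in seq_len(dim(m$arr)[3])) {
    sl <- matrix(m$arr[, , k], dim(m$arr)[1], dim(m$arr)[2])
    if (!any(sl)) next
    pts <- slice_corners(sl, m$spacing[1:2])
    best <- max(best, max_pairwise_points(pts))
  }
  best
}

# Sub-voxel boundary contour of one binary slice at membership level 0.5.
# The slice is zero-padded so contours close around shapes touching the
# array edge. Returns a list of contours, each a 2-column matrix (mm).
slice_contours <- function(slice, spacing) {
  nx <- nrow(slice); ny <- ncol(slice)
  padded <- matrix(0, nx + 2, ny + 2)
  padded[2:(nx + 1), 2:(ny + 1)] <- slice + 0
  xs <- ((0:(nx + 1)) - 1) * spacing[1]
  ys <- ((0:(ny + 1)) - 1) * spacing[2]
  cl <- grDevices::contourLines(xs, ys, padded, levels = 0.5)
  lapply(cl, function(c1) cbind(c1$x, c1$y))
}

# Direct least-squares ellipse fit to 2D points (conic-constrained,
# numerically stable block decomposition). Returns NULL when the fit is
# degenerate or not an ellipse; otherwise c(major, minor) full axis lengths.
fit_ellipse_axes <- function(pts) {
  if (nrow(pts) < 6) return(NULL)
  x <- pts[, 1] - mean(pts[, 1])
  y <- pts[, 2] - mean(pts[, 2])
  d1 <- cbind(x^2, x * y, y^2)
  d2 <- cbind(x, y, 1)
  s1 <- crossprod(d1)
  s2 <- crossprod(d1, d2)
  s3 <- crossprod(d2)
  t0 <- tryCatch(-solve(s3, t(s2)), error = function(e) NULL)
  if (is.null(t0)) return(NULL)
  m0 <- s1 + s2 %*% t0
  m <- rbind(m0[3, ] / 2, -m0[2, ], m0[1, ] / 2)
  ev <- tryCatch(eigen(m), error = function(e) NULL)
  if (is.null(ev)) return(NULL)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 1e-12)
  if (length(ok) == 0) return(NULL)
  a1 <- vecs[, ok[1]]
  coefs <- c(a1, t0 %*% a1)   # A, B, C, D, E, F with conic Ax^2+Bxy+Cy^2+Dx+Ey+F
  A <- coefs[1]; B <- coefs[2] / 2; C <- coefs[3]
  D <- coefs[4] / 2; E <- coefs[5] / 2; F <- coefs[6]
  den <- B^2 - A * C
  if (abs(den) < 1e-14) return(NULL)
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - 2 * B * D * E - A * C * F)
  s <- sqrt((A - C)^2 + 4 * B^2)
  ax1 <- num / (den * (s - (A + C)))
  ax2 <- num / (den * (-s - (A + C)))
  if (!is.finite(ax1) || !is.finite(ax2) || ax1 <= 0 || ax2 <= 0) return(NULL)
  axes <- 2 * sqrt(sort(c(ax1, ax2), decreasing = TRUE))
  axes
}

#' Maximal axial diameter, ellipse-fit method
#'
#' On every axial slice a sub-voxel boundary contour is traced at the 0.5
#' membership level and an ellipse is fitted to it by direct
#' conic-constrained least squares; the slice diameter is the fitted
#' ellipse's major axis, and the maximum over slices is returned (mm).
#' Because the least-squares ellipse averages over the whole contour it is
#' less sensitive to spiculation than the pairwise method. Slices whose
#' contour has fewer than 6 points, or whose fit is degenerate, fall back to
#' the pairwise diameter for that slice.
#'
#' @inheritParams nodule_volume
#' @return Diameter in mm.
#' @export
ellipse_fit_axial_diameter <- function(mask, spacing = NULL) {
  m <- resolve_mask(mask, spacing)
  if (!any(m$arr)) abort("Mask is empty; diameter is undefined.")
  best <- 0
  for (k in seq_len(dim(m$arr)[3])) {
    sl <- matrix(m$arr[, , k], dim(m$arr)[1], dim(m$arr)[2])
    if (!any(sl)) next
    conts <- slice_contours(sl, m$spacing[1:2])
    d_slice <- NA_real_
    if (length(conts) > 0) {
      # the outer boundary is the longest contour
      main <- conts[[which.max(vapply(conts, nrow, integer(1)))]]
      axes <- fit_ellipse_axes(main)
      if (!is.null(axes)) d_slice <- axes[1]
    }
    if (is.na(d_slice)) {
      pts <- slice_corners(sl, m$spacing[1:2])
      d_slice <- max_pairwise_points(pts)
    }
    best <- max(best, d_slice)
  }
  best
}

#' Measure one nodule
#'
#' Computes volume, equivalent spherical diameter, and both maximal axial
#' diameter estimators for a single mask, returning one tibble row ready to
#' bind into a per-nodule measurement table.
#'
#' @inheritParams nodule_volume
#' @param methods Character subset of
#'   `c("esd", "pairwise", "ellipse")`; the ellipse fit is the most
#'   expensive and can be dropped for large batch runs.
#' @return A one-row tibble with columns `volume_mm3`, `esd_mm`,
#'   `axial_diameter_pairwise_mm`, `axial_diameter_ellipse_mm` (NA when not
#'   requested).
#' @export
measure_nodule <- function(mask, spacing = NULL,
                           methods = c("esd", "pairwise", "ellipse")) {
  methods <- match.arg(methods, several.ok = TRUE)
  v <- nodule_volume(mask, spacing)
  tibble(
    volume_mm3 = v,
    esd_mm = if ("esd" %in% methods) equivalent_spherical_diameter(v) else NA_real_,
    axial_diameter_pairwise_mm =
      if ("pairwise" %in% methods) max_pairwise_axial_diameter(mask, spacing) else NA_real_,
    axial_diameter_ellipse_mm =
      if ("ellipse" %in% methods) ellipse_fit_axial_diameter(mask, spacing) else NA_real_
  )
}
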