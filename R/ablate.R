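#' Ablation specification
#'
#' Parameters of the three information-ablation operators. `mode`
#' identifies the operator: `parenchyma_only` translates the evaluated
#' window 15 mm (by default) beyond the furthermost nodule edge toward the
#' hilum, leaving background lung only; `uniform_density` replaces the
#' background with a fixed lung density (-825 HU by default) and the nodule
#' interior with its mean density, preserving mask geometry;
#' `implant_sphere` places a volume-matched sphere of mean nodule density
#' into the parenchyma-only window. `none` denotes the unmodified window
#' around the nodule.
#'
#' @param mode One of `"none"`, `"parenchyma_only"`, `"uniform_density"`,
#'   `"implant_sphere"`.
#' @param hilum_offset_mm Offset beyond the nodule margin toward the hilum,
#'   mm (> 0).
#' @param lung_fill_hu Replacement background density, HU.
#' @param patch_extent_mm Side of the cubic window handed to the
#'   classifier; must exceed the largest expected nodule.
#' @return A list of class `ablation_spec`.
#' @export
ablation_spec <- function(mode = c("none", "parenchyma_only",
                                   "uniform_density", "implant_sphere"),
                          hilum_offset_mm = 15,
                          lung_fill_hu = -825,
                          patch_extent_mm = 40) {
  mode <- match.arg(mode)
  if (hilum_offset_mm <= 0) abort("`hilum_offset_mm` must be positive.")
  if (patch_extent_mm <= 0) abort("`patch_extent_mm` must be positive.")
  structure(list(mode = mode, hilum_offset_mm = hilum_offset_mm,
                 lung_fill_hu = lung_fill_hu,
                 patch_extent_mm = patch_extent_mm),
            class = "ablation_spec")
}

#' Mean nodule density
#'
#' Arithmetic mean HU over all mask voxels.
#'
#' @param volume A `ct_volume`.
#' @param mask A congruent `nodule_mask` (or binary array).
#' @return Mean density in HU.
#' @export
mean_nodule_density <- function(volume, mask) {
  stopifnot(inherits(volume, "ct_volume"))
  m <- mask_binary(mask)
  stopifnot(identical(dim(m), dim(volume$values)))
  if (!any(m)) abort("Mask is empty; mean density is undefined.")
  mean(volume$values[m])
}

#' Uniform-density ablation
#'
#' Replaces every background voxel with `spec$lung_fill_hu` and every
#' nodule voxel with the mean density of the original nodule, erasing all
#' internal texture and background structure while leaving the mask
#' geometry (size, margin shape, component split) untouched. When the mask
#' carries component labels (solid core = 1, part-solid shell = 2) and
#' `per_component = TRUE`, each component is filled with its own mean so
#' the nodule-type cue stays visible; with `per_component = FALSE` a single
#' global mean is used.
#'
#' @inheritParams mean_nodule_density
#' @param spec An [ablation_spec()].
#' @param per_component Fill each mask component with its own mean.
#' @return A `ct_volume` with at most `1 + n_components` distinct values.
#' @export
uniform_density_ablation <- function(volume, mask,
                                     spec = ablation_spec("uniform_density"),
                                     per_component = TRUE) {
  stopifnot(inherits(volume, "ct_volume"))
  labels <- if (inherits(mask, "ct_volume")) mask$values else as.array(mask)
  stopifnot(identical(dim(labels), dim(volume$values)))
  if (!any(labels > 0)) abort("Mask is empty; nothing to ablate.")
  out <- volume
  vals <- array(spec$lung_fill_hu, dim(volume$values))
  if (per_component) {
    for (comp in setdiff(sort(unique(as.vector(labels))), 0)) {
      sel <- labels == comp
      vals[sel] <- mean(volume$values[sel])
    }
  } else {
    sel <- labels > 0
    vals[sel] <- mean(volume$values[sel])
  }
  out$values <- vals
  out
}

# Geometry shared by the translated-window operators: unit direction from
# the mask centroid to the hilum, and the mask surface point furthest along
# that direction.
hilum_geometry <- function(mask, hilum_point_mm) {
  stopifnot(inherits(mask, "ct_volume"))
  m <- mask_binary(mask)
  idx <- which(m, arr.ind = TRUE)
  ctr_mm <- colMeans(
    sweep(sweep(idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+"))
  ctr_mm <- unname(ctr_mm)
  u <- as.numeric(hilum_point_mm) - ctr_mm
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) abort("Hilum landmark coincides with the nodule centroid.")
  u <- u / nu
  pts <- sweep(sweep(idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
  proj <- pts %*% u
  p <- pts[which.max(proj), ]
  list(centroid = ctr_mm, u = u, surface_point = unname(as.numeric(p)))
}

#' Parenchyma-only window
#'
#' Extracts a cubic window of background lung that contains no part of the
#' nodule: the window is centred `hilum_offset_mm` beyond the mask surface
#' point that lies furthest along the direction from the nodule centroid to
#' the hilum landmark. If the window at the nominal offset would still
#' overlap the mask, the offset is increased in 1 mm steps until the window
#' and mask are disjoint; the realised offset is recorded in the
#' `realized_offset_mm` attribute of the result. Errors if the window
#' leaves the volume, naming the deficit.
#'
#' @inheritParams mean_nodule_density
#' @param hilum_point_mm World coordinate of the hilum landmark.
#' @param spec An [ablation_spec()]; `patch_extent_mm` sets the window
#'   side.
#' @return A `ct_volume` window with attributes `realized_offset_mm` and
#'   `center_mm`.
#' @export
parenchyma_only_patch <- function(volume, mask, hilum_point_mm,
                                  spec = ablation_spec("parenchyma_only")) {
  stopifnot(inherits(volume, "ct_volume"))
  geo <- hilum_geometry(mask, hilum_point_mm)
  m <- mask_binary(mask)
  offset <- spec$hilum_offset_mm
  repeat {
    center <- geo$surface_point + offset * geo$u
    patch <- extract_patch(volume, center, spec$patch_extent_mm)
    mpatch <- extract_patch(mask, center, spec$patch_extent_mm)
    if (!any(mask_binary(mpatch))) break
    offset <- offset + 1
    if (offset > 10 * spec$patch_extent_mm) {
      abort("Could not find a nodule-free window; geometry exhausted.")
    }
  }
  attr(patch, "realized_offset_mm") <- offset
  attr(patch, "center_mm") <- geo$surface_point + offset * geo$u
  patch
}

# Rasterize a sphere at `center_mm` on the patch grid. The radius is
# calibrated by bisection on the voxelised count; because the grid is
# symmetric about the patch centre, whole shells of equivalent voxels
# enter at once, so ties on the boundary shell are then resolved
# deterministically (by linear index) to match the target count to within
# one voxel.
calibrate_sphere <- function(patch, center_mm, target_mm3) {
  dims <- dim(patch$values)
  xs <- axis_coords(patch, 1) - center_mm[1]
  ys <- axis_coords(patch, 2) - center_mm[2]
  zs <- axis_coords(patch, 3) - center_mm[3]
  d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  voxvol <- prod(patch$spacing)
  lo <- 0
  hi <- max(patch$spacing) * max(dims) / 2
  count_at <- function(r) sum(d2 <= r^2)
  target_n <- max(1L, as.integer(round(target_mm3 / voxvol)))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (count_at(mid) < target_n) lo <- mid else hi <- mid
  }
  inside <- d2 <= lo^2
  n <- sum(inside)
  if (n < target_n) {
    # complete the boundary shell in deterministic order
    shell <- which(!inside & d2 <= hi^2)
    shell <- shell[order(d2[shell], shell)]
    inside[shell[seq_len(min(target_n - n, length(shell)))]] <- TRUE
  }
  list(inside = inside, radius = sqrt(max(d2[inside])), n = sum(inside))
}

#' Sphere implantation
#'
#' Builds the parenchyma-only window and implants at its centre a sphere of
#' the same volume as the nodule, filled with the nodule's mean density.
#' The sphere radius is calibrated by bisection on the rasterised voxel
#' count, with deterministic tie-breaking on the boundary shell, so the
#' implanted volume matches the measured nodule volume to within one
#' voxel. Size and mean density survive the ablation; margin shape,
#' internal texture, and the core/shell split do not.
#'
#' @inheritParams parenchyma_only_patch
#' @return A `ct_volume` window with attributes `sphere_radius_mm`,
#'   `implant_mean_hu`, `realized_offset_mm`, and `center_mm`.
#' @export
implant_sphere <- function(volume, mask, hilum_point_mm,
                           spec = ablation_spec("implant_sphere")) {
  patch <- parenchyma_only_patch(volume, mask, hilum_point_mm, spec)
  target <- nodule_volume(mask)
  dens <- mean_nodule_density(volume, mask)
  center <- index_to_world(patch, (dim(patch$values) + 1) / 2)
  cal <- calibrate_sphere(patch, center, target)
  if (2 * cal$radius > spec$patch_extent_mm) {
    abort(sprintf("Calibrated sphere (diameter %.1f mm) exceeds the %.0f mm window.",
                  2 * cal$radius, spec$patch_extent_mm))
  }
  patch$values[cal$inside] <- dens
  attr(patch, "sphere_radius_mm") <- cal$radius
  attr(patch, "implant_mean_hu") <- dens
  patch
}

#' Apply one ablation condition and return the classifier window
#'
#' Dispatcher used by the experiment pipeline: returns the cubic window for
#' a (volume, mask, hilum) triple under the requested condition. For
#' `none` and `uniform_density` the window is centred on the nodule
#' centroid; for `parenchyma_only` and `implant_sphere` it is the
#' translated window toward the hilum.
#'
#' @inheritParams parenchyma_only_patch
#' @param per_component Passed to [uniform_density_ablation()].
#' @return A `ct_volume` window of side `spec$patch_extent_mm`.
#' @export
apply_ablation <- function(volume, mask, hilum_point_mm, spec,
                           per_component = TRUE) {
  stopifnot(inherits(spec, "ablation_spec"))
  geo_center <- function() {
    m <- mask_binary(mask)
    idx <- which(m, arr.ind = TRUE)
    unname(colMeans(
      sweep(sweep(idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")))
  }
  switch(spec$mode,
    none = extract_patch(volume, geo_center(), spec$patch_extent_mm),
    uniform_density = extract_patch(
      uniform_density_ablation(volume, mask, spec, per_component),
      geo_center(), spec$patch_extent_mm),
    parenchyma_only = parenchyma_only_patch(volume, mask, hilum_point_mm, spec),
    implant_sphere = implant_sphere(volume, mask, hilum_point_mm, spec)
  )
}
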