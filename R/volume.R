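#' CT volumes and nodule masks
#'
#' A `ct_volume` is a 3D grid of Hounsfield-unit values with physical voxel
#' spacing and a world-coordinate origin (the centre of voxel `[1, 1, 1]`,
#' in mm). Axial slices are constant-z planes. A `nodule_mask` is a congruent
#' integer grid in which `0` marks background and positive integers mark
#' nodule membership; for part-solid nodules the solid core is labelled `1`
#' and the sub-solid shell `2`, so component-aware operators can treat them
#' separately. `as.logical`-style binary membership is available through
#' [mask_binary()].
#'
#' @param values 3D numeric array (HU for volumes; component labels for
#'   masks).
#' @param spacing Numeric length-3 voxel spacing `(dx, dy, dz)` in mm, all
#'   strictly positive.
#' @param origin Numeric length-3 world coordinate (mm) of the centre of
#'   voxel `[1, 1, 1]`.
#' @return An object of class `ct_volume` (and additionally `nodule_mask`
#'   for masks).
#' @export
ct_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3 || any(dim(values) == 0)) {
    abort("`values` must be a nonempty 3D array.")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three strictly positive numbers (mm).")
  }
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3, all(is.finite(origin)))
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @rdname ct_volume
#' @export
nodule_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  vol <- ct_volume(values, spacing, origin)
  if (any(vol$values < 0) || any(vol$values != round(vol$values))) {
    abort("Mask values must be nonnegative integer component labels.")
  }
  class(vol) <- c("nodule_mask", "ct_volume")
  vol
}

#' @export
print.ct_volume <- function(x, ...) {
  kind <- if (inherits(x, "nodule_mask")) "nodule_mask" else "ct_volume"
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s) mm\n",
              kind, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  if (inherits(x, "nodule_mask")) {
    cat(sprintf("  %d foreground voxels in %d component label(s)\n",
                sum(x$values > 0), length(setdiff(unique(as.vector(x$values)), 0))))
  } else {
    cat(sprintf("  HU range [%s, %s]\n", min(x$values), max(x$values)))
  }
  invisible(x)
}

#' @rdname ct_volume
#' @param mask A `nodule_mask` or integer/logical 3D array.
#' @export
mask_binary <- function(mask) {
  arr <- if (inherits(mask, "ct_volume")) mask$values else as.array(mask)
  arr > 0
}

# Accept a nodule_mask object or a raw array + spacing; return list(arr, spacing, origin).
resolve_mask <- function(mask, spacing = NULL) {
  if (inherits(mask, "ct_volume")) {
    list(arr = mask$values > 0, labels = mask$values,
         spacing = mask$spacing, origin = mask$origin)
  } else {
    if (is.null(spacing)) abort("`spacing` is required when `mask` is a bare array.")
    arr <- as.array(mask)
    list(arr = arr > 0, labels = arr, spacing = as.numeric(spacing),
         origin = c(0, 0, 0))
  }
}

#' World/voxel coordinate helpers
#'
#' Voxel index `i` (1-based) along axis `a` sits at world coordinate
#' `origin[a] + (i - 1) * spacing[a]`.
#'
#' @param vol A `ct_volume`.
#' @param axis Axis index 1..3.
#' @return `axis_coords()`: numeric vector of voxel-centre world coordinates.
#' @export
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$values)[axis]) - 1) * vol$spacing[axis]
}

#' @rdname axis_coords
#' @param point_mm World coordinate (length-3, mm).
#' @return `world_to_index()`: nearest voxel index (length-3 integer).
#' @export
world_to_index <- function(vol, point_mm) {
  idx <- round((as.numeric(point_mm) - vol$origin) / vol$spacing) + 1
  as.integer(idx)
}

#' @rdname axis_coords
#' @param index Voxel index (length-3).
#' @return `index_to_world()`: world coordinate of the voxel centre.
#' @export
index_to_world <- function(vol, index) {
  vol$origin + (as.numeric(index) - 1) * vol$spacing
}

#' Extract a cubic patch around a world point
#'
#' Crops an axis-aligned cube of physical side `extent_mm`, centred on the
#' voxel nearest `center_mm`. The voxel count per side is
#' `round(extent_mm / spacing)` forced odd so the centre voxel is unique.
#'
#' @param vol A `ct_volume` (or `nodule_mask`).
#' @param center_mm World coordinate of the patch centre.
#' @param extent_mm Physical cube side in mm.
#' @return A `ct_volume`/`nodule_mask` patch with adjusted origin.
#' @export
extract_patch <- function(vol, center_mm, extent_mm) {
  stopifnot(inherits(vol, "ct_volume"), extent_mm > 0)
  n <- patch_voxels(extent_mm, vol$spacing)
  ci <- world_to_index(vol, center_mm)
  half <- (n - 1L) %/% 2L
  lo <- ci - half
  hi <- ci + half
  dims <- dim(vol$values)
  if (any(lo < 1L) || any(hi > dims)) {
    deficit <- pmax(1L - lo, 0L) + pmax(hi - dims, 0L)
    abort(sprintf(
      "Patch of %.1f mm at (%s) leaves the volume; short by %s voxels on axes (x, y, z).",
      extent_mm, paste(signif(center_mm, 4), collapse = ", "),
      paste(deficit, collapse = ", ")))
  }
  sub <- vol$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out <- vol
  out$values <- sub
  out$origin <- index_to_world(vol, lo)
  out
}

# voxels per side for a cubic patch, forced odd
patch_voxels <- function(extent_mm, spacing) {
  n <- pmax(1L, as.integer(round(extent_mm / spacing)))
  n + 1L - (n %% 2L)
}

#' Read and write volumes as NIfTI-1
#'
#' World coordinates are in mm with voxel spacing carried in the NIfTI
#' `pixdim` field. Masks round-trip as integer grids.
#'
#' @param vol A `ct_volume` or `nodule_mask`.
#' @param path File path (`.nii` or `.nii.gz`).
#' @export
write_nifti_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @param mask Logical; read as a `nodule_mask` instead of a `ct_volume`.
#' @param origin Origin to attach (NIfTI offset handling is left to the
#'   caller; defaults to zero).
#' @export
read_nifti_volume <- function(path, mask = FALSE, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  if (mask) nodule_mask(round(arr), sp, origin) else ct_volume(arr, sp, origin)
}

#' Connected components of a binary 3D grid
#'
#' Labels foreground voxels under 26-connectivity. Used for mask validation
#' and for the shape descriptors of the surrogate classifier's features.
#'
#' @param arr Logical (or coercible) 3D array.
#' @return Integer array of component labels (0 = background), with
#'   components numbered in decreasing size order.
#' @export
label_components <- function(arr) {
  arr <- as.array(arr) > 0
  dims <- dim(arr)
  stopifnot(length(dims) == 3)
  lin <- which(arr)
  out <- array(0L, dims)
  if (length(lin) == 0) return(out)
  id <- integer(prod(dims))
  id[lin] <- seq_along(lin)
  coord <- arrayInd(lin, dims)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  # 13 forward neighbour offsets of the 26-neighbourhood
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[14 + seq_len(13), , drop = FALSE]
  edges <- vector("list", nrow(off))
  for (r in seq_len(nrow(off))) {
    dx <- off$dx[r]; dy <- off$dy[r]; dz <- off$dz[r]
    ok <- coord[, 1] + dx >= 1 & coord[, 1] + dx <= nx &
      coord[, 2] + dy >= 1 & coord[, 2] + dy <= ny &
      coord[, 3] + dz >= 1 & coord[, 3] + dz <= nz
    if (!any(ok)) next
    nb <- lin[ok] + dx + dy * nx + dz * nx * ny
    nb_id <- id[nb]
    hit <- nb_id > 0L
    if (!any(hit)) next
    edges[[r]] <- cbind(id[lin[ok]][hit], nb_id[hit])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_along(lin), seq_along(lin))), directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(lin)]
  sizes <- sort(table(comp), decreasing = TRUE)
  relabel <- integer(max(comp))
  relabel[as.integer(names(sizes))] <- seq_along(sizes)
  out[lin] <- relabel[comp]
  out
}

#' @rdname label_components
#' @return `is_connected_mask()`: `TRUE` when the foreground forms a single
#'   26-connected component.
#' @export
is_connected_mask <- function(arr) {
  if (inherits(arr, "ct_volume")) arr <- arr$values
  lab <- label_components(arr)
  n <- max(lab)
  n == 1L
}
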