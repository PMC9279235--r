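#' Configuration for a synthetic CT-nodule cohort
#'
#' Defines the generative model for a screening-like cohort of participants
#' carrying 1-4 pulmonary nodules each. Malignancy labels are drawn from a
#' logistic model on nodule size, spiculation, part-solid type, upper-lobe
#' location, participant age, and emphysema, with the intercept calibrated
#' so the realised prevalence matches `prevalence`. Rendered volumes are
#' CT-like patches: parenchyma around -825 HU, optional emphysema-like
#' low-density pockets, and an ellipsoidal solid or part-solid nodule with
#' optional radial spiculation. A hilum landmark is placed near one face of
#' every volume, at least 25 mm from the nodule centroid, so the
#' parenchyma-only ablation always has room to translate its window.
#'
#' Covariate rates default to values typical of a lung-screening population
#' (about 39% female, 50% emphysema, a third of nodules in upper lobes,
#' part-solid nodules a small minority). Effect directions mirror the Brock
#' model; magnitudes are chosen so each effect is recoverable at cohorts of
#' a few hundred participants, with nodule size dominant.
#'
#' @param n_participants Number of participants.
#' @param nodules_per_participant Named probability vector over counts
#'   `1..4`.
#' @param prevalence Target malignant fraction of nodules, in (0, 1).
#' @param diameter_range_mm Length-2 interval within \[4, 36\]; true nodule
#'   diameters are drawn log-uniformly over it.
#' @param logit_weights Named weights for
#'   `log_diameter`, `spiculation`, `part_solid`, `upper_lobe`, `age`,
#'   `emphysema` in the label model. `log_diameter` applies to the centred
#'   log of the size feature chosen by `size_feature`; `age` applies to
#'   `age - 62` years.
#' @param size_feature `"log_diameter"` (maximal axial diameter of the
#'   generated ellipsoid) or `"log_volume"` (volume-equivalent diameter);
#'   the latter makes labels depend on true volume rather than calliper
#'   size.
#' @param voxel_spacing_mm Length-3 voxel spacing.
#' @param patch_extent_mm Side of the rendered cubic volume, mm.
#' @param axis_ratio_range In-plane-minor and through-plane axis ratios of
#'   the nodule ellipsoid are drawn uniformly from this interval; the
#'   maximal axis always lies in the axial plane.
#' @param spiculation_rate,part_solid_rate,upper_lobe_rate,emphysema_rate,
#'   female_rate,family_history_rate Bernoulli rates of the attribute flags.
#' @param manual_noise_sd_mm SD of the manual-calliper reading error added
#'   to the true diameter to form `manual_diameter_mm`.
#' @param noise_sd_hu Parenchyma noise SD (HU), truncated at 3 SD.
#' @param solid_hu,shell_hu,background_hu Mean densities of solid tissue,
#'   part-solid shell, and background parenchyma.
#' @param emphysema_pocket_hu Density of emphysema-like pockets.
#' @param pocket_density_per_cm3 Expected pocket count per cm^3 in
#'   emphysema participants.
#' @param pocket_radius_range_mm Pocket radius interval.
#' @param core_fraction Part-solid core diameter as a fraction of the full
#'   nodule diameter.
#' @param nodule_texture_sd,spiculated_texture_sd SD (HU) of the nodule's
#'   internal texture for smooth and spiculated nodules respectively;
#'   spiculated (malignancy-prone) nodules are rendered with more
#'   heterogeneous interiors, so internal texture carries label-relevant
#'   information that the uniform-density ablation removes.
#' @param spike_count,spike_length_mm,spike_base_radius_mm Spiculation
#'   geometry: number of radial spikes, their length beyond the ellipsoid
#'   surface, and their base radius (tapering toward the tip).
#' @param max_calibration_iter Bisection iteration cap for the prevalence
#'   intercept.
#' @param seed Integer cohort seed; every draw flows from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 500,
                          nodules_per_participant = c("1" = 0.65, "2" = 0.20,
                                                      "3" = 0.10, "4" = 0.05),
                          prevalence = 0.12,
                          diameter_range_mm = c(6, 30),
                          logit_weights = c(log_diameter = 2.2,
                                            spiculation = 1.2,
                                            part_solid = 0.6,
                                            upper_lobe = 0.4,
                                            age = 0.03,
                                            emphysema = 0.6),
                          size_feature = c("log_diameter", "log_volume"),
                          voxel_spacing_mm = c(1.5, 1.5, 1.5),
                          patch_extent_mm = 92,
                          axis_ratio_range = c(0.95, 1),
                          spiculation_rate = 0.25,
                          part_solid_rate = 0.12,
                          upper_lobe_rate = 0.33,
                          emphysema_rate = 0.50,
                          female_rate = 0.39,
                          family_history_rate = 0.23,
                          manual_noise_sd_mm = 0.5,
                          noise_sd_hu = 30,
                          solid_hu = 30,
                          shell_hu = -500,
                          background_hu = -825,
                          emphysema_pocket_hu = -950,
                          pocket_density_per_cm3 = 0.04,
                          pocket_radius_range_mm = c(3, 7),
                          core_fraction = 0.6,
                          nodule_texture_sd = 18,
                          spiculated_texture_sd = 55,
                          spike_count = 8,
                          spike_length_mm = 5,
                          spike_base_radius_mm = 2,
                          max_calibration_iter = 200,
                          seed = 1) {
  size_feature <- match.arg(size_feature)
  cfg <- list(
    n_participants = as.integer(n_participants),
    nodules_per_participant = nodules_per_participant,
    prevalence = prevalence,
    diameter_range_mm = as.numeric(diameter_range_mm),
    logit_weights = logit_weights,
    size_feature = size_feature,
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    patch_extent_mm = patch_extent_mm,
    axis_ratio_range = as.numeric(axis_ratio_range),
    spiculation_rate = spiculation_rate,
    part_solid_rate = part_solid_rate,
    upper_lobe_rate = upper_lobe_rate,
    emphysema_rate = emphysema_rate,
    female_rate = female_rate,
    family_history_rate = family_history_rate,
    manual_noise_sd_mm = manual_noise_sd_mm,
    noise_sd_hu = noise_sd_hu,
    solid_hu = solid_hu,
    shell_hu = shell_hu,
    background_hu = background_hu,
    emphysema_pocket_hu = emphysema_pocket_hu,
    pocket_density_per_cm3 = pocket_density_per_cm3,
    pocket_radius_range_mm = as.numeric(pocket_radius_range_mm),
    core_fraction = core_fraction,
    nodule_texture_sd = nodule_texture_sd,
    spiculated_texture_sd = spiculated_texture_sd,
    spike_count = as.integer(spike_count),
    spike_length_mm = spike_length_mm,
    spike_base_radius_mm = spike_base_radius_mm,
    max_calibration_iter = as.integer(max_calibration_iter),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 1) abort("`n_participants` must be at least 1.")
  p <- cfg$nodules_per_participant
  if (is.null(names(p)) || !all(names(p) %in% as.character(1:4)) ||
      any(p < 0) || sum(p) <= 0) {
    abort("`nodules_per_participant` must be nonnegative weights named within '1'..'4'.")
  }
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1) {
    abort("`prevalence` must lie strictly in (0, 1).")
  }
  dr <- cfg$diameter_range_mm
  if (length(dr) != 2 || dr[1] >= dr[2] || dr[1] < 4 || dr[2] > 36) {
    abort("`diameter_range_mm` must be a nonempty interval within [4, 36].")
  }
  need <- c("log_diameter", "spiculation", "part_solid", "upper_lobe",
            "age", "emphysema")
  if (!all(need %in% names(cfg$logit_weights))) {
    abort(sprintf("`logit_weights` must name all of: %s.",
                  paste(need, collapse = ", ")))
  }
  if (any(cfg$voxel_spacing_mm <= 0) || length(cfg$voxel_spacing_mm) != 3) {
    abort("`voxel_spacing_mm` must be three strictly positive values.")
  }
  if (cfg$patch_extent_mm <= 0) abort("`patch_extent_mm` must be positive.")
  rr <- cfg$axis_ratio_range
  if (length(rr) != 2 || rr[1] > rr[2] || rr[1] <= 0 || rr[2] > 1) {
    abort("`axis_ratio_range` must be an interval within (0, 1].")
  }
  invisible(cfg)
}

# Bisection on the label-model intercept so the expected prevalence matches
# the target; errors out if the bracket does not converge.
calibrate_intercept <- function(lp, target, max_iter = 200, tol = 1e-8) {
  lo <- -40; hi <- 40
  f <- function(b0) mean(plogis(lp + b0)) - target
  if (f(lo) > 0 || f(hi) < 0) abort("Prevalence calibration failed: target outside achievable range.")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm > 0) hi <- mid else lo <- mid
  }
  mid <- (lo + hi) / 2
  if (abs(f(mid)) > 1e-4) {
    abort("Prevalence calibration failed to converge within the iteration cap.")
  }
  mid
}

#' Generate a synthetic cohort table
#'
#' Draws participants, their covariates, their nodules' attributes and
#' geometry, and malignancy labels from the logistic label model of
#' `config`. The result is one tidy tibble with one row per nodule and
#' participant covariates repeated across a participant's nodules (the
#' layout also used by the CSV external format). Rendering geometry (nodule
#' centre, hilum landmark, seed point, per-nodule render seed) is included
#' so [render_volume()] is fully determined by a row of this table.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per nodule.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  with_seed(config$seed, {
    n <- config$n_participants
    pw <- config$nodules_per_participant / sum(config$nodules_per_participant)
    counts <- sample(as.integer(names(pw)), n, replace = TRUE, prob = pw)
    part <- tibble(
      participant_id = sprintf("P%05d", seq_len(n)),
      age_years = as.integer(round(runif(n, 55, 74))),
      sex = ifelse(rbinom(n, 1, config$female_rate) == 1, "female", "male"),
      family_history = rbinom(n, 1, config$family_history_rate) == 1,
      emphysema = rbinom(n, 1, config$emphysema_rate) == 1,
      nodule_count = counts
    )
    nods <- part[rep(seq_len(n), counts), ]
    m <- nrow(nods)
    nods$nodule_id <- sprintf("%s_N%d", nods$participant_id,
                              sequence(counts))
    dr <- config$diameter_range_mm
    nods$true_diameter_mm <- exp(runif(m, log(dr[1]), log(dr[2])))
    nods$axis_ratio_b <- runif(m, config$axis_ratio_range[1], config$axis_ratio_range[2])
    nods$axis_ratio_c <- runif(m, config$axis_ratio_range[1], config$axis_ratio_range[2])
    nods$manual_diameter_mm <- pmax(
      0.5, nods$true_diameter_mm + rnorm(m, 0, config$manual_noise_sd_mm))
    nods$upper_lobe <- rbinom(m, 1, config$upper_lobe_rate) == 1
    nods$nodule_type <- ifelse(rbinom(m, 1, config$part_solid_rate) == 1,
                               "part_solid", "solid")
    nods$spiculation <- rbinom(m, 1, config$spiculation_rate) == 1

    # rendering geometry: nodule sits off-centre toward +x, hilum near the
    # -x face, guaranteeing >= 25 mm between the two (see cohort_config)
    L <- config$patch_extent_mm
    nods$center_x_mm <- 0.22 * L
    nods$center_y_mm <- runif(m, -3, 3)
    nods$center_z_mm <- runif(m, -3, 3)
    nods$hilum_x_mm <- -L / 2 + 4
    nods$hilum_y_mm <- runif(m, -2, 2)
    nods$hilum_z_mm <- runif(m, -2, 2)
    nods$render_seed <- sample.int(.Machine$integer.max, m)

    # label model
    w <- config$logit_weights
    size_mm <- if (config$size_feature == "log_volume") {
      nods$true_diameter_mm * (nods$axis_ratio_b * nods$axis_ratio_c)^(1 / 3)
    } else {
      nods$true_diameter_mm
    }
    lp <- w[["log_diameter"]] * (log(size_mm) - log(12)) +
      w[["spiculation"]] * nods$spiculation +
      w[["part_solid"]] * (nods$nodule_type == "part_solid") +
      w[["upper_lobe"]] * nods$upper_lobe +
      w[["age"]] * (nods$age_years - 62) +
      w[["emphysema"]] * nods$emphysema
    b0 <- calibrate_intercept(lp, config$prevalence, config$max_calibration_iter)
    nods$malignant <- rbinom(m, 1, plogis(lp + b0)) == 1

    out <- as_tibble(nods)[, c(
      "participant_id", "nodule_id", "age_years", "sex", "family_history",
      "emphysema", "nodule_count", "upper_lobe", "nodule_type", "spiculation",
      "manual_diameter_mm", "true_diameter_mm", "axis_ratio_b", "axis_ratio_c",
      "malignant", "center_x_mm", "center_y_mm", "center_z_mm",
      "hilum_x_mm", "hilum_y_mm", "hilum_z_mm", "render_seed")]
    attr(out, "intercept") <- b0
    out
  })
}

#' Participant-level covariates of a cohort table
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @return One row per participant.
#' @export
participants <- function(cohort) {
  dplyr::distinct(cohort, .data$participant_id, .data$age_years, .data$sex,
                  .data$family_history, .data$emphysema, .data$nodule_count)
}

#' Apply the study inclusion filters
#'
#' Retains nodules with manual diameter between `min_mm` and `max_mm`
#' inclusive and of solid or part-solid type; nodules measuring strictly
#' below 6 mm or strictly above 30 mm by manual calliper, and non-solid
#' nodules, are excluded. Row order is preserved and the input is not
#' modified.
#'
#' @param nodules A tibble with columns `manual_diameter_mm` and
#'   `nodule_type`.
#' @param min_mm,max_mm Inclusive manual-diameter bounds (mm).
#' @return The filtered tibble.
#' @export
apply_inclusion_filters <- function(nodules, min_mm = 6, max_mm = 30) {
  stopifnot(all(c("manual_diameter_mm", "nodule_type") %in% names(nodules)))
  dplyr::filter(
    nodules,
    .data$manual_diameter_mm >= min_mm,
    .data$manual_diameter_mm <= max_mm,
    .data$nodule_type %in% c("solid", "part_solid")
  )
}

#' Render one nodule's CT-like volume and mask
#'
#' Builds the cubic volume described by `config` for a single cohort row:
#' truncated-Gaussian parenchyma around the background density, low-density
#' pockets when the participant has emphysema, and an axis-aligned
#' ellipsoid nodule whose maximal axis (the `true_diameter_mm`) lies in the
#' axial plane. Part-solid nodules get a solid core (component label 1)
#' surrounded by a ground-glass shell at lower density (label 2);
#' spiculated nodules get tapering radial spikes that are part of the mask.
#' HU values are integers clipped to \[-1024, 600\]. Fully deterministic
#' given the row's `render_seed`.
#'
#' @param record One row of a cohort tibble (carrying both nodule and
#'   participant fields).
#' @param config The [cohort_config()] used to generate the cohort.
#' @return `list(volume = ct_volume, mask = nodule_mask)`.
#' @export
render_volume <- function(record, config) {
  stopifnot(inherits(config, "cohort_config"))
  record <- as.list(record[1, , drop = FALSE])
  sp <- config$voxel_spacing_mm
  L <- config$patch_extent_mm
  dims <- patch_voxels(L, sp)
  origin <- -(dims - 1) / 2 * sp
  xs <- origin[1] + (seq_len(dims[1]) - 1) * sp[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * sp[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * sp[3]

  d <- record$true_diameter_mm
  a <- d / 2
  b <- a * record$axis_ratio_b
  cc <- a * record$axis_ratio_c
  ctr <- c(record$center_x_mm, record$center_y_mm, record$center_z_mm)
  reach <- a + if (isTRUE(record$spiculation)) config$spike_length_mm else 0
  half <- (dims - 1) / 2 * sp
  if (any(abs(ctr) + reach > half - sp)) {
    abort(sprintf(
      "Nodule of %.1f mm (reach %.1f mm) does not fit in the %.0f mm patch extent.",
      d, reach, L))
  }

  with_seed(record$render_seed, {
    nvox <- prod(dims)
    noise <- clamp(rnorm(nvox, 0, config$noise_sd_hu),
                   -3 * config$noise_sd_hu, 3 * config$noise_sd_hu)
    vol <- array(config$background_hu + noise, dims)

    if (isTRUE(record$emphysema)) {
      vol_cm3 <- prod(dims * sp) / 1000
      n_pockets <- stats::rpois(1, config$pocket_density_per_cm3 * vol_cm3)
      for (p in seq_len(n_pockets)) {
        r <- runif(1, config$pocket_radius_range_mm[1], config$pocket_radius_range_mm[2])
        pc <- c(runif(1, xs[1] + r, xs[dims[1]] - r),
                runif(1, ys[1] + r, ys[dims[2]] - r),
                runif(1, zs[1] + r, zs[dims[3]] - r))
        ii <- which(abs(xs - pc[1]) <= r)
        jj <- which(abs(ys - pc[2]) <= r)
        kk <- which(abs(zs - pc[3]) <= r)
        if (!length(ii) || !length(jj) || !length(kk)) next
        d2 <- outer(outer((xs[ii] - pc[1])^2, (ys[jj] - pc[2])^2, "+"),
                    (zs[kk] - pc[3])^2, "+")
        inside <- d2 <= r^2
        sub <- vol[ii, jj, kk, drop = FALSE]
        sub[inside] <- config$emphysema_pocket_hu +
          clamp(rnorm(sum(inside), 0, 8), -24, 24)
        vol[ii, jj, kk] <- sub
      }
    }

    # ellipsoid quadratic form, separable across axes
    qx <- ((xs - ctr[1]) / a)^2
    qy <- ((ys - ctr[2]) / b)^2
    qz <- ((zs - ctr[3]) / cc)^2
    q <- outer(outer(qx, qy, "+"), qz, "+")
    mask <- array(0L, dims)
    # interiors of spiculated (malignancy-prone) nodules are rendered more
    # heterogeneous, mirroring the association between aggressive nodules
    # and internal texture; the mask and label model are unaffected
    tex_sd <- if (isTRUE(record$spiculation)) config$spiculated_texture_sd
              else config$nodule_texture_sd
    if (record$nodule_type == "part_solid") {
      core <- q <= config$core_fraction^2
      shell <- q <= 1 & !core
      mask[core] <- 1L
      mask[shell] <- 2L
      vol[core] <- config$solid_hu + rnorm(sum(core), 0, tex_sd)
      vol[shell] <- config$shell_hu + rnorm(sum(shell), 0, tex_sd)
    } else {
      inside <- q <= 1
      mask[inside] <- 1L
      vol[inside] <- config$solid_hu + rnorm(sum(inside), 0, tex_sd)
    }

    if (isTRUE(record$spiculation)) {
      dirs <- matrix(rnorm(3 * config$spike_count), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      for (s in seq_len(config$spike_count)) {
        v <- dirs[s, ]
        t_surf <- 1 / sqrt((v[1] / a)^2 + (v[2] / b)^2 + (v[3] / cc)^2)
        t0 <- 0.7 * t_surf
        t1 <- t_surf + config$spike_length_mm
        # bounding box of the spike segment plus base radius
        lo <- ctr + pmin(t0 * v, t1 * v) - config$spike_base_radius_mm
        hi <- ctr + pmax(t0 * v, t1 * v) + config$spike_base_radius_mm
        ii <- which(xs >= lo[1] & xs <= hi[1])
        jj <- which(ys >= lo[2] & ys <= hi[2])
        kk <- which(zs >= lo[3] & zs <= hi[3])
        if (!length(ii) || !length(jj) || !length(kk)) next
        px <- xs[ii] - ctr[1]; py <- ys[jj] - ctr[2]; pz <- zs[kk] - ctr[3]
        tt <- outer(outer(px * v[1], py * v[2], "+"), pz * v[3], "+")
        r2 <- outer(outer(px^2, py^2, "+"), pz^2, "+") - tt^2
        r2[r2 < 0] <- 0
        frac <- (tt - t0) / (t1 - t0)
        rad <- config$spike_base_radius_mm * (1 - 0.7 * pmax(frac, 0))
        inside <- tt >= t0 & tt <= t1 & r2 <= rad^2
        if (!any(inside)) next
        msub <- mask[ii, jj, kk, drop = FALSE]
        vsub <- vol[ii, jj, kk, drop = FALSE]
        newv <- inside & msub == 0L
        msub[newv] <- 1L
        vsub[newv] <- config$solid_hu + rnorm(sum(newv), 0, tex_sd)
        mask[ii, jj, kk] <- msub
        vol[ii, jj, kk] <- vsub
      }
    }

    if (!any(mask > 0)) {
      ci <- pmin(pmax(round((ctr - origin) / sp) + 1, 1), dims)
      mask[ci[1], ci[2], ci[3]] <- 1L
      vol[ci[1], ci[2], ci[3]] <- config$solid_hu
    }

    vol <- round(clamp(vol, -1024, 600))
    list(volume = ct_volume(vol, sp, origin),
         mask = nodule_mask(mask, sp, origin))
  })
}

#' Hilum landmark of a cohort row
#'
#' @param record One cohort row.
#' @return Length-3 world coordinate (mm).
#' @export
hilum_point <- function(record) {
  c(record$hilum_x_mm[1], record$hilum_y_mm[1], record$hilum_z_mm[1])
}

#' Nodule centre of a cohort row
#'
#' @param record One cohort row.
#' @return Length-3 world coordinate (mm).
#' @export
nodule_center <- function(record) {
  c(record$center_x_mm[1], record$center_y_mm[1], record$center_z_mm[1])
}

#' Read/write cohort tables as CSV
#'
#' @param cohort A cohort tibble.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
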