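#' Experiment configuration
#'
#' Bundles every stage's settings for [run_experiment()]: the synthetic
#' cohort, which ablation conditions to train the surrogate classifier on,
#' which Brock variants and size inputs to score, the fold protocol, and
#' the statistics settings. A single master seed fans out to per-stage
#' seeds through [derive_seeds()], so rerunning the same configuration
#' reproduces every artifact exactly.
#'
#' @param cohort A [cohort_config()]; its own seed is overridden by a seed
#'   derived from `seed`.
#' @param conditions Ablation conditions to evaluate (subset of
#'   `"none"`, `"uniform_density"`, `"implant_sphere"`,
#'   `"parenchyma_only"`).
#' @param brock_variants Brock variants to score (see
#'   [brock_variant_terms()]); empty to skip the Brock stage.
#' @param size_inputs Size inputs for the Brock stage, subset of
#'   `"manual"`, `"esd"`, `"pairwise_axial"`, `"ellipse_axial"`.
#' @param k Fold count for [make_folds()].
#' @param ablation_extent_mm Classifier window side, mm.
#' @param hilum_offset_mm Nominal parenchyma-only offset, mm.
#' @param per_component Component-wise fill for the uniform-density
#'   ablation.
#' @param n_boot,n_perm Bootstrap and permutation counts for the summary
#'   comparisons.
#' @param classifier_features Curated feature subset handed to
#'   [fit_and_score()]: one or two features per information channel
#'   (size, margin shape, type/texture, background density). `NULL` uses
#'   every feature.
#' @param seed Master seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              conditions = c("none", "uniform_density",
                                             "implant_sphere",
                                             "parenchyma_only"),
                              brock_variants = c("full", "no_spiculation",
                                                 "morphological_only",
                                                 "non_morphological"),
                              size_inputs = c("manual", "esd", "pairwise_axial"),
                              k = 8,
                              ablation_extent_mm = 44,
                              hilum_offset_mm = 15,
                              per_component = TRUE,
                              n_boot = 1000,
                              n_perm = 1000,
                              classifier_features = c(
                                "f_comp_esd_mm", "f_comp_sphericity",
                                "f_comp_mean_hu", "f_comp_sd_hu",
                                "f_frac_below_m880", "f_texture_sd"),
                              seed = 1) {
  stopifnot(inherits(cohort, "cohort_config"))
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (length(size_inputs) > 0) {
    size_inputs <- match.arg(size_inputs,
                             c("manual", "esd", "pairwise_axial", "ellipse_axial"),
                             several.ok = TRUE)
  }
  structure(list(cohort = cohort, conditions = conditions,
                 brock_variants = brock_variants, size_inputs = size_inputs,
                 k = as.integer(k),
                 ablation_extent_mm = ablation_extent_mm,
                 hilum_offset_mm = hilum_offset_mm,
                 per_component = per_component,
                 n_boot = n_boot, n_perm = n_perm,
                 classifier_features = classifier_features,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

size_input_column <- function(size_input) {
  switch(size_input,
    manual = "manual_diameter_mm",
    esd = "esd_mm",
    pairwise_axial = "axial_diameter_pairwise_mm",
    ellipse_axial = "axial_diameter_ellipse_mm",
    abort(sprintf("Unknown size input `%s`.", size_input)))
}

#' Render, measure, ablate, and featurize a cohort in one pass
#'
#' Renders each nodule's volume once, measures the requested size
#' quantities from its mask, and computes the classifier feature vector of
#' the window under each requested ablation condition. Volumes are
#' discarded after use, so memory stays flat in cohort size.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param config The matching [cohort_config()].
#' @param conditions Character vector of ablation conditions (may be
#'   empty).
#' @param measure_methods Passed to [measure_nodule()] (may be empty to
#'   skip measurement).
#' @param ablation_extent_mm,hilum_offset_mm,per_component Ablation
#'   settings.
#' @return List with `measurements` (tibble, one row per nodule) and
#'   `features` (tibble, one row per nodule x condition with `f_`
#'   columns); either may be `NULL` when not requested.
#' @export
process_cohort <- function(cohort, config,
                           conditions = character(),
                           measure_methods = c("esd", "pairwise"),
                           ablation_extent_mm = 40,
                           hilum_offset_mm = 15,
                           per_component = TRUE) {
  specs <- lapply(conditions, function(mode) {
    ablation_spec(mode, hilum_offset_mm = hilum_offset_mm,
                  patch_extent_mm = ablation_extent_mm)
  })
  names(specs) <- conditions
  meas_rows <- vector("list", nrow(cohort))
  feat_rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort[i, ]
    rendered <- render_volume(rec, config)
    if (length(measure_methods) > 0) {
      meas_rows[[i]] <- dplyr::bind_cols(
        tibble(participant_id = rec$participant_id, nodule_id = rec$nodule_id),
        measure_nodule(rendered$mask, methods = measure_methods))
    }
    if (length(conditions) > 0) {
      hp <- hilum_point(rec)
      feats <- purrr::map_dfr(conditions, function(cond) {
        patch <- apply_ablation(rendered$volume, rendered$mask, hp,
                                specs[[cond]], per_component)
        fv <- featurize(patch)
        row <- as_tibble(as.list(fv))
        names(row) <- paste0("f_", names(row))
        dplyr::bind_cols(
          tibble(participant_id = rec$participant_id,
                 nodule_id = rec$nodule_id, condition = cond,
                 label = rec$malignant), row)
      })
      feat_rows[[i]] <- feats
    }
  }
  list(
    measurements = if (length(measure_methods) > 0) dplyr::bind_rows(meas_rows) else NULL,
    features = if (length(conditions) > 0) dplyr::bind_rows(feat_rows) else NULL
  )
}

#' Bootstrap confidence interval for a single AUC
#'
#' Percentile interval over group (participant) resampling.
#'
#' @inheritParams bootstrap_auc_difference
#' @return List with `auc` and `ci95`.
#' @export
bootstrap_auc_ci <- function(scores, labels, group_ids = NULL,
                             n_boot = 1000, seed = 1) {
  labels <- as.logical(labels)
  if (is.null(group_ids)) group_ids <- seq_along(labels)
  groups <- split(seq_along(labels), group_ids)
  ng <- length(groups)
  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        take <- sample.int(ng, ng, replace = TRUE)
        idx <- unlist(groups[take], use.names = FALSE)
        if (length(unique(labels[idx])) == 2) break
      }
      auc(scores[idx], labels[idx])
    }, numeric(1))
  })
  list(auc = auc(scores, labels),
       ci95 = unname(quantile(draws, c(0.025, 0.975))))
}

#' Run the end-to-end ablation experiment
#'
#' Orchestrates the full pipeline on a synthetic cohort: generate and
#' filter the cohort; render and measure every nodule; score the Brock
#' variants for each requested size input; featurize the classifier window
#' under each ablation condition; train and score the surrogate classifier
#' under the participant-level fold protocol; and summarise out-of-fold
#' AUCs with bootstrap confidence intervals. When `out_dir` is given,
#' every stage's artifact is written there (CSV/JSON) together with the
#' master seed and a hash of the configuration.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory for artifacts.
#' @return A list of class `nodule_experiment` with elements `cohort`,
#'   `measurements`, `brock`, `scores`, `summary`, `plan`, `config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- derive_seeds(config$seed, 4)
  ccfg <- config$cohort
  ccfg$seed <- seeds[1]

  cohort <- apply_inclusion_filters(generate_cohort(ccfg))
  if (nrow(cohort) == 0) abort("Stage `cohort`: no nodules pass the inclusion filters.")

  measure_methods <- intersect(
    c(esd = "esd", pairwise_axial = "pairwise", ellipse_axial = "ellipse")[
      setdiff(config$size_inputs, "manual")], c("esd", "pairwise", "ellipse"))
  processed <- tryCatch(
    process_cohort(cohort, ccfg, conditions = config$conditions,
                   measure_methods = unname(measure_methods),
                   ablation_extent_mm = config$ablation_extent_mm,
                   hilum_offset_mm = config$hilum_offset_mm,
                   per_component = config$per_component),
    error = function(e) abort(sprintf("Stage `render/measure` failed: %s",
                                      conditionMessage(e))))
  measurements <- processed$measurements
  sized <- cohort
  if (!is.null(measurements)) {
    sized <- dplyr::left_join(cohort, measurements,
                              by = c("participant_id", "nodule_id"))
  }

  brock <- NULL
  if (length(config$brock_variants) > 0 && length(config$size_inputs) > 0) {
    brock <- purrr::map_dfr(config$size_inputs, function(si) {
      col <- size_input_column(si)
      purrr::map_dfr(config$brock_variants, function(v) {
        scored <- suppressWarnings(brock_risk(sized, col, variant = v))
        tibble(participant_id = scored$participant_id,
               nodule_id = scored$nodule_id,
               size_input = si, variant = v,
               size_mm = sized[[col]],
               linear_predictor = scored$brock_lp,
               probability = scored$brock_probability,
               label = scored$malignant)
      })
    })
  }

  scores <- NULL
  plan <- NULL
  if (length(config$conditions) > 0) {
    part <- cohort |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(label = any(.data$malignant), .groups = "drop")
    plan <- tryCatch(
      make_folds(part$participant_id, part$label, k = config$k, seed = seeds[2]),
      error = function(e) abort(sprintf("Stage `folds` failed: %s",
                                        conditionMessage(e))))
    scores <- tryCatch(
      fit_and_score(processed$features, plan, seed = seeds[3],
                    feature_cols = config$classifier_features),
      error = function(e) abort(sprintf("Stage `classifier` failed: %s",
                                        conditionMessage(e))))
  }

  # summary: out-of-fold AUC + bootstrap CI per classifier condition and
  # per Brock variant x size input
  stat_seeds <- derive_seeds(seeds[4], 64)
  rows <- list()
  si <- 1L
  if (!is.null(scores)) {
    for (cond in unique(scores$condition)) {
      s <- dplyr::filter(scores, .data$condition == cond)
      ci <- bootstrap_auc_ci(s$score, s$label, s$participant_id,
                             n_boot = config$n_boot, seed = stat_seeds[si])
      si <- si + 1L
      rows[[length(rows) + 1]] <- tibble(
        stage = "classifier", condition = cond, auc = ci$auc,
        ci_lower = ci$ci95[1], ci_upper = ci$ci95[2],
        n = nrow(s), n_malignant = sum(s$label))
    }
  }
  if (!is.null(brock)) {
    combos <- dplyr::distinct(brock, .data$size_input, .data$variant)
    for (j in seq_len(nrow(combos))) {
      s <- dplyr::filter(brock, .data$size_input == combos$size_input[j],
                         .data$variant == combos$variant[j])
      ci <- bootstrap_auc_ci(s$probability, s$label, s$participant_id,
                             n_boot = config$n_boot, seed = stat_seeds[si])
      si <- si + 1L
      rows[[length(rows) + 1]] <- tibble(
        stage = "brock",
        condition = sprintf("brock_%s_%s", combos$variant[j], combos$size_input[j]),
        auc = ci$auc, ci_lower = ci$ci95[1], ci_upper = ci$ci95[2],
        n = nrow(s), n_malignant = sum(s$label))
    }
  }
  summary <- dplyr::bind_rows(rows)

  result <- structure(list(cohort = cohort, measurements = measurements,
                           brock = brock, scores = scores, summary = summary,
                           plan = plan, config = config,
                           seed = config$seed,
                           config_hash = rlang::hash(unclass(config))),
                      class = "nodule_experiment")
  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$cohort, file.path(out_dir, "cohort.csv"))
  if (!is.null(result$measurements)) {
    readr::write_csv(result$measurements, file.path(out_dir, "measurements.csv"))
  }
  if (!is.null(result$brock)) {
    readr::write_csv(result$brock, file.path(out_dir, "brock_scores.csv"))
  }
  if (!is.null(result$scores)) {
    readr::write_csv(result$scores, file.path(out_dir, "score_table.csv"))
  }
  readr::write_csv(result$summary, file.path(out_dir, "summary.csv"))
  jsonlite::write_json(
    list(seed = result$seed, config_hash = result$config_hash,
         summary = result$summary),
    file.path(out_dir, "summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.nodule_experiment <- function(x, ...) {
  cat(sprintf("<nodule_experiment> %d nodules / %d participants (seed %d)\n",
              nrow(x$cohort), length(unique(x$cohort$participant_id)), x$seed))
  print(x$summary, n = Inf)
  invisible(x)
}

#' @rdname run_experiment
#' @param object A `nodule_experiment`.
#' @param ... Unused.
#' @export
autoplot.nodule_experiment <- function(object, ...) {
  plot_condition_auc(object$summary)
}

#' @rdname run_experiment
#' @param x A `nodule_experiment`.
#' @export
tidy.nodule_experiment <- function(x, ...) {
  x$summary
}

#' @rdname run_experiment
#' @export
glance.nodule_experiment <- function(x, ...) {
  tibble(n_nodules = nrow(x$cohort),
         n_participants = length(unique(x$cohort$participant_id)),
         n_malignant = sum(x$cohort$malignant),
         n_conditions = length(x$config$conditions),
         k = x$config$k, seed = x$seed, config_hash = x$config_hash)
}
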