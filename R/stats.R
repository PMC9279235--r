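#' Area under the ROC curve
#'
#' Mann-Whitney estimator with midrank tie handling: the probability that a
#' randomly chosen malignant nodule outranks a randomly chosen benign one,
#' counting ties as one half. Equals the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param scores Numeric risk scores.
#' @param labels Logical/0-1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) abort("`scores` and `labels` lengths differ.")
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) abort("Both classes must be present to compute an AUC.")
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' Sensitivity/1-specificity pairs at every score threshold, for plotting
#' or CSV export.
#'
#' @inheritParams auc
#' @return A tibble with `threshold`, `tpr`, `fpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  purrr::map_dfr(ths, function(t) {
    pred <- scores >= t
    tibble(threshold = t,
           tpr = sum(pred & labels) / sum(labels),
           fpr = sum(pred & !labels) / sum(!labels))
  })
}

#' Bootstrap distribution of a paired AUC difference
#'
#' Resamples resampling units (participants by default, so correlated
#' nodules stay together) with replacement and recomputes
#' `auc(scores_a) - auc(scores_b)` on each draw; the 95% confidence
#' interval is read off the 2.5/97.5 percentiles of the resulting
#' distribution. Draws whose labels collapse to a single class are redrawn
#' and counted.
#'
#' @param scores_a,scores_b Paired score vectors over the same nodules.
#' @param labels Logical/0-1 labels.
#' @param group_ids Resampling-unit ids (participant ids); `NULL`
#'   resamples nodules.
#' @param n_boot Number of bootstrap draws.
#' @param seed Integer seed; results are deterministic given it.
#' @return List with `diff` (observed difference), `ci95` (length-2),
#'   `draws` (numeric vector), `n_redrawn`.
#' @export
bootstrap_auc_difference <- function(scores_a, scores_b, labels,
                                     group_ids = NULL, n_boot = 10000,
                                     seed = 1) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  labels <- as.logical(labels)
  if (is.null(group_ids)) group_ids <- seq_along(labels)
  groups <- split(seq_along(labels), group_ids)
  ng <- length(groups)
  obs <- auc(scores_a, labels) - auc(scores_b, labels)
  n_redrawn <- 0L
  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        take <- sample.int(ng, ng, replace = TRUE)
        idx <- unlist(groups[take], use.names = FALSE)
        if (length(unique(labels[idx])) == 2) break
        n_redrawn <<- n_redrawn + 1L
      }
      auc(scores_a[idx], labels[idx]) - auc(scores_b[idx], labels[idx])
    }, numeric(1))
  })
  if (n_redrawn > 0) {
    inform(sprintf("%d bootstrap draws redrawn for single-class labels.", n_redrawn))
  }
  list(diff = obs,
       ci95 = unname(quantile(draws, c(0.025, 0.975))),
       draws = draws,
       n_redrawn = n_redrawn)
}

#' Two-sided permutation test for a paired AUC difference
#'
#' The null of exchangeable scorers is simulated by independently swapping
#' each nodule's (a, b) score pair with probability one half per
#' resampling; the two-sided p-value uses the add-one estimator
#' `(1 + #(|null| >= |observed|)) / (n_perm + 1)`, so it is never below
#' `1 / (n_perm + 1)`.
#'
#' @inheritParams bootstrap_auc_difference
#' @param n_perm Number of random resamplings.
#' @return List with `p_value`, `observed`, `n_perm`.
#' @export
permutation_test_auc <- function(scores_a, scores_b, labels,
                                 n_perm = 10000, seed = 1) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  labels <- as.logical(labels)
  n <- length(labels)
  obs <- auc(scores_a, labels) - auc(scores_b, labels)
  null_abs <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      swap <- runif(n) < 0.5
      a <- ifelse(swap, scores_b, scores_a)
      b <- ifelse(swap, scores_a, scores_b)
      abs(auc(a, labels) - auc(b, labels))
    }, numeric(1))
  })
  p <- (1 + sum(null_abs >= abs(obs) - 1e-15)) / (n_perm + 1)
  list(p_value = p, observed = obs, n_perm = n_perm)
}

#' Compare two risk scorers on the same nodules
#'
#' Bundles the paired AUCs, the bootstrap confidence interval of their
#' difference, and the permutation-test p-value into a `model_comparison`
#' object with `tidy()`, `glance()`, `print()`, and `autoplot()` methods.
#'
#' @inheritParams bootstrap_auc_difference
#' @param n_perm Permutation count for [permutation_test_auc()].
#' @param name_a,name_b Labels for the two scorers.
#' @return A `model_comparison` object.
#' @export
compare_auc <- function(scores_a, scores_b, labels, group_ids = NULL,
                        n_boot = 10000, n_perm = 10000, seed = 1,
                        name_a = "A", name_b = "B") {
  labels <- as.logical(labels)
  seeds <- derive_seeds(seed, 2)
  bt <- bootstrap_auc_difference(scores_a, scores_b, labels, group_ids,
                                 n_boot, seeds[1])
  pt <- permutation_test_auc(scores_a, scores_b, labels, n_perm, seeds[2])
  structure(list(
    name_a = name_a, name_b = name_b,
    auc_a = auc(scores_a, labels), auc_b = auc(scores_b, labels),
    diff = bt$diff, ci95 = bt$ci95, p_value = pt$p_value,
    n_boot = n_boot, n_perm = n_perm,
    resampling_unit = if (is.null(group_ids)) "nodule" else "participant",
    n = length(labels), n_malignant = sum(labels),
    scores_a = scores_a, scores_b = scores_b, labels = labels
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s vs %s (n = %d, %d malignant)\n",
              x$name_a, x$name_b, x$n, x$n_malignant))
  cat(sprintf("  AUC %s = %.3f, AUC %s = %.3f\n", x$name_a, x$auc_a,
              x$name_b, x$auc_b))
  cat(sprintf("  diff = %+.4f, 95%% CI [%+.4f, %+.4f] (%d bootstrap draws, %s resampling)\n",
              x$diff, x$ci95[1], x$ci95[2], x$n_boot, x$resampling_unit))
  cat(sprintf("  two-sided permutation p = %.4g (%d resamplings)\n",
              x$p_value, x$n_perm))
  invisible(x)
}

#' @rdname compare_auc
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @export
tidy.model_comparison <- function(x, ...) {
  tibble(model = c(x$name_a, x$name_b),
         auc = c(x$auc_a, x$auc_b),
         n = x$n, n_malignant = x$n_malignant)
}

#' @rdname compare_auc
#' @export
glance.model_comparison <- function(x, ...) {
  tibble(auc_a = x$auc_a, auc_b = x$auc_b, diff = x$diff,
         ci_lower = x$ci95[1], ci_upper = x$ci95[2], p_value = x$p_value,
         n_boot = x$n_boot, n_perm = x$n_perm,
         resampling_unit = x$resampling_unit, n = x$n,
         n_malignant = x$n_malignant)
}

#' Stratified comparisons of two scorers
#'
#' Runs the full comparison machinery independently within each level of a
#' stratifier (typically nodule type, mirroring a solid vs part-solid
#' subgroup analysis). Strata in which either class is absent are skipped
#' with a warning.
#'
#' @param score_table A tibble with columns `score_a`, `score_b`, `label`,
#'   optionally `participant_id`, and the stratifier column.
#' @param stratifier Name of the stratifier column.
#' @inheritParams compare_auc
#' @return A named list of `model_comparison` objects, one per usable
#'   stratum.
#' @export
subgroup_compare <- function(score_table, stratifier = "nodule_type",
                             n_boot = 10000, n_perm = 10000, seed = 1,
                             name_a = "A", name_b = "B") {
  if (!stratifier %in% names(score_table)) {
    abort(sprintf("No stratifier column `%s`.", stratifier))
  }
  strata <- split(score_table, score_table[[stratifier]])
  out <- list()
  for (level in names(strata)) {
    s <- strata[[level]]
    if (nrow(s) == 0 || length(unique(as.logical(s$label))) < 2) {
      warn(sprintf("Stratum `%s` skipped: fewer than two classes present.", level))
      next
    }
    gid <- if ("participant_id" %in% names(s)) s$participant_id else NULL
    out[[level]] <- compare_auc(s$score_a, s$score_b, s$label, gid,
                                n_boot, n_perm, seed,
                                name_a = name_a, name_b = name_b)
  }
  out
}
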