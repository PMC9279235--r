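#' Train and score the surrogate classifier under a fold plan
#'
#' For every ablation condition in `features`, and for every fold of
#' `plan`, fits an L2-regularised logistic scorer ([glmnet::glmnet()],
#' `alpha = 0`) on the training-group nodules, selects the regularisation
#' strength by out-of-sample binomial deviance on the validation group
#' (deviance is much smoother than AUC on validation groups that hold
#' only a handful of malignant participants), and scores the test-group
#' nodules. Each condition gets its own independently trained
#' models; pooling the test scores over folds yields exactly one
#' out-of-fold score per nodule per condition. Fold membership is at
#' participant level, so no participant ever contributes to both the
#' training and test side of a fold.
#'
#' @param features A tibble with columns `participant_id`, `nodule_id`,
#'   `condition`, `label` (logical), and feature columns prefixed `f_`
#'   (see [compute_condition_features()]).
#' @param plan A [make_folds()] plan covering every participant in
#'   `features`.
#' @param seed Integer seed (reserved for stochastic scorers; the default
#'   ridge path is deterministic).
#' @param feature_cols Feature columns to use (default: every `f_`
#'   column). The experiment pipeline passes a compact curated subset —
#'   one or two features per information channel — because heavily
#'   redundant feature sets dilute the weakly-informative channels under
#'   ridge shrinkage.
#' @return A score table: tibble with `condition`, `participant_id`,
#'   `nodule_id`, `fold`, `label`, `score` in \[0, 1\].
#' @export
fit_and_score <- function(features, plan, seed = 1, feature_cols = NULL) {
  stopifnot(inherits(plan, "fold_plan"))
  fcols <- feature_cols %||% grep("^f_", names(features), value = TRUE)
  if (length(fcols) == 0) abort("`features` has no `f_` feature columns.")
  if (!all(fcols %in% names(features))) {
    abort(sprintf("Missing feature columns: %s.",
                  paste(setdiff(fcols, names(features)), collapse = ", ")))
  }
  missing <- setdiff(unique(features$participant_id),
                     plan$assignments$participant_id)
  if (length(missing) > 0) {
    abort(sprintf("%d participants in `features` are absent from the fold plan.",
                  length(missing)))
  }
  conditions <- unique(features$condition)
  out <- purrr::map_dfr(conditions, function(cond) {
    dat <- dplyr::filter(features, .data$condition == cond)
    purrr::map_dfr(seq_len(plan$k), function(i) {
      tr_ids <- fold_participants(plan, i, "train")
      va_ids <- fold_participants(plan, i, "validation")
      te_ids <- fold_participants(plan, i, "test")
      tr <- dplyr::filter(dat, .data$participant_id %in% tr_ids)
      va <- dplyr::filter(dat, .data$participant_id %in% va_ids)
      te <- dplyr::filter(dat, .data$participant_id %in% te_ids)
      if (length(unique(tr$label)) < 2) {
        abort(sprintf("Fold %d has single-class training labels for condition `%s`.",
                      i, cond))
      }
      xtr <- as.matrix(tr[fcols]); xva <- as.matrix(va[fcols])
      xte <- as.matrix(te[fcols])
      fit <- glmnet::glmnet(xtr, as.numeric(tr$label), family = "binomial",
                            alpha = 0, nlambda = 30, standardize = TRUE)
      lams <- fit$lambda
      if (nrow(va) > 0) {
        pv <- predict(fit, newx = xva, type = "response")
        pv <- pmin(pmax(pv, 1e-12), 1 - 1e-12)
        yv <- as.numeric(va$label)
        dev <- apply(pv, 2, function(p) {
          -2 * sum(yv * log(p) + (1 - yv) * log(1 - p))
        })
        sel <- which.min(dev)
      } else {
        sel <- length(lams)  # no validation group: least regularised
      }
      sc <- as.numeric(predict(fit, newx = xte, type = "response",
                               s = lams[sel]))
      tibble(condition = cond, participant_id = te$participant_id,
             nodule_id = te$nodule_id, fold = i, label = te$label,
             score = sc)
    })
  })
  out
}

#' Pooled out-of-fold AUC per condition
#'
#' @param score_table Output of [fit_and_score()].
#' @return A tibble with `condition`, `auc`, `n`, `n_malignant`.
#' @export
score_table_auc <- function(score_table) {
  score_table |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(auc = auc(.data$score, .data$label),
                     n = dplyr::n(),
                     n_malignant = sum(.data$label),
                     .groups = "drop")
}
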