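#' Participant-level stratified fold plan
#'
#' Partitions participants into `k` disjoint, exhaustive groups with an
#' approximately equal proportion of malignant participants per group.
#' Fold `i` uses group `i` as its test partition, group `i + 1` (mod `k`)
#' as its validation partition, and the remaining `k - 2` groups for
#' training; with the default `k = 8` this realises a 6/8 : 1/8 : 1/8
#' train/validation/test split, and every participant is in the test
#' partition of exactly one fold.
#'
#' @param participant_ids Character vector of unique participant ids.
#' @param participant_labels Logical/0-1 vector (participant considered
#'   malignant, e.g. any malignant nodule), aligned with
#'   `participant_ids`.
#' @param k Number of folds/groups (>= 3).
#' @param seed Integer seed for the stratified shuffle.
#' @return A `fold_plan`: list with `k`, `assignments` (tibble of
#'   `participant_id`, `group`), and `roles` (tibble of `fold`, `role`,
#'   `group`).
#' @export
make_folds <- function(participant_ids, participant_labels, k = 8, seed = 1) {
  stopifnot(length(participant_ids) == length(participant_labels))
  if (anyDuplicated(participant_ids)) abort("`participant_ids` must be unique.")
  k <- as.integer(k)
  if (k < 3) abort("`k` must be at least 3 (train/validation/test need distinct groups).")
  lab <- as.logical(participant_labels)
  if (sum(lab) < k || sum(!lab) < k) {
    abort(sprintf("Need at least k = %d participants in each label class.", k))
  }
  with_seed(seed, {
    # shuffle within label class, then deal the concatenated order round-robin:
    # group sizes differ by at most one and each class spreads evenly
    ord <- c(sample(which(lab)), sample(which(!lab)))
    group <- integer(length(ord))
    group[ord] <- rep_len(seq_len(k), length(ord))
    assignments <- tibble(participant_id = participant_ids, group = group)
    roles <- purrr::map_dfr(seq_len(k), function(i) {
      tibble(fold = i,
             role = c("test", "validation", rep("train", k - 2)),
             group = c(i, i %% k + 1L,
                       setdiff(seq_len(k), c(i, i %% k + 1L))))
    })
    structure(list(k = k, assignments = assignments, roles = roles,
                   seed = seed),
              class = "fold_plan")
  })
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- table(x$assignments$group)
  cat(sprintf("<fold_plan> k = %d, %d participants (group sizes %s)\n",
              x$k, nrow(x$assignments), paste(sizes, collapse = "/")))
  invisible(x)
}

#' Participants playing a role in one fold
#'
#' @param plan A `fold_plan`.
#' @param fold Fold index in `1..k`.
#' @param role `"train"`, `"validation"`, or `"test"`.
#' @return Character vector of participant ids.
#' @export
fold_participants <- function(plan, fold, role = c("train", "validation", "test")) {
  role <- match.arg(role)
  groups <- plan$roles$group[plan$roles$fold == fold & plan$roles$role == role]
  plan$assignments$participant_id[plan$assignments$group %in% groups]
}
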