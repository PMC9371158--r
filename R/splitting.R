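## Train/validation partitions: subject-dependent (SD) hold-out,
## subject-independent (SI) subject partition, and per-activity biometric
## user identification (BUI) subsets.

new_split_plan <- function(strategy, train, val, seed = NULL, params = list(),
                           target = "activity") {
  structure(list(strategy = strategy,
                 train_indices = as.integer(train),
                 val_indices = as.integer(val),
                 seed = seed, params = params, target = target),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan %s> %d train / %d validation (target: %s)\n",
              x$strategy, length(x$train_indices), length(x$val_indices),
              x$target))
  invisible(x)
}

## Seeded Fisher-Yates shuffle driven by the package's RNG stream. Defined
## explicitly (rather than through a library shuffle) so the permutation rule
## is part of the artifact's contract: plans are reproducible here but not
## bit-identical to permutations produced elsewhere.
fisher_yates <- function(n, seed) {
  with_preserved_rng({
    set.seed(as.integer(seed))
    idx <- seq_len(n)
    for (i in n:2) {
      j <- floor(stats::runif(1) * i) + 1L
      tmp <- idx[i]; idx[i] <- idx[j]; idx[j] <- tmp
    }
    idx
  })
}

#' Subject-dependent hold-out split
#'
#' Shuffles all windows with a seeded Fisher-Yates permutation and holds out
#' the first `round(val_fraction * n)` (nearest rounding, ties to even) as
#' validation. Unstratified. Defaults follow the standard protocol:
#' 70/30 with seed 42.
#'
#' @param dataset a `har_dataset`.
#' @param val_fraction validation fraction in (0, 1) (default 0.3).
#' @param seed shuffle seed (default 42).
#' @param indices optional subset of window indices to partition (used by the
#'   BUI subsets); defaults to all windows.
#' @return a `split_plan` with strategy `"SD"`.
#' @export
split_subject_dependent <- function(dataset, val_fraction = 0.3, seed = 42L,
                                    indices = NULL) {
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("val_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (is.null(indices)) indices <- seq_len(n_windows(dataset))
  n <- length(indices)
  if (n < 2) stop("need at least 2 windows to split", call. = FALSE)
  perm <- indices[fisher_yates(n, seed)]
  n_val <- round(val_fraction * n)
  n_val <- max(1L, min(n - 1L, as.integer(n_val)))
  new_split_plan("SD", sort(perm[(n_val + 1L):n]), sort(perm[seq_len(n_val)]),
                 seed = as.integer(seed),
                 params = list(val_fraction = val_fraction))
}

#' Subject-independent split
#'
#' Routes every window by its subject: windows of `val_subjects` form the
#' validation set, all others the training set. No shuffling or seed is
#' involved. The default holds out subjects 1-9, i.e. 30% of a 30-subject
#' roster.
#'
#' @param dataset a `har_dataset`.
#' @param val_subjects subject ids held out for validation; must be a
#'   nonempty proper subset of the roster.
#' @return a `split_plan` with strategy `"SI"`.
#' @export
split_subject_independent <- function(dataset, val_subjects = 1:9) {
  val_subjects <- as.integer(val_subjects)
  roster <- dataset$subject_roster
  if (length(val_subjects) == 0 || !all(val_subjects %in% roster) ||
      length(setdiff(roster, val_subjects)) == 0) {
    stop("val_subjects must be a nonempty proper subset of the subject roster",
         call. = FALSE)
  }
  in_val <- dataset$meta$subject %in% val_subjects
  new_split_plan("SI", which(!in_val), which(in_val),
                 params = list(val_subjects = val_subjects))
}

#' Per-activity biometric-identification subsets
#'
#' For each activity with at least 2 windows and at least 2 distinct
#' subjects, filters the dataset to that activity and applies the
#' subject-dependent hold-out semantics within the subset (same fraction,
#' same seed). The class target of each plan is the subject identifier.
#' Ineligible activities are skipped and listed with a reason
#' (`SINGLE_SUBJECT` or `TOO_FEW_WINDOWS`).
#'
#' @param dataset a `har_dataset`.
#' @param val_fraction validation fraction (default 0.3).
#' @param seed shuffle seed (default 42).
#' @return list with `plans` (named list of `split_plan`, strategy `"BUI"`)
#'   and `skipped` (data frame: `activity`, `reason`).
#' @export
make_bui_subsets <- function(dataset, val_fraction = 0.3, seed = 42L) {
  if (n_windows(dataset) == 0) stop("dataset is empty", call. = FALSE)
  plans <- list()
  skipped <- list()
  for (act in dataset$activity_vocabulary) {
    idx <- which(dataset$meta$activity == act)
    if (length(idx) < 2) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        activity = act, reason = "TOO_FEW_WINDOWS")
      next
    }
    if (length(unique(dataset$meta$subject[idx])) < 2) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        activity = act, reason = "SINGLE_SUBJECT")
      next
    }
    p <- split_subject_dependent(dataset, val_fraction, seed, indices = idx)
    p$strategy <- "BUI"
    p$target <- "subject"
    p$params$activity <- act
    plans[[act]] <- p
  }
  list(plans = plans,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(activity = character(), reason = character()))
}

#' Check the partition invariants of a split plan
#'
#' Verifies disjointness and exhaustiveness over the plan's eligible indices,
#' subject disjointness for SI plans, and the single-activity requirement for
#' BUI plans.
#'
#' @param plan a `split_plan`.
#' @param dataset the `har_dataset` it refers to.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_split_plan <- function(plan, dataset) {
  tr <- plan$train_indices; va <- plan$val_indices
  if (length(intersect(tr, va)) > 0) stop("train and validation overlap", call. = FALSE)
  all_idx <- sort(c(tr, va))
  if (plan$strategy %in% c("SD", "SI")) {
    if (!identical(all_idx, seq_len(n_windows(dataset)))) {
      stop("plan does not cover every window exactly once", call. = FALSE)
    }
  }
  if (plan$strategy == "SI") {
    s_tr <- unique(dataset$meta$subject[tr])
    s_va <- unique(dataset$meta$subject[va])
    if (length(intersect(s_tr, s_va)) > 0) {
      stop("SI plan shares subjects across partitions", call. = FALSE)
    }
  }
  if (plan$strategy == "BUI") {
    acts <- unique(dataset$meta$activity[all_idx])
    if (length(acts) != 1) stop("BUI plan spans multiple activities", call. = FALSE)
  }
  invisible(TRUE)
}

#' Serialize a split plan to JSON
#' @param plan a `split_plan`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  obj <- list(strategy = plan$strategy, target = plan$target,
              seed = plan$seed, params = plan$params,
              train_indices = sort(plan$train_indices),
              val_indices = sort(plan$val_indices))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path, useBytes = TRUE)
  invisible(path)
}

#' Read a split plan from JSON
#' @param path file written by [write_split_plan()].
#' @return a `split_plan`.
#' @export
read_split_plan <- function(path) {
  obj <- jsonlite::fromJSON(path)
  new_split_plan(obj$strategy, obj$train_indices, obj$val_indices,
                 seed = obj$seed, params = as.list(obj$params),
                 target = obj$target)
}
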