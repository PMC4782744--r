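#' Seeded k-fold assignment
#'
#' Randomly partitions the samples into k groups whose sizes differ by
#' at most one (109 samples and k = 4 give groups of 28, 27, 27, 27).
#' The split is sample-level: points from one tooth may land in
#' different folds, as in the reference protocol. `group_by_tooth = TRUE`
#' instead keeps all points of a tooth in one fold (then only the
#' tooth-level sizes are balanced).
#'
#' @param data a [drs_dataset()].
#' @param k number of folds, at least 2 and at most the sample count.
#' @param seed integer seed; the assignment is deterministic for a fixed
#'   seed and leaves the global RNG state untouched.
#' @param group_by_tooth keep each tooth's points together (off by
#'   default).
#' @return an object of class `"fold_assignment"`: a data frame with
#'   columns `point_id` and `fold`, with attributes `k` and `seed`.
#' @export
make_folds <- function(data, k = 4L, seed, group_by_tooth = FALSE) {
  stopifnot(inherits(data, "drs_dataset"))
  k <- as.integer(k)
  n <- nrow(data$samples)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) {
    stop(sprintf("cannot split %d samples into %d folds", n, k), call. = FALSE)
  }
  fold <- integer(n)
  with_local_seed(seed, {
    if (group_by_tooth) {
      teeth <- unique(data$samples$tooth_id)
      tf <- rep_len(seq_len(k), length(teeth))[sample.int(length(teeth))]
      fold <- tf[match(data$samples$tooth_id, teeth)]
    } else {
      fold <- rep_len(seq_len(k), n)[sample.int(n)]
    }
  })
  structure(
    data.frame(point_id = data$samples$point_id, fold = fold,
               stringsAsFactors = FALSE),
    class = c("fold_assignment", "data.frame"),
    k = k, seed = as.integer(seed)
  )
}

# run code under a temporary seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Cross-validate the rule search
#'
#' For every fold, grows a rule set on the other k-1 folds and
#' classifies the held-out fold, so each sample is used for training in
#' k-1 folds and validated exactly once. A training set that lacks one
#' of the two classes cannot drive the search; it yields an empty rule
#' set with a warning.
#'
#' @param data a [drs_dataset()] of smoothed spectra.
#' @param cfg a [search_config()].
#' @param folds a [make_folds()] assignment for `data`.
#' @return an object of class `"drs_cv"`: a list with one element per
#'   fold, each a list with `fold`, `ruleset` and `confusion` (the
#'   held-out confusion matrix).
#' @export
cross_validate <- function(data, cfg, folds) {
  stopifnot(inherits(data, "drs_dataset"), inherits(folds, "fold_assignment"))
  fold_of <- folds$fold[match(data$samples$point_id, folds$point_id)]
  if (anyNA(fold_of)) {
    stop("fold assignment does not cover every sample", call. = FALSE)
  }
  k <- attr(folds, "k")
  out <- vector("list", k)
  for (f in seq_len(k)) {
    train <- subset_samples(data, fold_of != f)
    valid <- subset_samples(data, fold_of == f)
    if (length(unique(train$samples$label)) < 2L) {
      warning(sprintf("fold %d: training set has a single class; empty rule set",
                      f), call. = FALSE)
      rs <- rule_set(max_rules = cfg$max_rule_count)
    } else {
      rs <- grow_ruleset(train, cfg)
    }
    out[[f]] <- list(fold = f, ruleset = rs,
                     confusion = confusion_matrix(valid, rs))
  }
  structure(out, class = "drs_cv")
}

#' Consolidate fold rule sets into a median rule set
#'
#' The k folds of a cross-validation each produce a rule set; the final
#' classifier is their consolidation. The number of rules is the median
#' of the fold rule counts (a fractional median rounds down). Rules are
#' then matched across folds into groups of similar rules -- same
#' direction first, nearest channel second, by a deterministic greedy
#' matcher -- and each group is collapsed into one rule whose channel
#' and threshold are the per-field medians (an even-count channel median
#' takes the lower middle channel) and whose direction is the group
#' majority (ties prefer `"at_most"`).
#'
#' @param fold_rulesets a list of [rule_set()]s or a [cross_validate()]
#'   result.
#' @param grid the [wavelength_grid()] the rules were built on (used to
#'   stamp the median rule's wavelength).
#' @return a [rule_set()].
#' @export
median_ruleset <- function(fold_rulesets, grid = NULL) {
  if (inherits(fold_rulesets, "drs_cv")) {
    fold_rulesets <- lapply(fold_rulesets, `[[`, "ruleset")
  }
  fold_rulesets <- lapply(fold_rulesets, as_rule_set)
  sizes <- lengths(fold_rulesets)
  target <- as.integer(floor(stats::median(sizes)))
  if (target < 1L) return(rule_set())
  pools <- lapply(fold_rulesets, unclass)
  out <- vector("list", target)
  for (slot in seq_len(target)) {
    remaining <- lengths(pools)
    anchor_fold <- which.max(remaining)           # ties: lowest fold index
    anchor <- pools[[anchor_fold]][[1L]]
    group <- list(anchor)
    pools[[anchor_fold]] <- pools[[anchor_fold]][-1L]
    for (f in seq_along(pools)) {
      if (f == anchor_fold || !length(pools[[f]])) next
      cand <- pools[[f]]
      penalty <- vapply(cand, function(r) {
        (r$direction != anchor$direction) * 1e9 +
          abs(r$channel - anchor$channel)
      }, numeric(1L))
      chans <- vapply(cand, `[[`, numeric(1L), "channel")
      pick <- order(penalty, chans, seq_along(cand))[1L]
      group <- c(group, cand[pick])
      pools[[f]] <- cand[-pick]
    }
    out[[slot]] <- collapse_rule_group(group, grid)
  }
  rule_set(out, max_rules = max(lengths(fold_rulesets), length(out), 5L))
}

collapse_rule_group <- function(group, grid) {
  chans <- vapply(group, `[[`, numeric(1L), "channel")
  thrs <- vapply(group, `[[`, numeric(1L), "threshold")
  dirs <- vapply(group, `[[`, character(1L), "direction")
  ch <- as.integer(floor(stats::median(chans)))   # lower middle on ties
  n_most <- sum(dirs == "at_most")
  dir <- if (n_most >= length(dirs) - n_most) "at_most" else "at_least"
  wl <- if (!is.null(grid)) unclass(as_grid(grid))[ch] else NA_real_
  threshold_rule(ch, stats::median(thrs), dir, wavelength_nm = wl)
}

#' Confusion matrix of a rule set on labeled data
#'
#' Carious is the positive class: a correctly flagged carious sample is
#' a true positive (TP), a healthy sample flagged carious is a false
#' positive (FP), a missed carious sample a false negative (FN) and a
#' correctly passed healthy sample a true negative (TN).
#'
#' @param data a [drs_dataset()].
#' @param rules a [rule_set()] built on `data`'s grid.
#' @return an object of class `"drs_confusion"` with integer fields
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(data, rules) {
  pred <- classify_spectra(data, rules)
  truth <- data$samples$label
  confusion_counts(
    tp = sum(pred == "carious" & truth == "carious"),
    fp = sum(pred == "carious" & truth == "healthy"),
    fn = sum(pred == "healthy" & truth == "carious"),
    tn = sum(pred == "healthy" & truth == "healthy")
  )
}

#' @rdname confusion_matrix
#' @param tp,fp,fn,tn non-negative integer counts, for building a
#'   confusion matrix directly (e.g. from a published contingency
#'   table).
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  counts <- as.integer(counts)
  if (anyNA(counts) || any(counts < 0L)) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(list(tp = counts[1L], fp = counts[2L], fn = counts[3L],
                 tn = counts[4L]),
            class = "drs_confusion")
}

#' @export
print.drs_confusion <- function(x, ...) {
  cat(sprintf("<drs_confusion>  TP %d  FP %d\n                 FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

# round half up to an integer percent, the granularity of the published
# tables (round() is banker's and would turn 62.5 into 62)
percent_half_up <- function(x) {
  ifelse(is.na(x), NA_integer_, as.integer(floor(100 * x + 0.5)))
}

#' Diagnostic accuracy statistics
#'
#' The five standard statistics of a diagnostic test, computed from a
#' confusion matrix with carious as the positive class:
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), accuracy = (TP+TN)/total. A statistic with
#' a zero denominator is undefined: its ratio and percent are `NA` and
#' its name is listed in the `undefined` field. Percent forms are
#' rounded half-up to integer percent, matching the granularity of
#' published contingency tables.
#'
#' @param cm a [confusion_matrix()] / [confusion_counts()] object.
#' @return an object of class `"drs_accuracy"`: list with numeric
#'   fields `ppv`, `npv`, `sensitivity`, `specificity`, `accuracy`, an
#'   integer vector `percent`, and a character vector `undefined`.
#' @export
accuracy_report <- function(cm) {
  stopifnot(inherits(cm, "drs_confusion"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total < 1L) stop("empty confusion matrix", call. = FALSE)
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  vals <- c(
    ppv = ratio(cm$tp, cm$tp + cm$fp),
    npv = ratio(cm$tn, cm$tn + cm$fn),
    sensitivity = ratio(cm$tp, cm$tp + cm$fn),
    specificity = ratio(cm$tn, cm$tn + cm$fp),
    accuracy = (cm$tp + cm$tn) / total
  )
  structure(
    c(as.list(vals),
      list(percent = percent_half_up(vals),
           undefined = names(vals)[is.na(vals)])),
    class = "drs_accuracy"
  )
}

#' @export
print.drs_accuracy <- function(x, ...) {
  lbl <- c("PPV", "NPV", "Sens.", "Spec.", "Acc.")
  pct <- ifelse(is.na(x$percent), "--", sprintf("%d%%", x$percent))
  cat("<drs_accuracy>", paste(lbl, pct, collapse = "  "), "\n")
  if (length(x$undefined)) {
    cat("  undefined (zero denominator):",
        paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}
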