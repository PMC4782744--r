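#' Single-wavelength threshold rules
#'
#' The classifier is built from decision stumps: a rule fires (votes
#' "carious") when the normalized intensity at one channel is at most --
#' or at least -- a threshold I*. A rule therefore has three parameters:
#' the wavelength (here a channel index into the grid), the intensity
#' threshold, and whether the threshold is an upper or a lower limit.
#'
#' @param channel integer channel index into the wavelength grid.
#' @param threshold finite numeric intensity threshold I*.
#' @param direction `"at_most"` (fires when `I <= threshold`) or
#'   `"at_least"` (fires when `I >= threshold`).
#' @param wavelength_nm optional wavelength of `channel`, recorded so a
#'   rule can be checked against the grid it is applied to.
#' @return an object of class `"drs_rule"`.
#' @export
threshold_rule <- function(channel, threshold,
                           direction = c("at_most", "at_least"),
                           wavelength_nm = NA_real_) {
  direction <- match.arg(direction)
  channel <- as.integer(channel)
  threshold <- as.numeric(threshold)
  if (is.na(channel) || channel < 1L) {
    stop("channel must be a positive integer", call. = FALSE)
  }
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  structure(
    list(channel = channel, wavelength_nm = as.numeric(wavelength_nm),
         threshold = threshold, direction = direction),
    class = "drs_rule"
  )
}

#' @export
print.drs_rule <- function(x, ...) {
  cat(format_rule(x), "\n")
  invisible(x)
}

format_rule <- function(r) {
  sprintf("I(ch %d%s) %s %.6g", r$channel,
          if (is.na(r$wavelength_nm)) "" else
            sprintf(" ~ %.1f nm", r$wavelength_nm),
          if (r$direction == "at_most") "<=" else ">=", r$threshold)
}

#' Rule sets (disjunctions of threshold rules)
#'
#' A rule set classifies a sample as carious if, and only if, at least
#' one of its rules fires; with no rules everything is healthy. Rules
#' are kept in selection order.
#'
#' @param rules a list of [threshold_rule()]s (or several rules as
#'   separate arguments).
#' @param max_rules size bound recorded on the set (default 5).
#' @return an object of class `"drs_ruleset"` (a list of rules).
#' @export
rule_set <- function(rules = list(), max_rules = 5L) {
  if (inherits(rules, "drs_rule")) rules <- list(rules)
  if (!is.list(rules)) stop("rules must be a list", call. = FALSE)
  ok <- vapply(rules, inherits, logical(1L), what = "drs_rule")
  if (length(rules) && !all(ok)) {
    stop("all elements must be threshold_rule objects", call. = FALSE)
  }
  if (length(rules) > max_rules) {
    stop(sprintf("%d rules exceed the maximum of %d", length(rules), max_rules),
         call. = FALSE)
  }
  structure(rules, class = "drs_ruleset", max_rules = as.integer(max_rules))
}

as_rule_set <- function(x) {
  if (inherits(x, "drs_ruleset")) x else rule_set(x)
}

#' @export
print.drs_ruleset <- function(x, ...) {
  if (!length(x)) {
    cat("<drs_ruleset> empty (classifies everything healthy)\n")
  } else {
    cat(sprintf("<drs_ruleset> carious iff any of %d rule(s) fires:\n",
                length(x)))
    for (r in x) cat("  ", format_rule(r), "\n")
  }
  invisible(x)
}

# logical matrix-free evaluation: which samples does each rule fire on?
rule_fires <- function(rule, intensities) {
  v <- intensities[rule$channel, ]
  if (rule$direction == "at_most") v <= rule$threshold else v >= rule$threshold
}

check_rule_grid <- function(rules, grid) {
  w <- unclass(as_grid(grid))
  for (r in rules) {
    if (r$channel > length(w)) {
      stop(sprintf("rule channel %d outside the %d-channel grid",
                   r$channel, length(w)), call. = FALSE)
    }
    if (!is.na(r$wavelength_nm) &&
        abs(w[r$channel] - r$wavelength_nm) > 0.5) {
      stop(sprintf(
        "grid mismatch: rule expects %.4f nm at channel %d, grid has %.4f nm",
        r$wavelength_nm, r$channel, w[r$channel]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Classify samples with a rule set
#'
#' @param x a [drs_dataset()], or a channels-x-samples matrix / single
#'   spectrum (then no grid check is possible unless `grid` is given).
#' @param rules a [rule_set()].
#' @param grid optional grid for matrix input, checked against the
#'   wavelengths recorded on the rules.
#' @return factor of predictions with levels `healthy`, `carious`.
#' @export
classify_spectra <- function(x, rules, grid = NULL) {
  rules <- as_rule_set(rules)
  if (inherits(x, "drs_dataset")) grid <- x$grid
  m <- as_intensity_matrix(x)
  if (!is.null(grid)) {
    check_rule_grid(rules, grid)
  } else {
    for (r in rules) {
      if (r$channel > nrow(m)) {
        stop(sprintf("rule channel %d outside the %d-channel spectra",
                     r$channel, nrow(m)), call. = FALSE)
      }
    }
  }
  fired <- rep(FALSE, ncol(m))
  for (r in rules) fired <- fired | rule_fires(r, m)
  factor(ifelse(fired, "carious", "healthy"), levels = label_levels)
}

#' Search configuration for the rule search
#'
#' @param wavelength_option_count number W of equally spaced wavelengths
#'   offered as options for a rule's channel; the first and the last grid
#'   wavelength are always among them. At least 2.
#' @param max_rule_count largest allowed rule-set size (default 5).
#' @return an object of class `"search_config"`.
#' @export
search_config <- function(wavelength_option_count = 15L, max_rule_count = 5L) {
  W <- as.integer(wavelength_option_count)
  if (is.na(W) || W < 2L) {
    stop("wavelength_option_count must be at least 2", call. = FALSE)
  }
  m <- as.integer(max_rule_count)
  if (is.na(m) || m < 1L) {
    stop("max_rule_count must be at least 1", call. = FALSE)
  }
  structure(list(wavelength_option_count = W, max_rule_count = m),
            class = "search_config")
}

#' Wavelength options for the rule search
#'
#' Picks `count` target wavelengths equally spaced from the first to the
#' last grid wavelength inclusive, maps each to its nearest channel and
#' drops duplicate channels (which arise when `count` approaches the
#' grid length) preserving order.
#'
#' @param grid a [wavelength_grid()].
#' @param count integer between 2 and the grid length.
#' @return integer vector of channel indices, increasing.
#' @export
wavelength_options <- function(grid, count) {
  grid <- as_grid(grid)
  count <- as.integer(count)
  if (is.na(count) || count < 2L) {
    stop("count must be at least 2", call. = FALSE)
  }
  if (count > length(grid)) {
    stop(sprintf("count %d exceeds the %d-channel grid", count, length(grid)),
         call. = FALSE)
  }
  w <- unclass(grid)
  targets <- seq(w[1L], w[length(w)], length.out = count)
  unique(nearest_channel(grid, targets))
}

#' Threshold options at one channel
#'
#' Candidate thresholds are the midpoints between each two consecutive
#' distinct intensities observed at the channel: with n distinct values
#' there are n-1 candidates, and every achievable split of the observed
#' values corresponds to one of them. Fewer than two distinct values
#' admit no separating threshold and give an empty result.
#'
#' @param values numeric intensities at one channel.
#' @return numeric vector of candidate thresholds, increasing.
#' @export
threshold_options <- function(values) {
  v <- sort(unique(as.numeric(values)))
  if (length(v) < 2L) return(numeric(0L))
  (v[-length(v)] + v[-1L]) / 2
}

# accuracy of "fired => carious" against the labels
disjunction_accuracy <- function(fired, is_carious) {
  mean(fired == is_carious)
}

#' Select the next best rule
#'
#' Exhaustively evaluates every candidate rule -- each option channel
#' (see [wavelength_options()]), each midpoint threshold computed from
#' the training intensities at that channel, both directions -- appended
#' to the already-fixed rules under the disjunction semantics, and
#' returns the candidate with the highest training accuracy. Ties break
#' deterministically: lower channel first, then smaller threshold, then
#' `"at_most"` before `"at_least"`. If no candidate *strictly* improves
#' on the accuracy of the fixed rules alone, returns `NULL`.
#'
#' @param train a [drs_dataset()] of smoothed spectra with both labels
#'   present.
#' @param fixed a [rule_set()] of already selected rules.
#' @param cfg a [search_config()].
#' @return `NULL`, or a list with elements `rule` and `accuracy`.
#' @export
select_rule <- function(train, fixed = rule_set(), cfg = search_config()) {
  stopifnot(inherits(train, "drs_dataset"), inherits(cfg, "search_config"))
  fixed <- as_rule_set(fixed)
  y <- train$samples$label == "carious"
  if (!nrow(train$samples)) stop("empty training set", call. = FALSE)
  m <- train$intensities
  base_fired <- rep(FALSE, ncol(m))
  for (r in fixed) base_fired <- base_fired | rule_fires(r, m)
  best_acc <- disjunction_accuracy(base_fired, y)
  best <- NULL
  channels <- wavelength_options(train$grid, cfg$wavelength_option_count)
  for (ch in channels) {
    v <- m[ch, ]
    for (thr in threshold_options(v)) {
      for (dir in c("at_most", "at_least")) {
        fires <- if (dir == "at_most") v <= thr else v >= thr
        acc <- disjunction_accuracy(base_fired | fires, y)
        if (acc > best_acc) {
          best_acc <- acc
          best <- threshold_rule(ch, thr, dir,
                                 wavelength_nm = unclass(train$grid)[ch])
        }
      }
    }
  }
  if (is.null(best)) NULL else list(rule = best, accuracy = best_acc)
}

#' Grow a rule set greedily
#'
#' Starting from the empty rule set (which predicts everything healthy),
#' repeatedly appends the rule returned by [select_rule()] -- the one
#' giving the best training accuracy together with the rules selected so
#' far -- until the maximum rule count is reached or no new rule strictly
#' improves the accuracy. The training accuracy after each accepted rule
#' is recorded in the `"accuracy_trace"` attribute and is strictly
#' increasing.
#'
#' @inheritParams select_rule
#' @return a [rule_set()].
#' @export
grow_ruleset <- function(train, cfg = search_config()) {
  stopifnot(inherits(train, "drs_dataset"), inherits(cfg, "search_config"))
  rules <- rule_set(max_rules = cfg$max_rule_count)
  trace <- numeric(0L)
  while (length(rules) < cfg$max_rule_count) {
    nxt <- select_rule(train, rules, cfg)
    if (is.null(nxt)) break
    rules <- rule_set(c(unclass(rules), list(nxt$rule)),
                      max_rules = cfg$max_rule_count)
    trace <- c(trace, nxt$accuracy)
  }
  attr(rules, "accuracy_trace") <- trace
  rules
}
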