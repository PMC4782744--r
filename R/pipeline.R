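#' Replay the full two-pass study protocol
#'
#' Runs the complete analysis end to end:
#'
#' 1. **Pass 1** -- smooth the spectra, split into k folds, grow a rule
#'    set per fold, consolidate into a median rule set and evaluate it
#'    on all samples;
#' 2. **relabeling** -- apply misdiagnosis hypothesis 1 (false negatives
#'    of the pass-1 median rule set become healthy) and then hypothesis
#'    2 (carious-labeled samples caught by the stain rule become
#'    healthy);
#' 3. **Pass 2** -- rerun the fold-wise search and median consolidation
#'    on the relabeled data (same fold partition) and evaluate again.
#'
#' Everything is deterministic for a fixed seed, and the report carries
#' the resolved configuration, both rule sets, both confusion matrices
#' and every relabel event.
#'
#' @param data a [drs_dataset()] of *unsmoothed* normalized spectra;
#'   defaults to a synthetic cohort generated from `cohort`.
#' @param cohort a [cohort_spec()] used when `data` is missing; its seed
#'   is taken from `seed`.
#' @param seed integer seed controlling cohort generation and fold
#'   assignment.
#' @param search a [search_config()] (default: 15 wavelength options, at
#'   most 5 rules).
#' @param smoothing a [smoothing_config()] (default: window 61,
#'   degree 6).
#' @param k number of cross-validation folds (default 4).
#' @param stain a [stain_rule()]; defaults to the standard thresholds on
#'   the data's grid.
#' @param hypotheses which relabeling hypotheses to apply, a subset of
#'   `c("H1", "H2")`.
#' @return an object of class `"drs_replay"`: list with `config`,
#'   `pass1` and `pass2` (each with `cv`, `median_rules`, `confusion`,
#'   `report`), and `relabels` (the relabel log).
#' @export
run_study_replay <- function(data = NULL, cohort = cohort_spec(), seed = 1L,
                             search = search_config(),
                             smoothing = smoothing_config(), k = 4L,
                             stain = NULL, hypotheses = c("H1", "H2")) {
  stopifnot(inherits(search, "search_config"),
            inherits(smoothing, "smoothing_config"))
  hypotheses <- match.arg(hypotheses, several.ok = TRUE)
  if (is.null(data)) {
    cohort$seed <- as.integer(seed)
    data <- generate_cohort(cohort)$data
  }
  stopifnot(inherits(data, "drs_dataset"))
  if (is.null(stain)) stain <- stain_rule(data$grid)

  smoothed <- smooth_spectra(data, smoothing)
  folds <- make_folds(smoothed, k = k, seed = seed)

  run_pass <- function(d) {
    cv <- cross_validate(d, search, folds)
    med <- median_ruleset(cv, d$grid)
    cm <- confusion_matrix(d, med)
    list(cv = cv, median_rules = med, confusion = cm,
         report = accuracy_report(cm))
  }

  pass1 <- run_pass(smoothed)
  relabeled <- smoothed
  if ("H1" %in% hypotheses) {
    relabeled <- apply_hypothesis_1(relabeled, pass1$median_rules)
  }
  if ("H2" %in% hypotheses) {
    relabeled <- apply_hypothesis_2(relabeled, stain)
  }
  pass2 <- run_pass(relabeled)

  structure(
    list(
      config = list(seed = as.integer(seed), k = as.integer(k),
                    search = search, smoothing = smoothing, stain = stain,
                    hypotheses = hypotheses),
      pass1 = pass1,
      relabels = relabeled$relabel_log,
      pass2 = pass2
    ),
    class = "drs_replay"
  )
}

#' @export
print.drs_replay <- function(x, ...) {
  cat("<drs_replay>\n-- pass 1 --\n")
  print(x$pass1$median_rules)
  print(x$pass1$confusion)
  print(x$pass1$report)
  cat(sprintf("-- relabeled: %d sample(s) (%s) --\n",
              nrow(x$relabels),
              paste(sprintf("%s=%d", names(table(x$relabels$hypothesis)),
                            table(x$relabels$hypothesis)), collapse = ", ")))
  cat("-- pass 2 --\n")
  print(x$pass2$median_rules)
  print(x$pass2$confusion)
  print(x$pass2$report)
  invisible(x)
}

#' Serialize a replay report
#'
#' Writes a machine-readable key/value document containing the resolved
#' configuration, both median rule sets, per-fold rule counts, both
#' confusion matrices with their accuracy statistics, and every relabel
#' event. The document contains no timestamps, so identical runs write
#' byte-identical reports.
#'
#' @param replay a [run_study_replay()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_replay_report <- function(replay, path) {
  stopifnot(inherits(replay, "drs_replay"))
  fmt_pass <- function(tag, p) {
    cmx <- p$confusion
    rep <- p$report
    c(
      sprintf("%s.fold_rule_counts: %s", tag,
              paste(vapply(p$cv, function(f) length(f$ruleset), integer(1L)),
                    collapse = " ")),
      sprintf("%s.n_rules: %d", tag, length(p$median_rules)),
      unlist(lapply(seq_along(p$median_rules), function(i) {
        r <- p$median_rules[[i]]
        sprintf("%s.rule.%d.%s: %s", tag, i,
                c("channel", "wavelength_nm", "threshold", "direction"),
                c(r$channel, sprintf("%.4f", r$wavelength_nm),
                  sprintf("%.17g", r$threshold), r$direction))
      })),
      sprintf("%s.confusion: tp=%d fp=%d fn=%d tn=%d", tag,
              cmx$tp, cmx$fp, cmx$fn, cmx$tn),
      sprintf("%s.percent: ppv=%s npv=%s sens=%s spec=%s acc=%s", tag,
              rep$percent[1L], rep$percent[2L], rep$percent[3L],
              rep$percent[4L], rep$percent[5L])
    )
  }
  cfg <- replay$config
  lines <- c(
    "schema: drs-replay/1",
    sprintf("seed: %d", cfg$seed),
    sprintf("k: %d", cfg$k),
    sprintf("wavelength_option_count: %d", cfg$search$wavelength_option_count),
    sprintf("max_rule_count: %d", cfg$search$max_rule_count),
    sprintf("smoothing: window=%d degree=%d",
            cfg$smoothing$window_length, cfg$smoothing$poly_degree),
    sprintf("stain_rule: low<=%.17g nir<=%.17g",
            cfg$stain$low_threshold, cfg$stain$nir_threshold),
    sprintf("hypotheses: %s", paste(cfg$hypotheses, collapse = " ")),
    fmt_pass("pass1", replay$pass1),
    sprintf("relabel.%d: point=%s hypothesis=%s old_label=%s",
            seq_len(nrow(replay$relabels)), replay$relabels$point_id,
            replay$relabels$hypothesis, replay$relabels$old_label),
    fmt_pass("pass2", replay$pass2)
  )
  writeLines(lines, path)
  invisible(path)
}
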