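#' Stain-detection rule
#'
#' A caries lesion scatters strongly, so a sample that is dark (low
#' normalized intensity) at *both* a short visible wavelength and a
#' near-infrared wavelength is not behaving like a lesion: it is most
#' plausibly a stain on healthy enamel. The stain rule is therefore a
#' conjunction -- unlike the classifier, which is a disjunction:
#' stained iff `I(~420 nm) <= 0.206` AND `I(~815 nm) <= 0.313`
#' (the default thresholds).
#'
#' @param grid the [wavelength_grid()] on which the rule is applied.
#' @param low_nm,low_threshold visible-wavelength arm (defaults 420 nm,
#'   0.206).
#' @param nir_nm,nir_threshold near-infrared arm (defaults 815 nm,
#'   0.313).
#' @return an object of class `"stain_rule"`.
#' @export
stain_rule <- function(grid, low_nm = 420, low_threshold = 0.206,
                       nir_nm = 815, nir_threshold = 0.313) {
  grid <- as_grid(grid)
  if (!is.finite(low_threshold) || !is.finite(nir_threshold)) {
    stop("stain thresholds must be finite", call. = FALSE)
  }
  ch <- nearest_channel(grid, c(low_nm, nir_nm))
  structure(
    list(low_channel = ch[1L], low_wavelength_nm = unclass(grid)[ch[1L]],
         low_threshold = as.numeric(low_threshold),
         nir_channel = ch[2L], nir_wavelength_nm = unclass(grid)[ch[2L]],
         nir_threshold = as.numeric(nir_threshold)),
    class = "stain_rule"
  )
}

#' @export
print.stain_rule <- function(x, ...) {
  cat(sprintf("<stain_rule> I(%.1f nm) <= %.4g AND I(%.1f nm) <= %.4g\n",
              x$low_wavelength_nm, x$low_threshold,
              x$nir_wavelength_nm, x$nir_threshold))
  invisible(x)
}

#' Detect stained samples
#'
#' @param x a [drs_dataset()], channels-x-samples matrix or single
#'   spectrum.
#' @param rule a [stain_rule()]; its recorded wavelengths must match the
#'   data's grid.
#' @return logical vector, one value per sample: `TRUE` iff both arms of
#'   the conjunction hold.
#' @export
detect_stain <- function(x, rule) {
  stopifnot(inherits(rule, "stain_rule"))
  if (inherits(x, "drs_dataset")) {
    w <- unclass(x$grid)
    for (arm in c("low", "nir")) {
      ch <- rule[[paste0(arm, "_channel")]]
      if (ch > length(w) ||
          abs(w[ch] - rule[[paste0(arm, "_wavelength_nm")]]) > 0.5) {
        stop("grid mismatch: stain rule was built on a different grid",
             call. = FALSE)
      }
    }
  }
  m <- as_intensity_matrix(x)
  if (max(rule$low_channel, rule$nir_channel) > nrow(m)) {
    stop("stain rule channels outside the spectra", call. = FALSE)
  }
  m[rule$low_channel, ] <= rule$low_threshold &
    m[rule$nir_channel, ] <= rule$nir_threshold
}

relabel_to_healthy <- function(data, which, hypothesis) {
  idx <- which(which)
  if (!length(idx)) return(data)
  data$relabel_log <- rbind(
    data$relabel_log,
    data.frame(point_id = data$samples$point_id[idx],
               hypothesis = hypothesis,
               old_label = as.character(data$samples$label[idx]),
               stringsAsFactors = FALSE)
  )
  data$samples$label[idx] <- "healthy"
  data
}

#' Misdiagnosis hypothesis 1: false negatives were mislabeled
#'
#' After classification, samples diagnosed carious but classified
#' healthy (false negatives) whose spectra are indistinguishable from
#' healthy spectra are hypothesised to have been misdiagnosed. This
#' operation relabels every false negative under `rules` as healthy and
#' records the change (hypothesis tag `"H1"`, old label) in the
#' dataset's relabel log, so the original diagnoses remain recoverable.
#' Applying it twice is a no-op the second time.
#'
#' @param data a [drs_dataset()].
#' @param rules the [rule_set()] whose false negatives are relabeled.
#' @return the relabeled dataset.
#' @export
apply_hypothesis_1 <- function(data, rules) {
  stopifnot(inherits(data, "drs_dataset"))
  pred <- classify_spectra(data, rules)
  fn <- data$samples$label == "carious" & pred == "healthy"
  relabel_to_healthy(data, fn, "H1")
}

#' Misdiagnosis hypothesis 2: stained samples were mistaken for caries
#'
#' A stained but healthy point can look carious to the eye. This
#' operation applies the [stain_rule()] to every carious-labeled sample
#' and relabels the stained ones as healthy, recording the change
#' (hypothesis tag `"H2"`) in the relabel log. Healthy-labeled samples
#' are never touched -- the hypothesis concerns suspected false positive
#' *diagnoses* only. Set `scan_all = TRUE` to also report (as the
#' `"stained"` attribute) which samples of either label satisfy the
#' stain rule.
#'
#' @param data a [drs_dataset()].
#' @param stain a [stain_rule()].
#' @param scan_all also report stained healthy-labeled samples (no
#'   relabeling beyond the carious-labeled ones either way).
#' @return the relabeled dataset; with `scan_all`, the point ids of all
#'   stained samples are attached as attribute `"stained"`.
#' @export
apply_hypothesis_2 <- function(data, stain, scan_all = FALSE) {
  stopifnot(inherits(data, "drs_dataset"))
  stained <- detect_stain(data, stain)
  out <- relabel_to_healthy(data, stained & data$samples$label == "carious",
                            "H2")
  if (scan_all) attr(out, "stained") <- data$samples$point_id[stained]
  out
}
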