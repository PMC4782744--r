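#' Synthetic enamel cohort specification
#'
#' Describes a cohort of synthetic diffuse-reflectance spectra with the
#' statistical structure the analysis assumes, so that every pipeline
#' stage can be exercised without access to measured data. Four spectral
#' phenotypes are generated:
#'
#' * **healthy** enamel: a smooth per-tooth baseline with large
#'   between-tooth variability concentrated at visible wavelengths;
#' * **carious** enamel: the baseline plus a positive near-infrared
#'   elevation (increased scattering in the lesion) that clears a
#'   planted threshold at ~791 nm;
#' * **indistinct carious**: spectrally healthy -- drawn from the
#'   *central* part of the healthy parameter ranges -- but carrying an
#'   observed label of carious, emulating misdiagnosed points;
#' * **stained healthy**: a healthy curve suppressed multiplicatively so
#'   the intensity falls below the stain-rule thresholds at both ~420 nm
#'   and ~815 nm, also observed-labeled carious.
#'
#' The default composition (69 / 17 / 15 / 8 over 21 teeth) yields the
#' reference cohort of 109 points with observed labels 69 healthy and
#' 40 carious.
#'
#' @param n_teeth number of teeth; points are spread near-evenly over
#'   them.
#' @param n_healthy,n_carious,n_indistinct,n_stained phenotype counts.
#' @param replicate_count replicates averaged per point (default 100).
#' @param noise_sigma per-replicate zero-mean normal noise sd (default
#'   0.01). After averaging the effective noise sd is
#'   `noise_sigma / sqrt(replicate_count)`; a spec whose effective noise
#'   would overwhelm the planted class separation is rejected.
#' @param seed integer seed; generation is deterministic for a fixed
#'   seed.
#' @return an object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_teeth = 21L, n_healthy = 69L, n_carious = 17L,
                        n_indistinct = 15L, n_stained = 8L,
                        replicate_count = 100L, noise_sigma = 0.01,
                        seed = 1L) {
  spec <- list(
    n_teeth = as.integer(n_teeth), n_healthy = as.integer(n_healthy),
    n_carious = as.integer(n_carious), n_indistinct = as.integer(n_indistinct),
    n_stained = as.integer(n_stained),
    replicate_count = as.integer(replicate_count),
    noise_sigma = as.numeric(noise_sigma), seed = as.integer(seed)
  )
  if (spec$n_teeth < 1L || spec$replicate_count < 1L) {
    stop("n_teeth and replicate_count must be positive", call. = FALSE)
  }
  if (spec$n_healthy < 1L || spec$n_carious < 1L ||
      spec$n_indistinct < 0L || spec$n_stained < 0L) {
    stop("need at least one healthy and one carious point", call. = FALSE)
  }
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (spec$noise_sigma / sqrt(spec$replicate_count) > 0.005) {
    stop(paste("infeasible spec: averaged noise sd exceeds 0.005 and would",
               "overwhelm the planted class separation"), call. = FALSE)
  }
  structure(spec, class = "cohort_spec")
}

# phenotype shape parameters, shared by the generator and planted_truth().
# u is the wavelength position scaled to [0, 1] over 420-1000 nm.
.syn <- list(
  level_mean = 0.22, level_sd = 0.025, level_lo = 0.15, level_hi = 0.27,
  dlevel_sd = 0.006, dlevel_max = 0.015,
  amp_mean = 0.10, amp_sd = 0.05, amp_lo = 0.01, amp_hi = 0.24,
  damp_sd = 0.015, damp_max = 0.04,
  vis_center_lo = 0.05, vis_center_hi = 0.18, vis_width = 0.10,
  slope = 0.04,
  nir_center = 0.535, nir_scale = 0.02,
  carious_floor = 0.36, carious_jitter = 0.06,
  ind_level_sd = 0.012, ind_level_lo = 0.20, ind_level_hi = 0.24,
  ind_amp_sd = 0.02, ind_amp_lo = 0.06, ind_amp_hi = 0.14,
  stain_scale = 0.6, stain_low_cap = 0.185, stain_nir_cap = 0.28,
  planted_nm = 791
)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

rnorm_clamped <- function(n, mean, sd, lo, hi) {
  clamp(stats::rnorm(n, mean, sd), lo, hi)
}

# logistic near-infrared elevation profile of the carious phenotype
nir_profile <- function(u) stats::plogis((u - .syn$nir_center) / .syn$nir_scale)

#' Planted ground-truth rule of the synthetic generator
#'
#' The generator separates carious from non-carious clean curves at a
#' near-infrared channel: every non-carious clean curve stays below the
#' lower edge of a guaranteed intensity gap at ~791 nm and every carious
#' clean curve is constructed to reach at least its upper edge. The
#' planted rule fires at-least at the gap midpoint; the gap itself is
#' attached as attribute `"gap"` for parameter-recovery checks.
#'
#' @param spec a [cohort_spec()] (reserved; the planted rule currently
#'   depends only on the phenotype shape constants).
#' @param grid the [wavelength_grid()] the cohort is generated on.
#' @return a [threshold_rule()] with attribute `"gap"` (length-2
#'   numeric, the open interval separating the classes).
#' @export
planted_truth <- function(spec = cohort_spec(), grid = default_wavelength_grid()) {
  grid <- as_grid(grid)
  w <- unclass(grid)
  ch <- nearest_channel(grid, .syn$planted_nm)
  u <- (w[ch] - w[1L]) / (w[length(w)] - w[1L])
  vis_tail <- (.syn$amp_hi + .syn$damp_max) *
    exp(-((u - .syn$vis_center_hi)^2) / (2 * .syn$vis_width^2))
  nc_hi <- .syn$level_hi + .syn$dlevel_max + .syn$slope * u + vis_tail
  gap <- c(nc_hi, .syn$carious_floor)
  rule <- threshold_rule(ch, mean(gap), "at_least", wavelength_nm = w[ch])
  attr(rule, "gap") <- gap
  rule
}

#' Generate a synthetic labeled cohort
#'
#' Draws per-tooth baseline curves, assigns each measurement point a
#' phenotype, builds the clean phenotype curve, and adds the averaged
#' measurement noise (zero-mean normal with sd
#' `noise_sigma / sqrt(replicate_count)`, exactly the distribution of
#' the mean of `replicate_count` i.i.d. noisy replicates). Indistinct
#' and stained points carry the observed label "carious" while their
#' true phenotype is healthy(-stained); the returned truth table keeps
#' both.
#'
#' @param spec a [cohort_spec()].
#' @param grid the [wavelength_grid()] to generate on.
#' @return an object of class `"drs_cohort"`: list with
#'   * `data` -- a [drs_dataset()] with the *observed* labels,
#'   * `truth` -- data frame `point_id`, `tooth_id`, `phenotype`,
#'     `observed_label`,
#'   * `clean` -- matrix of noiseless phenotype curves,
#'   * `planted` -- the [planted_truth()] rule, and
#'   * `spec` -- the input spec.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            grid = default_wavelength_grid()) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- as_grid(grid)
  w <- unclass(grid)
  u <- (w - w[1L]) / (w[length(w)] - w[1L])
  nch <- length(w)
  n <- spec$n_healthy + spec$n_carious + spec$n_indistinct + spec$n_stained
  if (spec$n_teeth > n) {
    stop("more teeth than measurement points", call. = FALSE)
  }
  ch420 <- nearest_channel(grid, 420)
  ch815 <- nearest_channel(grid, 815)
  planted <- planted_truth(spec, grid)
  ch_nir <- planted$channel
  phi <- nir_profile(u)
  phi_nir <- phi[ch_nir]
  s <- .syn

  clean <- matrix(NA_real_, nch, n)
  out <- with_local_seed(spec$seed, {
    tooth <- sample(rep_len(seq_len(spec$n_teeth), n))
    phenotype <- sample(rep(
      c("healthy", "carious", "indistinct_carious", "stained_healthy"),
      c(spec$n_healthy, spec$n_carious, spec$n_indistinct, spec$n_stained)
    ))
    level_t <- rnorm_clamped(spec$n_teeth, s$level_mean, s$level_sd,
                             s$level_lo, s$level_hi)
    amp_t <- rnorm_clamped(spec$n_teeth, s$amp_mean, s$amp_sd,
                           s$amp_lo, s$amp_hi)
    center_t <- stats::runif(spec$n_teeth, s$vis_center_lo, s$vis_center_hi)
    for (i in seq_len(n)) {
      t <- tooth[i]
      if (phenotype[i] == "indistinct_carious") {
        # spectrally "typical" healthy: central parameter band, so these
        # points are never the population extreme at any channel
        level <- rnorm_clamped(1L, s$level_mean, s$ind_level_sd,
                               s$ind_level_lo, s$ind_level_hi)
        amp <- rnorm_clamped(1L, s$amp_mean, s$ind_amp_sd,
                             s$ind_amp_lo, s$ind_amp_hi)
      } else {
        level <- level_t[t] + rnorm_clamped(1L, 0, s$dlevel_sd,
                                            -s$dlevel_max, s$dlevel_max)
        amp <- clamp(amp_t[t] + rnorm_clamped(1L, 0, s$damp_sd,
                                              -s$damp_max, s$damp_max),
                     s$amp_lo, s$amp_hi + s$damp_max)
      }
      curve <- level +
        amp * exp(-((u - center_t[t])^2) / (2 * s$vis_width^2)) +
        s$slope * u
      if (phenotype[i] == "carious") {
        target <- s$carious_floor + stats::runif(1L, 0, s$carious_jitter)
        curve <- curve + (target - curve[ch_nir]) / phi_nir * phi
      } else if (phenotype[i] == "stained_healthy") {
        scale <- min(s$stain_scale,
                     s$stain_low_cap / curve[ch420],
                     s$stain_nir_cap / curve[ch815])
        curve <- curve * scale
      }
      clean[, i] <- curve
    }
    if (any(clean < 0) || any(clean > 1)) {
      stop("infeasible spec: clean curves stray outside [0, 1]", call. = FALSE)
    }
    noise_se <- spec$noise_sigma / sqrt(spec$replicate_count)
    observed <- clean + matrix(stats::rnorm(nch * n, 0, noise_se), nch, n)
    list(tooth = tooth, phenotype = phenotype, observed = observed)
  })

  point_id <- sprintf("p%03d", seq_len(n))
  tooth_id <- sprintf("t%02d", out$tooth)
  observed_label <- ifelse(out$phenotype == "healthy", "healthy", "carious")
  data <- drs_dataset(grid, out$observed, observed_label,
                      point_id = point_id, tooth_id = tooth_id)
  colnames(clean) <- point_id
  structure(
    list(
      data = data,
      truth = data.frame(point_id = point_id, tooth_id = tooth_id,
                         phenotype = out$phenotype,
                         observed_label = observed_label,
                         stringsAsFactors = FALSE),
      clean = clean,
      planted = planted,
      spec = spec
    ),
    class = "drs_cohort"
  )
}

#' @export
print.drs_cohort <- function(x, ...) {
  tab <- table(x$truth$phenotype)
  cat(sprintf(
    "<drs_cohort> %d points / %d teeth (seed %d)\n  phenotypes: %s\n",
    nrow(x$truth), x$spec$n_teeth, x$spec$seed,
    paste(names(tab), tab, sep = "=", collapse = ", ")
  ))
  cat("  planted:", format_rule(x$planted), "\n")
  invisible(x)
}
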