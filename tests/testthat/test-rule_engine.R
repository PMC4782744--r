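test_that("classification is the disjunction of the fired rules", {
  g <- default_wavelength_grid()
  ch420 <- nearest_channel(g, 420)
  ch750 <- nearest_channel(g, 750)
  rs <- rule_set(list(
    threshold_rule(ch420, 0.2642, "at_most"),
    threshold_rule(ch750, 0.3502, "at_least")
  ))
  fires_second <- probe_spectrum(g, 0.30, c(ch420, ch750), c(0.30, 0.40))
  neither <- probe_spectrum(g, 0.30, c(ch420, ch750), c(0.30, 0.30))
  expect_identical(as.character(classify_spectra(fires_second, rs)), "carious")
  expect_identical(as.character(classify_spectra(neither, rs)), "healthy")
  expect_identical(as.character(classify_spectra(neither, rule_set())),
                   "healthy")
  # thresholds are inclusive in both directions
  at_bounds <- probe_spectrum(g, 0.30, c(ch420, ch750), c(0.2642, 0.30))
  expect_identical(as.character(classify_spectra(at_bounds, rs)), "carious")
})

test_that("classification rejects rules from another grid", {
  d <- random_dataset(1, n_samples = 4L, n_channels = 10L)
  alien <- rule_set(threshold_rule(3L, 0.5, "at_most", wavelength_nm = 123.4))
  expect_error(classify_spectra(d, alien), "grid mismatch")
  far <- rule_set(threshold_rule(99L, 0.5, "at_most"))
  expect_error(classify_spectra(d, far), "outside")
})

test_that("wavelength options are equally spaced and span the grid", {
  g <- default_wavelength_grid()
  two <- wavelength_options(g, 2)
  expect_identical(two, c(1L, 2305L))
  three <- wavelength_options(wavelength_grid(seq(420, 1000, 10)), 3)
  w <- seq(420, 1000, 10)
  expect_equal(w[three], c(420, 710, 1000))
  all_ch <- wavelength_options(tiny_grid(9L), 9)
  expect_identical(all_ch, 1:9)
  expect_error(wavelength_options(g, 1), "at least 2")
  expect_error(wavelength_options(tiny_grid(5L), 6), "exceeds")
})

test_that("threshold options are midpoints of consecutive distinct values", {
  expect_equal(threshold_options(c(0.1, 0.2, 0.4)), c(0.15, 0.3))
  expect_identical(threshold_options(c(0.3, 0.3, 0.3)), numeric(0))
  expect_equal(threshold_options(c(0.4, 0.1, 0.2)), c(0.15, 0.3))
  expect_identical(threshold_options(0.7), numeric(0))
})

test_that("select_rule finds the separating stump on 1-D separable data", {
  g <- tiny_grid(2L)
  m <- rbind(c(0.1, 0.2, 0.6, 0.8), rep(0.5, 4))
  d <- drs_dataset(g, m, c("healthy", "healthy", "carious", "carious"))
  got <- select_rule(d, cfg = search_config(2))
  expect_equal(got$accuracy, 1)
  expect_identical(got$rule$channel, 1L)
  expect_equal(got$rule$threshold, 0.4)
  expect_identical(got$rule$direction, "at_least")
})

test_that("select_rule returns NULL when nothing beats the baseline", {
  g <- tiny_grid(3L)
  d <- drs_dataset(g, matrix(runif(12), 3, 4), rep("healthy", 4))
  expect_null(select_rule(d, cfg = search_config(3)))
})

test_that("select_rule matches the brute-force oracle accuracy", {
  for (seed in 1:25) {
    set.seed(seed)
    W <- sample(2:5, 1)
    d <- random_dataset(seed + 1000, n_samples = sample(10:25, 1))
    got <- select_rule(d, cfg = search_config(W))
    opts <- wavelength_options(d$grid, W)
    want <- oracle_best_accuracy(d, list(), opts)
    base <- mean(d$samples$label == "healthy")
    expect_equal(if (is.null(got)) base else got$accuracy, want)
  }
})

test_that("greedy growth finds one rule per carious region", {
  # carious iff low at channel 1 OR high at channel 3
  g <- tiny_grid(3L)
  m <- rbind(
    c(0.5, 0.55, 0.45, 0.1, 0.15, 0.5, 0.5),
    rep(0.5, 7),
    c(0.3, 0.35, 0.25, 0.3, 0.3, 0.8, 0.85)
  )
  lab <- c("healthy", "healthy", "healthy", "carious", "carious",
           "carious", "carious")
  d <- drs_dataset(g, m, lab)
  rs <- grow_ruleset(d, search_config(3))
  expect_length(rs, 2L)
  expect_equal(attr(rs, "accuracy_trace"),
               oracle_greedy_trace(d, wavelength_options(d$grid, 3)))
  expect_equal(attr(rs, "accuracy_trace")[2], 1)
  dirs <- sort(vapply(rs, `[[`, character(1), "direction"))
  expect_identical(dirs, c("at_least", "at_most"))
})

test_that("growth stops at one rule on separable data, empty when hopeless", {
  g <- tiny_grid(2L)
  d <- drs_dataset(g, rbind(c(0.1, 0.2, 0.7, 0.9), rep(0.5, 4)),
                   c("healthy", "healthy", "carious", "carious"))
  rs <- grow_ruleset(d, search_config(2))
  expect_length(rs, 1L)
  expect_equal(attr(rs, "accuracy_trace"), 1)

  # alternating labels on identical intensities: no stump beats majority
  d2 <- drs_dataset(g, matrix(0.5, 2, 6),
                    rep(c("healthy", "carious"), 3))
  expect_length(grow_ruleset(d2, search_config(2)), 0L)
})

test_that("adding rules never flips a carious prediction back to healthy", {
  for (seed in 1:10) {
    d <- random_dataset(seed + 50, n_samples = 15L)
    rs <- grow_ruleset(d, search_config(4))
    pred_prev <- classify_spectra(d, rule_set())
    for (len in seq_along(rs)) {
      pred <- classify_spectra(d, rule_set(unclass(rs)[1:len]))
      expect_true(all(pred[pred_prev == "carious"] == "carious"))
      pred_prev <- pred
    }
  }
})

test_that("the training accuracy trace is strictly increasing", {
  for (seed in 1:10) {
    d <- random_dataset(seed + 200, n_samples = 18L)
    tr <- attr(grow_ruleset(d, search_config(5)), "accuracy_trace")
    if (length(tr) > 1) expect_true(all(diff(tr) > 0))
  }
})

test_that("midpoints realize every interior-threshold stump outcome", {
  # any threshold strictly between the observed extremes induces the same
  # firing set as one of the midpoints; verify the midpoint set attains
  # the optimum of a dense sweep of interior thresholds
  for (seed in 1:20) {
    set.seed(seed)
    v <- runif(sample(5:15, 1))
    y <- sample(c(TRUE, FALSE), length(v), replace = TRUE)
    y[1:2] <- c(TRUE, FALSE)
    sv <- sort(v)
    exhaustive <- sort(c(sv[-1] - 1e-9, sv[-1],
                         sv[-length(sv)] + 1e-9))
    acc <- function(t, dir) {
      fires <- if (dir == "at_most") v <= t else v >= t
      mean(fires == y)
    }
    best_any <- max(vapply(exhaustive, acc, numeric(1), dir = "at_most"),
                    vapply(exhaustive, acc, numeric(1), dir = "at_least"))
    mids <- threshold_options(v)
    best_mid <- max(vapply(mids, acc, numeric(1), dir = "at_most"),
                    vapply(mids, acc, numeric(1), dir = "at_least"))
    expect_gte(best_mid, best_any)
  }
})

test_that("rule sets respect their size bound", {
  r <- threshold_rule(1L, 0.5)
  expect_error(rule_set(rep(list(r), 6)), "exceed")
  expect_silent(rule_set(rep(list(r), 6), max_rules = 6))
})
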