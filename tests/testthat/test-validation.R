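make_cohort_like <- function(seed, n = 109L) {
  random_dataset(seed, n_samples = n, n_channels = 12L)
}

test_that("folds are near-equal, seeded and deterministic", {
  d <- make_cohort_like(1)
  f <- make_folds(d, 4, seed = 10)
  expect_identical(sort(as.integer(table(f$fold)), decreasing = TRUE),
                   c(28L, 27L, 27L, 27L))
  expect_identical(f, make_folds(d, 4, seed = 10))
  expect_false(identical(f$fold, make_folds(d, 4, seed = 11)$fold))

  d8 <- random_dataset(2, n_samples = 8L)
  expect_identical(as.integer(table(make_folds(d8, 4, seed = 1)$fold)),
                   rep(2L, 4))
  expect_error(make_folds(d8, 9, seed = 1), "cannot split")
  expect_error(make_folds(d8, 1, seed = 1), "at least 2")
})

test_that("tooth-level folds keep each tooth together", {
  co <- generate_cohort(cohort_spec(seed = 3))
  f <- make_folds(co$data, 4, seed = 5, group_by_tooth = TRUE)
  per_tooth <- tapply(f$fold, co$data$samples$tooth_id,
                      function(x) length(unique(x)))
  expect_true(all(per_tooth == 1L))
})

test_that("cross-validation trains on k-1 folds and validates each sample once", {
  d <- random_dataset(7, n_samples = 24L)
  folds <- make_folds(d, 4, seed = 2)
  cv <- cross_validate(d, search_config(4), folds)
  expect_length(cv, 4L)
  validated <- unlist(lapply(seq_along(cv), function(f) {
    cm <- cv[[f]]$confusion
    cm$tp + cm$fp + cm$fn + cm$tn
  }))
  expect_identical(as.integer(validated), as.integer(table(folds$fold)))
  expect_identical(sum(validated), 24L)
})

test_that("sample order does not affect per-fold results", {
  d <- random_dataset(8, n_samples = 20L)
  folds <- make_folds(d, 4, seed = 3)
  cv1 <- cross_validate(d, search_config(3), folds)
  set.seed(99)
  shuffled <- subset_samples(d, sample(20L))
  cv2 <- cross_validate(shuffled, search_config(3), folds)
  for (f in 1:4) {
    expect_equal(cv1[[f]]$ruleset, cv2[[f]]$ruleset)
    expect_equal(cv1[[f]]$confusion, cv2[[f]]$confusion)
  }
})

test_that("a single-class training fold yields an empty rule set with warning", {
  g <- tiny_grid(4L)
  m <- matrix(runif(24), 4, 6)
  d <- drs_dataset(g, m, c("carious", rep("healthy", 5)))
  folds <- structure(
    data.frame(point_id = d$samples$point_id, fold = c(1L, 1L, 2L, 2L, 1L, 2L)),
    class = c("fold_assignment", "data.frame"), k = 2L, seed = 0L
  )
  # fold 2 held out -> training set {p1..} contains the only carious; fold 1
  # held out -> training has only healthy samples
  expect_warning(cv <- cross_validate(d, search_config(2), folds),
                 "single class")
  expect_length(cv[[1]]$ruleset, 0L)
})

test_that("the median rule set medians matched rules across folds", {
  g <- default_wavelength_grid()
  ch <- nearest_channel(g, 791)
  folds <- lapply(c(-3L, -1L, 1L, 3L), function(off) {
    rule_set(threshold_rule(ch + off, c(0.30, 0.32, 0.33, 0.35)[match(off, c(-3, -1, 1, 3))],
                            "at_least", wavelength_nm = unclass(g)[ch + off]))
  })
  med <- median_ruleset(folds, g)
  expect_length(med, 1L)
  expect_equal(med[[1]]$threshold, 0.325)
  expect_identical(med[[1]]$direction, "at_least")
  expect_identical(med[[1]]$channel, ch)  # median of ch+{-3,-1,1,3}
})

test_that("median consolidation is idempotent and order-insensitive", {
  g <- tiny_grid(30L)
  rs <- rule_set(list(
    threshold_rule(5L, 0.2, "at_most", wavelength_nm = unclass(g)[5]),
    threshold_rule(22L, 0.6, "at_least", wavelength_nm = unclass(g)[22])
  ))
  same <- median_ruleset(list(rs, rs, rs, rs), g)
  expect_equal(unclass(same), unclass(rs), ignore_attr = TRUE)

  jitter_rs <- function(d1, d2, t1, t2) rule_set(list(
    threshold_rule(5L + d1, 0.2 + t1, "at_most"),
    threshold_rule(22L + d2, 0.6 + t2, "at_least")
  ))
  sets <- list(jitter_rs(0, 0, 0, 0), jitter_rs(1, -1, 0.01, -0.01),
               jitter_rs(-1, 1, -0.01, 0.01), jitter_rs(2, -2, 0.02, -0.02))
  med <- median_ruleset(sets, g)
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    expect_equal(median_ruleset(sets[perm], g), med)
  }
})

test_that("a fractional median rule count rounds down", {
  r <- function(ch) threshold_rule(ch, 0.5, "at_least")
  sets <- list(rule_set(list(r(3L))), rule_set(list(r(4L))),
               rule_set(list(r(3L), r(10L))), rule_set(list(r(4L), r(11L))))
  med <- median_ruleset(sets)  # sizes 1,1,2,2 -> median 1.5 -> 1 rule
  expect_length(med, 1L)
  expect_length(median_ruleset(list(rule_set(), rule_set())), 0L)
})

test_that("confusion matrices count against carious as positive", {
  g <- tiny_grid(2L)
  m <- rbind(c(rep(0.2, 6), rep(0.8, 4)), rep(0.5, 10))
  d <- drs_dataset(g, m, c(rep("healthy", 6), rep("carious", 4)))
  cm <- confusion_matrix(d, rule_set(threshold_rule(1L, 0.5, "at_least")))
  expect_identical(c(cm$tp, cm$fp, cm$fn, cm$tn), c(4L, 0L, 0L, 6L))

  # empty rule set on the study composition: everything predicted healthy
  d2 <- random_dataset(4, n_samples = 109L)
  d2$samples$label <- factor(rep(c("carious", "healthy"), c(40, 69)),
                             levels = c("healthy", "carious"))
  cm2 <- confusion_matrix(d2, rule_set())
  expect_identical(c(cm2$tp, cm2$fp, cm2$fn, cm2$tn), c(0L, 0L, 40L, 69L))
})

test_that("accuracy statistics reproduce their defining ratios", {
  rep1 <- accuracy_report(confusion_counts(25, 2, 15, 67))
  expect_equal(rep1$ppv, 25 / 27)
  expect_equal(rep1$npv, 67 / 82)
  expect_equal(rep1$sensitivity, 25 / 40)
  expect_equal(rep1$specificity, 67 / 69)
  expect_equal(rep1$accuracy, 92 / 109)
  expect_identical(unname(rep1$percent), c(93L, 82L, 63L, 97L, 84L))

  deg <- accuracy_report(confusion_counts(0, 0, 0, 12))
  expect_true(all(c("ppv", "sensitivity") %in% deg$undefined))
  expect_identical(deg$percent[["specificity"]], 100L)
  expect_identical(deg$percent[["accuracy"]], 100L)
})

test_that("accuracy decomposes into prevalence-weighted sens and spec", {
  set.seed(31)
  for (i in 1:25) {
    cm <- confusion_counts(sample(1:50, 1), sample(1:50, 1),
                           sample(1:50, 1), sample(1:50, 1))
    r <- accuracy_report(cm)
    P <- cm$tp + cm$fn
    N <- cm$tn + cm$fp
    expect_equal(r$accuracy,
                 (r$sensitivity * P + r$specificity * N) / (P + N))
  }
})
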