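# Shared fixtures and independent oracles used across test files.

tiny_grid <- function(n = 12L, from = 420, to = 1000) {
  wavelength_grid(seq(from, to, length.out = n))
}

# random labeled dataset with both classes guaranteed
random_dataset <- function(seed, n_samples = 20L, n_channels = 12L) {
  set.seed(seed)
  m <- matrix(stats::runif(n_channels * n_samples), n_channels, n_samples)
  lab <- sample(c("healthy", "carious"), n_samples, replace = TRUE)
  lab[1:2] <- c("healthy", "carious")
  drs_dataset(tiny_grid(n_channels), m, lab)
}

# spectrum that is constant except at chosen channels
probe_spectrum <- function(grid, base = 0.30, at = integer(), values = numeric()) {
  x <- rep(base, length(grid))
  x[at] <- values
  x
}

# --- independent brute-force oracle for the stump search ----------------
# Enumerates every (channel option, midpoint threshold, direction)
# candidate appended to `fixed` and returns the maximum disjunction
# accuracy. Written against the spec of the search, not its code path.
oracle_fired <- function(rules, m) {
  fired <- rep(FALSE, ncol(m))
  for (r in rules) {
    v <- m[r$channel, ]
    fired <- fired |
      if (r$direction == "at_most") v <= r$threshold else v >= r$threshold
  }
  fired
}

oracle_best_accuracy <- function(data, fixed, option_channels) {
  m <- data$intensities
  y <- data$samples$label == "carious"
  base <- oracle_fired(fixed, m)
  best <- mean(base == y)
  for (ch in option_channels) {
    v <- sort(unique(m[ch, ]))
    if (length(v) < 2L) next
    mids <- (v[-length(v)] + v[-1L]) / 2
    for (t in mids) {
      for (dir in c("at_most", "at_least")) {
        fires <- if (dir == "at_most") m[ch, ] <= t else m[ch, ] >= t
        best <- max(best, mean((base | fires) == y))
      }
    }
  }
  best
}

# independent greedy replay: sequence of best accuracies, stopping on
# no strict improvement or the rule cap
oracle_greedy_trace <- function(data, option_channels, max_rules = 5L) {
  m <- data$intensities
  y <- data$samples$label == "carious"
  fixed <- list()
  trace <- numeric()
  base_acc <- mean(oracle_fired(fixed, m) == y)
  repeat {
    if (length(fixed) >= max_rules) break
    best <- base_acc
    best_rule <- NULL
    base <- oracle_fired(fixed, m)
    for (ch in option_channels) {
      v <- sort(unique(m[ch, ]))
      if (length(v) < 2L) next
      mids <- (v[-length(v)] + v[-1L]) / 2
      for (t in mids) {
        for (dir in c("at_most", "at_least")) {
          fires <- if (dir == "at_most") m[ch, ] <= t else m[ch, ] >= t
          acc <- mean((base | fires) == y)
          if (acc > best) {
            best <- acc
            best_rule <- threshold_rule(ch, t, dir)
          }
        }
      }
    }
    if (is.null(best_rule)) break
    fixed <- c(fixed, list(best_rule))
    trace <- c(trace, best)
    base_acc <- best
  }
  trace
}
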