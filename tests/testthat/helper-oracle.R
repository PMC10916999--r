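# Independent brute-force reference implementations of the four motor
# features, written directly from their plain definitions with explicit
# loops. They deliberately share no code with the package.

oracle_frequency <- function(down_ms, duration_s) {
  length(down_ms) / duration_s
}

oracle_variability <- function(down_ms) {
  n <- length(down_ms)
  if (n < 3) return(NA_real_)
  intervals <- numeric(n - 1)
  for (i in 2:n) intervals[i - 1] <- down_ms[i] - down_ms[i - 1]
  lg <- log(intervals)
  m <- sum(lg) / length(lg)
  ss <- 0
  for (v in lg) ss <- ss + (v - m)^2
  sqrt(ss / (length(lg) - 1))
}

oracle_dwell <- function(down_ms, up_ms) {
  n <- length(down_ms)
  if (n == 0) return(NA_real_)
  total <- 0
  for (i in seq_len(n)) total <- total + (up_ms[i] - down_ms[i])
  total / n
}

# expected-key sequence, re-derived from the documented convention:
# single-key expects the spacebar throughout; alternate-key alternates
# between "s" and "semicolon", anchored on the first press that hits either
# target (default anchor "s"), advancing on every press
oracle_expected <- function(keys, test_type) {
  n <- length(keys)
  if (test_type == "single_key") return(rep("space", n))
  anchor <- "s"
  offset <- 1
  for (i in seq_len(n)) {
    if (keys[i] %in% c("s", "semicolon")) {
      anchor <- keys[i]
      offset <- i
      break
    }
  }
  other <- if (anchor == "s") "semicolon" else "s"
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if ((i - offset) %% 2 == 0) anchor else other
  }
  out
}

oracle_accuracy <- function(keys, test_type, adjacency) {
  n <- length(keys)
  if (n == 0) return(NA_real_)
  expected <- oracle_expected(keys, test_type)
  total <- 0
  for (i in seq_len(n)) {
    pts <- 3
    if (keys[i] == expected[i]) {
      pts <- 1
    } else if (keys[i] %in% adjacency[[expected[i]]]) {
      pts <- 2
    }
    total <- total + pts
  }
  total / n
}

# Random small block generator for property tests: n_events presses with
# random integer intervals and a random mix of correct/adjacent/other keys.
random_block <- function(test_type = c("single_key", "alternate_key"),
                         n_events = sample(3:10, 1)) {
  test_type <- match.arg(test_type)
  duration_s <- block_duration_s(test_type)
  gaps <- sample(40:900, n_events, replace = TRUE)
  down <- cumsum(gaps)
  down <- down[down < duration_s * 1000 - 1]
  n <- length(down)
  dwell <- sample(20:200, n, replace = TRUE)
  up <- pmin(down + dwell, duration_s * 1000)
  adjacency <- default_adjacency()
  expected <- if (test_type == "single_key") {
    rep("space", n)
  } else {
    rep(c("s", "semicolon"), length.out = n)
  }
  keys <- character(n)
  for (i in seq_len(n)) {
    keys[i] <- switch(sample(c("correct", "adjacent", "other"), 1,
      prob = c(0.7, 0.2, 0.1)
    ),
    correct = expected[i],
    adjacent = sample(adjacency[[expected[i]]], 1),
    other = sample(c("q", "g", "h", "k"), 1)
    )
  }
  tapping_block(keys, down, up,
    test_type = test_type,
    hand = "dominant", block_index = 1L
  )
}

# Small simulated analysis tables are expensive; cache them per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached_analysis_table <- function(tag, n, seed, ...) {
  key <- paste0(tag, "_", n, "_", seed)
  if (!exists(key, envir = .fixture_cache)) {
    cfg <- sim_config(
      n_participants = n, seed = seed,
      exclusions = list(n_symptomatic = 0, n_pd = 0, n_ms = 0, n_incomplete = 0),
      ...
    )
    cohort <- simulate_cohort(cfg)
    features <- build_feature_table(cohort$events,
      participant_ids = cohort$participants$participant_id
    )
    assign(key, analysis_table(cohort$participants, features),
      envir = .fixture_cache
    )
  }
  get(key, envir = .fixture_cache)
}
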