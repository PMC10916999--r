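test_that("tapping frequency is presses per second", {
  down <- seq(0, by = 178, length.out = 56)
  b <- tapping_block(rep("space", 56), down, down + 90, "single_key")
  expect_equal(tapping_frequency(b), 5.6)
  empty <- tapping_block(character(0), numeric(0), numeric(0), "single_key")
  expect_equal(tapping_frequency(empty), 0)
})

test_that("variability is the sample SD of log inter-press intervals", {
  # perfectly rhythmic tapping has zero variability
  down <- seq(0, by = 180, length.out = 10)
  b <- tapping_block(rep("space", 10), down, down + 80, "single_key")
  expect_equal(tapping_variability(b), 0)

  # intervals 100 and 400 ms: sample SD of {ln 100, ln 400} = ln(4)/sqrt(2)
  b2 <- tapping_block(rep("space", 3), c(0, 100, 500), c(50, 150, 560),
    "single_key"
  )
  expect_equal(tapping_variability(b2), log(4) / sqrt(2), tolerance = 1e-12)

  # fewer than two intervals: missing value with a warning, not an error
  b3 <- tapping_block(rep("space", 2), c(0, 100), c(40, 150), "single_key")
  expect_warning(v <- tapping_variability(b3), "variability")
  expect_true(is.na(v))
})

test_that("variability is invariant to rescaling and translation of timestamps", {
  down <- c(0, 130, 310, 580, 720, 1100)
  b_ms <- tapping_block(rep("space", 6), down, down + 70, "single_key")
  b_shift <- tapping_block(rep("space", 6), down + 1234, down + 1304,
    "single_key"
  )
  b_scaled <- tapping_block(rep("space", 6), down / 1000, down / 1000 + 0.07,
    "single_key"
  )
  v <- tapping_variability(b_ms)
  expect_equal(tapping_variability(b_shift), v, tolerance = 1e-12)
  expect_equal(tapping_variability(b_scaled), v, tolerance = 1e-12)
})

test_that("dwell time is the mean key-held duration in ms", {
  b <- tapping_block("space", 10, 110, "single_key")
  expect_equal(dwell_time(b), 100)
  b2 <- tapping_block(c("space", "space"), c(0, 300), c(80, 420), "single_key")
  expect_equal(dwell_time(b2), 100) # mean of 80 and 120
  # a press held through the block end contributes its truncated duration
  b3 <- tapping_block("space", 9950, NA, "single_key")
  expect_equal(dwell_time(b3), 50)
  expect_true(b3$truncated)
})

test_that("accuracy weights correct/adjacent/other presses 1/2/3", {
  # 8 correct, 1 adjacent ("v" borders the spacebar), 1 other
  keys <- c(rep("space", 8), "v", "q")
  down <- seq(0, by = 200, length.out = 10)
  b <- tapping_block(keys, down, down + 80, "single_key")
  expect_equal(accuracy_score(b), 1.3)

  # all non-adjacent wrong keys hit the upper bound 3
  bad <- tapping_block(rep("q", 5), down[1:5], down[1:5] + 80, "single_key")
  expect_equal(accuracy_score(bad), 3)
})

test_that("alternate-key accuracy anchors on the first target key pressed", {
  down <- seq(0, by = 450, length.out = 6)
  # starting on semicolon and alternating perfectly is not penalized
  b <- tapping_block(
    rep(c("semicolon", "s"), 3), down, down + 100,
    "alternate_key"
  )
  expect_equal(accuracy_score(b), 1.0)
  # a repeated key breaks the alternation for that press only
  b2 <- tapping_block(
    c("s", "s", "s", "semicolon", "s", "semicolon"),
    down, down + 100, "alternate_key"
  )
  # expected: s ; s ; s ; -> presses 2 and 4 are wrong, 3 is wrong...
  expect_equal(accuracy_score(b2), oracle_accuracy(b2$key_label, "alternate_key", default_adjacency()))
})

test_that("all four features agree with the brute-force oracle on random blocks", {
  set.seed(914)
  adjacency <- default_adjacency()
  for (i in 1:80) {
    tt <- if (i %% 2 == 0) "single_key" else "alternate_key"
    b <- random_block(tt)
    expect_equal(tapping_frequency(b),
      oracle_frequency(b$down_ms, attr(b, "duration_s")),
      tolerance = 1e-12
    )
    expect_equal(suppressWarnings(tapping_variability(b)),
      oracle_variability(b$down_ms),
      tolerance = 1e-12
    )
    expect_equal(dwell_time(b), oracle_dwell(b$down_ms, b$up_ms),
      tolerance = 1e-12
    )
    expect_equal(accuracy_score(b),
      oracle_accuracy(b$key_label, tt, adjacency),
      tolerance = 1e-12
    )
    acc <- accuracy_score(b)
    expect_gte(acc, 1)
    expect_lte(acc, 3)
  }
})

test_that("feature table has one row per participant and 24 stable columns", {
  cfg <- sim_config(
    n_participants = 6, seed = 31,
    exclusions = list(n_symptomatic = 0, n_pd = 0, n_ms = 0, n_incomplete = 2)
  )
  cohort <- simulate_cohort(cfg)
  ft <- build_feature_table(cohort$events,
    participant_ids = cohort$participants$participant_id
  )
  expect_equal(nrow(ft), 6)
  expect_equal(names(ft), c("participant_id", feature_columns()))
  comp <- segment_protocol(cohort$events, cohort$participants$participant_id)
  full_ids <- comp$participant_id[comp$complete]
  complete_rows <- ft[ft$participant_id %in% full_ids, ]
  expect_false(anyNA(complete_rows))
  # missing blocks yield missing cells, never zeros
  incomplete_rows <- ft[!ft$participant_id %in% full_ids, ]
  expect_true(anyNA(incomplete_rows))
  expect_false(any(incomplete_rows[, -1] == 0, na.rm = TRUE))
})

test_that("a participant missing the non-dominant alternate block has exactly 4 missing features", {
  ev <- dplyr::bind_rows(
    lapply(1:4, function(b) {
      down <- seq(0, by = 200, length.out = 20)
      tibble::tibble(
        participant_id = "X", test_type = "single_key", hand = "dominant",
        block_index = b, key_label = "space", down_ms = down, up_ms = down + 80
      )
    }),
    tibble::tibble(
      participant_id = "X", test_type = "alternate_key", hand = "dominant",
      block_index = 1L, key_label = rep(c("s", "semicolon"), 10),
      down_ms = seq(0, by = 450, length.out = 20),
      up_ms = seq(0, by = 450, length.out = 20) + 100
    )
  )
  ft <- build_feature_table(ev)
  expect_equal(sum(is.na(ft[1, -1])), 4)
  expect_true(all(is.na(ft[1, paste0("ak_", c("freq", "var", "dwell", "acc"), "_nd")])))
})
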