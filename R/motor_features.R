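# The four block-level motor features. All time arithmetic is on key-DOWN
# events except dwell time, which is the only feature that uses key-up.

#' Tapping frequency of a block
#'
#' Number of key presses per second: the count of key-down events divided by
#' the block duration.
#'
#' @param block A [tapping_block()].
#' @return Presses per second (0 for an empty block).
#' @export
tapping_frequency <- function(block) {
  nrow(block) / attr(block, "duration_s")
}

#' Tapping variability (rhythm) of a block
#'
#' Standard deviation of the natural logarithm of inter-press intervals,
#' where an interval is the difference between successive key-down times.
#' The sample SD (n - 1 denominator) is used. The measure is dimensionless
#' and invariant to rescaling or shifting of the timestamps.
#'
#' @param block A [tapping_block()].
#' @return SD of log intervals; `NA` (with a warning) when fewer than two
#'   intervals are available.
#' @export
tapping_variability <- function(block) {
  intervals <- diff(block$down_ms)
  if (length(intervals) < 2) {
    warning("fewer than 2 inter-press intervals; variability undefined",
      call. = FALSE
    )
    return(NA_real_)
  }
  sd(log(intervals))
}

#' Mean dwell time of a block
#'
#' Mean duration, in milliseconds, that keys are held down (key-down to
#' key-up). Presses whose key-up was truncated at the block end contribute
#' their clamped duration.
#'
#' @param block A [tapping_block()].
#' @return Mean dwell in milliseconds; `NA` for an empty block.
#' @export
dwell_time <- function(block) {
  if (nrow(block) == 0) return(NA_real_)
  mean(block$up_ms - block$down_ms)
}

#' Default QWERTY adjacency map
#'
#' For each canonical target key, the set of physically bordering keys on a
#' standard QWERTY layout. Used to award the intermediate (2-point) score in
#' [accuracy_score()]. The map is a plain named list and can be replaced
#' wholesale or per key.
#'
#' @return Named list: target key -> character vector of adjacent keys.
#' @export
default_adjacency <- function() {
  list(
    space = c("c", "v", "b", "n", "m"),
    s = c("a", "d", "w", "e", "z", "x"),
    semicolon = c("l", "p", "apostrophe", "slash", "period", "bracketleft")
  )
}

#' Expected-key sequence for a block
#'
#' Single-key blocks expect `"space"` on every press. Alternate-key blocks
#' expect strict alternation between `"s"` and `"semicolon"`; the sequence is
#' anchored on whichever of the two target keys the participant pressed
#' first (so starting on ";" is not penalized), and advances by one on every
#' press whether or not the press was correct. If no press hits either
#' target, the sequence is anchored on `"s"`.
#'
#' @param block A [tapping_block()].
#' @return Character vector, one expected key per press.
#' @export
expected_keys <- function(block) {
  n <- nrow(block)
  if (n == 0) return(character(0))
  if (attr(block, "test_type") == "single_key") {
    return(rep("space", n))
  }
  targets <- c("s", "semicolon")
  first_hit <- which(block$key_label %in% targets)[1]
  anchor <- if (is.na(first_hit)) "s" else block$key_label[first_hit]
  offset <- if (is.na(first_hit)) 1L else first_hit
  other <- setdiff(targets, anchor)
  # position offset expects `anchor`; parity alternates from there
  ifelse((seq_len(n) - offset) %% 2 == 0, anchor, other)
}

#' Weighted target-accuracy index of a block
#'
#' Each press scores 1 point if it hits the expected key, 2 points if it hits
#' a key adjacent to the expected key, and 3 points otherwise; the index is
#' the total divided by the number of presses, so it lies in \[1, 3\] and
#' equals 1.0 exactly when every press is correct.
#'
#' @param block A [tapping_block()].
#' @param adjacency Adjacency map, see [default_adjacency()].
#' @param expected Optional explicit expected-key vector overriding
#'   [expected_keys()].
#' @return Accuracy index in \[1, 3\]; `NA` for an empty block.
#' @export
accuracy_score <- function(block, adjacency = default_adjacency(),
                           expected = NULL) {
  n <- nrow(block)
  if (n == 0) return(NA_real_)
  if (is.null(expected)) expected <- expected_keys(block)
  stopifnot(length(expected) == n)
  points <- rep(3, n)
  points[block$key_label == expected] <- 1
  for (e in unique(expected)) {
    miss <- which(expected == e & points == 3)
    adj <- adjacency[[e]]
    if (length(miss) > 0 && length(adj) > 0) {
      points[miss[block$key_label[miss] %in% adj]] <- 2
    }
  }
  sum(points) / n
}

#' All four motor features of one block
#'
#' @param block A [tapping_block()] (or `NULL` for a missing block).
#' @param adjacency Adjacency map for the accuracy index.
#' @return Named numeric vector `c(freq, var, dwell, acc)`; all `NA` when the
#'   block is missing.
#' @export
block_features <- function(block, adjacency = default_adjacency()) {
  if (is.null(block)) {
    return(c(freq = NA_real_, var = NA_real_, dwell = NA_real_, acc = NA_real_))
  }
  c(
    freq = tapping_frequency(block),
    var = suppressWarnings(tapping_variability(block)),
    dwell = dwell_time(block),
    acc = accuracy_score(block, adjacency)
  )
}

#' Feature-table column names
#'
#' The 24 per-participant motor-feature columns in their stable order:
#' 4 features x 4 single-key blocks (`sk_<feat>_b<i>`), then 4 features x 2
#' alternate-key hands (`ak_<feat>_dom`, `ak_<feat>_nd`).
#'
#' @return Character vector of length 24.
#' @export
feature_columns <- function() {
  feats <- c("freq", "var", "dwell", "acc")
  c(
    unlist(lapply(1:4, function(b) paste0("sk_", feats, "_b", b))),
    paste0("ak_", feats, "_dom"),
    paste0("ak_", feats, "_nd")
  )
}

#' Build the per-participant motor feature table
#'
#' Computes the four motor features for every protocol block of every
#' participant in an event table. Participants appear once each; features of
#' blocks that were not recorded are `NA`, never silent zeros.
#'
#' @param events Validated event tibble ([read_events()] /
#'   [validate_events()]).
#' @param adjacency Adjacency map for the accuracy index.
#' @param participant_ids Optional participants to force into the table even
#'   without events.
#' @return Tibble: `participant_id` plus the 24 [feature_columns()].
#' @export
build_feature_table <- function(events, adjacency = default_adjacency(),
                                participant_ids = NULL) {
  ids <- unique(c(events$participant_id, participant_ids))
  rows <- lapply(ids, function(id) {
    vals <- numeric(0)
    for (b in 1:4) {
      blk <- get_block(events, id, "single_key", "dominant", b)
      f <- block_features(blk, adjacency)
      names(f) <- paste0("sk_", c("freq", "var", "dwell", "acc"), "_b", b)
      vals <- c(vals, f)
    }
    hands <- c(dominant = "dom", non_dominant = "nd")
    for (hand in names(hands)) {
      blk <- get_block(events, id, "alternate_key", hand, 1L)
      f <- block_features(blk, adjacency)
      names(f) <- paste0("ak_", c("freq", "var", "dwell", "acc"), "_", hands[[hand]])
      vals <- c(vals, f)
    }
    tibble::as_tibble(c(list(participant_id = id), as.list(vals)))
  })
  out <- dplyr::bind_rows(rows)
  out[, c("participant_id", feature_columns())]
}
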