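#' @importFrom rlang .data
#' @importFrom stats as.formula coef logLik median nobs quantile rbinom rlnorm
#'   rnbinom rnorm rpois sd setNames vcov
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

# Protocol constants: block durations in seconds and the expected block layout.
.SINGLE_KEY_DURATION_S <- 10
.ALTERNATE_KEY_DURATION_S <- 30

.EVENT_COLUMNS <- c(
  "participant_id", "test_type", "hand", "block_index",
  "key_label", "down_ms", "up_ms"
)

.EDUCATION_LEVELS <- c(
  "left_before_16", "left_at_16", "left_at_17_18",
  "undergraduate", "masters", "phd"
)

.PARTICIPANT_BOOLEANS <- c(
  "memory_change", "dementia_dx", "memory_impairment_dx", "pd_dx", "ms_dx"
)

#' Duration of a protocol tapping block
#'
#' Single-key blocks last 10 s; alternate-key blocks last 30 s.
#'
#' @param test_type `"single_key"` or `"alternate_key"`.
#' @return Duration in seconds.
#' @export
block_duration_s <- function(test_type) {
  ifelse(test_type == "single_key", .SINGLE_KEY_DURATION_S,
    .ALTERNATE_KEY_DURATION_S
  )
}

#' Normalize a raw key label
#'
#' Maps raw key captures (e.g. `" "`, `";"`, `"S"`) onto the canonical
#' lowercase names used throughout the package (`"space"`, `"semicolon"`,
#' `"s"`, ...). Unknown labels are lowercased and passed through.
#'
#' @param key_label Character vector of raw labels.
#' @param aliases Named character vector mapping raw label -> canonical name;
#'   defaults to [default_key_aliases()].
#' @return Character vector of canonical labels.
#' @export
normalize_key_label <- function(key_label, aliases = default_key_aliases()) {
  x <- tolower(trimws(as.character(key_label)))
  x[x == ""] <- "space"
  hit <- x %in% names(aliases)
  x[hit] <- unname(aliases[x[hit]])
  x
}

#' Default raw-key alias map
#'
#' @return Named character vector: raw capture -> canonical label.
#' @export
default_key_aliases <- function() {
  c(
    " " = "space", "spacebar" = "space", "space" = "space",
    ";" = "semicolon", ":" = "semicolon", "semi" = "semicolon",
    "'" = "apostrophe", "," = "comma", "." = "period", "/" = "slash",
    "[" = "bracketleft"
  )
}

#' Construct a tapping block
#'
#' A tapping block is a tibble of key events (one row per press, columns
#' `key_label`, `down_ms`, `up_ms`, `truncated`) carrying the block metadata
#' (`test_type`, `hand`, `block_index`, `duration_s`) as attributes. Events
#' are sorted by `down_ms`. A press whose key-up was not observed (key still
#' held at block end) is given `up_ms` equal to the block end and flagged
#' `truncated = TRUE` rather than dropped, so frequency counts are preserved
#' and dwell time stays defined.
#'
#' @param key_label Character vector of canonical key labels.
#' @param down_ms Integer key-down times, milliseconds from block start.
#' @param up_ms Integer key-up times in milliseconds; `NA` marks a press with
#'   no observed key-up.
#' @param test_type `"single_key"` or `"alternate_key"`.
#' @param hand `"dominant"` or `"non_dominant"`; single-key blocks are always
#'   performed with the dominant hand.
#' @param block_index Block number (1-4 for single-key, 1 for alternate-key).
#' @param duration_s Block duration in seconds; defaults to the protocol
#'   duration for `test_type`.
#' @return A `tapping_block` object.
#' @export
tapping_block <- function(key_label, down_ms, up_ms,
                          test_type = c("single_key", "alternate_key"),
                          hand = c("dominant", "non_dominant"),
                          block_index = 1L,
                          duration_s = NULL) {
  test_type <- match.arg(test_type)
  hand <- match.arg(hand)
  if (is.null(duration_s)) duration_s <- block_duration_s(test_type)
  if (test_type == "single_key" && hand != "dominant") {
    stop("single_key blocks are performed with the dominant hand", call. = FALSE)
  }
  n <- length(down_ms)
  stopifnot(length(key_label) == n, length(up_ms) == n)
  down_ms <- as.numeric(down_ms)
  up_ms <- as.numeric(up_ms)
  dur_ms <- duration_s * 1000
  if (n > 0) {
    if (any(down_ms < 0) || any(down_ms >= dur_ms)) {
      stop("down_ms must lie within [0, block duration)", call. = FALSE)
    }
    truncated <- is.na(up_ms) | up_ms > dur_ms
    up_ms[truncated] <- dur_ms
    if (any(up_ms <= down_ms)) {
      bad <- which(up_ms <= down_ms)
      stop(
        "up_ms must exceed down_ms (press ", paste(bad, collapse = ", "), ")",
        call. = FALSE
      )
    }
  } else {
    truncated <- logical(0)
  }
  ord <- order(down_ms)
  out <- tibble::tibble(
    key_label = as.character(key_label)[ord],
    down_ms = down_ms[ord],
    up_ms = up_ms[ord],
    truncated = truncated[ord]
  )
  structure(out,
    test_type = test_type, hand = hand,
    block_index = as.integer(block_index), duration_s = duration_s,
    class = c("tapping_block", class(out))
  )
}

#' @export
print.tapping_block <- function(x, ...) {
  cat(
    sprintf(
      "<tapping_block> %s / %s / block %d — %d presses in %gs\n",
      attr(x, "test_type"), attr(x, "hand"), attr(x, "block_index"),
      nrow(x), attr(x, "duration_s")
    )
  )
  NextMethod()
}

#' Read a keystroke event log
#'
#' Reads the long-form event CSV (one key event per row; columns
#' `participant_id`, `test_type`, `hand`, `block_index`, `key_label`,
#' `down_ms`, `up_ms`) and validates it: schema, value domains, the
#' `up_ms > down_ms` invariant, and that no event starts beyond its block's
#' protocol duration. Key labels are normalized through the alias map. Rows
#' with a missing `up_ms` are truncated to the block end and flagged.
#'
#' @param path Path to the CSV file.
#' @param aliases Key alias map, see [default_key_aliases()].
#' @return A tibble of validated events sorted by participant, block and
#'   `down_ms`, with a logical `truncated` column appended.
#' @export
read_events <- function(path, aliases = default_key_aliases()) {
  if (!file.exists(path)) stop("event log not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  validate_events(raw, aliases = aliases)
}

#' Validate an in-memory event table
#'
#' The same checks as [read_events()] applied to a data frame. Malformed rows
#' are reported with their (1-based, header-excluded) row numbers.
#'
#' @param events Data frame with the event-log columns.
#' @inheritParams read_events
#' @return Validated, normalized, sorted event tibble.
#' @export
validate_events <- function(events, aliases = default_key_aliases()) {
  missing_cols <- setdiff(.EVENT_COLUMNS, names(events))
  if (length(missing_cols) > 0) {
    stop(
      "event log schema error: missing column(s) ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  ev <- tibble::as_tibble(events)[, union(.EVENT_COLUMNS, names(events))]
  ev$participant_id <- as.character(ev$participant_id)
  ev$key_label <- normalize_key_label(ev$key_label, aliases)
  ev$block_index <- as.integer(ev$block_index)
  ev$down_ms <- as.numeric(ev$down_ms)
  ev$up_ms <- as.numeric(ev$up_ms)

  bad_type <- which(!ev$test_type %in% c("single_key", "alternate_key"))
  if (length(bad_type) > 0) {
    stop("invalid test_type at row(s) ", .row_list(bad_type), call. = FALSE)
  }
  bad_hand <- which(!ev$hand %in% c("dominant", "non_dominant"))
  if (length(bad_hand) > 0) {
    stop("invalid hand at row(s) ", .row_list(bad_hand), call. = FALSE)
  }
  bad_sk_hand <- which(ev$test_type == "single_key" & ev$hand != "dominant")
  if (length(bad_sk_hand) > 0) {
    stop(
      "single_key events must use the dominant hand: row(s) ",
      .row_list(bad_sk_hand),
      call. = FALSE
    )
  }
  dur_ms <- block_duration_s(ev$test_type) * 1000
  bad_down <- which(is.na(ev$down_ms) | ev$down_ms < 0 | ev$down_ms >= dur_ms)
  if (length(bad_down) > 0) {
    stop(
      "down_ms outside [0, block duration) at row(s) ", .row_list(bad_down),
      call. = FALSE
    )
  }
  if (!"truncated" %in% names(ev)) ev$truncated <- FALSE
  no_up <- is.na(ev$up_ms) | ev$up_ms > dur_ms
  ev$truncated <- ev$truncated | no_up
  ev$up_ms[no_up] <- dur_ms[no_up]
  bad_up <- which(ev$up_ms <= ev$down_ms)
  if (length(bad_up) > 0) {
    stop(
      "validation error: up_ms <= down_ms at row(s) ", .row_list(bad_up),
      call. = FALSE
    )
  }
  dplyr::arrange(
    ev, .data$participant_id, .data$test_type, .data$hand,
    .data$block_index, .data$down_ms
  )
}

.row_list <- function(idx, max_show = 10) {
  shown <- paste(head(idx, max_show), collapse = ", ")
  if (length(idx) > max_show) shown <- paste0(shown, ", ...")
  shown
}

#' Write a keystroke event log
#'
#' Inverse of [read_events()]; `read_events(write_events(x))` reproduces all
#' fields. The internal `truncated` flag is not written (it is recomputed on
#' read from the missing `up_ms` convention only when `up_ms` is `NA`), so
#' truncated events are written with their clamped `up_ms`.
#'
#' @param events Event tibble as returned by [read_events()] or the simulator.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- as.data.frame(events)[, .EVENT_COLUMNS]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the participant table
#'
#' Reads the participant CSV (one row per participant: demographics, HADS
#' scores, the three cognitive-symptom questions, PD/MS diagnosis flags and
#' the three CANTAB-style count outcomes). Booleans are encoded "yes"/"no";
#' missing answers stay `NA` and are *not* silently treated as "no".
#'
#' @param path Path to the participant CSV.
#' @return Tibble with typed columns; `education_level` is a factor with the
#'   six cohort levels; `sex` is a factor (`female`, `male`).
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop("participant table not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  validate_participants(raw)
}

#' Validate an in-memory participant table
#'
#' @param participants Data frame of participant records.
#' @return Typed, validated tibble.
#' @export
validate_participants <- function(participants) {
  req <- c(
    "participant_id", "age_years", "sex", "education_level",
    "hads_anxiety", "hads_depression", .PARTICIPANT_BOOLEANS,
    "paltea6", "swmbe6", "swms"
  )
  missing_cols <- setdiff(req, names(participants))
  if (length(missing_cols) > 0) {
    stop(
      "participant table schema error: missing column(s) ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  p <- tibble::as_tibble(participants)
  p$participant_id <- as.character(p$participant_id)
  if (anyDuplicated(p$participant_id)) {
    stop("duplicate participant_id values", call. = FALSE)
  }
  p$sex <- factor(p$sex, levels = c("female", "male"))
  if (anyNA(p$sex)) stop("sex must be 'female' or 'male'", call. = FALSE)
  p$education_level <- factor(p$education_level, levels = .EDUCATION_LEVELS)
  if (anyNA(p$education_level)) {
    stop(
      "education_level must be one of: ",
      paste(.EDUCATION_LEVELS, collapse = ", "),
      call. = FALSE
    )
  }
  for (col in .PARTICIPANT_BOOLEANS) {
    p[[col]] <- .parse_yes_no(p[[col]], col)
  }
  for (col in c("hads_anxiety", "hads_depression")) {
    v <- p[[col]]
    if (any(!is.na(v) & (v < 0 | v > 21))) {
      stop(col, " must lie in [0, 21]", call. = FALSE)
    }
  }
  for (col in c("paltea6", "swmbe6", "swms")) {
    v <- p[[col]]
    if (any(!is.na(v) & (v < 0 | v != round(v)))) {
      stop(col, " must be a non-negative integer count", call. = FALSE)
    }
    p[[col]] <- as.integer(v)
  }
  p
}

.parse_yes_no <- function(x, col) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("yes", "true", "1")] <- TRUE
  out[x %in% c("no", "false", "0")] <- FALSE
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0) {
    stop(
      "column ", col, ": unrecognized yes/no value at row(s) ",
      .row_list(bad),
      call. = FALSE
    )
  }
  out
}

#' Write the participant table
#'
#' @param participants Participant tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(participants, path) {
  out <- as.data.frame(participants)
  for (col in .PARTICIPANT_BOOLEANS) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA,
      ifelse(out[[col]], "yes", "no")
    )
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract one tapping block from an event table
#'
#' @param events Validated event tibble.
#' @param participant_id,test_type,hand,block_index Block coordinates.
#' @return A [tapping_block()], or `NULL` if no events match.
#' @export
get_block <- function(events, participant_id, test_type, hand,
                      block_index = 1L) {
  sel <- events$participant_id == participant_id &
    events$test_type == test_type &
    events$hand == hand &
    events$block_index == block_index
  if (!any(sel)) return(NULL)
  e <- events[sel, ]
  up <- e$up_ms
  if ("truncated" %in% names(e)) up[e$truncated] <- NA
  tapping_block(e$key_label, e$down_ms, up,
    test_type = test_type, hand = hand, block_index = block_index
  )
}

#' Protocol completeness report
#'
#' Checks, per participant, whether the full tapping protocol was recorded:
#' exactly four single-key blocks (indices 1-4, dominant hand) and one
#' alternate-key block per hand. Duplicated block coordinates and missing
#' blocks are both reported; the report never throws.
#'
#' @param events Validated event tibble (any number of participants).
#' @param participant_ids Optional character vector of participants that must
#'   appear in the report even if they contributed no events (they are then
#'   reported as entirely missing).
#' @return Tibble with columns `participant_id`, `n_single_blocks`,
#'   `n_alternate_hands`, `complete`, `duplicated_blocks`, `missing`.
#' @export
segment_protocol <- function(events, participant_ids = NULL) {
  ids <- unique(c(events$participant_id, participant_ids))
  res <- lapply(ids, function(id) {
    e <- events[events$participant_id == id, ]
    sk <- unique(e$block_index[e$test_type == "single_key"])
    ak <- unique(e$hand[e$test_type == "alternate_key"])
    # Blocks outside the protocol grid (single-key index not in 1-4, or a
    # second alternate-key block for the same hand) count as duplicates.
    ak_idx <- unique(e$block_index[e$test_type == "alternate_key"])
    dup <- any(!sk %in% 1:4) || any(ak_idx != 1L)
    missing <- character(0)
    miss_sk <- setdiff(1:4, sk)
    if (length(miss_sk) > 0) {
      missing <- c(missing, paste0("single block ", miss_sk))
    }
    miss_ak <- setdiff(c("dominant", "non_dominant"), ak)
    if (length(miss_ak) > 0) {
      missing <- c(missing, paste0("alternate ", miss_ak))
    }
    tibble::tibble(
      participant_id = id,
      n_single_blocks = length(sk),
      n_alternate_hands = length(ak),
      complete = length(miss_sk) == 0 && length(miss_ak) == 0,
      duplicated_blocks = dup,
      missing = paste(missing, collapse = "; ")
    )
  })
  dplyr::bind_rows(res)
}
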