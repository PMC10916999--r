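# Cohort eligibility: the study analyses cognitively asymptomatic adults
# only, so anyone reporting memory change, a dementia or memory-impairment
# diagnosis, or PD/MS is excluded, as is anyone with an incomplete tapping
# protocol or missing cognitive scores.

.EXCLUSION_REASONS <- c(
  "cognitive_symptoms", "pd_dx", "ms_dx", "incomplete_tapping",
  "missing_cognitive"
)

#' Apply the cohort exclusion rules
#'
#' A participant is excluded when any of the following holds, and receives
#' exactly one reason code, assigned in this fixed priority order:
#'
#' 1. `cognitive_symptoms` — answered yes to any of the three symptom
#'    questions (noticed substantial memory change; told they have dementia;
#'    told they have memory impairment).
#' 2. `pd_dx` — self-reported Parkinson's disease diagnosis.
#' 3. `ms_dx` — self-reported multiple sclerosis diagnosis.
#' 4. `incomplete_tapping` — fewer than 4 single-key blocks or missing an
#'    alternate-key hand.
#' 5. `missing_cognitive` — any of the three cognitive scores missing.
#'
#' Missing answers to the symptom or diagnosis questions are a validation
#' error, never treated as "no".
#'
#' @param participants Validated participant tibble
#'   ([read_participants()]).
#' @param completeness Protocol completeness report from
#'   [segment_protocol()]; participants absent from the report are treated
#'   as having no tapping data (incomplete).
#' @return A list with class `exclusion_result`: `included` (filtered
#'   participant tibble), `ledger` (one row per participant: `participant_id`,
#'   `status`, `reason`), and `counts` (named exclusion tally).
#' @export
apply_exclusions <- function(participants, completeness) {
  flags <- participants[, c(
    "memory_change", "dementia_dx", "memory_impairment_dx", "pd_dx", "ms_dx"
  )]
  if (anyNA(flags)) {
    bad <- which(apply(is.na(flags), 1, any))
    stop(
      "missing symptom/diagnosis answers for participant(s) ",
      paste(head(participants$participant_id[bad], 10), collapse = ", "),
      "; yes/no answers are required and are never assumed",
      call. = FALSE
    )
  }
  complete_ids <- completeness$participant_id[completeness$complete]
  symptoms <- participants$memory_change | participants$dementia_dx |
    participants$memory_impairment_dx
  incomplete <- !participants$participant_id %in% complete_ids
  missing_cog <- is.na(participants$paltea6) | is.na(participants$swmbe6) |
    is.na(participants$swms)

  reason <- rep(NA_character_, nrow(participants))
  reason[missing_cog] <- "missing_cognitive"
  reason[incomplete] <- "incomplete_tapping"
  reason[participants$ms_dx] <- "ms_dx"
  reason[participants$pd_dx] <- "pd_dx"
  reason[symptoms] <- "cognitive_symptoms"

  ledger <- tibble::tibble(
    participant_id = participants$participant_id,
    status = ifelse(is.na(reason), "included", "excluded"),
    reason = reason
  )
  counts <- table(factor(reason, levels = .EXCLUSION_REASONS))
  structure(
    list(
      included = participants[is.na(reason), ],
      ledger = ledger,
      counts = setNames(as.integer(counts), names(counts))
    ),
    class = "exclusion_result"
  )
}

#' @export
print.exclusion_result <- function(x, ...) {
  n_total <- nrow(x$ledger)
  n_in <- nrow(x$included)
  cat(sprintf(
    "<exclusion_result> %d participants: %d included, %d excluded\n",
    n_total, n_in, n_total - n_in
  ))
  for (r in names(x$counts)) {
    if (x$counts[[r]] > 0) cat(sprintf("  %-20s %d\n", r, x$counts[[r]]))
  }
  invisible(x)
}
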