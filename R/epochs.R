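# Respiratory-event epoch labelling on the 30-second scoring grid.
#
# A 30-s epoch is a respiratory-event (RE) epoch when it contains at least
# 10 s of a single respiratory event, or when it starts less than 5 s after
# an event ends ("after event" rule, capturing the post-event
# bradycardia-tachycardia/arousal aftermath). Epochs are half-open
# [30k, 30k + 30); an event ending exactly on an epoch boundary triggers the
# after-rule for the next epoch (distance 0 < 5).

RE_EVENT_KINDS <- c("obstructive_apnea", "hypopnea", "central_apnea", "mixed_apnea")

MIN_EVENT_OVERLAP <- 10   # seconds of event inside an epoch (inclusive)
AFTER_EVENT_GAP <- 5      # strict: epoch start < 5 s after event end

check_events <- function(events) {
  check_df_cols(events, c("kind", "onset_s", "duration_s"), "events")
  bad <- setdiff(unique(events$kind), RE_EVENT_KINDS)
  if (length(bad)) {
    abort(sprintf(
      "Unknown respiratory event kind(s): %s. Allowed: %s.",
      paste(bad, collapse = ", "), paste(RE_EVENT_KINDS, collapse = ", ")
    ))
  }
  if (any(events$onset_s < 0)) abort("Event onsets must be >= 0 s.")
  if (any(events$duration_s < MIN_EVENT_OVERLAP)) {
    abort("Respiratory events must last at least 10 s (scoring minimum).")
  }
  invisible(events)
}

#' Label 30-second epochs as respiratory-event epochs
#'
#' Applies the two RE-epoch rules to a table of respiratory events:
#' an epoch is positive if a single event overlaps it by at least 10 s,
#' or if it starts strictly less than 5 s after an event's end.
#'
#' @param events Tibble of respiratory events with columns `kind`
#'   (`obstructive_apnea`, `hypopnea`, `central_apnea`, `mixed_apnea`),
#'   `onset_s`, `duration_s` (and optionally `desaturation_pct`, `arousal`).
#'   Harmonise hypopnea scoring first with [harmonise_hypopneas()].
#' @param n_epochs Number of 30-s epochs in the recording.
#' @return A tibble with one row per epoch: `epoch` (0-based index),
#'   `re_class` (logical), `overlap_rule` and `after_rule` (which rule
#'   fired), `characterisation` (kind of the longest event in the epoch,
#'   `after_event` for purely after-triggered epochs, `none` otherwise),
#'   `after_combination` (`not_applicable` / `after` / `no_after` /
#'   `pure_after`) and `analysable` (all `TRUE` until a sleep mask is
#'   applied with [apply_sleep_mask()]).
#' @export
#' @examples
#' ev <- tibble::tibble(kind = "hypopnea", onset_s = 25, duration_s = 15)
#' label_re_epochs(ev, n_epochs = 3)
label_re_epochs <- function(events, n_epochs) {
  check_number(n_epochs, "n_epochs", lower = 1)
  n_epochs <- as.integer(n_epochs)
  labels <- tibble(
    epoch = seq_len(n_epochs) - 1L,
    re_class = FALSE,
    overlap_rule = FALSE,
    after_rule = FALSE,
    characterisation = "none",
    after_combination = "not_applicable",
    analysable = TRUE
  )
  if (is.null(events) || nrow(events) == 0) return(labels)
  check_events(events)
  # canonical order so overlap ties resolve identically for any input order
  events <- events[order(events$onset_s, events$duration_s, events$kind), ]

  rec_end <- n_epochs * EPOCH_LEN
  ends <- events$onset_s + events$duration_s
  if (any(ends > rec_end)) {
    warn("Event(s) extend beyond the recording end; clipped to the last epoch.")
  }

  starts <- epoch_starts(n_epochs)
  # Longest single-event overlap per epoch, and the kind achieving it.
  best_overlap <- numeric(n_epochs)
  best_kind <- rep("none", n_epochs)
  rule1 <- logical(n_epochs)
  rule2 <- logical(n_epochs)

  for (i in seq_len(nrow(events))) {
    on <- events$onset_s[i]
    off <- min(ends[i], rec_end)
    if (off > on) {
      k0 <- max(0L, as.integer(floor(on / EPOCH_LEN)))
      k1 <- min(n_epochs - 1L, as.integer(ceiling(off / EPOCH_LEN)) - 1L)
      ks <- k0:k1
      ov <- interval_overlap(on, off, starts[ks + 1L], starts[ks + 1L] + EPOCH_LEN)
      rule1[ks + 1L] <- rule1[ks + 1L] | (ov >= MIN_EVENT_OVERLAP)
      upd <- ov > best_overlap[ks + 1L]
      best_overlap[ks + 1L][upd] <- ov[upd]
      best_kind[ks + 1L][upd] <- events$kind[i]
    }
    # After-rule: raw (unclipped) end; epoch k starts < 5 s after the end.
    e <- ends[i]
    k_after <- as.integer(ceiling(e / EPOCH_LEN))     # first epoch starting at/after e
    if (k_after <= n_epochs - 1L) {
      if (starts[k_after + 1L] - e < AFTER_EVENT_GAP && starts[k_after + 1L] >= e) {
        rule2[k_after + 1L] <- TRUE
      }
    }
  }

  labels$overlap_rule <- rule1
  labels$after_rule <- rule2
  labels$re_class <- rule1 | rule2
  labels$characterisation <- dplyr::case_when(
    rule2 & !rule1 & best_overlap == 0 ~ "after_event",
    best_overlap > 0 ~ best_kind,
    rule2 ~ "after_event",
    TRUE ~ "none"
  )
  labels$after_combination <- dplyr::case_when(
    !labels$re_class ~ "not_applicable",
    rule2 & rule1 ~ "after",
    rule1 ~ "no_after",
    TRUE ~ "pure_after"
  )
  labels
}

#' Characterise RE epochs by their dominant event
#'
#' Re-derives the per-epoch characterisation (kind of the event with the
#' longest overlap, or `after_event` for epochs positive only through the
#' 5-s post-event rule) and the after-combination tag from the raw event
#' list. [label_re_epochs()] already populates these columns; this
#' function recomputes them for a label table whose events may have
#' changed.
#'
#' @inheritParams label_re_epochs
#' @param labels Label tibble as returned by [label_re_epochs()].
#' @return `labels` with `characterisation` and `after_combination`
#'   refreshed.
#' @export
characterise_epochs <- function(events, labels) {
  check_df_cols(labels, c("epoch", "re_class"), "labels")
  fresh <- label_re_epochs(events, nrow(labels))
  labels$characterisation <- fresh$characterisation
  labels$after_combination <- fresh$after_combination
  labels$overlap_rule <- fresh$overlap_rule
  labels$after_rule <- fresh$after_rule
  labels
}

#' Restrict epoch labels to sleep
#'
#' Marks wake epochs as non-analysable: the AHI is computed over sleep
#' epochs only, since wake acts as a cardiovascular confounder.
#'
#' @param labels Label tibble from [label_re_epochs()].
#' @param stages Character vector of per-epoch stages, `"wake"` or
#'   `"sleep"`, the same length as the label table.
#' @return `labels` with `analysable` set to `stages == "sleep"`.
#' @export
apply_sleep_mask <- function(labels, stages) {
  check_df_cols(labels, "analysable", "labels")
  if (length(stages) != nrow(labels)) {
    abort(sprintf(
      "Hypnogram length (%d) does not match the epoch count (%d).",
      length(stages), nrow(labels)
    ))
  }
  bad <- setdiff(unique(stages), c("wake", "sleep"))
  if (length(bad)) {
    abort(sprintf("Unknown stage token(s): %s.", paste(bad, collapse = ", ")))
  }
  labels$analysable <- stages == "sleep"
  labels
}
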