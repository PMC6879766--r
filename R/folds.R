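# Conditioned, participant-level, stratified cross-validation folds.

#' Build conditioned stratified folds
#'
#' Participant-level k-fold assignment stratified on an AHI >= 15
#' indicator plus optional disorder tags, with recordings optionally
#' forced into every fold's training set or every fold's validation set
#' (e.g. datasets whose annotation style differs from the training
#' pool). Deterministic given `seed`.
#'
#' @param metadata Tibble with `record_id`, `ahi` and optionally
#'   `disorder` (character tag used as an extra stratification key).
#' @param k Number of folds (>= 2).
#' @param forced_train,forced_validation Character vectors of record ids.
#' @param seed Integer seed.
#' @return A `fold_plan`: tibble `record_id`, `assignment`
#'   (`train_only`, `validation_only`, or a fold index 1..k giving the
#'   fold in which the recording is validation).
#' @export
build_folds <- function(metadata, k = 5L, forced_train = character(0),
                        forced_validation = character(0), seed = 1L) {
  check_df_cols(metadata, c("record_id", "ahi"), "metadata")
  check_number(k, "k", lower = 2)
  k <- as.integer(k)
  ids <- metadata$record_id
  if (anyDuplicated(ids)) abort("`metadata$record_id` must be unique.")
  overlap <- intersect(forced_train, forced_validation)
  if (length(overlap)) {
    abort(sprintf("Recording(s) forced both ways: %s.", paste(overlap, collapse = ", ")))
  }

  assignment <- rep(NA_character_, nrow(metadata))
  assignment[ids %in% forced_train] <- "train_only"
  assignment[ids %in% forced_validation] <- "validation_only"
  free <- which(is.na(assignment))

  strat <- paste0(
    ifelse(metadata$ahi >= 15, "high", "low"),
    if ("disorder" %in% names(metadata)) paste0(":", metadata$disorder) else ""
  )[free]
  # merge strata smaller than k
  tab <- table(strat)
  small <- names(tab)[tab < k]
  if (length(small)) {
    warn(sprintf(
      "Stratum(a) smaller than k merged into a pooled stratum: %s.",
      paste(small, collapse = ", ")
    ))
    strat[strat %in% small] <- "(merged)"
  }

  set.seed(as.integer(seed))
  folds <- integer(length(free))
  fill <- integer(k) # least-filled-first keeps overall and per-stratum balance
  for (s in unique(strat)) {
    idx <- which(strat == s)
    idx <- idx[sample.int(length(idx))]
    start <- sample.int(k, 1)
    for (i in idx) {
      rot <- c(start:k, seq_len(start - 1L)) # rotate ties deterministically
      f <- rot[which.min(fill[rot])]
      folds[i] <- f
      fill[f] <- fill[f] + 1L
      start <- (start %% k) + 1L
    }
  }
  assignment[free] <- as.character(folds)

  structure(
    tibble(record_id = ids, assignment = assignment),
    class = c("fold_plan", "tbl_df", "tbl", "data.frame"),
    k = k
  )
}

#' Train/validation record ids for one fold
#'
#' @param plan A `fold_plan` from [build_folds()].
#' @param fold Fold index, 1..k.
#' @return List with `train` and `validation` record-id vectors (forced
#'   assignments honoured; a participant never appears on both sides).
#' @export
fold_members <- function(plan, fold) {
  k <- attr(plan, "k")
  check_number(fold, "fold", lower = 1, upper = k)
  is_val <- plan$assignment == "validation_only" | plan$assignment == as.character(fold)
  list(
    train = plan$record_id[!is_val & plan$assignment != "validation_only"],
    validation = plan$record_id[is_val]
  )
}

#' Serialise a fold plan to JSON
#' @param plan A `fold_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
fold_plan_to_json <- function(plan, path) {
  jsonlite::write_json(
    list(k = attr(plan, "k"), assignment = as.list(setNames(plan$assignment, plan$record_id))),
    path,
    auto_unbox = TRUE
  )
  invisible(path)
}
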