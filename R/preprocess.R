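# R-peak detection and inter-beat-interval (IBI) cleaning.
#
# Detection follows the classic Hamilton-Tompkins recipe: zero-phase
# band-pass (8-20 Hz), rectified derivative, short moving-window
# integration, adaptive thresholding with a 250 ms refractory period,
# then refinement of each detection to the local extremum of the raw
# signal within +/-50 ms (narrower than half the shortest admissible
# IBI, so refinement cannot jump beats). Rejection rules: IBIs outside
# [0.5, 2] s are non-physiological during sleep; an IBI more than 1.5
# times its predecessor marks an ectopic pair (short coupling interval
# before the ectopic beat, compensatory pause after), and both intervals
# are discarded.

IBI_MIN <- 0.5
IBI_MAX <- 2.0
ECTOPIC_RATIO <- 1.5
REFINE_WINDOW <- 0.05 # seconds

moving_avg <- function(x, w) {
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2, circular = FALSE))
}

#' Detect R peaks in a single-lead ECG
#'
#' @param ecg An `ecg_record` (see [read_edf()], [render_ecg()]); sampling
#'   rate must be at least 100 Hz.
#' @return Tibble with one column `peak_s`, strictly increasing R-peak
#'   times in seconds.
#' @export
detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "ecg_record"))
  fs <- ecg$sampling_rate
  if (fs < 100) abort("R-peak detection requires a sampling rate of at least 100 Hz.")
  x <- ecg$samples
  if (length(x) < fs || isTRUE(sd(x) == 0) || all(!is.finite(x))) {
    warn("ECG signal is flat or too short; no R peaks detected.")
    return(tibble(peak_s = numeric(0)))
  }

  bp <- signal::butter(3, c(8, 20) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bp, x)
  d <- abs(c(0, diff(y)))
  w <- max(3L, as.integer(round(0.08 * fs)))
  env <- moving_avg(d, w)
  env[is.na(env)] <- 0

  # adaptive threshold per 10-s block, floored by a global noise estimate
  block <- as.integer(10 * fs)
  n <- length(env)
  thr <- numeric(n)
  global_ref <- quantile(env, 0.99, na.rm = TRUE)
  for (b0 in seq(1, n, by = block)) {
    idx <- b0:min(n, b0 + block - 1)
    thr[idx] <- max(0.3 * max(env[idx]), 0.15 * global_ref)
  }

  above <- env > thr
  # local maxima of env above threshold
  cand <- which(above & env >= c(env[-1], 0) & env > c(0, env[-n]))
  if (!length(cand)) {
    warn("No QRS-like activity found; no R peaks detected.")
    return(tibble(peak_s = numeric(0)))
  }
  # enforce 250 ms refractory period, keep the stronger candidate
  refractory <- as.integer(0.25 * fs)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refractory) {
      keep <- c(keep, i)
      last <- i
    } else if (env[i] > env[keep[length(keep)]]) {
      keep[length(keep)] <- i
      last <- i
    }
  }

  # refine to the raw-signal extremum (polarity-agnostic) within +/-50 ms
  half <- as.integer(REFINE_WINDOW * fs)
  refined <- vapply(keep, function(i) {
    lo <- max(1L, i - half)
    hi <- min(length(x), i + half)
    win <- x[lo:hi]
    lo + which.max(abs(win - median(win))) - 1L
  }, 1L)
  refined <- sort(unique(refined))
  tibble(peak_s = (refined - 1) / fs)
}

#' Inter-beat intervals from R-peak times
#'
#' @param peaks Tibble with column `peak_s` (strictly increasing), or a
#'   numeric vector of peak times.
#' @return IBI tibble: `onset_s` (time of the beat opening the interval),
#'   `ibi_s`, `valid` (all `TRUE`), `reason` (all `"ok"`).
#' @export
ibis_from_peaks <- function(peaks) {
  pk <- if (is.data.frame(peaks)) peaks$peak_s else as.numeric(peaks)
  if (length(pk) < 2) abort("At least two R peaks are needed to form an IBI series.")
  if (any(diff(pk) <= 0)) abort("Peak times must be strictly increasing.")
  tibble(
    onset_s = pk[-length(pk)],
    ibi_s = diff(pk),
    valid = TRUE,
    reason = "ok"
  )
}

#' Apply physiological and ectopic IBI rejection rules
#'
#' Stage 1 tags intervals outside `[0.5, 2]` s as `out_of_range`.
#' Stage 2 examines each pair of still-valid intervals that share a beat
#' (no gap between them): if the ratio of the current to the preceding
#' interval exceeds 1.5 (strict), both are tagged `ectopic`. Tags are
#' never reverted, so the operation is idempotent.
#'
#' @param ibis IBI tibble (`onset_s`, `ibi_s`, and optionally `valid`,
#'   `reason`).
#' @return The tibble with `valid`/`reason` updated.
#' @export
#' @examples
#' ib <- ibis_from_peaks(c(0, 1, 1.8, 3.1))
#' reject_invalid_ibis(ib)
reject_invalid_ibis <- function(ibis) {
  check_df_cols(ibis, c("onset_s", "ibi_s"), "ibis")
  if (!nrow(ibis)) abort("IBI series is empty.")
  reason <- ibis$reason %||% rep("ok", nrow(ibis))
  v <- ibis$ibi_s
  reason[reason == "ok" & (v > IBI_MAX | v < IBI_MIN)] <- "out_of_range"
  n <- nrow(ibis)
  if (n >= 2) {
    i <- 2:n
    contiguous <- abs(ibis$onset_s[i] - (ibis$onset_s[i - 1] + v[i - 1])) < 1e-6
    both_valid <- reason[i] == "ok" & reason[i - 1] == "ok"
    ratio_bad <- v[i] / v[i - 1] > ECTOPIC_RATIO
    hit <- i[contiguous & both_valid & ratio_bad]
    reason[hit] <- "ectopic"
    reason[hit - 1L] <- "ectopic"
  }
  ibis$reason <- reason
  ibis$valid <- reason == "ok"
  ibis
}

#' Recording-level exclusion verdict
#'
#' A recording is excluded when more than 3% of its IBIs are tagged
#' ectopic, when more than 30% of its epochs have at least 70% of the
#' features missing, or when inputs are technically unusable (empty IBI
#' series or absent feature matrix). The verdict is advisory; callers
#' decide whether to halt.
#'
#' @param ibis Cleaned IBI tibble (after [reject_invalid_ibis()]).
#' @param features Feature matrix tibble (see [extract_feature_matrix()]),
#'   or `NULL` when feature extraction failed.
#' @return List with `excluded` (logical) and `reasons` (character subset
#'   of `ectopic_fraction`, `feature_coverage`, `technical`).
#' @export
exclusion_check <- function(ibis, features = NULL) {
  reasons <- character(0)
  if (is.null(ibis) || !nrow(ibis)) {
    reasons <- c(reasons, "technical")
  } else {
    frac_ect <- mean((ibis$reason %||% "ok") == "ectopic")
    if (frac_ect > 0.03) reasons <- c(reasons, "ectopic_fraction")
  }
  if (is.null(features) || !nrow(features)) {
    reasons <- c(reasons, "technical")
  } else {
    feat_cols <- setdiff(names(features), c("record_id", "epoch"))
    if (length(feat_cols)) {
      miss_frac <- rowMeans(is.na(features[, feat_cols, drop = FALSE]))
      if (mean(miss_frac >= 0.7) > 0.30) {
        reasons <- c(reasons, "feature_coverage")
      }
    }
  }
  reasons <- unique(reasons)
  list(excluded = length(reasons) > 0, reasons = reasons)
}
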