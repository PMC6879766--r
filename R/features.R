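# Per-epoch cardiovascular feature extraction.
#
# Each feature family is computed over a time window centred on the
# 30-second epoch it is assigned to (window length per family, Table of
# the registry below). Two coverage rules gate every computation: valid
# IBIs must cover at least half of the (nominal) window, and at least
# 1/6 of the central 30 s (5 s). Windows truncated at the record edges
# are computed on the truncated data but the coverage test uses the
# nominal window length, so edge epochs go missing unless genuinely well
# covered. Failed coverage or undefined computations yield NA, never a
# fill value.

FAMILY_WINDOWS <- c(
  hrv_time = 300, hrv_freq = 300, dfa = 360, dfa_progressive = 60,
  dfa_windowed = 360, sample_entropy = 300, multiscale_entropy = 540,
  activity_counts = 30
)

# ---- registry --------------------------------------------------------------

plugin_env <- new.env(parent = emptyenv())

#' Register a plugin feature family
#'
#' External feature families (for example methods defined only in cited
#' methodological papers) can be plugged into the extraction, the
#' transformation optimiser and the classifier transparently.
#'
#' @param family Family name.
#' @param window Window length in seconds, centred on the epoch.
#' @param fn Function `(values, onsets, context)` returning a named
#'   numeric vector of features; `context` carries `window_start`,
#'   `window_end` and the `ecg_record` when available.
#' @return Invisibly, the family name.
#' @export
register_feature_family <- function(family, window, fn) {
  stopifnot(is.function(fn))
  check_number(window, "window", lower = EPOCH_LEN)
  assign(family, list(window = window, fn = fn), envir = plugin_env)
  invisible(family)
}

#' Feature registry
#'
#' Lists the features produced by the requested families, with their
#' family and window length.
#'
#' @param families Character vector of family names; any mix of the
#'   built-in families (`hrv_time`, `hrv_freq`, `dfa`, `dfa_progressive`,
#'   `dfa_windowed`, `sample_entropy`, `multiscale_entropy`,
#'   `activity_counts`) and registered plugins.
#' @return Tibble `name`, `family`, `window`.
#' @export
feature_registry <- function(families = names(FAMILY_WINDOWS)) {
  rows <- map(families, function(fam) {
    if (fam %in% names(FAMILY_WINDOWS)) {
      nm <- switch(fam,
        hrv_time = names(hrv_time_features(c(0.8, 0.9, 1.0))),
        hrv_freq = names(hrv_freq_features(NULL)),
        dfa = c("dfa_alpha1", "dfa_alpha2", "dfa_alpha_all"),
        dfa_progressive = "dfa_progressive",
        dfa_windowed = "dfa_windowed",
        sample_entropy = "sampen",
        multiscale_entropy = sprintf("mse_scale%02d", 1:20),
        activity_counts = "activity_counts"
      )
      tibble(name = nm, family = fam, window = FAMILY_WINDOWS[[fam]])
    } else if (exists(fam, envir = plugin_env)) {
      pl <- get(fam, envir = plugin_env)
      probe <- pl$fn(c(0.8, 0.9, 1.0), c(0, 0.8, 1.7), list())
      tibble(name = names(probe), family = fam, window = pl$window)
    } else {
      abort(sprintf("Unknown feature family '%s'.", fam))
    }
  })
  list_rbind(rows)
}

# ---- coverage --------------------------------------------------------------

#' Coverage test for a feature window
#'
#' Valid IBIs must cover at least half of the window (the nominal length
#' when the window is truncated at a record edge) and at least 5 s
#' (1/6) of the central 30-s epoch.
#'
#' @param ibis Cleaned IBI tibble.
#' @param window_start,window_end Window bounds in seconds.
#' @param epoch_start Start of the central epoch (defaults to the window
#'   centre minus 15 s).
#' @param nominal_length Length used for the half-window rule (defaults
#'   to `window_end - window_start`).
#' @return `TRUE` when both rules pass.
#' @export
epoch_coverage_ok <- function(ibis, window_start, window_end,
                              epoch_start = (window_start + window_end) / 2 - 15,
                              nominal_length = window_end - window_start) {
  o <- ibis$onset_s[ibis$valid %||% rep(TRUE, nrow(ibis))]
  v <- ibis$ibi_s[ibis$valid %||% rep(TRUE, nrow(ibis))]
  cov_win <- sum(interval_overlap(o, o + v, window_start, window_end))
  cov_epoch <- sum(interval_overlap(o, o + v, epoch_start, epoch_start + EPOCH_LEN))
  cov_win >= 0.5 * nominal_length && cov_epoch >= EPOCH_LEN / 6
}

# ---- family computations ---------------------------------------------------

skewness_ <- function(x) {
  n <- length(x)
  s <- pop_sd(x)
  if (is.na(s) || s == 0) return(NA_real_)
  mean((x - mean(x))^3) / s^3
}

kurtosis_ <- function(x) {
  s <- pop_sd(x)
  if (is.na(s) || s == 0) return(NA_real_)
  mean((x - mean(x))^4) / s^4 - 3
}

# values in seconds; reported in ms where conventional
hrv_time_features <- function(v) {
  ms <- v * 1000
  d <- diff(ms)
  hr <- 60 / v
  c(
    mean_nn = mean(ms), sdnn = pop_sd(ms), median_nn = median(ms),
    rmssd = if (length(d)) sqrt(mean(d^2)) else NA_real_,
    sdsd = if (length(d) > 1) pop_sd(d) else NA_real_,
    pnn50 = if (length(d)) 100 * mean(abs(d) > 50) else NA_real_,
    pnn20 = if (length(d)) 100 * mean(abs(d) > 20) else NA_real_,
    iqr_nn = unname(diff(quantile(ms, c(0.25, 0.75)))),
    range_nn = diff(range(ms)),
    mad_nn = mean(abs(ms - mean(ms))),
    cv_nn = pop_sd(ms) / mean(ms),
    p10_nn = unname(quantile(ms, 0.10)), p90_nn = unname(quantile(ms, 0.90)),
    skew_nn = skewness_(ms), kurt_nn = kurtosis_(ms),
    mean_hr = mean(hr), sd_hr = pop_sd(hr)
  )
}

# Welch-averaged periodogram; x evenly sampled at fs.
welch_psd <- function(x, fs, seg_len = 256, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, as.integer(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1)) # Hann
  norm <- sum(win^2)
  nf <- seg_len %/% 2L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + seg_len - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(fft(seg))^2 / (fs * norm)
    acc <- acc + 2 * sp[2:(nf + 1L)]
  }
  list(
    freq = (1:nf) * fs / seg_len,
    psd = acc / length(starts),
    df = fs / seg_len
  )
}

HRV_BANDS <- list(vlf = c(0.003, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.4))

# x: evenly resampled IBI (ms) at fs Hz, or NULL to list feature names
hrv_freq_features <- function(x, fs = 4) {
  nms <- c(
    "vlf_power", "lf_power", "hf_power", "total_power",
    "lf_hf_ratio", "lf_nu", "hf_nu", "hf_peak_freq"
  )
  if (is.null(x)) {
    return(setNames(rep(NA_real_, length(nms)), nms))
  }
  if (length(x) < 64 || pop_sd(x) == 0) {
    return(setNames(rep(NA_real_, length(nms)), nms))
  }
  w <- welch_psd(x, fs)
  bp <- function(b) sum(w$psd[w$freq > b[1] & w$freq <= b[2]]) * w$df
  vlf <- bp(HRV_BANDS$vlf)
  lf <- bp(HRV_BANDS$lf)
  hf <- bp(HRV_BANDS$hf)
  hf_idx <- which(w$freq > 0.15 & w$freq <= 0.4)
  setNames(c(
    vlf, lf, hf, vlf + lf + hf,
    if (hf > 0) lf / hf else NA_real_,
    if (lf + hf > 0) lf / (lf + hf) else NA_real_,
    if (lf + hf > 0) hf / (lf + hf) else NA_real_,
    if (length(hf_idx)) w$freq[hf_idx[which.max(w$psd[hf_idx])]] else NA_real_
  ), nms)
}

# Detrended fluctuation analysis; x is the (beat-indexed) IBI series.
dfa_alpha <- function(x, scales) {
  n <- length(x)
  scales <- scales[scales <= n %/% 4]
  if (length(scales) < 3 || pop_sd(x) == 0) return(NA_real_)
  y <- cumsum(x - mean(x))
  fl <- vapply(scales, function(s) {
    nb <- n %/% s
    res2 <- 0
    tt <- seq_len(s)
    stt <- sum(tt)
    stt2 <- sum(tt^2)
    denom <- s * stt2 - stt^2
    for (b in seq_len(nb)) {
      seg <- y[((b - 1) * s + 1):(b * s)]
      sy <- sum(seg)
      sty <- sum(tt * seg)
      beta <- (s * sty - stt * sy) / denom
      alpha <- (sy - beta * stt) / s
      res2 <- res2 + sum((seg - alpha - beta * tt)^2)
    }
    sqrt(res2 / (nb * s))
  }, 1)
  ok <- fl > 0
  if (sum(ok) < 3) return(NA_real_)
  unname(coef(lm(log(fl[ok]) ~ log(scales[ok])))[2])
}

dfa_features <- function(v) {
  c(
    dfa_alpha1 = dfa_alpha(v, 4:11),
    dfa_alpha2 = dfa_alpha(v, 2^seq(4, 6, by = 0.5)),
    dfa_alpha_all = dfa_alpha(v, unique(round(2^seq(2, 6, by = 0.25))))
  )
}

dfa_windowed_feature <- function(v, sub = 64, step = 32) {
  if (length(v) < sub) return(c(dfa_windowed = NA_real_))
  a <- vapply(seq(1, length(v) - sub + 1, by = step), function(i) {
    dfa_alpha(v[i:(i + sub - 1)], 4:11)
  }, 1)
  c(dfa_windowed = mean(a, na.rm = TRUE))
}

#' Sample entropy
#'
#' SampEn(m, r) of a numeric series: the negative log conditional
#' probability that sequences matching for `m` points (Chebyshev
#' distance < `r`) also match for `m + 1`.
#'
#' @param x Numeric series.
#' @param m Embedding dimension.
#' @param r Tolerance; defaults to `0.2 * sd(x)`.
#' @return Sample entropy, or `NA` when undefined (constant series, too
#'   few points, or no template matches).
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * pop_sd(x)) {
  n <- length(x)
  if (n < m + 10 || is.na(r) || r <= 0) return(NA_real_)
  count_matches <- function(mm) {
    ne <- n - mm
    within <- matrix(TRUE, ne, ne)
    for (k in seq_len(mm)) {
      xe <- x[(k):(k + ne - 1)]
      within <- within & (abs(outer(xe, xe, "-")) < r)
    }
    (sum(within) - ne) / 2 # exclude self-matches
  }
  B <- count_matches(m)
  A <- count_matches(m + 1L)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

mse_features <- function(v, scales = 1:20) {
  r <- 0.2 * pop_sd(v)
  out <- vapply(scales, function(s) {
    nb <- length(v) %/% s
    if (nb < 30) return(NA_real_)
    cg <- colMeans(matrix(v[seq_len(nb * s)], nrow = s))
    sample_entropy(cg, m = 2L, r = r)
  }, 1)
  setNames(out, sprintf("mse_scale%02d", scales))
}

# ECG-derived activity count for one 30-s epoch: high-pass filtered,
# rectified amplitude integrated over the epoch. Constants configurable.
activity_count_epoch <- function(ecg_hp, fs, epoch_start) {
  i0 <- max(1L, as.integer(epoch_start * fs) + 1L)
  i1 <- min(length(ecg_hp), as.integer((epoch_start + EPOCH_LEN) * fs))
  if (i1 <= i0) return(NA_real_)
  sum(abs(ecg_hp[i0:i1])) / fs
}

# ---- matrix extraction -----------------------------------------------------

#' Extract the per-epoch feature matrix
#'
#' Computes every feature of the requested families for each 30-s epoch,
#' honouring per-family windows (centred on the epoch) and the coverage
#' rules. `NA` marks epochs where a rule failed or a computation was
#' undefined.
#'
#' @param ibis Cleaned IBI tibble (see [reject_invalid_ibis()]).
#' @param n_epochs Number of epochs in the recording.
#' @param families Feature families to compute; `activity_counts`
#'   requires `ecg`.
#' @param ecg Optional `ecg_record` for the activity-count family.
#' @param record_id Identifier stamped on each row.
#' @param activity_hp_hz High-pass cutoff (Hz) for the activity counts.
#' @return Tibble with `record_id`, `epoch`, and one column per feature;
#'   the registry is attached as attribute `"spec"`.
#' @export
extract_feature_matrix <- function(ibis, n_epochs,
                                   families = c("hrv_time", "hrv_freq"),
                                   ecg = NULL, record_id = "record",
                                   activity_hp_hz = 25) {
  check_number(n_epochs, "n_epochs", lower = 1)
  n_epochs <- as.integer(n_epochs)
  reg <- feature_registry(families)
  valid <- ibis[(ibis$valid %||% rep(TRUE, nrow(ibis))) & !is.na(ibis$ibi_s), ]
  o <- valid$onset_s
  v <- valid$ibi_s
  ends <- o + v
  rec_end <- n_epochs * EPOCH_LEN
  centers <- epoch_starts(n_epochs) + EPOCH_LEN / 2

  # 4 Hz evenly resampled IBI (ms) for spectral features, computed once
  grid <- NULL
  if ("hrv_freq" %in% families && length(o) >= 4) {
    gt <- seq(0, rec_end, by = 0.25)
    grid <- approx(o, v * 1000, xout = gt, rule = 1)$y
  }
  ecg_hp <- NULL
  if ("activity_counts" %in% families) {
    if (is.null(ecg)) {
      warn("activity_counts requested without an ECG; the column will be NA.")
    } else {
      hp <- signal::butter(2, min(0.99, activity_hp_hz / (ecg$sampling_rate / 2)),
        type = "high"
      )
      ecg_hp <- signal::filtfilt(hp, ecg$samples)
    }
  }

  out <- matrix(NA_real_, nrow = n_epochs, ncol = nrow(reg))
  colnames(out) <- reg$name

  for (fam in unique(reg$family)) {
    cols <- reg$name[reg$family == fam]
    W <- reg$window[reg$family == fam][1]
    plugin <- !fam %in% names(FAMILY_WINDOWS)
    for (k in seq_len(n_epochs)) {
      ws <- max(0, centers[k] - W / 2)
      we <- min(rec_end, centers[k] + W / 2)
      ep_start <- centers[k] - EPOCH_LEN / 2
      sel <- which(o < we & ends > ws)
      cov_win <- sum(interval_overlap(o[sel], ends[sel], ws, we))
      cov_ep <- sum(interval_overlap(
        o[sel], ends[sel], ep_start, ep_start + EPOCH_LEN
      ))
      if (cov_win < 0.5 * W || cov_ep < EPOCH_LEN / 6) next
      vw <- v[sel]
      ow <- o[sel]
      vals <- if (plugin) {
        pl <- get(fam, envir = plugin_env)
        pl$fn(vw, ow, list(window_start = ws, window_end = we, ecg = ecg))
      } else {
        switch(fam,
          hrv_time = hrv_time_features(vw),
          hrv_freq = {
            gi <- grid[seq(
              from = as.integer(ws / 0.25) + 1L,
              to = min(length(grid), as.integer(we / 0.25) + 1L)
            )]
            hrv_freq_features(gi[!is.na(gi)])
          },
          dfa = dfa_features(vw),
          dfa_progressive = c(dfa_progressive = dfa_alpha(vw, 4:11)),
          dfa_windowed = dfa_windowed_feature(vw),
          sample_entropy = c(sampen = sample_entropy(vw)),
          multiscale_entropy = mse_features(vw),
          activity_counts = c(activity_counts = if (is.null(ecg_hp)) {
            NA_real_
          } else {
            activity_count_epoch(ecg_hp, ecg$sampling_rate, ep_start)
          })
        )
      }
      vals[!is.finite(vals)] <- NA_real_
      out[k, cols] <- vals[cols]
    }
  }

  res <- as_tibble(out)
  res <- dplyr::bind_cols(
    tibble(record_id = record_id, epoch = seq_len(n_epochs) - 1L), res
  )
  attr(res, "spec") <- reg
  res
}
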