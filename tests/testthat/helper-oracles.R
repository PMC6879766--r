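# Shared fixtures and independent oracles used across the suite.

# Independent 1-ms rasterisation oracle for RE-epoch labelling.
# Events must lie on the millisecond grid (integer ms onset/duration).
# Marks millisecond cells covered by each event and counts per-epoch
# coverage cell by cell; the 5-s after-rule is rasterised as an
# "afterglow" cell mask queried at each epoch's first cell.
oracle_label_re <- function(events, n_epochs) {
  ms_per_epoch <- 30L * 1000L
  total <- n_epochs * ms_per_epoch
  cell_epoch <- rep(seq_len(n_epochs), each = ms_per_epoch)
  rule1 <- logical(n_epochs)
  afterglow <- logical(total + 5000L)
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      on <- as.integer(round(events$onset_s[i] * 1000))
      end <- as.integer(round((events$onset_s[i] + events$duration_s[i]) * 1000))
      cells <- (on + 1L):min(end, total) # cell j covers [j-1, j) ms
      cnt <- tabulate(cell_epoch[cells], nbins = n_epochs)
      rule1 <- rule1 | (cnt >= 10000L)
      glow <- (end + 1L):min(end + 5000L, length(afterglow))
      afterglow[glow] <- TRUE
    }
  }
  first_cell <- (seq_len(n_epochs) - 1L) * ms_per_epoch + 1L
  rule2 <- afterglow[first_cell]
  rule1 | rule2
}

# Random millisecond-grid event set on an n_epochs grid.
random_event_set <- function(n_epochs, max_events = 6) {
  n_ev <- sample.int(max_events, 1)
  dur_ms <- sample(10000:45000, n_ev, replace = TRUE)
  on_ms <- sample.int(max(1, n_epochs * 30000 - 46000), n_ev, replace = TRUE)
  tibble::tibble(
    kind = sample(c(
      "obstructive_apnea", "hypopnea", "central_apnea", "mixed_apnea"
    ), n_ev, replace = TRUE),
    onset_s = on_ms / 1000,
    duration_s = dur_ms / 1000
  )
}

# IBI tibble from a constant heart rate covering [0, duration).
constant_ibis <- function(duration, ibi = 1.0) {
  onsets <- seq(0, duration - ibi, by = ibi)
  tibble::tibble(
    onset_s = onsets, ibi_s = ibi, valid = TRUE, reason = "ok"
  )
}

# Catalogue spec lookup by name (first parameterisation unless index given).
spec_by_name <- function(name, i = 1L) {
  hits <- purrr::keep(cardioahi::transformation_catalogue(), ~ .x$name == name)
  hits[[i]]
}

# Independent Table-of-groups oracle for the transformation graph:
# group -> set of groups allowed as predecessor (the "input groups").
GRAPH_ORACLE <- list(
  winsor = c(0, 4, 6, 7, 8, 9),
  median_removal = c(0, 1),
  zscore = c(0, 1, 4), percentile = c(0, 1, 4), amplitude = c(0, 1, 4),
  boxcox = c(0, 1, 6, 7, 8, 9), histogram = c(0, 1, 6, 7, 8, 9),
  quantile_norm = c(0, 1, 6, 7, 8, 9), tukey_ladder = c(0, 1, 6, 7, 8, 9),
  time_shift = 0,
  roll_mad = c(0, 5), roll_sd = c(0, 5), abs_value = c(0, 5),
  diff_value = c(0, 5), integrate = c(0, 5),
  roll_mean = c(0, 5, 6), roll_median = c(0, 5, 6), lpf = c(0, 5, 6),
  subtract_median = c(0, 5, 6, 7), hpf = c(0, 5, 6, 7),
  exponential = c(0, 5, 6, 7, 8), log = c(0, 5, 6, 7, 8)
)

GROUP_ORACLE <- c(
  winsor = 1, median_removal = 2, zscore = 3, percentile = 3, amplitude = 3,
  boxcox = 4, histogram = 4, quantile_norm = 4, tukey_ladder = 4,
  time_shift = 5, roll_mad = 6, roll_sd = 6, abs_value = 6, diff_value = 6,
  integrate = 6, roll_mean = 7, roll_median = 7, lpf = 7,
  subtract_median = 8, hpf = 8, exponential = 9, log = 9
)
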