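# Synthetic cardiorespiratory recordings with known ground truth.
#
# The generator works at the inter-beat-interval level (all downstream
# computation consumes IBIs); an ECG rendering layer (template QRS pulses
# at the simulated beat times) is available for testing R-peak detection.
# Each respiratory event imprints the characteristic bradycardia during
# the event followed by a sharp tachycardia within a few seconds of its
# end, on top of baseline variability (respiratory sinus arrhythmia,
# low-frequency modulation, white noise). Ectopic beats and movement
# bursts are injected at configurable rates and logged, so rejection
# rules can be checked against the injection log.

#' Simulation configuration
#'
#' Defaults describe a plausible adult overnight recording: resting
#' sleeping heart rate near 60 bpm (baseline IBI 1 s), respiratory sinus
#' arrhythmia at 0.25 Hz, a low-frequency (~0.1 Hz) autonomic component,
#' hypopnea-dominant event mix, event durations 10-60 s centred near
#' 22 s, and a 15% wake fraction in alternating bouts.
#'
#' @param duration_h Recording length in hours.
#' @param target_ahi Target apnea-hypopnea index, events per hour of sleep.
#' @param event_mix Named fractions over the four event kinds; must sum to 1.
#' @param event_duration_meanlog,event_duration_sdlog Log-normal duration
#'   parameters (seconds), truncated to `[10, 60]`.
#' @param desat_mean,desat_sd Hypopnea desaturation distribution (percent),
#'   truncated to `[0.5, 12]`.
#' @param arousal_prob Probability a hypopnea is followed by an arousal.
#' @param baseline_ibi Mean sleeping inter-beat interval, seconds.
#' @param ibi_noise_sd White-noise IBI standard deviation, seconds.
#' @param rsa_amp,rsa_freq Respiratory sinus arrhythmia amplitude (s) and
#'   frequency (Hz).
#' @param lf_amp,lf_freq Low-frequency modulation amplitude (s) and
#'   frequency (Hz).
#' @param brady_depth Fractional IBI lengthening at full event effect.
#' @param tachy_surge Fractional IBI shortening of the post-event surge.
#' @param response_lag Seconds after event end before the surge peaks.
#' @param tachy_tau Exponential decay constant of the surge, seconds.
#' @param wake_fraction Fraction of epochs spent awake.
#' @param wake_bout_mean Mean wake bout length, epochs.
#' @param ectopic_rate Per-beat probability of a premature (ectopic) beat.
#' @param movement_rate Movement bursts per hour (IBI noise inflation).
#' @param seed Integer seed; identical seeds give identical recordings.
#' @return A `cardioahi_sim_config` list.
#' @export
sim_config <- function(duration_h = 8,
                       target_ahi = 15,
                       event_mix = c(
                         obstructive_apnea = 0.30, hypopnea = 0.55,
                         central_apnea = 0.10, mixed_apnea = 0.05
                       ),
                       event_duration_meanlog = log(22),
                       event_duration_sdlog = 0.30,
                       desat_mean = 5, desat_sd = 2,
                       arousal_prob = 0.6,
                       baseline_ibi = 1.0,
                       ibi_noise_sd = 0.025,
                       rsa_amp = 0.025, rsa_freq = 0.25,
                       lf_amp = 0.02, lf_freq = 0.095,
                       brady_depth = 0.15,
                       tachy_surge = 0.20,
                       response_lag = 2,
                       tachy_tau = 4,
                       wake_fraction = 0.15,
                       wake_bout_mean = 4,
                       ectopic_rate = 0.002,
                       movement_rate = 4,
                       seed = 1L) {
  mix <- event_mix[RE_EVENT_KINDS]
  if (anyNA(mix) || abs(sum(mix) - 1) > 1e-8) {
    abort("`event_mix` must name all four event kinds and sum to 1.")
  }
  check_number(duration_h, "duration_h", lower = 0.05)
  check_number(target_ahi, "target_ahi", lower = 0)
  check_number(wake_fraction, "wake_fraction", lower = 0, upper = 0.9)
  cfg <- list(
    duration_h = duration_h, target_ahi = target_ahi, event_mix = mix,
    event_duration_meanlog = event_duration_meanlog,
    event_duration_sdlog = event_duration_sdlog,
    desat_mean = desat_mean, desat_sd = desat_sd, arousal_prob = arousal_prob,
    baseline_ibi = baseline_ibi, ibi_noise_sd = ibi_noise_sd,
    rsa_amp = rsa_amp, rsa_freq = rsa_freq, lf_amp = lf_amp, lf_freq = lf_freq,
    brady_depth = brady_depth, tachy_surge = tachy_surge,
    response_lag = response_lag, tachy_tau = tachy_tau,
    wake_fraction = wake_fraction, wake_bout_mean = wake_bout_mean,
    ectopic_rate = ectopic_rate, movement_rate = movement_rate,
    seed = as.integer(seed)
  )
  structure(cfg, class = "cardioahi_sim_config")
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  pmin(pmax(x, lo), hi)
}

# Alternating sleep/wake bouts with geometric lengths.
sim_hypnogram <- function(n_epochs, wake_fraction, wake_bout_mean) {
  if (wake_fraction <= 0) return(rep("sleep", n_epochs))
  sleep_bout_mean <- wake_bout_mean * (1 - wake_fraction) / wake_fraction
  stages <- character(0)
  state <- "wake" # recordings start with lights-on wake
  while (length(stages) < n_epochs) {
    m <- if (state == "wake") wake_bout_mean else sleep_bout_mean
    len <- 1L + stats::rgeom(1, 1 / m)
    stages <- c(stages, rep(state, len))
    state <- if (state == "wake") "sleep" else "wake"
  }
  stages[seq_len(n_epochs)]
}

# Place non-overlapping events inside sleep bouts with a renewal process:
# exponential gaps plus a refractory period of event duration + 10 s.
sim_events <- function(cfg, stages) {
  n_epochs <- length(stages)
  sleep_s <- sum(stages == "sleep") * EPOCH_LEN
  if (cfg$target_ahi == 0 || sleep_s == 0) {
    return(tibble(
      kind = character(0), onset_s = numeric(0), duration_s = numeric(0),
      desaturation_pct = numeric(0), arousal = logical(0)
    ))
  }
  mean_dur <- exp(cfg$event_duration_meanlog + cfg$event_duration_sdlog^2 / 2)
  occupied <- mean_dur + 10
  target_gap <- 3600 / cfg$target_ahi - occupied
  if (target_gap <= 1) {
    abort(sprintf(
      "target_ahi = %.1f events/h is infeasible: events plus refractory periods occupy the full sleep time.",
      cfg$target_ahi
    ))
  }
  # sleep bouts as [start, end) second intervals
  r <- rle(stages == "sleep")
  ends_ep <- cumsum(r$lengths)
  starts_ep <- ends_ep - r$lengths
  bouts <- tibble(
    start = starts_ep[r$values] * EPOCH_LEN,
    end = ends_ep[r$values] * EPOCH_LEN
  )
  out <- list()
  for (b in seq_len(nrow(bouts))) {
    t <- bouts$start[b]
    repeat {
      t <- t + stats::rexp(1, rate = 1 / target_gap)
      dur <- rtrunc_lnorm(1, cfg$event_duration_meanlog, cfg$event_duration_sdlog, 10, 60)
      if (t + dur > bouts$end[b]) break
      out[[length(out) + 1L]] <- c(t, dur)
      t <- t + dur + 10
    }
  }
  if (!length(out)) {
    return(tibble(
      kind = character(0), onset_s = numeric(0), duration_s = numeric(0),
      desaturation_pct = numeric(0), arousal = logical(0)
    ))
  }
  m <- do.call(rbind, out)
  n <- nrow(m)
  kinds <- sample(RE_EVENT_KINDS, n, replace = TRUE, prob = cfg$event_mix)
  desat <- pmin(pmax(rnorm(n, cfg$desat_mean, cfg$desat_sd), 0.5), 12)
  arousal <- runif(n) < cfg$arousal_prob
  tibble(
    kind = kinds, onset_s = m[, 1], duration_s = m[, 2],
    desaturation_pct = ifelse(kinds == "hypopnea", desat, NA_real_),
    arousal = ifelse(kinds == "hypopnea", arousal, NA)
  )
}

# Multiplicative IBI modulation from events at time t (vectorised over t).
event_modulation <- function(t, events, cfg) {
  mod <- rep(0, length(t))
  if (!nrow(events)) return(mod)
  for (i in seq_len(nrow(events))) {
    on <- events$onset_s[i]
    off <- on + events$duration_s[i]
    during <- t >= on & t < off
    # bradycardia ramps up over the first 10 s of the event
    mod[during] <- mod[during] + cfg$brady_depth * pmin(1, (t[during] - on) / 10)
    after <- t >= off & t < off + 15
    dt <- t[after] - off
    surge <- -cfg$tachy_surge *
      ifelse(dt < cfg$response_lag, dt / cfg$response_lag,
        exp(-(dt - cfg$response_lag) / cfg$tachy_tau)
      )
    mod[after] <- mod[after] + surge
  }
  mod
}

#' Generate one synthetic recording
#'
#' Simulates a hypnogram, respiratory events placed in sleep only, and a
#' beat-by-beat IBI series carrying the event-locked
#' bradycardia-tachycardia response, with ectopic beats and movement
#' bursts injected and logged.
#'
#' The ground-truth AHI is the number of events surviving hypopnea
#' harmonisation (see [harmonise_hypopneas()]) divided by hours of sleep,
#' i.e. the index a scorer applying the 4%-desaturation/arousal rule
#' would report.
#'
#' @param config A [sim_config()] object.
#' @return A `cardioahi_recording` list with elements `record_id`, `ibis`
#'   (tibble `onset_s`, `ibi_s`), `beat_times`, `events` (raw, pre
#'   harmonisation), `stages`, `n_epochs`, `true_ahi`, `injected`
#'   (ectopic-beat and movement logs) and `config`.
#' @export
#' @examples
#' rec <- generate_recording(sim_config(duration_h = 1, target_ahi = 20, seed = 7))
#' rec$true_ahi
generate_recording <- function(config) {
  stopifnot(inherits(config, "cardioahi_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  dur_s <- cfg$duration_h * 3600
  n_epochs <- as.integer(floor(dur_s / EPOCH_LEN))

  stages <- sim_hypnogram(n_epochs, cfg$wake_fraction, cfg$wake_bout_mean)
  events <- sim_events(cfg, stages)
  kept <- harmonise_hypopneas(events, quiet = TRUE)
  sleep_h <- sum(stages == "sleep") * EPOCH_LEN / 3600
  true_ahi <- if (sleep_h > 0) nrow(kept) / sleep_h else NA_real_

  wake_by_epoch <- stages == "wake"

  # Event modulation precomputed on a 4 Hz grid, looked up per beat.
  grid_dt <- 0.25
  grid_t <- seq(0, dur_s, by = grid_dt)
  grid_mod <- event_modulation(grid_t, events, cfg)

  # Beat-by-beat simulation.
  n_guess <- ceiling(dur_s / (cfg$baseline_ibi * 0.6)) + 10
  beat_times <- numeric(n_guess)
  phase_lf <- runif(1, 0, 2 * pi)
  t <- runif(1, 0, 0.5)
  nb <- 0L
  # movement bursts
  n_mov <- stats::rpois(1, cfg$movement_rate * cfg$duration_h)
  mov_on <- sort(runif(n_mov, 0, dur_s))
  mov_dur <- runif(n_mov, 3, 8)
  in_burst <- function(tt) any(tt >= mov_on & tt < mov_on + mov_dur)
  ect_log <- numeric(0)
  while (t < dur_s) {
    nb <- nb + 1L
    beat_times[nb] <- t
    ep <- min(n_epochs, 1L + as.integer(t %/% EPOCH_LEN))
    base <- cfg$baseline_ibi * if (wake_by_epoch[ep]) 0.93 else 1
    ibi <- base * (1 + grid_mod[1L + as.integer(t / grid_dt)]) +
      cfg$rsa_amp * sin(2 * pi * cfg$rsa_freq * t) +
      cfg$lf_amp * sin(2 * pi * cfg$lf_freq * t + phase_lf) +
      rnorm(1, 0, cfg$ibi_noise_sd * if (n_mov && in_burst(t)) 5 else 1)
    ibi <- max(ibi, 0.3)
    if (runif(1) < cfg$ectopic_rate && ibi > 0.92 && ibi < 1.35) {
      # premature beat: short coupling interval then compensatory pause,
      # both inside the physiological range so the ectopic rule (not the
      # range rule) is what catches them
      ect_log <- c(ect_log, t + 0.6 * ibi)
      if (nb + 2L > length(beat_times)) beat_times <- c(beat_times, numeric(n_guess))
      beat_times[nb + 1L] <- t + 0.6 * ibi
      nb <- nb + 1L
      t <- t + 0.6 * ibi + 1.4 * ibi # compensatory pause
    } else {
      t <- t + ibi
    }
    if (nb + 1L > length(beat_times)) beat_times <- c(beat_times, numeric(n_guess))
  }
  beat_times <- beat_times[seq_len(nb)]
  ibis <- tibble(
    onset_s = beat_times[-nb],
    ibi_s = diff(beat_times)
  )

  structure(list(
    record_id = sprintf("sim-%d", cfg$seed),
    ibis = ibis,
    beat_times = beat_times,
    events = events,
    stages = stages,
    n_epochs = n_epochs,
    true_ahi = true_ahi,
    injected = list(
      ectopic_times = ect_log,
      movement = tibble(onset_s = mov_on, duration_s = mov_dur)
    ),
    config = cfg
  ), class = "cardioahi_recording")
}

#' @exportS3Method base::print
print.cardioahi_recording <- function(x, ...) {
  cat(sprintf(
    "<cardioahi_recording %s: %.1f h, %d epochs, %d events, true AHI %.1f events/h>\n",
    x$record_id, x$n_epochs * EPOCH_LEN / 3600, x$n_epochs,
    nrow(x$events), x$true_ahi
  ))
  invisible(x)
}

#' Generate a synthetic population
#'
#' Draws per-recording target AHIs to match a severity mix (uniform
#' within each class: normal `[0,5)`, mild `[5,15)`, moderate `[15,30)`,
#' severe `[30,60)`) and generates each recording with a seed derived
#' from the master seed, so the whole population is reproducible.
#'
#' @param n Number of recordings (>= 2).
#' @param severity_mix Named fractions over
#'   `c("normal", "mild", "moderate", "severe")`.
#' @param config_template A [sim_config()] whose non-AHI fields are shared
#'   by all recordings.
#' @param seed Master seed.
#' @return List of `cardioahi_recording` objects.
#' @export
generate_population <- function(n, severity_mix = c(
                                  normal = 0.25, mild = 0.25,
                                  moderate = 0.25, severe = 0.25
                                ),
                                config_template = sim_config(), seed = 1L) {
  check_number(n, "n", lower = 2)
  mix <- severity_mix[severity_levels]
  if (anyNA(mix) || abs(sum(mix) - 1) > 1e-8) {
    abort("`severity_mix` must name the four severity classes and sum to 1.")
  }
  counts <- floor(n * mix)
  while (sum(counts) < n) { # distribute remainders in class order
    i <- which.max(n * mix - counts)
    counts[i] <- counts[i] + 1
  }
  bounds <- list(
    normal = c(0.5, 5), mild = c(5, 15), moderate = c(15, 30), severe = c(30, 60)
  )
  set.seed(as.integer(seed))
  targets <- unlist(map2(severity_levels, counts, function(cl, k) {
    runif(k, bounds[[cl]][1], bounds[[cl]][2])
  }))
  targets <- sample(targets) # shuffle so list order is severity-agnostic
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  map2(seq_len(n), targets, function(i, ahi) {
    cfg <- config_template
    cfg$target_ahi <- ahi
    cfg$seed <- sub_seeds[i]
    rec <- generate_recording(cfg)
    rec$record_id <- sprintf("sim-%03d", i)
    rec
  })
}

#' Render a synthetic ECG from simulated beat times
#'
#' Convolves a template QRS complex (difference-of-Gaussians giving the
#' characteristic narrow R wave with small Q/S deflections) with the
#' recording's beat times, adding baseline wander and measurement noise.
#' Used to exercise R-peak detection against known ground-truth beats.
#'
#' @param recording A `cardioahi_recording`.
#' @param sampling_rate Samples per second.
#' @param noise_sd Additive white noise, in units of R amplitude.
#' @param wander_amp Baseline wander amplitude (0.33 Hz respiratory band).
#' @return An `ecg_record` list: `samples`, `sampling_rate`, `duration`,
#'   `record_id`.
#' @export
render_ecg <- function(recording, sampling_rate = 256, noise_sd = 0.02,
                       wander_amp = 0.1) {
  stopifnot(inherits(recording, "cardioahi_recording"))
  fs <- sampling_rate
  dur <- recording$n_epochs * EPOCH_LEN
  n <- as.integer(dur * fs)
  x <- numeric(n)
  # template: R spike minus wider S/Q lobes, ~80 ms QRS (odd length)
  half <- as.integer(round(0.06 * fs))
  tt <- (-half:half) / fs
  template <- exp(-(tt / 0.012)^2) - 0.25 * exp(-((tt - 0.025) / 0.02)^2) -
    0.15 * exp(-((tt + 0.025) / 0.02)^2)
  idx <- round(recording$beat_times * fs) + 1L
  idx <- idx[idx > half & idx <= n - half]
  for (i in idx) {
    rng <- (i - half):(i + half)
    x[rng] <- x[rng] + template
  }
  ts <- (seq_len(n) - 1) / fs
  x <- x + wander_amp * sin(2 * pi * 0.33 * ts) + rnorm(n, 0, noise_sd)
  # movement bursts appear as broadband (EMG-like) noise in the ECG
  mov <- recording$injected$movement
  if (!is.null(mov) && nrow(mov)) {
    for (i in seq_len(nrow(mov))) {
      i0 <- max(1L, as.integer(mov$onset_s[i] * fs))
      i1 <- min(n, as.integer((mov$onset_s[i] + mov$duration_s[i]) * fs))
      if (i1 > i0) x[i0:i1] <- x[i0:i1] + rnorm(i1 - i0 + 1, 0, 0.3)
    }
  }
  structure(list(
    samples = x, sampling_rate = fs, duration = dur,
    record_id = recording$record_id
  ), class = "ecg_record")
}
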