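# Feature-transformation catalogue and greedy chain optimisation.
#
# Twenty-two transformations, each belonging to a group 0-9; a directed
# graph (the "input groups" of each transformation) constrains which
# transformation may follow which. Chains are grown greedily, per
# feature, to maximise the absolute mean standardized distance (AMSD)
# between RE- and non-RE-epochs, stopping when no successor strictly
# improves the score or at depth five. All transformations are applied
# per recording: every statistic (percentile, median, mean/SD, Box-Cox
# lambda, quantile map) is computed within one recording's series only.

#' Absolute mean standardized distance (AMSD)
#'
#' Class separability of a feature: the absolute difference of the class
#' means divided by the standard deviation over the pooled epochs of both
#' classes. The population (n-denominator) SD convention is used.
#' Missing values are ignored. The score is invariant under global
#' positive affine maps of the feature.
#'
#' @param values Numeric feature values pooled across recordings.
#' @param labels Logical (or two-level) class labels, `TRUE` = RE-epoch.
#' @return Non-negative score; `NA` (with a warning) when only one class
#'   is present among the non-missing values or the pooled SD is zero.
#' @export
#' @examples
#' amsd(c(1, 3, 0, 2), c(TRUE, TRUE, FALSE, FALSE))
amsd <- function(values, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(values) & !is.na(labels)
  v <- values[ok]
  l <- labels[ok]
  if (!any(l) || all(l)) {
    warn("AMSD undefined: only one class present among non-missing values.")
    return(NA_real_)
  }
  s <- pop_sd(v)
  if (is.na(s) || s == 0) {
    warn("AMSD undefined: pooled standard deviation is zero.")
    return(NA_real_)
  }
  abs(mean(v[l]) - mean(v[!l])) / s
}

# ---- catalogue -------------------------------------------------------------

ROLL_WINDOWS <- c(7L, 15L, 23L, 31L)
ROLL_ALIGNS <- c("backward", "forward", "centred")
BUTTER_CUTOFFS <- c(0.25, 0.5, 0.75)

windowed_params <- function() {
  out <- list()
  for (w in ROLL_WINDOWS) {
    for (a in ROLL_ALIGNS) out[[length(out) + 1L]] <- list(window = w, alignment = a)
  }
  out
}

build_catalogue <- function() {
  add <- function(acc, name, group, inputs, params_list = list(NULL)) {
    for (p in params_list) {
      acc[[length(acc) + 1L]] <- list(
        name = name, group = group, input_groups = inputs, params = p
      )
    }
    acc
  }
  cat_ <- list()
  cat_ <- add(cat_, "winsor", 1L, c(0L, 4L, 6L, 7L, 8L, 9L),
    list(list(lo = 1, hi = 99), list(lo = 5, hi = 95))
  )
  cat_ <- add(cat_, "median_removal", 2L, c(0L, 1L))
  cat_ <- add(cat_, "zscore", 3L, c(0L, 1L, 4L))
  cat_ <- add(cat_, "percentile", 3L, c(0L, 1L, 4L))
  cat_ <- add(cat_, "amplitude", 3L, c(0L, 1L, 4L))
  g4_in <- c(0L, 1L, 6L, 7L, 8L, 9L)
  cat_ <- add(cat_, "boxcox", 4L, g4_in)
  cat_ <- add(cat_, "histogram", 4L, g4_in)
  cat_ <- add(cat_, "quantile_norm", 4L, g4_in, list(
    list(reference = "normal"), list(reference = "exponential"),
    list(reference = "uniform")
  ))
  cat_ <- add(cat_, "tukey_ladder", 4L, g4_in)
  cat_ <- add(cat_, "time_shift", 5L, 0L, list(list(shift = -1L), list(shift = 1L)))
  cat_ <- add(cat_, "roll_mad", 6L, c(0L, 5L), windowed_params())
  cat_ <- add(cat_, "roll_sd", 6L, c(0L, 5L), windowed_params())
  cat_ <- add(cat_, "abs_value", 6L, c(0L, 5L))
  cat_ <- add(cat_, "diff_value", 6L, c(0L, 5L))
  cat_ <- add(cat_, "integrate", 6L, c(0L, 5L))
  cat_ <- add(cat_, "roll_mean", 7L, c(0L, 5L, 6L), windowed_params())
  cat_ <- add(cat_, "roll_median", 7L, c(0L, 5L, 6L), windowed_params())
  cat_ <- add(cat_, "lpf", 7L, c(0L, 5L, 6L), map(BUTTER_CUTOFFS, ~ list(cutoff = .x)))
  cat_ <- add(cat_, "subtract_median", 8L, c(0L, 5L, 6L, 7L), windowed_params())
  cat_ <- add(cat_, "hpf", 8L, c(0L, 5L, 6L, 7L), map(BUTTER_CUTOFFS, ~ list(cutoff = .x)))
  cat_ <- add(cat_, "exponential", 9L, c(0L, 5L, 6L, 7L, 8L), list(
    list(exponent = "square"), list(exponent = "square_root")
  ))
  cat_ <- add(cat_, "log", 9L, c(0L, 5L, 6L, 7L, 8L))
  for (i in seq_along(cat_)) cat_[[i]]$id <- i
  cat_
}

the_catalogue <- NULL

#' Transformation catalogue
#'
#' All parameterised transformations in their fixed catalogue order
#' (the order also breaks AMSD ties in the greedy search).
#'
#' @return List of transformation specs, each with `name`, `group`,
#'   `input_groups`, `params`, `id`.
#' @export
transformation_catalogue <- function() {
  if (is.null(the_catalogue)) {
    # memoise in the package namespace on first use
    utils::assignInMyNamespace("the_catalogue", build_catalogue())
  }
  the_catalogue
}

#' Legal successors of a transformation chain
#'
#' A transformation may follow the chain when its input-group set
#' contains the group of the chain's last transformation (group 0 for
#' the empty chain) and the chain is shorter than five.
#'
#' @param chain A `transformation_chain` (see [optimise_feature()]) or
#'   `NULL`/empty for the raw feature.
#' @return List of catalogue specs (empty at the depth-5 cap).
#' @export
valid_successor_specs <- function(chain = NULL) {
  specs <- if (is.null(chain)) list() else chain$specs
  if (length(specs) >= 5L) return(list())
  last_group <- if (length(specs)) specs[[length(specs)]]$group else 0L
  keep(transformation_catalogue(), ~ last_group %in% .x$input_groups)
}

# ---- individual transformations -------------------------------------------

# Shift a series to strict positivity (min maps to a small epsilon).
shift_positive <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  mn <- min(x[ok])
  eps <- max(1e-6, 1e-3 * (max(x[ok]) - mn))
  if (mn <= 0) x - mn + eps else x
}

roll_idx_cache <- new.env(parent = emptyenv())

roll_indices <- function(n, w, alignment) {
  key <- paste(n, w, alignment, sep = "-")
  hit <- roll_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  offs <- switch(alignment,
    backward = (-w + 1L):0L,
    forward = 0L:(w - 1L),
    centred = (-(w %/% 2L)):(w %/% 2L)
  )
  idx <- outer(seq_len(n), offs, "+")
  idx[idx < 1L | idx > n] <- NA_integer_
  roll_idx_cache[[key]] <- idx
  idx
}

roll_stat <- function(x, w, alignment, stat) {
  n <- length(x)
  if (stat == "median") {
    out <- roll_median_c(
      as.numeric(x), as.integer(w),
      match(alignment, c("backward", "forward", "centred")) - 1L
    )
    return(out)
  }
  idx <- roll_indices(n, w, alignment)
  m <- matrix(x[idx], nrow = n)
  out <- switch(stat,
    mean = rowMeans(m, na.rm = TRUE),
    mad = rowMeans(abs(m - rowMeans(m, na.rm = TRUE)), na.rm = TRUE),
    sd = {
      mu <- rowMeans(m, na.rm = TRUE)
      cnt <- rowSums(!is.na(m))
      sqrt(rowSums((m - mu)^2, na.rm = TRUE) / pmax(cnt, 1))
    }
  )
  out[is.nan(out)] <- NA_real_
  out[is.na(x)] <- NA_real_ # missing values propagate
  out
}

butter_filter <- function(x, cutoff, type) {
  ok <- which(!is.na(x))
  if (length(ok) < 13) return(rep(NA_real_, length(x))) # filtfilt needs 3x filter length
  lo <- min(ok)
  hi <- max(ok)
  core <- x[lo:hi]
  nas <- is.na(core)
  if (any(nas)) { # bridge interior gaps for the filter, restore NA after
    core <- approx(which(!nas), core[!nas], xout = seq_along(core))$y
  }
  b <- signal::butter(2, cutoff, type = type)
  filt <- signal::filtfilt(b, core)
  filt[nas] <- NA_real_
  out <- rep(NA_real_, length(x))
  out[lo:hi] <- filt
  out
}

tukey_exponents <- c(-2, -1, -0.5, 0, 0.5, 1, 2)

apply_tukey <- function(x, lambda) {
  if (lambda == 0) return(log(x))
  if (lambda < 0) return(-(x^lambda)) # sign flip preserves order
  x^lambda
}

#' Apply one transformation to a per-recording feature series
#'
#' All statistics are computed within the given series (one recording).
#' Missing values propagate; windowed operators ignore missing values
#' inside the window; the time shift pads with missing values.
#'
#' @param series Numeric per-recording feature series (epoch-indexed).
#' @param spec A catalogue spec (see [transformation_catalogue()]).
#' @return Transformed series, same length.
#' @export
apply_transformation <- function(series, spec) {
  x <- as.numeric(series)
  p <- spec$params
  ok <- !is.na(x)
  if (sum(ok) < 2) return(x)
  switch(spec$name,
    winsor = {
      q <- quantile(x[ok], c(p$lo, p$hi) / 100)
      pmin(pmax(x, q[1]), q[2])
    },
    median_removal = x - median(x[ok]),
    zscore = {
      s <- pop_sd(x)
      if (s == 0) x - mean(x[ok]) else (x - mean(x[ok])) / s
    },
    percentile = {
      out <- rep(NA_real_, length(x))
      r <- rank(x[ok], ties.method = "average")
      out[ok] <- if (sum(ok) > 1) (r - 1) / (sum(ok) - 1) else 0.5
      out
    },
    amplitude = {
      mx <- max(abs(x[ok]))
      if (mx == 0) x else x / mx
    },
    boxcox = {
      y <- shift_positive(x)
      ly <- log(y[!is.na(y)])
      n <- length(ly)
      ll <- vapply(seq(-2, 2, by = 0.1), function(lam) {
        z <- if (lam == 0) ly else (exp(ly * lam) - 1) / lam
        (lam - 1) * sum(ly) - n / 2 * log(max(var(z) * (n - 1) / n, 1e-300))
      }, 1)
      lam <- seq(-2, 2, by = 0.1)[which.max(ll)]
      z <- if (lam == 0) log(y) else (y^lam - 1) / lam
      s <- pop_sd(z)
      if (is.na(s) || s == 0) z - mean(z, na.rm = TRUE) else (z - mean(z, na.rm = TRUE)) / s
    },
    histogram = { # 10-bin empirical CDF equalisation to [0, 1]
      edges <- seq(min(x[ok]), max(x[ok]), length.out = 11L)
      if (edges[1] == edges[11]) return(ifelse(ok, 0.5, NA_real_))
      cdf <- c(0, cumsum(tabulate(
        pmin(findInterval(x[ok], edges, rightmost.closed = TRUE), 10L),
        nbins = 10L
      )) / sum(ok))
      approx(edges, cdf, xout = x, rule = 2)$y
    },
    quantile_norm = {
      out <- rep(NA_real_, length(x))
      r <- rank(x[ok], ties.method = "average") / (sum(ok) + 1)
      out[ok] <- switch(p$reference,
        normal = qnorm(r),
        exponential = qexp(r),
        uniform = qunif(r)
      )
      out
    },
    tukey_ladder = {
      y <- shift_positive(x)
      sk <- vapply(tukey_exponents, function(l) {
        abs(skewness_(apply_tukey(y[!is.na(y)], l)))
      }, 1)
      sk[is.na(sk)] <- Inf
      apply_tukey(y, tukey_exponents[which.min(sk)])
    },
    time_shift = {
      n <- length(x)
      if (p$shift == 1L) c(NA_real_, x[-n]) else c(x[-1], NA_real_)
    },
    roll_mad = roll_stat(x, p$window, p$alignment, "mad"),
    roll_sd = roll_stat(x, p$window, p$alignment, "sd"),
    abs_value = abs(x),
    diff_value = c(NA_real_, diff(x)),
    integrate = {
      out <- rep(NA_real_, length(x))
      out[ok] <- cumsum(x[ok] - mean(x[ok]))
      out
    },
    roll_mean = roll_stat(x, p$window, p$alignment, "mean"),
    roll_median = roll_stat(x, p$window, p$alignment, "median"),
    lpf = butter_filter(x, p$cutoff, "low"),
    subtract_median = x - roll_stat(x, p$window, p$alignment, "median"),
    hpf = butter_filter(x, p$cutoff, "high"),
    exponential = if (p$exponent == "square") x^2 else sqrt(shift_positive(x)),
    log = log(shift_positive(x)),
    abort(sprintf("Unknown transformation '%s'.", spec$name))
  )
}

# Apply a spec per recording (split by record_ids) and re-concatenate.
apply_spec_by_record <- function(values, rec_index, spec) {
  out <- values
  for (g in rec_index) out[g] <- apply_transformation(values[g], spec)
  out
}

#' Replay a transformation chain
#'
#' @param values Pooled feature values.
#' @param record_ids Recording identifier per value (transformations are
#'   applied within each recording).
#' @param chain A `transformation_chain`.
#' @return Transformed values.
#' @export
apply_chain <- function(values, record_ids, chain) {
  rec_index <- split(seq_along(values), record_ids)
  for (spec in chain$specs) {
    values <- apply_spec_by_record(values, rec_index, spec)
  }
  values
}

# ---- greedy search ---------------------------------------------------------

amsd_or_zero <- function(values, labels) {
  s <- suppressWarnings(amsd(values, labels))
  if (is.na(s)) 0 else s
}

#' Greedy per-feature transformation-chain optimisation
#'
#' Starting from the raw feature, repeatedly applies every legal
#' successor transformation (per recording), keeps the single one that
#' most improves the AMSD, and stops when no successor strictly improves
#' it or a chain of five is reached. Ties go to the first transformation
#' in catalogue order.
#'
#' @param values Pooled feature values across the training recordings.
#' @param labels Logical RE/non-RE labels, same length.
#' @param record_ids Recording identifier per value.
#' @param feature_name Stored on the returned chain.
#' @param max_depth Chain-length cap.
#' @return A `transformation_chain`: `feature_name`, `specs` (ordered
#'   list), `achieved_amsd`, `amsd_trace` (score after each link,
#'   starting with the raw feature's).
#' @export
optimise_feature <- function(values, labels, record_ids,
                             feature_name = "feature", max_depth = 5L) {
  labels <- as.logical(labels)
  rec_index <- split(seq_along(values), record_ids)
  chain <- structure(
    list(
      feature_name = feature_name, specs = list(),
      achieved_amsd = 0, amsd_trace = numeric(0)
    ),
    class = "transformation_chain"
  )
  base <- amsd_or_zero(values, labels)
  chain$achieved_amsd <- base
  chain$amsd_trace <- base
  if (all(is.na(values)) || base == 0 && length(unique(values[!is.na(values)])) <= 1) {
    return(chain)
  }
  current <- values
  repeat {
    if (length(chain$specs) >= max_depth) break
    succs <- valid_successor_specs(chain)
    best_score <- chain$achieved_amsd
    best_spec <- NULL
    best_vals <- NULL
    for (spec in succs) {
      cand <- apply_spec_by_record(current, rec_index, spec)
      sc <- amsd_or_zero(cand, labels)
      if (sc > best_score) {
        best_score <- sc
        best_spec <- spec
        best_vals <- cand
      }
    }
    if (is.null(best_spec)) break
    chain$specs[[length(chain$specs) + 1L]] <- best_spec
    chain$achieved_amsd <- best_score
    chain$amsd_trace <- c(chain$amsd_trace, best_score)
    current <- best_vals
  }
  chain
}

#' @exportS3Method base::print
print.transformation_chain <- function(x, ...) {
  steps <- if (length(x$specs)) {
    paste(vapply(x$specs, function(s) s$name, ""), collapse = " -> ")
  } else {
    "(raw)"
  }
  cat(sprintf(
    "<transformation_chain %s: %s, AMSD %.4f>\n",
    x$feature_name, steps, x$achieved_amsd
  ))
  invisible(x)
}

#' Optimise every feature column of a training table
#'
#' @param features Feature tibble with `record_id`, `epoch` and feature
#'   columns (see [extract_feature_matrix()]).
#' @param labels Logical RE labels aligned with the rows.
#' @param cols Feature columns to optimise (default: all).
#' @param max_depth Chain-length cap per feature.
#' @return Named list of `transformation_chain`s.
#' @export
optimise_features <- function(features, labels,
                              cols = setdiff(names(features), c("record_id", "epoch")),
                              max_depth = 5L) {
  setNames(map(cols, function(cl) {
    optimise_feature(features[[cl]], labels, features$record_id,
      feature_name = cl, max_depth = max_depth
    )
  }), cols)
}

#' Apply a bundle of chains to a feature table
#'
#' @param features Feature tibble.
#' @param chains Named list of chains from [optimise_features()].
#' @return The tibble with each chained column transformed per recording.
#' @export
apply_chain_bundle <- function(features, chains) {
  for (cl in names(chains)) {
    if (!cl %in% names(features)) next
    features[[cl]] <- apply_chain(features[[cl]], features$record_id, chains[[cl]])
  }
  features
}

# ---- serialisation ---------------------------------------------------------

#' Serialise transformation chains to JSON
#'
#' @param chains Named list of chains.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
chains_to_json <- function(chains, path) {
  payload <- map(chains, function(ch) {
    list(
      feature_name = ch$feature_name,
      achieved_amsd = ch$achieved_amsd,
      amsd_trace = ch$amsd_trace,
      specs = map(ch$specs, function(s) {
        list(name = s$name, group = s$group, params = s$params)
      })
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read transformation chains from JSON
#'
#' @param path JSON path written by [chains_to_json()].
#' @return Named list of `transformation_chain`s.
#' @export
chains_from_json <- function(path) {
  payload <- jsonlite::read_json(path)
  cat_ <- transformation_catalogue()
  map(payload, function(ch) {
    specs <- map(ch$specs, function(s) {
      hit <- keep(cat_, function(cs) {
        cs$name == s$name && identical(
          lapply(cs$params, as.character) %||% list(),
          lapply(s$params, as.character) %||% list()
        )
      })
      if (!length(hit)) abort(sprintf("Chain spec '%s' not found in catalogue.", s$name))
      hit[[1]]
    })
    structure(list(
      feature_name = ch$feature_name, specs = specs,
      achieved_amsd = ch$achieved_amsd,
      amsd_trace = unlist(ch$amsd_trace)
    ), class = "transformation_chain")
  })
}
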