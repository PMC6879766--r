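# Epoch classification and AHI estimation.
#
# The epoch classifier is trained on all epochs (wake included) after
# SMOTE oversampling of the minority RE class and edited-nearest-
# neighbour cleaning. The RE-probability threshold and the calibration
# slope beta are chosen on sleep epochs only: beta is the Theil-Sen
# slope relating the per-recording true RE-epoch fraction to the
# reference AHI, and the threshold maximises Cohen's kappa between the
# estimated and reference OSA severity classes. The predicted AHI is
# beta times the fraction of detected RE-epochs among sleep epochs.

# ---- balancing -------------------------------------------------------------

# brute-force k-nearest neighbours within `x` (rows), chunked
knn_indices <- function(x, k) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  out <- matrix(0L, n, k)
  chunk <- max(1L, 2e6 %/% n)
  for (i0 in seq(1, n, by = chunk)) {
    idx <- i0:min(n, i0 + chunk - 1)
    d2 <- outer(sq[idx], sq, "+") - 2 * x[idx, , drop = FALSE] %*% t(x)
    d2[cbind(seq_along(idx), idx)] <- Inf # exclude self
    out[idx, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  out
}

#' Balance epochs with SMOTE and edited-nearest-neighbour cleaning
#'
#' Oversamples the minority class to parity by interpolating each drawn
#' minority sample towards one of its `k` nearest minority neighbours,
#' then removes (from both classes) every sample whose 3 nearest
#' neighbours vote against its label. Deterministic under the caller's
#' RNG seed.
#'
#' @param x Numeric matrix (epochs x features), no missing values.
#' @param labels Logical labels, `TRUE` = minority RE class (either class
#'   may be the minority; parity is always reached before cleaning).
#' @param k Number of SMOTE neighbours.
#' @return List with balanced `x` and `labels`.
#' @export
balance_epochs <- function(x, labels, k = 5L) {
  x <- as.matrix(x)
  labels <- as.logical(labels)
  if (anyNA(x)) abort("`x` must not contain missing values; impute first.")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  minority <- if (n_pos <= n_neg) TRUE else FALSE
  n_min <- min(n_pos, n_neg)
  n_need <- abs(n_pos - n_neg)
  if (n_need > 0) {
    if (n_min < k + 1) {
      abort(sprintf(
        "Minority class has %d samples; SMOTE with k = %d needs at least %d. Reduce k or provide more data.",
        n_min, k, k + 1
      ))
    }
    xm <- x[labels == minority, , drop = FALSE]
    nn <- knn_indices(xm, k)
    base <- sample.int(nrow(xm), n_need, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k, n_need, replace = TRUE))]
    u <- runif(n_need)
    synth <- xm[base, , drop = FALSE] + u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
    x <- rbind(x, synth)
    labels <- c(labels, rep(minority, n_need))
  }
  # ENN cleaning: 3-NN leave-one-out vote
  cl <- factor(labels, levels = c(FALSE, TRUE))
  pred <- class::knn.cv(x, cl, k = 3L)
  keep <- !is.na(pred) & pred == cl
  list(x = x[keep, , drop = FALSE], labels = labels[keep])
}

# ---- model candidates ------------------------------------------------------

MODEL_KINDS <- c("logistic_elastic_net", "huber_linear", "lda", "qda")

fit_candidate <- function(x, y, kind, lambda = 1e-3, alpha = 0.5) {
  x <- as.matrix(x)
  switch(kind,
    logistic_elastic_net = glmnet::glmnet(x, factor(y),
      family = "binomial",
      alpha = alpha, lambda = lambda, standardize = FALSE
    ),
    huber_linear = MASS::rlm(x, ifelse(y, 1, 0), psi = MASS::psi.huber, maxit = 50),
    lda = MASS::lda(x, grouping = factor(y)),
    qda = MASS::qda(x, grouping = factor(y)),
    abort(sprintf("Unknown model kind '%s'.", kind))
  )
}

predict_candidate <- function(fit, x, kind) {
  x <- as.matrix(x)
  switch(kind,
    logistic_elastic_net = as.numeric(predict(fit, x, type = "response")),
    huber_linear = pmin(pmax(as.numeric(x %*% fit$coefficients), 0), 1),
    lda = as.numeric(predict(fit, x)$posterior[, "TRUE"]),
    qda = as.numeric(predict(fit, x)$posterior[, "TRUE"])
  )
}

#' Area under the precision-recall curve (average precision)
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical labels.
#' @return Average precision in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  l <- labels[ord]
  if (!any(l)) return(NA_real_)
  prec <- cumsum(l) / seq_along(l)
  sum(prec[l]) / sum(l)
}

#' Select the epoch classifier by inner-CV precision-recall AUC
#'
#' Candidates (logistic elastic net, Huber-loss linear, LDA, QDA) are
#' graded by their mean PR-AUC over participant-disjoint inner folds;
#' ties break towards the earlier candidate.
#'
#' @param x Numeric feature matrix (imputed, standardised).
#' @param labels Logical RE labels.
#' @param record_ids Participant/recording id per row.
#' @param k_inner Number of inner folds.
#' @param seed Seed for fold construction.
#' @return The winning model kind (character scalar), with the per-model
#'   mean PR-AUC attached as attribute `"scores"`.
#' @export
select_model <- function(x, labels, record_ids, k_inner = 4L, seed = 1L) {
  x <- as.matrix(x)
  meta <- tibble(
    record_id = unique(record_ids),
    ahi = vapply(
      unique(record_ids),
      function(r) mean(labels[record_ids == r]) * 100, 1
    )
  )
  plan <- build_folds(meta, k = k_inner, seed = seed)
  scores <- matrix(NA_real_, k_inner, length(MODEL_KINDS),
    dimnames = list(NULL, MODEL_KINDS)
  )
  for (f in seq_len(k_inner)) {
    mem <- fold_members(plan, f)
    tr <- record_ids %in% mem$train
    va <- record_ids %in% mem$validation
    if (length(unique(labels[tr])) < 2 || length(unique(labels[va])) < 2) {
      warn(sprintf("Inner fold %d is single-class; skipped.", f))
      next
    }
    for (kind in MODEL_KINDS) {
      fit <- tryCatch(fit_candidate(x[tr, , drop = FALSE], labels[tr], kind),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      p <- predict_candidate(fit, x[va, , drop = FALSE], kind)
      scores[f, kind] <- pr_auc(p, labels[va])
    }
  }
  mean_scores <- colMeans(scores, na.rm = TRUE)
  winner <- MODEL_KINDS[which.max(mean_scores)] # which.max keeps first on ties
  structure(winner, scores = mean_scores)
}

# Inner participant-disjoint CV over the training pool. Tunes the
# elastic-net penalty by mean PR-AUC (ties towards the stronger penalty)
# and returns out-of-fold RE probabilities at the chosen settings, so the
# probability threshold can be selected on predictions the classifier did
# not see in training — in-sample probabilities are over-sharp and make
# the kappa-optimal threshold transfer poorly to new recordings.
inner_cv_probs <- function(x, labels, record_ids, model_kind,
                           lambda_grid, alpha = 0.5,
                           smote_k = 5L, k_inner = 4L, seed = 1L) {
  grid <- sort(lambda_grid)
  meta <- tibble(
    record_id = unique(record_ids),
    ahi = vapply(unique(record_ids), function(r) {
      mean(labels[record_ids == r]) * 100
    }, 1)
  )
  plan <- suppressWarnings(build_folds(meta, k = k_inner, seed = seed))
  scores <- matrix(NA_real_, k_inner, length(grid))
  fold_rows <- list()
  fold_prob_grid <- list()
  for (f in seq_len(k_inner)) {
    mem <- fold_members(plan, f)
    tr <- record_ids %in% mem$train
    va <- record_ids %in% mem$validation
    if (length(unique(labels[tr])) < 2 || !any(va)) next
    bal <- balance_epochs(x[tr, , drop = FALSE], labels[tr], k = smote_k)
    if (model_kind == "logistic_elastic_net") {
      fit <- glmnet::glmnet(bal$x, factor(bal$labels),
        family = "binomial",
        alpha = alpha, lambda = rev(grid), standardize = FALSE
      )
      p <- predict(fit, x[va, , drop = FALSE], type = "response")
      cols <- vapply(grid, function(l) which.min(abs(fit$lambda - l)), 1L)
      scores[f, ] <- vapply(cols, function(cl) pr_auc(p[, cl], labels[va]), 1)
      fold_prob_grid[[f]] <- p[, cols, drop = FALSE]
    } else {
      fit <- fit_candidate(bal$x, bal$labels, model_kind, alpha = alpha)
      fold_prob_grid[[f]] <- matrix(predict_candidate(fit, x[va, , drop = FALSE], model_kind))
      scores[f, ] <- pr_auc(fold_prob_grid[[f]][, 1], labels[va])
    }
    fold_rows[[f]] <- which(va)
  }
  mean_sc <- colMeans(scores, na.rm = TRUE)
  best_j <- if (all(is.na(mean_sc))) length(grid) else {
    max(which(mean_sc == max(mean_sc, na.rm = TRUE)))
  }
  oof <- rep(NA_real_, nrow(x))
  for (f in seq_along(fold_rows)) {
    if (is.null(fold_rows[[f]])) next
    pj <- if (model_kind == "logistic_elastic_net") best_j else 1L
    oof[fold_rows[[f]]] <- fold_prob_grid[[f]][, pj]
  }
  list(lambda = grid[best_j], oof_probs = oof)
}

# ---- Theil-Sen calibration -------------------------------------------------

#' Theil-Sen slope
#'
#' Median of all pairwise slopes; pairs with equal x are skipped.
#'
#' @param x,y Paired numeric vectors.
#' @return The slope.
#' @export
#' @examples
#' theil_sen_slope(c(0.1, 0.2, 0.3), c(5, 10, 15))
theil_sen_slope <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) abort("Theil-Sen needs at least two points.")
  pairs <- utils::combn(n, 2)
  dx <- x[pairs[2, ]] - x[pairs[1, ]]
  dy <- y[pairs[2, ]] - y[pairs[1, ]]
  keep <- dx != 0
  if (!any(keep)) abort("Theil-Sen slope undefined: all x values are equal.")
  median(dy[keep] / dx[keep])
}

#' Estimate the AHI calibration coefficient beta
#'
#' For each training recording, the true RE-epoch fraction over sleep
#' epochs is paired with the reference AHI; beta is the Theil-Sen slope
#' of AHI on the fraction. There is no intercept: the AHI model is
#' purely multiplicative.
#'
#' @param reference_ahis Numeric reference AHI per recording.
#' @param label_list List of per-recording logical RE labels (true
#'   labels, all epochs).
#' @param mask_list List of per-recording logical sleep masks.
#' @return `beta`, events/h per unit epoch fraction.
#' @export
estimate_beta <- function(reference_ahis, label_list, mask_list) {
  stopifnot(length(reference_ahis) == length(label_list))
  ratios <- map_dbl(seq_along(label_list), function(i) {
    m <- mask_list[[i]]
    if (!any(m)) return(NA_real_)
    mean(label_list[[i]][m])
  })
  ok <- !is.na(ratios)
  if (sum(ok) < 2) abort("Need at least two recordings with analysable epochs.")
  theil_sen_slope(ratios[ok], reference_ahis[ok])
}

# ---- threshold selection ---------------------------------------------------

#' Select the RE-probability threshold by severity-kappa maximisation
#'
#' Sweeps thresholds 0.01..0.99; for each, the training AHI is predicted
#' from the thresholded probabilities (sleep epochs only) via `beta`,
#' mapped to a severity class, and compared with the reference severity
#' through the multi-class Cohen's kappa. The highest threshold
#' achieving the maximal kappa is returned (specificity is favoured over
#' sensitivity).
#'
#' @param prob_list List of per-recording RE probabilities, sleep epochs
#'   only.
#' @param reference_ahis Reference AHI per recording.
#' @param beta Calibration slope from [estimate_beta()].
#' @param grid Threshold grid.
#' @return The selected threshold.
#' @export
select_probability_threshold <- function(prob_list, reference_ahis, beta,
                                         grid = seq_len(99) / 100) {
  ref_sev <- ahi_severity(reference_ahis)
  kappas <- map_dbl(grid, function(t) {
    pred_ahi <- map_dbl(prob_list, function(p) beta * mean(p >= t))
    cohens_kappa(ahi_severity(pred_ahi), ref_sev)
  })
  best <- max(kappas)
  grid[max(which(kappas == best))]
}

# ---- AHI estimation --------------------------------------------------------

#' Estimate the AHI from epoch probabilities
#'
#' Counts analysable (sleep) epochs whose RE probability reaches the
#' threshold and scales the detected fraction by beta.
#'
#' @param probabilities Per-epoch RE probabilities.
#' @param estimator A `cardioahi_estimator` (see [train_ahi_pipeline()]),
#'   or a list with elements `probability_threshold` and `beta`.
#' @param analysable Logical mask of sleep epochs.
#' @param record_id Identifier for the output row.
#' @return One-row tibble: `record_id`, `n_analysable_epochs`,
#'   `n_detected_re_epochs`, `ahi_pred`, `severity`.
#' @export
estimate_ahi <- function(probabilities, estimator, analysable,
                         record_id = "record") {
  if (length(probabilities) != length(analysable)) {
    abort("`probabilities` and `analysable` must have the same length.")
  }
  if (!any(analysable)) {
    abort("No analysable (sleep) epochs: the AHI is undefined for this recording.")
  }
  thr <- estimator$probability_threshold
  beta <- estimator$beta
  p <- probabilities[analysable]
  detected <- sum(p >= thr, na.rm = TRUE)
  n <- sum(analysable)
  ahi <- beta * detected / n
  tibble(
    record_id = record_id,
    n_analysable_epochs = n,
    n_detected_re_epochs = detected,
    ahi_pred = ahi,
    severity = as.character(ahi_severity(ahi))
  )
}

# ---- end-to-end pipeline ---------------------------------------------------

#' Prepare a recording for training or prediction
#'
#' Cleans the IBI series, harmonises hypopneas, labels RE epochs, applies
#' the sleep mask and extracts features.
#'
#' @param recording A `cardioahi_recording` (see [generate_recording()])
#'   or a list with `ibis` (`onset_s`, `ibi_s`), `events`, `stages`,
#'   `n_epochs`, `record_id` and optionally `true_ahi`.
#' @param families Feature families to extract.
#' @param ecg Optional `ecg_record` for activity counts.
#' @return Tibble with `record_id`, `epoch`, `re_class`, `analysable` and
#'   feature columns; reference AHI (when known) in attribute
#'   `"true_ahi"`.
#' @export
prepare_recording <- function(recording, families = c("hrv_time", "hrv_freq"),
                              ecg = NULL) {
  ib <- tibble(
    onset_s = recording$ibis$onset_s, ibi_s = recording$ibis$ibi_s,
    valid = TRUE, reason = "ok"
  )
  ib <- reject_invalid_ibis(ib)
  events <- harmonise_hypopneas(recording$events, quiet = TRUE)
  labels <- label_re_epochs(events, recording$n_epochs)
  labels <- apply_sleep_mask(labels, recording$stages)
  feats <- extract_feature_matrix(ib, recording$n_epochs,
    families = families,
    ecg = ecg, record_id = recording$record_id
  )
  out <- dplyr::bind_cols(
    labels[, c("epoch", "re_class", "analysable")],
    feats[, setdiff(names(feats), c("epoch"))]
  )
  out <- dplyr::relocate(out, "record_id")
  attr(out, "true_ahi") <- recording$true_ahi %||% NA_real_
  attr(out, "spec") <- attr(feats, "spec")
  out
}

impute_standardise <- function(features, cols, centers = NULL, scales = NULL,
                               fallback_medians = NULL) {
  x <- as.matrix(features[, cols])
  # per-recording median imputation
  for (rid in unique(features$record_id)) {
    rows <- features$record_id == rid
    for (j in seq_along(cols)) {
      v <- x[rows, j]
      if (anyNA(v)) {
        med <- median(v, na.rm = TRUE)
        if (is.na(med)) med <- fallback_medians[j] %||% 0
        v[is.na(v)] <- med
        x[rows, j] <- v
      }
    }
  }
  if (is.null(centers)) {
    centers <- colMeans(x)
    scales <- apply(x, 2, pop_sd)
    scales[scales == 0 | is.na(scales)] <- 1
  }
  list(
    x = sweep(sweep(x, 2, centers), 2, scales, "/"),
    centers = centers, scales = scales
  )
}

#' Train the full AHI estimation pipeline
#'
#' Runs the training stack on prepared recordings: per-feature
#' transformation-chain optimisation on all epochs, per-recording median
#' imputation and standardisation, SMOTE + ENN balancing, classifier
#' fitting, Theil-Sen beta calibration and severity-kappa threshold
#' selection (the last two on sleep epochs only).
#'
#' @param prepared List of tibbles from [prepare_recording()].
#' @param reference_ahis Reference AHI per recording (defaults to the
#'   `true_ahi` attributes).
#' @param model_kind One of `logistic_elastic_net` (default),
#'   `huber_linear`, `lda`, `qda`, or `"auto"` to run inner-CV model
#'   selection.
#' @param max_depth Transformation-chain depth cap.
#' @param lambda Elastic-net penalty: a number, or `"cv"` (default) to
#'   choose it from `lambda_grid` by mean precision-recall AUC over
#'   participant-disjoint inner folds (ties towards the stronger
#'   penalty).
#' @param lambda_grid Candidate penalties for `lambda = "cv"`.
#' @param alpha Elastic-net mixing parameter.
#' @param smote_k SMOTE neighbour count.
#' @param seed Seed for every stochastic stage.
#' @return A `cardioahi_estimator`.
#' @export
train_ahi_pipeline <- function(prepared,
                               reference_ahis = map_dbl(prepared, ~ attr(.x, "true_ahi")),
                               model_kind = "logistic_elastic_net",
                               max_depth = 5L,
                               lambda = "cv",
                               lambda_grid = 10^seq(-4, -1, by = 0.5),
                               alpha = 0.5,
                               smote_k = 5L, seed = 1L) {
  pooled <- list_rbind(prepared)
  cols <- setdiff(names(pooled), c("record_id", "epoch", "re_class", "analysable"))
  keep_cols <- cols[vapply(cols, function(cl) {
    v <- pooled[[cl]]
    mean(is.na(v)) < 0.8 && length(unique(v[!is.na(v)])) > 1
  }, TRUE)]

  set.seed(as.integer(seed))
  chains <- optimise_features(pooled, pooled$re_class,
    cols = keep_cols,
    max_depth = max_depth
  )
  pooled <- apply_chain_bundle(pooled, chains)

  fallback <- vapply(keep_cols, function(cl) {
    median(pooled[[cl]], na.rm = TRUE)
  }, 1)
  std <- impute_standardise(pooled, keep_cols, fallback_medians = fallback)

  if (identical(model_kind, "auto")) {
    model_kind <- as.character(
      select_model(std$x, pooled$re_class, pooled$record_id, seed = seed)
    )
  }
  inner <- inner_cv_probs(std$x, pooled$re_class, pooled$record_id, model_kind,
    lambda_grid = if (is.numeric(lambda)) lambda else lambda_grid,
    alpha = alpha, smote_k = smote_k, seed = seed
  )
  if (!is.numeric(lambda)) lambda <- inner$lambda
  bal <- balance_epochs(std$x, pooled$re_class, k = smote_k)
  fit <- fit_candidate(bal$x, bal$labels, model_kind, lambda = lambda, alpha = alpha)

  # calibration on sleep epochs only
  rec_split <- split(seq_len(nrow(pooled)), pooled$record_id)
  rec_ids <- names(rec_split)
  id_by_prepared <- vapply(prepared, function(p) p$record_id[1], "")
  ref <- setNames(reference_ahis, id_by_prepared)[rec_ids]

  beta <- estimate_beta(
    ref,
    map(rec_split, ~ pooled$re_class[.x]),
    map(rec_split, ~ pooled$analysable[.x])
  )

  # threshold selection uses out-of-fold probabilities (in-sample ones are
  # over-sharp); rows never held out fall back to the final fit
  probs <- inner$oof_probs
  if (anyNA(probs)) {
    insample <- predict_candidate(fit, std$x, model_kind)
    probs[is.na(probs)] <- insample[is.na(probs)]
  }
  prob_list <- map(rec_split, ~ probs[.x][pooled$analysable[.x]])
  threshold <- select_probability_threshold(prob_list, ref, beta)

  structure(list(
    model_kind = model_kind,
    fit = fit,
    families = unique(attr(prepared[[1]], "spec")$family),
    feature_names = keep_cols,
    chains = chains,
    centers = std$centers,
    scales = std$scales,
    fallback_medians = fallback,
    probability_threshold = threshold,
    beta = beta,
    lambda = lambda, alpha = alpha, seed = seed
  ), class = "cardioahi_estimator")
}

#' Per-epoch RE probabilities for a prepared recording
#'
#' @param estimator A `cardioahi_estimator`.
#' @param prepared Tibble from [prepare_recording()].
#' @return Numeric vector of probabilities, one per epoch.
#' @export
predict_epoch_probabilities <- function(estimator, prepared) {
  df <- prepared
  for (cl in estimator$feature_names) {
    if (!cl %in% names(df)) df[[cl]] <- NA_real_
  }
  df <- apply_chain_bundle(df, estimator$chains[estimator$feature_names])
  std <- impute_standardise(df, estimator$feature_names,
    centers = estimator$centers, scales = estimator$scales,
    fallback_medians = estimator$fallback_medians
  )
  predict_candidate(estimator$fit, std$x, estimator$model_kind)
}

#' Predict the AHI for a prepared recording
#'
#' @inheritParams predict_epoch_probabilities
#' @return One-row tibble (see [estimate_ahi()]).
#' @export
predict_ahi <- function(estimator, prepared) {
  probs <- predict_epoch_probabilities(estimator, prepared)
  estimate_ahi(probs, estimator, prepared$analysable,
    record_id = prepared$record_id[1]
  )
}

#' @exportS3Method base::print
print.cardioahi_estimator <- function(x, ...) {
  cat(sprintf(
    "<cardioahi_estimator: %s on %d features, threshold %.2f, beta %.1f events/h>\n",
    x$model_kind, length(x$feature_names), x$probability_threshold, x$beta
  ))
  invisible(x)
}

#' Tidy the fitted epoch classifier
#'
#' @param x A `cardioahi_estimator`.
#' @param ... Unused.
#' @return Tibble of model terms: feature, estimate (classifier weight),
#'   and the length and achieved AMSD of the feature's transformation
#'   chain.
#' @export
tidy.cardioahi_estimator <- function(x, ...) {
  w <- switch(x$model_kind,
    logistic_elastic_net = as.numeric(coef(x$fit))[-1],
    huber_linear = as.numeric(x$fit$coefficients),
    rep(NA_real_, length(x$feature_names))
  )
  tibble(
    term = x$feature_names,
    estimate = w,
    chain_length = map_int(x$chains[x$feature_names], ~ length(.x$specs)),
    achieved_amsd = map_dbl(x$chains[x$feature_names], "achieved_amsd")
  )
}

#' One-row summary of a trained estimator
#'
#' @param x A `cardioahi_estimator`.
#' @param ... Unused.
#' @return Tibble: model kind, number of features, probability threshold,
#'   beta.
#' @export
glance.cardioahi_estimator <- function(x, ...) {
  tibble(
    model_kind = x$model_kind,
    n_features = length(x$feature_names),
    probability_threshold = x$probability_threshold,
    beta = x$beta
  )
}
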