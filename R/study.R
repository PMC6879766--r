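# End-to-end synthetic validation study: simulate a population with known
# AHIs, train the full pipeline on one part, predict the held-out part,
# and evaluate agreement, screening and severity estimation.

#' Run the synthetic end-to-end validation study
#'
#' Generates `n_train + n_test` recordings with a uniform severity mix,
#' runs the full training stack (feature extraction, transformation-chain
#' optimisation, SMOTE+ENN balancing, classifier fitting, Theil-Sen beta
#' and kappa-based threshold selection) on the training part, predicts
#' the AHI of every held-out recording, and evaluates the predictions
#' against the generator's ground truth.
#'
#' @param seed Master seed for every stochastic stage.
#' @param n_train,n_test Number of training and held-out recordings.
#' @param duration_h Recording length, hours.
#' @param families Feature families used by the classifier.
#' @param max_depth Transformation-chain depth cap.
#' @param model_kind Classifier (see [train_ahi_pipeline()]).
#' @param ecg_fs Sampling rate used to render ECG when the
#'   `activity_counts` family is requested; `NULL` skips rendering.
#' @param config_template Shared simulation settings.
#' @param verbose Print progress.
#' @return List: `estimator`, `truth`, `predictions` (tibble),
#'   `agreement` ([agreement_report()]), `screening`
#'   ([screening_report()]).
#' @export
synthetic_validation_study <- function(seed = 1L,
                                       n_train = 60L, n_test = 30L,
                                       duration_h = 2,
                                       families = c(
                                         "hrv_time", "hrv_freq",
                                         "activity_counts"
                                       ),
                                       max_depth = 5L,
                                       model_kind = "logistic_elastic_net",
                                       ecg_fs = 128,
                                       config_template = sim_config(duration_h = duration_h),
                                       verbose = FALSE) {
  seed <- as.integer(seed)
  config_template$duration_h <- duration_h
  n <- n_train + n_test
  pop <- generate_population(n, config_template = config_template, seed = seed)
  need_ecg <- "activity_counts" %in% families && !is.null(ecg_fs)
  prepared <- map(seq_along(pop), function(i) {
    if (verbose && i %% 10 == 0) message("prepared ", i, "/", n)
    rec <- pop[[i]]
    ecg <- if (need_ecg) render_ecg(rec, sampling_rate = ecg_fs) else NULL
    prepare_recording(rec, families = families, ecg = ecg)
  })
  train <- prepared[seq_len(n_train)]
  test <- prepared[n_train + seq_len(n_test)]

  estimator <- train_ahi_pipeline(train,
    max_depth = max_depth,
    model_kind = model_kind, seed = seed
  )
  if (verbose) message("trained: threshold ", estimator$probability_threshold)

  predictions <- list_rbind(map(test, ~ predict_ahi(estimator, .x)))
  truth <- map_dbl(test, ~ attr(.x, "true_ahi"))

  list(
    estimator = estimator,
    truth = truth,
    predictions = predictions,
    agreement = agreement_report(truth, predictions$ahi_pred),
    screening = suppressWarnings(screening_report(truth, predictions$ahi_pred))
  )
}
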