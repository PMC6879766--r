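# Performance analysis: AHI agreement, OSA screening and severity
# estimation metrics.

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement from the marginal products. When both raters are constant
#' and identical (`p_e = 1`), kappa is defined as 1.
#'
#' @param labels_a,labels_b Equal-length label vectors over a shared
#'   alphabet.
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' cohens_kappa(c(1, 1, 0, 0), c(1, 0, 0, 0))
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("Label vectors must have equal length.")
  }
  lev <- union(unique(as.character(labels_a)), unique(as.character(labels_b)))
  a <- factor(as.character(labels_a), levels = lev)
  b <- factor(as.character(labels_b), levels = lev)
  n <- length(a)
  tab <- table(a, b)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' AHI agreement report
#'
#' Spearman correlation, Bland-Altman bias and limits of agreement
#' (bias +/- 1.96 times the sample SD of the differences AHI - AHI_pred),
#' per-severity mean estimation error, per-recording flags for
#' considerable over/under-estimation (|difference| > 30 events/h), and
#' the Breusch-Pagan heteroscedasticity p-value of the AHI_pred-on-AHI
#' regression residuals.
#'
#' @param reference_ahis,predicted_ahis Paired AHI vectors, n >= 3.
#' @return An `ahi_agreement` list; see Details for fields.
#' @export
agreement_report <- function(reference_ahis, predicted_ahis) {
  stopifnot(length(reference_ahis) == length(predicted_ahis))
  n <- length(reference_ahis)
  if (n < 3) abort("Agreement analysis needs at least 3 paired recordings.")
  d <- reference_ahis - predicted_ahis
  rho <- if (pop_sd(predicted_ahis) == 0 || pop_sd(reference_ahis) == 0) {
    warn("Spearman correlation undefined: a variable is constant.")
    NA_real_
  } else {
    suppressWarnings(cor(reference_ahis, predicted_ahis, method = "spearman"))
  }
  bias <- mean(d)
  loa_half <- 1.96 * sd(d) # sample SD, conventional for limits of agreement
  flags <- dplyr::case_when(
    d > 30 ~ "considerably_under",
    d < -30 ~ "considerably_over",
    TRUE ~ "ok"
  )
  sev <- ahi_severity(reference_ahis)
  per_sev <- tibble(severity = sev, err = d) |>
    group_by(.data$severity) |>
    summarise(mean_error = mean(.data$err), n = dplyr::n(), .groups = "drop")
  bp_p <- tryCatch(
    lmtest::bptest(lm(predicted_ahis ~ reference_ahis))$p.value,
    error = function(e) NA_real_
  )
  structure(list(
    n = n,
    spearman_rho = unname(rho),
    bland_altman_bias = bias,
    limits_of_agreement = c(lower = bias - loa_half, upper = bias + loa_half),
    per_severity_error = per_sev,
    flags = flags,
    breusch_pagan_p = unname(bp_p),
    differences = d,
    reference = reference_ahis,
    predicted = predicted_ahis
  ), class = "ahi_agreement")
}

#' @exportS3Method base::print
print.ahi_agreement <- function(x, ...) {
  cat(sprintf(
    "<ahi_agreement n=%d: rho %.3f, bias %.2f, LoA [%.2f, %.2f] events/h>\n",
    x$n, x$spearman_rho, x$bland_altman_bias,
    x$limits_of_agreement[1], x$limits_of_agreement[2]
  ))
  invisible(x)
}

binary_metrics <- function(tp, fn, fp, tn) {
  c(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / (tp + fn + fp + tn),
    ppv = tp / (tp + fp)
  )
}

roc_curve <- function(scores, labels) {
  cuts <- c(-Inf, sort(unique(scores)), Inf)
  pts <- map(cuts, function(ct) {
    pos <- scores >= ct
    c(
      cut = ct,
      sens = sum(pos & labels) / sum(labels),
      spec = sum(!pos & !labels) / sum(!labels)
    )
  })
  df <- as_tibble(do.call(rbind, pts))
  df <- df[order(1 - df$spec, df$sens), ]
  # trapezoidal AUC over (FPR, TPR)
  fpr <- 1 - df$spec
  auc <- sum(diff(fpr) * (head(df$sens, -1) + tail(df$sens, -1)) / 2)
  list(curve = df, auc = auc)
}

#' OSA screening report
#'
#' For each canonical severity threshold (AHI of 5, 15 and 30 events/h):
#' the binary screening metrics of `predicted >= t` against
#' `reference >= t`, Cohen's kappa, the ROC over all predicted-AHI cuts
#' with its AUC, and the operating point with the smallest Euclidean
#' distance to perfect sensitivity and specificity. Also returns the
#' 4-class severity confusion matrix.
#'
#' @param reference_ahis,predicted_ahis Paired AHI vectors.
#' @param thresholds Screening thresholds, events/h.
#' @return An `osa_screening` list: `per_threshold` tibble, `roc` curves,
#'   `confusion` (counts) and `confusion_pct` (row percentages).
#' @export
screening_report <- function(reference_ahis, predicted_ahis,
                             thresholds = c(5, 15, 30)) {
  stopifnot(length(reference_ahis) == length(predicted_ahis))
  rows <- list()
  rocs <- list()
  for (t in thresholds) {
    ref_pos <- reference_ahis >= t
    if (all(ref_pos) || !any(ref_pos)) {
      warn(sprintf("Threshold %g events/h: reference is single-class; metrics undefined.", t))
      rows[[as.character(t)]] <- tibble(
        threshold = t, kappa = NA_real_, sensitivity = NA_real_,
        specificity = NA_real_, accuracy = NA_real_, ppv = NA_real_,
        roc_auc = NA_real_, optimal_cut = NA_real_
      )
      next
    }
    pred_pos <- predicted_ahis >= t
    m <- binary_metrics(
      sum(pred_pos & ref_pos), sum(!pred_pos & ref_pos),
      sum(pred_pos & !ref_pos), sum(!pred_pos & !ref_pos)
    )
    roc <- roc_curve(predicted_ahis, ref_pos)
    dist <- sqrt((1 - roc$curve$sens)^2 + (1 - roc$curve$spec)^2)
    opt <- roc$curve$cut[which.min(dist)]
    rocs[[as.character(t)]] <- roc
    rows[[as.character(t)]] <- tibble(
      threshold = t,
      kappa = cohens_kappa(pred_pos, ref_pos),
      sensitivity = unname(m["sensitivity"]), specificity = unname(m["specificity"]),
      accuracy = unname(m["accuracy"]), ppv = unname(m["ppv"]),
      roc_auc = roc$auc, optimal_cut = opt
    )
  }
  ref_sev <- ahi_severity(reference_ahis)
  pred_sev <- ahi_severity(predicted_ahis)
  conf <- table(reference = ref_sev, predicted = pred_sev)
  conf_pct <- prop.table(conf, margin = 1) * 100
  structure(list(
    per_threshold = list_rbind(rows),
    roc = rocs,
    confusion = conf,
    confusion_pct = conf_pct,
    severity_accuracy = sum(diag(conf)) / sum(conf),
    severity_kappa = cohens_kappa(pred_sev, ref_sev)
  ), class = "osa_screening")
}

#' @exportS3Method base::print
print.osa_screening <- function(x, ...) {
  cat("<osa_screening>\n")
  print(x$per_threshold)
  cat(sprintf("severity accuracy %.1f%%\n", 100 * x$severity_accuracy))
  invisible(x)
}

#' Compare two correlation coefficients (Fisher z)
#'
#' Two-sided test of equal correlations from independent samples using
#' the arctanh transform with standard error
#' `sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param rho1,rho2 Correlation coefficients, |rho| < 1.
#' @param n1,n2 Sample sizes, >= 4.
#' @return Two-sided p-value.
#' @export
#' @examples
#' compare_correlations(0.7, 100, 0.7, 100)
compare_correlations <- function(rho1, n1, rho2, n2) {
  check_number(n1, "n1", lower = 4)
  check_number(n2, "n2", lower = 4)
  if (abs(rho1) >= 1 || abs(rho2) >= 1) {
    warn("A correlation has magnitude 1; the z statistic is infinite, p = 0.")
    return(0)
  }
  z <- (atanh(rho1) - atanh(rho2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * pnorm(-abs(z))
}

# ---- plots -----------------------------------------------------------------

#' Bland-Altman plot of an agreement report
#'
#' @param x An `ahi_agreement` from [agreement_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ahi_agreement <- function(x, ...) {
  df <- tibble(
    mean_ahi = (x$reference + x$predicted) / 2,
    diff = x$differences,
    flag = x$flags
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_ahi, .data$diff, colour = .data$flag)) +
    ggplot2::geom_hline(yintercept = x$bland_altman_bias, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = x$limits_of_agreement, linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      ok = "grey30", considerably_under = "blue", considerably_over = "red"
    )) +
    ggplot2::labs(
      x = "Mean of reference and predicted AHI (events/h)",
      y = "Reference - predicted AHI (events/h)",
      colour = NULL,
      title = sprintf(
        "Bland-Altman: bias %.2f, LoA [%.1f, %.1f] events/h",
        x$bland_altman_bias, x$limits_of_agreement[1], x$limits_of_agreement[2]
      )
    ) +
    ggplot2::theme_minimal()
}

#' ROC curves of a screening report
#'
#' @param x An `osa_screening` from [screening_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.osa_screening <- function(x, ...) {
  df <- list_rbind(imap(x$roc, function(r, t) {
    mutate(r$curve, threshold = sprintf("AHI >= %s (AUC %.2f)", t, r$auc))
  }))
  ggplot2::ggplot(df, ggplot2::aes(1 - .data$spec, .data$sens, colour = .data$threshold)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity", colour = NULL,
      title = "OSA screening ROC by severity threshold"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
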