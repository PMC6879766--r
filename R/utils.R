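# Shared small helpers: epoch grid arithmetic and input checks.

#' Epoch grid constants
#'
#' Epochs are the standard 30-second scoring grid, half-open intervals
#' `[30k, 30k + 30)` with `k = 0, 1, ...` counted from the start of the
#' recording.
#' @name epoch-grid
#' @keywords internal
NULL

EPOCH_LEN <- 30

epoch_starts <- function(n_epochs) (seq_len(n_epochs) - 1) * EPOCH_LEN

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

check_df_cols <- function(df, cols, name) {
  if (!is.data.frame(df)) abort(sprintf("`%s` must be a data frame.", name))
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    abort(sprintf(
      "`%s` is missing column(s): %s.", name,
      paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(df)
}

# Population (n-denominator) standard deviation.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Overlap length of [a1, a2) with [b1, b2).
interval_overlap <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}

#' OSA severity from an AHI value
#'
#' Maps events/h to the canonical severity classes with inclusive lower
#' edges: normal `[0, 5)`, mild `[5, 15)`, moderate `[15, 30)`, severe
#' `>= 30`.
#'
#' @param ahi Numeric vector of AHI values (events/h).
#' @return Factor with levels `normal`, `mild`, `moderate`, `severe`.
#' @export
#' @examples
#' ahi_severity(c(2, 5, 20, 30))
ahi_severity <- function(ahi) {
  if (any(ahi < 0, na.rm = TRUE)) abort("AHI values must be non-negative.")
  cut(ahi,
    breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
    labels = c("normal", "mild", "moderate", "severe")
  )
}

severity_levels <- c("normal", "mild", "moderate", "severe")
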