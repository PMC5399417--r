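#' Confusion counts
#'
#' @param TP,FP,TN,FN non-negative integer counts.
#' @return a `pd_confusion` object.
#' @export
pd_confusion <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(is.na(counts)) || any(counts < 0))
    stop("confusion counts must be non-negative")
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "pd_confusion")
}

#' @export
print.pd_confusion <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(actual = c("pos", "neg"),
                              predicted = c("pos", "neg")))
  print(m)
  invisible(x)
}

#' Performance metrics for imbalanced prediction
#'
#' Computes precision, sensitivity, specificity, F1-score and G-mean from a
#' confusion table. Accuracy is uninformative at low prevalence (predicting
#' everyone negative scores `1 - prevalence`), so the F1-score (harmonic
#' mean of precision and sensitivity, defined 0 when `TP = 0`) and the
#' G-mean (geometric mean of sensitivity and specificity) are the summary
#' criteria. All zero-denominator cases return 0 so the metrics are total
#' functions and cross-validation never drops folds.
#'
#' @param counts a [pd_confusion()] (or anything with `TP`,`FP`,`TN`,`FN`).
#' @return a named list of class `pd_metrics` with fields `precision`,
#'   `sensitivity`, `specificity`, `f1`, `g_mean`.
#' @export
#' @examples
#' pd_metrics(pd_confusion(TP = 2, FP = 1, TN = 3, FN = 0))
pd_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  if (any(c(TP, FP, TN, FN) < 0)) stop("confusion counts must be non-negative")
  pre  <- if (TP + FP > 0) TP / (TP + FP) else 0
  sen  <- if (TP + FN > 0) TP / (TP + FN) else 0
  spec <- if (TN + FP > 0) TN / (TN + FP) else 0
  f1   <- if (TP == 0) 0 else 2 * pre * sen / (pre + sen)
  structure(list(precision = pre, sensitivity = sen, specificity = spec,
                 f1 = f1, g_mean = sqrt(sen * spec)),
            class = "pd_metrics")
}

#' @export
print.pd_metrics <- function(x, digits = 3, ...) {
  v <- unlist(x)
  print(round(v, digits))
  invisible(x)
}

#' F1-score from precision and sensitivity
#'
#' Harmonic mean `2 * pre * sen / (pre + sen)`, returning 0 when both rates
#' are 0. Used e.g. for the theoretical F1 of the fair-coin baseline,
#' `f1_from_rates(prevalence, 0.5)`.
#'
#' @param pre,sen rates in `[0, 1]`.
#' @return the F1-score.
#' @export
#' @examples
#' f1_from_rates(0.149, 0.5)  # ~0.23, the random baseline at 14.9% prevalence
f1_from_rates <- function(pre, sen) {
  stopifnot(all(pre >= 0 & pre <= 1), all(sen >= 0 & sen <= 1))
  out <- ifelse(pre + sen == 0, 0, 2 * pre * sen / (pre + sen))
  out
}

#' G-mean from sensitivity and specificity
#'
#' @param sen,spec rates in `[0, 1]`.
#' @return `sqrt(sen * spec)`.
#' @export
g_mean <- function(sen, spec) sqrt(sen * spec)
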