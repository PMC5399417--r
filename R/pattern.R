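#' Construct a pattern
#'
#' A pattern is the model at the heart of this package: a subset of
#' attributes `P`, one category per attribute `S`, and a matching-ratio
#' threshold `r` in (0, 1]. A record matches the pattern when at least
#' `r * w` of its `w` pattern cells equal the pattern's values. Missing cells
#' never equal anything (including another missing), so noise and
#' missingness are tolerated as mismatches rather than breaking prediction.
#'
#' @param attrs character vector of distinct attribute names (length `w`).
#' @param values character vector of the corresponding categories.
#' @param r matching-ratio threshold in (0, 1]. Trained patterns always use
#'   a grid value `k/w`; hand-authored patterns may use any fraction.
#' @return an object of class `pd_pattern`.
#' @export
#' @examples
#' pd_pattern(c("PCI History", "Hemoglobin", "CRP"),
#'            c("Yes", "Abnormal", "Abnormal"), r = 2/3)
pd_pattern <- function(attrs, values, r) {
  attrs <- as.character(attrs); values <- as.character(values)
  if (length(attrs) < 1L) stop("pattern needs at least one attribute")
  if (length(attrs) != length(values))
    stop("attrs and values must have equal length")
  if (anyDuplicated(attrs)) stop("pattern attributes must be distinct")
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0 || r > 1)
    stop("r must be a single number in (0, 1]")
  structure(list(attrs = attrs, values = values, r = as.numeric(r)),
            class = "pd_pattern")
}

pattern_width <- function(pattern) length(pattern$attrs)

#' Match a pattern against records
#'
#' Counts, per record, how many pattern attribute-values are equal
#' (missing cells count as mismatches) and declares a match when
#' `matched / w >= r`. For a rational threshold `k/w` this is exactly
#' `matched >= k`.
#'
#' @param pattern a [pd_pattern()].
#' @param data a data frame containing every pattern attribute.
#' @return a list with logical vector `match` and integer vector
#'   `matched_count`.
#' @export
match_pattern <- function(pattern, data) {
  stopifnot(inherits(pattern, "pd_pattern"))
  absent <- setdiff(pattern$attrs, names(data))
  if (length(absent))
    stop("pattern attribute(s) absent from data: ",
         paste(absent, collapse = ", "))
  w <- pattern_width(pattern)
  n <- nrow(data)
  counts <- integer(n)
  for (k in seq_len(w)) {
    cell <- as.character(data[[pattern$attrs[k]]])
    hit <- !is.na(cell) & cell == pattern$values[k]
    counts <- counts + as.integer(hit)
  }
  # same floating division on both sides keeps k/w thresholds exact
  list(match = counts / w >= pattern$r, matched_count = counts)
}

#' Confusion counts of a pattern on a labelled dataset
#'
#' Predicts positive exactly where the pattern matches and tallies the
#' 2x2 confusion table against the target labels.
#'
#' @param pattern a [pd_pattern()].
#' @param data a labelled data frame (no missing target cells).
#' @param target a [pd_target()].
#' @return a `pd_confusion` object (fields `TP`, `FP`, `TN`, `FN`).
#' @export
evaluate_pattern <- function(pattern, data, target) {
  if (nrow(data) == 0L) stop("empty dataset")
  pos <- target_indicator(data, target)
  pred <- match_pattern(pattern, data)$match
  pd_confusion(TP = sum(pred & pos),  FP = sum(pred & !pos),
               TN = sum(!pred & !pos), FN = sum(!pred & pos))
}

#' @export
format.pd_pattern <- function(x, ...) {
  w <- pattern_width(x)
  k <- round(x$r * w)
  rtxt <- if (isTRUE(all.equal(k / w, x$r)))
    sprintf("%d/%d (%.0f%%)", k, w, 100 * x$r)
  else sprintf("%.3f (%.0f%%)", x$r, 100 * x$r)
  paste0(paste(x$attrs, "=", x$values, collapse = ", "), "; r = ", rtxt)
}

#' @export
print.pd_pattern <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Pattern serialization helpers
#'
#' `pattern_to_list()` / `pattern_from_list()` round-trip a pattern through
#' a plain list suitable for YAML/JSON storage.
#'
#' @param pattern a `pd_pattern`; `x` a list with `attrs`, `values`, `r`.
#' @return a list, or a `pd_pattern`.
#' @export
pattern_to_list <- function(pattern) {
  list(attrs = pattern$attrs, values = pattern$values, r = pattern$r)
}

#' @rdname pattern_to_list
#' @param x a plain list as produced by `pattern_to_list`.
#' @export
pattern_from_list <- function(x) {
  attrs <- unlist(x$attrs)
  r <- x$r
  # snap a threshold that is a grid value k/w up to serialization rounding
  k <- round(r * length(attrs))
  if (k >= 1 && abs(r - k / length(attrs)) < 1e-9) r <- k / length(attrs)
  pd_pattern(attrs, unlist(x$values), r)
}
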