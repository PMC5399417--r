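#' Categorization rules for numeric attributes
#'
#' The pattern model works on categorical attributes, so numeric clinical
#' measurements must first be mapped to categories using clinical guideline
#' cutoffs or domain knowledge. Three rule kinds are supported:
#'
#' * `pd_rule_bins()` -- ordered half-open intervals `[low, high)`, each with
#'   a label; a value on a bin's lower boundary belongs to that bin.
#' * `pd_rule_sign()` -- two labels split at zero, strictly positive values
#'   getting `label_pos` and values `<= 0` getting `label_nonpos` (the
#'   convention used for sign-categorized gene-expression components).
#' * `pd_rule_combine()` -- a predicate over two source columns producing a
#'   yes/no category (e.g. deriving a COPD indicator from two spirometry
#'   measurements).
#'
#' Missing inputs always map to missing outputs; a non-missing numeric value
#' that falls outside every bin is an error, which forces rules to be
#' complete over the observed range.
#'
#' @param source column name(s) the rule reads.
#' @param output name of the categorical column the rule writes.
#' @param breaks numeric vector of n+1 cut points for n bins, increasing.
#' @param labels character vector of n bin labels.
#' @param label_pos,label_nonpos labels for the sign rule.
#' @param predicate for `pd_rule_combine`: a function of two numeric/character
#'   vectors returning logical.
#' @param label_true,label_false labels emitted by the combine predicate.
#' @param drop_source if `TRUE` (default for combine rules, `FALSE`
#'   otherwise) the source column(s) are removed from the output.
#' @return a `pd_rule` object.
#' @name pd_rules
NULL

#' @rdname pd_rules
#' @export
pd_rule_bins <- function(source, output, breaks, labels,
                         drop_source = FALSE) {
  stopifnot(length(breaks) == length(labels) + 1L, !is.unsorted(breaks),
            length(source) == 1L)
  structure(list(kind = "bins", source = source, output = output,
                 breaks = as.numeric(breaks), labels = as.character(labels),
                 drop_source = drop_source),
            class = "pd_rule")
}

#' @rdname pd_rules
#' @export
pd_rule_sign <- function(source, output = source, label_pos = "Abnormal",
                         label_nonpos = "Normal", drop_source = FALSE) {
  structure(list(kind = "sign", source = source, output = output,
                 label_pos = label_pos, label_nonpos = label_nonpos,
                 drop_source = drop_source),
            class = "pd_rule")
}

#' @rdname pd_rules
#' @export
pd_rule_combine <- function(source, output, predicate,
                            label_true = "Yes", label_false = "No",
                            drop_source = TRUE) {
  stopifnot(length(source) == 2L, is.function(predicate))
  structure(list(kind = "combine", source = source, output = output,
                 predicate = predicate, label_true = label_true,
                 label_false = label_false, drop_source = drop_source),
            class = "pd_rule")
}

#' @export
print.pd_rule <- function(x, ...) {
  cat("<pd_rule ", x$kind, "> ", paste(x$source, collapse = ","),
      " -> ", x$output, "\n", sep = "")
  invisible(x)
}

apply_rule <- function(data, rule) {
  miss <- setdiff(rule$source, names(data))
  if (length(miss))
    stop("rule source attribute(s) not in data: ",
         paste(miss, collapse = ", "))
  if (rule$kind == "combine") {
    a <- data[[rule$source[1L]]]; b <- data[[rule$source[2L]]]
    keep <- !(is.na(a) | is.na(b))
    out <- rep(NA_character_, nrow(data))
    out[keep] <- ifelse(rule$predicate(a[keep], b[keep]),
                        rule$label_true, rule$label_false)
    lv <- c(rule$label_true, rule$label_false)
  } else {
    x <- data[[rule$source]]
    if (!is.numeric(x)) x <- suppressWarnings(as.numeric(as.character(x)))
    out <- rep(NA_character_, length(x))
    if (rule$kind == "sign") {
      out[!is.na(x)] <- ifelse(x[!is.na(x)] > 0,
                               rule$label_pos, rule$label_nonpos)
      lv <- unique(c(rule$label_nonpos, rule$label_pos))
    } else {
      # half-open [low, high): findInterval with left-closed bins
      idx <- findInterval(x, rule$breaks, rightmost.closed = FALSE,
                          left.open = FALSE)
      bad <- !is.na(x) & (idx < 1L | idx > length(rule$labels) |
                            x == rule$breaks[length(rule$breaks)])
      if (any(bad))
        stop("values outside all bins for rule '", rule$output, "': ",
             paste(utils::head(unique(x[bad]), 5L), collapse = ", "))
      out[!is.na(x)] <- rule$labels[idx[!is.na(x)]]
      lv <- rule$labels
    }
  }
  factor(out, levels = lv)
}

#' Apply categorization rules to a dataset
#'
#' Applies rules in order; each rule writes (or overwrites) its output
#' column. Columns not named by any rule pass through untouched, and missing
#' cells propagate to missing categories.
#'
#' @param data a data frame.
#' @param rules a single `pd_rule` or a list of them.
#' @return the transformed data frame.
#' @export
#' @examples
#' d <- data.frame(axis1 = c(-0.2, 0, 1.7))
#' categorize(d, pd_rule_sign("axis1", label_pos = "pos",
#'                            label_nonpos = "nonpos"))
categorize <- function(data, rules) {
  if (inherits(rules, "pd_rule")) rules <- list(rules)
  for (rule in rules) {
    newcol <- apply_rule(data, rule)
    if (isTRUE(rule$drop_source)) {
      keep_src <- setdiff(rule$source, rule$output)
      data <- data[, setdiff(names(data), keep_src), drop = FALSE]
    }
    data[[rule$output]] <- newcol
  }
  data
}

#' Read categorization rules from a YAML or JSON file
#'
#' The file holds a top-level `rules:` list applied in order. Each entry has
#' a `kind` (`bins`, `sign` or `combine`), `source`, `output`, and
#' kind-specific fields (`breaks` + `labels`; `label_pos` + `label_nonpos`;
#' or `op` in `> >= < <= == !=` comparing the two sources plus
#' `label_true`/`label_false`).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON rule file.
#' @return a list of `pd_rule` objects.
#' @export
read_pd_rules <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$rules)) stop("rule file has no top-level 'rules' list")
  lapply(cfg$rules, function(r) {
    kind <- match.arg(r$kind, c("bins", "sign", "combine"))
    switch(kind,
      bins = pd_rule_bins(r$source, r$output, unlist(r$breaks),
                          unlist(r$labels),
                          drop_source = isTRUE(r$drop_source)),
      sign = pd_rule_sign(r$source,
                          output = r$output %||% r$source,
                          label_pos = r$label_pos %||% "Abnormal",
                          label_nonpos = r$label_nonpos %||% "Normal",
                          drop_source = isTRUE(r$drop_source)),
      combine = {
        op <- match.arg(r$op, c(">", ">=", "<", "<=", "==", "!="))
        f <- get(op, mode = "function")
        pd_rule_combine(unlist(r$source), r$output, predicate = f,
                        label_true = r$label_true %||% "Yes",
                        label_false = r$label_false %||% "No",
                        drop_source = !isFALSE(r$drop_source))
      })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
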