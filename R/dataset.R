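#' Read a categorical dataset from CSV or ARFF
#'
#' Reads a tabular dataset of categorical (nominal) attributes, mapping a
#' configurable set of missing-value tokens to \code{NA}. Categorical columns
#' become factors; for ARFF input the factor levels are the nominal domains
#' declared in the file header (not merely the observed values). Numeric
#' columns are kept numeric until [categorize()] is applied -- the discovery
#' algorithm refuses raw numeric predictors, which forces an explicit,
#' auditable categorization step.
#'
#' @param path path to the input file.
#' @param format `"csv"` or `"arff"`. Defaults to the file extension.
#' @param missing_tokens character vector of cell values treated as missing.
#'   The defaults cover the common clinical-export conventions: ARFF's `"?"`,
#'   spreadsheet `"N/A"`, and the empty string.
#' @return a `data.frame` whose categorical columns are factors and whose
#'   missing cells are `NA`.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write.csv(data.frame(x = c("a", "?", "b"), y = c("N/A", "u", "v")),
#'           path, row.names = FALSE)
#' read_pd_table(path)
read_pd_table <- function(path, format = c("auto", "csv", "arff"),
                          missing_tokens = c("?", "N/A", "")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "arff") "arff" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "arff") {
    df <- tryCatch(foreign::read.arff(path),
                   error = function(e) stop("malformed ARFF file '", path,
                                            "': ", conditionMessage(e)))
    # restore header-declared nominal domains (read.arff keeps only the
    # observed levels)
    domains <- arff_declared_domains(path)
    for (nm in intersect(names(domains), names(df))) {
      if (is.factor(df[[nm]]))
        df[[nm]] <- factor(as.character(df[[nm]]), levels = domains[[nm]])
    }
    # foreign maps "?" to NA already; apply any extra tokens to factor cols
    extra <- setdiff(missing_tokens, c("?", ""))
    if (length(extra)) {
      for (j in seq_along(df)) {
        if (is.factor(df[[j]])) {
          lv <- levels(df[[j]])
          hit <- lv %in% extra
          if (any(hit)) {
            x <- as.character(df[[j]])
            x[x %in% extra] <- NA
            df[[j]] <- factor(x, levels = lv[!hit])
          }
        }
      }
    }
  } else {
    df <- tryCatch(
      utils::read.csv(path, na.strings = missing_tokens,
                      stringsAsFactors = TRUE, check.names = FALSE),
      error = function(e) stop("malformed CSV file '", path, "': ",
                               conditionMessage(e)))
  }
  if (nrow(df) == 0L) stop("no data rows in ", path)
  if (anyDuplicated(names(df)))
    stop("duplicate attribute names: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  df
}

# nominal domains declared in an ARFF header: name -> character levels
arff_declared_domains <- function(path) {
  lines <- readLines(path, warn = FALSE)
  upto <- grep("^\\s*@data", lines, ignore.case = TRUE)
  if (length(upto)) lines <- lines[seq_len(upto[1L] - 1L)]
  decl <- grep("^\\s*@attribute", lines, ignore.case = TRUE, value = TRUE)
  out <- list()
  for (d in decl) {
    m <- regmatches(d, regexec(
      "^\\s*@attribute\\s+('[^']*'|\"[^\"]*\"|\\S+)\\s+\\{(.*)\\}\\s*$",
      d, ignore.case = TRUE))[[1L]]
    if (length(m) == 3L) {
      nm <- gsub("^['\"]|['\"]$", "", m[2L])
      lv <- trimws(strsplit(m[3L], ",")[[1L]])
      out[[nm]] <- gsub("^['\"]|['\"]$", "", lv)
    }
  }
  out
}

#' Write a categorical dataset to CSV or ARFF
#'
#' Inverse of [read_pd_table()]: `read_pd_table(write_pd_table(df, p), p)`
#' restores the same data frame, including declared factor domains for ARFF.
#'
#' @param data a data frame.
#' @param path output path.
#' @param format `"csv"` or `"arff"` (default from extension).
#' @param missing_token string written for `NA` cells in CSV output.
#' @return `path`, invisibly.
#' @export
write_pd_table <- function(data, path, format = c("auto", "csv", "arff"),
                           missing_token = "?") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "arff") "arff" else "csv"
  }
  if (format == "arff") {
    foreign::write.arff(data, path)
  } else {
    utils::write.csv(data, path, row.names = FALSE, na = missing_token)
  }
  invisible(path)
}

#' Target specification
#'
#' Names the nominal target attribute and which of its categories is the
#' (minority) class of interest. All other target values are pooled as the
#' negative class, so multi-valued targets reduce to binary prediction.
#'
#' @param target_name name of the target column.
#' @param positive_value the category counted as positive.
#' @return an object of class `pd_target`.
#' @export
pd_target <- function(target_name, positive_value) {
  stopifnot(is.character(target_name), length(target_name) == 1L,
            length(positive_value) == 1L)
  structure(list(target_name = target_name,
                 positive_value = as.character(positive_value)),
            class = "pd_target")
}

#' @export
print.pd_target <- function(x, ...) {
  cat("Target: ", x$target_name, " = ", x$positive_value, "\n", sep = "")
  invisible(x)
}

# Logical positive indicator for a dataset; errors on missing target cells.
target_indicator <- function(data, target) {
  stopifnot(inherits(target, "pd_target"))
  if (!target$target_name %in% names(data))
    stop("target attribute '", target$target_name, "' not in data")
  y <- data[[target$target_name]]
  if (anyNA(y)) stop("missing values in target attribute '",
                     target$target_name, "'")
  as.character(y) == target$positive_value
}

#' Prevalence and positive/negative ratio of a target
#'
#' The prevalence is `#(T = t) / n`; the class ratio is
#' `#(T = t) / #(T != t)` (reported as `NA` with a flag when there are no
#' negatives). Targets of clinical interest are typically well below 50%
#' prevalence, which is what makes their prediction hard.
#'
#' @param data a data frame with no missing target cells.
#' @param target a [pd_target()].
#' @return a list with `prevalence`, `ratio`, `n_positive`, `n_negative`,
#'   and `ratio_defined`.
#' @export
#' @examples
#' d <- data.frame(T = c("Yes", "Yes", "No", "No", "No", "No"))
#' pd_prevalence(d, pd_target("T", "Yes"))  # prevalence 1/3, ratio 0.5
pd_prevalence <- function(data, target) {
  if (nrow(data) < 1L) stop("empty dataset")
  pos <- target_indicator(data, target)
  np <- sum(pos); nn <- sum(!pos)
  list(prevalence = np / length(pos),
       ratio = if (nn > 0L) np / nn else NA_real_,
       n_positive = np, n_negative = nn,
       ratio_defined = nn > 0L)
}
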