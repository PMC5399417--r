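#' Discovery configuration
#'
#' Controls the training pipeline. Pattern width is driven either by a fixed
#' top-`width` selection or by a chi-squared p-value cutoff (default 0.05);
#' exactly one of the two applies (`width`, when given, wins).
#'
#' @param width maximal pattern width `W`: keep the `W` most significant
#'   attributes. `NULL` (default) selects all attributes with
#'   `p <= p_cutoff` instead.
#' @param p_cutoff chi-squared significance cutoff, default 0.05.
#' @param imbalance_trigger_ratio fit the log-likelihood fallback when the
#'   training positive/negative ratio is below this value. The default 2 is
#'   the smallest integer above the balanced-data boundary of 1, so the
#'   fallback is active for every imbalanced (and mildly positive-heavy)
#'   training set.
#' @param smoothing additive (Laplace) pseudo-count for the conditional
#'   probability tables, default 1.
#' @param value_heuristic how the per-attribute category is chosen from the
#'   class-conditional percentage table: `"dominant-positive"` (default)
#'   takes the category with the highest positive-class percentage among
#'   those where positives dominate negatives; `"max-difference"` takes the
#'   category maximising the positive-minus-negative percentage difference.
#' @param r_tie_break when several grid thresholds achieve the best training
#'   G-mean, keep the `"largest"` (default; strictest pattern, favouring
#'   specificity on unseen data) or `"smallest"` r.
#' @param include_priors include class log-priors in the log-likelihood
#'   comparison (Naive-Bayes-style posterior scoring, the default); `FALSE`
#'   compares pure likelihoods.
#' @return an object of class `pd_config`.
#' @export
pd_config <- function(width = NULL, p_cutoff = 0.05,
                      imbalance_trigger_ratio = 2, smoothing = 1,
                      value_heuristic = c("dominant-positive",
                                          "max-difference"),
                      r_tie_break = c("largest", "smallest"),
                      include_priors = TRUE) {
  if (!is.null(width)) {
    stopifnot(length(width) == 1L, width >= 1, width == round(width))
  }
  stopifnot(p_cutoff > 0, p_cutoff <= 1, imbalance_trigger_ratio > 0,
            smoothing >= 0)
  structure(list(width = width, p_cutoff = p_cutoff,
                 imbalance_trigger_ratio = imbalance_trigger_ratio,
                 smoothing = smoothing,
                 value_heuristic = match.arg(value_heuristic),
                 r_tie_break = match.arg(r_tie_break),
                 include_priors = include_priors),
            class = "pd_config")
}

# predictor columns must be categorical before discovery runs
assert_categorical <- function(data, attrs) {
  num <- attrs[vapply(data[attrs], is.numeric, logical(1L))]
  if (length(num))
    stop("numeric predictor(s) must be categorized first (see categorize()): ",
         paste(num, collapse = ", "))
}

#' Rank attributes by chi-squared association with the target
#'
#' Runs a Pearson chi-squared test of independence (no continuity
#' correction) on each attribute's contingency table against the binarised
#' target (positive vs pooled negatives), using non-missing cells only.
#' Attributes are ranked by ascending p-value, ties broken by descending
#' statistic then by original column order, and the ranking is truncated to
#' the top `config$width` attributes or filtered at `config$p_cutoff`.
#'
#' Attributes with a single observed category carry no information: they are
#' assigned statistic 0 and p-value 1 (ranked last), not an error.
#' Attributes whose cells are all missing are dropped with a warning.
#' `expected_ok` records whether all expected counts reached 5 (the usual
#' validity guideline for the chi-squared approximation; small clinical
#' tables routinely fall below it).
#'
#' @param data a data frame of categorical predictors plus the target.
#' @param target a [pd_target()].
#' @param config a [pd_config()].
#' @param attrs attributes to test; defaults to every non-target column.
#' @return a data.frame with columns `attribute`, `statistic`, `df`,
#'   `p_value`, `expected_ok`, ranked and truncated; the untruncated ranking
#'   is attached as attribute `"full_ranking"`.
#' @export
chi_squared_select <- function(data, target, config = pd_config(),
                               attrs = NULL) {
  pos <- target_indicator(data, target)
  if (length(unique(pos)) < 2L)
    stop("both target classes must be present")
  if (is.null(attrs)) attrs <- setdiff(names(data), target$target_name)
  assert_categorical(data, attrs)
  rows <- lapply(seq_along(attrs), function(i) {
    a <- attrs[i]
    x <- as.character(data[[a]])
    keep <- !is.na(x)
    if (!any(keep)) return(NULL)
    tab <- table(factor(pos[keep], levels = c(TRUE, FALSE)), x[keep])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2L || any(rowSums(tab) == 0)) {
      data.frame(attribute = a, statistic = 0, df = 0L, p_value = 1,
                 expected_ok = TRUE, order = i)
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(attribute = a, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = unname(ct$p.value),
                 expected_ok = all(ct$expected >= 5), order = i)
    }
  })
  dropped <- attrs[vapply(rows, is.null, logical(1L))]
  if (length(dropped))
    warning("attribute(s) with all cells missing excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0L) stop("no testable attributes")
  res <- res[order(res$p_value, -res$statistic, res$order), , drop = FALSE]
  res$order <- NULL
  rownames(res) <- NULL
  full <- res
  if (!is.null(config$width)) {
    res <- utils::head(res, config$width)
  } else {
    res <- res[res$p_value <= config$p_cutoff, , drop = FALSE]
  }
  attr(res, "full_ranking") <- full
  res
}

#' Choose the pattern value for one attribute
#'
#' Builds the two-row table of category counts for the positive and negative
#' class (non-missing cells only), converts each row to percentages, and
#' compares them column by column. Under the default `"dominant-positive"`
#' heuristic the chosen category is the one with the largest positive-class
#' percentage among categories where the positive percentage is at least the
#' negative percentage (falling back to the overall positive-row argmax when
#' no category qualifies). Under `"max-difference"` it is the category with
#' the largest positive-minus-negative percentage gap. Ties go to the
#' earliest category in the attribute's domain order.
#'
#' @param data a data frame.
#' @param target a [pd_target()].
#' @param attribute attribute name.
#' @param mode value heuristic, see [pd_config()].
#' @return the selected category (character scalar), with the percentage
#'   table attached as attribute `"table"`.
#' @export
select_value <- function(data, target, attribute,
                         mode = c("dominant-positive", "max-difference")) {
  mode <- match.arg(mode)
  pos <- target_indicator(data, target)
  x <- data[[attribute]]
  if (is.null(x)) stop("attribute '", attribute, "' not in data")
  domain <- if (is.factor(x)) levels(x) else unique(as.character(x[!is.na(x)]))
  x <- as.character(x)
  if (all(is.na(x[pos])))
    stop("all positive-class cells missing for attribute '", attribute, "'")
  xf <- factor(x, levels = domain)
  cnt_pos <- table(xf[pos]); cnt_neg <- table(xf[!pos])
  pct_pos <- if (sum(cnt_pos) > 0) 100 * cnt_pos / sum(cnt_pos) else cnt_pos * 0
  pct_neg <- if (sum(cnt_neg) > 0) 100 * cnt_neg / sum(cnt_neg) else cnt_neg * 0
  pick <- if (mode == "max-difference") {
    which.max(pct_pos - pct_neg)
  } else {
    ok <- which(pct_pos >= pct_neg & cnt_pos > 0)
    if (length(ok)) ok[which.max(pct_pos[ok])] else which.max(pct_pos)
  }
  out <- domain[pick]
  attr(out, "table") <- rbind(positive = as.numeric(pct_pos),
                              negative = as.numeric(pct_neg))
  colnames(attr(out, "table")) <- domain
  out
}

#' Optimize the matching-ratio threshold
#'
#' Sweeps the full grid `r = 1/w, 2/w, ..., w/w` for a fixed attribute-value
#' candidate, evaluating each threshold on the training data, and returns
#' the grid point with the best training G-mean. Because sensitivity can
#' only fall and specificity only rise as `r` grows, the grid trades the two
#' off directly; ties are broken towards the largest `r` by default.
#'
#' @param attrs,values the candidate pattern's attributes and values.
#' @param data training data.
#' @param target a [pd_target()].
#' @param tie_break `"largest"` or `"smallest"`.
#' @return a list with `r`, `k`, `w`, `g_mean` and the full `grid`
#'   data.frame (one row per threshold with its confusion and G-mean).
#' @export
optimize_threshold <- function(attrs, values, data, target,
                               tie_break = c("largest", "smallest")) {
  tie_break <- match.arg(tie_break)
  w <- length(attrs)
  stopifnot(w >= 1L, length(values) == w)
  counts <- match_pattern(pd_pattern(attrs, values, 1), data)$matched_count
  pos <- target_indicator(data, target)
  grid <- do.call(rbind, lapply(seq_len(w), function(k) {
    pred <- counts >= k
    cc <- pd_confusion(sum(pred & pos), sum(pred & !pos),
                       sum(!pred & !pos), sum(!pred & pos))
    m <- pd_metrics(cc)
    data.frame(k = k, r = k / w, TP = cc$TP, FP = cc$FP, TN = cc$TN,
               FN = cc$FN, sensitivity = m$sensitivity,
               specificity = m$specificity, g_mean = m$g_mean)
  }))
  best <- max(grid$g_mean)
  ties <- which(grid$g_mean == best)
  k <- if (tie_break == "largest") max(ties) else min(ties)
  list(r = k / w, k = k, w = w, g_mean = best, grid = grid)
}

#' Fit the Naive-Bayes-style log-likelihood table
#'
#' Estimates, for each selected attribute, the class-conditional category
#' probabilities with additive smoothing over the attribute's category
#' domain (missing cells excluded from the counts), plus class priors from
#' the training class frequencies. Used as the fallback scorer that accepts
#' cases the pattern misses when the target is imbalanced.
#'
#' @param data training data (both classes present).
#' @param target a [pd_target()].
#' @param attrs the selected attributes.
#' @param smoothing pseudo-count (default 1).
#' @return a `pd_likelihoods` object: per-attribute log-probability matrices
#'   (rows `positive`/`negative`), per-attribute unseen-category log mass,
#'   and log class priors.
#' @export
fit_likelihoods <- function(data, target, attrs, smoothing = 1) {
  pos <- target_indicator(data, target)
  if (length(unique(pos)) < 2L) stop("both target classes must be present")
  tables <- list()
  for (a in attrs) {
    x <- data[[a]]
    domain <- if (is.factor(x)) levels(x) else
      unique(as.character(x[!is.na(x)]))
    x <- as.character(x)
    d <- length(domain)
    tab <- matrix(NA_real_, 2, d,
                  dimnames = list(c("positive", "negative"), domain))
    unseen <- c(positive = NA_real_, negative = NA_real_)
    for (cls in 1:2) {
      inc <- if (cls == 1) pos else !pos
      cx <- x[inc & !is.na(x)]
      n_cls <- length(cx)
      cnt <- table(factor(cx, levels = domain))
      tab[cls, ] <- log((as.numeric(cnt) + smoothing) /
                          (n_cls + smoothing * d))
      unseen[cls] <- log(smoothing / (n_cls + smoothing * d))
    }
    attr(tab, "unseen") <- unseen
    tables[[a]] <- tab
  }
  structure(list(tables = tables,
                 log_priors = c(positive = log(mean(pos)),
                                negative = log(mean(!pos))),
                 smoothing = smoothing),
            class = "pd_likelihoods")
}

# per-record class scores: log prior (optional) + sum of conditional
# log-probabilities over non-missing selected attributes
likelihood_scores <- function(lik, data, include_priors = TRUE) {
  n <- nrow(data)
  s_pos <- s_neg <- if (include_priors)
    c(rep(lik$log_priors["positive"], n)) else numeric(n)
  if (include_priors) s_neg <- rep(lik$log_priors["negative"], n)
  for (a in names(lik$tables)) {
    tab <- lik$tables[[a]]
    x <- as.character(data[[a]])
    idx <- match(x, colnames(tab))
    seen <- !is.na(x)
    known <- seen & !is.na(idx)
    unseen <- attr(tab, "unseen")
    s_pos[known] <- s_pos[known] + tab["positive", idx[known]]
    s_neg[known] <- s_neg[known] + tab["negative", idx[known]]
    s_pos[seen & !known] <- s_pos[seen & !known] + unseen["positive"]
    s_neg[seen & !known] <- s_neg[seen & !known] + unseen["negative"]
  }
  cbind(positive = s_pos, negative = s_neg)
}

#' Train the pattern discovery classifier
#'
#' Fits the full pipeline on a labelled categorical dataset: chi-squared
#' attribute ranking, per-attribute value selection by the class-conditional
#' percentage heuristic, exhaustive matching-threshold search maximising the
#' training G-mean, and -- when the training positive/negative ratio is
#' below `config$imbalance_trigger_ratio` -- a smoothed log-likelihood table
#' used as a fallback scorer at prediction time. G-mean optimisation uses
#' training data only.
#'
#' @param formula a formula naming the target on the left, e.g.
#'   `Risk1Yr ~ .` or `Bleeding ~ PCI + CRP`.
#' @param data a data frame of categorical predictors (categorize numeric
#'   columns first with [categorize()]); the target column must have no
#'   missing values.
#' @param positive the target category of interest (the minority class).
#' @param config a [pd_config()].
#' @return an object of class `pattern_discovery` with components `pattern`
#'   (a [pd_pattern()]), `p_values`, `ranking`, `likelihoods` (or `NULL`),
#'   `threshold_grid`, `train_metrics`, `prevalence`, `ratio`, `config`,
#'   `target` and `call`. Supports `print`, `summary`, `coef`, `predict`
#'   and `format`.
#' @export
#' @examples
#' d <- data.frame(
#'   Gender = c("Male", "Female", "Male", NA, "Female", "Male"),
#'   `PCI History` = c("Yes", "No", "No", "Yes", "Yes", "No"),
#'   Hemoglobin = c("Abnormal", "Abnormal", NA, "Normal", NA, "Normal"),
#'   Diabetes = c("No", NA, "No", "No", "No", "No"),
#'   CRP = c("Abnormal", "Abnormal", "Normal", "Normal", "Abnormal",
#'           "Normal"),
#'   Bleeding = c("Yes", "No", "No", "No", "Yes", "No"),
#'   check.names = FALSE)
#' fit <- pattern_discovery(Bleeding ~ ., d, positive = "Yes",
#'                          config = pd_config(width = 3))
#' fit
#' predict(fit, d)
pattern_discovery <- function(formula, data, positive,
                              config = pd_config()) {
  cl <- match.call()
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  if (missing(positive)) stop("'positive' (the target category) is required")
  tname <- all.vars(formula[[2L]])
  if (length(tname) != 1L) stop("formula must have a single target")
  rhs <- gsub("^`|`$", "",
              attr(stats::terms(formula, data = data), "term.labels"))
  if (!length(rhs)) stop("formula must name at least one predictor")
  target <- pd_target(tname, positive)
  data <- data[, c(rhs, tname), drop = FALSE]
  pos <- target_indicator(data, target)
  if (!any(pos)) stop("no records with ", tname, " = ", positive)
  if (all(pos)) stop("no negative records; both classes are required")

  ranking <- chi_squared_select(data, target, config, attrs = rhs)
  if (nrow(ranking) == 0L)
    stop("no attribute passes p-value cutoff ", config$p_cutoff,
         "; consider fixed-width selection via pd_config(width = K)")
  attrs <- ranking$attribute
  values <- vapply(attrs, function(a)
    as.character(select_value(data, target, a, config$value_heuristic)),
    character(1L))
  opt <- optimize_threshold(attrs, values, data, target,
                            tie_break = config$r_tie_break)
  pattern <- pd_pattern(attrs, values, opt$r)

  prev <- pd_prevalence(data, target)
  lik <- if (prev$ratio_defined &&
             prev$ratio < config$imbalance_trigger_ratio)
    fit_likelihoods(data, target, attrs, config$smoothing) else NULL

  structure(list(pattern = pattern,
                 p_values = stats::setNames(ranking$p_value,
                                            ranking$attribute),
                 ranking = ranking,
                 likelihoods = lik,
                 threshold_grid = opt$grid,
                 train_g_mean = opt$g_mean,
                 train_metrics = pd_metrics(
                   pd_confusion(opt$grid$TP[opt$k], opt$grid$FP[opt$k],
                                opt$grid$TN[opt$k], opt$grid$FN[opt$k])),
                 prevalence = prev$prevalence,
                 ratio = prev$ratio,
                 config = config,
                 target = target,
                 n = nrow(data),
                 call = cl),
            class = "pattern_discovery")
}

#' Predict with a trained pattern discovery classifier
#'
#' A record is classified positive when it matches the pattern, or -- if the
#' log-likelihood fallback was fitted -- when its positive-class score
#' strictly exceeds its negative-class score (ties are negative). With no
#' fallback table the classifier is exactly the pattern match.
#'
#' @param object a `pattern_discovery` fit.
#' @param newdata data frame covering the pattern attributes.
#' @param type `"class"` for a factor of `negative`/`positive`, or
#'   `"explain"` for a per-record data.frame with the matched count, the two
#'   log-likelihood scores (when available), and which branch fired.
#' @param ... unused.
#' @return a factor or a data.frame, one entry/row per record.
#' @export
predict.pattern_discovery <- function(object, newdata,
                                      type = c("class", "explain"), ...) {
  type <- match.arg(type)
  m <- match_pattern(object$pattern, newdata)
  by_lik <- rep(FALSE, nrow(newdata))
  scores <- NULL
  if (!is.null(object$likelihoods)) {
    scores <- likelihood_scores(object$likelihoods, newdata,
                                object$config$include_priors)
    by_lik <- scores[, "positive"] > scores[, "negative"]
  }
  positive <- m$match | by_lik
  cls <- factor(ifelse(positive, "positive", "negative"),
                levels = c("negative", "positive"))
  if (type == "class") return(cls)
  out <- data.frame(matched_count = m$matched_count, match = m$match,
                    prediction = cls)
  if (!is.null(scores)) {
    out$loglik_positive <- scores[, "positive"]
    out$loglik_negative <- scores[, "negative"]
    out$by_likelihood <- !m$match & by_lik
  }
  out
}

#' @export
print.pattern_discovery <- function(x, ...) {
  cat("Pattern discovery classifier for", x$target$target_name, "=",
      x$target$positive_value, "\n")
  cat("Pattern: ", format(x$pattern), "\n", sep = "")
  cat(sprintf("Training G-mean %.3f on n = %d (prevalence %.1f%%)\n",
              x$train_g_mean, x$n, 100 * x$prevalence))
  cat("Log-likelihood fallback:",
      if (is.null(x$likelihoods)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
coef.pattern_discovery <- function(object, ...) {
  stats::setNames(object$pattern$values, object$pattern$attrs)
}

# Table-style two-branch report: the pattern/likelihood branch predicting
# positive, and the OTHERWISE branch predicting negative. coverage =
# fraction of records the branch fires on; accuracy = fraction of its
# predictions that are correct.
branch_report <- function(object, data) {
  pred <- predict(object, data) == "positive"
  pos <- target_indicator(data, object$target)
  cov_pos <- mean(pred)
  acc_pos <- if (any(pred)) mean(pos[pred]) else NA_real_
  acc_neg <- if (any(!pred)) mean(!pos[!pred]) else NA_real_
  data.frame(
    branch = c(paste0(format(object$pattern), " -> ",
                      object$target$target_name, " = ",
                      object$target$positive_value),
               paste0("OTHERWISE -> ", object$target$target_name, " != ",
                      object$target$positive_value)),
    coverage = c(cov_pos, 1 - cov_pos),
    accuracy = c(acc_pos, acc_neg))
}

#' @export
summary.pattern_discovery <- function(object, data = NULL, ...) {
  structure(list(fit = object,
                 branches = if (!is.null(data)) branch_report(object, data)),
            class = "summary.pattern_discovery")
}

#' @export
print.summary.pattern_discovery <- function(x, ...) {
  print(x$fit)
  cat("\nSelected attributes (chi-squared ranking):\n")
  print(x$fit$ranking, row.names = FALSE)
  cat("\nThreshold grid (training):\n")
  print(x$fit$threshold_grid, row.names = FALSE)
  tm <- x$fit$train_metrics
  cat(sprintf(paste0("\nTraining metrics: precision %.3f, sensitivity %.3f,",
                     " specificity %.3f, F1 %.3f, G-mean %.3f\n"),
              tm$precision, tm$sensitivity, tm$specificity, tm$f1,
              tm$g_mean))
  if (!is.null(x$branches)) {
    cat("\nRule branches:\n")
    print(x$branches, row.names = FALSE, digits = 2)
  }
  invisible(x)
}

#' Serialize / reload a trained classifier
#'
#' Writes the fitted pattern, chi-squared p-values, configuration and (when
#' present) the smoothed log-likelihood table to a YAML file, and reads it
#' back into a `pattern_discovery` object.
#'
#' @param object a `pattern_discovery` fit.
#' @param path output path (YAML).
#' @return `write_classifier` returns `path` invisibly;
#'   `read_classifier` returns a `pattern_discovery` object.
#' @export
write_classifier <- function(object, path) {
  lik <- object$likelihoods
  yaml::write_yaml(list(
    target = list(name = object$target$target_name,
                  positive = object$target$positive_value),
    pattern = pattern_to_list(object$pattern),
    pattern_line = format(object$pattern),
    p_values = as.list(object$p_values),
    config = unclass(object$config),
    train_g_mean = object$train_g_mean,
    prevalence = object$prevalence,
    likelihoods = if (!is.null(lik)) list(
      log_priors = as.list(lik$log_priors),
      smoothing = lik$smoothing,
      tables = lapply(lik$tables, function(tab) list(
        domain = colnames(tab),
        positive = as.numeric(tab["positive", ]),
        negative = as.numeric(tab["negative", ]),
        unseen = as.list(attr(tab, "unseen")))))
  ), path, precision = 15)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  x <- yaml::read_yaml(path)
  lik <- NULL
  if (!is.null(x$likelihoods)) {
    tables <- lapply(x$likelihoods$tables, function(tt) {
      tab <- rbind(positive = unlist(tt$positive),
                   negative = unlist(tt$negative))
      colnames(tab) <- unlist(tt$domain)
      attr(tab, "unseen") <- unlist(tt$unseen)
      tab
    })
    lik <- structure(list(tables = tables,
                          log_priors = unlist(x$likelihoods$log_priors),
                          smoothing = x$likelihoods$smoothing),
                     class = "pd_likelihoods")
  }
  cfg <- do.call(pd_config, x$config[!vapply(x$config, is.null,
                                             logical(1L))])
  structure(list(pattern = pattern_from_list(x$pattern),
                 p_values = unlist(x$p_values),
                 likelihoods = lik,
                 train_g_mean = x$train_g_mean,
                 prevalence = x$prevalence,
                 config = cfg,
                 target = pd_target(x$target$name, x$target$positive),
                 call = NULL),
            class = "pattern_discovery")
}
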