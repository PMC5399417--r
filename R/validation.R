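# evaluate code under a transient, seed-determined RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Cross-validation plan
#'
#' Describes the repeated stratified cross-validation protocol: `runs`
#' independent repetitions of `k`-fold stratified splitting, with every
#' compared method trained on identical folds within a run, optional
#' minority up-sampling applied to training folds only, and run-level
#' metric values taken as the mean over each run's test folds.
#'
#' @param k number of folds (default 10).
#' @param runs number of repetitions (default 20).
#' @param seed base seed; run `i` uses `seed + i - 1`.
#' @param ratios up-sampling positive/negative ratios; `"original"` (no
#'   up-sampling) and/or positive numbers.
#' @return a `pd_cv_plan` object.
#' @export
cv_plan <- function(k = 10, runs = 20, seed = 1, ratios = "original") {
  stopifnot(k >= 2, runs >= 1)
  structure(list(k = as.integer(k), runs = as.integer(runs),
                 seed = as.integer(seed), ratios = ratios),
            class = "pd_cv_plan")
}

#' Stratified k-fold assignment
#'
#' Partitions record indices into `k` disjoint folds preserving class
#' balance: per-fold counts of each class differ by at most one. Shuffling
#' is driven solely by `seed`, so the same seed always yields the same
#' folds. A class with fewer than `k` members is spread over distinct folds.
#'
#' @param data a labelled data frame.
#' @param target a [pd_target()].
#' @param k number of folds, `2 <= k <= nrow(data)`.
#' @param seed integer seed (or `NULL` to use the current RNG state).
#' @return a list of `k` integer index vectors partitioning `1:nrow(data)`.
#' @export
stratified_folds <- function(data, target, k, seed = NULL) {
  pos <- target_indicator(data, target)
  n <- length(pos)
  if (k < 2 || k > n) stop("k must be between 2 and the number of records")
  with_seed(seed, {
    fold_of <- integer(n)
    tot <- integer(k)
    for (cls in list(which(pos), which(!pos))) {
      nc <- length(cls)
      if (nc == 0L) next
      # base size per fold; remainders go to the currently smallest folds
      # (random among ties) so overall fold sizes also stay balanced
      sizes <- rep(nc %/% k, k)
      extra <- nc %% k
      if (extra > 0L) {
        pref <- sample.int(k)
        bump <- pref[order(tot[pref])][seq_len(extra)]
        sizes[bump] <- sizes[bump] + 1L
      }
      fold_of[cls[sample.int(nc)]] <- rep(seq_len(k), times = sizes)
      tot <- tot + sizes
    }
    lapply(seq_len(k), function(i) which(fold_of == i))
  })
}

#' Up-sample minority positives in a training set
#'
#' Appends seeded uniform-with-replacement duplicates of existing positive
#' records until the positive/negative count ratio reaches the smallest
#' achievable value at or above `ratio`. Negatives and all original records
#' are untouched and no synthetic values are generated, so every appended
#' record is value-identical to an original positive. Intended for training
#' folds only; test data is never up-sampled.
#'
#' @param data training data frame.
#' @param target a [pd_target()].
#' @param ratio desired positive/negative ratio (`"original"` returns the
#'   data unchanged); must be at least the current ratio.
#' @param seed integer seed (or `NULL`).
#' @return the up-sampled data frame.
#' @export
upsample_training <- function(data, target, ratio, seed = NULL) {
  if (identical(ratio, "original")) return(data)
  pos <- target_indicator(data, target)
  np <- sum(pos); nn <- sum(!pos)
  if (nn == 0L) stop("no negative records; ratio undefined")
  current <- np / nn
  if (ratio < current)
    stop(sprintf("ratio %.3f below current %.3f: down-sampling unsupported",
                 ratio, current))
  need <- ceiling(ratio * nn) - np
  if (need <= 0L) return(data)
  with_seed(seed, {
    idx <- which(pos)
    extra <- idx[sample.int(length(idx), need, replace = TRUE)]
    out <- rbind(data, data[extra, , drop = FALSE])
    rownames(out) <- NULL
    out
  })
}

#' Comparator protocol
#'
#' A comparator is a named pair of functions: `fit(data, target)` returning
#' any model object, and `predict(model, newdata)` returning a logical
#' vector (`TRUE` = positive). All comparators in an experiment are trained
#' on identical folds. Built-ins cover pattern discovery and the fair-coin
#' random baseline; `comparator_logistic()`, `comparator_naive_bayes()` and
#' `comparator_decision_tree()` plug in the host ecosystem's standard
#' implementations (stats::glm, e1071, rpart) at default parameters.
#'
#' @param name display name.
#' @param fit function `(data, target) -> model`.
#' @param predict function `(model, newdata) -> logical`.
#' @return a `pd_comparator` object.
#' @export
pd_comparator <- function(name, fit, predict) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict),
            class = "pd_comparator")
}

#' @rdname pd_comparator
#' @param config a [pd_config()] for the pattern discovery comparator.
#' @export
comparator_pattern_discovery <- function(config = pd_config()) {
  pd_comparator(
    "pattern_discovery",
    fit = function(data, target) {
      f <- stats::reformulate(".", response = as.name(target$target_name))
      pattern_discovery(f, data, positive = target$positive_value,
                        config = config)
    },
    predict = function(model, newdata)
      predict(model, newdata) == "positive")
}

#' Fair-coin random baseline
#'
#' Predicts positive with probability exactly 1/2 for every record,
#' regardless of its values; fitting is a no-op. Serves as the
#' non-informative reference: its theoretical sensitivity and specificity
#' are both 0.5 and its theoretical precision equals the prevalence, giving
#' theoretical F1 `f1_from_rates(prevalence, 0.5)`.
#'
#' @return a `pd_comparator`.
#' @export
comparator_random_baseline <- function() {
  pd_comparator(
    "random_baseline",
    fit = function(data, target) list(),
    predict = function(model, newdata) stats::runif(nrow(newdata)) < 0.5)
}

#' @rdname pd_comparator
#' @export
comparator_logistic <- function() {
  pd_comparator(
    "logistic_regression",
    fit = function(data, target) {
      df <- data[, setdiff(names(data), target$target_name), drop = FALSE]
      df$.y <- factor(target_indicator(data, target),
                      levels = c(FALSE, TRUE))
      list(model = suppressWarnings(
        stats::glm(.y ~ ., data = df, family = stats::binomial,
                   na.action = stats::na.omit)),
        predictors = setdiff(names(data), target$target_name))
    },
    predict = function(model, newdata) {
      df <- newdata[, model$predictors, drop = FALSE]
      out <- rep(FALSE, nrow(df))
      ok <- stats::complete.cases(df)
      if (any(ok)) {
        p <- suppressWarnings(
          stats::predict(model$model, df[ok, , drop = FALSE],
                         type = "response"))
        out[ok] <- !is.na(p) & p > 0.5
      }
      out
    })
}

#' @rdname pd_comparator
#' @export
comparator_naive_bayes <- function() {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("comparator_naive_bayes requires the e1071 package")
  pd_comparator(
    "naive_bayes",
    fit = function(data, target) {
      x <- data[, setdiff(names(data), target$target_name), drop = FALSE]
      y <- factor(target_indicator(data, target), levels = c(FALSE, TRUE))
      list(model = e1071::naiveBayes(x, y),
           predictors = names(x))
    },
    predict = function(model, newdata) {
      p <- stats::predict(model$model,
                          newdata[, model$predictors, drop = FALSE])
      p == "TRUE"
    })
}

#' @rdname pd_comparator
#' @export
comparator_decision_tree <- function() {
  if (!requireNamespace("rpart", quietly = TRUE))
    stop("comparator_decision_tree requires the rpart package")
  pd_comparator(
    "decision_tree",
    fit = function(data, target) {
      df <- data[, setdiff(names(data), target$target_name), drop = FALSE]
      df$.y <- factor(target_indicator(data, target),
                      levels = c(FALSE, TRUE))
      list(model = rpart::rpart(.y ~ ., data = df, method = "class"),
           predictors = setdiff(names(data), target$target_name))
    },
    predict = function(model, newdata) {
      p <- stats::predict(model$model,
                          newdata[, model$predictors, drop = FALSE],
                          type = "class")
      p == "TRUE"
    })
}

#' One-sided paired Wilcoxon signed-rank test
#'
#' Tests whether paired values `a` systematically exceed `b` using the
#' signed-rank statistic with a normal approximation: zero differences are
#' dropped before ranking, ties get average ranks with the standard
#' tie-corrected variance, and by default no continuity correction is
#' applied. With 20 pairs all favouring `a` with distinct differences the
#' p-value is 4.43e-5. An exact-distribution p-value (tie-free data only)
#' is available via `exact = TRUE`.
#'
#' @param a,b equal-length numeric vectors of paired values.
#' @param continuity apply the 0.5 continuity correction (default `FALSE`).
#' @param exact use the exact signed-rank distribution (default `FALSE`).
#' @return the p-value for the alternative `a > b`.
#' @export
wilcoxon_one_sided_greater <- function(a, b, continuity = FALSE,
                                       exact = FALSE) {
  stopifnot(length(a) == length(b), length(a) >= 1L)
  d <- a - b
  if (all(d == 0)) stop("no non-zero differences")
  suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, alternative = "greater",
                       exact = exact, correct = continuity)$p.value)
}

#' Run the repeated cross-validation experiment
#'
#' For each run: seeded stratified folds are generated once and shared by
#' every comparator; for each fold and up-sampling ratio the training
#' portion is up-sampled (test portion untouched), every comparator is
#' fitted and evaluated on the held-out fold, and the run-level value of
#' each metric is the mean over the `k` test folds. The report aggregates
#' mean and standard deviation over runs and, when a comparator named
#' `"pattern_discovery"` is present, one-sided paired Wilcoxon p-values of
#' pattern discovery versus every other comparator, per metric and ratio.
#'
#' @param data a labelled data frame.
#' @param target a [pd_target()].
#' @param comparators a list of [pd_comparator()] objects.
#' @param plan a [cv_plan()].
#' @return a `pd_cv` object: long data.frame `values` (method, ratio, run,
#'   metric, value), `failures`, the plan, and the dataset prevalence.
#' @export
run_experiment <- function(data, target, comparators, plan = cv_plan()) {
  stopifnot(length(comparators) >= 1L)
  if (inherits(comparators, "pd_comparator")) comparators <- list(comparators)
  names(comparators) <- vapply(comparators, `[[`, character(1L), "name")
  metrics_names <- c("precision", "sensitivity", "specificity", "f1",
                     "g_mean")
  values <- list()
  failures <- list()
  prev <- pd_prevalence(data, target)
  for (run in seq_len(plan$runs)) {
    run_seed <- plan$seed + run - 1L
    with_seed(run_seed, {
      folds <- stratified_folds(data, target, plan$k, seed = NULL)
      for (ratio in plan$ratios) {
        rat <- if (identical(ratio, "original")) "original"
               else as.numeric(ratio)
        # per-comparator per-fold metric accumulator
        acc <- array(NA_real_, c(length(comparators), plan$k,
                                 length(metrics_names)),
                     dimnames = list(names(comparators), NULL,
                                     metrics_names))
        for (fi in seq_len(plan$k)) {
          test <- data[folds[[fi]], , drop = FALSE]
          train <- data[-folds[[fi]], , drop = FALSE]
          train_up <- upsample_training(train, target, rat, seed = NULL)
          pos_test <- target_indicator(test, target)
          for (ci in seq_along(comparators)) {
            cmp <- comparators[[ci]]
            res <- tryCatch({
              model <- cmp$fit(train_up, target)
              pred <- cmp$predict(model, test)
              cc <- pd_confusion(sum(pred & pos_test),
                                 sum(pred & !pos_test),
                                 sum(!pred & !pos_test),
                                 sum(!pred & pos_test))
              unlist(pd_metrics(cc))
            }, error = function(e) {
              failures[[length(failures) + 1L]] <<- data.frame(
                method = cmp$name, ratio = as.character(ratio),
                run = run, fold = fi, error = conditionMessage(e))
              rep(NA_real_, length(metrics_names))
            })
            acc[ci, fi, ] <- res
          }
        }
        for (ci in seq_along(comparators)) {
          run_means <- colMeans(acc[ci, , , drop = TRUE])
          values[[length(values) + 1L]] <- data.frame(
            method = names(comparators)[ci], ratio = as.character(ratio),
            run = run, metric = metrics_names,
            value = as.numeric(run_means))
        }
      }
    })
  }
  structure(list(values = do.call(rbind, values),
                 failures = if (length(failures))
                   do.call(rbind, failures) else NULL,
                 plan = plan, prevalence = prev$prevalence,
                 methods = names(comparators)),
            class = "pd_cv")
}

#' @export
summary.pd_cv <- function(object, reference = "pattern_discovery", ...) {
  v <- object$values
  agg <- stats::aggregate(value ~ method + ratio + metric, v,
                          function(x) c(mean = mean(x), sd = stats::sd(x)))
  agg <- cbind(agg[c("method", "ratio", "metric")],
               mean = agg$value[, "mean"], sd = agg$value[, "sd"])
  wil <- NULL
  if (reference %in% v$method && length(unique(v$method)) >= 2L) {
    combos <- expand.grid(method = setdiff(unique(v$method), reference),
                          ratio = unique(v$ratio),
                          metric = unique(v$metric),
                          stringsAsFactors = FALSE)
    pv <- mapply(function(m, rat, met) {
      a <- v$value[v$method == reference & v$ratio == rat & v$metric == met]
      b <- v$value[v$method == m & v$ratio == rat & v$metric == met]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok) || all(a[ok] == b[ok])) return(NA_real_)
      wilcoxon_one_sided_greater(a[ok], b[ok])
    }, combos$method, combos$ratio, combos$metric)
    wil <- cbind(combos, p_value = as.numeric(pv))
  }
  structure(list(summary = agg, wilcoxon = wil, plan = object$plan,
                 failures = object$failures,
                 prevalence = object$prevalence),
            class = "summary.pd_cv")
}

#' @export
print.summary.pd_cv <- function(x, digits = 3, ...) {
  cat(sprintf("Repeated stratified CV: %d runs x %d folds (prevalence %.1f%%)\n",
              x$plan$runs, x$plan$k, 100 * x$prevalence))
  s <- x$summary
  s$mean <- round(s$mean, digits); s$sd <- round(s$sd, digits)
  print(s, row.names = FALSE)
  if (!is.null(x$wilcoxon)) {
    cat("\nOne-sided Wilcoxon p-values (pattern discovery greater):\n")
    w <- x$wilcoxon
    w$p_value <- signif(w$p_value, 3)
    print(w, row.names = FALSE)
  }
  if (!is.null(x$failures))
    cat("\nNOTE:", nrow(x$failures), "fold-level comparator failures\n")
  invisible(x)
}

#' @export
print.pd_cv <- function(x, ...) {
  print(summary(x), ...)
  invisible(x)
}

#' Write a cross-validation report to disk
#'
#' Emits the full run-level table as CSV (`cv_values.csv`), the summary and
#' Wilcoxon tables as CSV (`cv_summary.csv`, `cv_wilcoxon.csv`), and a JSON
#' bundle (`cv_report.json`) containing all three.
#'
#' @param report a `pd_cv` object from [run_experiment()].
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- summary(report)
  utils::write.csv(report$values, file.path(dir, "cv_values.csv"),
                   row.names = FALSE)
  utils::write.csv(s$summary, file.path(dir, "cv_summary.csv"),
                   row.names = FALSE)
  if (!is.null(s$wilcoxon))
    utils::write.csv(s$wilcoxon, file.path(dir, "cv_wilcoxon.csv"),
                     row.names = FALSE)
  jsonlite::write_json(list(values = report$values, summary = s$summary,
                            wilcoxon = s$wilcoxon,
                            plan = unclass(report$plan),
                            prevalence = report$prevalence),
                       file.path(dir, "cv_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
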