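#' Specification for a synthetic imbalanced categorical dataset
#'
#' Describes a seeded generator emulating the data regime of imbalanced
#' clinical repositories: a minority target (prevalence well below 50%), a
#' planted attribute-value pattern enriched in positives, target-independent
#' noise attributes, and sparse per-cell missingness. The defaults describe
#' a mid-sized cohort: 500 records at 10% prevalence, a width-4 planted
#' pattern carried by 90% of positives and 20% of negatives, ten noise
#' attributes with three categories each, and 1% missing cells.
#'
#' @param n number of records.
#' @param prevalence positive fraction, in (0, 0.5); the positive count is
#'   exact (`round(n * prevalence)`), not Bernoulli-sampled, so fold
#'   stratification and the imbalance trigger are deterministic.
#' @param planted_width number of pattern attributes.
#' @param adherence_pos,adherence_neg probability that a positive /
#'   negative record carries each planted value (independently per cell);
#'   recovery requires `adherence_pos > adherence_neg`.
#' @param n_noise_attrs number of target-independent noise attributes.
#' @param categories_per_attr category count per attribute (>= 2).
#' @param missing_rate per-cell missingness probability on predictors
#'   (never the target).
#' @param seed integer seed fully determining the dataset.
#' @return a `pd_synthetic_spec` object.
#' @export
synthetic_spec <- function(n = 500, prevalence = 0.10, planted_width = 4,
                           adherence_pos = 0.9, adherence_neg = 0.2,
                           n_noise_attrs = 10, categories_per_attr = 3,
                           missing_rate = 0.01, seed = 1) {
  stopifnot(n >= 10, prevalence > 0, prevalence < 0.5,
            planted_width >= 1, categories_per_attr >= 2,
            adherence_pos >= 0, adherence_pos <= 1,
            adherence_neg >= 0, adherence_neg <= 1,
            missing_rate >= 0, missing_rate <= 1, n_noise_attrs >= 0)
  structure(list(n = as.integer(n), prevalence = prevalence,
                 planted_width = as.integer(planted_width),
                 adherence_pos = adherence_pos,
                 adherence_neg = adherence_neg,
                 n_noise_attrs = as.integer(n_noise_attrs),
                 categories_per_attr = as.integer(categories_per_attr),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "pd_synthetic_spec")
}

#' Generate a synthetic dataset with a planted pattern
#'
#' Draws a categorical dataset per a [synthetic_spec()]: exactly
#' `round(n * prevalence)` positives; each planted attribute takes its
#' planted value with probability `adherence_pos` in positives and
#' `adherence_neg` in negatives, otherwise a uniformly random other
#' category; noise attributes are uniform and independent of the target;
#' missing cells are injected per predictor cell at `missing_rate`. The same
#' seed always yields the identical dataset.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with `data` (data.frame; target column `"target"` with
#'   values `"case"`/`"control"`), `truth` (the planted [pd_pattern()] at
#'   `r = 1`), `target` (a [pd_target()]), and `spec`.
#' @export
#' @examples
#' sim <- synthetic_dataset(synthetic_spec(n = 100, seed = 7))
#' table(sim$data$target)
synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "pd_synthetic_spec"))
  m <- spec$planted_width + spec$n_noise_attrs
  if (spec$planted_width > m) stop("planted_width exceeds total attributes")
  cats <- paste0("c", seq_len(spec$categories_per_attr))
  planted_attrs <- sprintf("signal%02d", seq_len(spec$planted_width))
  noise_attrs <- if (spec$n_noise_attrs > 0)
    sprintf("noise%02d", seq_len(spec$n_noise_attrs)) else character(0)
  n_pos <- round(spec$n * spec$prevalence)

  with_seed(spec$seed, {
    pos <- c(rep(TRUE, n_pos), rep(FALSE, spec$n - n_pos))
    planted_values <- sample(cats, spec$planted_width, replace = TRUE)
    df <- list()
    for (j in seq_len(spec$planted_width)) {
      v <- planted_values[j]
      other <- setdiff(cats, v)
      adhere <- ifelse(pos, spec$adherence_pos, spec$adherence_neg)
      take <- stats::runif(spec$n) < adhere
      col <- character(spec$n)
      col[take] <- v
      col[!take] <- other[sample.int(length(other), sum(!take),
                                     replace = TRUE)]
      df[[planted_attrs[j]]] <- col
    }
    for (a in noise_attrs)
      df[[a]] <- cats[sample.int(length(cats), spec$n, replace = TRUE)]
    data <- as.data.frame(lapply(df, factor, levels = cats))
    if (spec$missing_rate > 0) {
      for (a in names(data)) {
        hole <- stats::runif(spec$n) < spec$missing_rate
        data[[a]][hole] <- NA
      }
    }
    data$target <- factor(ifelse(pos, "case", "control"),
                          levels = c("control", "case"))
    # deterministic record order shuffle so class blocks are not contiguous
    data <- data[sample.int(spec$n), , drop = FALSE]
    rownames(data) <- NULL
    list(data = data,
         truth = pd_pattern(planted_attrs, planted_values, r = 1),
         target = pd_target("target", "case"),
         spec = spec)
  })
}
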