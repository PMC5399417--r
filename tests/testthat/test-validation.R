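make_imbalanced <- function(n, n_pos, seed = 1) {
  set.seed(seed)
  data.frame(x = sample(c("a", "b", "c"), n, replace = TRUE),
             z = sample(c("u", "v"), n, replace = TRUE),
             y = c(rep("p", n_pos), rep("q", n - n_pos)))
}

test_that("stratified folds balance both classes within one record", {
  d <- make_imbalanced(470, 70)
  tg <- pd_target("y", "p")
  folds <- stratified_folds(d, tg, k = 10, seed = 3)
  expect_equal(sort(unlist(folds)), 1:470)
  sizes <- lengths(folds)
  pos_counts <- vapply(folds, function(f) sum(d$y[f] == "p"), integer(1))
  expect_true(all(sizes == 47))
  expect_true(all(pos_counts == 7))
  # general within-1 property at awkward sizes
  d2 <- make_imbalanced(53, 11, seed = 2)
  f2 <- stratified_folds(d2, tg, k = 5, seed = 9)
  pc <- vapply(f2, function(f) sum(d2$y[f] == "p"), integer(1))
  expect_lte(max(pc) - min(pc), 1)
  expect_lte(max(lengths(f2)) - min(lengths(f2)), 2)  # 1 per class
})

test_that("folds are seed-deterministic and k is validated", {
  d <- make_imbalanced(40, 8)
  tg <- pd_target("y", "p")
  expect_identical(stratified_folds(d, tg, 4, seed = 5),
                   stratified_folds(d, tg, 4, seed = 5))
  expect_error(stratified_folds(d, tg, 41, seed = 1), "between")
  # leave-one-out degenerate case: every fold has one record
  loo <- stratified_folds(d, tg, 40, seed = 1)
  expect_true(all(lengths(loo) == 1))
})

test_that("up-sampling duplicates positives to the requested ratio", {
  d <- make_imbalanced(110, 10)
  tg <- pd_target("y", "p")
  up <- upsample_training(d, tg, 0.5, seed = 4)
  expect_equal(sum(up$y == "p"), 50)
  expect_equal(sum(up$y == "q"), 100)
  # negatives and the original positive multiset are conserved
  expect_identical(up[1:110, ], d)
  # appended rows are value-identical to original positives
  extra <- up[-(1:110), c("x", "z", "y")]
  orig_pos <- d[d$y == "p", c("x", "z", "y")]
  key <- function(df) apply(df, 1, paste, collapse = "\r")
  expect_true(all(key(extra) %in% key(orig_pos)))
  # requesting the current ratio is a no-op; lower is an error
  expect_identical(upsample_training(d, tg, 10 / 100, seed = 1), d)
  expect_error(upsample_training(d, tg, 0.05, seed = 1), "down-sampling")
})

test_that("one-sided Wilcoxon reproduces the normal-approximation closed form", {
  # all-positive distinct differences: z = [n(n+1)/4] / sqrt(n(n+1)(2n+1)/24)
  for (n in 5:30) {
    set.seed(n)
    b <- runif(n)
    a <- b + runif(n, 0.01, 1)
    p <- wilcoxon_one_sided_greater(a, b)
    z <- (n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
    expect_equal(p, 1 - pnorm(z), tolerance = 1e-8,
                 info = paste("n =", n))
  }
  # swapping the arguments complements the p-value
  set.seed(1); b <- runif(20); a <- b + runif(20, 0.01, 1)
  expect_equal(wilcoxon_one_sided_greater(b, a),
               1 - wilcoxon_one_sided_greater(a, b), tolerance = 1e-12)
  # antisymmetric differences sit at the null mean
  d <- rep(c(0.3, -0.3), 10) + rep(c(0.001, -0.001), each = 10)
  expect_equal(wilcoxon_one_sided_greater(d, rep(0, 20)), 0.5,
               tolerance = 0.05)
  expect_error(wilcoxon_one_sided_greater(rep(1, 5), rep(1, 5)),
               "non-zero")
})

test_that("fair-coin baseline is calibrated and seed-deterministic", {
  cmp <- comparator_random_baseline()
  d <- data.frame(x = rep("a", 1e5))
  set.seed(123)
  frac <- mean(cmp$predict(list(), d))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e5))
  set.seed(77); p1 <- cmp$predict(list(), d[1:100, , drop = FALSE])
  set.seed(77); p2 <- cmp$predict(list(), d[1:100, , drop = FALSE])
  expect_identical(p1, p2)
})

test_that("experiment report has the right shape and shared folds", {
  sim <- synthetic_dataset(synthetic_spec(n = 120, prevalence = 0.2,
                                          n_noise_attrs = 3, seed = 8))
  plan <- cv_plan(k = 5, runs = 2, seed = 10,
                  ratios = list("original", 0.5))
  rep <- run_experiment(sim$data, sim$target,
                        list(comparator_pattern_discovery(pd_config(width = 4)),
                             comparator_random_baseline()),
                        plan)
  v <- rep$values
  # exactly runs values per method x ratio x metric cell
  counts <- table(v$method, v$ratio, v$metric)
  expect_true(all(counts == 2))
  expect_setequal(unique(v$method),
                  c("pattern_discovery", "random_baseline"))
  s <- summary(rep)
  expect_true(all(c("mean", "sd") %in% names(s$summary)))
  expect_true(is.null(rep$failures))
  # single-run single-comparator degenerate shape
  rep1 <- run_experiment(sim$data, sim$target,
                         list(comparator_random_baseline()),
                         cv_plan(k = 2, runs = 1, seed = 1))
  expect_equal(nrow(rep1$values), 5L)  # one run-level value per metric
  expect_null(summary(rep1)$wilcoxon)
})

test_that("baseline CV metrics match their theoretical values", {
  sim <- synthetic_dataset(synthetic_spec(n = 200, prevalence = 0.25,
                                          n_noise_attrs = 2, seed = 21))
  rep <- run_experiment(sim$data, sim$target,
                        list(comparator_random_baseline()),
                        cv_plan(k = 5, runs = 20, seed = 31))
  v <- rep$values
  sen <- v$value[v$metric == "sensitivity"]
  pre <- v$value[v$metric == "precision"]
  se_sen <- sd(sen) / sqrt(length(sen))
  se_pre <- sd(pre) / sqrt(length(pre))
  expect_lt(abs(mean(sen) - 0.5), 3 * se_sen)
  expect_lt(abs(mean(pre) - 0.25), 3 * se_pre)
})

test_that("comparator plug-ins run on the shared folds", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("rpart")
  sim <- synthetic_dataset(synthetic_spec(n = 150, prevalence = 0.2,
                                          n_noise_attrs = 2, seed = 12))
  rep <- run_experiment(sim$data, sim$target,
                        list(comparator_pattern_discovery(pd_config(width = 4)),
                             comparator_logistic(),
                             comparator_naive_bayes(),
                             comparator_decision_tree()),
                        cv_plan(k = 5, runs = 2, seed = 2))
  s <- summary(rep)
  expect_setequal(unique(s$wilcoxon$method),
                  c("logistic_regression", "naive_bayes", "decision_tree"))
  expect_true(all(is.na(s$wilcoxon$p_value) |
                    (s$wilcoxon$p_value > 0 & s$wilcoxon$p_value <= 1)))
})

test_that("reports write JSON and CSV artefacts", {
  sim <- synthetic_dataset(synthetic_spec(n = 100, prevalence = 0.2,
                                          n_noise_attrs = 2, seed = 3))
  rep <- run_experiment(sim$data, sim$target,
                        list(comparator_pattern_discovery(pd_config(width = 2)),
                             comparator_random_baseline()),
                        cv_plan(k = 4, runs = 2, seed = 6))
  dir <- file.path(tempdir(), "cvrep")
  write_cv_report(rep, dir)
  expect_true(file.exists(file.path(dir, "cv_values.csv")))
  expect_true(file.exists(file.path(dir, "cv_summary.csv")))
  expect_true(file.exists(file.path(dir, "cv_report.json")))
  j <- jsonlite::read_json(file.path(dir, "cv_report.json"),
                           simplifyVector = TRUE)
  expect_equal(nrow(j$values), nrow(rep$values))
})
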