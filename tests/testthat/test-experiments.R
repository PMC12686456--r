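# Experiment harness tests run deliberately small search budgets; the
# mechanisms, not absolute performance magnitudes, are under test.

tiny_moga <- function() moga_config(population_size = 10, generations = 4,
                                    stagnation_patience = 2)

test_that("stratified folds preserve class balance exactly when divisible", {
  y <- rep(c(0, 1), each = 50)
  f <- stratified_folds(y, 5, seed = 3)
  expect_equal(unname(table(f)), rep(20L, 5), ignore_attr = TRUE)
  for (k in 1:5) expect_equal(sum(y[f == k]), 10)
  expect_identical(stratified_folds(y, 5, seed = 3), f)   # paired design anchor
  expect_error(stratified_folds(c(0, 1, 1, 1), 3), "fewer members")
})

test_that("kfold_cv aggregates are recomputable and constant metrics give SD 0", {
  sc <- small_signal_cohort(n = 60, seed = 41)
  rr <- kfold_cv(sc, k = 3, seeds = 1,
                 trainer = function(train, seed) stub_model(0.9))
  # constant predictor: accuracy constant across folds up to stratification
  agg <- rr$aggregate
  for (m in agg$metric) {
    expect_equal(agg$mean[agg$metric == m],
                 mean(rr$per_fold[[m]]), tolerance = 1e-12)
    expect_equal(agg$sd[agg$metric == m],
                 sd(rr$per_fold[[m]]), tolerance = 1e-12)
  }
  expect_equal(agg$sd[agg$metric == "sensitivity"], 0)   # always predicts 1
})

test_that("the full pipeline cross-validates end to end with an EVI", {
  sc <- small_signal_cohort(n = 90, seed = 43)
  rr <- kfold_cv(sc, k = 3, seeds = 1, trainer = function(train, seed)
    train_pipeline(train, tiny_moga(), fusion = "uniform",
                   surrogate_epochs = 10, member_epochs = 15, seed = seed))
  expect_equal(nrow(rr$per_fold), 3)
  expect_true(all(rr$per_fold$accuracy >= 0 & rr$per_fold$accuracy <= 1))
  expect_false(is.na(rr$evi))
  expect_gte(rr$evi, 0)
})

test_that("pipeline variants share folds and reject unknown names", {
  expect_error(run_variant(small_signal_cohort(n = 40, seed = 2), "bogus"),
               "should be one of|'arg'")
  # the paired-design anchor: identical derived fold assignments per seed
  y <- small_signal_cohort(n = 60, seed = 44)$y
  f1 <- stratified_folds(y, 3, seed = semogen:::derive_seed(9, 31L))
  f2 <- stratified_folds(y, 3, seed = semogen:::derive_seed(9, 31L))
  expect_identical(f1, f2)
})

test_that("robustness tables are self-consistent and anchored at zero for clean data", {
  sc <- small_signal_cohort(n = 240, seed = 45)
  folds <- stratified_folds(sc$y, 5, seed = 1)
  train <- semogen:::subset_cohort(sc, folds != 1)
  test <- semogen:::subset_cohort(sc, folds == 1)
  champ <- list(bits = c(1L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L, 0L),
                objectives = NULL)
  model <- build_ensemble(train, list(champ), fusion = "uniform",
                          epochs = 40, seed = 3)
  tab <- robustness_experiment(model, test, noise_fractions = c(0, 0.2),
                               seed = 11)
  expect_equal(tab$condition[1:3], c("clean", "noise_0", "noise_20"))
  expect_equal(tab$ri_accuracy[2], 0)            # zero-noise row
  expect_equal(tab$ri_auc[2], 0)
  # stored indices reproduce from the table's own entries
  for (i in 2:nrow(tab)) {
    expect_equal(tab$ri_accuracy[i],
                 robustness_index(tab$accuracy_pct[1], tab$accuracy_pct[i]))
    expect_equal(tab$ri_auc[i],
                 robustness_index(tab$auc[1], tab$auc[i]))
  }
  expect_true(all(c("missing_mean", "missing_median") %in% tab$condition))
})

test_that("heavier noise does not improve held-out accuracy on planted signal", {
  sc <- small_signal_cohort(n = 300, seed = 46)
  folds <- stratified_folds(sc$y, 5, seed = 2)
  train <- semogen:::subset_cohort(sc, folds != 1)
  test <- semogen:::subset_cohort(sc, folds == 1)
  champ <- list(bits = c(1L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L, 0L),
                objectives = NULL)
  model <- build_ensemble(train, list(champ), fusion = "uniform",
                          epochs = 60, seed = 3)
  accs <- sapply(c(0, 0.3), function(fr) {
    mean(sapply(1:5, function(s) {
      tc <- if (fr == 0) test else
        inject_gaussian_noise(test, perturbation_spec("gaussian_noise", fr,
                                                      1, seed = 100 + s))
      evaluate_model(model, tc)[["accuracy"]]
    }))
  })
  expect_gte(accs[1], accs[2] - 0.02)
})

test_that("ablation covers the three switches and degrades from its own table", {
  sc <- small_signal_cohort(n = 80, seed = 47)
  tab <- ablation_experiment(sc, tiny_moga(), k = 3, seeds = 1,
                             surrogate_epochs = 8, member_epochs = 10)
  expect_equal(tab$variant,
               c("full", "no_ensemble_terms", "no_moga_weighting",
                 "no_diversity_constraint"))
  full <- tab[1, ]
  for (i in 2:4) {
    expect_equal(tab$degradation_accuracy[i],
                 degradation_pct(full$accuracy_pct, tab$accuracy_pct[i]))
    expect_equal(tab$degradation_auc[i],
                 degradation_pct(full$auc, tab$auc[i]))
  }
  expect_equal(degradation_pct(full$accuracy_pct, full$accuracy_pct), 0)
  expect_error(ablation_experiment(sc, tiny_moga(), switches = "nope"),
               "unknown ablation switch")
})

test_that("weighting strategies are normalized and coincide for one member", {
  sc <- small_signal_cohort(n = 100, seed = 48)
  champ <- list(bits = c(1L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L, 0L),
                objectives = c(f1 = 0.7, f2 = 0.2, f3 = 2.4, f4 = 0.68))
  tab <- weighting_comparison(sc, list(champ), seeds = 1, member_epochs = 20)
  expect_equal(sort(unique(tab$strategy)), c("heuristic", "moga", "uniform"))
  accs <- tab$accuracy
  expect_true(all(abs(accs - accs[1]) < 1e-12))  # K = 1: all strategies equal
  for (w in tab$weights) expect_equal(sum(w), 1, tolerance = 1e-12)
})

test_that("reports round-trip byte-stably and refuse missing directories", {
  sc <- small_signal_cohort(n = 60, seed = 49)
  rr <- kfold_cv(sc, k = 3, seeds = 1,
                 trainer = function(train, seed) stub_model(0.7))
  dir <- tempfile(); dir.create(dir)
  paths <- write_report(rr, dir)
  expect_true(all(file.exists(paths)))
  back <- read_report(dir)
  expect_equal(back$per_fold$accuracy, rr$per_fold$accuracy)
  expect_equal(back$aggregate$mean, rr$aggregate$mean)
  expect_equal(back$provenance$config_hash, rr$provenance$config_hash)
  # regenerable byte-identically
  first <- readLines(file.path(dir, "metrics.json"))
  write_report(rr, dir)
  expect_identical(readLines(file.path(dir, "metrics.json")), first)
  expect_error(write_report(rr, file.path(tempfile(), "nested")), "I/O error")
})

test_that("the G-mean objective separates subsets at moderate imbalance", {
  # at 30:70 the surrogate clears the decision threshold, so f4 carries
  # information that the accuracy objective alone does not
  spec <- default_cohort_spec(n = 500, prevalence = 0.3, seed = 52)
  sc <- minmax_fit_transform(impute(generate_cohort(spec)))$cohort
  ctx <- fitness_context(sc, seed = 6)
  f4_inf <- f4_gmean(c("oldpeak", "thalach", "age"), ctx)
  f4_noise <- f4_gmean(c("fbs", "restecg", "slope"), ctx)
  expect_gt(f4_inf, f4_noise)
  expect_gt(f4_inf, 0)
})
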