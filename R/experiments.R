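# Experiment harnesses: pipeline variants, cross-validation, robustness,
# ablation, weighting and imbalance comparisons. All runs are paired: the
# same (cohort, seed, fold) triple always yields the same folds and the
# same derived training seeds, whichever experiment invokes it.

#' Fit the full two-stage pipeline on a training cohort
#'
#' Runs the genetic feature selection under the requested objective set and
#' feedback mode, extracts champions (per-objective representatives, or the
#' top-k accuracy subsets when the diversity constraint is ablated), and
#' trains the fused MLP ensemble.
#'
#' @param train_cohort Preprocessed training `cohort`.
#' @param moga A [moga_config()] (its seed is overridden by `seed`).
#' @param objectives Active objective subset.
#' @param feedback `"off"` or `"on"`.
#' @param fusion `"uniform"`, `"weighted"` or `"adaboost"`.
#' @param champion_rule `"representative"` (one champion per objective) or
#'   `"top_f1"` (top-k by accuracy regardless of spread).
#' @param n_champions Number of ensemble members.
#' @param surrogate_epochs,member_epochs Training schedules for the fitness
#'   surrogate and the final members.
#' @param seed Integer seed driving every stochastic stage.
#' @return An `ensemble_model` with the `moga_result` attached as
#'   attribute `"moga"`.
#' @export
train_pipeline <- function(train_cohort, moga = moga_config(),
                           objectives = c("f1", "f2", "f3", "f4"),
                           feedback = "off",
                           fusion = "adaboost",
                           champion_rule = c("representative", "top_f1"),
                           n_champions = 4,
                           surrogate_epochs = 30, member_epochs = 100,
                           seed = 1L) {
  champion_rule <- match.arg(champion_rule)
  ctx <- fitness_context(train_cohort, objectives = objectives,
                         feedback_mode = feedback,
                         surrogate_epochs = surrogate_epochs,
                         seed = derive_seed(seed, 21L))
  moga$seed <- derive_seed(seed, 22L)
  res <- run_moga(moga, ctx)
  champions <- if (champion_rule == "representative") {
    select_representative_subsets(res$front, k = n_champions)
  } else {
    f1s <- vapply(res$front, function(i) i$objectives[["f1"]], numeric(1))
    ord <- order(-f1s)
    res$front[ord[((seq_len(n_champions) - 1) %% length(ord)) + 1]]
  }
  model <- build_ensemble(train_cohort, champions, fusion = fusion,
                          epochs = member_epochs,
                          seed = derive_seed(seed, 23L))
  attr(model, "moga") <- res
  model
}

#' Scalar evaluation of a model on a cohort
#'
#' @param model Object with a `predict` method returning probabilities.
#' @param test_cohort A preprocessed `cohort`.
#' @return Named vector: accuracy, sensitivity, specificity, precision,
#'   f1, g_mean, mcc, auc.
#' @export
evaluate_model <- function(model, test_cohort) {
  p <- predict(model, test_cohort, type = "prob")
  m <- scalar_metrics(confusion(test_cohort$y, as.integer(p >= 0.5)))
  c(m, auc = auc_roc(test_cohort$y, p))
}

subset_cohort <- function(x, rows) {
  cohort(x$X[rows, , drop = FALSE], x$y[rows], x$schema,
         x$missing_mask[rows, , drop = FALSE])
}

#' Stratified k-fold cross-validation of a model-fitting routine
#'
#' For every seed, partitions the cohort into stratified folds, fits
#' `trainer` on each training part, scores the held-out part via
#' [evaluate_model()], and (when the fitted model is an ensemble) records
#' the per-fold ensemble variance index. The aggregate block is always
#' recomputable from the per-fold table.
#'
#' @param x A preprocessed `cohort`.
#' @param k Folds (5 or 10 typically).
#' @param seeds Integer vector of seeds.
#' @param trainer `function(train_cohort, seed)` returning a model with a
#'   `predict` method.
#' @return A `run_result`: `per_fold` table, `aggregate` (mean, sd per
#'   metric), `evi` (mean of per-fold EVIs, NA for single models),
#'   `provenance`.
#' @export
kfold_cv <- function(x, k = 5, seeds = 1L, trainer) {
  rows <- list()
  evis <- numeric()
  for (s in seeds) {
    folds <- stratified_folds(x$y, k, seed = derive_seed(s, 31L))
    for (f in seq_len(k)) {
      train <- subset_cohort(x, folds != f)
      test <- subset_cohort(x, folds == f)
      model <- trainer(train, derive_seed(s, 32L, f))
      met <- evaluate_model(model, test)
      rows[[length(rows) + 1L]] <-
        data.frame(seed = s, fold = f, t(as.matrix(met)))
      if (inherits(model, "ensemble_model") && length(model$members) >= 2)
        evis <- c(evis, ensemble_variance_index(member_probs(model, test)))
    }
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- setdiff(colnames(per_fold), c("seed", "fold"))
  aggregate <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_fold[[m]]), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(per_fold[[m]]), numeric(1)),
    row.names = NULL
  )
  structure(list(per_fold = per_fold, aggregate = aggregate,
                 evi = if (length(evis)) mean(evis) else NA_real_,
                 provenance = list(k = k, seeds = seeds,
                                   config_hash = cheap_hash(list(k = k, seeds = seeds)))),
            class = "run_result")
}

#' Compare the three pipeline architectures
#'
#' `traditional` reduces feature selection to a single-objective (accuracy)
#' GA feeding one MLP; `cascaded` runs the full four-objective selection
#' without feedback and fuses four members with AdaBoost; `feedback`
#' additionally couples the selection fitness to the evolving ensemble via
#' the archive. Folds and derived seeds are identical across variants
#' (paired design).
#'
#' @param x Preprocessed `cohort`.
#' @param variant One of `"traditional"`, `"cascaded"`, `"feedback"`.
#' @param moga A [moga_config()].
#' @param k,seeds Cross-validation folds and seeds.
#' @param surrogate_epochs,member_epochs Training schedules.
#' @return A `run_result`.
#' @export
run_variant <- function(x, variant = c("traditional", "cascaded", "feedback"),
                        moga = moga_config(), k = 5, seeds = 1L,
                        surrogate_epochs = 30, member_epochs = 100) {
  variant <- match.arg(variant)
  trainer <- switch(variant,
    traditional = function(train, seed)
      train_pipeline(train, moga, objectives = "f1", fusion = "uniform",
                     n_champions = 1, surrogate_epochs = surrogate_epochs,
                     member_epochs = member_epochs, seed = seed),
    cascaded = function(train, seed)
      train_pipeline(train, moga, fusion = "adaboost",
                     surrogate_epochs = surrogate_epochs,
                     member_epochs = member_epochs, seed = seed),
    feedback = function(train, seed)
      train_pipeline(train, moga, feedback = "on", fusion = "adaboost",
                     surrogate_epochs = surrogate_epochs,
                     member_epochs = member_epochs, seed = seed)
  )
  out <- kfold_cv(x, k = k, seeds = seeds, trainer = trainer)
  out$provenance$variant <- variant
  out
}

#' Robustness of a trained model to noise and missingness
#'
#' Evaluates the model on the clean test cohort and on perturbed copies:
#' additive Gaussian noise over 10/20/30 percent of continuous cells (one
#' feature-SD scale), and MCAR missingness re-imputed with mean or median
#' substitution. Accuracy is tabulated in percent (1 decimal), AUC to 3
#' decimals, and the robustness indices are recomputed from the table's own
#' stored entries so the table is self-consistent by construction.
#'
#' @param model A fitted model.
#' @param test_cohort Clean preprocessed test `cohort`.
#' @param noise_fractions Cell fractions for the noise conditions.
#' @param noise_scale Noise SD in per-feature-SD units.
#' @param missing_fraction Cell fraction for the missingness conditions.
#' @param missing_strategies Imputation strategies to test.
#' @param seed Integer seed for the perturbation masks.
#' @return Data frame with one row per condition: condition, accuracy_pct,
#'   auc, ri_accuracy, ri_auc.
#' @export
robustness_experiment <- function(model, test_cohort,
                                  noise_fractions = c(0.1, 0.2, 0.3),
                                  noise_scale = 1.0,
                                  missing_fraction = 0.1,
                                  missing_strategies = c("mean", "median"),
                                  seed = 1L) {
  score <- function(tc) {
    m <- evaluate_model(model, tc)
    c(acc = round_half_up(100 * m[["accuracy"]], 1),
      auc = round_half_up(m[["auc"]], 3))
  }
  rows <- list(data.frame(condition = "clean", t(score(test_cohort))))
  for (fr in noise_fractions) {
    p <- perturbation_spec("gaussian_noise", fraction = fr,
                           noise_scale = noise_scale,
                           seed = derive_seed(seed, 41L, round(100 * fr)))
    rows[[length(rows) + 1L]] <-
      data.frame(condition = sprintf("noise_%d", round(100 * fr)),
                 t(score(inject_gaussian_noise(test_cohort, p))))
  }
  for (st in missing_strategies) {
    p <- perturbation_spec("missing", fraction = missing_fraction,
                           seed = derive_seed(seed, 42L))
    pert <- impute(inject_missingness(test_cohort, p), numeric_strategy = st)
    rows[[length(rows) + 1L]] <-
      data.frame(condition = paste0("missing_", st), t(score(pert)))
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("condition", "accuracy_pct", "auc")
  tab$ri_accuracy <- c(NA, robustness_index(tab$accuracy_pct[1],
                                            tab$accuracy_pct[-1]))
  tab$ri_auc <- c(NA, robustness_index(tab$auc[1], tab$auc[-1]))
  tab
}

#' Component ablation study
#'
#' The full model couples the four-objective fitness, per-objective
#' representative champions, and fitness-derived weighted fusion. Each
#' switch removes one component: `ensemble_terms` reduces the fitness to
#' accuracy only; `moga_weighting` replaces weighted fusion by uniform;
#' `diversity_constraint` replaces representative extraction by the top-4
#' accuracy champions. Metrics come from stratified k-fold CV with folds
#' shared across variants; degradations are recomputed from the table's own
#' stored entries.
#'
#' @param x Preprocessed `cohort`.
#' @param moga A [moga_config()].
#' @param switches Character subset of `c("ensemble_terms",
#'   "moga_weighting", "diversity_constraint")`; the full model always runs.
#' @param k,seeds CV folds and seeds.
#' @param surrogate_epochs,member_epochs Training schedules.
#' @return Data frame: variant, accuracy_pct, sensitivity_pct, auc and the
#'   three degradation columns (NA for the full row).
#' @export
ablation_experiment <- function(x, moga = moga_config(),
                                switches = c("ensemble_terms", "moga_weighting",
                                             "diversity_constraint"),
                                k = 5, seeds = 1L,
                                surrogate_epochs = 30, member_epochs = 100) {
  bad <- setdiff(switches, c("ensemble_terms", "moga_weighting",
                             "diversity_constraint"))
  if (length(bad)) stop("unknown ablation switch: ", paste(bad, collapse = ", "))
  make_trainer <- function(objectives, fusion, rule) {
    function(train, seed)
      train_pipeline(train, moga, objectives = objectives, fusion = fusion,
                     champion_rule = rule, surrogate_epochs = surrogate_epochs,
                     member_epochs = member_epochs, seed = seed)
  }
  variants <- list(full = make_trainer(c("f1", "f2", "f3", "f4"), "weighted",
                                       "representative"))
  if ("ensemble_terms" %in% switches)
    variants$no_ensemble_terms <- make_trainer("f1", "weighted", "representative")
  if ("moga_weighting" %in% switches)
    variants$no_moga_weighting <- make_trainer(c("f1", "f2", "f3", "f4"),
                                               "uniform", "representative")
  if ("diversity_constraint" %in% switches)
    variants$no_diversity_constraint <- make_trainer(c("f1", "f2", "f3", "f4"),
                                                     "weighted", "top_f1")
  rows <- lapply(names(variants), function(nm) {
    rr <- kfold_cv(x, k = k, seeds = seeds, trainer = variants[[nm]])
    ag <- rr$aggregate
    data.frame(variant = nm,
               accuracy_pct = round_half_up(100 * ag$mean[ag$metric == "accuracy"], 1),
               sensitivity_pct = round_half_up(100 * ag$mean[ag$metric == "sensitivity"], 1),
               auc = round_half_up(ag$mean[ag$metric == "auc"], 3))
  })
  tab <- do.call(rbind, rows)
  full <- tab[tab$variant == "full", ]
  tab$degradation_accuracy <- ifelse(tab$variant == "full", NA,
    degradation_pct(full$accuracy_pct, tab$accuracy_pct))
  tab$degradation_sensitivity <- ifelse(tab$variant == "full", NA,
    degradation_pct(full$sensitivity_pct, tab$sensitivity_pct))
  tab$degradation_auc <- ifelse(tab$variant == "full", NA,
    degradation_pct(full$auc, tab$auc))
  tab
}

#' Compare ensemble weighting strategies over fixed members
#'
#' Trains the champions' members once per seed on a stratified training
#' split, then fuses the same members three ways: uniform, heuristic
#' (weights proportional to member validation accuracy on a held-out
#' validation split), and fitness-derived ([moga_weights()]). Scored on the
#' test split.
#'
#' @param x Preprocessed `cohort`.
#' @param champions Evaluated individuals defining the members.
#' @param seeds Integer seeds.
#' @param member_epochs Member training schedule.
#' @return Data frame: seed, strategy, accuracy, auc, sensitivity, plus the
#'   weights used (as a list column).
#' @export
weighting_comparison <- function(x, champions, seeds = 1L, member_epochs = 100) {
  rows <- list()
  for (s in seeds) {
    folds <- stratified_folds(x$y, 5, seed = derive_seed(s, 51L))
    test <- folds == 1L; val <- folds == 2L; tr <- !(test | val)
    train_c <- subset_cohort(x, tr)
    val_c <- subset_cohort(x, val)
    test_c <- subset_cohort(x, test)
    model <- build_ensemble(train_c, champions, fusion = "uniform",
                            epochs = member_epochs, seed = derive_seed(s, 52L))
    Pval <- member_probs(model, val_c)
    val_acc <- apply(Pval, 1, function(p) mean((p >= 0.5) == (val_c$y == 1)))
    heuristic <- if (sum(val_acc) == 0) rep(1 / length(val_acc), length(val_acc))
                 else val_acc / sum(val_acc)
    moga_w <- moga_weights(champions)
    Ptest <- member_probs(model, test_c)
    strategies <- list(uniform = rep(1 / nrow(Ptest), nrow(Ptest)),
                       heuristic = heuristic, moga = moga_w)
    for (nm in names(strategies)) {
      p <- weighted_fuse(Ptest, strategies[[nm]])
      m <- scalar_metrics(confusion(test_c$y, as.integer(p >= 0.5)))
      rows[[length(rows) + 1L]] <-
        data.frame(seed = s, strategy = nm,
                   accuracy = m[["accuracy"]], sensitivity = m[["sensitivity"]],
                   auc = auc_roc(test_c$y, p))
      rows[[length(rows)]]$weights <- I(list(strategies[[nm]]))
    }
  }
  do.call(rbind, rows)
}

#' Compare imbalance-handling strategies on a generated cohort
#'
#' Three arms on the same generated cohorts and splits: `standard` uses an
#' accuracy-only fitness; `smote` additionally oversamples the minority
#' class inside the training split (never the test split) while keeping the
#' accuracy-only fitness; `imbalance_aware` uses the full four-objective
#' fitness. Each arm's champions feed a uniform-fused ensemble; minority
#' metrics are scored on the held-out split.
#'
#' @param spec A [cohort_spec()] (typically low prevalence).
#' @param seeds Integer seeds; each seed regenerates the cohort.
#' @param moga A [moga_config()].
#' @param strategies Which arms to run (subset of `"standard"`, `"smote"`,
#'   `"imbalance_aware"`).
#' @param smote_k SMOTE neighbour count.
#' @param surrogate_epochs,member_epochs Training schedules.
#' @return Data frame: seed, strategy, minority precision/recall/f1,
#'   g_mean, mcc.
#' @export
imbalance_comparison <- function(spec, seeds = 1L, moga = moga_config(),
                                 strategies = c("standard", "smote",
                                                "imbalance_aware"),
                                 smote_k = 5, surrogate_epochs = 30,
                                 member_epochs = 100) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  rows <- list()
  for (s in seeds) {
    gspec <- spec; gspec$seed <- derive_seed(s, 61L)
    coh <- generate_cohort(gspec)
    sc <- minmax_fit_transform(impute(coh))$cohort
    folds <- stratified_folds(sc$y, 5, seed = derive_seed(s, 62L))
    test <- folds == 1L
    train_c <- subset_cohort(sc, !test)
    test_c <- subset_cohort(sc, test)
    minority <- as.integer(sum(sc$y == 1) <= sum(sc$y == 0))
    arms <- list()
    if ("standard" %in% strategies)
      arms$standard <- list(train = train_c, objectives = "f1")
    if ("smote" %in% strategies)
      arms$smote <- list(train = smote(train_c, k = smote_k,
                                       seed = derive_seed(s, 63L)),
                         objectives = "f1")
    if ("imbalance_aware" %in% strategies)
      arms$imbalance_aware <- list(train = train_c,
                                   objectives = c("f1", "f2", "f3", "f4"))
    for (nm in names(arms)) {
      model <- train_pipeline(arms[[nm]]$train, moga,
                              objectives = arms[[nm]]$objectives,
                              fusion = "uniform",
                              surrogate_epochs = surrogate_epochs,
                              member_epochs = member_epochs,
                              seed = derive_seed(s, 64L))
      pred <- predict(model, test_c, type = "class")
      # minority-class one-vs-rest confusion
      cm <- confusion(as.integer(test_c$y == minority),
                      as.integer(pred == minority))
      m <- scalar_metrics(cm)
      full <- scalar_metrics(confusion(test_c$y, pred))
      rows[[length(rows) + 1L]] <-
        data.frame(seed = s, strategy = nm,
                   precision_minority = m[["precision"]],
                   recall_minority = m[["sensitivity"]],
                   f1_minority = m[["f1"]],
                   g_mean = full[["g_mean"]], mcc = full[["mcc"]])
    }
  }
  do.call(rbind, rows)
}

#' Write and reload a cross-validation run report
#'
#' Emits `metrics.json` (aggregate block, EVI, provenance), a per-fold CSV
#' and a config snapshot into `dir`; regenerable byte-identically from the
#' same `run_result`.
#'
#' @param result A `run_result`.
#' @param dir Output directory (must exist).
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(result, dir) {
  if (!dir.exists(dir)) stop("I/O error: directory does not exist: ", dir)
  jpath <- file.path(dir, "metrics.json")
  cpath <- file.path(dir, "per_fold.csv")
  spath <- file.path(dir, "config.json")
  jsonlite::write_json(list(aggregate = result$aggregate, evi = result$evi,
                            provenance = result$provenance[c("k", "seeds",
                                                             "config_hash",
                                                             "variant")]),
                       jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(result$per_fold, cpath, row.names = FALSE)
  jsonlite::write_json(result$provenance, spath, auto_unbox = TRUE, digits = NA)
  invisible(c(jpath, cpath, spath))
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  per_fold <- utils::read.csv(file.path(dir, "per_fold.csv"))
  meta <- jsonlite::read_json(file.path(dir, "metrics.json"), simplifyVector = TRUE)
  list(per_fold = per_fold, aggregate = meta$aggregate, evi = meta$evi,
       provenance = meta$provenance)
}

# Small deterministic FNV-style hash for provenance stamps.
cheap_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
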