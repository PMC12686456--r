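# Seeded simulation studies shared by the test suite and the acceptance
# script. Problem sizes are fixed here so every caller measures the same
# conditions.

#' Planted-feature recovery study
#'
#' For each seed, generates the default planted-signal cohort
#' ([default_cohort_spec()]) at `n` rows, runs the four-objective genetic
#' selection, and records how many of the five planted continuous features
#' the front-1 accuracy champion contains, together with the accuracy and
#' redundancy champions' f2 values.
#'
#' @param n_seeds Number of independent seeded runs.
#' @param n Cohort size per run.
#' @param moga A [moga_config()]; the default search budget (population
#'   36, up to 50 generations, stagnation patience 10) is sized so a run
#'   takes about a minute on one core.
#' @param base_seed Base seed from which all per-run seeds are derived.
#' @return Data frame: seed, planted_hits, f2_accuracy_champion,
#'   f2_redundancy_champion, accuracy_champion (comma-joined features).
#' @export
planted_recovery_study <- function(n_seeds = 10, n = 600,
                                   moga = moga_config(population_size = 36,
                                                      generations = 50,
                                                      stagnation_patience = 10),
                                   base_seed = 1L) {
  planted <- c("age", "trestbps", "chol", "thalach", "oldpeak")
  rows <- lapply(seq_len(n_seeds), function(s) {
    seed <- derive_seed(base_seed, s)
    spec <- default_cohort_spec(n = n, seed = derive_seed(seed, 7L))
    sc <- minmax_fit_transform(impute(generate_cohort(spec)))$cohort
    ctx <- fitness_context(sc, seed = derive_seed(seed, 8L))
    cfg <- moga
    cfg$seed <- seed
    res <- run_moga(cfg, ctx)
    ch <- select_representative_subsets(res$front)
    acc_feats <- decode_chromosome(ch[[1]]$bits, sc$schema)
    data.frame(seed = s,
               planted_hits = sum(planted %in% acc_feats),
               f2_accuracy_champion = unname(ch[[1]]$objectives["f2"]),
               f2_redundancy_champion = unname(ch[[2]]$objectives["f2"]),
               accuracy_champion = paste(acc_feats, collapse = ","))
  })
  do.call(rbind, rows)
}

#' Ensemble-benefit study: fusion versus mean member
#'
#' For each seed, generates a planted-signal cohort, draws four member
#' subsets (size 4-6, seeded), and runs stratified 5-fold CV training the
#' four MLP members per fold; records the uniformly fused ensemble's
#' pooled CV accuracy against the mean of the members' individual pooled
#' accuracies — the variance-reduction property motivating the fusion
#' stage.
#'
#' @param n_seeds Number of seeded runs.
#' @param n Cohort size.
#' @param member_epochs Member training schedule.
#' @param base_seed Base seed.
#' @return Data frame: seed, fused_accuracy, mean_member_accuracy,
#'   fused_wins.
#' @export
ensemble_benefit_study <- function(n_seeds = 20, n = 300,
                                   member_epochs = 100, base_seed = 1L) {
  d <- length(cleveland_schema()$names)
  rows <- lapply(seq_len(n_seeds), function(s) {
    seed <- derive_seed(base_seed, 200L, s)
    spec <- default_cohort_spec(n = n, seed = derive_seed(seed, 1L))
    sc <- minmax_fit_transform(impute(generate_cohort(spec)))$cohort
    subsets <- with_seed(derive_seed(seed, 2L), {
      lapply(1:4, function(k) {
        bits <- integer(d)
        bits[sample.int(d, sample(4:6, 1))] <- 1L
        bits
      })
    })
    folds <- stratified_folds(sc$y, 5, seed = derive_seed(seed, 3L))
    member_p <- matrix(NA_real_, 4, n)
    for (f in 1:5) {
      tr <- folds != f
      train_c <- subset_cohort(sc, tr)
      for (k in 1:4) {
        feats <- decode_chromosome(subsets[[k]], sc$schema)
        X <- design_matrix(train_c, feats)
        spec_m <- mlp_spec(ncol(X), epochs = member_epochs,
                           seed = derive_seed(seed, 4L, f, k))
        fit <- train_mlp(spec_m, X, train_c$y)
        member_p[k, !tr] <- mlp_forward(fit, design_matrix(subset_cohort(sc, !tr), feats))
      }
    }
    fused <- uniform_fuse(member_p)
    fused_acc <- mean((fused >= 0.5) == (sc$y == 1))
    member_acc <- apply(member_p, 1, function(p) mean((p >= 0.5) == (sc$y == 1)))
    data.frame(seed = s, fused_accuracy = fused_acc,
               mean_member_accuracy = mean(member_acc),
               fused_wins = fused_acc >= mean(member_acc))
  })
  do.call(rbind, rows)
}

#' Imbalance-mechanism study: four-objective versus accuracy-only fitness
#'
#' Runs [imbalance_comparison()] at the given prevalence with the
#' `standard` (accuracy-only) and `imbalance_aware` (four-objective) arms,
#' and tabulates per-seed minority recall for both.
#'
#' @param n_seeds Number of seeded runs.
#' @param n Cohort size.
#' @param prevalence Minority prevalence of the generated cohorts.
#' @param moga A [moga_config()]; a compact search budget suffices for the
#'   two-arm contrast.
#' @param base_seed Base seed.
#' @return Data frame: seed, recall_standard, recall_aware, aware_higher.
#' @export
imbalance_mechanism_study <- function(n_seeds = 20, n = 400, prevalence = 0.1,
                                      moga = moga_config(population_size = 14,
                                                         generations = 10,
                                                         stagnation_patience = 5),
                                      base_seed = 1L) {
  spec <- default_cohort_spec(n = n, prevalence = prevalence)
  tab <- imbalance_comparison(spec,
                              seeds = vapply(seq_len(n_seeds),
                                             function(s) derive_seed(base_seed, 300L, s),
                                             integer(1)),
                              moga = moga,
                              strategies = c("standard", "imbalance_aware"))
  std <- tab[tab$strategy == "standard", ]
  aw <- tab[tab$strategy == "imbalance_aware", ]
  data.frame(seed = seq_len(n_seeds),
             recall_standard = std$recall_minority,
             recall_aware = aw$recall_minority,
             aware_higher = aw$recall_minority > std$recall_minority)
}
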