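# Multi-objective genetic feature selection.
#
# Chromosomes are bit vectors over the schema's base features. The fitness
# couples four directed objectives: cross-validated surrogate accuracy (up),
# mean absolute pairwise correlation among the selected features (down), the
# mean clinician interpretability score (up), and the G-mean of sensitivity
# and specificity from the same pooled CV predictions (up). Survivor
# selection is NSGA-style: fast non-dominated sorting plus crowding distance,
# with per-objective champions carried over as elites.

OBJ_DIRECTIONS <- c(f1 = 1, f2 = -1, f3 = 1, f4 = 1)

#' MOGA configuration
#'
#' Defaults follow the tuned configuration for the 13-feature problem:
#' population 50, up to 100 generations with a 10-generation stagnation
#' stop, uniform crossover at rate 0.9, per-bit mutation 0.05, tournament
#' size 3, 2 elites, and a hard cardinality cap of 6 enforced by repair.
#' `exp11_profile = TRUE` switches to the alternative benchmarking profile
#' (population 100, 200 generations, tournament 2, mutation 1/13).
#'
#' @param population_size,generations,crossover_rate,mutation_rate
#'   Core GA parameters.
#' @param tournament_size,elitism_count,max_cardinality,stagnation_patience
#'   Selection and termination parameters.
#' @param seed Integer seed.
#' @param exp11_profile Use the alternative large-population profile.
#' @return An object of class `moga_config`.
#' @export
moga_config <- function(population_size = 50, generations = 100,
                        crossover_rate = 0.9, mutation_rate = 0.05,
                        tournament_size = 3, elitism_count = 2,
                        max_cardinality = 6, stagnation_patience = 10,
                        seed = 1L, exp11_profile = FALSE) {
  if (exp11_profile) {
    population_size <- 100; generations <- 200
    tournament_size <- 2; mutation_rate <- 1 / 13
    elitism_count <- max(1L, round(0.05 * population_size))
  }
  if (crossover_rate < 0 || crossover_rate > 1 || mutation_rate < 0 || mutation_rate > 1)
    stop("rates must lie in [0, 1]")
  if (population_size < 1 || tournament_size < 1) stop("sizes must be >= 1")
  if (elitism_count >= population_size) stop("elitism_count must be < population_size")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 elitism_count = as.integer(elitism_count),
                 max_cardinality = as.integer(max_cardinality),
                 stagnation_patience = as.integer(stagnation_patience),
                 seed = as.integer(seed)),
            class = "moga_config")
}

#' Fitness context for subset evaluation
#'
#' Holds everything the four objectives need: the preprocessed cohort, the
#' stratified CV folds the surrogate is scored on, the surrogate's reduced
#' training schedule, the interpretability map, and (optionally) the
#' archive used by the semantic feedback loop, in which f1/f4 score the
#' uniform fusion of the archived champions' predictions with the
#' candidate's.
#'
#' @param cohort Preprocessed `cohort` (imputed, scaled).
#' @param cv_folds Number of stratified folds (>= 2).
#' @param imap An [interpretability_map()].
#' @param objectives Character subset of `c("f1","f2","f3","f4")` that is
#'   actively optimized; the rest are frozen at 0.
#' @param feedback_mode `"off"` or `"on"`.
#' @param surrogate_epochs Epochs for the reduced surrogate schedule
#'   (no early stopping).
#' @param surrogate_lr Surrogate learning rate. The shortened schedule
#'   needs a larger step than the final members' 0.001 to act as a
#'   converged subset-quality proxy; 0.01 tracks a logistic oracle on
#'   planted-signal cohorts.
#' @param dropout_rate Dropout rate for the surrogate.
#' @param seed Integer seed fixing folds and surrogate streams.
#' @return An object of class `fitness_context`.
#' @export
fitness_context <- function(cohort, cv_folds = 5,
                            imap = default_interpretability_map(),
                            objectives = c("f1", "f2", "f3", "f4"),
                            feedback_mode = c("off", "on"),
                            surrogate_epochs = 30, surrogate_lr = 0.01,
                            dropout_rate = 0.2, seed = 1L) {
  feedback_mode <- match.arg(feedback_mode)
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  if (!all(objectives %in% c("f1", "f2", "f3", "f4")))
    stop("unknown objective name")
  if (length(unique(cohort$y)) < 2) stop("cohort must contain both classes")
  ctx <- new.env(parent = emptyenv())
  ctx$cohort <- cohort
  ctx$cv_folds <- as.integer(cv_folds)
  ctx$imap <- imap
  ctx$objectives <- objectives
  ctx$feedback_mode <- feedback_mode
  ctx$surrogate_epochs <- as.integer(surrogate_epochs)
  ctx$surrogate_lr <- surrogate_lr
  ctx$dropout_rate <- dropout_rate
  ctx$seed <- as.integer(seed)
  ctx$folds <- stratified_folds(cohort$y, cv_folds, seed = derive_seed(seed, 11L))
  ctx$memo <- new.env(parent = emptyenv())
  ctx$prob_memo <- new.env(parent = emptyenv())
  ctx$archive <- list()          # champion out-of-fold probability vectors
  ctx$archive_version <- 0L
  class(ctx) <- c("fitness_context", class(ctx))
  ctx
}

#' Decode a chromosome into feature names
#'
#' @param bits 0/1 vector of length d.
#' @param schema A `feature_schema`.
#' @return Character vector of selected feature names in schema order.
#' @export
decode_chromosome <- function(bits, schema) {
  if (length(bits) != length(schema$names))
    stop("chromosome length does not match schema")
  schema$names[bits == 1]
}

#' Repair a chromosome to the admissible cardinality band
#'
#' Clears surplus bits uniformly at random down to `max_cardinality`, and
#' sets one random bit on an empty chromosome. Valid chromosomes pass
#' through unchanged. Uses the caller's RNG stream.
#'
#' @param bits 0/1 vector.
#' @param max_cardinality Upper popcount bound.
#' @return Repaired bit vector with popcount in `[1, max_cardinality]`.
#' @export
repair_chromosome <- function(bits, max_cardinality = 6) {
  k <- sum(bits)
  if (k == 0) {
    bits[sample.int(length(bits), 1)] <- 1L
  } else if (k > max_cardinality) {
    on <- which(bits == 1)
    drop <- sample(on, k - max_cardinality)
    bits[drop] <- 0L
  }
  as.integer(bits)
}

# Out-of-fold surrogate probabilities for a subset (memoized per context).
surrogate_cv_probs <- function(bits, ctx) {
  key <- paste(bits, collapse = "")
  hit <- get0(key, envir = ctx$prob_memo)
  if (!is.null(hit)) return(hit)
  features <- decode_chromosome(bits, ctx$cohort$schema)
  X <- design_matrix(ctx$cohort, features)
  y <- ctx$cohort$y
  probs <- numeric(length(y))
  bits_id <- sum(bits * 2^(seq_along(bits) - 1))
  for (f in seq_len(ctx$cv_folds)) {
    tr <- ctx$folds != f
    spec <- mlp_spec(n_in = ncol(X), l2_lambda = 0.001,
                     dropout_rate = ctx$dropout_rate,
                     learning_rate = ctx$surrogate_lr,
                     epochs = ctx$surrogate_epochs,
                     early_stopping_patience = NULL,
                     seed = derive_seed(ctx$seed, bits_id, f))
    fit <- train_mlp(spec, X[tr, , drop = FALSE], y[tr])
    probs[!tr] <- mlp_forward(fit, X[!tr, , drop = FALSE])
  }
  assign(key, probs, envir = ctx$prob_memo)
  probs
}

# Pooled CV predictions (optionally fused with the feedback archive).
pooled_predictions <- function(bits, ctx) {
  probs <- surrogate_cv_probs(bits, ctx)
  if (ctx$feedback_mode == "on" && length(ctx$archive) > 0) {
    all_probs <- do.call(cbind, c(ctx$archive, list(probs)))
    probs <- rowMeans(all_probs)
  }
  probs
}

#' Objective f1: pooled cross-validated accuracy
#'
#' `(TP + TN) / n` of the surrogate's 0.5-thresholded out-of-fold
#' predictions, pooled over the context's stratified folds.
#'
#' @param subset 0/1 chromosome or character vector of feature names.
#' @param context A `fitness_context`.
#' @return Accuracy in \[0, 1\].
#' @export
f1_accuracy <- function(subset, context) {
  bits <- as_bits(subset, context$cohort$schema)
  if (sum(bits) == 0) stop("empty subset")
  p <- pooled_predictions(bits, context)
  mean((p >= 0.5) == (context$cohort$y == 1))
}

#' Objective f2: redundancy as mean absolute pairwise correlation
#'
#' Pearson correlation computed on the selected base features' numeric
#' codes (categoricals as their level codes, not one-hot), averaged over
#' all unordered pairs; singletons score 0, and pairs involving a
#' zero-variance column contribute 0.
#'
#' @param subset 0/1 chromosome or character vector of feature names.
#' @param cohort A `cohort`.
#' @return Redundancy in \[0, 1\].
#' @export
f2_redundancy <- function(subset, cohort) {
  bits <- as_bits(subset, cohort$schema)
  cols <- which(bits == 1)
  if (length(cols) < 2) return(0)
  M <- cohort$X[, cols, drop = FALSE]
  sds <- apply(M, 2, stats::sd)
  C <- suppressWarnings(stats::cor(M))
  C[!is.finite(C)] <- 0          # zero-variance columns contribute 0
  vals <- abs(C[upper.tri(C)])
  mean(vals)
}

#' Objective f3: mean interpretability score
#'
#' @param subset 0/1 chromosome or character vector of feature names.
#' @param map An [interpretability_map()].
#' @param schema Schema used to decode a bit-vector subset.
#' @return Mean score in \[1, 3\].
#' @export
f3_interpretability <- function(subset, map = default_interpretability_map(),
                                schema = cleveland_schema()) {
  features <- if (is.character(subset)) subset else decode_chromosome(subset, schema)
  if (length(features) == 0) stop("empty subset")
  s <- map$scores[features]
  s[is.na(s)] <- map$default_score
  mean(s)
}

#' Objective f4: G-mean of the surrogate's pooled CV predictions
#'
#' `sqrt(sensitivity * specificity)` from the same pooled out-of-fold
#' predictions as [f1_accuracy()].
#'
#' @inheritParams f1_accuracy
#' @return G-mean in \[0, 1\].
#' @export
f4_gmean <- function(subset, context) {
  bits <- as_bits(subset, context$cohort$schema)
  if (sum(bits) == 0) stop("empty subset")
  if (length(unique(context$cohort$y)) < 2) stop("a class is absent")
  p <- pooled_predictions(bits, context)
  m <- scalar_metrics(confusion(context$cohort$y, as.integer(p >= 0.5)))
  unname(m["g_mean"])
}

as_bits <- function(subset, schema) {
  if (is.character(subset)) {
    bad <- setdiff(subset, schema$names)
    if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
    as.integer(schema$names %in% subset)
  } else {
    if (length(subset) != length(schema$names))
      stop("chromosome length does not match schema")
    as.integer(subset)
  }
}

# Evaluate one chromosome -> named objective vector (memoized; the memo key
# includes the archive version so feedback refreshes invalidate it).
evaluate_bits <- function(bits, ctx) {
  key <- paste0(paste(bits, collapse = ""), "@", ctx$archive_version)
  hit <- get0(key, envir = ctx$memo)
  if (!is.null(hit)) return(hit)
  obj <- c(f1 = 0, f2 = 0, f3 = 0, f4 = 0)
  if ("f1" %in% ctx$objectives) obj["f1"] <- f1_accuracy(bits, ctx)
  if ("f2" %in% ctx$objectives) obj["f2"] <- f2_redundancy(bits, ctx$cohort)
  if ("f3" %in% ctx$objectives)
    obj["f3"] <- f3_interpretability(bits, ctx$imap, ctx$cohort$schema)
  if ("f4" %in% ctx$objectives) obj["f4"] <- f4_gmean(bits, ctx)
  assign(key, obj, envir = ctx$memo)
  obj
}

#' Evaluate a population of individuals
#'
#' Attaches the four-component objective vector to every individual.
#' Identical chromosomes share a memoized evaluation, so they always carry
#' identical vectors.
#'
#' @param population List of individuals (`list(bits = ...)`).
#' @param context A `fitness_context`.
#' @return The population with `$objectives` filled in.
#' @export
evaluate_population <- function(population, context) {
  lapply(population, function(ind) {
    ind$objectives <- evaluate_bits(ind$bits, context)
    ind
  })
}

#' Pareto dominance under the directed objectives
#'
#' `a` dominates `b` iff it is no worse in every directed objective
#' (f1 up, f2 down, f3 up, f4 up) and strictly better in at least one.
#'
#' @param a,b Named objective vectors (f1..f4).
#' @return Logical.
#' @export
dominates <- function(a, b) {
  da <- OBJ_DIRECTIONS * a[names(OBJ_DIRECTIONS)]
  db <- OBJ_DIRECTIONS * b[names(OBJ_DIRECTIONS)]
  all(da >= db) && any(da > db)
}

#' Fast non-dominated sorting
#'
#' Partitions the population into successive non-dominated fronts
#' (Deb's bookkeeping: dominance counts plus dominated-sets).
#'
#' @param objectives m x 4 matrix of objective vectors (columns f1..f4), or
#'   an evaluated population list.
#' @return List of integer index vectors, one per front.
#' @export
fast_nondominated_sort <- function(objectives) {
  M <- objectives_matrix(objectives)
  m <- nrow(M)
  D <- sweep(M, 2, OBJ_DIRECTIONS[colnames(M)], `*`)
  n_dom <- integer(m)
  dominated_by <- vector("list", m)
  for (i in seq_len(m)) {
    ge <- sweep(D, 2, D[i, ], `>=`)
    gt <- sweep(D, 2, D[i, ], `>`)
    dom_over_i <- rowSums(ge) == ncol(D) & rowSums(gt) > 0   # j dominates i
    n_dom[i] <- sum(dom_over_i)
    le <- !gt                     # D[j,] <= D[i,]
    lt <- !ge                     # D[j,] <  D[i,]
    i_dom_over <- rowSums(le) == ncol(D) & rowSums(lt) > 0   # i dominates j
    dominated_by[[i]] <- which(i_dom_over)
  }
  fronts <- list()
  current <- which(n_dom == 0)
  while (length(current)) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated_by[[i]]) {
        n_dom[j] <- n_dom[j] - 1L
        if (n_dom[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- sort(nxt)
  }
  fronts
}

objectives_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    M <- do.call(rbind, lapply(x, function(ind) ind$objectives))
  } else {
    M <- as.matrix(x)
  }
  if (is.null(colnames(M))) colnames(M) <- names(OBJ_DIRECTIONS)
  M
}

#' Crowding distance within a front
#'
#' For each objective the front is sorted, the two extremes receive
#' infinite distance, and interior members accrue the normalized gap
#' between their neighbours; an objective constant across the front
#' contributes 0.
#'
#' @param front_objectives m x 4 matrix (or evaluated front list).
#' @return Numeric vector of distances, length m.
#' @export
crowding_distance <- function(front_objectives) {
  M <- objectives_matrix(front_objectives)
  m <- nrow(M)
  if (m <= 2) return(rep(Inf, m))
  dist <- numeric(m)
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    rng <- max(v) - min(v)
    if (rng == 0) next
    ord <- order(v)
    dist[ord[1]] <- Inf
    dist[ord[m]] <- Inf
    for (i in 2:(m - 1))
      dist[ord[i]] <- dist[ord[i]] + (v[ord[i + 1]] - v[ord[i - 1]]) / rng
  }
  dist
}

#' Tournament selection
#'
#' Draws `size` distinct candidates uniformly; the winner has the lowest
#' front rank, ties broken by larger crowding distance, then by draw order.
#' Uses the caller's RNG stream.
#'
#' @param population Evaluated, ranked and crowded population list.
#' @param size Tournament size.
#' @return The winning individual.
#' @export
tournament_select <- function(population, size = 3) {
  n <- length(population)
  cand <- sample.int(n, min(size, n))
  best <- cand[1]
  for (i in cand[-1]) {
    if (population[[i]]$rank < population[[best]]$rank ||
        (population[[i]]$rank == population[[best]]$rank &&
         population[[i]]$crowding > population[[best]]$crowding)) {
      best <- i
    }
  }
  population[[best]]
}

#' Uniform crossover
#'
#' With probability `1 - rate` the parents are copied; otherwise every bit
#' position independently swaps between the two children with probability
#' 0.5. Children are repaired before return. Uses the caller's RNG stream.
#'
#' @param a,b Parent bit vectors of equal length.
#' @param rate Crossover rate.
#' @param max_cardinality Repair cap.
#' @return List of two repaired children.
#' @export
uniform_crossover <- function(a, b, rate = 0.9, max_cardinality = 6) {
  if (length(a) != length(b)) stop("parents must have equal length")
  c1 <- as.integer(a); c2 <- as.integer(b)
  if (stats::runif(1) < rate) {
    swap <- stats::runif(length(a)) < 0.5
    tmp <- c1[swap]; c1[swap] <- c2[swap]; c2[swap] <- tmp
  }
  list(repair_chromosome(c1, max_cardinality),
       repair_chromosome(c2, max_cardinality))
}

#' Bit-flip mutation
#'
#' Each bit flips independently with probability `rate`; the result is
#' repaired. Uses the caller's RNG stream.
#'
#' @param bits Chromosome.
#' @param rate Per-bit flip probability.
#' @param max_cardinality Repair cap.
#' @return Repaired mutated chromosome.
#' @export
bitflip_mutate <- function(bits, rate = 0.05, max_cardinality = 6) {
  flip <- stats::runif(length(bits)) < rate
  repair_chromosome(as.integer(xor(bits, flip)), max_cardinality)
}

rank_and_crowd <- function(population) {
  fronts <- fast_nondominated_sort(population)
  for (r in seq_along(fronts)) {
    idx <- fronts[[r]]
    cd <- crowding_distance(lapply(population[idx], identity))
    for (k in seq_along(idx)) {
      population[[idx[k]]]$rank <- r
      population[[idx[k]]]$crowding <- cd[k]
    }
  }
  attr(population, "fronts") <- fronts
  population
}

# Per-objective champions used as elites (f1, f4, f2, f3 priority order so
# the accuracy and G-mean leaders always survive, keeping best-f1
# monotone across generations under memoized fitness).
elite_indices <- function(population, count) {
  M <- objectives_matrix(population)
  pick <- function(col, dir) {
    v <- M[, col] * dir
    best <- which(v == max(v))
    if (length(best) > 1) {
      cr <- vapply(population[best], function(i) i$crowding, numeric(1))
      best <- best[order(-cr)]
    }
    best[1]
  }
  order_cols <- list(c("f1", 1), c("f4", 1), c("f2", -1), c("f3", 1))
  idx <- integer(0)
  k <- 1
  while (length(idx) < count) {
    oc <- order_cols[[(k - 1) %% 4 + 1]]
    cand <- pick(oc[1], as.numeric(oc[2]))
    if (!(cand %in% idx)) idx <- c(idx, cand)
    k <- k + 1
    if (k > 4 && length(idx) < count) {
      # fill with best-crowding rank-1 members
      rest <- setdiff(order(vapply(population, function(i) i$rank, numeric(1)),
                            -vapply(population, function(i) i$crowding, numeric(1))),
                      idx)
      idx <- c(idx, rest[seq_len(count - length(idx))])
    }
  }
  idx[seq_len(count)]
}

#' Run the multi-objective genetic feature selection
#'
#' Evolutionary loop: evaluate, sort, crowd; copy the per-objective elites
#' unconditionally; fill the next generation with tournament-selected,
#' crossed-over, mutated (and repaired) offspring. Stops at the generation
#' limit or once the multiset of front-1 objective vectors (rounded to
#' 1e-6) has been unchanged for `stagnation_patience` consecutive
#' generations. Fully deterministic under `config$seed`.
#'
#' @param config A [moga_config()].
#' @param context A [fitness_context()].
#' @return An object of class `moga_result`: `front` (deduplicated rank-1
#'   individuals), `history` (per-generation best f1, front size),
#'   `generations_run`.
#' @export
run_moga <- function(config, context) {
  d <- length(context$cohort$schema$names)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(derive_seed(config$seed, 101L))
  pop <- lapply(seq_len(config$population_size), function(i) {
    bits <- as.integer(stats::runif(d) < 0.5)
    list(bits = repair_chromosome(bits, config$max_cardinality))
  })
  pop <- evaluate_population(pop, context)
  pop <- rank_and_crowd(pop)

  front_signature <- function(p) {
    f1idx <- attr(p, "fronts")[[1]]
    M <- round(objectives_matrix(p[f1idx]), 6)
    paste(sort(apply(M, 1, paste, collapse = ",")), collapse = ";")
  }
  sig <- front_signature(pop)
  stagnation <- 0L
  history <- data.frame(generation = 0L,
                        best_f1 = max(objectives_matrix(pop)[, "f1"]),
                        front_size = length(attr(pop, "fronts")[[1]]))
  gens_run <- 0L
  for (gen in seq_len(config$generations)) {
    if (context$feedback_mode == "on" && gen %% 5L == 1L) {
      refresh_archive(pop, context)
    }
    elites <- pop[elite_indices(pop, config$elitism_count)]
    offspring <- list()
    while (length(offspring) < config$population_size - config$elitism_count) {
      p1 <- tournament_select(pop, config$tournament_size)
      p2 <- tournament_select(pop, config$tournament_size)
      kids <- uniform_crossover(p1$bits, p2$bits, config$crossover_rate,
                                config$max_cardinality)
      for (kb in kids) {
        if (length(offspring) >= config$population_size - config$elitism_count) break
        mb <- bitflip_mutate(kb, config$mutation_rate, config$max_cardinality)
        offspring[[length(offspring) + 1L]] <- list(bits = mb)
      }
    }
    pop <- c(lapply(elites, function(e) list(bits = e$bits)), offspring)
    pop <- evaluate_population(pop, context)
    pop <- rank_and_crowd(pop)
    gens_run <- gen
    history <- rbind(history,
                     data.frame(generation = gen,
                                best_f1 = max(objectives_matrix(pop)[, "f1"]),
                                front_size = length(attr(pop, "fronts")[[1]])))
    new_sig <- front_signature(pop)
    if (identical(new_sig, sig)) stagnation <- stagnation + 1L else stagnation <- 0L
    sig <- new_sig
    if (stagnation >= config$stagnation_patience) break
  }
  f1idx <- attr(pop, "fronts")[[1]]
  front <- pop[f1idx]
  keys <- vapply(front, function(i) paste(i$bits, collapse = ""), character(1))
  front <- front[!duplicated(keys)]
  structure(list(front = front, history = history, generations_run = gens_run,
                 config = config),
            class = "moga_result")
}

# Refresh the semantic-feedback archive with the current per-objective
# champions' out-of-fold probability vectors.
refresh_archive <- function(population, context) {
  champs <- select_representative_subsets(population, k = 4)
  probs <- lapply(champs, function(ch) surrogate_cv_probs(ch$bits, context))
  keys <- vapply(champs, function(ch) paste(ch$bits, collapse = ""), character(1))
  context$archive <- probs[!duplicated(keys)]
  context$archive_version <- context$archive_version + 1L
  invisible(context)
}

#' Representative subsets from a Pareto front
#'
#' One champion per objective: best f1, lowest f2, best f3, best f4. Ties
#' break by larger crowding distance, then lexicographically smaller bits.
#' A front smaller than `k` yields repeated champions.
#'
#' @param front Evaluated front (list of individuals).
#' @param k Number of representatives (default 4).
#' @return List of `k` individuals.
#' @export
select_representative_subsets <- function(front, k = 4) {
  front <- unclass(front)
  attr(front, "fronts") <- NULL
  if (length(front) == 0) stop("empty front")
  M <- objectives_matrix(front)
  crowd <- vapply(front, function(i) {
    if (is.null(i$crowding)) 0 else i$crowding
  }, numeric(1))
  bitstr <- vapply(front, function(i) paste(i$bits, collapse = ""), character(1))
  pick <- function(col, dir) {
    v <- M[, col] * dir
    ord <- order(-v, -crowd, bitstr)
    ord[1]
  }
  cols <- list(c("f1", 1), c("f2", -1), c("f3", 1), c("f4", 1))
  idx <- vapply(seq_len(k), function(i) {
    oc <- cols[[(i - 1) %% 4 + 1]]
    pick(oc[1], as.numeric(oc[2]))
  }, integer(1))
  front[idx]
}

#' Fitness-derived ensemble weights
#'
#' Each champion's objective vector is min-max normalized over the champion
#' set (f2 inverted so that lower redundancy scores higher; an objective
#' constant across champions contributes a neutral 0.5); the per-champion
#' scalar is the mean of the normalized components and weights are the
#' scalars normalized to sum to 1. Degenerate (all-equal) inputs yield
#' uniform weights.
#'
#' @param champions Evaluated individuals (or an objectives matrix).
#' @return Nonnegative weight vector summing to 1.
#' @export
moga_weights <- function(champions) {
  M <- objectives_matrix(champions)
  K <- nrow(M)
  N <- matrix(0.5, K, ncol(M))
  for (j in seq_len(ncol(M))) {
    rng <- max(M[, j]) - min(M[, j])
    if (rng == 0) next
    N[, j] <- (M[, j] - min(M[, j])) / rng
    if (colnames(M)[j] == "f2") N[, j] <- 1 - N[, j]
  }
  s <- rowMeans(N)
  if (sum(s) == 0 || max(s) - min(s) < 1e-15) return(rep(1 / K, K))
  s / sum(s)
}
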