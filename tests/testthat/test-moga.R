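test_that("chromosomes decode to schema-ordered feature names", {
  sch <- cleveland_schema()
  bits <- c(1, 0, 1, 0, 1, 0, 0, 1, 1, 0, 0, 0, 1)
  expect_equal(decode_chromosome(bits, sch),
               c("age", "cp", "chol", "thalach", "exang", "thal"))
  expect_equal(decode_chromosome(rep(0, 13), sch), character(0))
  expect_equal(decode_chromosome(rep(1, 13), sch), sch$names)
  expect_error(decode_chromosome(rep(1, 12), sch), "length")
})

test_that("repair enforces the cardinality band without inventing bits", {
  set.seed(1)
  over <- c(rep(1L, 8), rep(0L, 5))
  r <- repair_chromosome(over, 6)
  expect_equal(sum(r), 6)
  expect_true(all(which(r == 1) %in% which(over == 1)))
  expect_equal(sum(repair_chromosome(rep(0L, 13), 6)), 1)
  ok <- c(rep(1L, 4), rep(0L, 9))
  expect_identical(repair_chromosome(ok, 6), ok)
})

test_that("redundancy objective is the mean absolute pairwise correlation", {
  X <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),  # exact copy (x2)
             g = c(1, 2, 3, 1, 2), s = c(0, 1, 0, 1, 0))
  coh <- cohort(X, c(0, 1, 0, 1, 0), toy_schema())
  expect_equal(f2_redundancy(c("a", "b"), coh), 1)
  expect_equal(f2_redundancy("a", coh), 0)

  # three mutually orthogonal columns
  Xo <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1),
              g = c(1, -1, -1, 1), s = c(0, 1, 0, 1))
  sch <- feature_schema(c("a", "b", "g", "s"),
                        c("continuous", "continuous", "continuous", "binary"))
  coho <- cohort(Xo, c(0, 1, 0, 1), sch)
  expect_lt(f2_redundancy(c("a", "b", "g"), coho), 1e-12)

  # zero-variance member contributes 0 to its pairs
  Xz <- cbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), g = c(1, 2, 1, 2), s = c(0, 1, 0, 1))
  cohz <- cohort(Xz, c(0, 1, 0, 1), toy_schema())
  expect_equal(f2_redundancy(c("a", "b"), cohz), 0)
})

test_that("interpretability objective averages the clinician map", {
  expect_equal(f3_interpretability(c("age", "sex", "chol", "trestbps")), 3)
  imap <- interpretability_map(c(x = 3, y = 2, z = 1))
  sch <- feature_schema(c("x", "y", "z"), rep("continuous", 3))
  expect_equal(f3_interpretability(c("x", "y", "z"), imap, sch), 2)
  expect_equal(f3_interpretability(c(1, 1, 1), imap, sch), 2)
  expect_error(f3_interpretability(character(0), imap, sch), "empty")
  expect_error(interpretability_map(c(x = 5)), "1, 2 or 3")
})

test_that("dominance follows the four directed objectives", {
  a <- c(f1 = 0.9, f2 = 0.1, f3 = 3.0, f4 = 0.9)
  b <- c(f1 = 0.8, f2 = 0.2, f3 = 2.0, f4 = 0.8)
  expect_true(dominates(a, b))
  expect_false(dominates(b, a))
  expect_false(dominates(a, a))
  c1 <- c(f1 = 0.9, f2 = 0.3, f3 = 2.0, f4 = 0.8)  # better f1, worse f2
  expect_false(dominates(c1, b))
  expect_false(dominates(b, c1))
})

test_that("fast non-dominated sorting matches a brute-force oracle", {
  # forced structure: one dominator
  M <- rbind(c(0.9, 0.1, 3, 0.9), c(0.5, 0.5, 2, 0.5), c(0.4, 0.6, 1, 0.4))
  colnames(M) <- c("f1", "f2", "f3", "f4")
  fr <- fast_nondominated_sort(M)
  expect_equal(fr[[1]], 1L)
  expect_length(fast_nondominated_sort(M[1, , drop = FALSE]), 1)

  set.seed(99)
  for (rep in 1:200) {
    m <- sample(2:50, 1)
    M <- random_objectives(m)
    got <- fast_nondominated_sort(M)
    want <- brute_nds(M)
    expect_equal(lapply(got, sort), lapply(want, sort))
  }
  # front 1 is mutually non-dominated
  M <- random_objectives(30)
  f1idx <- fast_nondominated_sort(M)[[1]]
  for (i in f1idx) for (j in f1idx)
    if (i != j) expect_false(dominates(M[i, ], M[j, ]))
})

test_that("crowding distance matches the reference and handles edge cases", {
  expect_equal(crowding_distance(random_objectives(2)), c(Inf, Inf))

  # three members equally spaced on one objective, others constant
  M <- cbind(f1 = c(0, 0.5, 1), f2 = 0.2, f3 = 2, f4 = 0.5)
  cd <- crowding_distance(M)
  expect_equal(cd[2], 1)
  expect_equal(cd[c(1, 3)], c(Inf, Inf))

  # constant objective contributes nothing
  Mc <- cbind(f1 = c(0, 0.4, 1), f2 = 0.3, f3 = 2, f4 = 0.5)
  expect_equal(crowding_distance(Mc)[2], (1 - 0) / 1)

  set.seed(7)
  for (rep in 1:50) {
    M <- random_objectives(sample(3:40, 1))
    expect_equal(crowding_distance(M), brute_crowding(M))
  }
})

test_that("tournament selection prefers rank then crowding, deterministically", {
  pop <- list(list(bits = c(1, 0), rank = 1, crowding = 0.5),
              list(bits = c(0, 1), rank = 2, crowding = Inf),
              list(bits = c(1, 1), rank = 3, crowding = Inf))
  set.seed(5)
  win <- tournament_select(pop, size = 3)
  expect_equal(win$rank, 1)

  tie <- list(list(bits = c(1, 0), rank = 1, crowding = Inf),
              list(bits = c(0, 1), rank = 1, crowding = 0.4))
  set.seed(5)
  expect_equal(tournament_select(tie, size = 2)$crowding, Inf)

  seq1 <- {set.seed(3); replicate(20, sum(tournament_select(pop, 2)$bits))}
  seq2 <- {set.seed(3); replicate(20, sum(tournament_select(pop, 2)$bits))}
  expect_identical(seq1, seq2)
})

test_that("uniform crossover copies at rate 0 and swaps positions fairly", {
  a <- c(rep(1L, 6), rep(0L, 7)); b <- rev(a)
  set.seed(1)
  kids <- uniform_crossover(a, b, rate = 0, max_cardinality = 13)
  expect_identical(kids[[1]], a)
  expect_identical(kids[[2]], b)

  set.seed(2)
  same <- uniform_crossover(a, a, rate = 1, max_cardinality = 13)
  expect_identical(same[[1]], a)
  expect_identical(same[[2]], a)

  # complementary parents, no repair interference (cap 13): per-position
  # swap frequency ~ Bernoulli(0.5)
  comp <- 1L - a
  set.seed(11)
  swaps <- matrix(0L, 0, 13)
  for (i in 1:10000) {
    k <- uniform_crossover(a, comp, rate = 1, max_cardinality = 13)
    swaps <- rbind(swaps, as.integer(k[[1]] != a))
  }
  freq <- colMeans(swaps)
  expect_true(all(abs(freq - 0.5) < 0.02))
  expect_error(uniform_crossover(a, a[-1]), "equal length")
})

test_that("bit-flip mutation has the right flip mass and limits", {
  bits <- c(rep(1L, 6), rep(0L, 7))
  set.seed(1)
  expect_identical(bitflip_mutate(bits, 0, 13), bits)
  set.seed(2)
  expect_identical(bitflip_mutate(bits, 1, 13), 1L - bits)
  set.seed(3)
  flips <- replicate(10000, sum(bitflip_mutate(bits, 0.05, 13) != bits))
  expect_lt(abs(mean(flips) - 0.65), 0.03)
})

test_that("evaluation is memoized and feedback with an empty archive is a no-op", {
  sc <- small_signal_cohort()
  ctx_off <- fitness_context(sc, seed = 4)
  ctx_on <- fitness_context(sc, feedback_mode = "on", seed = 4)
  bits <- as_bits_vec <- c(1L, 0L, 0L, 1L, 0L, 0L, 0L, 1L, 0L, 1L, 0L, 0L, 0L)
  pop <- list(list(bits = bits), list(bits = bits))
  ev <- evaluate_population(pop, ctx_off)
  expect_identical(ev[[1]]$objectives, ev[[2]]$objectives)
  expect_equal(evaluate_population(list(list(bits = bits)), ctx_on)[[1]]$objectives,
               ev[[1]]$objectives)
  expect_error(f1_accuracy(rep(0L, 13), ctx_off), "empty")
})

test_that("the GA is deterministic, respects caps, honors stagnation, and keeps the f1 elite", {
  sc <- small_signal_cohort()
  cfg <- moga_config(population_size = 12, generations = 6,
                     stagnation_patience = 3, seed = 77)
  r1 <- run_moga(cfg, fitness_context(sc, seed = 13))
  r2 <- run_moga(cfg, fitness_context(sc, seed = 13))
  expect_identical(lapply(r1$front, `[[`, "bits"), lapply(r2$front, `[[`, "bits"))
  expect_identical(r1$history, r2$history)

  for (ind in r1$front) {
    expect_gte(sum(ind$bits), 1)
    expect_lte(sum(ind$bits), cfg$max_cardinality)
  }
  # front-1 mutually non-dominated
  for (i in seq_along(r1$front)) for (j in seq_along(r1$front))
    if (i != j) expect_false(dominates(r1$front[[i]]$objectives,
                                       r1$front[[j]]$objectives))
  # elitism keeps best f1 monotone
  expect_true(all(diff(r1$history$best_f1) >= -1e-12))

  cfg0 <- moga_config(population_size = 10, generations = 50,
                      stagnation_patience = 0, seed = 5)
  r0 <- run_moga(cfg0, fitness_context(sc, seed = 13))
  expect_equal(r0$generations_run, 1)
})

test_that("with a single active objective the GA reduces to an accuracy argmax", {
  sc <- small_signal_cohort()
  ctx <- fitness_context(sc, objectives = "f1", seed = 19)
  cfg <- moga_config(population_size = 14, generations = 8,
                     stagnation_patience = 4, seed = 3)
  res <- run_moga(cfg, ctx)
  f1s <- vapply(res$front, function(i) i$objectives[["f1"]], numeric(1))
  expect_true(all(abs(f1s - max(f1s)) < 1e-12))
})

test_that("semantic feedback populates the archive and stays deterministic", {
  sc <- small_signal_cohort()
  cfg <- moga_config(population_size = 10, generations = 6,
                     stagnation_patience = 3, seed = 31)
  ctx1 <- fitness_context(sc, feedback_mode = "on", seed = 13)
  r1 <- run_moga(cfg, ctx1)
  expect_gt(ctx1$archive_version, 0)             # archive refreshed
  expect_gt(length(ctx1$archive), 0)
  for (p in ctx1$archive) {
    expect_length(p, nrow(sc$X))
    expect_true(all(p > 0 & p < 1))
  }
  ctx2 <- fitness_context(sc, feedback_mode = "on", seed = 13)
  r2 <- run_moga(cfg, ctx2)
  expect_identical(lapply(r1$front, `[[`, "bits"),
                   lapply(r2$front, `[[`, "bits"))
  # fused evaluation differs from the archive-free evaluation in general
  ctx_off <- fitness_context(sc, seed = 13)
  bits <- r1$front[[1]]$bits
  expect_true(is.finite(f1_accuracy(bits, ctx1)))
  expect_true(is.finite(f1_accuracy(bits, ctx_off)))
})

test_that("schema YAML round-trips through read_schema/write_schema", {
  p <- tempfile(fileext = ".yaml")
  write_schema(cleveland_schema(), p)
  back <- read_schema(p)
  expect_equal(back$names, cleveland_schema()$names)
  expect_equal(back$kinds, cleveland_schema()$kinds)
  expect_equal(back$levels, cleveland_schema()$levels)
  expect_equal(back$label_name, "target")
})

test_that("representative subsets are per-objective champions with stated tie-breaks", {
  mk <- function(bits, f1, f2, f3, f4, crowd = 0)
    list(bits = bits, objectives = c(f1 = f1, f2 = f2, f3 = f3, f4 = f4),
         crowding = crowd)
  single <- list(mk(c(1, 0, 1), 0.8, 0.2, 2, 0.7))
  reps <- select_representative_subsets(single)
  expect_length(reps, 4)
  expect_identical(reps[[1]]$bits, reps[[4]]$bits)

  front <- list(mk(c(1, 0, 0), 0.9, 0.5, 1, 0.5),    # best f1
                mk(c(0, 1, 0), 0.5, 0.0, 1, 0.5),    # best f2 (lowest)
                mk(c(0, 0, 1), 0.5, 0.5, 3, 0.5),    # best f3
                mk(c(1, 1, 0), 0.5, 0.5, 1, 0.9))    # best f4
  reps <- select_representative_subsets(front)
  expect_identical(lapply(reps, `[[`, "bits"),
                   lapply(front, `[[`, "bits"))

  tied <- list(mk(c(1, 0, 0), 0.9, 0.2, 2, 0.7, crowd = Inf),
               mk(c(0, 1, 0), 0.9, 0.1, 2, 0.7, crowd = 0.2))
  expect_identical(select_representative_subsets(tied)[[1]]$crowding, Inf)
  expect_error(select_representative_subsets(list()), "empty")
})

test_that("fitness-derived weights normalize, reward dominance, degrade to uniform", {
  mk <- function(f1, f2, f3, f4) list(bits = c(1, 0),
    objectives = c(f1 = f1, f2 = f2, f3 = f3, f4 = f4))
  same <- replicate(4, mk(0.8, 0.2, 2, 0.7), simplify = FALSE)
  expect_equal(moga_weights(same), rep(0.25, 4))

  set.seed(8)
  for (rep in 1:20) {
    ch <- replicate(4, mk(runif(1), runif(1), runif(1, 1, 3), runif(1)),
                    simplify = FALSE)
    w <- moga_weights(ch)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
  dom <- list(mk(0.95, 0.05, 3, 0.95), mk(0.7, 0.3, 2, 0.7),
              mk(0.6, 0.4, 1.5, 0.6), mk(0.65, 0.35, 1.8, 0.66))
  w <- moga_weights(dom)
  expect_equal(which.max(w), 1L)
})
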