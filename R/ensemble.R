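#' Uniform fusion of member probabilities
#'
#' Column-wise arithmetic mean of the K member probability rows.
#'
#' @param member_probs K x n matrix (rows = members).
#' @return Length-n fused probabilities.
#' @export
uniform_fuse <- function(member_probs) {
  member_probs <- as.matrix(member_probs)
  if (nrow(member_probs) == 0) stop("no ensemble members")
  colMeans(member_probs)
}

#' Weighted fusion of member probabilities
#'
#' @param member_probs K x n matrix.
#' @param weights Nonnegative weights of length K summing to 1.
#' @return Length-n fused probabilities (a convex combination, so always
#'   between the member-wise min and max).
#' @export
weighted_fuse <- function(member_probs, weights) {
  member_probs <- as.matrix(member_probs)
  if (length(weights) != nrow(member_probs))
    stop("weights length must match member count")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be nonnegative and sum to 1")
  as.numeric(t(member_probs) %*% weights)
}

#' Fit AdaBoost coefficients over a fixed pool of trained members
#'
#' Boosting over a fixed hypothesis pool: instance weights start uniform,
#' each round selects the member with minimal weighted error of its
#' 0.5-thresholded predictions (members are reusable across rounds), the
#' round weight is `alpha = 0.5 log((1 - eps)/eps)` with `eps` clipped to
#' `[1e-10, 1 - 1e-10]`, and instance weights are multiplied by
#' `exp(-alpha y h(x))` (labels in \{-1, +1\} internally) and renormalized.
#' The loop stops early once every member has weighted error >= 0.5.
#'
#' @param member_probs K x n matrix of member probabilities on the
#'   training data.
#' @param y Training 0/1 labels, length n.
#' @param rounds Number of boosting rounds T (default 10).
#' @return An `adaboost_state`: `rounds` data frame (member, eps, alpha)
#'   and final distribution `D`.
#' @export
adaboost_fit <- function(member_probs, y, rounds = 10) {
  member_probs <- as.matrix(member_probs)
  K <- nrow(member_probs)
  if (K == 0) stop("no ensemble members")
  n <- ncol(member_probs)
  y_pm <- ifelse(as.integer(y) == 1L, 1, -1)
  H <- ifelse(member_probs >= 0.5, 1, -1)        # K x n member votes
  D <- rep(1 / n, n)
  log <- data.frame(member = integer(), eps = numeric(), alpha = numeric())
  for (t in seq_len(rounds)) {
    errs <- apply(H, 1, function(h) sum(D[h != y_pm]))
    if (all(errs >= 0.5)) break
    m <- which.min(errs)
    eps <- min(max(errs[m], 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - eps) / eps)
    D <- D * exp(-alpha * y_pm * H[m, ])
    D <- D / sum(D)
    log <- rbind(log, data.frame(member = m, eps = eps, alpha = alpha))
  }
  structure(list(rounds = log, D = D), class = "adaboost_state")
}

#' AdaBoost ensemble prediction
#'
#' `score(x) = sum_t alpha_t h_t(x)` with member votes in \{-1, +1\};
#' the label is `sign(score)` with a zero score resolved to the positive
#' class, and `sigma(score)` gives the probabilistic form.
#'
#' @param member_probs K x n matrix of member probabilities on the data to
#'   score.
#' @param state An `adaboost_state`.
#' @return List with `label` (0/1), `score`, and `prob` (`sigma(score)`).
#' @export
adaboost_predict <- function(member_probs, state) {
  member_probs <- as.matrix(member_probs)
  if (nrow(state$rounds) == 0) stop("empty AdaBoost state")
  H <- ifelse(member_probs >= 0.5, 1, -1)
  score <- rep(0, ncol(member_probs))
  for (r in seq_len(nrow(state$rounds))) {
    score <- score + state$rounds$alpha[r] * H[state$rounds$member[r], ]
  }
  list(label = as.integer(score >= 0), score = score,
       prob = 1 / (1 + exp(-score)))
}

#' Build the MLP ensemble from representative subsets
#'
#' Trains one regularized MLP per champion on that champion's columns only
#' (with one-hot expansion of selected categoricals), then attaches the
#' requested fusion: uniform averaging, fitness-derived weighting via
#' [moga_weights()], or AdaBoost coefficients fitted on the training
#' predictions.
#'
#' @param cohort Preprocessed training `cohort`.
#' @param champions List of evaluated individuals (chromosome + objective
#'   vector), typically from [select_representative_subsets()].
#' @param fusion `"uniform"`, `"weighted"` or `"adaboost"`.
#' @param epochs,dropout_rate,early_stopping_patience Member training
#'   schedule (Table-style defaults).
#' @param adaboost_rounds Boosting rounds for adaboost fusion.
#' @param seed Integer seed; member k trains under a derived seed.
#' @return An `ensemble_model`.
#' @export
build_ensemble <- function(cohort, champions,
                           fusion = c("adaboost", "uniform", "weighted"),
                           epochs = 100, dropout_rate = 0.2,
                           early_stopping_patience = 10,
                           adaboost_rounds = 10, seed = 1L) {
  fusion <- match.arg(fusion)
  if (length(champions) == 0) stop("no champions supplied")
  members <- list()
  for (k in seq_along(champions)) {
    feats <- decode_chromosome(champions[[k]]$bits, cohort$schema)
    X <- design_matrix(cohort, feats)
    spec <- mlp_spec(n_in = ncol(X), epochs = epochs,
                     dropout_rate = dropout_rate,
                     early_stopping_patience = early_stopping_patience,
                     seed = derive_seed(seed, 1000L + k))
    fit <- train_mlp(spec, X, cohort$y)
    members[[k]] <- list(mlp = fit, features = feats,
                         bits = champions[[k]]$bits,
                         objectives = champions[[k]]$objectives)
  }
  model <- structure(list(members = members, fusion = fusion,
                          weights = NULL, boost = NULL,
                          decision_threshold = 0.5,
                          schema = cohort$schema),
                     class = "ensemble_model")
  if (fusion == "weighted") {
    has_obj <- !vapply(champions, function(c) is.null(c$objectives), logical(1))
    if (!all(has_obj)) stop("weighted fusion needs evaluated champions")
    model$weights <- moga_weights(champions)
  } else if (fusion == "adaboost") {
    P <- member_probs(model, cohort)
    model$boost <- adaboost_fit(P, cohort$y, rounds = adaboost_rounds)
  }
  model
}

# K x n matrix of member probabilities on a cohort.
member_probs <- function(model, cohort) {
  do.call(rbind, lapply(model$members, function(m) {
    mlp_forward(m$mlp, design_matrix(cohort, m$features))
  }))
}

#' Predict with an ensemble model
#'
#' @param object An `ensemble_model`.
#' @param newdata A `cohort` preprocessed like the training data.
#' @param type `"prob"` or `"class"`.
#' @param ... Unused.
#' @return Probabilities or 0/1 labels.
#' @export
predict.ensemble_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  P <- member_probs(object, newdata)
  p <- switch(object$fusion,
    uniform = uniform_fuse(P),
    weighted = weighted_fuse(P, object$weights),
    adaboost = adaboost_predict(P, object$boost)$prob
  )
  if (type == "prob") p else {
    if (object$fusion == "adaboost") adaboost_predict(P, object$boost)$label
    else as.integer(p >= object$decision_threshold)
  }
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model> ", length(x$members), " members, fusion = ",
      x$fusion, "\n", sep = "")
  for (m in x$members)
    cat("  [", paste(m$features, collapse = ", "), "]\n", sep = "")
  invisible(x)
}
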