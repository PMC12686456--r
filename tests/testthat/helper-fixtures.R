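# Shared fixtures and slow-but-obviously-correct reference implementations
# used as oracles.

# A tiny hand-built cohort over a 4-feature schema (2 continuous, 1
# categorical, 1 binary).
toy_schema <- function() {
  feature_schema(
    names = c("a", "b", "g", "s"),
    kinds = c("continuous", "continuous", "categorical", "binary"),
    levels = list(g = c(1, 2, 3))
  )
}

toy_cohort <- function() {
  X <- cbind(a = c(1, 2, 3, 4), b = c(10, 20, 30, 40),
             g = c(1, 2, 3, 1), s = c(0, 1, 0, 1))
  cohort(X, c(0, 1, 0, 1), toy_schema())
}

# Write a small Cleveland-format CSV (13 features + target) with optional
# "?" cells; returns the path.
write_cleveland_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- c(cleveland_schema()$names, "target")
  writeLines(c(paste(header, collapse = ","), rows), path)
  path
}

# Three plausible Cleveland-like rows (values in UCI ranges).
cleveland_rows <- function() c(
  "63,1,1,145,233,1,2,150,0,2.3,3,0,6,0",
  "67,1,4,160,286,0,2,108,1,1.5,2,3,3,1",
  "41,0,2,130,204,0,2,172,0,1.4,1,0,3,0"
)

# Synthetic rows in the UCI "processed" dialect (no header, "?" markers,
# 0-4 outcome codes). Entirely synthetic stand-ins for parser tests.
synthetic_uci_lines <- function() c(
  "63.0,1.0,1.0,145.0,233.0,1.0,2.0,150.0,0.0,2.3,3.0,0.0,6.0,0",
  "67.0,1.0,4.0,160.0,286.0,0.0,2.0,108.0,1.0,1.5,2.0,3.0,3.0,2",
  "41.0,0.0,2.0,130.0,204.0,0.0,2.0,172.0,0.0,1.4,1.0,?,3.0,1",
  "56.0,1.0,3.0,130.0,256.0,1.0,2.0,142.0,1.0,0.6,2.0,1.0,?,3",
  "57.0,0.0,4.0,120.0,354.0,0.0,0.0,163.0,1.0,0.6,1.0,0.0,3.0,0"
)

# Brute-force non-dominated sorting: repeatedly remove the set of
# individuals not dominated by any remaining individual.
brute_nds <- function(M) {
  remaining <- seq_len(nrow(M))
  fronts <- list()
  while (length(remaining)) {
    nd <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j)
        j != i && dominates(M[j, ], M[i, ]), logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1L]] <- nd
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

# Literal reference crowding distance.
brute_crowding <- function(M) {
  m <- nrow(M)
  if (m <= 2) return(rep(Inf, m))
  out <- numeric(m)
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    if (max(v) == min(v)) next
    ord <- order(v)
    out[ord[1]] <- out[ord[m]] <- Inf
    for (k in 2:(m - 1))
      out[ord[k]] <- out[ord[k]] + (v[ord[k + 1]] - v[ord[k - 1]]) / (max(v) - min(v))
  }
  out
}

# All-pairs Mann-Whitney AUC.
brute_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

random_objectives <- function(m) {
  cbind(f1 = runif(m), f2 = runif(m), f3 = runif(m, 1, 3), f4 = runif(m))
}

# Constant-probability stub model honoring the predict(model, cohort)
# contract that kfold_cv expects.
stub_model <- function(p) structure(list(p = p), class = "semogen_stub")
predict.semogen_stub <- function(object, newdata, type = "prob", ...) {
  p <- rep_len(object$p, nrow(newdata$X))
  if (identical(type, "class")) as.integer(p >= 0.5) else p
}
.S3method("predict", "semogen_stub", predict.semogen_stub)

# A small preprocessed planted-signal cohort for GA tests.
small_signal_cohort <- function(n = 150, seed = 11) {
  minmax_fit_transform(impute(generate_cohort(
    default_cohort_spec(n = n, seed = seed))))$cohort
}
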