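#' Impute missing cohort cells
#'
#' Continuous columns are filled with the mean or median of their observed
#' values; categorical and binary columns with the modal observed level,
#' ties broken by the first-encountered level in row order.
#'
#' @param x A `cohort`.
#' @param numeric_strategy `"mean"` or `"median"`.
#' @param categorical_strategy `"mode"` (the only supported strategy).
#' @return A `cohort` with no missing cells.
#' @export
impute <- function(x, numeric_strategy = c("mean", "median"),
                   categorical_strategy = "mode") {
  numeric_strategy <- match.arg(numeric_strategy)
  stopifnot(identical(categorical_strategy, "mode"))
  X <- x$X
  for (j in seq_along(x$schema$names)) {
    miss <- x$missing_mask[, j]
    if (!any(miss)) next
    obs <- X[!miss, j]
    if (length(obs) == 0)
      stop("unimputable: column '", x$schema$names[j], "' is fully missing")
    if (x$schema$kinds[j] == "continuous") {
      fill <- if (numeric_strategy == "mean") mean(obs) else stats::median(obs)
    } else {
      lv <- unique(obs)                      # first-encountered order
      fill <- lv[which.max(tabulate(match(obs, lv)))]
    }
    X[miss, j] <- fill
  }
  cohort(X, x$y, x$schema, matrix(FALSE, nrow(X), ncol(X)))
}

#' Min-max scale the continuous features
#'
#' When `fitted` is absent, per-feature min and max are learned so that the
#' fitting split maps onto \[0, 1\]; a constant column maps to 0. When prior
#' parameters are supplied they are applied as-is and out-of-range values
#' are deliberately not clipped, so transformed data may fall outside
#' \[0, 1\]. Categorical and binary columns are untouched.
#'
#' @param x A `cohort` with no missing continuous cells.
#' @param fitted Optional `scaler_params` from a previous fit.
#' @return A list with elements `cohort` and `params`.
#' @export
minmax_fit_transform <- function(x, fitted = NULL) {
  cont <- which(x$schema$kinds == "continuous")
  if (any(x$missing_mask[, cont]))
    stop("continuous columns must be imputed before scaling")
  if (is.null(fitted)) {
    mins <- apply(x$X[, cont, drop = FALSE], 2, min)
    maxs <- apply(x$X[, cont, drop = FALSE], 2, max)
    fitted <- structure(list(features = x$schema$names[cont],
                             min = mins, max = maxs),
                        class = "scaler_params")
  } else {
    if (!identical(fitted$features, x$schema$names[cont]))
      stop("scaler params do not match the schema's continuous features")
  }
  X <- x$X
  for (k in seq_along(cont)) {
    j <- cont[k]
    rng <- fitted$max[k] - fitted$min[k]
    X[, j] <- if (rng == 0) 0 else (X[, j] - fitted$min[k]) / rng
  }
  list(cohort = cohort(X, x$y, x$schema, x$missing_mask), params = fitted)
}

#' One-hot encode multi-level categorical features
#'
#' Each categorical feature with three or more levels expands to one 0/1
#' indicator column per schema level, named `"<feature>=<level>"`; binary
#' features stay as a single column (expanding them would only add a
#' perfectly collinear complement). Exactly one indicator fires per original
#' categorical per row. A value outside the schema's levels is an error.
#'
#' @param x An imputed `cohort`.
#' @return A `cohort` whose schema holds the derived indicator columns
#'   (all of kind `"binary"`).
#' @export
one_hot <- function(x) {
  if (any(x$missing_mask)) stop("impute before one-hot encoding")
  cols <- list(); names_out <- character(); kinds_out <- character()
  for (j in seq_along(x$schema$names)) {
    nm <- x$schema$names[j]; kind <- x$schema$kinds[j]
    if (kind == "categorical" && length(x$schema$levels[[nm]]) >= 3) {
      lv <- x$schema$levels[[nm]]
      bad <- !(x$X[, j] %in% lv)
      if (any(bad))
        stop("unknown level ", x$X[which(bad)[1], j], " in feature '", nm, "'")
      for (l in lv) {
        cols[[length(cols) + 1L]] <- as.numeric(x$X[, j] == l)
        names_out <- c(names_out, paste0(nm, "=", format(l)))
        kinds_out <- c(kinds_out, "binary")
      }
    } else {
      cols[[length(cols) + 1L]] <- x$X[, j]
      names_out <- c(names_out, nm)
      kinds_out <- c(kinds_out, if (kind == "categorical") "binary" else kind)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names_out
  sch <- feature_schema(names_out, ifelse(kinds_out == "continuous", "continuous", "binary"),
                        label_name = x$schema$label_name)
  cohort(X, x$y, sch)
}

#' SMOTE minority oversampling
#'
#' Appends synthetic minority rows until the minority/majority ratio reaches
#' `target_ratio`. Each synthetic row interpolates a minority seed point x
#' towards one of its k nearest minority neighbours z (Euclidean distance on
#' the continuous columns): continuous cells become `x + u (z - x)` with
#' `u ~ U[0, 1]`; categorical and binary cells copy the seed point.
#'
#' @param x A `cohort` with scaled continuous features and no missing cells.
#' @param k Neighbour count (default 5).
#' @param target_ratio Desired minority/majority ratio (default 1).
#' @param seed Integer seed; the draw is byte-reproducible.
#' @return A `cohort` with the synthetic rows appended.
#' @export
smote <- function(x, k = 5, target_ratio = 1.0, seed = 1L) {
  if (any(x$missing_mask)) stop("impute before SMOTE")
  n1 <- sum(x$y == 1L); n0 <- sum(x$y == 0L)
  minority <- if (n1 <= n0) 1L else 0L
  n_min <- min(n1, n0); n_maj <- max(n1, n0)
  n_new <- round(target_ratio * n_maj) - n_min
  if (n_new <= 0) return(x)
  if (n_min <= k)
    stop("minority class has ", n_min, " members; SMOTE needs more than k = ", k)
  cont <- which(x$schema$kinds == "continuous")
  idx_min <- which(x$y == minority)
  M <- x$X[idx_min, cont, drop = FALSE]
  D <- as.matrix(stats::dist(M))
  diag(D) <- Inf
  nn <- do.call(rbind, lapply(seq_len(nrow(D)),
                              function(i) order(D[i, ])[seq_len(k)]))
  old_seed <- get_rng_state(); on.exit(restore_rng_state(old_seed))
  set.seed(seed)
  seeds <- sample(seq_along(idx_min), n_new, replace = TRUE)
  picks <- vapply(seeds, function(i) nn[i, sample.int(k, 1)], integer(1))
  u <- stats::runif(n_new)
  new_rows <- x$X[idx_min[seeds], , drop = FALSE]
  zc <- x$X[idx_min[picks], cont, drop = FALSE]
  new_rows[, cont] <- new_rows[, cont] + u * (zc - new_rows[, cont])
  X <- rbind(x$X, new_rows)
  y <- c(x$y, rep(minority, n_new))
  cohort(X, y, x$schema)
}

#' Stratum-wise statistical descriptor columns
#'
#' For every continuous feature and every stratum, appends the stratum's
#' mean, SD, min, max and IQR as constant-within-stratum columns
#' (`<feature>_mean`, ...); for every categorical/binary feature appends the
#' within-stratum relative frequency of the row's own level
#' (`<feature>_freq`). Quartiles use linear interpolation between order
#' statistics; a stratum with fewer than two rows gets SD 0. The default
#' stratification crosses age tertiles with sex when those features exist,
#' otherwise a single stratum.
#'
#' @param x An imputed `cohort`.
#' @param strata Optional factor/vector of length n defining the strata;
#'   `NULL` uses the default rule above.
#' @return A list with `cohort` (augmented; descriptor columns are appended
#'   to the schema as continuous) and `strata` (the grouping used).
#' @export
statistical_descriptors <- function(x, strata = NULL) {
  if (any(x$missing_mask)) stop("impute before computing descriptors")
  n <- nrow(x$X)
  if (is.null(strata)) {
    if (all(c("age", "sex") %in% x$schema$names)) {
      age <- x$X[, "age"]
      br <- unique(stats::quantile(age, c(0, 1/3, 2/3, 1), type = 7))
      tert <- cut(age, breaks = br, include.lowest = TRUE, labels = FALSE)
      strata <- interaction(tert, x$X[, "sex"], drop = TRUE)
    } else {
      strata <- factor(rep(1L, n))
    }
  }
  strata <- factor(strata)
  if (length(strata) != n) stop("strata must have one entry per row")
  cols <- list(); nms <- character()
  for (j in seq_along(x$schema$names)) {
    nm <- x$schema$names[j]
    v <- x$X[, j]
    if (x$schema$kinds[j] == "continuous") {
      stats_by <- lapply(split(v, strata), function(g) {
        c(mean = mean(g),
          sd = if (length(g) < 2) 0 else stats::sd(g),
          min = min(g), max = max(g),
          iqr = unname(stats::quantile(g, 0.75, type = 7) -
                       stats::quantile(g, 0.25, type = 7)))
      })
      mat <- do.call(rbind, stats_by)[as.integer(strata), , drop = FALSE]
      for (s in c("mean", "sd", "min", "max", "iqr")) {
        cols[[length(cols) + 1L]] <- unname(mat[, s])
        nms <- c(nms, paste0(nm, "_", s))
      }
    } else {
      freq <- numeric(n)
      for (g in levels(strata)) {
        sel <- strata == g
        tab <- table(v[sel]) / sum(sel)
        freq[sel] <- as.numeric(tab[as.character(v[sel])])
      }
      cols[[length(cols) + 1L]] <- freq
      nms <- c(nms, paste0(nm, "_freq"))
    }
  }
  Xd <- do.call(cbind, cols)
  colnames(Xd) <- nms
  sch <- feature_schema(c(x$schema$names, nms),
                        c(x$schema$kinds, rep("continuous", length(nms))),
                        levels = x$schema$levels,
                        label_name = x$schema$label_name)
  list(cohort = cohort(cbind(x$X, Xd), x$y, sch), strata = strata)
}

#' Model design matrix for a feature subset
#'
#' Builds the numeric input matrix an MLP consumes: continuous and binary
#' columns pass through; each selected multi-level categorical expands to
#' its one-hot indicators. Expansion happens after subset selection, so the
#' input width can exceed the number of selected base features.
#'
#' @param x A `cohort` (imputed, scaled).
#' @param features Character vector of base feature names to include.
#' @return Numeric matrix with one column per derived input.
#' @export
design_matrix <- function(x, features) {
  if (length(features) == 0) stop("empty feature subset")
  bad <- setdiff(features, x$schema$names)
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  cols <- list(); nms <- character()
  for (nm in features) {
    j <- match(nm, x$schema$names)
    if (x$schema$kinds[j] == "categorical" && length(x$schema$levels[[nm]]) >= 3) {
      for (l in x$schema$levels[[nm]]) {
        cols[[length(cols) + 1L]] <- as.numeric(x$X[, j] == l)
        nms <- c(nms, paste0(nm, "=", format(l)))
      }
    } else {
      cols[[length(cols) + 1L]] <- x$X[, j]
      nms <- c(nms, nm)
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nms
  m
}
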