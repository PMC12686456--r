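#' Specification for a synthetic Cleveland-like cohort
#'
#' Describes a generator with known ground truth: labels are Bernoulli with
#' the given prevalence; each continuous feature is class-conditionally
#' Normal with unit variance and a stated standardized mean shift between
#' classes; a redundant pair replaces the copy feature's standardized values
#' with `rho * z_source + sqrt(1 - rho^2) * noise`; categorical features are
#' drawn from class-conditional level probabilities.
#'
#' @param n Row count (>= 10).
#' @param prevalence P(y = 1), in (0, 1).
#' @param schema A `feature_schema` (defaults to [cleveland_schema()]).
#' @param informative Named numeric vector of standardized mean shifts for
#'   continuous features (unlisted continuous features shift 0).
#' @param redundant_pairs List of `list(source=, copy=, rho=)` entries;
#'   `copy` must be continuous and its values are rebuilt from `source`.
#' @param categorical_specs Named list; each element is a 2-row matrix of
#'   class-conditional level probabilities (row 1 = class 0, row 2 = class
#'   1, columns follow the schema's levels). Unlisted categoricals are
#'   uniform; binary features may appear with two columns for levels 0/1.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, prevalence, schema = cleveland_schema(),
                        informative = numeric(), redundant_pairs = list(),
                        categorical_specs = list(), seed = 1L) {
  if (n < 10) stop("too small: n must be >= 10")
  if (!(prevalence > 0 && prevalence < 1)) stop("prevalence must be in (0,1)")
  if (length(informative) && !all(is.finite(informative)))
    stop("shifts must be finite")
  cont <- schema$names[schema$kinds == "continuous"]
  bad <- setdiff(names(informative), cont)
  if (length(bad)) stop("informative features must be continuous: ",
                        paste(bad, collapse = ", "))
  for (p in redundant_pairs) {
    if (!all(c("source", "copy") %in% names(p)) || is.null(p$rho))
      stop("redundant pair needs source, copy, rho")
    if (abs(p$rho) > 1) stop("rho must lie in [-1, 1]")
    if (!all(c(p$source, p$copy) %in% cont))
      stop("redundant pair members must be continuous features")
  }
  for (nm in names(categorical_specs)) {
    pm <- categorical_specs[[nm]]
    if (any(abs(rowSums(pm) - 1) > 1e-8))
      stop("level probabilities for '", nm, "' must sum to 1 per class")
  }
  structure(list(n = as.integer(n), prevalence = prevalence, schema = schema,
                 informative = informative, redundant_pairs = redundant_pairs,
                 categorical_specs = categorical_specs, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default planted-signal cohort specification
#'
#' Mimics the Cleveland data's shape: 303 rows at prevalence 165/303, 13
#' features (5 continuous, 8 categorical/binary). The planted signal sits
#' in exactly five continuous features with standardized class shifts
#' spread over 0.3-0.9 SD (oldpeak 0.9, thalach 0.75, age 0.6, chol 0.45,
#' trestbps 0.3), and trestbps is rebuilt as a rho = 0.9 redundant copy of
#' oldpeak, inheriting most of its signal through the correlation.
#' Categorical and binary features are drawn uniformly with no class
#' association, so ground truth stays unambiguous for recovery tests;
#' class-conditional level tilts can be planted via `categorical_specs`.
#'
#' @param n Row count.
#' @param prevalence P(y = 1).
#' @param categorical_specs Optional class-conditional level probabilities
#'   (see [cohort_spec()]).
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(n = 303, prevalence = 165 / 303,
                                categorical_specs = list(), seed = 1L) {
  cohort_spec(
    n = n, prevalence = prevalence, schema = cleveland_schema(),
    informative = c(oldpeak = 0.9, thalach = 0.75, age = 0.6,
                    chol = 0.45, trestbps = 0.3),
    redundant_pairs = list(list(source = "oldpeak", copy = "trestbps", rho = 0.9)),
    categorical_specs = categorical_specs,
    seed = seed
  )
}

#' Generate a synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return A [cohort()] with no missing cells. Deterministic under
#'   `spec$seed`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sch <- spec$schema
  n <- spec$n
  with_seed(spec$seed, {
    y <- stats::rbinom(n, 1, spec$prevalence)
    d <- length(sch$names)
    X <- matrix(0, n, d, dimnames = list(NULL, sch$names))
    noise <- list()   # standardized noise component per continuous feature
    for (j in seq_len(d)) {
      nm <- sch$names[j]; kind <- sch$kinds[j]
      if (kind == "continuous") {
        shift <- if (nm %in% names(spec$informative)) spec$informative[[nm]] else 0
        e <- stats::rnorm(n)
        noise[[nm]] <- e
        X[, j] <- shift * y + e
      } else {
        lv <- if (kind == "binary") c(0, 1) else sch$levels[[nm]]
        pm <- spec$categorical_specs[[nm]]
        if (is.null(pm)) pm <- rbind(rep(1 / length(lv), length(lv)),
                                     rep(1 / length(lv), length(lv)))
        draw <- function(cls, m) {
          if (m == 0) return(numeric(0))
          lv[sample.int(length(lv), m, replace = TRUE, prob = pm[cls + 1L, ])]
        }
        v <- numeric(n)
        v[y == 0] <- draw(0L, sum(y == 0))
        v[y == 1] <- draw(1L, sum(y == 1))
        X[, j] <- v
      }
    }
    # redundant copies: rebuild the copy from the source's standardized values
    for (p in spec$redundant_pairs) {
      zsrc <- as.numeric(scale(X[, p$source]))
      eps <- stats::rnorm(n)
      X[, p$copy] <- p$rho * zsrc + sqrt(1 - p$rho^2) * eps
    }
    cohort(X, y, sch)
  })
}

#' Perturbation specification for robustness stress tests
#'
#' @param mode `"gaussian_noise"` or `"missing"`.
#' @param fraction Share of eligible cells affected, in \[0, 1\].
#' @param noise_scale Noise SD as a multiple of the per-feature SD
#'   (gaussian mode only).
#' @param seed Integer seed.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(mode = c("gaussian_noise", "missing"),
                              fraction, noise_scale = 1.0, seed = 1L) {
  mode <- match.arg(mode)
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  structure(list(mode = mode, fraction = fraction,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Inject additive Gaussian noise into continuous cells
#'
#' A Bernoulli(`fraction`) mask selects continuous cells; each selected cell
#' receives additive Normal(0, (noise_scale * SD_feature)^2) noise, where
#' SD_feature is the feature's sample SD. Categorical cells are untouched.
#'
#' @param x A `cohort`.
#' @param p A `perturbation_spec` with mode `"gaussian_noise"`.
#' @return A perturbed `cohort`. Deterministic under `p$seed`.
#' @export
inject_gaussian_noise <- function(x, p) {
  stopifnot(inherits(p, "perturbation_spec"), p$mode == "gaussian_noise")
  if (p$fraction == 0 || p$noise_scale == 0) return(x)
  cont <- which(x$schema$kinds == "continuous")
  X <- x$X
  with_seed(p$seed, {
    for (j in cont) {
      sdj <- stats::sd(X[, j], na.rm = TRUE)
      hit <- stats::runif(nrow(X)) < p$fraction
      hit <- hit & !x$missing_mask[, j]
      X[hit, j] <- X[hit, j] + stats::rnorm(sum(hit), 0, p$noise_scale * sdj)
    }
  })
  cohort(X, x$y, x$schema, x$missing_mask)
}

#' Inject missing-completely-at-random cells
#'
#' A Bernoulli(`fraction`) mask over all feature cells marks them missing
#' (value set to `NA`, `missing_mask` set); recover values via [impute()].
#'
#' @param x A `cohort`.
#' @param p A `perturbation_spec` with mode `"missing"`.
#' @return A `cohort` with enlarged missing mask. Deterministic under
#'   `p$seed`.
#' @export
inject_missingness <- function(x, p) {
  stopifnot(inherits(p, "perturbation_spec"), p$mode == "missing")
  if (p$fraction >= 1)
    stop("fraction 1 would produce fully missing columns")
  if (p$fraction == 0) return(x)
  X <- x$X; mask <- x$missing_mask
  with_seed(p$seed, {
    hit <- matrix(stats::runif(length(X)) < p$fraction, nrow(X), ncol(X))
  })
  mask <- mask | hit
  X[hit] <- NA_real_
  cohort(X, x$y, x$schema, mask)
}
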