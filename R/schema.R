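#' Feature schema for a tabular clinical cohort
#'
#' A schema names the candidate features in a fixed order, declares each
#' feature's kind, and lists the admissible level codes for categorical
#' features. The binary outcome column is named separately and is never part
#' of the feature list.
#'
#' @param names Character vector of unique feature names, in column order.
#' @param kinds Character vector, one of `"continuous"`, `"categorical"`,
#'   `"binary"` per feature.
#' @param levels Named list mapping each categorical feature to its numeric
#'   level codes (at least two). Binary features are implicitly `c(0, 1)`.
#' @param label_name Name of the 0/1 outcome column.
#' @return An object of class `feature_schema`.
#' @export
feature_schema <- function(names, kinds, levels = list(), label_name = "target") {
  names <- as.character(names)
  kinds <- as.character(kinds)
  if (length(names) != length(kinds)) stop("names and kinds must have equal length")
  if (anyDuplicated(names)) stop("feature names must be unique")
  if (!all(kinds %in% c("continuous", "categorical", "binary")))
    stop("kinds must be continuous, categorical or binary")
  if (label_name %in% names) stop("label_name must not appear among feature names")
  cats <- names[kinds == "categorical"]
  missing_levels <- setdiff(cats, base::names(levels))
  if (length(missing_levels))
    stop("levels missing for categorical feature(s): ", paste(missing_levels, collapse = ", "))
  for (nm in cats) {
    if (length(levels[[nm]]) < 2) stop("categorical feature '", nm, "' needs >= 2 levels")
  }
  structure(
    list(names = names, kinds = kinds, levels = levels[cats], label_name = label_name),
    class = "feature_schema"
  )
}

#' The 13-feature Cleveland heart-disease schema
#'
#' Five continuous features (age, trestbps, chol, thalach, oldpeak), five
#' multi-level categoricals (cp, restecg, slope, ca, thal with their usual
#' UCI level codes) and three binaries (sex, fbs, exang). The outcome column
#' is `target` (1 = disease present).
#'
#' @return A `feature_schema`.
#' @export
cleveland_schema <- function() {
  feature_schema(
    names = c("age", "sex", "cp", "trestbps", "chol", "fbs", "restecg",
              "thalach", "exang", "oldpeak", "slope", "ca", "thal"),
    kinds = c("continuous", "binary", "categorical", "continuous", "continuous",
              "binary", "categorical", "continuous", "binary", "continuous",
              "categorical", "categorical", "categorical"),
    levels = list(
      cp      = c(1, 2, 3, 4),
      restecg = c(0, 1, 2),
      slope   = c(1, 2, 3),
      ca      = c(0, 1, 2, 3),
      thal    = c(3, 6, 7)
    ),
    label_name = "target"
  )
}

#' Read or write a schema as YAML
#'
#' @param path File path.
#' @return `read_schema` returns a `feature_schema`; `write_schema` returns
#'   `path` invisibly.
#' @export
read_schema <- function(path) {
  s <- yaml::read_yaml(path)
  feature_schema(s$names, s$kinds, lapply(s$levels, as.numeric),
                 label_name = if (is.null(s$label_name)) "target" else s$label_name)
}

#' @rdname read_schema
#' @param schema A `feature_schema`.
#' @export
write_schema <- function(schema, path) {
  yaml::write_yaml(list(names = schema$names, kinds = schema$kinds,
                        levels = schema$levels, label_name = schema$label_name),
                   path)
  invisible(path)
}

#' Interpretability scores for feature subsets
#'
#' Clinician-facing transparency scores on a 1-3 scale (3 = directly
#' interpretable bedside quantity, 2 = moderately interpretable, 1 = abstract
#' encoded measurement). The default map scores age, sex, chol and trestbps
#' as 3; thal, ca and slope as 2; restecg as 1; any feature not listed gets
#' `default_score`.
#'
#' @param scores Named numeric vector with values in \{1, 2, 3\}.
#' @param default_score Score for unlisted features.
#' @return An object of class `interpretability_map`.
#' @export
interpretability_map <- function(scores, default_score = 2) {
  scores <- unlist(scores)
  if (length(scores) && (is.null(names(scores)) || any(names(scores) == "")))
    stop("scores must be a named vector")
  if (!all(scores %in% 1:3) || !(default_score %in% 1:3))
    stop("interpretability scores must be 1, 2 or 3")
  structure(list(scores = scores, default_score = default_score),
            class = "interpretability_map")
}

#' @rdname interpretability_map
#' @export
default_interpretability_map <- function() {
  interpretability_map(
    c(age = 3, sex = 3, chol = 3, trestbps = 3,
      thal = 2, ca = 2, slope = 2, restecg = 1),
    default_score = 2
  )
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> ", length(x$names), " features, label '",
      x$label_name, "'\n", sep = "")
  cat(paste0("  ", format(x$names), "  ", x$kinds, collapse = "\n"), "\n")
  invisible(x)
}
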