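#' Construct a cohort object
#'
#' A cohort couples a numeric feature matrix `X` (columns in schema order,
#' categorical features stored as their level codes), a 0/1 outcome vector
#' `y`, the [feature_schema()], and a logical `missing_mask` marking cells
#' whose value is unobserved (those cells are `NA` in `X`).
#'
#' @param X Numeric matrix or data frame, n x d, column names matching
#'   `schema$names`.
#' @param y Integer vector of 0/1 labels, length n.
#' @param schema A `feature_schema`.
#' @param missing_mask Optional logical matrix, n x d; defaults to `is.na(X)`.
#' @return An object of class `cohort`.
#' @export
cohort <- function(X, y, schema, missing_mask = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 1) stop("cohort must contain at least one row")
  if (is.null(colnames(X))) colnames(X) <- schema$names
  if (!identical(colnames(X), schema$names))
    stop("column order of X must follow the schema")
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("y length must equal nrow(X)")
  if (!all(y %in% c(0L, 1L))) stop("y must contain only 0/1")
  if (is.null(missing_mask)) missing_mask <- is.na(X)
  missing_mask <- as.matrix(missing_mask)
  if (!identical(dim(missing_mask), dim(X)))
    stop("missing_mask must have the same dimensions as X")
  if (any(is.na(X) & !missing_mask))
    stop("NA found in X outside missing_mask")
  dimnames(missing_mask) <- dimnames(X)
  structure(list(X = X, y = y, schema = schema, missing_mask = missing_mask),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$X), " rows x ", ncol(x$X), " features; ",
      sum(x$y == 1L), " positive / ", sum(x$y == 0L), " negative; ",
      sum(x$missing_mask), " missing cells\n", sep = "")
  invisible(x)
}

#' Read a tabular cohort from disk
#'
#' Two dialects are supported. `csv_header` is an ordinary comma-separated
#' file with a header row containing the schema's feature names plus the
#' label column (empty cells or `?` are missing). `uci_processed` is the
#' UCI heart-disease "processed" layout: no header, comma- or
#' whitespace-delimited, columns in schema order followed by the outcome
#' code, `?` marking missing cells; outcome codes greater than 0 are
#' binarized to 1.
#'
#' @param path File path.
#' @param schema A `feature_schema`.
#' @param dialect `"csv_header"` or `"uci_processed"`.
#' @return A [cohort()].
#' @export
read_cohort <- function(path, schema, dialect = c("csv_header", "uci_processed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- length(schema$names)
  if (dialect == "csv_header") {
    raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                           na.strings = character())
    need <- c(schema$names, schema$label_name)
    if (!all(need %in% colnames(raw)))
      stop("schema error: file columns do not cover the schema (missing: ",
           paste(setdiff(need, colnames(raw)), collapse = ", "), ")")
    raw <- raw[, need, drop = FALSE]
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    toks <- lapply(lines, function(l) {
      l <- gsub(",", " ", l, fixed = TRUE)
      strsplit(trimws(l), "\\s+")[[1]]
    })
    ncols <- lengths(toks)
    if (length(unique(ncols)) != 1L || ncols[1] != d + 1L)
      stop("schema error: expected ", d + 1L, " columns, found ",
           paste(unique(ncols), collapse = "/"))
    raw <- as.data.frame(do.call(rbind, toks), stringsAsFactors = FALSE)
    colnames(raw) <- c(schema$names, schema$label_name)
  }
  parse_col <- function(v, name, kind) {
    miss <- v %in% c("?", "", "NA")
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!miss & is.na(out))
    if (length(bad)) {
      if (kind == "continuous")
        stop("parse error: non-numeric token '", v[bad[1]], "' in continuous column '",
             name, "', row ", bad[1])
      stop("parse error: non-numeric token '", v[bad[1]], "' in column '",
           name, "', row ", bad[1])
    }
    out[miss] <- NA_real_
    out
  }
  Xcols <- mapply(function(nm, kind) parse_col(raw[[nm]], nm, kind),
                  schema$names, schema$kinds, SIMPLIFY = FALSE)
  X <- do.call(cbind, Xcols)
  colnames(X) <- schema$names
  yraw <- parse_col(raw[[schema$label_name]], schema$label_name, "label")
  if (anyNA(yraw)) stop("missing values in label column")
  y <- if (dialect == "uci_processed") as.integer(yraw > 0) else as.integer(yraw)
  cohort(X, y, schema)
}

#' Write a cohort to disk
#'
#' Inverse of [read_cohort()]. In `csv_header` mode missing cells are written
#' as empty fields; in `uci_processed` mode rows are comma-delimited without
#' a header and missing cells are written as `?`.
#'
#' @param x A `cohort`.
#' @param path Output path.
#' @param dialect `"csv_header"` or `"uci_processed"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, dialect = c("csv_header", "uci_processed")) {
  dialect <- match.arg(dialect)
  fmt <- function(v) {
    out <- vapply(v, function(z) if (is.na(z)) NA_character_ else format(z, digits = 15),
                  character(1))
    out
  }
  cells <- apply(x$X, 2, fmt)
  if (nrow(x$X) == 1L) cells <- matrix(cells, nrow = 1, dimnames = list(NULL, colnames(x$X)))
  if (dialect == "csv_header") {
    cells[is.na(cells)] <- ""
    df <- as.data.frame(cells, stringsAsFactors = FALSE, check.names = FALSE)
    df[[x$schema$label_name]] <- x$y
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    cells[is.na(cells)] <- "?"
    lines <- apply(cbind(cells, x$y), 1, paste, collapse = ",")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Per-class counts and proportions
#'
#' @param x A `cohort`, or a 0/1 label vector.
#' @return A data frame with columns `class`, `count`, `proportion`.
#' @export
class_balance_report <- function(x) {
  y <- if (inherits(x, "cohort")) x$y else as.integer(x)
  if (length(y) == 0) stop("empty cohort")
  counts <- c(`0` = sum(y == 0L), `1` = sum(y == 1L))
  data.frame(class = c(0L, 1L), count = as.integer(counts),
             proportion = as.numeric(counts) / length(y))
}
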