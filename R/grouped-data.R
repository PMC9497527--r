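#' Grouped observations for one-way ANOVA
#'
#' A `grouped_data` object holds observations partitioned into k groups
#' (blocks), the setting of the one-way fixed-effects model
#' \eqn{y_{ij} = \mu_i + \varepsilon_{ij}}.  Group order is the order of
#' first appearance, never alphabetical, and observations keep their input
#' order within each group.
#'
#' @param values numeric vector of observations.
#' @param groups vector of group labels, same length as `values`.
#' @return An object of class `grouped_data`: a list with components
#'   `blocks` (named list of numeric vectors), `labels`, `sizes` (n_i) and
#'   `N` (total sample size).
#' @examples
#' gd <- grouped_data(c(1.2, 0.8, 1.1, 3.2, 2.9), c("a", "a", "a", "b", "b"))
#' gd$sizes
#' @export
grouped_data <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("`values` and `groups` must have the same length", call. = FALSE)
  }
  if (!is.numeric(values)) {
    stop("`values` must be numeric", call. = FALSE)
  }
  labels <- as.character(unique(groups))
  blocks <- split(as.numeric(values), factor(groups, levels = labels))
  out <- structure(
    list(
      blocks = blocks,
      labels = labels,
      sizes = vapply(blocks, length, integer(1)),
      N = length(values)
    ),
    class = "grouped_data"
  )
  validate_grouped_data(out)
}

#' Validate a grouped_data object
#'
#' Checks the container invariants: at least two groups, at least two
#' observations per group (the common scale must be estimable), and all
#' values finite.  Errors name the offending block and index.
#'
#' @param data a `grouped_data` object.
#' @return `data`, unchanged, if all invariants hold.
#' @export
validate_grouped_data <- function(data) {
  if (!inherits(data, "grouped_data")) {
    stop("not a grouped_data object", call. = FALSE)
  }
  k <- length(data$blocks)
  if (k < 2) {
    stop("at least 2 groups are required, got ", k, call. = FALSE)
  }
  for (i in seq_len(k)) {
    b <- data$blocks[[i]]
    if (length(b) < 2) {
      stop("group '", data$labels[i], "' has fewer than 2 observations",
           call. = FALSE)
    }
    bad <- which(!is.finite(b))
    if (length(bad) > 0) {
      stop("non-finite value in group '", data$labels[i], "' at position ",
           bad[1], call. = FALSE)
    }
  }
  if (sum(data$sizes) != data$N) {
    stop("block sizes do not sum to N", call. = FALSE)
  }
  data
}

#' Read grouped data from a delimited text table
#'
#' Reads a long-format CSV/TSV table (header required) with a group-label
#' column and a numeric response column.  Groups are ordered by first
#' appearance in the file.  Rows with missing or non-numeric responses are
#' an error unless `drop_missing = TRUE`, in which case they are removed
#' and their count reported via a message.
#'
#' @param source path to a delimited text file, or a connection.
#' @param group_col name of the group-label column.
#' @param value_col name of the numeric response column.
#' @param sep field delimiter; `","` (default) or `"\t"` etc.
#' @param drop_missing drop rows with missing/non-numeric responses instead
#'   of failing.
#' @param row_filter optional function taking the parsed data frame and
#'   returning a logical keep-vector; applied before grouping (e.g. to
#'   exclude administratively censored records in a case study).
#' @return a [grouped_data] object.
#' @export
read_grouped_table <- function(source, group_col, value_col, sep = ",",
                               drop_missing = FALSE, row_filter = NULL) {
  df <- tryCatch(
    utils::read.table(source, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, colClasses = "character",
                      check.names = FALSE),
    error = function(e) stop("cannot parse input table: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (nrow(df) == 0) stop("input table is empty", call. = FALSE)
  for (col in c(group_col, value_col)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found in input", call. = FALSE)
    }
  }
  if (!is.null(row_filter)) {
    keep <- row_filter(df)
    df <- df[keep, , drop = FALSE]
    if (nrow(df) == 0) stop("row filter removed all rows", call. = FALSE)
  }
  raw <- df[[value_col]]
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(vals))
  if (length(bad) > 0) {
    if (!drop_missing) {
      stop("non-numeric or missing value '", raw[bad[1]], "' in column '",
           value_col, "' at row ", bad[1],
           " (set drop_missing = TRUE to drop such rows)", call. = FALSE)
    }
    message("dropped ", length(bad), " row(s) with missing/non-numeric values")
    df <- df[-bad, , drop = FALSE]
    vals <- vals[-bad]
  }
  grouped_data(vals, df[[group_col]])
}

#' Write grouped data as a long-format delimited table
#'
#' Inverse of [read_grouped_table()]: emits one row per observation with the
#' group label and the value at full precision, groups in stored order, so
#' that a write/read round trip is the identity.
#'
#' @param data a `grouped_data` object.
#' @param file output path or connection.
#' @param sep field delimiter.
#' @param group_col,value_col column names to use in the header.
#' @return `data`, invisibly.
#' @export
write_grouped_table <- function(data, file, sep = ",",
                                group_col = "group", value_col = "value") {
  validate_grouped_data(data)
  df <- as.data.frame(data)
  names(df) <- c(group_col, value_col)
  df[[value_col]] <- sprintf("%.17g", df[[value_col]])
  utils::write.table(df, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(data)
}

#' @export
as.data.frame.grouped_data <- function(x, ...) {
  data.frame(
    group = rep(x$labels, x$sizes),
    value = unlist(x$blocks, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Serialize grouped data to JSON (fixture format)
#'
#' @param data a `grouped_data` object.
#' @return a JSON string with `labels` and `blocks`.
#' @export
grouped_data_json <- function(data) {
  validate_grouped_data(data)
  jsonlite::toJSON(list(labels = data$labels, blocks = unname(data$blocks)),
                   digits = NA)
}

#' Deserialize grouped data from JSON
#'
#' @param txt JSON string or path as produced by [grouped_data_json()].
#' @return a [grouped_data] object.
#' @export
grouped_data_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  vals <- unlist(obj$blocks, use.names = FALSE)
  n <- vapply(obj$blocks, length, integer(1))
  grouped_data(vals, rep(obj$labels, n))
}

#' @export
print.grouped_data <- function(x, ...) {
  cat("Grouped data: k =", length(x$blocks), "groups, N =", x$N,
      "observations\n")
  cat("  sizes:", paste0(x$labels, "=", x$sizes, collapse = ", "), "\n")
  invisible(x)
}

# flat (y, g) view used by the fitting engine
gd_flat <- function(data) {
  list(
    y = unlist(data$blocks, use.names = FALSE),
    g = rep(seq_along(data$blocks), data$sizes),
    k = length(data$blocks),
    sizes = unname(data$sizes),
    N = data$N
  )
}
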