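#' Binary response matrix
#'
#' The universal pipeline input: an n x p matrix over {0,1}, one respondent
#' per row and one recoded item per column, with no missing entries and
#' both response categories present in every column (the Ising nodewise
#' regressions are undefined for constant items).
#'
#' @param values numeric/integer matrix of 0s and 1s.
#' @param item_ids column labels; defaults to `colnames(values)`.
#' @param respondent_ids optional row labels.
#' @param group optional respondent-level grouping factor (e.g. sex), used
#'   by the network comparison test.
#' @param check_variance reject zero-variance columns (default `TRUE`).
#' @return Object of class `response_matrix`.
#' @export
response_matrix <- function(values, item_ids = colnames(values),
                            respondent_ids = rownames(values),
                            group = NULL, check_variance = TRUE) {
  values <- as.matrix(values)
  if (length(values) == 0) stop("response matrix is empty")
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(ncol(values)))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing response at row %d, item '%s'", idx[1], item_ids[idx[2]]))
  }
  if (!all(values %in% c(0, 1))) {
    bad <- which(matrix(!(values %in% c(0, 1)), nrow(values)),
                 arr.ind = TRUE)[1, ]
    stop(sprintf("non-binary value at row %d, item '%s'", bad[1], item_ids[bad[2]]))
  }
  storage.mode(values) <- "integer"
  if (check_variance) {
    cm <- colMeans(values)
    if (any(cm == 0 | cm == 1))
      stop("zero-variance item(s): ",
           paste(item_ids[cm == 0 | cm == 1], collapse = ", "),
           " (both response categories must be present)")
  }
  if (!is.null(group)) {
    if (length(group) != nrow(values))
      stop("group must have one entry per respondent")
    group <- as.character(group)
  }
  colnames(values) <- item_ids
  structure(list(values = values, item_ids = item_ids,
                 respondent_ids = respondent_ids, group = group),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d respondents x %d items\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$group))
    cat("  groups:", paste(names(table(x$group)), table(x$group),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

# Coerce pipeline inputs (plain matrix / data.frame / response_matrix) to an
# integer {0,1} matrix.
response_values <- function(X) {
  if (inherits(X, "response_matrix")) return(X$values)
  response_matrix(as.matrix(X), check_variance = FALSE)$values
}

#' Load raw questionnaire responses and recode them via a codebook
#'
#' Reads a UTF-8 CSV with one respondent per row and a header of item ids,
#' applies [recode_item()] column by column, and validates the result.
#' Rows are kept in file order. Missing cells and out-of-domain values are
#' hard errors naming the offending row and column; responses are never
#' imputed.
#'
#' @param path CSV path.
#' @param codebook an [item_codebook()] describing every item column.
#' @param group_col optional name of a grouping column in the CSV (kept as
#'   respondent metadata, not an item).
#' @param agree_codes Likert agree-pole convention, see [recode_item()].
#' @return A [response_matrix()].
#' @export
load_responses <- function(path, codebook, group_col = NULL, agree_codes = c(1L, 2L)) {
  codebook <- validate_codebook(as.data.frame(codebook))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         check.names = FALSE)
  missing_cols <- setdiff(codebook$item_id, names(raw))
  if (length(missing_cols) > 0)
    stop("response file lacks codebook column(s): ",
         paste(missing_cols, collapse = ", "))
  group <- NULL
  if (!is.null(group_col)) {
    if (!group_col %in% names(raw))
      stop("group column '", group_col, "' not found")
    group <- raw[[group_col]]
  }
  p <- nrow(codebook)
  out <- matrix(0L, nrow(raw), p, dimnames = list(NULL, codebook$item_id))
  for (j in seq_len(p)) {
    id <- codebook$item_id[j]
    col <- raw[[id]]
    blank <- is.na(col) | trimws(col) == ""
    if (any(blank))
      stop(sprintf("missing response at row %d, item '%s'", which(blank)[1], id))
    out[, j] <- recode_item(col, codebook$response_type[j], codebook$key[j],
                            agree_codes = agree_codes)
  }
  response_matrix(out, item_ids = codebook$item_id, group = group)
}

# Round half up (the printed-table convention, unlike R's banker's rounding).
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  floor(x * scale + 0.5 + 1e-9) / scale
}

#' Per-item endorsement descriptives
#'
#' Counts and percentage endorsed per item, with the percentage rounded
#' half-up to two decimals as in printed descriptive tables.
#'
#' @param X a [response_matrix()], matrix or data frame over {0,1}.
#' @return Data frame with `item_id`, `n_endorsed`, `n_not_endorsed`,
#'   `pct_endorsed`.
#' @export
descriptive_table <- function(X) {
  V <- response_values(X)
  if (nrow(V) == 0 || ncol(V) == 0) stop("empty response matrix")
  n <- nrow(V)
  endorsed <- colSums(V)
  data.frame(
    item_id = colnames(V),
    n_endorsed = as.integer(endorsed),
    n_not_endorsed = as.integer(n - endorsed),
    pct_endorsed = round_half_up(100 * endorsed / n, 2),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write a response matrix as CSV
#'
#' Emits the CSV dialect [load_responses()] reads. Without a codebook the
#' recoded 0/1 values are written directly; with a codebook each item is
#' mapped back to a canonical raw label (keyed pole for 1), so that loading
#' the file through the same codebook exercises the full recoding path and
#' reproduces `X` exactly. Likert items use the smallest agree / largest
#' disagree code as representatives (dichotomization is many-to-one).
#'
#' @param X a [response_matrix()].
#' @param path destination CSV.
#' @param codebook optional [item_codebook()] for raw-label output.
#' @param agree_codes Likert agree-pole convention, see [recode_item()].
#' @export
write_responses <- function(X, path, codebook = NULL, agree_codes = c(1L, 2L)) {
  V <- response_values(X)
  if (is.null(codebook)) {
    df <- as.data.frame(V)
  } else {
    codebook <- validate_codebook(as.data.frame(codebook))
    stopifnot(identical(colnames(V), codebook$item_id))
    df <- as.data.frame(matrix("", nrow(V), ncol(V),
                               dimnames = list(NULL, colnames(V))),
                        stringsAsFactors = FALSE)
    for (j in seq_len(ncol(V))) {
      rt <- codebook$response_type[j]
      keyed <- codebook$key[j] == "positive"
      v <- V[, j] == 1L
      if (!keyed && rt != "likert4") v <- !v
      df[[j]] <- switch(rt,
        yes_no = ifelse(v, "Yes", "No"),
        know_dontknow = ifelse(v, "Know", "Don't know"),
        likert4 = {
          endorsed <- if (keyed) V[, j] == 1L else V[, j] == 0L
          ifelse(endorsed, min(agree_codes), max(setdiff(1:4, agree_codes)))
        })
    }
  }
  if (inherits(X, "response_matrix") && !is.null(X$group)) df$group <- X$group
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
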