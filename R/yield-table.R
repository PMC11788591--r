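#' Substrate-by-condition yield tables
#'
#' A `yield_table` holds the observed outcomes of a screening campaign: one
#' row per substrate, one column per candidate reaction condition, each cell
#' the observed yield (percent scale, or a raw analytical response
#' proportional to yield). Unobserved reactions are `NA` and are excluded
#' from every downstream computation. This object is the single source of
#' ground truth for fitting and evaluating condition rankers.
#'
#' @param yields Numeric matrix or wide data frame of nonnegative yields;
#'   `NA` marks an unobserved substrate/condition pair. If a data frame, the
#'   first column may hold substrate identifiers (any non-numeric column is
#'   treated as the identifier column).
#' @param substrate_ids,condition_ids Optional identifier vectors; default to
#'   dimnames or `s1..sn` / `c1..ck`.
#'
#' @return An object of class `yield_table` with fields `yields` (numeric
#'   matrix, `NA` = unobserved), `substrate_ids`, `condition_ids`.
#'
#' @details Invariants enforced: at least two conditions, every substrate has
#'   at least one observed condition, no negative yields.
#'
#' @examples
#' yt <- yield_table(rbind(c(80, 50, 20, 0), c(30, NA, 70, NA)))
#' yt
#' as_tibble(yt)
#' @export
yield_table <- function(yields, substrate_ids = NULL, condition_ids = NULL) {
  if (is.data.frame(yields)) {
    id_col <- which(!vapply(yields, is.numeric, logical(1)))
    if (length(id_col) > 1) {
      abort("at most one non-numeric (identifier) column is allowed in a wide yield table")
    }
    if (length(id_col) == 1) {
      if (is.null(substrate_ids)) substrate_ids <- as.character(yields[[id_col]])
      yields <- yields[, -id_col, drop = FALSE]
    }
    yields <- as.matrix(yields)
  }
  if (!is.matrix(yields) || !is.numeric(yields)) {
    abort("`yields` must be a numeric matrix or a wide data frame")
  }
  n <- nrow(yields)
  k <- ncol(yields)
  if (k < 2) abort("a yield table needs at least 2 conditions")
  if (n < 1) abort("empty yield table")
  if (any(yields < 0, na.rm = TRUE)) {
    bad <- which(yields < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative yield at substrate %d, condition %d", bad[1], bad[2]))
  }
  none_obs <- rowSums(!is.na(yields)) == 0
  if (any(none_obs)) {
    abort(sprintf(
      "substrate(s) with no observed conditions: %s",
      paste(which(none_obs), collapse = ", ")
    ))
  }
  if (is.null(substrate_ids)) {
    substrate_ids <- rownames(yields) %||% paste0("s", seq_len(n))
  }
  if (is.null(condition_ids)) {
    condition_ids <- colnames(yields) %||% paste0("c", seq_len(k))
  }
  if (length(substrate_ids) != n) abort("substrate_ids length does not match rows")
  if (length(condition_ids) != k) abort("condition_ids length does not match columns")
  dimnames(yields) <- NULL
  structure(
    list(
      yields = yields,
      substrate_ids = as.character(substrate_ids),
      condition_ids = as.character(condition_ids)
    ),
    class = "yield_table"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.yield_table <- function(x, ...) {
  n_obs <- sum(!is.na(x$yields))
  cat(sprintf(
    "<yield_table> %d substrates x %d conditions (%d observed, %d missing)\n",
    n_substrates(x), n_conditions(x), n_obs, length(x$yields) - n_obs
  ))
  print(head(as_tibble(x)))
  invisible(x)
}

#' @rdname yield_table
#' @param x A `yield_table`.
#' @param ... Unused.
#' @export
as_tibble.yield_table <- function(x, ...) {
  tibble(
    substrate = rep(x$substrate_ids, times = n_conditions(x)),
    condition = rep(x$condition_ids, each = n_substrates(x)),
    yield = as.vector(x$yields)
  ) %>%
    filter(!is.na(.data$yield)) %>%
    arrange(match(.data$substrate, x$substrate_ids))
}

#' @rdname yield_table
#' @export
n_substrates <- function(x) nrow(x$yields)

#' @rdname yield_table
#' @export
n_conditions <- function(x) ncol(x$yields)

#' Observation mask of a yield table
#'
#' @param x A [yield_table()].
#' @return Logical matrix, `TRUE` where the reaction was observed.
#' @export
observed_mask <- function(x) !is.na(x$yields)

#' Build a yield table from a long record of reactions
#'
#' Long layout: one row per observed reaction with columns
#' `substrate`, `condition`, `yield` (names configurable). Substrate/condition
#' pairs appearing more than once are an error.
#'
#' @param data Data frame in long layout.
#' @param substrate,condition,yield Column names.
#' @return A [yield_table()].
#' @export
long_to_yield_table <- function(data, substrate = "substrate",
                                condition = "condition", yield = "yield") {
  for (col in c(substrate, condition, yield)) {
    if (!col %in% names(data)) abort(sprintf("long table is missing column '%s'", col))
  }
  if (nrow(data) == 0) abort("empty yield table")
  key <- paste(data[[substrate]], data[[condition]], sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    d <- data[dup, , drop = FALSE][1, ]
    abort(sprintf(
      "duplicate cell for substrate '%s', condition '%s'",
      d[[substrate]], d[[condition]]
    ))
  }
  sids <- unique(as.character(data[[substrate]]))
  cids <- unique(as.character(data[[condition]]))
  m <- matrix(NA_real_, length(sids), length(cids))
  m[cbind(
    match(as.character(data[[substrate]]), sids),
    match(as.character(data[[condition]]), cids)
  )] <- data[[yield]]
  yield_table(m, substrate_ids = sids, condition_ids = cids)
}

# mean observed yield per condition (NaN-free: conditions with zero
# observations return NA)
condition_means <- function(table) {
  colMeans(table$yields, na.rm = TRUE)
}

# subset rows of a yield table
slice_table <- function(table, idx) {
  yield_table(
    table$yields[idx, , drop = FALSE],
    substrate_ids = table$substrate_ids[idx],
    condition_ids = table$condition_ids
  )
}
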