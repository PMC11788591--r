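#' Read a yield table from CSV
#'
#' Wide layout: one row per substrate, first column the substrate
#' identifier, remaining columns one per condition. Long layout: columns
#' `substrate`, `condition`, `yield`, one row per observed reaction.
#' Missing tokens (empty cell, `NA`, `nan` by default) become unobserved
#' cells; negative yields and duplicate long-format pairs are rejected with
#' the offending entity named.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @param missing_tokens Strings read as unobserved.
#' @return A [yield_table()].
#' @export
read_yield_table <- function(path, layout = c("wide", "long"),
                             missing_tokens = c("", "NA", "nan")) {
  layout <- match.arg(layout)
  df <- readr::read_csv(path,
    na = missing_tokens, show_col_types = FALSE,
    progress = FALSE
  )
  if (nrow(df) == 0) abort(sprintf("empty yield table: %s", path))
  if (layout == "wide") {
    yield_table(as.data.frame(df))
  } else {
    long_to_yield_table(df)
  }
}

#' Write a yield table to CSV
#'
#' @param table A [yield_table()].
#' @param path Output path.
#' @param layout `"wide"` (unobserved cells empty) or `"long"` (observed
#'   reactions only).
#' @return `path`, invisibly.
#' @export
write_yield_table <- function(table, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (layout == "wide") {
    df <- as.data.frame(table$yields)
    names(df) <- table$condition_ids
    df <- cbind(substrate = table$substrate_ids, df)
    readr::write_csv(df, path, na = "")
  } else {
    readr::write_csv(as_tibble(table), path)
  }
  invisible(path)
}

#' Read a substrate feature matrix from CSV
#'
#' Any non-numeric column is treated as the substrate identifier and used
#' for row names; all remaining columns must be numeric.
#'
#' @param path CSV file path.
#' @return Numeric matrix.
#' @export
read_features <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  id_col <- which(!vapply(df, is.numeric, logical(1)))
  ids <- NULL
  if (length(id_col) > 1) abort("feature files may contain at most one identifier column")
  if (length(id_col) == 1) {
    ids <- as.character(df[[id_col]])
    df <- df[, -id_col, drop = FALSE]
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  m
}

#' Fingerprint SMILES strings
#'
#' Computes 1024-bit structural fingerprints through the ChemmineR /
#' ChemmineOB (OpenBabel) toolkit. The fingerprints are binary path-based
#' (OpenBabel FP2) vectors; identical molecules give identical rows
#' regardless of SMILES writing. Unparseable SMILES abort with the
#' offending row indices. When the toolkit is unavailable, supply a
#' precomputed feature CSV instead ([read_features()]); the rest of the
#' pipeline is unchanged.
#'
#' @param smiles Character vector of SMILES.
#' @param n_bits Fingerprint width (default 1024).
#' @return Numeric matrix, one row per input molecule.
#' @export
featurize_smiles <- function(smiles, n_bits = 1024) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    abort(paste(
      "SMILES fingerprinting needs the ChemmineR and ChemmineOB packages;",
      "alternatively supply a precomputed feature CSV"
    ))
  }
  if (length(smiles) == 0) abort("no SMILES given")
  rows <- vector("list", length(smiles))
  bad <- integer(0)
  for (i in seq_along(smiles)) {
    fp <- tryCatch(
      {
        sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles[i]))
        m <- ChemmineR::as.matrix(ChemmineR::fingerprintOB(sdf, "FP2"))
        if (ncol(m) != n_bits || all(m == 0)) stop("empty fingerprint")
        as.numeric(m[1, ])
      },
      error = function(e) NULL
    )
    if (is.null(fp)) bad <- c(bad, i) else rows[[i]] <- fp
  }
  if (length(bad)) {
    abort(sprintf(
      "unparseable SMILES at row(s): %s", paste(bad, collapse = ", ")
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- names(smiles)
  out
}

#' Write an evaluation report to disk
#'
#' Writes the per-cell metric records as tidy CSV (one row per model x fold
#' x mask replicate) and a JSON summary keyed by model.
#'
#' @param report An `eval_report` from [run_protocol()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(report), file.path(dir, "records.csv"))
  g <- glance(report)
  summary <- setNames(
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, -1])),
    g$model
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read an evaluation run configuration
#'
#' YAML file mirroring the [eval_protocol()] fields plus dataset paths
#' (`yields`, `features`, `fingerprints`, `layout`, `out`).
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort(sprintf("not a configuration file: %s", path))
  cfg
}

#' Save or restore a fitted ranker
#'
#' Model state is written as a versioned RDS archive. Restoring checks the
#' format version and the model name registry.
#'
#' @param object A fitted [fit_ranker()] object.
#' @param path Archive path (conventionally `.rds`).
#' @return `save_ranker()` returns `path` invisibly; `load_ranker()` the
#'   restored ranker.
#' @export
save_ranker <- function(object, path) {
  if (!inherits(object, "label_ranker")) abort("not a fitted ranker")
  saveRDS(list(format = "rxnrank-ranker", version = 1L, model = object), path)
  invisible(path)
}

#' @rdname save_ranker
#' @export
load_ranker <- function(path) {
  archive <- readRDS(path)
  if (!identical(archive$format, "rxnrank-ranker")) {
    abort(sprintf("not a ranker archive: %s", path))
  }
  if (archive$version > 1L) {
    abort(sprintf("archive version %d is newer than this package", archive$version))
  }
  archive$model
}
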