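#' @keywords internal
"_PACKAGE"

LAYER_IDS <- c("methylation", "gene_expression", "mirna",
               "proteins", "serum_metab", "urine_metab")

#' Construct an omics layer
#'
#' An omics layer is a features-by-samples numeric matrix together with the
#' layer's identity (methylation, gene expression, miRNA, proteins, serum or
#' urine metabolites) and its transform state. Missing values are explicit
#' (`NA`); zeros are data, which matters for below-limit-of-detection filters.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   unique non-empty rownames (feature ids) and colnames (sample ids).
#' @param layer_id one of `"methylation"`, `"gene_expression"`, `"mirna"`,
#'   `"proteins"`, `"serum_metab"`, `"urine_metab"`.
#' @param is_log2 has the matrix already been log2-transformed?
#' @param is_methylation_beta are the values methylation beta-values? If so,
#'   all non-missing values must lie in \[0, 1\].
#' @return An object of class `"omics_layer"`.
#' @export
omics_layer <- function(values, layer_id,
                        is_log2 = FALSE,
                        is_methylation_beta = identical(layer_id, "methylation")) {
  layer_id <- match.arg(layer_id, LAYER_IDS)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (features x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (is_methylation_beta) {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("methylation beta-values must lie in [0, 1]")
  }
  structure(list(values = values, layer_id = layer_id,
                 is_log2 = isTRUE(is_log2),
                 is_methylation_beta = isTRUE(is_methylation_beta)),
            class = "omics_layer")
}

#' @export
print.omics_layer <- function(x, ...) {
  cat(sprintf("<omics_layer> %s: %d features x %d samples\n",
              x$layer_id, nrow(x$values), ncol(x$values)))
  state <- c(if (x$is_log2) "log2", if (x$is_methylation_beta) "beta-values")
  if (length(state)) cat("  scale:", paste(state, collapse = ", "), "\n")
  nmiss <- sum(is.na(x$values))
  if (nmiss) cat(sprintf("  missing cells: %d (%.1f%%)\n",
                         nmiss, 100 * nmiss / length(x$values)))
  invisible(x)
}

#' @export
dim.omics_layer <- function(x) dim(x$values)

feature_ids <- function(layer) rownames(layer$values)
sample_ids  <- function(layer) colnames(layer$values)

#' Read an omics layer from delimited text
#'
#' Reads a TSV/CSV matrix with an id header row and id first column.
#' Empty cells and `"NA"` parse as missing, never as zero. The matrix is
#' normalised to features-in-rows orientation regardless of how the file is
#' laid out.
#'
#' @param path file path.
#' @param layer_id the layer identity (see [omics_layer()]).
#' @param orientation `"features_in_rows"` (default) or `"features_in_columns"`,
#'   describing the file layout.
#' @param sep field separator; `"\t"` by default, use `","` for CSV.
#' @param ... passed on to [omics_layer()] (e.g. `is_log2`).
#' @return An [omics_layer()].
#' @export
read_layer <- function(path, layer_id,
                       orientation = c("features_in_rows", "features_in_columns"),
                       sep = "\t", ...) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          row.names = NULL, na.strings = c("", "NA"),
                          colClasses = "character", comment.char = "",
                          quote = "\"")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate ids in first column of ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  if (anyDuplicated(names(body)))
    stop("duplicate ids in header of ", path, ": ",
         paste(unique(names(body)[duplicated(names(body))]), collapse = ", "))
  m <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(ids, names(body)))
  for (j in seq_len(ncol(body))) {
    raw <- body[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell in %s at row '%s', column '%s': '%s'",
                   path, ids[bad[1L]], names(body)[j], raw[bad[1L]]))
    m[, j] <- num
  }
  if (orientation == "features_in_columns") m <- t(m)
  omics_layer(m, layer_id, ...)
}

#' Write a tabular result to delimited text
#'
#' Writes omics layers, data frames and matrices as UTF-8 tab-separated text
#' with a header. Missing values are written as `"NA"` (never 0), so a write
#' followed by [read_layer()] (or `read.delim`) round-trips losslessly at full
#' stored precision.
#'
#' @param obj an `omics_layer`, matrix or data.frame.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path, sep = "\t") {
  if (inherits(obj, "omics_layer")) obj <- obj$values
  if (is.matrix(obj)) {
    df <- data.frame(feature_id = rownames(obj), obj,
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else if (is.data.frame(obj)) {
    df <- obj
  } else stop("write_table() handles omics_layer, matrix or data.frame objects")
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop("cannot open '", path, "' for writing"))
  on.exit(close(con))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a study design table
#'
#' The design table holds one row per sample: `sample_id`, `child_id`,
#' `cohort`, `visit` (A/B) and any explanatory variables. Validates uniqueness
#' of `(child_id, visit)` and that inter-individual variables, when present,
#' are constant within child.
#'
#' @param path file path of a TSV with a header row.
#' @param sep field separator.
#' @return A validated `data.frame`.
#' @export
read_design <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  validate_design(df)
}

INTER_VARS <- c("sex", "ancestry", "age", "maternal_education",
                "kidmed_score", "zbmi")

validate_design <- function(design) {
  need <- c("sample_id", "child_id", "cohort", "visit")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design table lacks required columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design table")
  key <- paste(design$child_id, design$visit)
  if (anyDuplicated(key))
    stop("duplicate (child_id, visit) pairs in design table")
  if (!all(design$visit %in% c("A", "B")))
    stop("visit must be 'A' or 'B'")
  for (v in intersect(INTER_VARS, names(design))) {
    n_per_child <- tapply(design[[v]], design$child_id,
                          function(x) length(unique(x[!is.na(x)])))
    if (any(n_per_child > 1, na.rm = TRUE))
      stop("inter-individual variable '", v, "' varies within a child")
  }
  design
}

#' Align an omics layer with a study design
#'
#' Restricts the layer to samples present in the design (and vice versa) and
#' reorders the layer's samples to match the design row order. With
#' `pairs_only = TRUE`, children lacking either visit in this layer are
#' dropped, leaving a complete two-visit panel.
#'
#' @param layer an [omics_layer()].
#' @param design a design `data.frame` (see [read_design()]).
#' @param pairs_only keep only children with both visits present in the layer?
#' @return A list with elements `layer` and `design`, sample-aligned.
#' @export
align <- function(layer, design, pairs_only = FALSE) {
  design <- validate_design(design)
  keep <- design$sample_id[design$sample_id %in% sample_ids(layer)]
  if (!length(keep))
    stop("no samples shared between layer and design")
  d <- design[match(keep, design$sample_id), , drop = FALSE]
  if (pairs_only) {
    tab <- table(d$child_id, d$visit)
    ok <- rownames(tab)[tab[, "A"] >= 1 & tab[, "B"] >= 1]
    d <- d[d$child_id %in% ok, , drop = FALSE]
    if (!nrow(d)) stop("no children with both visits present in this layer")
  }
  rownames(d) <- NULL
  out <- layer
  out$values <- layer$values[, d$sample_id, drop = FALSE]
  list(layer = out, design = d)
}
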