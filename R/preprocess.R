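# Feature-exclusion rules, transforms and nuisance correction applied before
# the variance models. The boundary conventions follow the exclusion table
# they implement literally: "< threshold" rules (call rate, probe ICC, linear
# range) exclude strictly below the threshold, "> threshold" rules (CV,
# below-LOD fraction) exclude strictly above it.

new_filter_report <- function(layer_id, n_input, excluded_ids) {
  excluded_ids <- excluded_ids[vapply(excluded_ids, length, 1L) >= 0]
  all_excluded <- unique(unlist(excluded_ids, use.names = FALSE))
  structure(list(layer_id = layer_id,
                 n_input = n_input,
                 n_excluded = vapply(excluded_ids, length, 1L),
                 excluded_ids = excluded_ids,
                 n_output = n_input - length(all_excluded)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %s: %d features in, %d out\n",
              x$layer_id, x$n_input, x$n_output))
  for (rule in names(x$n_excluded))
    cat(sprintf("  %-16s excluded %d\n", rule, x$n_excluded[[rule]]))
  invisible(x)
}

drop_features <- function(layer, ids) {
  layer$values <- layer$values[!rownames(layer$values) %in% ids, , drop = FALSE]
  layer
}

check_flags <- function(flags, layer, what) {
  if (is.null(flags)) stop("missing ", what, " flags")
  if (!is.matrix(flags) ||
      !identical(sort(colnames(flags)), sort(sample_ids(layer))))
    stop(what, " flags must be a feature x sample matrix covering all samples")
  flags[, sample_ids(layer), drop = FALSE]
}

#' Call-rate filter
#'
#' Excludes features detected in strictly less than `min_rate` of samples
#' (features at exactly the threshold are kept). Default thresholds follow
#' the platform conventions: 0.98 for methylation arrays, 0.25 for
#' expression/miRNA.
#'
#' @param layer an [omics_layer()].
#' @param flags logical feature x sample detection matrix.
#' @param min_rate minimum detected fraction, in \[0, 1\].
#' @return `list(layer, report)`.
#' @export
filter_call_rate <- function(layer, flags,
                             min_rate = if (layer$layer_id == "methylation") 0.98 else 0.25) {
  stopifnot(min_rate >= 0, min_rate <= 1)
  flags <- check_flags(flags, layer, "detection")
  flags <- flags[rownames(layer$values), , drop = FALSE]
  rate <- rowMeans(flags)
  out <- rownames(layer$values)[rate < min_rate]
  list(layer = drop_features(layer, out),
       report = new_filter_report(layer$layer_id, nrow(layer$values),
                                  list(call_rate = out)))
}

#' Probe-reliability (ICC) filter
#'
#' Excludes features whose annotated intraclass correlation coefficient is
#' strictly below `min_icc` (default 0.625, i.e. probes that do not reach
#' 62.5% ICC in technical-replicate studies). Features without an ICC
#' annotation are kept and counted separately.
#'
#' @param layer an [omics_layer()].
#' @param annotation data.frame with `feature_id` and `icc` columns.
#' @param min_icc exclusion threshold.
#' @return `list(layer, report)`.
#' @export
filter_icc <- function(layer, annotation, min_icc = 0.625) {
  icc <- annotation$icc[match(rownames(layer$values), annotation$feature_id)]
  if (any(icc < 0 | icc > 1, na.rm = TRUE)) stop("icc values must lie in [0, 1]")
  out <- rownames(layer$values)[!is.na(icc) & icc < min_icc]
  no_ann <- rownames(layer$values)[is.na(icc)]
  rep <- new_filter_report(layer$layer_id, nrow(layer$values),
                           list(icc = out))
  rep$n_unannotated <- length(no_ann)
  list(layer = drop_features(layer, out), report = rep)
}

#' Coefficient-of-variation and below-LOD filters
#'
#' CV is sd/mean per feature across all samples on the raw (pre-log) scale;
#' features with CV strictly above `max_cv` are excluded, as are (when
#' `bld_flags` is given) features whose fraction of below-limit-of-detection
#' or zero values is strictly above `max_bld`. The two rules are applied
#' independently and itemized separately. A feature with mean 0 has an
#' undefined CV and is excluded under its own rule. Refuses to run on a
#' log2-transformed layer, where the CV is meaningless.
#'
#' @param layer an [omics_layer()], raw scale.
#' @param max_cv CV exclusion threshold (default 0.30).
#' @param bld_flags optional logical feature x sample matrix of below-LOD
#'   calls.
#' @param max_bld below-LOD-or-zero fraction threshold (default 0.30).
#' @return `list(layer, report)`.
#' @export
filter_cv <- function(layer, max_cv = 0.30, bld_flags = NULL, max_bld = 0.30) {
  if (layer$is_log2)
    stop("CV filtering must run on the raw (pre-log2) scale")
  v <- layer$values
  mu <- rowMeans(v, na.rm = TRUE)
  sdv <- apply(v, 1, stats::sd, na.rm = TRUE)
  undefined <- rownames(v)[mu == 0]
  cv <- sdv / mu
  out_cv <- rownames(v)[!is.na(cv) & mu != 0 & cv > max_cv]
  rules <- list(cv = out_cv, undefined_cv = undefined)
  if (!is.null(bld_flags)) {
    bld_flags <- check_flags(bld_flags, layer, "below-LOD")
    bld_flags <- bld_flags[rownames(v), , drop = FALSE]
    frac <- rowMeans(bld_flags | (!is.na(v) & v == 0))
    rules$bld <- rownames(v)[frac > max_bld]
  }
  list(layer = drop_features(layer, unlist(rules, use.names = FALSE)),
       report = new_filter_report(layer$layer_id, nrow(v), rules))
}

#' Linear-range filter for targeted protein panels
#'
#' Excludes proteins with strictly less than `min_fraction` of measurements
#' inside the assay's linear range.
#'
#' @param layer an [omics_layer()].
#' @param linear_range_flags logical feature x sample matrix.
#' @param min_fraction minimum in-range fraction (default 0.30).
#' @return `list(layer, report)`.
#' @export
filter_linear_range <- function(layer, linear_range_flags, min_fraction = 0.30) {
  flags <- check_flags(linear_range_flags, layer, "linear-range")
  flags <- flags[rownames(layer$values), , drop = FALSE]
  frac <- rowMeans(flags)
  out <- rownames(layer$values)[frac < min_fraction]
  list(layer = drop_features(layer, out),
       report = new_filter_report(layer$layer_id, nrow(layer$values),
                                  list(linear_range = out)))
}

#' log2 transform
#'
#' Replaces values by `log2(value + offset)` and flags the layer as log2.
#' Methylation beta-values are never log-transformed; applying the transform
#' twice is an error.
#'
#' @param layer an [omics_layer()].
#' @param offset non-negative offset added before the log (for zeros).
#' @return The transformed [omics_layer()].
#' @export
log2_transform <- function(layer, offset = 0) {
  if (layer$is_methylation_beta)
    stop("methylation beta-values are not log2-transformed")
  if (layer$is_log2) stop("layer is already log2-transformed")
  v <- layer$values + offset
  if (any(v <= 0, na.rm = TRUE))
    stop("non-positive values; declare a positive offset")
  layer$values <- log2(v)
  layer$is_log2 <- TRUE
  layer
}

#' Plate centering
#'
#' Per feature, centers each processing plate at the overall mean:
#' `value - plate mean + overall mean`, computed on non-missing values.
#' After correction every plate's per-feature mean equals the overall
#' per-feature mean, and the overall mean is unchanged.
#'
#' @param layer an [omics_layer()].
#' @param plate per-sample plate labels, named by sample id or in layer
#'   column order.
#' @return The corrected [omics_layer()].
#' @export
plate_center <- function(layer, plate) {
  if (!is.null(names(plate))) {
    if (!all(sample_ids(layer) %in% names(plate)))
      stop("plate labels missing for some samples")
    plate <- plate[sample_ids(layer)]
  } else if (length(plate) != ncol(layer$values)) {
    stop("plate labels missing for some samples")
  }
  if (anyNA(plate)) stop("plate labels missing for some samples")
  v <- layer$values
  overall <- rowMeans(v, na.rm = TRUE)
  for (pl in unique(plate)) {
    j <- which(plate == pl)
    pm <- rowMeans(v[, j, drop = FALSE], na.rm = TRUE)
    v[, j] <- v[, j, drop = FALSE] - pm + overall
  }
  layer$values <- v
  layer
}

#' Protected residualization against nuisance covariates
#'
#' Removes the part of each feature explained by nuisance covariates (for
#' example precomputed surrogate variables, batch labels or cell fractions)
#' while protecting a set of design variables: per feature, a least-squares
#' model on \[intercept, protected variables, nuisance\] is fitted jointly and
#' only the nuisance contribution is subtracted. Nuisance columns are first
#' projected orthogonal to the protected block, so variation shared with the
#' protected variables is retained rather than removed. Idempotent for a
#' fixed protected/nuisance pair; missing values stay missing.
#'
#' @param layer an [omics_layer()].
#' @param design aligned design table.
#' @param protect character vector of design variables to protect (may be
#'   empty).
#' @param nuisance numeric matrix of nuisance covariates, one row per sample
#'   (layer column order), or `NULL`/zero-column for a no-op.
#' @return The residualized [omics_layer()].
#' @export
residualize <- function(layer, design, protect = character(0), nuisance = NULL) {
  if (is.null(nuisance) || NCOL(nuisance) == 0) return(layer)
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != ncol(layer$values))
    stop("nuisance must have one row per sample of the layer")
  miss <- setdiff(protect, names(design))
  if (length(miss))
    stop("protected variables not in design: ", paste(miss, collapse = ", "))
  if (length(protect)) {
    fml <- stats::as.formula(paste("~", paste(protect, collapse = " + ")))
    P <- stats::model.matrix(fml, data = design)
  } else {
    P <- matrix(1, ncol(layer$values), 1)
  }
  qrP <- qr(P)
  if (qrP$rank < ncol(P))
    stop("protected design block is rank deficient")
  # project nuisance orthogonal to the protected block (documented behavior
  # when the two are collinear; harmless otherwise)
  Nt <- nuisance - qr.fitted(qrP, nuisance)
  keep <- apply(Nt, 2, function(x) sum(x^2) > 1e-12 * nrow(Nt))
  Nt <- Nt[, keep, drop = FALSE]
  if (!ncol(Nt)) return(layer)
  qrN <- qr(Nt)
  v <- layer$values
  complete <- !anyNA(v)
  if (complete) {
    fitted_n <- t(qr.fitted(qrN, t(v)))
    v <- v - fitted_n
  } else {
    for (j in seq_len(nrow(v))) {
      ok <- !is.na(v[j, ])
      if (sum(ok) <= ncol(Nt) + qrP$rank) next
      if (all(ok)) {
        v[j, ] <- v[j, ] - qr.fitted(qrN, v[j, ])
      } else {
        Po <- P[ok, , drop = FALSE]
        No <- nuisance[ok, , drop = FALSE]
        qpo <- qr(Po)
        Nto <- No - qr.fitted(qpo, No)
        ok2 <- apply(Nto, 2, function(x) sum(x^2) > 1e-12 * nrow(Nto))
        Nto <- Nto[, ok2, drop = FALSE]
        if (ncol(Nto))
          v[j, ok] <- v[j, ok] - qr.fitted(qr(Nto), v[j, ok])
      }
    }
  }
  layer$values <- v
  layer
}
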