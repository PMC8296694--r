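# Genomic-context enrichment of high-variability CpG quartiles, and
# concordance of intra-individual variability with external probe
# reliability.

#' Flag features in the top quartile of a variance component
#'
#' A feature is flagged when its fraction is at or above the component's
#' 75th percentile (linear-interpolation quantile; boundary ties included).
#' Flags for different components are computed independently.
#'
#' @param fractions numeric vector of per-feature fractions (named or not).
#' @param quartile which quartile boundary (default 0.75).
#' @return logical vector, same length/names as `fractions`.
#' @export
quartile_flags <- function(fractions, quartile = 0.75) {
  x <- fractions[!is.na(fractions)]
  if (length(x) < 4) stop("need at least 4 features to define quartiles")
  thr <- stats::quantile(x, quartile, type = 7, names = FALSE)
  out <- !is.na(fractions) & fractions >= thr
  names(out) <- names(fractions)
  out
}

haldane_or <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  (a * d) / (b * c)
}

#' CpG-context enrichment of a feature quartile
#'
#' For each genomic-context category (island, shore, shelf, open sea), a
#' 2x2 table of flagged vs not x in-category vs not over all annotated
#' features, a two-sided Fisher exact p, an odds ratio (Haldane 0.5
#' correction when any cell is 0) and Benjamini-Hochberg q-values across
#' the categories. Unannotated features are excluded and counted;
#' categories absent from the data are skipped with a note.
#'
#' @param flags logical per-feature flags (from [quartile_flags()]), named
#'   by feature id or aligned with `annotation`.
#' @param annotation data.frame with `feature_id` and `island_context`.
#' @return data.frame of class `"enrichment_result"`: one row per category
#'   with counts, `odds_ratio`, `p`, `q`; attribute `n_unannotated`.
#' @export
context_enrichment <- function(flags, annotation) {
  if (!is.null(names(flags))) {
    ctx <- annotation$island_context[match(names(flags), annotation$feature_id)]
  } else {
    if (length(flags) != nrow(annotation))
      stop("unnamed flags must match the annotation row for row")
    ctx <- annotation$island_context
  }
  keep <- !is.na(ctx)
  n_unann <- sum(!keep)
  flags <- flags[keep]; ctx <- ctx[keep]
  if (!length(ctx)) stop("no annotated features")
  cats <- c("island", "shore", "shelf", "open_sea")
  skipped <- setdiff(cats, unique(ctx))
  out <- NULL
  for (cat in intersect(cats, unique(ctx))) {
    a <- sum(flags & ctx == cat)       # flagged, in category
    b <- sum(flags & ctx != cat)
    c_ <- sum(!flags & ctx == cat)
    d <- sum(!flags & ctx != cat)
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    out <- rbind(out, data.frame(
      category = cat, flagged_in = a, flagged_out = b,
      unflagged_in = c_, unflagged_out = d,
      odds_ratio = haldane_or(a, b, c_, d), p = p,
      stringsAsFactors = FALSE))
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  structure(out, class = c("enrichment_result", "data.frame"),
            n_unannotated = n_unann, skipped = skipped)
}

#' Concordance of intra-individual variability with external probe ICCs
#'
#' Spearman rank correlation (average ranks for ties) between the estimated
#' intra-individual fraction and an external reliability annotation, with
#' the large-sample p-value. A reliable probe (high ICC) should show low
#' intra-individual noise, so the expected sign is negative.
#'
#' @param intra_fractions named numeric vector of intra-individual
#'   fractions.
#' @param annotation data.frame with `feature_id` and `icc`.
#' @return list with `rho`, `p`, `n`; `rho`/`p` are `NA` when either input
#'   is constant.
#' @export
icc_concordance <- function(intra_fractions, annotation) {
  icc <- annotation$icc[match(names(intra_fractions), annotation$feature_id)]
  ok <- !is.na(icc) & !is.na(intra_fractions)
  x <- intra_fractions[ok]; y <- icc[ok]
  if (length(x) < 10) stop("need at least 10 features with both values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
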