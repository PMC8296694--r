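# Gaussian graphical model on between-visit change scores.
#
# The estimator is the analytic-shrinkage partial-correlation scheme:
# the sample correlation R of the standardized delta columns is shrunk
# toward the identity with intensity
#   lambda* = sum_{i<j} Var^(r_ij) / sum_{i<j} r_ij^2   (clamped to [0, 1]),
#   Var^(r_ij) = n / (n-1)^3 * sum_k (w_kij - wbar_ij)^2,  w_kij = z_ki z_kj,
# partial correlations come from the inverse of R* = lambda I + (1-lambda) R
# (through a Woodbury identity when features outnumber samples), the null
# distribution of partial correlations is f0(r; kappa) proportional to
# (1 - r^2)^((kappa-3)/2) with kappa fitted on the central bulk, and edges
# are called by Benjamini-Hochberg at the chosen FDR level.

#' Select features for the delta network
#'
#' Methylation contributes CpGs whose intra-individual fraction is 1 (within
#' `tol`); proteins and serum/urine metabolites contribute features at or
#' above their layer's 75th percentile of intra-individual variability (ties
#' at the boundary included). Gene expression and miRNA are excluded by
#' default. A layer whose selection is empty is dropped with a warning.
#'
#' @param varpart_results named list of `varpart` results (or data.frames
#'   with `feature_id` and `frac_intra`), one per layer.
#' @param layers layers to consider.
#' @param tol tolerance for the methylation intra-fraction-equals-1 rule.
#' @return data.frame of `feature_id`, `layer_id`.
#' @export
select_ggm_features <- function(varpart_results,
                                layers = c("methylation", "proteins",
                                           "serum_metab", "urine_metab"),
                                tol = 1e-9) {
  out <- NULL
  for (lid in intersect(layers, names(varpart_results))) {
    res <- as.data.frame(varpart_results[[lid]])
    fi <- res$frac_intra
    sel <- if (lid == "methylation") {
      !is.na(fi) & fi >= 1 - tol
    } else {
      q3 <- stats::quantile(fi, 0.75, na.rm = TRUE, type = 7, names = FALSE)
      !is.na(fi) & fi >= q3
    }
    if (!any(sel)) {
      warning("no features selected for layer ", lid, "; layer dropped")
      next
    }
    out <- rbind(out, data.frame(feature_id = res$feature_id[sel],
                                 layer_id = lid, stringsAsFactors = FALSE))
  }
  out
}

#' Build the between-visit delta matrix
#'
#' For every selected feature, visit-B minus visit-A per child; only
#' children with both visits (and no missing value) in every included layer
#' are kept, so the matrix is complete. Columns are standardized to mean 0,
#' variance 1; zero-variance columns are dropped with a warning.
#'
#' @param layers named list of [omics_layer()]s.
#' @param design design table covering the layers' samples.
#' @param features data.frame from [select_ggm_features()] (or with columns
#'   `feature_id`, `layer_id`).
#' @param standardize standardize columns? (Partial correlations are scale
#'   invariant; this only conditions the numerics.)
#' @return An object of class `"delta_matrix"`: the children x features
#'   matrix with attributes `layer_id` (per column) and `standardized`.
#' @export
build_delta <- function(layers, design, features, standardize = TRUE) {
  design <- validate_design(design)
  blocks <- list(); provenance <- character(0)
  kids <- NULL
  per_layer <- split(features$feature_id, features$layer_id)
  for (lid in names(per_layer)) {
    layer <- layers[[lid]]
    if (is.null(layer)) stop("layer '", lid, "' not supplied")
    al <- align(layer, design, pairs_only = TRUE)
    d <- al$design
    ids <- intersect(per_layer[[lid]], rownames(al$layer$values))
    a <- al$layer$values[ids, d$sample_id[d$visit == "A"], drop = FALSE]
    b <- al$layer$values[ids, d$sample_id[d$visit == "B"], drop = FALSE]
    ch_a <- d$child_id[d$visit == "A"]; ch_b <- d$child_id[d$visit == "B"]
    b <- b[, match(ch_a, ch_b), drop = FALSE]
    delta <- t(b - a)          # children x features
    rownames(delta) <- ch_a
    ok <- rowSums(is.na(delta)) == 0
    delta <- delta[ok, , drop = FALSE]
    blocks[[lid]] <- delta
    provenance <- c(provenance, stats::setNames(rep(lid, ncol(delta)),
                                                colnames(delta)))
    kids <- if (is.null(kids)) rownames(delta) else
      intersect(kids, rownames(delta))
  }
  if (is.null(kids) || !length(kids))
    stop("no children complete across the included layers")
  m <- do.call(cbind, lapply(blocks, function(b) b[kids, , drop = FALSE]))
  colnames(m) <- unlist(lapply(blocks, colnames), use.names = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance delta column(s) dropped")
    m <- m[, sds > 0, drop = FALSE]
  }
  if (standardize)
    m <- scale(m)
  attr(m, "scaled:center") <- NULL; attr(m, "scaled:scale") <- NULL
  structure(m, layer_id = provenance[colnames(m)], standardized = standardize,
            class = c("delta_matrix", "matrix", "array"))
}

#' Analytic shrinkage of the delta correlation matrix
#'
#' Computes the sample correlation R of the standardized columns and the
#' analytic shrinkage intensity toward the identity target (see the module
#' header for the formula), returning `R* = lambda I + (1 - lambda) R`.
#'
#' @param delta children x features matrix (rows are observations).
#' @return list with `R_star`, `lambda_star`, `R`, `n`, `Z` (the
#'   standardized data, kept for the Woodbury inversion path).
#' @export
shrink_correlation <- function(delta) {
  x <- unclass(delta)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 observations to estimate the shrinkage intensity")
  z <- scale(x)              # mean 0, sd 1 (denominator n-1)
  R <- crossprod(z) / (n - 1)
  # vectorized Var^(r_ij): with W = z_i * z_j per observation,
  # sum_k (w - wbar)^2 = sum_k w^2 - (sum_k w)^2 / n
  S1 <- crossprod(z)          # sum_k w_kij
  S2 <- crossprod(z^2)        # sum_k w_kij^2
  V <- n / (n - 1)^3 * (S2 - S1^2 / n)
  num <- sum(V[upper.tri(V)])
  den <- sum(R[upper.tri(R)]^2)
  lambda <- if (den == 0) 1 else min(1, max(0, num / den))
  R_star <- (1 - lambda) * R
  diag(R_star) <- lambda + (1 - lambda) * diag(R)
  list(R_star = R_star, lambda_star = lambda, R = R, n = n, Z = z)
}

#' Partial correlations from a shrunk correlation matrix
#'
#' Inverts `R* = lambda I + (1 - lambda) R` and scales the negated inverse:
#' `rho_ij = -omega_ij / sqrt(omega_ii omega_jj)`, diagonal set to 1. When
#' features outnumber observations and the standardized data are available,
#' the inverse goes through the Woodbury identity
#' `(lambda I + A A')^{-1} = (I - A (lambda I + A'A)^{-1} A') / lambda`
#' with `A = sqrt((1-lambda)/(n-1)) Z'`, which costs O(p^2 n) instead of a
#' dense O(p^3) inversion; the two paths agree to high precision.
#'
#' @param shrunk result of [shrink_correlation()], or a correlation matrix
#'   (then `lambda` must make it positive definite already).
#' @param method `"auto"`, `"dense"` or `"woodbury"`.
#' @return Symmetric partial-correlation matrix with unit diagonal.
#' @export
partial_correlations <- function(shrunk, method = c("auto", "dense", "woodbury")) {
  method <- match.arg(method)
  if (is.matrix(shrunk)) shrunk <- list(R_star = shrunk, lambda_star = NA)
  R_star <- shrunk$R_star
  p <- ncol(R_star)
  lambda <- shrunk$lambda_star
  can_woodbury <- !is.null(shrunk$Z) && !is.na(lambda) && lambda > 0
  if (method == "auto")
    method <- if (can_woodbury && p > shrunk$n) "woodbury" else "dense"
  if (method == "woodbury") {
    if (!can_woodbury)
      stop("Woodbury path needs the standardized data and lambda > 0")
    A <- t(shrunk$Z) * sqrt((1 - lambda) / (shrunk$n - 1))  # p x n
    core <- diag(ncol(A)) * lambda + crossprod(A)
    omega <- -(A %*% solve(core, t(A))) / lambda
    diag(omega) <- diag(omega) + 1 / lambda
  } else {
    ev <- min(eigen(R_star, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-12)
      stop("shrunk correlation matrix is singular; increase shrinkage")
    omega <- solve(R_star)
  }
  d <- sqrt(diag(omega))
  pcor <- -omega / tcrossprod(d)
  pcor <- (pcor + t(pcor)) / 2
  diag(pcor) <- 1
  dimnames(pcor) <- dimnames(R_star)
  pcor
}

# Null density of partial correlations: f0(r; kappa) = C (1 - r^2)^((kappa-3)/2)
# on (-1, 1); r^2 ~ Beta(1/2, (kappa-1)/2), so the CDF and tail areas reduce
# to incomplete-beta calls.
null_cdf <- function(r, kappa) {
  b <- stats::pbeta(r^2, 0.5, (kappa - 1) / 2)
  ifelse(r >= 0, 0.5 + b / 2, 0.5 - b / 2)
}

null_logpdf <- function(r, kappa) {
  (kappa - 3) / 2 * log1p(-r^2) - lbeta(0.5, (kappa - 1) / 2)
}

#' Sample from the partial-correlation null density
#'
#' Draws from `f0(r; kappa)` via `r = s * sqrt(B)` with
#' `B ~ Beta(1/2, (kappa-1)/2)` and a random sign.
#'
#' @param m number of draws.
#' @param kappa degrees-of-freedom parameter (> 3 for a proper bulk shape).
#' @return numeric vector in (-1, 1).
#' @export
rnull_pcor <- function(m, kappa) {
  sqrt(stats::rbeta(m, 0.5, (kappa - 1) / 2)) *
    sample(c(-1, 1), m, replace = TRUE)
}

#' Fit the null degrees-of-freedom parameter kappa
#'
#' Treats the central bulk of the off-diagonal partial correlations as null
#' draws from `f0(r; kappa)` and fits `kappa` by maximum likelihood on the
#' values inside the central quantile band (default central 80%), using the
#' correctly truncated likelihood. Falls back to the method-of-moments
#' relation `Var(r) = 1/kappa` with a warning if the optimizer fails; a
#' degenerate all-zero input also falls back. The estimate is constrained to
#' `kappa > 3`.
#'
#' @param pcor_values off-diagonal partial correlations (>= 100 of them).
#' @param band central quantile band treated as null (default 0.8).
#' @return `kappa_hat` (numeric scalar).
#' @export
fit_null_kappa <- function(pcor_values, band = 0.8) {
  r <- pcor_values[!is.na(pcor_values)]
  if (length(r) < 100) stop("need at least 100 partial-correlation values")
  lo <- stats::quantile(r, (1 - band) / 2, names = FALSE)
  hi <- stats::quantile(r, 1 - (1 - band) / 2, names = FALSE)
  rb <- r[r >= lo & r <= hi]
  moment <- function() {
    v <- stats::var(r)
    if (!is.finite(v) || v <= 0) {
      warning("degenerate partial-correlation values; kappa set to its floor")
      return(3 + 1e-6)
    }
    max(3 + 1e-6, 1 / v)
  }
  if (length(unique(rb)) < 3 || hi <= lo) return(moment())
  nll <- function(log_km3) {
    kappa <- 3 + exp(log_km3)
    mass <- null_cdf(hi, kappa) - null_cdf(lo, kappa)
    if (!is.finite(mass) || mass <= 0) return(1e10)
    -(sum(null_logpdf(rb, kappa)) - length(rb) * log(mass))
  }
  opt <- tryCatch(stats::optimize(nll, c(log(1e-4), log(1e7))),
                  error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective) || opt$objective >= 1e10) {
    warning("kappa optimizer failed; falling back to the moment estimate")
    return(moment())
  }
  3 + exp(opt$minimum)
}

#' Two-sided null p-values for partial correlations
#'
#' `p = 2 (1 - F0(|r|; kappa))`, evaluated through the incomplete-beta
#' representation of the null CDF: symmetric in the sign of `r`, equal to 1
#' at `r = 0` and strictly decreasing in `|r|`. Values with `|r| >= 1` get
#' p = 0 with a warning.
#'
#' @param pcor partial-correlation matrix or vector.
#' @param kappa_hat fitted null parameter (> 3).
#' @return p-values with the same shape as `pcor`.
#' @export
pcor_pvalues <- function(pcor, kappa_hat) {
  if (kappa_hat <= 3) stop("kappa_hat must exceed 3")
  r <- pcor
  off <- if (is.matrix(r)) r[row(r) != col(r)] else r
  if (any(abs(off) >= 1, na.rm = TRUE))
    warning("|r| >= 1 encountered; assigned p = 0")
  p <- stats::pbeta(r^2, 0.5, (kappa_hat - 1) / 2, lower.tail = FALSE)
  if (is.matrix(pcor)) diag(p) <- 1
  p
}

#' Benjamini-Hochberg edge calling
#'
#' Step-up FDR control over all feature pairs; pairs with q-value at or
#' below `q` become edges, reported with `i < j`, the partial correlation,
#' p and q.
#'
#' @param pcor partial-correlation matrix.
#' @param pvalues matching p-value matrix (from [pcor_pvalues()]).
#' @param q FDR level (default 0.05).
#' @return data.frame of edges: `from`, `to`, `pcor`, `p`, `q`.
#' @export
fdr_edges <- function(pcor, pvalues, q = 0.05) {
  stopifnot(q > 0, q < 1)
  ut <- upper.tri(pcor)
  idx <- which(ut, arr.ind = TRUE)
  p <- pvalues[ut]
  qv <- stats::p.adjust(p, method = "BH")
  keep <- qv <= q
  ids <- colnames(pcor)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(pcor)))
  out <- data.frame(from = ids[idx[keep, 1]], to = ids[idx[keep, 2]],
                    pcor = pcor[ut][keep], p = p[keep], q = qv[keep],
                    stringsAsFactors = FALSE)
  out[order(out$p, out$from, out$to), , drop = FALSE]
}

#' Fit a shrinkage Gaussian graphical model on a delta matrix
#'
#' One call running the whole estimator: shrinkage intensity, partial
#' correlations, empirical-null kappa, p-values and FDR edge calling.
#'
#' @param delta a `delta_matrix` from [build_delta()] (or any observations x
#'   features matrix).
#' @param q FDR level for edge calling.
#' @param lambda optional fixed shrinkage intensity overriding the analytic
#'   value (0 disables shrinkage).
#' @param band central quantile band for the null fit.
#' @return An object of class `"delta_ggm"` with entries `pcor`,
#'   `lambda_star`, `kappa_hat`, `pvalues`, `edges`, `n`, `p` and the
#'   per-feature `layer_id` when the input carries provenance.
#' @export
delta_ggm <- function(delta, q = 0.05, lambda = NULL, band = 0.8) {
  sh <- shrink_correlation(delta)
  if (!is.null(lambda)) {
    sh$lambda_star <- lambda
    sh$R_star <- (1 - lambda) * sh$R
    diag(sh$R_star) <- lambda + (1 - lambda) * diag(sh$R)
  }
  pcor <- partial_correlations(sh)
  kappa <- fit_null_kappa(pcor[upper.tri(pcor)], band = band)
  pv <- pcor_pvalues(pcor, kappa)
  edges <- fdr_edges(pcor, pv, q = q)
  structure(list(pcor = pcor, lambda_star = sh$lambda_star,
                 kappa_hat = kappa, pvalues = pv, edges = edges,
                 q = q, n = sh$n, p = ncol(pcor),
                 layer_id = attr(delta, "layer_id")),
            class = "delta_ggm")
}

#' @export
print.delta_ggm <- function(x, ...) {
  cat(sprintf("<delta_ggm> %d features, %d children\n", x$p, x$n))
  cat(sprintf("  lambda* = %.4f, kappa^ = %.1f\n", x$lambda_star, x$kappa_hat))
  cat(sprintf("  %d edges at FDR <= %g\n", nrow(x$edges), x$q))
  invisible(x)
}

#' @export
summary.delta_ggm <- function(object, ...) {
  network_summary(object$edges, object$layer_id)
}

#' @export
plot.delta_ggm <- function(x, ...) {
  g <- ggm_graph(x$edges, x$layer_id)
  if (igraph::vcount(g) == 0) {
    warning("empty network; nothing to plot")
    return(invisible(x))
  }
  plot(g, vertex.size = 4, vertex.label = NA,
       edge.width = 2 * abs(igraph::E(g)$weight) / max(abs(igraph::E(g)$weight)),
       ...)
  invisible(x)
}

ggm_graph <- function(edges, provenance = NULL) {
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to"), drop = FALSE], directed = FALSE)
  if (nrow(edges) && !is.null(edges$pcor)) igraph::E(g)$weight <- edges$pcor
  if (!is.null(provenance)) {
    lay <- provenance[igraph::V(g)$name]
    igraph::V(g)$layer <- ifelse(is.na(lay), "unknown", lay)
  }
  g
}

#' Connected components, degrees and layer composition of the edge network
#'
#' Nodes are the features with at least one edge. Components are numbered
#' deterministically by decreasing size, ties broken by the smallest feature
#' id; composition labels each component single-layer or cross-omics.
#'
#' @param edges edge data.frame from [fdr_edges()].
#' @param provenance optional named vector feature id -> layer id.
#' @return A list of class `"network_summary"`: `n_nodes`, `n_edges`,
#'   `components` (a data.frame with size and composition), `membership`,
#'   `degree`.
#' @export
network_summary <- function(edges, provenance = NULL) {
  g <- ggm_graph(edges, provenance)
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  storage.mode(deg) <- "integer"
  nodes <- igraph::V(g)$name
  comp_tab <- NULL
  membership <- integer(0)
  if (comp$no > 0) {
    first_node <- vapply(seq_len(comp$no), function(k)
      min(nodes[comp$membership == k]), "")
    ord <- order(-comp$csize, first_node)
    renum <- match(seq_len(comp$no), ord)
    membership <- stats::setNames(renum[comp$membership], nodes)
    comp_tab <- data.frame(component = seq_len(comp$no),
                           size = as.integer(comp$csize[ord]),
                           stringsAsFactors = FALSE)
    if (!is.null(provenance)) {
      comp_tab$layers <- vapply(seq_len(comp$no), function(k) {
        lls <- unique(igraph::V(g)$layer[membership == k])
        paste(sort(lls), collapse = "+")
      }, "")
      comp_tab$cross_omics <- grepl("\\+", comp_tab$layers)
    }
  }
  structure(list(n_nodes = length(nodes), n_edges = nrow(edges),
                 components = comp_tab, membership = membership,
                 degree = deg),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("<network_summary> %d nodes, %d edges, %d components\n",
              x$n_nodes, x$n_edges,
              if (is.null(x$components)) 0 else nrow(x$components)))
  if (!is.null(x$components)) {
    utils::head(x$components, 10) |> print()
    if (!is.null(x$components$cross_omics))
      cat(sprintf("  cross-omics components: %d (%.1f%%)\n",
                  sum(x$components$cross_omics),
                  100 * mean(x$components$cross_omics)))
  }
  invisible(x)
}

#' Export the network for graph tools
#'
#' Writes the edge network as SIF and/or GraphML plus node and edge
#' attribute TSVs. Edge weights are the partial correlations; node
#' attributes carry degree and layer.
#'
#' @param edges edge data.frame from [fdr_edges()].
#' @param summary a [network_summary()] (computed if `NULL`).
#' @param dir output directory.
#' @param formats subset of `"sif"`, `"graphml"`, `"tsv"`.
#' @param provenance optional named feature id -> layer id vector.
#' @param name base file name.
#' @return Character vector of written paths, invisibly.
#' @export
export_network <- function(edges, summary = NULL, dir = ".",
                           formats = c("sif", "graphml", "tsv"),
                           provenance = NULL, name = "net") {
  bad <- setdiff(formats, c("sif", "graphml", "tsv"))
  if (length(bad)) stop("unknown format: ", paste(bad, collapse = ", "))
  if (is.null(summary)) summary <- network_summary(edges, provenance)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if ("sif" %in% formats) {
    f <- file.path(dir, paste0(name, ".sif"))
    writeLines(if (nrow(edges)) sprintf("%s pcor %s", edges$from, edges$to)
               else character(0), f)
    paths <- c(paths, f)
  }
  if ("graphml" %in% formats) {
    f <- file.path(dir, paste0(name, ".graphml"))
    g <- ggm_graph(edges, provenance)
    if (igraph::vcount(g)) igraph::V(g)$degree <- summary$degree[igraph::V(g)$name]
    igraph::write_graph(g, f, format = "graphml")
    paths <- c(paths, f)
  }
  if ("tsv" %in% formats) {
    fe <- file.path(dir, paste0(name, "_edges.tsv"))
    write_table(edges, fe)
    nodes <- data.frame(feature_id = names(summary$degree),
                        degree = as.integer(summary$degree),
                        component = as.integer(summary$membership[names(summary$degree)]),
                        stringsAsFactors = FALSE)
    if (!is.null(provenance))
      nodes$layer_id <- provenance[nodes$feature_id]
    fn <- file.path(dir, paste0(name, "_nodes.tsv"))
    write_table(nodes, fn)
    paths <- c(paths, fe, fn)
  }
  invisible(paths)
}
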