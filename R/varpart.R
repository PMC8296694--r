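# Per-feature variance decomposition with linear mixed models.
#
# Model 1 partitions each feature's variance into inter-individual (child
# random intercept), cohort (cohort random intercept) and intra-individual
# (residual) components. Model 2 adds explanatory variables: categorical
# ones as random intercepts, continuous ones as standardized fixed slopes,
# whose explained variance is the empirical variance of their fitted
# contribution. Fractions are each component over the total of all
# components, so they sum to one.

MODEL2_CONTINUOUS <- c("age", "zbmi", "kidmed_score", "fasting_hours",
                       "sampling_hour")
MODEL2_CATEGORICAL <- c("sex", "ancestry", "maternal_education", "season",
                        "weekday", "has_cold", "heavy_exercise")

#' Model specification for the variance decomposition
#'
#' @param random_terms categorical design variables fitted as random
#'   intercepts; must include `child_id` (the inter-individual term).
#' @param fixed_continuous continuous covariates fitted as fixed slopes
#'   (standardized internally).
#' @param categorical_covariates additional categorical covariates, also
#'   fitted as random intercepts but reported as explanatory terms rather
#'   than design structure.
#' @return An object of class `"varpart_spec"`.
#' @export
varpart_spec <- function(random_terms = c("child_id", "cohort"),
                         fixed_continuous = character(0),
                         categorical_covariates = character(0)) {
  if (!"child_id" %in% random_terms)
    stop("random_terms must include child_id")
  all_vars <- c(random_terms, fixed_continuous, categorical_covariates)
  if (anyDuplicated(all_vars))
    stop("a variable is listed twice in the model specification")
  structure(list(random_terms = random_terms,
                 fixed_continuous = fixed_continuous,
                 categorical_covariates = categorical_covariates),
            class = "varpart_spec")
}

#' Default model specification for a layer
#'
#' Model 1 contains only the design structure (child and cohort random
#' intercepts). Model 2 adds the standard explanatory variables: sex,
#' ancestry, age, maternal education, diet score and zBMI as
#' inter-individual terms, and fasting hours, heavy exercise, colds,
#' sampling hour, weekday and season as intra-individual terms. The urine
#' metabolome model swaps in run order and drops fasting hours and sampling
#' hour (pooled morning/night samples make them meaningless there).
#' Variables absent from the design are silently omitted.
#'
#' @param model 1 or 2.
#' @param layer_id the layer the model is for.
#' @param design design table (used to check availability).
#' @return A [varpart_spec()].
#' @export
default_varpart_spec <- function(model = 1, layer_id = "methylation",
                                 design = NULL) {
  if (model == 1) return(varpart_spec())
  cont <- MODEL2_CONTINUOUS
  cat <- MODEL2_CATEGORICAL
  if (identical(layer_id, "urine_metab")) {
    cont <- c(setdiff(cont, c("fasting_hours", "sampling_hour")), "run_order")
  }
  if (!is.null(design)) {
    cont <- intersect(cont, names(design))
    cat <- intersect(cat, names(design))
  }
  varpart_spec(fixed_continuous = cont, categorical_covariates = cat)
}

build_model_frame <- function(y, design, spec) {
  df <- data.frame(.y = y, stringsAsFactors = FALSE)
  for (v in c(spec$random_terms, spec$categorical_covariates)) {
    if (is.null(design[[v]])) stop("design lacks variable '", v, "'")
    df[[v]] <- factor(design[[v]])
  }
  for (v in spec$fixed_continuous) {
    if (is.null(design[[v]])) stop("design lacks variable '", v, "'")
    x <- design[[v]]
    if (!is.numeric(x)) stop("fixed continuous variable '", v, "' is not numeric")
    s <- stats::sd(x, na.rm = TRUE)
    df[[v]] <- if (is.na(s) || s == 0) 0 * x else (x - mean(x, na.rm = TRUE)) / s
  }
  df
}

varpart_formula <- function(spec, random_drop = character(0)) {
  rt <- setdiff(c(spec$random_terms, spec$categorical_covariates), random_drop)
  rhs <- c("1", spec$fixed_continuous, sprintf("(1 | %s)", rt))
  stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
}

lmer_ctrl <- function() {
  lme4::lmerControl(calc.derivs = FALSE,
                    check.conv.singular = "ignore",
                    optCtrl = list(xtol_abs = 1e-10, ftol_abs = 1e-10,
                                   maxeval = 5000))
}

fit_lmm <- function(fml, data) {
  conv <- TRUE
  fit <- suppressMessages(withCallingHandlers(
    lme4::lmer(fml, data = data, REML = TRUE, control = lmer_ctrl()),
    warning = function(w) {
      conv <<- FALSE
      invokeRestart("muffleWarning")
    }))
  if (!conv) {
    for (opt in c("bobyqa", "Nelder_Mead")) {
      ok <- TRUE
      alt <- tryCatch(withCallingHandlers(
        lme4::lmer(fml, data = data, REML = TRUE,
                   control = lme4::lmerControl(optimizer = opt,
                                               calc.derivs = FALSE,
                                               check.conv.singular = "ignore")),
        warning = function(w) { ok <<- FALSE; invokeRestart("muffleWarning") }),
        error = function(e) NULL)
      if (!is.null(alt) && (ok ||
          stats::deviance(alt, REML = TRUE) < stats::deviance(fit, REML = TRUE))) {
        fit <- alt
        conv <- ok
      }
      if (conv) break
    }
  }
  list(fit = fit, converged = conv)
}

extract_components <- function(fit, spec, data, random_dropped = character(0)) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- stats::setNames(vc$vcov, vc$grp)
  sigma2 <- c()
  for (term in c(spec$random_terms, spec$categorical_covariates)) {
    sigma2[term] <- if (term %in% names(comp)) comp[[term]]
                    else 0  # dropped as degenerate (all-singleton levels)
  }
  sigma2["residual"] <- comp[["Residual"]]
  beta <- lme4::fixef(fit)
  X <- stats::model.matrix(fit)
  v <- c()
  for (term in spec$fixed_continuous) {
    cols <- which(colnames(X) == term)
    v[term] <- if (length(cols) && term %in% names(beta))
      stats::var(as.vector(X[, cols, drop = FALSE] %*% beta[cols])) else 0
  }
  list(sigma2 = sigma2, explained = v, fixed = beta,
       fixed_cov = as.matrix(stats::vcov(fit)),
       n_used = nrow(data), random_dropped = random_dropped)
}

#' REML fit of the variance-decomposition mixed model for one feature
#'
#' Fits the linear mixed model by restricted maximum likelihood (through
#' lme4), with non-negativity of variance components enforced at the
#' boundary, and restarts with alternative optimizers if the first fit does
#' not converge cleanly. A random term whose levels are all singletons is
#' confounded with the residual; its component is set to 0 with a degeneracy
#' note rather than fitted.
#'
#' @param y numeric vector of per-sample values (missing values dropped).
#' @param design aligned design table, one row per element of `y`.
#' @param spec a [varpart_spec()].
#' @return A list with `sigma2` (named variance components including
#'   `residual`), `explained` (per continuous covariate explained variance),
#'   `fixed` and `fixed_cov` (GLS fixed-effect estimates and covariance),
#'   `converged`, `n_used`, `random_dropped`.
#' @export
reml_fit <- function(y, design, spec = varpart_spec()) {
  ok <- !is.na(y)
  if (sum(ok) < 2) stop("need at least 2 non-missing samples")
  df <- build_model_frame(y[ok], design[ok, , drop = FALSE], spec)
  drop <- character(0)
  for (term in c(spec$random_terms, spec$categorical_covariates)) {
    nl <- length(unique(df[[term]]))
    if (nl < 2)
      stop("random term '", term, "' has fewer than 2 levels")
    if (nl == nrow(df)) drop <- c(drop, term)
  }
  fr <- fit_lmm(varpart_formula(spec, drop), df)
  out <- extract_components(fr$fit, spec, df, drop)
  out$converged <- fr$converged
  out
}

#' Variance fractions from fitted components
#'
#' The total is the sum of all random-effect variances, the residual
#' variance and the explained variance of each continuous fixed covariate
#' (the empirical variance of its fitted contribution); each fraction is its
#' component over the total. The residual fraction is the intra-individual
#' variability, the `child_id` fraction the inter-individual one.
#'
#' @param fit output of [reml_fit()].
#' @return Named numeric vector of fractions summing to 1, or all-`NA` if
#'   the total is 0 (degenerate feature).
#' @export
variance_fractions <- function(fit) {
  parts <- c(fit$sigma2, fit$explained)
  total <- sum(parts)
  if (total <= 0)
    return(stats::setNames(rep(NA_real_, length(parts)), names(parts)))
  parts / total
}

#' Collinearity score of the fixed-effect design
#'
#' Converts the covariance of the fixed-effect estimates (intercept
#' excluded) to a correlation matrix and reports the maximum absolute
#' off-diagonal entry. A score above 0.99 flags a design in which the
#' variance attribution to fixed effects is not trustworthy.
#'
#' @param fixed_cov covariance matrix of fixed-effect estimates, intercept
#'   column included or not.
#' @param threshold flag threshold (default 0.99, strict `>`).
#' @return A list with `score`, `pair`, `flagged`.
#' @export
collinearity_score <- function(fixed_cov, threshold = 0.99) {
  fixed_cov <- as.matrix(fixed_cov)
  keep <- setdiff(colnames(fixed_cov), "(Intercept)")
  fixed_cov <- fixed_cov[keep, keep, drop = FALSE]
  if (ncol(fixed_cov) < 2)
    return(list(score = 0, pair = character(0), flagged = FALSE))
  if (any(diag(fixed_cov) <= 0))
    stop("fixed-effect covariance has non-positive diagonal")
  cc <- stats::cov2cor(fixed_cov)
  diag(cc) <- 0
  idx <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
  list(score = max(abs(cc)),
       pair = colnames(cc)[sort(idx)],
       flagged = max(abs(cc)) > threshold)
}

#' Per-feature variance decomposition of an omics layer
#'
#' Fits the mixed model to every feature of an aligned layer and returns the
#' per-feature variance fractions: `frac_inter` (child), `frac_cohort`,
#' `frac_intra` (residual) and one fraction per explanatory variable in
#' model 2. For model 2 the collinearity of the shared fixed-effect design
#' is checked once before fitting and the run aborts if the score exceeds
#' 0.99 unless `force = TRUE`. Features sharing the layer's complete-case
#' structure are refitted through a single prebuilt model structure for
#' speed.
#'
#' @param layer an [omics_layer()] aligned to `design` (see [align()]).
#' @param design design table in layer sample order.
#' @param spec optional [varpart_spec()]; defaults to
#'   [default_varpart_spec()] for `model` and the layer.
#' @param model 1 (design structure only) or 2 (with explanatory variables).
#' @param force proceed despite a flagged collinearity score.
#' @return An object of class `"varpart"`: a data.frame of per-feature
#'   components and fractions with the model specification, collinearity
#'   report and summary attached as attributes.
#' @export
varpart <- function(layer, design, spec = NULL, model = 1, force = FALSE) {
  stopifnot(inherits(layer, "omics_layer"))
  design <- validate_design(design)
  if (!identical(colnames(layer$values), design$sample_id))
    stop("layer and design are not aligned; call align() first")
  if (is.null(spec))
    spec <- default_varpart_spec(model, layer$layer_id, design)
  v <- layer$values
  p <- nrow(v)
  feature_ids <- rownames(v)

  base_y <- v[1, ]
  base_fit <- NULL
  collin <- list(score = 0, pair = character(0), flagged = FALSE)
  complete_rows <- rowSums(is.na(v)) == 0
  if (any(complete_rows)) {
    template_y <- v[which(complete_rows)[1], ]
    df <- build_model_frame(template_y, design, spec)
    drop <- names(which(vapply(c(spec$random_terms, spec$categorical_covariates),
                               function(t) length(unique(df[[t]])) == nrow(df),
                               TRUE)))
    base <- fit_lmm(varpart_formula(spec, drop), df)
    base_fit <- base$fit
    if (length(spec$fixed_continuous) >= 2) {
      collin <- collinearity_score(extract_components(base_fit, spec, df)$fixed_cov)
      if (collin$flagged && !force)
        stop(sprintf(paste0("collinearity score %.4f between %s exceeds 0.99; ",
                            "rerun with force = TRUE to override"),
                     collin$score, paste(collin$pair, collapse = " and ")))
    }
  }

  rows <- vector("list", p)
  for (j in seq_len(p)) {
    y <- v[j, ]
    res <- tryCatch({
      if (complete_rows[j] && !is.null(base_fit)) {
        conv <- TRUE
        fit <- suppressMessages(withCallingHandlers(
          lme4::refit(base_fit, newresp = y),
          warning = function(w) { conv <<- FALSE; invokeRestart("muffleWarning") }))
        if (!conv) {
          out <- reml_fit(y, design, spec)
        } else {
          df_j <- build_model_frame(y, design, spec)
          out <- extract_components(fit, spec, df_j)
          out$converged <- TRUE
        }
        out
      } else {
        reml_fit(y, design, spec)
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      rows[[j]] <- NULL
      next
    }
    fr <- variance_fractions(res)
    nm <- names(fr)
    nm[nm == "child_id"] <- "inter"
    nm[nm == "cohort"] <- "cohort"
    nm[nm == "residual"] <- "intra"
    row <- c(stats::setNames(as.list(res$sigma2),
                             paste0("sigma2_", names(res$sigma2))),
             stats::setNames(as.list(fr), paste0("frac_", nm)),
             list(converged = res$converged, n_used = res$n_used))
    rows[[j]] <- row
  }
  keep <- !vapply(rows, is.null, TRUE)
  out <- do.call(rbind, lapply(which(keep), function(j)
    as.data.frame(rows[[j]], check.names = FALSE)))
  out <- cbind(feature_id = feature_ids[keep], out)
  rownames(out) <- NULL
  structure(out, class = c("varpart", "data.frame"),
            layer_id = layer$layer_id, model = model, spec = spec,
            collinearity = collin, n_failed = sum(!keep))
}

#' @export
print.varpart <- function(x, ...) {
  cat(sprintf("<varpart> model %d, layer %s: %d features\n",
              attr(x, "model"), attr(x, "layer_id"), nrow(x)))
  cl <- attr(x, "collinearity")
  if (length(cl$pair))
    cat(sprintf("  collinearity score %.3f (%s)%s\n", cl$score,
                paste(cl$pair, collapse = " ~ "),
                if (cl$flagged) " FLAGGED" else ""))
  if (attr(x, "n_failed") > 0)
    cat("  features that failed to fit:", attr(x, "n_failed"), "\n")
  fr <- x[, c("frac_inter", if ("frac_cohort" %in% names(x)) "frac_cohort",
              "frac_intra")]
  print(round(apply(fr, 2, stats::quantile,
                    probs = c(0.25, 0.5, 0.75), na.rm = TRUE), 3))
  invisible(x)
}

#' @export
summary.varpart <- function(object, thresholds = c(0.01, 0.02, 0.05), ...) {
  summarize_fractions(object, thresholds)
}

#' @export
plot.varpart <- function(x, ...) {
  fr <- x[, grep("^frac_", names(x)), drop = FALSE]
  colnames(fr) <- sub("^frac_", "", colnames(fr))
  graphics::boxplot(as.data.frame(fr), las = 2,
                    ylab = "fraction of variance",
                    main = sprintf("variance decomposition (%s, model %d)",
                                   attr(x, "layer_id"), attr(x, "model")), ...)
  invisible(x)
}

#' Summary of variance fractions across features
#'
#' Median and quartiles (linear-interpolation quantiles) of each fraction
#' column, plus the share of features in which the component explains at
#' least each threshold of variance.
#'
#' @param results a `varpart` object or data.frame with `frac_*` columns.
#' @param thresholds explained-variance thresholds for the share columns.
#' @return A data.frame, one row per component.
#' @export
summarize_fractions <- function(results, thresholds = c(0.01, 0.02, 0.05)) {
  fr <- as.data.frame(results)[, grep("^frac_", names(results)), drop = FALSE]
  if (!nrow(fr)) stop("no results to summarize")
  comp <- sub("^frac_", "", names(fr))
  out <- data.frame(component = comp,
                    median = NA_real_, q1 = NA_real_, q3 = NA_real_)
  for (th in thresholds) out[[sprintf("share_ge_%g", 100 * th)]] <- NA_real_
  for (i in seq_along(fr)) {
    x <- fr[[i]]
    xx <- x[!is.na(x)]
    if (length(xx)) {
      q <- stats::quantile(xx, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      out$median[i] <- q[2]; out$q1[i] <- q[1]; out$q3[i] <- q[3]
      for (th in thresholds)
        out[[sprintf("share_ge_%g", 100 * th)]][i] <- mean(xx >= th)
    } else {
      for (th in thresholds) out[[sprintf("share_ge_%g", 100 * th)]][i] <- 0
    }
  }
  out
}
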