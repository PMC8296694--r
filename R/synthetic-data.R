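# Synthetic multi-omics panel studies with known ground truth.
#
# The generator is the forward model of the variance decomposition: for child
# i in cohort c at visit t,
#   y = mu + sum_k beta_k z_k(i,t) + b_i + g_c + eps_it,
# b ~ N(0, s2_id), g ~ N(0, s2_cohort), eps ~ N(0, s2_res), with the three
# variances scaled so their fractions of the covariate-free total equal the
# requested (f_inter, f_cohort, f_intra). Features belonging to the delta
# network have their two residual draws coupled so the visit-B minus visit-A
# differences follow N(0, Sigma_delta) with Sigma_delta the (rescaled)
# inverse of the requested precision matrix.

# Deterministic named substreams from one root seed, so each stage of a
# study can be regenerated independently.
substream_seed <- function(root, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483562
  as.integer((h + (root %% 2147483562) * 69069) %% 2147483562) + 1L
}

with_substream <- function(root, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
            assign(".Random.seed", old, envir = globalenv()))
  set.seed(substream_seed(root, name))
  expr
}

#' Generate a two-visit panel study design
#'
#' Emulates a multi-cohort European child panel: two visits about six months
#' apart, cohort sizes as equal as possible, inter-individual variables
#' (sex, ancestry, age, maternal education, diet score, zBMI) constant within
#' child and visit-varying sampling covariates drawn independently per visit.
#' Defaults mirror the source panel's population: zBMI ~ N(0.4, 1.2),
#' cohort-specific age means between 6.3 and 10.8 years, and a 89:67
#' male:female ratio.
#'
#' @param n_children number of children (>= `n_cohorts`).
#' @param n_cohorts number of cohorts (default 5).
#' @param seed integer seed; same seed gives an identical table.
#' @param n_plates number of processing plates samples are spread over.
#' @return A design `data.frame` with one row per sample (child x visit).
#' @export
generate_design <- function(n_children, n_cohorts = 5, seed = 1, n_plates = 4) {
  if (n_cohorts < 1 || n_children < n_cohorts)
    stop("need n_children >= n_cohorts >= 1")
  age_means <- rep_len(c(6.7, 10.8, 6.7, 6.3, 8.6), n_cohorts)
  age_sds   <- rep_len(c(0.2, 0.5, 0.5, 0.12, 0.5), n_cohorts)
  with_substream(seed, "design", {
    cohort <- sort(rep_len(seq_len(n_cohorts), n_children))
    child <- sprintf("child_%03d", seq_len(n_children))
    sex <- sample(c("male", "female"), n_children, replace = TRUE,
                  prob = c(89, 67) / 156)
    ancestry <- sample(c("european", "pakistani", "other"), n_children,
                       replace = TRUE, prob = c(145, 10, 1) / 156)
    age <- round(stats::rnorm(n_children, age_means[cohort], age_sds[cohort]), 2)
    medu <- sample(c("primary", "secondary", "university"), n_children,
                   replace = TRUE, prob = c(0.2, 0.4, 0.4))
    kidmed <- pmin(12, pmax(0, round(stats::rnorm(n_children, 5, 2.5))))
    zbmi <- round(stats::rnorm(n_children, 0.4, 1.2), 3)
    per_visit <- function(visit) {
      data.frame(
        sample_id = sprintf("S_%03d_%s", seq_len(n_children), visit),
        child_id = child, cohort = sprintf("cohort_%d", cohort), visit = visit,
        sex = sex, ancestry = ancestry, age = age, maternal_education = medu,
        kidmed_score = kidmed, zbmi = zbmi,
        fasting_hours = round(pmax(0.5, stats::rnorm(n_children,
                              if (visit == "A") 3.5 else 2.6, 1.25)), 2),
        sampling_hour = round(pmin(22, pmax(8, stats::rnorm(n_children,
                              if (visit == "A") 16.9 else 16.3, 3))), 2),
        season = sample(c("winter", "spring", "summer", "autumn"),
                        n_children, replace = TRUE),
        weekday = sample(c("mon", "tue", "wed", "thu", "fri", "sat", "sun"),
                         n_children, replace = TRUE),
        has_cold = sample(c("no", "yes"), n_children, replace = TRUE,
                          prob = c(0.9, 0.1)),
        heavy_exercise = sample(c("no", "yes"), n_children, replace = TRUE,
                                prob = c(0.8, 0.2)),
        stringsAsFactors = FALSE)
    }
    d <- rbind(per_visit("A"), per_visit("B"))
    d <- d[order(d$child_id, d$visit), , drop = FALSE]
    d$run_order <- sample(nrow(d))
    d$plate <- sprintf("plate_%d", 1 + (sample(nrow(d)) %% n_plates))
    rownames(d) <- NULL
    validate_design(d)
  })
}

#' Chain-plus-star precision matrix with known partial correlations
#'
#' Builds a sparse symmetric positive-definite precision matrix whose implied
#' nonzero partial correlations are exactly `rho`: a chain 1-2-...-k,
#' optionally followed by hub-and-leaf stars (a metabolite-like hub connected
#' to several CpG-like leaves). Used as ground truth for network recovery
#' tests. If the unit-diagonal matrix is not positive definite the diagonal is
#' boosted (which shrinks the achieved partial correlations, recorded in the
#' `"diag_boost"` attribute); boosting beyond `boost_cap` is an error.
#'
#' @param p matrix dimension (>= 2).
#' @param rho target partial correlation on the edges, |rho| < 1.
#' @param hub_fraction fraction of the p nodes set aside for stars.
#' @param seed unused randomness guard kept for interface stability; the
#'   construction is deterministic.
#' @param star_size leaves per hub.
#' @param boost_cap maximum diagonal boost factor.
#' @return A `p` x `p` precision matrix with attributes `"pcor"` (the implied
#'   partial-correlation matrix) and `"edges"` (two-column index matrix).
#' @export
generate_chain_precision <- function(p, rho, hub_fraction = 0, seed = 1,
                                     star_size = 4, boost_cap = 4) {
  if (p < 2) stop("need p >= 2")
  if (abs(rho) >= 1) stop("need |rho| < 1")
  n_star_nodes <- floor(hub_fraction * p / (star_size + 1)) * (star_size + 1)
  n_chain <- p - n_star_nodes
  edges <- NULL
  if (n_chain >= 2)
    edges <- cbind(seq_len(n_chain - 1), seq_len(n_chain - 1) + 1L)
  if (n_star_nodes > 0) {
    starts <- seq(n_chain + 1L, p, by = star_size + 1L)
    for (h in starts)
      edges <- rbind(edges, cbind(h, h + seq_len(star_size)))
  }
  omega <- diag(p)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    omega[i, j] <- omega[j, i] <- -rho
  }
  boost <- 1
  while (TRUE) {
    om <- omega; diag(om) <- boost
    if (min(eigen(om, symmetric = TRUE, only.values = TRUE)$values) > 1e-10) break
    boost <- boost * 1.1
    if (boost > boost_cap)
      stop("precision matrix not positive definite within diagonal boost cap")
  }
  diag(omega) <- boost
  d <- sqrt(diag(omega))
  pcor <- -omega / tcrossprod(d)
  diag(pcor) <- 1
  structure(omega, pcor = pcor, edges = edges, diag_boost = boost)
}

# Dirichlet draw, one row per feature.
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

#' Assemble a ground-truth object for the synthetic generator
#'
#' @param features data.frame with columns `feature_id`, `layer_id`,
#'   `f_inter`, `f_cohort`, `f_intra` (fractions summing to 1), and optionally
#'   `mu` (feature mean, default 0), `total_var` (covariate-free total
#'   variance, default 1) and `beta_mean` (target methylation beta mean).
#' @param effects optional data.frame with columns `feature_id`, `variable`,
#'   `beta`: fixed shifts `beta * z` added on the standardized scale of the
#'   design variable, on top of the fraction-scaled noise.
#' @param delta_precision optional precision matrix from
#'   [generate_chain_precision()] whose row/colnames name the coupled
#'   features.
#' @param seed root seed all generation substreams derive from.
#' @return An object of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(features, effects = NULL, delta_precision = NULL,
                            seed = 1) {
  stopifnot(is.data.frame(features),
            all(c("feature_id", "layer_id", "f_inter", "f_cohort", "f_intra")
                %in% names(features)))
  if (anyDuplicated(features$feature_id)) stop("duplicate feature_id in truth")
  s <- features$f_inter + features$f_cohort + features$f_intra
  if (any(abs(s - 1) > 1e-12))
    stop("fractions (f_inter, f_cohort, f_intra) must sum to 1")
  if (any(features$f_inter < 0 | features$f_cohort < 0 | features$f_intra < 0))
    stop("fractions must be non-negative")
  if (is.null(features$mu)) features$mu <- 0
  if (is.null(features$total_var)) features$total_var <- 1
  if (!is.null(delta_precision)) {
    ids <- rownames(delta_precision)
    if (is.null(ids) || !all(ids %in% features$feature_id))
      stop("delta_precision row names must name features in the truth table")
    if (max(abs(delta_precision - t(delta_precision))) > 1e-12)
      stop("delta_precision must be symmetric")
  }
  structure(list(features = features, effects = effects,
                 delta_precision = delta_precision, seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d features over %d layers, seed %d\n",
              nrow(x$features), length(unique(x$features$layer_id)), x$seed))
  if (!is.null(x$effects))
    cat("  trait effects on", length(unique(x$effects$feature_id)), "features\n")
  if (!is.null(x$delta_precision))
    cat("  delta network over", nrow(x$delta_precision), "features\n")
  invisible(x)
}

# Joint delta draws for all network-coupled features, on the correlation
# scale (unit marginal variance), keyed on the truth's own substream so the
# same draws are shared by every layer containing coupled features.
coupled_deltas <- function(truth, child_ids) {
  omega <- truth$delta_precision
  sigma <- solve(omega)
  cc <- stats::cov2cor(sigma)
  ch <- chol(cc)
  with_substream(truth$seed, "delta", {
    z <- matrix(stats::rnorm(length(child_ids) * nrow(cc)), length(child_ids))
    d <- z %*% ch
    dimnames(d) <- list(child_ids, rownames(omega))
    d
  })
}

#' Generate one omics layer from ground truth
#'
#' Draws per-feature cohort effects, child effects and residuals scaled to
#' the truth's variance fractions, adds any fixed trait shifts on the
#' standardized covariate scale, couples the residuals of delta-network
#' features so between-visit differences follow the truth's precision matrix,
#' and (for methylation, by default) squashes values into (0, 1) with a
#' logistic map centered at the feature mean.
#'
#' @param design a design table from [generate_design()].
#' @param truth a [synthetic_truth()] covering this layer's features.
#' @param layer_id which layer to generate.
#' @param squash apply the logistic beta-value squash? Defaults to `TRUE` for
#'   methylation. Recovery tests run on the pre-squash scale by passing
#'   `FALSE`.
#' @return An [omics_layer()].
#' @export
generate_layer <- function(design, truth, layer_id,
                           squash = identical(layer_id, "methylation")) {
  design <- validate_design(design)
  ft <- truth$features[truth$features$layer_id == layer_id, , drop = FALSE]
  if (!nrow(ft)) stop("truth has no features for layer ", layer_id)
  n <- nrow(design)
  children <- unique(design$child_id)
  cohorts <- unique(design$cohort)
  i_child <- match(design$child_id, children)
  i_coh <- match(design$cohort, cohorts)
  is_b <- design$visit == "B"

  coupled <- character(0)
  if (!is.null(truth$delta_precision))
    coupled <- intersect(rownames(truth$delta_precision), ft$feature_id)
  dmat <- if (length(coupled)) coupled_deltas(truth, children) else NULL

  eff <- truth$effects
  if (!is.null(eff)) eff <- eff[eff$feature_id %in% ft$feature_id, , drop = FALSE]
  zcols <- list()
  if (!is.null(eff) && nrow(eff)) {
    for (v in unique(eff$variable)) {
      x <- design[[v]]
      if (is.null(x)) stop("effect variable '", v, "' not in design")
      if (!is.numeric(x)) x <- as.numeric(factor(x))
      zcols[[v]] <- as.numeric(scale(x))
    }
  }

  with_substream(truth$seed, paste0("layer:", layer_id), {
    p <- nrow(ft)
    s_id <- sqrt(ft$f_inter * ft$total_var)
    s_coh <- sqrt(ft$f_cohort * ft$total_var)
    s_res <- sqrt(ft$f_intra * ft$total_var)
    # random-effect draws are rescaled to their exact empirical variance so
    # the realized variance fractions equal the truth's, not just in
    # expectation: with few levels (5 cohorts) the raw draws' sample
    # variance would otherwise dominate the recovery error of any estimator
    exact_rows <- function(m) {
      if (ncol(m) < 2) return(m * 0)
      m <- m - rowMeans(m)
      sd_r <- sqrt(rowSums(m^2) / (ncol(m) - 1))
      sd_r[sd_r == 0] <- 1
      m / sd_r
    }
    B <- exact_rows(matrix(stats::rnorm(p * length(children)), p)) * s_id
    G <- exact_rows(matrix(stats::rnorm(p * length(cohorts)), p)) * s_coh
    E <- matrix(stats::rnorm(p * n), p) * s_res
    if (length(coupled)) {
      # eps_A = (s - d)/2, eps_B = (s + d)/2 with Var(s) = Var(d) = 2 s2_res
      # gives Var(eps) = s2_res, Cov(eps_A, eps_B) = 0, and
      # eps_B - eps_A = d with the requested cross-feature delta covariance.
      jj <- match(coupled, ft$feature_id)
      D <- t(dmat[, coupled, drop = FALSE]) * (sqrt(2) * s_res[jj])
      S <- matrix(stats::rnorm(length(jj) * length(children)),
                  length(jj)) * (sqrt(2) * s_res[jj])
      Ec <- (S[, i_child, drop = FALSE] +
               D[, i_child, drop = FALSE] * rep(ifelse(is_b, 1, -1),
                                                each = length(jj))) / 2
      E[jj, ] <- Ec
    }
    y <- ft$mu + B[, i_child, drop = FALSE] + G[, i_coh, drop = FALSE] + E
    dimnames(y) <- list(ft$feature_id, design$sample_id)
    if (!is.null(eff) && nrow(eff)) {
      for (r in seq_len(nrow(eff)))
        y[eff$feature_id[r], ] <- y[eff$feature_id[r], ] +
          eff$beta[r] * zcols[[eff$variable[r]]]
    }
    if (squash) {
      bm <- if (!is.null(ft$beta_mean)) ft$beta_mean else
        stats::runif(nrow(ft), 0.15, 0.85)
      y <- stats::plogis(y - ft$mu + stats::qlogis(bm))
      omics_layer(y, layer_id, is_methylation_beta = TRUE)
    } else {
      omics_layer(y, layer_id, is_log2 = !identical(layer_id, "methylation"),
                  is_methylation_beta = FALSE)
    }
  })
}

#' Default configuration for [generate_study()]
#'
#' Returns the full configuration list with the shipped defaults: 150
#' children in 5 cohorts, six omics layers at reduced feature counts,
#' per-layer Dirichlet priors over (inter, cohort, intra) fractions, a
#' CpG/serum-metabolite delta network of chain and metabolite-hub stars,
#' trait effects on a few features, plate shifts on the protein layer,
#' planted quality-control violations with known counts, and a CpG-context
#' annotation with shore enrichment among high inter-individual-variability
#' CpGs.
#'
#' @return A named list; override entries via the `config` argument of
#'   [generate_study()].
#' @export
default_study_config <- function() {
  list(
    n_children = 150,
    n_cohorts = 5,
    n_plates = 4,
    missing_child_rate = 0.04,
    layers = list(
      methylation     = list(n_features = 120, fraction_alpha = c(2, 0.3, 3)),
      gene_expression = list(n_features = 80,  fraction_alpha = c(1, 0.5, 4)),
      mirna           = list(n_features = 30,  fraction_alpha = c(1.5, 0.5, 3)),
      proteins        = list(n_features = 36,  fraction_alpha = c(3, 1, 2)),
      serum_metab     = list(n_features = 60,  fraction_alpha = c(3, 0.5, 3)),
      urine_metab     = list(n_features = 44,  fraction_alpha = c(1.5, 0.5, 4))
    ),
    effects = list(
      list(variable = "zbmi", layer = "proteins", n_features = 6, frac = 0.15),
      list(variable = "sampling_hour", layer = "serum_metab", n_features = 10,
           frac = 0.10)
    ),
    plant = list(
      call_rate = c(methylation = 6, gene_expression = 8, mirna = 4),
      icc = c(methylation = 24),
      cv = c(serum_metab = 8, urine_metab = 5),
      bld = c(serum_metab = 6),
      linear_range = c(proteins = 5)
    ),
    plate_effect_sd = 0.25,
    metab_raw_scale = TRUE,
    context = list(plant_component = "inter", category = "shore", fold = 3),
    network = list(n_cpg = 40, n_serum = 10, rho = 0.45, star_size = 2)
  )
}

check_config_keys <- function(config, defaults, where = "config") {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown ", where, " key: ", paste(unknown, collapse = ", "))
  invisible(TRUE)
}

#' Draw CpG island-context annotations, optionally enriched in a quartile
#'
#' Assigns island/shore/shelf/open-sea labels. When `plant` is given, features
#' in the top quartile of the named fraction component receive the planted
#' category with `fold` times its baseline probability (capped, remaining
#' probabilities renormalized), creating a known enrichment signal.
#'
#' @param fractions data.frame with `feature_id` and fraction columns
#'   (`f_inter`, `f_intra`, ...).
#' @param plant `NULL` or `list(component = "f_inter", category = "shore",
#'   fold = 3)`.
#' @param seed integer seed.
#' @param base_probs baseline category probabilities.
#' @return data.frame of `feature_id`, `island_context`.
#' @export
generate_cpg_context <- function(fractions, plant = NULL, seed = 1,
                                 base_probs = c(island = 0.30, shore = 0.25,
                                                shelf = 0.15, open_sea = 0.30)) {
  cats <- names(base_probs)
  with_substream(seed, "context", {
    n <- nrow(fractions)
    ctx <- sample(cats, n, replace = TRUE, prob = base_probs)
    if (!is.null(plant)) {
      comp <- fractions[[plant$component]]
      if (is.null(comp)) stop("unknown fraction component ", plant$component)
      q3 <- stats::quantile(comp, 0.75, type = 7, names = FALSE)
      hot <- which(comp >= q3)
      pp <- base_probs
      pp[plant$category] <- min(0.9, plant$fold * base_probs[[plant$category]])
      rest <- setdiff(cats, plant$category)
      pp[rest] <- pp[rest] * (1 - pp[plant$category]) / sum(base_probs[rest])
      ctx[hot] <- sample(cats, length(hot), replace = TRUE, prob = pp)
    }
    data.frame(feature_id = fractions$feature_id, island_context = ctx,
               stringsAsFactors = FALSE)
  })
}

# Detection-style flag matrix with an exact set of violating features:
# violators get a detected fraction strictly below min_rate, the rest are
# detected at or above it. Violators default to the last features so planted
# rule sets stay clear of the network features at the front of each layer.
plant_flag_matrix <- function(feature_ids, sample_ids, n_bad, min_rate,
                              bad_rate = max(0, min_rate - 0.1),
                              good_rate = 1,
                              bad_idx = utils::tail(seq_along(feature_ids), n_bad)) {
  p <- length(feature_ids); n <- length(sample_ids)
  flags <- matrix(TRUE, p, n, dimnames = list(feature_ids, sample_ids))
  n_det_bad <- min(n - 1, floor(bad_rate * n))
  if (n_det_bad / n >= min_rate) n_det_bad <- ceiling(min_rate * n) - 1L
  n_det_good <- max(ceiling(good_rate * n * 0.999), ceiling(min_rate * n))
  n_det_good <- min(n, n_det_good)
  for (j in seq_len(p)) {
    k <- if (j %in% bad_idx) n_det_bad else n_det_good
    if (k < n) flags[j, sample(n, n - k)] <- FALSE
  }
  flags
}

#' Generate a complete synthetic multi-omics panel study
#'
#' Builds a self-consistent study: design table, six omics layers generated
#' from sampled ground-truth variance fractions, per-layer feature
#' annotations (probe reliability, CpG context, detection / linear-range /
#' below-LOD flags with exact planted violation counts), plate shifts on the
#' protein layer, raw-scale metabolite matrices with controlled coefficients
#' of variation, and a known sparse delta-network over CpG and serum features.
#' The ground truth is retained for recovery tests.
#'
#' @param config partial configuration; entries override
#'   [default_study_config()]. Unknown keys are an error.
#' @param seed root seed; all stages derive named substreams from it.
#' @return A list with elements `layers` (named [omics_layer()]s), `design`,
#'   `annotations` (per layer: `table`, and flag matrices where applicable),
#'   `truth` (a [synthetic_truth()]), and `planted` (the violation counts).
#' @export
generate_study <- function(config = list(), seed = 1) {
  defaults <- default_study_config()
  check_config_keys(config, defaults)
  if (!is.null(config$layers)) {
    check_config_keys(config$layers, defaults$layers, "config$layers")
    for (nm in names(config$layers)) {
      check_config_keys(config$layers[[nm]], c(defaults$layers[[nm]],
                                               list(total_var = 1)),
                        paste0("config$layers$", nm))
      defaults$layers[[nm]] <- utils::modifyList(defaults$layers[[nm]],
                                                 config$layers[[nm]])
    }
    config$layers <- NULL
  }
  cfg <- utils::modifyList(defaults, config)

  design <- generate_design(cfg$n_children, cfg$n_cohorts, seed, cfg$n_plates)

  # --- ground-truth fractions per layer
  feats <- NULL
  with_substream(seed, "fractions", {
    for (lid in names(cfg$layers)) {
      lc <- cfg$layers[[lid]]
      fr <- rdirichlet(lc$n_features, lc$fraction_alpha)
      feats <- rbind(feats, data.frame(
        feature_id = sprintf("%s_%04d", sub("_.*", "", lid), seq_len(lc$n_features)),
        layer_id = lid, f_inter = fr[, 1], f_cohort = fr[, 2], f_intra = fr[, 3],
        mu = stats::rnorm(lc$n_features, 0, 2),
        total_var = if (is.null(lc$total_var)) 1 else lc$total_var,
        stringsAsFactors = FALSE))
    }
  })

  # --- delta network: chain of CpGs plus serum-metabolite hubs with CpG leaves
  net <- cfg$network
  delta_prec <- NULL
  if (!is.null(net) && net$n_cpg + net$n_serum >= 2) {
    meth_ids <- feats$feature_id[feats$layer_id == "methylation"]
    serum_ids <- feats$feature_id[feats$layer_id == "serum_metab"]
    if (length(meth_ids) < net$n_cpg || length(serum_ids) < net$n_serum)
      stop("network spec asks for more features than the layers hold")
    cpg_net <- meth_ids[seq_len(net$n_cpg)]
    ser_net <- serum_ids[seq_len(net$n_serum)]
    p_net <- net$n_cpg + net$n_serum
    n_star_nodes <- net$n_serum * (net$star_size + 1)
    if (n_star_nodes > p_net) stop("star_size too large for network spec")
    hub_fraction <- n_star_nodes / p_net
    delta_prec <- generate_chain_precision(p_net, net$rho, hub_fraction,
                                           star_size = net$star_size)
    # order ids so the star hubs are the serum metabolites
    n_chain <- p_net - n_star_nodes
    leaf_cpgs <- cpg_net[-seq_len(n_chain)]
    ord <- cpg_net[seq_len(n_chain)]
    for (h in seq_len(net$n_serum)) {
      ord <- c(ord, ser_net[h],
               leaf_cpgs[(h - 1) * net$star_size + seq_len(net$star_size)])
    }
    dimnames(delta_prec) <- list(ord, ord)
    # network CpGs are pure intra-individual signal; network metabolites sit
    # high in the intra distribution so the quartile rule selects them
    i_cpg <- match(cpg_net, feats$feature_id)
    feats$f_inter[i_cpg] <- 0; feats$f_cohort[i_cpg] <- 0; feats$f_intra[i_cpg] <- 1
    i_ser <- match(ser_net, feats$feature_id)
    feats$f_intra[i_ser] <- 0.92
    feats$f_inter[i_ser] <- 0.06
    feats$f_cohort[i_ser] <- 0.02
  }

  # --- trait effects
  eff_tab <- NULL
  with_substream(seed, "effects", {
    for (e in cfg$effects) {
      pool <- feats$feature_id[feats$layer_id == e$layer]
      if (!is.null(delta_prec)) pool <- setdiff(pool, rownames(delta_prec))
      pick <- sample(pool, min(e$n_features, length(pool)))
      tv <- feats$total_var[match(pick, feats$feature_id)]
      eff_tab <- rbind(eff_tab, data.frame(
        feature_id = pick, variable = e$variable,
        beta = sqrt(e$frac / (1 - e$frac) * tv), stringsAsFactors = FALSE))
    }
  })

  truth <- synthetic_truth(feats, effects = eff_tab,
                           delta_precision = delta_prec, seed = seed)

  # --- layers, with per-layer sample availability
  layers <- list(); annotations <- list()
  planted <- cfg$plant
  for (lid in names(cfg$layers)) {
    layer <- generate_layer(design, truth, lid)
    with_substream(seed, paste0("dropout:", lid), {
      n_drop <- round(cfg$missing_child_rate * cfg$n_children)
      if (n_drop > 0) {
        ch <- sample(unique(design$child_id), n_drop)
        drop_sids <- design$sample_id[design$child_id %in% ch & design$visit == "B"]
        layer$values <- layer$values[, !colnames(layer$values) %in% drop_sids,
                                     drop = FALSE]
      }
    })
    sid <- colnames(layer$values)
    fid <- rownames(layer$values)
    ann <- list(table = data.frame(feature_id = fid, stringsAsFactors = FALSE))

    with_substream(seed, paste0("annot:", lid), {
      # planted rule sets occupy disjoint blocks at the tail of the layer so
      # sequentially applied filters each find exactly their planted count
      n_cr <- if (lid %in% names(planted$call_rate)) planted$call_rate[[lid]] else 0
      n_icc <- if (lid %in% names(planted$icc)) planted$icc[[lid]] else 0
      n_cv <- if (lid %in% names(planted$cv)) planted$cv[[lid]] else 0
      n_bld <- if (lid %in% names(planted$bld)) planted$bld[[lid]] else 0
      p_lay <- length(fid)
      if (n_cr > 0) {
        min_rate <- if (lid == "methylation") 0.98 else 0.25
        ann$detection <- plant_flag_matrix(fid, sid, n_cr, min_rate,
                                           bad_idx = utils::tail(seq_len(p_lay), n_cr))
      }
      if (n_icc > 0) {
        icc <- stats::runif(p_lay, 0.63, 0.99)
        icc_idx <- p_lay - n_cr - seq_len(n_icc) + 1L
        icc[icc_idx] <- stats::runif(n_icc, 0.30, 0.62)
        ann$table$icc <- round(icc, 4)
      }
      if (lid %in% names(planted$linear_range)) {
        n_lin <- planted$linear_range[[lid]]
        ann$linear_range <- plant_flag_matrix(fid, sid, n_lin, 0.30,
                                              bad_rate = 0.2, good_rate = 0.9)
      }
      if (n_bld > 0) {
        bld_idx <- p_lay - n_cv - seq_len(n_bld) + 1L
        bld <- !plant_flag_matrix(fid, sid, n_bld, 0.65,
                                  bad_rate = 0.6, good_rate = 0.95,
                                  bad_idx = bld_idx)
        # bld fraction: planted ~0.4 (> 0.30 excluded), clean ~0.05
        ann$below_lod <- bld
      }
      if (lid == "methylation") {
        ctx <- generate_cpg_context(feats[feats$layer_id == lid, ],
                                    plant = list(
                                      component = paste0("f_", sub("^f_", "",
                                        cfg$context$plant_component)),
                                      category = cfg$context$category,
                                      fold = cfg$context$fold),
                                    seed = substream_seed(seed, "ctx"))
        ann$table$island_context <- ctx$island_context[match(fid, ctx$feature_id)]
      }
    })

    # plate shifts then raw-scale transform where the real pipelines expect it
    if (lid == "proteins" && cfg$plate_effect_sd > 0) {
      with_substream(seed, "plate", {
        pl <- design$plate[match(sid, design$sample_id)]
        shifts <- matrix(stats::rnorm(length(fid) * cfg$n_plates, 0,
                                      cfg$plate_effect_sd), length(fid))
        colnames(shifts) <- sort(unique(design$plate))
        layer$values <- layer$values + shifts[, pl, drop = FALSE]
      })
    }
    if (cfg$metab_raw_scale && lid %in% c("serum_metab", "urine_metab")) {
      with_substream(seed, paste0("raw:", lid), {
        n_cv <- if (lid %in% names(planted$cv)) planted$cv[[lid]] else 0
        p <- length(fid)
        cv <- stats::runif(p, 0.08, 0.27)
        if (n_cv > 0) {
          bad <- p - seq_len(n_cv) + 1L  # last features carry the CV violations
          cv[bad] <- stats::runif(n_cv, 0.35, 0.55)
        }
        m <- 2^stats::runif(p, 5, 10)
        z <- layer$values
        z <- (z - rowMeans(z)) / apply(z, 1, stats::sd)
        clamp <- pmin(2.8, 0.9 / cv)
        z <- pmin(pmax(z, -clamp), clamp)
        z <- (z - rowMeans(z)) / apply(z, 1, stats::sd)  # exact mean 0, sd 1
        layer$values <- m * (1 + cv * z)
        layer$is_log2 <- FALSE
        ann$table$true_cv <- round(cv, 4)
      })
    }
    layers[[lid]] <- layer
    annotations[[lid]] <- ann
  }

  list(layers = layers, design = design, annotations = annotations,
       truth = truth, planted = planted, config = cfg)
}

#' Write a synthetic study to a directory of delimited-text fixtures
#'
#' One TSV per layer and annotation table, flag matrices as 0/1 TSVs, the
#' design table, and the ground truth as JSON. Same seed, same files,
#' byte for byte.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(as.data.frame(study$design), file.path(dir, "design.tsv"))
  for (lid in names(study$layers)) {
    write_table(study$layers[[lid]], file.path(dir, paste0(lid, ".tsv")))
    ann <- study$annotations[[lid]]
    if (!is.null(ann$table) && ncol(ann$table) > 1)
      write_table(ann$table, file.path(dir, paste0(lid, "_annotation.tsv")))
    for (fl in c("detection", "linear_range", "below_lod")) {
      if (!is.null(ann[[fl]]))
        write_table(ann[[fl]] * 1, file.path(dir, paste0(lid, "_", fl, ".tsv")))
    }
  }
  tr <- study$truth
  jsonlite::write_json(
    list(features = tr$features, effects = tr$effects,
         delta_precision = tr$delta_precision,
         delta_feature_ids = rownames(tr$delta_precision),
         seed = tr$seed, planted = study$planted),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
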