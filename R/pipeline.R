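# End-to-end orchestration: simulate (or read) -> preprocess -> variance
# partition (models 1 and 2) -> delta-network feature selection and GGM ->
# CpG-context enrichment, with a JSON run manifest. Every stage is also an
# exported function with the same contract, so the pipeline is a thin
# sequence of library calls.

default_run_config <- function() {
  list(
    study = list(),        # overrides for generate_study()
    inputs = NULL,         # or list(design = path, layers = named paths,
                           #         is_log2 = ids of already-log2 layers)
    filters = list(call_rate_methylation = 0.98, call_rate_expression = 0.25,
                   min_icc = 0.625, max_cv = 0.30, max_bld = 0.30,
                   min_linear_range = 0.30),
    log2_offset = 0,
    model2 = TRUE,
    ggm = TRUE,
    q = 0.05,
    ggm_layers = c("methylation", "proteins", "serum_metab", "urine_metab"),
    enrichment = TRUE
  )
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- default_run_config()
  check_config_keys(config, defaults, "run config")
  if (!is.null(config$filters))
    check_config_keys(config$filters, defaults$filters, "config$filters")
  utils::modifyList(defaults, config, keep.null = TRUE)
}

read_study_inputs <- function(inputs) {
  if (is.null(inputs$design)) stop("config$inputs lacks key: design")
  if (is.null(inputs$layers)) stop("config$inputs lacks key: layers")
  design <- read_design(inputs$design)
  layers <- list()
  for (lid in names(inputs$layers))
    layers[[lid]] <- read_layer(inputs$layers[[lid]], lid,
                                is_log2 = lid %in% inputs$is_log2)
  list(design = design, layers = layers,
       annotations = lapply(layers, function(l)
         list(table = data.frame(feature_id = rownames(l$values),
                                 stringsAsFactors = FALSE))),
       truth = NULL)
}

preprocess_layer <- function(layer, ann, design, filters, log2_offset) {
  reports <- list()
  lid <- layer$layer_id
  if (!is.null(ann$detection)) {
    rate <- if (lid == "methylation") filters$call_rate_methylation
            else filters$call_rate_expression
    r <- filter_call_rate(layer, ann$detection, rate)
    layer <- r$layer; reports <- c(reports, list(r$report))
  }
  if (!is.null(ann$table$icc)) {
    r <- filter_icc(layer, ann$table, filters$min_icc)
    layer <- r$layer; reports <- c(reports, list(r$report))
  }
  if (!is.null(ann$linear_range)) {
    r <- filter_linear_range(layer, ann$linear_range, filters$min_linear_range)
    layer <- r$layer; reports <- c(reports, list(r$report))
  }
  if (lid %in% c("serum_metab", "urine_metab") && !layer$is_log2) {
    r <- filter_cv(layer, filters$max_cv, bld_flags = ann$below_lod,
                   max_bld = filters$max_bld)
    layer <- r$layer; reports <- c(reports, list(r$report))
  }
  if (!layer$is_log2 && !layer$is_methylation_beta)
    layer <- log2_transform(layer, offset = log2_offset)
  if (lid == "proteins" && "plate" %in% names(design)) {
    plate <- stats::setNames(design$plate, design$sample_id)
    layer <- plate_center(layer, plate[sample_ids(layer)])
  }
  list(layer = layer, reports = reports)
}

report_to_list <- function(rep) {
  list(layer_id = rep$layer_id, n_input = rep$n_input,
       n_output = rep$n_output, n_excluded = as.list(rep$n_excluded))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> preprocess -> variance partition (model 1
#' and, optionally, model 2) -> delta-network feature selection, GGM and
#' export -> CpG-context enrichment, writing all stage outputs and a
#' manifest JSON under `out_dir`. Reruns with the same config and seed
#' produce byte-identical outputs.
#'
#' @param config a configuration list or path to a YAML file; see
#'   `omicvar:::default_run_config()` for the keys. With `inputs = NULL`
#'   (default) a synthetic study is generated from `config$study`.
#' @param out_dir output directory, created if needed.
#' @param seed root seed for the synthetic study.
#' @return The manifest, invisibly. A failed stage raises an error after
#'   writing a manifest whose `failed_stage` names it; outputs of earlier
#'   stages are retained.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("omicvar_run_"),
                         seed = 1) {
  cfg <- load_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("omicvar")),
                   seed = seed, q = cfg$q, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  study <- stage("simulate", {
    if (is.null(cfg$inputs)) generate_study(cfg$study, seed)
    else read_study_inputs(cfg$inputs)
  })
  manifest$stages$simulate <- list(
    n_children = length(unique(study$design$child_id)),
    n_samples = nrow(study$design),
    layers = lapply(study$layers, function(l) nrow(l$values)))

  pp <- stage("preprocess", {
    out <- list(); reps <- list()
    for (lid in names(study$layers)) {
      r <- preprocess_layer(study$layers[[lid]], study$annotations[[lid]],
                            study$design, cfg$filters, cfg$log2_offset)
      out[[lid]] <- r$layer
      reps[[lid]] <- lapply(r$reports, report_to_list)
    }
    jsonlite::write_json(reps, file.path(out_dir, "filter_reports.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out
  })
  manifest$stages$preprocess <- lapply(pp, function(l) nrow(l$values))

  vp1 <- list(); vp2 <- list()
  stage("varpart", {
    for (lid in names(pp)) {
      al <- align(pp[[lid]], study$design, pairs_only = TRUE)
      vp1[[lid]] <- varpart(al$layer, al$design, model = 1)
      write_table(as.data.frame(vp1[[lid]]),
                  file.path(out_dir, paste0("fractions_model1_", lid, ".tsv")))
      write_table(summarize_fractions(vp1[[lid]]),
                  file.path(out_dir, paste0("summary_model1_", lid, ".tsv")))
      if (isTRUE(cfg$model2)) {
        vp2[[lid]] <- varpart(al$layer, al$design, model = 2)
        write_table(as.data.frame(vp2[[lid]]),
                    file.path(out_dir, paste0("fractions_model2_", lid, ".tsv")))
        write_table(summarize_fractions(vp2[[lid]]),
                    file.path(out_dir, paste0("summary_model2_", lid, ".tsv")))
      }
    }
  })
  manifest$stages$varpart <- list(
    model1 = lapply(vp1, nrow),
    model2 = if (length(vp2)) lapply(vp2, nrow) else NULL,
    collinearity = lapply(vp2, function(v) attr(v, "collinearity")$score))

  ggm <- if (isTRUE(cfg$ggm)) stage("ggm", {
    feats <- select_ggm_features(vp1[intersect(cfg$ggm_layers, names(vp1))])
    if (is.null(feats) || nrow(feats) < 3)
      stop("fewer than 3 features selected for the delta network")
    delta <- build_delta(pp, study$design, feats)
    fit <- delta_ggm(delta, q = cfg$q)
    ns <- network_summary(fit$edges, attr(delta, "layer_id"))
    export_network(fit$edges, ns, out_dir, provenance = attr(delta, "layer_id"))
    jsonlite::write_json(
      list(n_children = nrow(delta), n_features = ncol(delta),
           lambda_star = fit$lambda_star, kappa_hat = fit$kappa_hat,
           n_nodes = ns$n_nodes, n_edges = ns$n_edges,
           n_components = if (is.null(ns$components)) 0 else nrow(ns$components),
           cross_omics_components = if (!is.null(ns$components$cross_omics))
             sum(ns$components$cross_omics) else 0),
      file.path(out_dir, "ggm_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(fit = fit, summary = ns, delta = delta)
  }) else NULL
  if (!is.null(ggm))
    manifest$stages$ggm <- list(n_children = nrow(ggm$delta),
                                n_features = ncol(ggm$delta),
                                n_edges = nrow(ggm$fit$edges),
                                lambda_star = ggm$fit$lambda_star,
                                kappa_hat = ggm$fit$kappa_hat)

  if (isTRUE(cfg$enrichment) && "methylation" %in% names(vp1) &&
      "island_context" %in% names(study$annotations$methylation$table)) {
    enr <- stage("enrichment", {
      res <- as.data.frame(vp1$methylation)
      ann <- study$annotations$methylation$table
      out <- NULL
      for (comp in c("frac_inter", "frac_intra")) {
        fl <- quartile_flags(stats::setNames(res[[comp]], res$feature_id))
        e <- context_enrichment(fl, ann)
        e$component <- sub("^frac_", "", comp)
        out <- rbind(out, as.data.frame(e))
      }
      if ("icc" %in% names(ann)) {
        cc <- icc_concordance(stats::setNames(res$frac_intra, res$feature_id), ann)
        jsonlite::write_json(cc, file.path(out_dir, "icc_concordance.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      }
      write_table(out, file.path(out_dir, "enrichment.tsv"))
      out
    })
    manifest$stages$enrichment <- list(n_tests = nrow(enr))
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest$outputs <- as.list(stats::setNames(
    unname(tools::md5sum(file.path(out_dir, files))), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
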