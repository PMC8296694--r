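fake_varpart <- function(ids, intra) {
  data.frame(feature_id = ids, frac_intra = intra, stringsAsFactors = FALSE)
}

test_that("feature selection follows the per-layer quartile and unity rules", {
  res <- list(
    serum_metab = fake_varpart(sprintf("m%d", 1:8), seq(0.1, 0.8, by = 0.1)),
    methylation = fake_varpart(c("c1", "c2", "c3", "c4"),
                               c(1, 0.999999999, 0.99, 0.5)))
  sel <- select_ggm_features(res)
  # serum: top quartile of 8 = the two largest
  expect_identical(sel$feature_id[sel$layer_id == "serum_metab"],
                   c("m7", "m8"))
  # methylation: exactly-one within tolerance
  expect_identical(sel$feature_id[sel$layer_id == "methylation"],
                   c("c1", "c2"))
  # quartile-boundary ties are all included
  res2 <- list(proteins = fake_varpart(sprintf("p%d", 1:8),
                                       c(0.1, 0.2, 0.3, 0.4, 0.7, 0.7, 0.7, 0.7)))
  sel2 <- select_ggm_features(res2)
  expect_identical(sort(sel2$feature_id), c("p5", "p6", "p7", "p8"))
  # expression is not eligible by default; empty layers drop with a warning
  res3 <- list(gene_expression = fake_varpart("g1", 1),
               methylation = fake_varpart("c1", 0.2))
  expect_warning(sel3 <- select_ggm_features(res3), "dropped")
  expect_null(sel3)
})

test_that("delta assembly pairs visits, drops incomplete children, standardizes", {
  d <- generate_design(6, 2, seed = 9)
  m <- matrix(0, 2, 12, dimnames = list(c("f1", "f2"), d$sample_id))
  m["f1", ] <- ifelse(d$visit == "A", 1.0, 2.5)
  m["f2", ] <- rnorm(12)
  lay <- toy_layer(m, "serum_metab")
  feats <- data.frame(feature_id = c("f1", "f2"), layer_id = "serum_metab")
  # constant delta of 1.5 for f1 -> zero variance -> dropped with warning
  expect_warning(dm <- build_delta(list(serum_metab = lay), d, feats),
                 "zero-variance")
  expect_identical(colnames(dm), "f2")
  # unstandardized check of the raw difference
  dm2 <- suppressWarnings(build_delta(list(serum_metab = lay), d, feats,
                                      standardize = FALSE))
  expect_equal(unname(attr(dm2, "layer_id")[["f2"]]), "serum_metab")

  # child missing visit B in one layer vanishes from all rows
  keep <- !(d$child_id == "child_003" & d$visit == "B")
  lay2 <- toy_layer(matrix(rnorm(2 * sum(keep)), 2,
                           dimnames = list(c("g1", "g2"), d$sample_id[keep])),
                    "urine_metab")
  feats2 <- rbind(feats,
                  data.frame(feature_id = c("g1", "g2"),
                             layer_id = "urine_metab"))
  dm3 <- suppressWarnings(
    build_delta(list(serum_metab = lay, urine_metab = lay2), d, feats2))
  expect_false("child_003" %in% rownames(dm3))
  # standardized columns have mean 0, sd 1
  expect_true(all(abs(colMeans(dm3)) < 1e-12))
  expect_equal(unname(apply(dm3, 2, sd)), rep(1, ncol(dm3)))
})

test_that("shrinkage intensity matches the double-loop oracle exactly", {
  set.seed(31)
  x <- matrix(rnorm(50), 5, 10)
  sh <- shrink_correlation(x)
  expect_equal(sh$lambda_star, lambda_star_oracle(x), tolerance = 1e-12)
  x2 <- matrix(rnorm(200), 20, 10)
  expect_equal(shrink_correlation(x2)$lambda_star, lambda_star_oracle(x2),
               tolerance = 1e-12)
  expect_error(shrink_correlation(x[1:2, ]), "at least 3")
})

test_that("a zero variance-of-correlations numerator means no shrinkage", {
  # columns standardized to constant magnitude: every product w_k is 1, so
  # the variance-of-correlations numerator is exactly 0 and lambda* = 0
  s <- rep(c(1, -1), 10)
  x <- cbind(s, 3 * s)
  sh <- shrink_correlation(x)
  expect_equal(sh$lambda_star, 0)
  expect_equal(sh$R_star[1, 2], 1, tolerance = 1e-12)

  lambdas <- vapply(1:20, function(s) {
    set.seed(s)
    shrink_correlation(matrix(rnorm(20 * 50), 20, 50))$lambda_star
  }, 1)
  expect_gt(mean(lambdas), 0.5)
})

test_that("partial correlations equal the regression-residual oracle", {
  for (p in c(4, 7, 10)) {
    set.seed(p)
    x <- matrix(rnorm(200 * p), 200, p)
    x[, p] <- rowSums(x[, 1:2]) + rnorm(200, sd = 0.3)
    sh <- shrink_correlation(x)
    sh$lambda_star <- 0
    sh$R_star <- sh$R
    pc <- partial_correlations(sh, method = "dense")
    expect_equal(pc, pcor_residual_oracle(x), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("two-variable and identity cases reduce to closed forms", {
  set.seed(4)
  x <- matrix(rnorm(60), 30, 2)
  sh <- shrink_correlation(x)
  pc <- partial_correlations(sh)
  expect_equal(pc[1, 2], sh$R_star[1, 2] /
                 sqrt(sh$R_star[1, 1] * sh$R_star[2, 2]), tolerance = 1e-10)
  pc_id <- partial_correlations(list(R_star = diag(3), lambda_star = NA))
  expect_equal(pc_id, diag(3), ignore_attr = TRUE)
})

test_that("the Woodbury inversion path agrees with dense inversion", {
  set.seed(8)
  x <- matrix(rnorm(30 * 80), 30, 80)   # p > n
  sh <- shrink_correlation(x)
  pw <- partial_correlations(sh, method = "woodbury")
  pd <- partial_correlations(sh, method = "dense")
  expect_lt(max(abs(pw - pd)), 1e-10)
  # auto picks a working path for p > n
  pa <- partial_correlations(sh)
  expect_lt(max(abs(pa - pd)), 1e-10)
  # pcor invariants
  expect_equal(diag(pw), rep(1, 80), ignore_attr = TRUE)
  expect_lt(max(abs(pw[upper.tri(pw)])), 1)
  expect_equal(pw, t(pw))
})

test_that("pcor matrices are invariant to column order up to permutation", {
  set.seed(12)
  x <- matrix(rnorm(40 * 6), 40, 6)
  colnames(x) <- paste0("v", 1:6)
  perm <- c(4, 2, 6, 1, 3, 5)
  pc <- partial_correlations(shrink_correlation(x))
  pc_perm <- partial_correlations(shrink_correlation(x[, perm]))
  expect_equal(pc_perm, pc[perm, perm], tolerance = 1e-10)
})

test_that("kappa is recovered from its own null density", {
  set.seed(21)
  for (kappa in c(20, 100)) {
    r <- rnull_pcor(2e4, kappa)
    k_hat <- fit_null_kappa(r)
    expect_lt(abs(k_hat - kappa) / kappa, 0.1)
  }
  expect_warning(k0 <- fit_null_kappa(rep(0, 200)), "degenerate|fall")
  expect_gt(k0, 3)
  expect_error(fit_null_kappa(rnorm(50)), "at least 100")
})

test_that("null p-values have the stated shape and match quadrature", {
  expect_equal(pcor_pvalues(0, 50), 1)
  r <- seq(-0.9, 0.9, by = 0.1)
  p <- pcor_pvalues(r, 30)
  expect_equal(p, rev(p), tolerance = 1e-14)           # symmetric in sign
  expect_true(all(diff(p[r >= 0]) < 0))                # decreasing in |r|
  for (rr in c(0.1, 0.3, 0.6)) {
    expect_equal(pcor_pvalues(rr, 50),
                 pcor_pvalue_quadrature_oracle(rr, 50), tolerance = 1e-8)
  }
  expect_warning(p1 <- pcor_pvalues(c(0.2, 1), 50), ">= 1")
  expect_equal(p1[2], 0)
  expect_error(pcor_pvalues(0.5, 2.5), "exceed 3")
})

test_that("edge calling reproduces Benjamini-Hochberg step-up", {
  pc <- diag(3); pc[1, 2] <- pc[2, 1] <- 0.5
  pc[1, 3] <- pc[3, 1] <- 0.4; pc[2, 3] <- pc[3, 2] <- 0.3
  dimnames(pc) <- list(letters[1:3], letters[1:3])
  pv <- pc; pv[1, 2] <- pv[2, 1] <- 0.01
  pv[1, 3] <- pv[3, 1] <- 0.02; pv[2, 3] <- pv[3, 2] <- 0.04
  diag(pv) <- 1
  e <- fdr_edges(pc, pv, q = 0.05)
  expect_identical(nrow(e), 3L)        # 0.04 <= 0.05 * 3/3 pulls all in
  expect_true(all(e$q <= 0.05))

  pv1 <- pv; pv1[upper.tri(pv1)] <- 1; pv1[lower.tri(pv1)] <- 1
  expect_identical(nrow(fdr_edges(pc, pv1, q = 0.05)), 0L)

  set.seed(9)
  p_rand <- runif(1e4)
  expect_equal(stats::p.adjust(p_rand, "BH"), bh_oracle(p_rand),
               tolerance = 1e-12)
})

test_that("network summaries match a breadth-first-search oracle", {
  e <- data.frame(from = c("a", "c"), to = c("b", "d"))
  ns <- network_summary(e)
  expect_identical(ns$n_nodes, 4L)
  expect_identical(ns$components$size, c(2L, 2L))
  expect_true(all(ns$degree == 1))

  star <- data.frame(from = rep("hub", 5), to = paste0("leaf", 1:5))
  ns2 <- network_summary(star)
  expect_identical(unname(ns2$degree[["hub"]]), 5L)
  expect_identical(ns2$components$size, 6L)

  set.seed(15)
  for (rep in 1:100) {
    nodes <- paste0("n", seq_len(sample(4:12, 1)))
    ne <- sample(1:10, 1)
    ed <- unique(data.frame(from = sample(nodes, ne, replace = TRUE),
                            to = sample(nodes, ne, replace = TRUE)))
    ed <- ed[ed$from != ed$to, , drop = FALSE]
    if (!nrow(ed)) next
    ns3 <- network_summary(ed)
    used <- union(ed$from, ed$to)
    oracle <- bfs_components_oracle(ed, used)
    # same partition: two nodes share a component iff the oracle says so
    for (i in seq_along(used)) {
      for (j in seq_len(i - 1)) {
        expect_identical(ns3$membership[[used[i]]] == ns3$membership[[used[j]]],
                         oracle[[used[i]]] == oracle[[used[j]]])
      }
    }
  }
})

test_that("component numbering is deterministic by size then smallest id", {
  e <- data.frame(from = c("z1", "a1", "a2"), to = c("z2", "a2", "a3"))
  ns <- network_summary(e)
  expect_identical(unname(ns$membership[c("a1", "z1")]), c(1L, 2L))
  expect_identical(ns$components$size, c(3L, 2L))
})

test_that("exports produce loadable SIF and GraphML with weights", {
  e <- data.frame(from = c("a", "c"), to = c("b", "d"),
                  pcor = c(0.5, -0.3), p = c(1e-8, 1e-6), q = c(1e-6, 1e-4))
  dir <- withr::local_tempdir()
  paths <- export_network(e, dir = dir,
                          provenance = c(a = "methylation", b = "methylation",
                                         c = "serum_metab", d = "methylation"))
  sif <- readLines(file.path(dir, "net.sif"))
  expect_identical(sif, c("a pcor b", "c pcor d"))
  g <- igraph::read_graph(file.path(dir, "net.graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), 4, ignore_attr = TRUE)
  expect_equal(igraph::ecount(g), 2, ignore_attr = TRUE)
  expect_equal(sort(igraph::E(g)$weight), c(-0.3, 0.5))
  nodes <- utils::read.delim(file.path(dir, "net_nodes.tsv"))
  expect_identical(sort(nodes$feature_id), c("a", "b", "c", "d"))
  expect_error(export_network(e, dir = dir, formats = "gexf"), "unknown format")
  # empty network still yields valid files
  e0 <- e[0, ]
  paths0 <- export_network(e0, dir = dir, name = "empty")
  g0 <- igraph::read_graph(file.path(dir, "empty.graphml"), format = "graphml")
  expect_equal(igraph::ecount(g0), 0, ignore_attr = TRUE)
})

test_that("the full fit is coherent on a detectable network", {
  om <- generate_chain_precision(30, 0.4)
  set.seed(33)
  z <- matrix(rnorm(150 * 30), 150) %*% chol(cov2cor(solve(om)))
  colnames(z) <- sprintf("v%02d", 1:30)
  fit <- delta_ggm(z, q = 0.05)
  expect_s3_class(fit, "delta_ggm")
  expect_gt(nrow(fit$edges), 10)
  expect_true(all(fit$edges$q <= 0.05))
  ed <- attr(om, "edges")
  truth <- paste(sprintf("v%02d", ed[, 1]), sprintf("v%02d", ed[, 2]))
  called <- paste(fit$edges$from, fit$edges$to)
  expect_gt(mean(called %in% truth), 0.8)   # few false edges
})
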