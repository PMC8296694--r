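# Independent oracles used to check the implementation. Each is written the
# dumb, direct way (closed forms, double loops, enumeration) and never calls
# the code path it checks.

# Balanced one-way random-effects ANOVA estimator: with two visits per child
# and no cohort term, REML coincides with the mean-squares solution in the
# interior of the parameter space.
anova_components_oracle <- function(y, child) {
  ybar <- mean(y)
  means <- tapply(y, child, mean)
  k <- length(means)
  n_tot <- length(y)
  ssb <- 2 * sum((means - ybar)^2)
  ssw <- sum((y - means[as.character(child)])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n_tot - k)
  c(sigma2_id = max(0, (msb - msw) / 2), sigma2_res = msw)
}

# Double-loop evaluation of the analytic shrinkage intensity.
lambda_star_oracle <- function(x) {
  n <- nrow(x); p <- ncol(x)
  z <- scale(x)
  num <- den <- 0
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      w <- z[, i] * z[, j]
      num <- num + n / (n - 1)^3 * sum((w - mean(w))^2)
      den <- den + (sum(w) / (n - 1))^2
    }
  }
  min(1, max(0, num / den))
}

# Partial correlation as the correlation of the two regression residuals
# against all remaining variables.
pcor_residual_oracle <- function(x) {
  p <- ncol(x)
  out <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      rest <- x[, -c(i, j), drop = FALSE]
      ri <- if (ncol(rest)) stats::lm.fit(cbind(1, rest), x[, i])$residuals
            else x[, i] - mean(x[, i])
      rj <- if (ncol(rest)) stats::lm.fit(cbind(1, rest), x[, j])$residuals
            else x[, j] - mean(x[, j])
      out[i, j] <- out[j, i] <- stats::cor(ri, rj)
    }
  }
  out
}

# Benjamini-Hochberg step-up by its definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Connected components by breadth-first search over an adjacency list.
bfs_components_oracle <- function(edges, nodes) {
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes), identity)
  for (k in seq_len(nrow(edges))) {
    a <- edges$from[k]; b <- edges$to[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
      }
    }
  }
  comp
}

# Two-sided Fisher exact p by hypergeometric enumeration: sum the
# probabilities of all tables (same margins) no more likely than the
# observed one.
fisher_exact_oracle <- function(a, b, c, d) {
  m <- a + b        # row 1 total
  n <- c + d        # row 2 total
  k <- a + c        # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Spearman rho by average-rank-then-Pearson.
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Null p-value by adaptive quadrature of the partial-correlation null
# density.
pcor_pvalue_quadrature_oracle <- function(r, kappa) {
  f0 <- function(t) (1 - t^2)^((kappa - 3) / 2) / beta(0.5, (kappa - 1) / 2)
  2 * stats::integrate(f0, abs(r), 1, rel.tol = 1e-12)$value
}

# Small helpers to build toy fixtures in code.
toy_layer <- function(values, layer_id = "proteins", ...) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  omics_layer(values, layer_id, ...)
}

toy_design <- function(n_children, n_cohorts = 2, seed = 1) {
  generate_design(n_children, n_cohorts, seed = seed)
}
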