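# Shared fixtures and independent brute-force oracles. The oracles
# deliberately avoid the package's own linear-algebra path: scatter
# matrices are accumulated with explicit loops, Wilks/Pillai come from
# determinant/trace identities, tolerances from per-variable lm fits, and
# classification from exhaustive per-case distances.

# random gaussian group data as a sample_table
make_blobs <- function(n_per_group = c(8, 8, 8), p = 3, sep = 0, seed = 1) {
  set.seed(seed)
  k <- length(n_per_group)
  centers <- matrix(stats::rnorm(k * p, sd = sep), k, p)
  rows <- lapply(seq_len(k), function(g) {
    x <- matrix(stats::rnorm(n_per_group[g] * p), n_per_group[g], p) +
      matrix(centers[g, ], n_per_group[g], p, byrow = TRUE)
    x <- x - min(x)  # keep concentrations non-negative
    data.frame(sample_id = sprintf("g%d_s%d", g, seq_len(n_per_group[g])),
               group = paste0("G", g), x, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df)[-(1:2)] <- paste0("v", seq_len(p))
  as_sample_table(df)
}

# explicit-loop scatter matrices
oracle_scatter <- function(x, g) {
  g <- factor(g)
  p <- ncol(x)
  grand <- colMeans(x)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (lev in levels(g)) {
    xi <- x[g == lev, , drop = FALSE]
    mi <- colMeans(xi)
    for (r in seq_len(nrow(xi))) {
      d <- xi[r, ] - mi
      W <- W + outer(d, d)
    }
    B <- B + nrow(xi) * outer(mi - grand, mi - grand)
  }
  list(W = W, B = B)
}

oracle_wilks <- function(x, g) {
  sc <- oracle_scatter(x, g)
  det(sc$W) / det(sc$W + sc$B)
}

oracle_pillai <- function(x, g) {
  sc <- oracle_scatter(x, g)
  sum(diag(sc$B %*% solve(sc$W + sc$B)))
}

# eigenvalues of W^{-1} B formed explicitly, via the general eigensolver
oracle_wb_eigenvalues <- function(x, g, s) {
  sc <- oracle_scatter(x, g)
  ev <- eigen(solve(sc$W) %*% sc$B)$values
  sort(Re(ev), decreasing = TRUE)[seq_len(s)]
}

# per-variable tolerance by a plain lm on group-centered data
oracle_tolerance <- function(samples, vars) {
  x <- conc_matrix(samples)[, vars, drop = FALSE]
  g <- factor(samples$group)
  for (lev in levels(g)) {
    i <- g == lev
    x[i, ] <- sweep(x[i, , drop = FALSE], 2, colMeans(x[i, , drop = FALSE]))
  }
  vapply(vars, function(v) {
    d <- as.data.frame(x)
    fit <- stats::lm(stats::reformulate(setdiff(vars, v), response = v),
                     data = d)
    1 - summary(fit)$r.squared
  }, numeric(1))
}

# exhaustive per-case nearest-centroid classification in score space
oracle_classify <- function(scores, centroids) {
  apply(scores, 1, function(s) {
    d2 <- apply(centroids, 1, function(ce) sum((s - ce)^2))
    rownames(centroids)[which.min(d2)]
  })
}
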