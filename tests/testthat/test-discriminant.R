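test_that("tolerance screen detects exact collinearity and independence", {
  st <- make_blobs(c(6, 6, 6), p = 3, sep = 0.5, seed = 41)
  st$v4 <- st$v1  # duplicated column
  scr <- tolerance_screen(st)
  expect_length(scr$excluded, 1)
  expect_true(scr$excluded %in% c("v1", "v4"))
  expect_lt(scr$tolerance[scr$excluded], 0.001)

  # independent large-n variables: tolerances near one
  big <- make_blobs(c(300), p = 4, sep = 0, seed = 42)
  scr2 <- tolerance_screen(big)
  expect_true(all(scr2$tolerance > 0.9))
})

test_that("tolerances match the per-variable regression oracle", {
  st <- make_blobs(c(8, 8, 8), p = 5, sep = 0.7, seed = 17)
  scr <- tolerance_screen(st)
  expect_length(scr$excluded, 0)
  oracle <- oracle_tolerance(st, paste0("v", 1:5))
  expect_equal(scr$tolerance[names(oracle)], oracle, tolerance = 1e-10)
})

test_that("two-group discrimination reduces to a single function", {
  st <- make_blobs(c(10, 10), p = 3, sep = 1.5, seed = 51)
  fit <- fit_lda(st)
  expect_length(fit$eigenvalues, 1)
  # canonical correlation^2 equals SSB/(SSB+SSW) of the score
  sc <- fit$scores[, 1]
  g <- st$group
  grand <- mean(sc)
  ssb <- sum(tapply(sc, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(sc, g, function(v) sum((v - mean(v))^2)))
  expect_equal(fit$canonical_corr[1]^2, ssb / (ssb + ssw),
               tolerance = 1e-10)
  # pooled within-group variance of each score is one by construction
  expect_equal(ssw / (nrow(st) - 2), 1, tolerance = 1e-10)
})

test_that("eigenvalue chain matches the explicit generalized eigenproblem", {
  for (seed in c(6, 28)) {
    st <- make_blobs(c(9, 8, 10), p = 4, sep = 1, seed = seed)
    fit <- fit_lda(st)
    expect_length(fit$eigenvalues, 2)
    oracle <- oracle_wb_eigenvalues(conc_matrix(st), st$group, 2)
    expect_equal(fit$eigenvalues, oracle, tolerance = 1e-8)
    expect_equal(fit$canonical_corr,
                 sqrt(oracle / (1 + oracle)), tolerance = 1e-8)
    expect_equal(sum(fit$pct_variance), 100, tolerance = 1e-8)
    # Bartlett chain head equals the full Wilks lambda identity
    x <- conc_matrix(st)
    expect_equal(fit$wilks_chain$wilks_lambda[1],
                 oracle_wilks(x, st$group), tolerance = 1e-10)
    expect_equal(fit$wilks_chain$df[1],
                 (ncol(x) - 1 + 1) * (3 - 1))
  }
})

test_that("discriminant directions agree with the reference LDA fitter", {
  skip_if_not_installed("MASS")
  st <- make_blobs(c(12, 12, 12), p = 4, sep = 1.2, seed = 63)
  fit <- fit_lda(st)
  ref <- MASS::lda(conc_matrix(st), grouping = st$group)
  ref_scores <- predict(ref)$x
  for (j in 1:2)
    expect_gt(abs(stats::cor(fit$scores[, j], ref_scores[, j])),
              1 - 1e-6)
})

test_that("structure matrix equals pooled within-group correlations", {
  st <- make_blobs(c(10, 9, 11), p = 4, sep = 1, seed = 35)
  fit <- fit_lda(st)
  x <- conc_matrix(st)
  g <- factor(st$group)
  # oracle: correlation from explicitly pooled scatter of (variable, score)
  for (v in colnames(x)) for (j in seq_along(fit$eigenvalues)) {
    sw_xy <- 0; sw_xx <- 0; sw_yy <- 0
    for (lev in levels(g)) {
      xi <- x[g == lev, v] - mean(x[g == lev, v])
      yi <- fit$scores[g == lev, j] - mean(fit$scores[g == lev, j])
      sw_xy <- sw_xy + sum(xi * yi)
      sw_xx <- sw_xx + sum(xi^2)
      sw_yy <- sw_yy + sum(yi^2)
    }
    expect_equal(fit$structure_matrix[v, j], sw_xy / sqrt(sw_xx * sw_yy),
                 tolerance = 1e-10)
  }
  expect_true(all(abs(fit$structure_matrix) <= 1 + 1e-12))
  # each function oriented so its largest-|structure| entry is positive
  for (j in seq_along(fit$eigenvalues)) {
    sm <- fit$structure_matrix[, j]
    expect_gt(sm[which.max(abs(sm))], 0)
  }
})

test_that("discrimination power ranks by max |structure| with stable ties", {
  st <- make_blobs(c(10, 10, 10), p = 3, sep = 1, seed = 44)
  fit <- fit_lda(st)
  rank <- discrimination_power(fit)
  expect_equal(rank$power, sort(apply(abs(fit$structure_matrix), 1, max),
                                decreasing = TRUE), ignore_attr = TRUE)
  # a variable equal to a discriminant score has power one
  st2 <- st
  st2$v1 <- fit$scores[, 1] - min(fit$scores[, 1])
  fit2 <- fit_lda(st2)
  rank2 <- discrimination_power(fit2)
  expect_equal(rank2$power[rank2$compound == "v1"], 1, tolerance = 1e-6)
})

test_that("scores are invariant to affine rescaling of an input variable", {
  st <- make_blobs(c(9, 9, 9), p = 3, sep = 1, seed = 70)
  fit1 <- fit_lda(st)
  st2 <- st
  st2$v2 <- 12 * st2$v2 + 3
  fit2 <- fit_lda(st2)
  expect_equal(fit1$scores, fit2$scores, tolerance = 1e-8)
})

test_that("classification matches the exhaustive distance oracle", {
  st <- make_blobs(c(8, 9, 7), p = 3, sep = 1.1, seed = 12)
  fit <- fit_lda(st)
  cm <- classify(fit, st, "original")
  oracle_pred <- oracle_classify(fit$scores, fit$centroids)
  expect_identical(as.character(predict(fit)$class), unname(oracle_pred))
  expect_equal(unname(rowSums(cm$counts)),
               unname(as.integer(table(st$group)[rownames(cm$counts)])))
  expect_equal(cm$overall_rate, sum(diag(cm$counts)) / nrow(st) * 100)
})

test_that("well-separated groups classify perfectly; loocv is stable on ties", {
  st <- make_blobs(c(8, 8), p = 2, sep = 25, seed = 90)
  fit <- fit_lda(st)
  expect_equal(classify(fit, st, "original")$overall_rate, 100)

  # interchangeable duplicated points: leaving one out changes nothing
  base <- make_blobs(c(4, 4), p = 2, sep = 8, seed = 91)
  dup <- base[rep(seq_len(nrow(base)), each = 3), ]
  dup$sample_id <- paste0(dup$sample_id, "_", seq_len(nrow(dup)))
  dup <- as_sample_table(as.data.frame(dup))
  fit_d <- fit_lda(dup)
  orig <- classify(fit_d, dup, "original")
  loo <- classify(fit_d, dup, "loocv")
  expect_identical(orig$counts, loo$counts)
  expect_equal(unname(rowSums(loo$counts)),
               unname(as.integer(table(dup$group)[rownames(loo$counts)])))
})

test_that("PCA matches its eigendecomposition and the reference fitter", {
  st <- make_blobs(c(20), p = 4, sep = 0, seed = 55)
  pca <- fit_pca(st)
  x <- conc_matrix(st)
  ee <- eigen(stats::cor(x), symmetric = TRUE)
  expect_equal(pca$eigenvalues, pmax(ee$values, 0), tolerance = 1e-10)
  expect_equal(sum(pca$eigenvalues), 4, tolerance = 1e-10)
  ref <- stats::prcomp(x, scale. = TRUE)
  expect_equal(pca$eigenvalues, unname(ref$sdev^2), tolerance = 1e-10)
  for (j in 1:4)
    expect_equal(abs(pca$loadings[, j] / sqrt(pca$eigenvalues[j])),
                 abs(ref$rotation[, j]), tolerance = 1e-8)
  expect_true(all(diff(pca$cumulative_pct) >= -1e-12))
  expect_equal(pca$cumulative_pct[4], 100, tolerance = 1e-8)
})

test_that("PCA degenerate geometries behave", {
  # two perfectly correlated variables: eigenvalues (2, 0)
  df <- data.frame(sample_id = paste0("s", 1:10), group = "G1",
                   a = 1:10, b = 2 * (1:10) + 5)
  pca <- fit_pca(as_sample_table(df))
  expect_equal(pca$eigenvalues, c(2, 0), tolerance = 1e-10)
  expect_equal(pca$pct_variance[1], 100, tolerance = 1e-10)
  expect_identical(unname(pca$retained), 1L)

  # independent variables at large n: all eigenvalues near 1, none dominant
  big <- make_blobs(c(4000), p = 3, sep = 0, seed = 66)
  pca2 <- fit_pca(big)
  expect_true(all(abs(pca2$eigenvalues - 1) < 0.1))

  # constant variable dropped with warning; too few samples error
  df$b <- 3
  expect_warning(fit_pca(as_sample_table(df)), "constant")
  expect_error(fit_pca(as_sample_table(df[1, ])), "at least 2")
})
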