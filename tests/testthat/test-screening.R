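test_that("two-group F equals the squared pooled-variance t statistic", {
  st <- make_blobs(c(6, 9), p = 2, sep = 1, seed = 31)
  an <- anova_per_compound(st)
  m <- conc_matrix(st)
  for (j in 1:2) {
    tt <- stats::t.test(m[st$group == "G1", j], m[st$group == "G2", j],
                        var.equal = TRUE)
    expect_equal(an$f_value[j], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(an$p_value[j], tt$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate and null compounds are handled", {
  st <- make_blobs(c(5, 5), p = 2, sep = 0, seed = 8)
  st$v1 <- 1  # identical everywhere
  an <- anova_per_compound(st)
  expect_equal(an$f_value[an$compound == "v1"], 0)
  expect_true(an$degenerate[an$compound == "v1"])
  expect_identical(an$sig_code[an$compound == "v1"], "ns")
})

test_that("F statistics are invariant under affine rescaling", {
  st <- make_blobs(c(5, 6, 7), p = 2, sep = 1, seed = 13)
  an1 <- anova_per_compound(st)
  st2 <- st
  st2$v1 <- 3.7 * st2$v1 + 2
  an2 <- anova_per_compound(st2)
  expect_equal(an1$f_value, an2$f_value, tolerance = 1e-10)
})

test_that("significance codes follow the star convention", {
  st <- make_blobs(c(40, 40), p = 1, sep = 0, seed = 77)
  an <- anova_per_compound(st)
  expect_identical(an$sig_code, ifelse(an$p_value < 0.001, "***",
                                ifelse(an$p_value < 0.01, "**",
                                ifelse(an$p_value < 0.05, "*", "ns"))))
})

test_that("significance filter honors alpha and preserves order", {
  st <- make_blobs(c(8, 8, 8), p = 4, sep = 2, seed = 5)
  an <- anova_per_compound(st)
  expect_identical(filter_significant(an, alpha = 1), an$compound)
  expect_warning(none <- filter_significant(an, alpha = 0),
                 "no compound significant")
  expect_length(none, 0)
})

test_that("large-n simulation recovers the published significance set", {
  tab <- load_fixture()
  st <- simulate_samples(tab, sim_config(
    group_sizes = stats::setNames(rep(2000L, 5), tab$groups),
    seed = 19, noise_model = "normal"))
  an <- anova_per_compound(st)
  sig <- filter_significant(an)
  published <- names(tab$sig_code)[tab$sig_code != "ns"]
  expect_gte(length(intersect(sig, published)), 29)
})

test_that("MANOVA statistics match determinant/trace oracles", {
  for (seed in c(2, 14, 59)) {
    st <- make_blobs(c(7, 6, 9), p = 3, sep = 0.8, seed = seed)
    mv <- manova_volatiles(st)
    x <- conc_matrix(st)
    expect_equal(mv$wilks_lambda, oracle_wilks(x, st$group),
                 tolerance = 1e-10)
    expect_equal(mv$pillai_trace, oracle_pillai(x, st$group),
                 tolerance = 1e-10)
    # and agree with the standard MANOVA fitter's approximate F tests
    fit <- stats::manova(x ~ factor(st$group))
    sw <- summary(fit, test = "Wilks")$stats
    sp <- summary(fit, test = "Pillai")$stats
    expect_equal(mv$wilks_f, sw[1, "approx F"], tolerance = 1e-8)
    expect_equal(mv$wilks_p, sw[1, "Pr(>F)"], tolerance = 1e-8)
    expect_equal(mv$pillai_f, sp[1, "approx F"], tolerance = 1e-8)
    expect_equal(mv$pillai_p, sp[1, "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("univariate MANOVA reduces to ANOVA and null means give Wilks 1", {
  st <- make_blobs(c(6, 7), p = 1, sep = 2, seed = 3)
  mv <- manova_volatiles(st)
  an <- anova_per_compound(st)
  # Wilks = SSW/(SSW+SSB) so F from Wilks equals the ANOVA F
  expect_equal(mv$wilks_f, an$f_value[1], tolerance = 1e-8)

  # exactly equal group means with within-group spread: B = 0
  df <- data.frame(sample_id = paste0("s", 1:6),
                   group = rep(c("A", "B"), each = 3),
                   v1 = c(1, 2, 3, 1, 2, 3), v2 = c(5, 4, 9, 5, 4, 9))
  mv0 <- manova_volatiles(as_sample_table(df))
  expect_equal(mv0$wilks_lambda, 1)
  expect_equal(mv0$pillai_trace, 0)
})

test_that("observed power has its limiting and monotone properties", {
  # very large effect: power 1.000 at three decimals
  expect_equal(round(observed_power(500, 4, 39), 3), 1)
  # vanishing effect: power tends to the test level
  expect_equal(observed_power(1e-12, 3, 40), 0.05, tolerance = 1e-6)
  # monotone in the noncentrality (grid scan)
  pows <- vapply(seq(0.5, 30, by = 0.5),
                 function(f) observed_power(f, 3, 40), numeric(1))
  expect_true(all(diff(pows) > 0))
})

test_that("required sample size behaves like noncentral-F theory", {
  # enormous effect: the minimal allocation satisfying df constraints
  tiny <- required_sample_size(1e3, groups = 4)
  expect_equal(tiny$n_total, 8)
  expect_equal(unname(tiny$n_per_group), rep(2, 4))
  # monotone: halving the effect never lowers the requirement
  effs <- 2^seq(0, -4)
  ns <- vapply(effs, function(e)
    required_sample_size(e, groups = 4)$n_total, numeric(1))
  expect_true(all(diff(ns) >= 0))
  # asymptotic 1/effect^2 growth
  n1 <- required_sample_size(0.05, groups = 4)$n_total
  n2 <- required_sample_size(0.025, groups = 4)$n_total
  expect_lt(abs(n2 / n1 - 4), 0.8)
  expect_error(required_sample_size(1e-6, groups = 3, n_max = 500),
               "unreachable")
})

test_that("pairwise correlations match the direct formula", {
  st <- make_blobs(c(12), p = 4, sep = 0, seed = 23)
  pc <- pairwise_correlations(st)
  m <- conc_matrix(st)
  expect_equal(diag(pc$r), rep(1, 4), ignore_attr = TRUE)
  # brute-force covariance formula oracle
  for (i in 1:3) for (j in (i + 1):4) {
    xi <- m[, i]; xj <- m[, j]
    r_oracle <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(pc$r[i, j], r_oracle, tolerance = 1e-12)
    ct <- stats::cor.test(xi, xj)
    expect_equal(pc$p[i, j], ct$p.value, tolerance = 1e-10)
  }
  # exact anti-correlation
  st$v2 <- max(st$v1) - st$v1
  pc2 <- pairwise_correlations(st)
  expect_equal(pc2$r["v1", "v2"], -1)
  # zero-variance compound flagged undefined
  st$v3 <- 1
  pc3 <- pairwise_correlations(st)
  expect_identical(pc3$undefined, "v3")
  expect_true(is.na(pc3$r["v3", "v3"]))
})
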