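# Univariate and multivariate screening of compounds across origin groups:
# per-compound one-way ANOVA, one-way MANOVA (Wilks' lambda with Rao's F,
# Pillai's trace with its standard F approximation), SPSS-convention
# observed power, and noncentral-F sample-size analysis.

sig_code_for <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Per-compound one-way ANOVA across groups
#'
#' Fixed-effects one-way ANOVA of each compound's concentration on the
#' group label, via `stats::lm`/`stats::anova`. Compounds identical in
#' every sample (no between- and no within-group variance) get F = 0,
#' p = 1 and are flagged degenerate.
#'
#' @param samples a `sample_table` with >= 2 groups.
#' @return data frame (class `anova_table`) with one row per compound:
#'   `compound`, `f_value`, `df_between`, `df_within`, `p_value`,
#'   `sig_code` (`ns` / `*` / `**` / `***` at 0.05 / 0.01 / 0.001),
#'   `degenerate`.
#' @export
anova_per_compound <- function(samples) {
  stopifnot(inherits(samples, "sample_table"))
  g <- factor(samples$group)
  if (nlevels(g) < 2) stop("need at least two groups")
  x <- conc_matrix(samples)
  df_b <- nlevels(g) - 1L
  df_w <- nrow(x) - nlevels(g)
  if (df_w <= 0) stop("no within-group degrees of freedom")
  rows <- lapply(colnames(x), function(cc) {
    v <- x[, cc]
    if (stats::var(v) < .Machine$double.eps) {
      return(data.frame(compound = cc, f_value = 0, df_between = df_b,
                        df_within = df_w, p_value = 1, sig_code = "ns",
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    aa <- stats::anova(stats::lm(v ~ g))
    f <- aa$`F value`[1]
    p <- aa$`Pr(>F)`[1]
    if (!is.finite(f)) { # zero residual variance, nonzero between
      f <- Inf
      p <- 0
    }
    data.frame(compound = cc, f_value = f, df_between = df_b,
               df_within = df_w, p_value = p, sig_code = sig_code_for(p),
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Significance filter for discriminant-analysis inputs
#'
#' @param rows an `anova_table` from [anova_per_compound()].
#' @param alpha significance level (default 0.05).
#' @return character vector of compounds with p < alpha, input order
#'   preserved; warns when empty.
#' @export
filter_significant <- function(rows, alpha = 0.05) {
  keep <- rows$compound[rows$p_value < alpha]
  if (length(keep) == 0) warning("no compound significant at alpha = ", alpha)
  keep
}

# Between- and pooled within-group scatter matrices for a samples x
# variables matrix and a grouping factor.
scatter_matrices <- function(x, g) {
  g <- factor(g)
  grand <- colMeans(x)
  W <- matrix(0, ncol(x), ncol(x), dimnames = list(colnames(x), colnames(x)))
  B <- W
  for (lev in levels(g)) {
    xi <- x[g == lev, , drop = FALSE]
    ci <- sweep(xi, 2, colMeans(xi))
    W <- W + crossprod(ci)
    d <- colMeans(xi) - grand
    B <- B + nrow(xi) * tcrossprod(d)
  }
  list(W = W, B = B)
}

# Eigenvalues of W^{-1} B via the symmetric reduction K = W^{-1/2} B
# W^{-1/2}, with W^{-1/2} from the spectral decomposition of W. Exact for
# positive-definite W and more forgiving than Cholesky near singularity.
wb_eigen <- function(W, B) {
  ew <- eigen((W + t(W)) / 2, symmetric = TRUE)
  tol <- ncol(W) * .Machine$double.eps * max(ew$values)
  if (min(ew$values) <= tol)
    stop("pooled within-group scatter is singular; ",
         "filter collinear compounds first", call. = FALSE)
  Whalf_inv <- ew$vectors %*% (t(ew$vectors) / sqrt(ew$values))
  K <- Whalf_inv %*% B %*% Whalf_inv
  ee <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- pmax(ee$values, 0)
  vec <- Whalf_inv %*% ee$vectors   # eigenvectors of W^{-1} B
  list(values = lam, vectors = vec)
}

#' One-way MANOVA across origin groups
#'
#' Tests equality of group mean vectors over the given compound subset.
#' Wilks' lambda (prod 1/(1+lambda_i)) is converted to an F via Rao's
#' approximation; Pillai's trace (sum lambda_i/(1+lambda_i)) via its
#' standard F approximation; both noncentral-plug-in observed powers are
#' reported. Compounds constant across all samples are excluded with a
#' message.
#'
#' @param samples a `sample_table`.
#' @param compounds character vector of compounds to include (default all).
#' @return a `manova_result` list: `wilks_lambda`, `wilks_f`, `wilks_df`,
#'   `wilks_p`, `pillai_trace`, `pillai_f`, `pillai_df`, `pillai_p`,
#'   `eigenvalues`, `observed_power` (Wilks- and Pillai-based), and the
#'   compounds used.
#' @export
manova_volatiles <- function(samples, compounds = NULL) {
  stopifnot(inherits(samples, "sample_table"))
  x <- conc_matrix(samples)
  if (!is.null(compounds)) x <- x[, compounds, drop = FALSE]
  keep <- apply(x, 2, function(v) stats::var(v) > .Machine$double.eps)
  if (any(!keep)) {
    message("excluding ", sum(!keep),
            " compound(s) constant across all samples: ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  g <- factor(samples$group)
  p <- ncol(x)
  k <- nlevels(g)
  N <- nrow(x)
  df_h <- k - 1L
  df_e <- N - k
  if (p < 1) stop("no non-constant compounds left")
  if (df_e < p)
    stop("pooled within-group scatter is singular (more variables than ",
         "within-group degrees of freedom); filter collinear compounds")

  sc <- scatter_matrices(x, g)
  lam <- wb_eigen(sc$W, sc$B)$values
  s <- min(p, df_h)
  lam <- lam[seq_len(s)]

  wilks <- prod(1 / (1 + lam))
  pillai <- sum(lam / (1 + lam))

  # Rao's F approximation for Wilks' lambda
  t_den <- p^2 + df_h^2 - 5
  t <- if (t_den > 0) sqrt((p^2 * df_h^2 - 4) / t_den) else 1
  w <- df_e + df_h - (p + df_h + 1) / 2
  df1_w <- p * df_h
  df2_w <- w * t - (p * df_h - 2) / 2
  lam_t <- wilks^(1 / t)
  f_w <- (1 - lam_t) / lam_t * df2_w / df1_w
  p_w <- stats::pf(f_w, df1_w, df2_w, lower.tail = FALSE)

  # standard F approximation for Pillai's trace
  m <- (abs(p - df_h) - 1) / 2
  nn <- (df_e - p - 1) / 2
  df1_p <- s * (2 * m + s + 1)
  df2_p <- s * (2 * nn + s + 1)
  f_p <- (2 * nn + s + 1) / (2 * m + s + 1) * pillai / (s - pillai)
  p_p <- stats::pf(f_p, df1_p, df2_p, lower.tail = FALSE)

  out <- list(
    wilks_lambda = wilks, wilks_f = f_w, wilks_df = c(df1_w, df2_w),
    wilks_p = p_w,
    pillai_trace = pillai, pillai_f = f_p, pillai_df = c(df1_p, df2_p),
    pillai_p = p_p,
    eigenvalues = lam, n = N, groups = levels(g), compounds = colnames(x),
    observed_power = c(
      wilks = observed_power(f_w, df1_w, df2_w),
      pillai = observed_power(f_p, df1_p, df2_p))
  )
  class(out) <- "manova_result"
  out
}

#' @export
print.manova_result <- function(x, ...) {
  cat("One-way MANOVA,", length(x$compounds), "compounds,",
      length(x$groups), "groups, n =", x$n, "\n")
  cat(sprintf("  Wilks' lambda = %.3f  (F = %.3f, df = %.0f/%.1f, p = %.3g, power = %.3f)\n",
              x$wilks_lambda, x$wilks_f, x$wilks_df[1], x$wilks_df[2],
              x$wilks_p, x$observed_power["wilks"]))
  cat(sprintf("  Pillai's trace = %.3f (F = %.3f, df = %.0f/%.1f, p = %.3g, power = %.3f)\n",
              x$pillai_trace, x$pillai_f, x$pillai_df[1], x$pillai_df[2],
              x$pillai_p, x$observed_power["pillai"]))
  invisible(x)
}

#' Observed (post hoc) power of an F test
#'
#' Plug-in convention: the noncentrality is estimated as the observed F
#' statistic times its numerator degrees of freedom (the convention used by
#' common statistical GUIs when reporting "observed power"; it is biased
#' upward but is what published tables show). Power is the probability that
#' a noncentral F at that noncentrality exceeds the central critical value.
#'
#' @param f observed F statistic.
#' @param df1,df2 numerator/denominator degrees of freedom.
#' @param alpha test level (default 0.05).
#' @return power in \[0, 1\].
#' @export
observed_power <- function(f, df1, df2, alpha = 0.05) {
  stopifnot(df1 > 0, df2 > 0, f >= 0)
  ncp <- f * df1
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = ncp, lower.tail = FALSE)
}

#' Minimal total sample size for a one-way design at target power
#'
#' The effect size is the root-mean-square standardized effect (RMSSE):
#' the root mean square of the standardized group-mean deviations
#' (mu_g - mu)/sigma over g - 1 degrees of freedom. The noncentrality at
#' total size N allocated as n_g is lambda = sum n_g * delta_g^2 with
#' delta_g^2 = RMSSE^2 * (g - 1)/g assumed spread evenly over groups.
#' N is grown (respecting allocation weights, every group >= 2) until the
#' noncentral-F power reaches the target.
#'
#' @param effect_size RMSSE (> 0).
#' @param groups number of groups.
#' @param weights allocation weights (default equal); normalized to sum 1.
#' @param alpha test level (default 0.05).
#' @param target_power desired power (default 0.8).
#' @param n_max search cap (default 1e6).
#' @return list: `n_total`, `n_per_group`, `power`.
#' @export
required_sample_size <- function(effect_size, groups, weights = NULL,
                                 alpha = 0.05, target_power = 0.8,
                                 n_max = 1e6) {
  stopifnot(effect_size > 0, groups >= 2,
            alpha > 0, alpha < 1, target_power > 0, target_power < 1)
  if (is.null(weights)) weights <- rep(1, groups)
  stopifnot(length(weights) == groups, all(weights > 0))
  weights <- weights / sum(weights)
  df1 <- groups - 1
  d2 <- effect_size^2 * (groups - 1) / groups  # per-group delta^2
  for (N in (groups * 2):n_max) {
    ng <- pmax(2L, round(weights * N))
    Nt <- sum(ng)
    df2 <- Nt - groups
    if (df2 < 1) next
    lambda <- Nt * d2
    pow <- stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2,
                     ncp = lambda, lower.tail = FALSE)
    if (pow >= target_power)
      return(list(n_total = Nt, n_per_group = ng, power = pow))
  }
  stop("target power unreachable below n_max = ", n_max,
       " at effect size ", effect_size)
}

#' Pairwise Pearson correlations with two-sided p-values
#'
#' @param samples a `sample_table` (>= 3 samples).
#' @param compounds compounds to include (default all).
#' @return list with symmetric matrices `r` and `p`; zero-variance
#'   compounds yield `NA` entries and are named in `undefined`.
#' @export
pairwise_correlations <- function(samples, compounds = NULL) {
  x <- conc_matrix(samples)
  if (!is.null(compounds)) x <- x[, compounds, drop = FALSE]
  n <- nrow(x)
  if (n < 3) stop("need at least 3 samples")
  sds <- apply(x, 2, stats::sd)
  undefined <- colnames(x)[sds == 0]
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- ifelse(sds > 0, 1, NA)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  diag(p) <- NA
  list(r = r, p = p, n = n, undefined = undefined)
}
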