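# Canonical linear discriminant analysis in the convention of classical
# statistical packages: tolerance pre-screen for collinear predictors,
# discriminant functions scaled to unit pooled within-group variance,
# eigenvalue / canonical-correlation / percent-variance chain, Bartlett
# chi-square tests of residual discrimination, structure matrix (pooled
# within-group correlations of predictors with scores), group centroids,
# and original + leave-one-out classification. Plus Kaiser-criterion PCA.

# pooled within-group centering
group_center <- function(x, g) {
  g <- factor(g)
  for (lev in levels(g)) {
    i <- g == lev
    x[i, ] <- sweep(x[i, , drop = FALSE], 2,
                    colMeans(x[i, , drop = FALSE]))
  }
  x
}

#' Tolerance screen for collinear predictors
#'
#' The tolerance of a variable is 1 - R^2 from regressing it on the other
#' kept variables after pooled within-group centering. Variables with
#' tolerance below `min_tol` are removed iteratively, lowest first,
#' re-computing tolerances after each removal (variables that fail only
#' because of a mutually collinear partner are retained once the partner
#' leaves).
#'
#' @param samples a `sample_table`.
#' @param compounds compounds to screen (default all).
#' @param min_tol minimum tolerance (default 0.001, the conventional
#'   discriminant-analysis default).
#' @return list: `kept`, `excluded`, and `tolerance` — the final tolerance
#'   of every variable (excluded ones at the value that removed them).
#' @export
tolerance_screen <- function(samples, compounds = NULL, min_tol = 0.001) {
  x <- conc_matrix(samples)
  if (!is.null(compounds)) x <- x[, compounds, drop = FALSE]
  xc <- group_center(x, samples$group)
  kept <- colnames(x)
  excluded <- character(0)
  tol_out <- stats::setNames(rep(NA_real_, ncol(x)), colnames(x))
  repeat {
    if (length(kept) == 0)
      stop("tolerance screen excluded every variable")
    if (length(kept) == 1) {
      tol_out[kept] <- 1
      break
    }
    tol <- vapply(kept, function(v) {
      others <- setdiff(kept, v)
      fit <- stats::lm.fit(cbind(1, xc[, others, drop = FALSE]), xc[, v])
      ssr <- sum(fit$residuals^2)
      sst <- sum(xc[, v]^2)
      if (sst < .Machine$double.eps) return(0)
      max(0, min(1, ssr / sst))
    }, numeric(1))
    tol_out[kept] <- tol
    if (min(tol) >= min_tol) break
    worst <- kept[which.min(tol)]
    excluded <- c(excluded, worst)
    kept <- setdiff(kept, worst)
  }
  list(kept = kept, excluded = excluded, tolerance = tol_out)
}

#' Fit a canonical linear discriminant model
#'
#' Solves the generalized eigenproblem of the between-group scatter B
#' against the pooled within-group scatter W; keeps
#' min(groups - 1, variables) discriminant functions; scales coefficients
#' so each function's pooled within-group variance is one. Reports the
#' eigenvalue chain with canonical correlations
#' sqrt(lambda/(1 + lambda)) and percent-of-discrimination shares, the
#' Bartlett chi-square chain testing functions k..s jointly
#' (X^2 = -(N - 1 - (p + g)/2) ln Lambda_k, df = (p - k + 1)(g - k)), the
#' structure matrix, and group centroids in discriminant space. Each
#' function's sign is fixed so its largest-|structure| entry is positive.
#'
#' @param samples a `sample_table` with >= 2 samples in every group.
#' @param compounds predictor compounds (should have passed
#'   [tolerance_screen()]).
#' @param priors `"equal"` (default) or `"proportional"` — stored for
#'   classification.
#' @return an object of class `canonical_lda`.
#' @examples
#' st <- simulate_samples(load_fixture(), sim_config(seed = 7))
#' keep <- tolerance_screen(st)$kept
#' fit <- fit_lda(st, keep)
#' fit$eigenvalues
#' @export
fit_lda <- function(samples, compounds = NULL,
                    priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  stopifnot(inherits(samples, "sample_table"))
  x <- conc_matrix(samples)
  if (!is.null(compounds)) x <- x[, compounds, drop = FALSE]
  g <- factor(samples$group)
  if (any(table(g) < 2)) stop("every group needs at least 2 samples")
  N <- nrow(x)
  p <- ncol(x)
  k <- nlevels(g)
  if (N - k < p)
    stop("singular pooled scatter: ", p, " variables exceed ", N - k,
         " within-group degrees of freedom; screen variables first")

  sc <- scatter_matrices(x, g)
  ee <- wb_eigen(sc$W, sc$B)
  s <- min(k - 1, p)
  lam <- ee$values[seq_len(s)]
  A <- ee$vectors[, seq_len(s), drop = FALSE]
  # v from the symmetric problem satisfies a' W a = 1; rescale so the
  # pooled within-group variance a' (W / (N - k)) a equals 1
  A <- A * sqrt(N - k)

  grand <- colMeans(x)
  scores <- sweep(x, 2, grand) %*% A
  colnames(scores) <- paste0("LD", seq_len(s))
  rownames(A) <- colnames(x)
  colnames(A) <- colnames(scores)

  # structure matrix: pooled within-group correlations
  structure_m <- suppressWarnings(
    stats::cor(group_center(x, g), group_center(scores, g)))

  # orient each function so its largest-|structure| loading is positive
  for (j in seq_len(s)) {
    sm <- structure_m[, j]
    if (all(is.na(sm))) next
    top <- which.max(abs(sm))
    if (sm[top] < 0) {
      A[, j] <- -A[, j]
      scores[, j] <- -scores[, j]
      structure_m[, j] <- -structure_m[, j]
    }
  }

  centroids <- apply(scores, 2, function(sc_) tapply(sc_, g, mean))
  if (s == 1) {
    centroids <- matrix(centroids, ncol = 1,
                        dimnames = list(levels(g), colnames(scores)))
  }

  # Bartlett chain: test of functions k..s
  wilks_chain <- data.frame(
    function_from = seq_len(s),
    wilks_lambda = rev(cumprod(rev(1 / (1 + lam)))),
    stringsAsFactors = FALSE)
  cfac <- N - 1 - (p + k) / 2
  wilks_chain$chi_sq <- -cfac * log(wilks_chain$wilks_lambda)
  wilks_chain$df <- (p - wilks_chain$function_from + 1) *
    (k - wilks_chain$function_from)
  wilks_chain$p_value <- stats::pchisq(wilks_chain$chi_sq, wilks_chain$df,
                                       lower.tail = FALSE)

  prior_w <- if (priors == "equal") rep(1 / k, k) else as.numeric(table(g)) / N
  names(prior_w) <- levels(g)

  out <- list(
    coefficients = A,
    constants = -drop(crossprod(grand, A)),
    grand_mean = grand,
    eigenvalues = lam,
    canonical_corr = sqrt(lam / (1 + lam)),
    pct_variance = if (sum(lam) > 0) lam / sum(lam) * 100 else rep(0, s),
    wilks_chain = wilks_chain,
    structure_matrix = structure_m,
    centroids = centroids,
    scores = scores,
    groups = g,
    priors = prior_w,
    prior_type = priors,
    compounds = colnames(x),
    n = N
  )
  class(out) <- "canonical_lda"
  out
}

#' @export
print.canonical_lda <- function(x, ...) {
  s <- length(x$eigenvalues)
  cat("Canonical discriminant analysis:", length(x$compounds),
      "variables,", nlevels(x$groups), "groups, n =", x$n, "\n")
  tab <- data.frame(
    eigenvalue = round(x$eigenvalues, 3),
    pct_variance = round(x$pct_variance, 1),
    canonical_corr = round(x$canonical_corr, 3),
    wilks_lambda = round(x$wilks_chain$wilks_lambda, 3),
    chi_sq = round(x$wilks_chain$chi_sq, 2),
    df = x$wilks_chain$df,
    p = signif(x$wilks_chain$p_value, 3))
  rownames(tab) <- paste0("LD", seq_len(s))
  print(tab)
  invisible(x)
}

#' @export
coef.canonical_lda <- function(object, ...) object$coefficients

#' @export
summary.canonical_lda <- function(object, ...) {
  print(object)
  cat("\nGroup centroids (discriminant space):\n")
  print(round(object$centroids, 3))
  cat("\nTop discrimination power (max |structure coefficient|):\n")
  print(utils::head(discrimination_power(object), 7))
  invisible(object)
}

#' Discriminant scores and classification for new data
#'
#' @param object a `canonical_lda`.
#' @param newdata a `sample_table` or matrix carrying the model's
#'   compounds; default the training data.
#' @param ... unused.
#' @return list with `scores` and `class` (assignment by smallest
#'   Mahalanobis distance to centroid in discriminant space, adjusted by
#'   -2 log prior when priors are proportional).
#' @export
predict.canonical_lda <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    scores <- object$scores
  } else {
    x <- if (inherits(newdata, "sample_table")) conc_matrix(newdata) else
      as.matrix(newdata)
    x <- x[, object$compounds, drop = FALSE]
    scores <- sweep(x, 2, object$grand_mean) %*% object$coefficients
  }
  cent <- object$centroids
  d2 <- sapply(seq_len(nrow(cent)), function(i)
    rowSums(sweep(scores, 2, cent[i, ])^2))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  colnames(d2) <- rownames(cent)
  if (object$prior_type == "proportional")
    d2 <- sweep(d2, 2, 2 * log(object$priors), "-")
  cls <- factor(rownames(cent)[apply(d2, 1, which.min)],
                levels = levels(object$groups))
  list(scores = scores, class = cls, dist2 = d2)
}

#' Rank compounds by discrimination power
#'
#' Discrimination power of a compound is its largest absolute structure
#' coefficient (pooled within-group correlation with any discriminant
#' function). Ties are broken by the model's input compound order.
#'
#' @param model a `canonical_lda`.
#' @return data frame `compound`, `power`, `function_` sorted descending.
#' @export
discrimination_power <- function(model) {
  stopifnot(inherits(model, "canonical_lda"))
  sm <- abs(model$structure_matrix)
  pow <- apply(sm, 1, max)
  fn <- colnames(sm)[apply(sm, 1, which.max)]
  ord <- order(-pow, seq_along(pow))
  data.frame(compound = rownames(sm)[ord], power = unname(pow[ord]),
             function_ = fn[ord], stringsAsFactors = FALSE)
}

#' Classify samples and tabulate a confusion matrix
#'
#' `method = "original"` resubstitutes the training data through the fitted
#' model; `method = "loocv"` refits the discriminant model without each
#' case in turn and classifies the held-out case (the variable set is NOT
#' re-screened per fold). Folds that would leave a group with fewer than
#' two members are flagged and the case counted unclassifiable.
#'
#' @param model a `canonical_lda`.
#' @param samples the `sample_table` to classify (default: training data
#'   must be re-supplied for loocv).
#' @param method `"original"` or `"loocv"`.
#' @return a `confusion_matrix`: list with `counts` (true x predicted),
#'   `per_group_rate` (%), `overall_rate` (%), `method`, `unclassified`.
#' @export
classify <- function(model, samples, method = c("original", "loocv")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "canonical_lda"),
            inherits(samples, "sample_table"))
  truth <- factor(samples$group, levels = levels(model$groups))
  lev <- levels(truth)
  unclassified <- 0L
  if (method == "original") {
    pred <- predict(model, samples)$class
  } else {
    pred <- factor(rep(NA_character_, nrow(samples)), levels = lev)
    for (i in seq_len(nrow(samples))) {
      rest <- samples[-i, , drop = FALSE]
      class(rest) <- c("sample_table", "data.frame")
      if (any(table(factor(rest$group, levels = lev)) < 2)) {
        unclassified <- unclassified + 1L
        next
      }
      fit_i <- tryCatch(
        fit_lda(rest, model$compounds, priors = model$prior_type),
        error = function(e) NULL)
      if (is.null(fit_i)) {  # singular fold: flag, count unclassifiable
        unclassified <- unclassified + 1L
        next
      }
      pred[i] <- predict(fit_i, samples[i, , drop = FALSE])$class
    }
  }
  # unclassifiable folds stay in the table under their own column so
  # row sums always equal the group sizes
  pch <- as.character(pred)
  plev <- lev
  if (anyNA(pch)) {
    pch[is.na(pch)] <- "(unclassified)"
    plev <- c(lev, "(unclassified)")
  }
  counts <- table(true = truth, predicted = factor(pch, levels = plev))
  hits <- counts[cbind(lev, lev)]
  per_group <- hits / rowSums(counts) * 100
  overall <- sum(hits) / length(truth) * 100
  out <- list(counts = counts, per_group_rate = per_group,
              overall_rate = overall, method = method,
              unclassified = unclassified)
  class(out) <- "confusion_matrix"
  out
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Classification (", x$method, "): overall ",
      sprintf("%.1f", x$overall_rate), "% correct\n", sep = "")
  print(x$counts)
  cat("Per-group rate (%):\n")
  print(round(x$per_group_rate, 1))
  if (x$unclassified > 0)
    cat(x$unclassified, "case(s) unclassifiable under leave-one-out\n")
  invisible(x)
}

#' Score plot of the first two discriminant functions
#'
#' @param x a `canonical_lda`.
#' @param ... passed to `plot`.
#' @export
plot.canonical_lda <- function(x, ...) {
  s <- ncol(x$scores)
  if (s < 2) {
    graphics::stripchart(x$scores[, 1] ~ x$groups, method = "jitter",
                         xlab = "LD1", ...)
    return(invisible(x))
  }
  cols <- seq_len(nlevels(x$groups))
  graphics::plot(x$scores[, 1], x$scores[, 2],
                 col = cols[as.integer(x$groups)],
                 pch = as.integer(x$groups),
                 xlab = sprintf("LD1 (%.1f%%)", x$pct_variance[1]),
                 ylab = sprintf("LD2 (%.1f%%)", x$pct_variance[2]), ...)
  graphics::points(x$centroids[, 1], x$centroids[, 2], pch = 8, cex = 1.5,
                   col = cols)
  graphics::legend("topright", legend = levels(x$groups), col = cols,
                   pch = cols, cex = 0.8)
  invisible(x)
}

#' Principal component analysis with Kaiser retention
#'
#' Eigendecomposition of the correlation matrix (default) or covariance
#' matrix of the selected compounds. Loadings are eigenvectors scaled by
#' the square root of their eigenvalues; component signs are fixed so the
#' largest-|loading| entry of each is positive. Components with
#' (correlation-matrix) eigenvalue > 1 are marked retained (Kaiser
#' criterion). Constant compounds are dropped with a warning.
#'
#' @param samples a `sample_table` (>= 2 samples).
#' @param compounds compounds to include (default all).
#' @param standardize use the correlation matrix (default TRUE).
#' @return a `pca_result`: `eigenvalues`, `loadings`, `scores`,
#'   `pct_variance`, `cumulative_pct`, `retained`, `standardize`.
#' @export
fit_pca <- function(samples, compounds = NULL, standardize = TRUE) {
  x <- conc_matrix(samples)
  if (!is.null(compounds)) x <- x[, compounds, drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant compound(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  S <- if (standardize) stats::cor(x) else stats::cov(x)
  ee <- eigen(S, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  vecs <- ee$vectors
  dimnames(vecs) <- list(colnames(x), paste0("PC", seq_along(vals)))
  # sign convention
  for (j in seq_along(vals)) {
    top <- which.max(abs(vecs[, j]))
    if (vecs[top, j] < 0) vecs[, j] <- -vecs[, j]
  }
  loadings <- sweep(vecs, 2, sqrt(vals), "*")
  xc <- scale(x, center = TRUE, scale = standardize)
  scores <- xc %*% vecs
  pct <- vals / sum(vals) * 100
  out <- list(eigenvalues = vals, loadings = loadings, scores = scores,
              pct_variance = pct, cumulative_pct = cumsum(pct),
              retained = which(vals > 1), standardize = standardize)
  class(out) <- "pca_result"
  out
}

#' @export
print.pca_result <- function(x, ...) {
  k <- max(length(x$retained), 2)
  cat("PCA (", if (x$standardize) "correlation" else "covariance",
      " matrix): ", nrow(x$loadings), " variables\n", sep = "")
  tab <- data.frame(eigenvalue = round(x$eigenvalues[1:k], 3),
                    pct = round(x$pct_variance[1:k], 3),
                    cumulative = round(x$cumulative_pct[1:k], 3))
  rownames(tab) <- colnames(x$loadings)[1:k]
  print(tab)
  cat("Retained by Kaiser criterion (eigenvalue > 1):",
      length(x$retained), "components\n")
  invisible(x)
}
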