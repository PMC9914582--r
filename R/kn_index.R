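# The marker-ratio geographic-origin index: the summed semi-quantitative
# content of a small set of discriminant marker compounds divided by the
# total semi-quantitative volatile content (TSQVC).

#' The seven default marker compounds
#'
#' The compounds with the highest discrimination power in the canonical
#' discriminant analysis of citrus-honey origin; frozen as the package
#' default so the headline index is reproducible without refitting.
#'
#' @return character vector of seven compound names.
#' @export
default_markers <- function() {
  c("Lilac aldehyde (isomer IV, D)",
    "Dill ether",
    "2-Methylbutanal",
    "Heptane",
    "Benzaldehyde",
    "alpha,4-Dimethyl-3-cyclohexene-1-acetaldehyde",
    "Herboxide isomer II")
}

#' Build a marker set
#'
#' @param compounds character vector of compound names (non-empty).
#' @param provenance one of `"published"`, `"top-k-from-model"`,
#'   `"user"`.
#' @return a `marker_set`.
#' @export
marker_set <- function(compounds = default_markers(),
                       provenance = c("published", "top-k-from-model",
                                      "user")) {
  provenance <- match.arg(provenance)
  stopifnot(length(compounds) >= 1)
  structure(list(compounds = compounds, provenance = provenance),
            class = "marker_set")
}

#' Select top-k markers from a discrimination-power ranking
#'
#' @param ranking data frame from [discrimination_power()] (already sorted
#'   descending, ties broken by input order).
#' @param k number of markers (default 7).
#' @return a `marker_set` with provenance `"top-k-from-model"`.
#' @export
select_markers <- function(ranking, k = 7) {
  if (k <= 0) stop("k must be positive")
  stopifnot(nrow(ranking) >= k)
  marker_set(ranking$compound[seq_len(k)], provenance = "top-k-from-model")
}

#' Total semi-quantitative volatile content
#'
#' Sum of all compound concentrations (mg/kg); non-detected compounds
#' contribute 0.
#'
#' @param conc numeric vector of non-negative concentrations.
#' @return total, mg/kg.
#' @export
tsqvc <- function(conc) {
  stopifnot(all(conc >= 0 | is.na(conc)))
  sum(conc, na.rm = TRUE)
}

#' Marker-ratio geographic-origin index
#'
#' R = (sum of marker-compound concentrations) / TSQVC, computed on group
#' mean concentrations (default, which reproduces the published table
#' arithmetic) or per sample. The value lies in \[0, 1\], is invariant to
#' global rescaling of all concentrations, and is reported rounded
#' half-up to 2 decimals with full precision retained.
#'
#' @param x a `group_summary` (uses group means) or a `sample_table`
#'   (per-sample mode).
#' @param markers a [marker_set()] (default: the seven frozen markers).
#' @return a `kn_index` object. Group-mean mode: data frame `group`,
#'   `marker_sum`, `tsqvc`, `r_value`, `r_rounded`. Per-sample mode adds a
#'   `per_sample` data frame with one R per sample and, with >= 2 samples
#'   per group, group-difference letters from
#'   [compare_r_across_groups()].
#' @examples
#' kn_index(load_fixture())
#' @export
kn_index <- function(x, markers = marker_set()) {
  UseMethod("kn_index")
}

#' @export
kn_index.group_summary <- function(x, markers = marker_set()) {
  idx <- match_compounds(x, markers$compounds)
  tot <- colSums(x$mean)
  if (any(tot == 0)) stop("TSQVC is zero for group(s): ",
                          paste(x$groups[tot == 0], collapse = ", "))
  msum <- colSums(x$mean[idx, , drop = FALSE])
  tab <- data.frame(group = x$groups, marker_sum = msum, tsqvc = tot,
                    r_value = msum / tot,
                    r_rounded = round_half_up(msum / tot, 2),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, markers = markers, mode = "group-means"),
            class = "kn_index")
}

#' @export
kn_index.sample_table <- function(x, markers = marker_set()) {
  m <- conc_matrix(x)
  midx <- match(normalize_name(markers$compounds),
                normalize_name(colnames(m)))
  if (anyNA(midx))
    stop("marker(s) absent from sample table: ",
         paste(markers$compounds[is.na(midx)], collapse = ", "))
  tot <- rowSums(m)
  if (any(tot == 0)) stop("TSQVC is zero for sample(s): ",
                          paste(x$sample_id[tot == 0], collapse = ", "))
  r <- rowSums(m[, midx, drop = FALSE]) / tot
  per_sample <- data.frame(sample_id = x$sample_id, group = x$group,
                           r_value = r, stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(per_sample, per_sample$group), function(d)
    data.frame(group = d$group[1], n = nrow(d), r_mean = mean(d$r_value),
               r_sd = stats::sd(d$r_value), stringsAsFactors = FALSE)))
  agg <- agg[order(match(agg$group, unique(x$group))), ]
  rownames(agg) <- NULL
  agg$r_rounded <- round_half_up(agg$r_mean, 2)
  letters <- tryCatch(compare_r_across_groups(per_sample),
                      error = function(e) NULL)
  if (!is.null(letters)) agg$letter <- letters[agg$group]
  structure(list(table = agg, per_sample = per_sample, markers = markers,
                 mode = "per-sample"),
            class = "kn_index")
}

#' @export
print.kn_index <- function(x, ...) {
  cat("Marker-ratio origin index (", length(x$markers$compounds),
      " markers, ", x$markers$provenance, ", ", x$mode, ")\n", sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
write_report.kn_index <- function(x, path, ...) {
  utils::write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}

#' Group-difference letters for per-sample index values
#'
#' All group pairs are tested (Welch two-sample t) at the stated level;
#' groups whose index distributions are not distinguished share a letter.
#' Letters are assigned in descending mean order (a = highest). Groups
#' with a single sample cannot be tested: they get their own letter and
#' are flagged with a warning.
#'
#' @param per_sample data frame with columns `group` and `r_value`.
#' @param alpha significance level for the pairwise tests (default 0.001,
#'   the level used for the published letter codes).
#' @return named character vector of letters per group.
#' @export
compare_r_across_groups <- function(per_sample, alpha = 0.001) {
  g <- factor(per_sample$group)
  lev <- levels(g)
  k <- length(lev)
  if (k < 2) stop("need at least 2 groups")
  ns <- table(g)
  untested <- names(ns)[ns < 2]
  if (length(untested) > 0)
    warning("group(s) with a single sample assigned letters descriptively: ",
            paste(untested, collapse = ", "))
  means <- tapply(per_sample$r_value, g, mean)
  ord <- names(sort(means, decreasing = TRUE))
  # same[i, j]: groups indistinguishable at alpha
  same <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  diag(same) <- TRUE
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- per_sample$r_value[g == lev[i]]
    b <- per_sample$r_value[g == lev[j]]
    if (length(a) < 2 || length(b) < 2) next  # untestable -> different
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      same[i, j] <- same[j, i] <- isTRUE(all.equal(mean(a), mean(b)))
    } else {
      p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA)
      same[i, j] <- same[j, i] <- is.na(p) || p >= alpha
    }
  }
  # greedy letter assignment in descending-mean order
  letters_out <- stats::setNames(rep("", k), lev)
  groups_of_letter <- list()
  for (gname in ord) {
    placed <- FALSE
    for (li in seq_along(groups_of_letter)) {
      members <- groups_of_letter[[li]]
      if (all(same[gname, members])) {
        groups_of_letter[[li]] <- c(members, gname)
        letters_out[gname] <- paste0(letters_out[gname], letters[li])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups_of_letter[[length(groups_of_letter) + 1]] <- gname
      letters_out[gname] <- paste0(letters_out[gname],
                                   letters[length(groups_of_letter)])
    }
  }
  letters_out
}
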