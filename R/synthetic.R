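# Synthetic per-sample data with the statistical structure of the packaged
# group summary. The published study never deposited per-sample
# concentrations, so downstream stages are exercised on draws from the
# group means/SDs instead.

#' Simulation configuration
#'
#' @param group_sizes named integer vector of samples per group; defaults to
#'   the study design (Egypt 7, Morocco 6, Greece 17, Spain 8, Nectar 6).
#' @param seed master integer seed; per-group streams are derived from it so
#'   changing one group's size does not reshuffle the others.
#' @param noise_model `"censored-normal"` (draw Normal(mean, sd), clamp
#'   negatives to 0; the default, since many tabulated SDs equal or exceed
#'   their means), `"truncated-normal"` (inverse-CDF sample from the
#'   positive part), `"normal"` (uncensored draws, negatives allowed — a
#'   diagnostic mode whose sample means are unbiased for the tabulated
#'   means, used in convergence checks), or `"none"` (every sample equals
#'   its group mean).
#' @param duplicate_cv relative SD between duplicate instrument runs of the
#'   same sample (default 0.05).
#' @param is_area internal-standard peak area in arbitrary units
#'   (default 1e5).
#' @param c_is internal-standard concentration, mg/kg (default 1).
#' @param correlation optional within-group correlation (0..1) applied
#'   uniformly across compounds via a Gaussian copula factor; default 0
#'   (compounds independent, as tabulated).
#' @return a `sim_config` list.
#' @export
sim_config <- function(group_sizes = NULL, seed = 1L,
                       noise_model = c("censored-normal", "truncated-normal",
                                       "normal", "none"),
                       duplicate_cv = 0.05, is_area = 1e5, c_is = 1,
                       correlation = 0) {
  noise_model <- match.arg(noise_model)
  stopifnot(duplicate_cv >= 0, is_area > 0, c_is > 0,
            correlation >= 0, correlation < 1)
  if (!is.null(group_sizes)) stopifnot(all(group_sizes >= 1))
  structure(list(group_sizes = group_sizes, seed = as.integer(seed),
                 noise_model = noise_model, duplicate_cv = duplicate_cv,
                 is_area = is_area, c_is = c_is, correlation = correlation),
            class = "sim_config")
}

# deterministic per-group seed stream derived from the master seed
group_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * i) %% .Machine$integer.max)
}

#' Simulate per-sample concentration tables from a group summary
#'
#' For each group g and compound c, draws n\[g\] values from
#' Normal(mean\[c,g\], sd\[c,g\]) and applies the configured censoring.
#' Cells with mean 0 and sd 0 ("nd" in the source table) are exactly 0.
#'
#' @param summary a `group_summary` (see [load_fixture()]).
#' @param cfg a [sim_config()].
#' @return a `sample_table` with one row per simulated sample.
#' @examples
#' st <- simulate_samples(load_fixture(), sim_config(seed = 42))
#' table(st$group)
#' @export
simulate_samples <- function(summary, cfg = sim_config()) {
  stopifnot(inherits(summary, "group_summary"))
  sizes <- cfg$group_sizes
  if (is.null(sizes)) sizes <- summary$n
  if (is.null(names(sizes))) {
    if (length(sizes) != length(summary$groups))
      stop("unnamed group_sizes must match the number of summary groups")
    names(sizes) <- summary$groups
  }
  unknown <- setdiff(names(sizes), summary$groups)
  if (length(unknown) > 0)
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))

  comps <- summary$compounds$compound
  p <- length(comps)
  blocks <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    g <- names(sizes)[i]
    n <- sizes[[i]]
    set.seed(group_seed(cfg$seed, i))
    mu <- summary$mean[, g]
    sg <- summary$sd[, g]
    x <- matrix(0, nrow = n, ncol = p, dimnames = list(NULL, comps))
    # shared within-group factor implements the optional uniform correlation
    z_common <- stats::rnorm(n)
    rho <- cfg$correlation
    for (j in seq_len(p)) {
      if (mu[j] == 0 && sg[j] == 0) next  # nd cells stay exactly zero
      if (cfg$noise_model == "none" || sg[j] == 0) {
        x[, j] <- mu[j]
        next
      }
      z <- stats::rnorm(n)
      if (rho > 0) z <- sqrt(rho) * z_common + sqrt(1 - rho) * z
      v <- mu[j] + sg[j] * z
      if (cfg$noise_model == "censored-normal") {
        v[v < 0] <- 0
      } else if (cfg$noise_model == "normal") {
        # uncensored diagnostic draws: leave v as-is
      } else {  # truncated-normal, by inverse-CDF on the positive part
        u <- stats::pnorm(0, mu[j], sg[j]) +
          stats::pnorm(z) * (1 - stats::pnorm(0, mu[j], sg[j]))
        v <- stats::qnorm(u, mu[j], sg[j])
        v[v < 0] <- 0  # numerical guard
      }
      x[, j] <- v
    }
    blocks[[i]] <- data.frame(
      sample_id = sprintf("%s_%02d", g, seq_len(n)),
      group = g, x, check.names = FALSE, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, blocks)
  if (cfg$noise_model == "normal") {
    # uncensored draws may be negative; skip the non-negativity validation
    rownames(df) <- NULL
    class(df) <- c("sample_table", "data.frame")
    df
  } else {
    as_sample_table(df)
  }
}

#' Simulate duplicate-run GC-MS peak tables from sample concentrations
#'
#' Inverts the internal-standard semi-quantification: each compound's peak
#' area is `conc * is_area / c_is`, perturbed multiplicatively by
#' `duplicate_cv` per run, with retention times jittered by at most 0.02 min
#' around the summary's values. Two runs per sample.
#'
#' @param samples a `sample_table`.
#' @param summary a `group_summary` supplying retention times.
#' @param cfg a [sim_config()].
#' @return a `peak_table` data frame with columns `sample_id`, `run`,
#'   `compound`, `rt_min`, `area`, `is_area`.
#' @export
simulate_peaks <- function(samples, summary, cfg = sim_config()) {
  stopifnot(inherits(samples, "sample_table"),
            inherits(summary, "group_summary"))
  if (cfg$is_area <= 0) stop("is_area must be positive")
  comps <- setdiff(names(samples), c("sample_id", "group"))
  idx <- match_compounds(summary, comps)
  rt <- summary$compounds$rt_min[idx]

  set.seed(group_seed(cfg$seed, 997L))
  out <- vector("list", nrow(samples) * 2L)
  k <- 0L
  for (i in seq_len(nrow(samples))) {
    conc <- as.numeric(samples[i, comps])
    for (run in 1:2) {
      area <- conc * cfg$is_area / cfg$c_is
      if (cfg$duplicate_cv > 0) {
        area <- area * (1 + stats::rnorm(length(area), 0, cfg$duplicate_cv))
        area[area < 0] <- 0
      }
      k <- k + 1L
      out[[k]] <- data.frame(
        sample_id = samples$sample_id[i], run = run, compound = comps,
        rt_min = rt + stats::runif(length(rt), -0.02, 0.02),
        area = area, is_area = cfg$is_area,
        stringsAsFactors = FALSE)
    }
  }
  pk <- do.call(rbind, out)
  class(pk) <- c("peak_table", "data.frame")
  pk
}

#' Simulate an n-alkane retention ladder (C8-C20)
#'
#' Octane and nonane are pinned at their measured retention times (12.26 and
#' 14.94 min); later alkanes extend that spacing linearly, matching a
#' constant-ramp temperature program.
#'
#' @param cfg a [sim_config()] (unused fields ignored).
#' @return data frame with columns `carbon` (8..20) and `rt_min`, strictly
#'   increasing.
#' @export
simulate_alkane_ladder <- function(cfg = sim_config()) {
  carbon <- 8:20
  rt <- 12.26 + (carbon - 8) * (14.94 - 12.26)
  data.frame(carbon = carbon, rt_min = rt)
}
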