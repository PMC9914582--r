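# Internal-standard semi-quantification and temperature-programmed
# retention indexing.

#' Quantification configuration
#'
#' @param c_is internal-standard concentration in mg/kg (default 1, the
#'   benzophenone spike level).
#' @param ladder data frame of alkane anchors with columns `carbon` and
#'   `rt_min`, strictly increasing in both.
#' @return a `quant_config` list.
#' @export
quant_config <- function(c_is = 1, ladder = simulate_alkane_ladder()) {
  stopifnot(c_is > 0)
  validate_ladder(ladder)
  structure(list(c_is = c_is, ladder = ladder), class = "quant_config")
}

validate_ladder <- function(ladder) {
  stopifnot(is.data.frame(ladder),
            all(c("carbon", "rt_min") %in% names(ladder)),
            nrow(ladder) >= 2)
  if (is.unsorted(ladder$carbon, strictly = TRUE) ||
      is.unsorted(ladder$rt_min, strictly = TRUE))
    stop("alkane ladder must be strictly increasing in carbon and rt_min")
  invisible(ladder)
}

#' Semi-quantify a peak table against the internal standard
#'
#' Concentration of each analyte is its peak area divided by the
#' internal-standard area, times the internal-standard concentration,
#' assuming a response factor of one for every compound.
#'
#' @param peaks a `peak_table` (columns `sample_id`, `run`, `compound`,
#'   `area`, `is_area`) or a data frame of one run.
#' @param cfg a [quant_config()].
#' @return the peak table with an added `conc` column (mg/kg).
#' @examples
#' pk <- data.frame(sample_id = "s1", run = 1, compound = "x",
#'                  rt_min = 10, area = 500, is_area = 1000)
#' semi_quantify(pk, quant_config(c_is = 1))$conc  # 0.5
#' @export
semi_quantify <- function(peaks, cfg = quant_config()) {
  stopifnot(all(c("sample_id", "run", "compound", "area", "is_area") %in%
                  names(peaks)))
  if (any(peaks$is_area <= 0))
    stop("internal-standard area must be positive (ratio undefined at 0)")
  if (any(peaks$area < 0)) stop("negative peak area")
  peaks$conc <- peaks$area / peaks$is_area * cfg$c_is
  peaks
}

#' Average duplicate runs into a per-sample concentration table
#'
#' Arithmetic mean of each compound's concentration across a sample's runs;
#' a compound absent from one run contributes 0 there.
#'
#' @param quantified output of [semi_quantify()] (must carry `conc`).
#' @param groups optional named character vector mapping sample_id to group
#'   label; defaults to `"unknown"`.
#' @return a `sample_table`.
#' @export
average_duplicates <- function(quantified, groups = NULL) {
  stopifnot("conc" %in% names(quantified))
  ids <- unique(quantified$sample_id)
  comps <- unique(quantified$compound)
  m <- matrix(0, nrow = length(ids), ncol = length(comps),
              dimnames = list(ids, comps))
  for (i in seq_along(ids)) {
    sub <- quantified[quantified$sample_id == ids[i], , drop = FALSE]
    runs <- unique(sub$run)
    if (length(runs) == 0) stop("no runs for sample ", ids[i])
    acc <- matrix(0, nrow = length(runs), ncol = length(comps),
                  dimnames = list(NULL, comps))
    for (r in seq_along(runs)) {
      rr <- sub[sub$run == runs[r], , drop = FALSE]
      acc[r, rr$compound] <- rr$conc
    }
    m[i, ] <- colMeans(acc)
  }
  gr <- if (is.null(groups)) rep("unknown", length(ids)) else
    unname(groups[ids])
  as_sample_table(data.frame(sample_id = ids, group = gr, m,
                             check.names = FALSE, stringsAsFactors = FALSE))
}

#' Linear (temperature-programmed) retention index
#'
#' For a retention time t between consecutive ladder alkanes with carbon
#' numbers n and n+1 eluting at t_n and t_(n+1),
#' RI = 100 * (n + (t - t_n) / (t_(n+1) - t_n)). This is the van den Dool &
#' Kratz convention appropriate to a linear temperature ramp; ladder
#' alkanes map to exactly 100 times their carbon number. Retention times
#' outside the ladder are not extrapolated: they return `NA` with a range
#' flag (`"below"` / `"above"`).
#'
#' @param rt numeric vector of retention times (minutes).
#' @param ladder alkane ladder data frame (`carbon`, `rt_min`).
#' @return numeric vector of unrounded retention indices with attribute
#'   `range` (`"in"`, `"below"`, or `"above"` per element).
#' @examples
#' lad <- simulate_alkane_ladder()
#' round_half_up(retention_index(13.25, lad))  # 837
#' @export
retention_index <- function(rt, ladder = simulate_alkane_ladder()) {
  validate_ladder(ladder)
  ri <- rep(NA_real_, length(rt))
  range <- rep("in", length(rt))
  below <- rt < ladder$rt_min[1]
  above <- rt > ladder$rt_min[nrow(ladder)]
  range[below] <- "below"
  range[above] <- "above"
  ok <- !below & !above & !is.na(rt)
  if (any(ok)) {
    seg <- findInterval(rt[ok], ladder$rt_min, rightmost.closed = TRUE)
    t0 <- ladder$rt_min[seg]
    t1 <- ladder$rt_min[seg + 1]
    n0 <- ladder$carbon[seg]
    n1 <- ladder$carbon[seg + 1]
    ri[ok] <- 100 * (n0 + (n1 - n0) * (rt[ok] - t0) / (t1 - t0))
  }
  attr(ri, "range") <- range
  ri
}

#' Round half-up to a given number of decimals
#'
#' Unlike R's banker's rounding, ties always round away from zero upward;
#' used for reported retention indices (integer) and ratio-index values
#' (2 decimals).
#'
#' @param x numeric.
#' @param digits decimal places (default 0).
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Format retention indices the way the summary table prints them
#'
#' In-range values are rounded to integer; below-range values print as
#' `"<k"` where k is 100 times the first ladder carbon; above-range as
#' `">k"` at the last.
#'
#' @param ri output of [retention_index()].
#' @param ladder the ladder used.
#' @return character vector.
#' @export
format_ri <- function(ri, ladder = simulate_alkane_ladder()) {
  range <- attr(ri, "range")
  out <- as.character(round_half_up(ri))
  out[range == "below"] <- paste0("<", 100 * ladder$carbon[1])
  out[range == "above"] <- paste0(">", 100 * ladder$carbon[nrow(ladder)])
  out
}
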