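#' @keywords internal
"_PACKAGE"

# Compound-name normalization used everywhere names are matched:
# lowercase, collapse runs of whitespace, transliterate Greek letters.
normalize_name <- function(x) {
  x <- gsub("\u03b1", "alpha", x)
  x <- gsub("\u03b2", "beta", x)
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

#' Load the packaged volatile-compound group summary
#'
#' Reads the machine-readable summary of 41 volatile compounds measured in
#' citrus honey from four origins (Egypt, Morocco, Greece, Spain) plus a
#' fifth group of other nectar honeys: per-compound, per-group mean and
#' standard-deviation concentrations (mg/kg), retention data, and
#' significance of the per-compound F tests. Cells printed "nd" (not
#' detected) are encoded as mean 0, sd 0.
#'
#' @return An object of class `group_summary`: a list with components
#'   `compounds` (data frame: `compound`, `class`, `rt_min`, `ri`,
#'   `ri_below_range`), `groups` (character), `n` (named integer group
#'   sizes), `mean` and `sd` (compound x group matrices, mg/kg),
#'   `f_value`, `sig_code`, and `printed` (the published TSQVC and
#'   ratio-index summary rows with their group-difference letters).
#' @examples
#' tab <- load_fixture()
#' tab$mean["Dill ether", "Morocco"]
#' @export
load_fixture <- function() {
  path <- system.file("extdata", "table1_volatiles.csv", package = "honeyvola",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  gpath <- system.file("extdata", "table1_groups.csv", package = "honeyvola",
                       mustWork = TRUE)
  grp <- utils::read.csv(gpath, stringsAsFactors = FALSE)
  ppath <- system.file("extdata", "table1_summary_rows.csv",
                       package = "honeyvola", mustWork = TRUE)
  printed <- utils::read.csv(ppath, stringsAsFactors = FALSE)

  groups <- grp$group
  mean_cols <- paste0("mean_", groups)
  sd_cols <- paste0("sd_", groups)
  missing <- setdiff(c(mean_cols, sd_cols), names(raw))
  if (length(missing) > 0)
    stop("fixture integrity failure: missing columns ",
         paste(missing, collapse = ", "))

  mm <- as.matrix(raw[, mean_cols])
  ss <- as.matrix(raw[, sd_cols])
  dimnames(mm) <- dimnames(ss) <- list(raw$compound, groups)
  check <- which(!is.finite(mm) | mm < 0 | !is.finite(ss) | ss < 0,
                 arr.ind = TRUE)
  if (nrow(check) > 0)
    stop("fixture integrity failure at compound '",
         raw$compound[check[1, 1]], "'")
  if (anyDuplicated(raw$compound))
    stop("fixture integrity failure: duplicated compound '",
         raw$compound[anyDuplicated(raw$compound)], "'")
  if (!all(raw$sig_code %in% c("ns", "*", "**", "***")))
    stop("fixture integrity failure: bad significance code")

  below <- raw$ri == "<800"
  ri <- suppressWarnings(as.numeric(raw$ri))

  out <- list(
    compounds = data.frame(
      compound = raw$compound,
      class = raw$class,
      rt_min = raw$rt_min,
      ri = ri,
      ri_below_range = below,
      stringsAsFactors = FALSE
    ),
    groups = groups,
    n = stats::setNames(as.integer(grp$n), groups),
    mean = mm,
    sd = ss,
    f_value = stats::setNames(raw$f_value, raw$compound),
    sig_code = stats::setNames(raw$sig_code, raw$compound),
    printed = printed
  )
  class(out) <- "group_summary"
  out
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Volatile-compound group summary\n")
  cat("  compounds:", nrow(x$compounds), "in",
      length(unique(x$compounds$class)), "chemical classes\n")
  cat("  groups:   ", paste0(x$groups, " (n=", x$n, ")", collapse = ", "),
      "\n")
  nsig <- sum(x$sig_code != "ns")
  cat("  significant per-compound F tests:", nsig, "of", nrow(x$compounds),
      "\n")
  invisible(x)
}

#' Look up compounds in a group summary by normalized name
#'
#' Matching is case-insensitive, collapses whitespace, and accepts Greek
#' alpha/beta or their transliterations.
#'
#' @param summary a `group_summary`.
#' @param names character vector of compound names.
#' @return integer row indices into `summary$compounds`.
#' @export
match_compounds <- function(summary, names) {
  idx <- match(normalize_name(names), normalize_name(summary$compounds$compound))
  if (anyNA(idx))
    stop("unknown compound(s): ", paste(names[is.na(idx)], collapse = ", "))
  idx
}

#' Read a per-sample concentration table from CSV
#'
#' The expected layout is one row per sample: `sample_id`, `group`, then one
#' numeric column per compound (mg/kg). Blank cells are read as 0 with a
#' warning; negative concentrations and duplicated sample ids are errors.
#'
#' @param path CSV file path.
#' @return a `sample_table`: a data frame with columns `sample_id`, `group`,
#'   then compound concentrations.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)[1:2]))
    stop("sample table must start with columns 'sample_id', 'group'")
  comp_cols <- setdiff(names(df), c("sample_id", "group"))
  for (cc in comp_cols) {
    v <- df[[cc]]
    if (is.character(v)) {
      blank <- !nzchar(trimws(v))
      v[blank] <- "0"
      v <- as.numeric(v)
      if (any(blank)) warning("blank cells in '", cc, "' read as 0")
    }
    if (anyNA(v)) {
      warning("missing cells in '", cc, "' read as 0")
      v[is.na(v)] <- 0
    }
    df[[cc]] <- v
  }
  as_sample_table(df)
}

#' Construct/validate a sample table
#'
#' @param df data frame with `sample_id`, `group`, then compound columns.
#' @return validated `sample_table`.
#' @export
as_sample_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("sample table needs 'sample_id' and 'group' columns")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         df$sample_id[anyDuplicated(df$sample_id)][1])
  conc <- df[, setdiff(names(df), c("sample_id", "group")), drop = FALSE]
  bad <- vapply(conc, function(v) any(v < 0), logical(1))
  if (any(bad))
    stop("negative concentration in compound(s): ",
         paste(names(conc)[bad], collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Concentration matrix of a sample table
#'
#' @param st a `sample_table`.
#' @return numeric matrix, samples x compounds, rownames = sample ids.
#' @export
conc_matrix <- function(st) {
  m <- as.matrix(st[, setdiff(names(st), c("sample_id", "group")),
                    drop = FALSE])
  rownames(m) <- st$sample_id
  m
}

#' Write a sample table to CSV
#'
#' @param st a `sample_table`.
#' @param path output path.
#' @export
write_sample_table <- function(st, path) {
  utils::write.csv(st, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.sample_table <- function(x, ...) {
  nc <- ncol(x) - 2L
  cat("Sample concentration table:", nrow(x), "samples x", nc, "compounds\n")
  cat("  groups:", paste(names(table(x$group)), table(x$group),
                         sep = ":", collapse = "  "), "\n")
  NextMethod()
}

#' Write a human-readable report for a stage result
#'
#' A generic plain-text/CSV reporter. Methods exist for the ratio-index
#' result, the canonical discriminant model, ANOVA screening tables and the
#' default (captured `print`). Output is deterministic for identical input.
#'
#' @param x a stage result object.
#' @param path output file path.
#' @param ... passed to methods.
#' @return the path, invisibly.
#' @export
write_report <- function(x, path, ...) UseMethod("write_report")

#' @export
write_report.default <- function(x, path, ...) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(utils::capture.output(print(x)), con)
  invisible(path)
}

#' @export
write_report.data.frame <- function(x, path, ...) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
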