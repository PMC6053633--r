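#' Read a Tessier five-fraction speciation table
#'
#' Reads a delimited text file of sequential-extraction records, one row per
#' site/metal/period observation with the five operationally defined fractions
#' of the Tessier scheme: exchangeable (F1), carbonate-bound (F2),
#' Fe-Mn-oxide-bound (F3), organic-bound (F4) and residual (F5), all in mg/kg
#' dry weight.
#'
#' Column names are matched case-insensitively; `col_map` renames
#' non-standard headers (e.g. `c(site = "station")`). Every row is validated:
#' fractions must be present, finite and non-negative. Offending rows are
#' reported with their line numbers.
#'
#' @param path Path to a delimited text file with header columns
#'   `site, metal, period, f1, f2, f3, f4, f5`.
#' @param sep Field separator; comma by default, `"\t"` accepted.
#' @param col_map Optional named character vector mapping standard names to
#'   the names used in the file.
#' @return A tibble with columns `site`, `metal`, `period`, `f1`..`f5`.
#' @seealso [fraction_totals()], [speciation_indices()], [write_fraction_table()]
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("site,metal,period,F1,F2,F3,F4,F5",
#'              "QUE,Cd,Jun,1.0,1.0,1.0,0.7,0.68"), tf)
#' read_fraction_table(tf)
#' @export
read_fraction_table <- function(path, sep = ",", col_map = NULL) {
  df <- read_delimited(path, sep)
  df <- remap_columns(df, col_map)
  need <- c("site", "metal", "period", paste0("f", 1:5))
  check_schema(df, need, path)
  df <- df[need]
  for (f in paste0("f", 1:5)) df[[f]] <- as.numeric(df[[f]])
  bad <- which(!stats::complete.cases(df[paste0("f", 1:5)]) |
                 apply(df[paste0("f", 1:5)], 1, function(x) any(x < 0)))
  if (length(bad)) {
    stop("invalid fraction value(s) (missing or negative) in ", path,
         " at data row(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(df$metal))) {
    stop("empty metal symbol in ", path, call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write a fraction table to delimited text
#'
#' Inverse of [read_fraction_table()]; numeric fields are written with 17
#' significant digits (full double precision) so a write/read round trip
#' reproduces them exactly.
#'
#' @param records Tibble of fraction records.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_fraction_table <- function(records, path, sep = ",") {
  out <- as.data.frame(records)
  for (f in paste0("f", 1:5)) out[[f]] <- sprintf("%.17g", out[[f]])
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a table of total metal concentrations
#'
#' Reads site/metal/period records of total concentration `c` (mg/kg dry
#' weight), with an optional standard deviation column `sd`.
#'
#' @inheritParams read_fraction_table
#' @return A tibble with columns `site`, `metal`, `period`, `c` and, when
#'   present in the file, `sd`.
#' @export
read_concentration_table <- function(path, sep = ",", col_map = NULL) {
  df <- read_delimited(path, sep)
  df <- remap_columns(df, col_map)
  check_schema(df, c("site", "metal", "period", "c"), path)
  keep <- intersect(c("site", "metal", "period", "c", "sd"), names(df))
  df <- df[keep]
  df$c <- as.numeric(df$c)
  if (any(is.na(df$c) | df$c < 0)) {
    stop("invalid concentration (missing or negative) in ", path,
         " at data row(s): ", paste(which(is.na(df$c) | df$c < 0), collapse = ", "),
         call. = FALSE)
  }
  if ("sd" %in% names(df)) {
    df$sd <- as.numeric(df$sd)
    if (any(df$sd < 0, na.rm = TRUE)) stop("negative sd in ", path, call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Total concentration from the five Tessier fractions
#'
#' Sums F1..F5 per record, the operational definition of total metal content
#' in a sequential extraction.
#'
#' @param records Tibble of fraction records (see [read_fraction_table()]).
#' @return A tibble of concentration records: `site`, `metal`, `period`, `c`.
#' @export
fraction_totals <- function(records) {
  tibble::tibble(
    site = records$site, metal = records$metal, period = records$period,
    c = records$f1 + records$f2 + records$f3 + records$f4 + records$f5)
}

#' Aggregate periodic concentrations to a site-by-metal matrix
#'
#' Collapses the periods (e.g. sampling months) of each (site, metal) cell to
#' a single concentration with the chosen statistic. All downstream indices
#' consume this matrix: one concentration C_i per metal per site.
#'
#' @param records Tibble with columns `site`, `metal`, `c` (period optional).
#' @param method `"mean"` (default, the annual mean of monthly values) or
#'   `"median"`.
#' @return A numeric matrix, sites in rows and metals in columns (both in
#'   first-appearance order), with attribute `aggregation` recording `method`.
#'   Every cell must be covered by at least one record; missing (site, metal)
#'   combinations are an error.
#' @examples
#' x <- case_study_concentrations()
#' aggregate_concentrations(x)["DOU", "Ni"]  # 2.1967
#' @export
aggregate_concentrations <- function(records, method = c("mean", "median")) {
  method <- match.arg(method)
  stat <- if (method == "mean") mean else median
  sites <- unique(records$site)
  metals <- unique(records$metal)
  agg <- dplyr::summarise(dplyr::group_by(records, .data$site, .data$metal),
                          c = stat(.data$c), .groups = "drop")
  m <- matrix(NA_real_, length(sites), length(metals),
              dimnames = list(sites, metals))
  m[cbind(match(agg$site, sites), match(agg$metal, metals))] <- agg$c
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop("no records for (site, metal) cell(s): ",
         paste(sites[miss[, 1]], metals[miss[, 2]], sep = "/", collapse = ", "),
         call. = FALSE)
  }
  attr(m, "aggregation") <- method
  m
}

#' Read a sediment quality guideline table
#'
#' Loads per-metal TEL, PEL and SEL effect thresholds (mg/kg dry weight):
#' concentrations below the threshold effect level rarely harm benthic
#' organisms, above the probable effect level frequently do, and above the
#' severe effect level affect the majority of benthic species.
#'
#' @param path Path to a delimited file with header `metal,tel,pel,sel`, or
#'   the name `"default-guidelines"` for the bundled compilation (file header
#'   documents its literature provenance). `sel` may be empty for a metal; the
#'   mHQ is then computed from the available reciprocal terms and flagged.
#' @param sep Field separator.
#' @return A tibble `metal`, `tel`, `pel`, `sel`.
#' @export
read_guidelines <- function(path = "default-guidelines", sep = ",") {
  if (identical(path, "default-guidelines")) {
    path <- system.file("extdata", "default-guidelines.csv", package = "sedqual",
                        mustWork = TRUE)
  }
  df <- read_delimited(path, sep)
  check_schema(df, c("metal", "tel", "pel", "sel"), path)
  df <- df[c("metal", "tel", "pel", "sel")]
  for (v in c("tel", "pel", "sel")) df[[v]] <- as.numeric(df[[v]])
  if (anyDuplicated(df$metal)) {
    stop("duplicate metal in guideline table: ",
         paste(unique(df$metal[duplicated(df$metal)]), collapse = ", "), call. = FALSE)
  }
  bad <- !is.na(df$tel) & !is.na(df$pel) & (df$tel <= 0 | df$tel >= df$pel)
  if (any(bad)) {
    stop("guideline invariant 0 < tel < pel violated for: ",
         paste(df$metal[bad], collapse = ", "), call. = FALSE)
  }
  if (any(df$sel <= 0, na.rm = TRUE)) stop("sel must be positive", call. = FALSE)
  unknown <- setdiff(df$metal, the_metals)
  if (length(unknown)) {
    warning("guideline table extends beyond the bundled metal set: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read background concentrations and toxic-response factors
#'
#' Loads the constants used by the classical indices: per-metal crustal or
#' regional background concentrations B_i (mg/kg, for contamination factors)
#' and dimensionless Hakanson toxic-response factors Tr (for potential
#' ecological risk).
#'
#' @param path Path to a delimited file with header `metal,background,tr`, or
#'   `"default-constants"` for the bundled set (average-shale backgrounds and
#'   standard toxic-response factors; provenance in the file header).
#' @param sep Field separator.
#' @return A tibble `metal`, `background`, `tr`.
#' @export
read_constants <- function(path = "default-constants", sep = ",") {
  if (identical(path, "default-constants")) {
    path <- system.file("extdata", "default-constants.csv", package = "sedqual",
                        mustWork = TRUE)
  }
  df <- read_delimited(path, sep)
  check_schema(df, c("metal", "background", "tr"), path)
  df <- df[c("metal", "background", "tr")]
  df$background <- as.numeric(df$background)
  df$tr <- as.numeric(df$tr)
  if (anyDuplicated(df$metal)) stop("duplicate metal in constants table", call. = FALSE)
  if (any(df$background <= 0 | df$tr <= 0, na.rm = TRUE)) {
    stop("background and tr must be positive", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Bundled default guideline and constants tables
#'
#' Convenience accessors for [read_guidelines()] and [read_constants()] with
#' the bundled defaults.
#' @return A tibble (see the reader each wraps).
#' @export
default_guidelines <- function() read_guidelines("default-guidelines")

#' @rdname default_guidelines
#' @export
default_constants <- function() read_constants("default-constants")

# -- internal helpers ---------------------------------------------------------

read_delimited <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                   stringsAsFactors = FALSE, strip.white = TRUE,
                   fileEncoding = "UTF-8", check.names = FALSE,
                   blank.lines.skip = TRUE)
  names(df) <- tolower(trimws(names(df)))
  df
}

remap_columns <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  for (std in names(col_map)) {
    from <- tolower(col_map[[std]])
    if (from %in% names(df)) names(df)[names(df) == from] <- tolower(std)
  }
  df
}

check_schema <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# guideline/constants rows for a metal vector, erroring on absences
match_metals <- function(tab, metals, what) {
  idx <- match(metals, tab$metal)
  if (anyNA(idx)) {
    stop("no ", what, " entry for metal(s): ",
         paste(metals[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  tab[idx, , drop = FALSE]
}
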