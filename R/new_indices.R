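#' Modified hazard quotient (mHQ)
#'
#' Per-metal severity index comparing a sediment concentration against the
#' three effect-level guidelines at once:
#' \deqn{mHQ_i = \sqrt{C_i \left(\frac{1}{TEL_i} + \frac{1}{PEL_i} +
#'   \frac{1}{SEL_i}\right)}}
#' The square root acts as a drawdown, compressing the scale so that classes
#' (see [classify_mhq()]) are spaced evenly in index units. mHQ is strictly
#' increasing in `c` and obeys a square-root scaling law: quadrupling the
#' concentration doubles the index.
#'
#' A missing (`NA`) guideline level drops its reciprocal term; the result is
#' then on a compressed scale and callers should flag it (as [mhq_table()]
#' does). All three levels missing is an error.
#'
#' @param c Concentration(s), mg/kg dry weight; non-negative.
#' @param tel,pel,sel Effect levels, mg/kg; positive or `NA`.
#' @return Numeric vector of mHQ values, dimensionless and non-negative.
#' @examples
#' mhq(4.8, tel = 0.68, pel = 4.21, sel = 10)  # 2.946
#' @export
mhq <- function(c, tel, pel, sel = NA_real_) {
  if (any(c < 0, na.rm = TRUE)) stop("concentration must be non-negative", call. = FALSE)
  for (g in list(tel, pel, sel)) {
    if (any(g <= 0, na.rm = TRUE)) stop("guideline levels must be positive", call. = FALSE)
  }
  n <- max(length(c), length(tel), length(pel), length(sel))
  terms <- cbind(1 / rep_len(tel, n), 1 / rep_len(pel, n), 1 / rep_len(sel, n))
  s <- rowSums(terms, na.rm = TRUE)
  if (any(rowSums(!is.na(terms)) == 0)) {
    stop("at least one of tel, pel, sel must be available", call. = FALSE)
  }
  sqrt(rep_len(c, n) * s)
}

#' Severity classification of the modified hazard quotient
#'
#' Maps mHQ values to the eight-step severity scale. Intervals are
#' left-closed (`a <= mHQ < b`) with 0.5-unit steps from 0.5 to 3.5; a value
#' on a boundary belongs to the upper class.
#'
#' @param x Non-negative mHQ value(s).
#' @return Character vector of severity labels.
#' @export
classify_mhq <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("mHQ must be non-negative", call. = FALSE)
  mhq_severity_classes$label[
    findInterval(x, mhq_severity_classes$lower, left.open = FALSE)]
}

#' @rdname classify_mhq
#' @format NULL
#' @export
mhq_severity_classes <- tibble::tibble(
  lower = c(0, 0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 3.5),
  label = c("Nil to very low severity of contamination",
            "Very low severity of contamination",
            "Low severity of contamination",
            "Moderate severity of contamination",
            "Considerable severity of contamination",
            "High severity of contamination",
            "Very high severity of contamination",
            "Extreme severity of contamination"))

#' mHQ for every site and metal of a concentration matrix
#'
#' @param concentrations Site-by-metal matrix from [aggregate_concentrations()]
#'   (or any numeric matrix with site rownames and metal colnames).
#' @param guidelines Guideline tibble from [read_guidelines()].
#' @return Tibble with columns `site`, `metal`, `mhq`, `severity` and logical
#'   `partial_guidelines` (TRUE when a missing effect level dropped a term).
#' @export
mhq_table <- function(concentrations, guidelines = default_guidelines()) {
  metals <- colnames(concentrations)
  g <- match_metals(guidelines, metals, "guideline")
  long <- expand.grid(site = rownames(concentrations), metal = metals,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(long$metal, g$metal)
  long$mhq <- mhq(concentrations[cbind(long$site, long$metal)],
                  g$tel[gi], g$pel[gi], g$sel[gi])
  long$severity <- classify_mhq(long$mhq)
  long$partial_guidelines <- is.na(g$tel[gi]) | is.na(g$pel[gi]) | is.na(g$sel[gi])
  tibble::as_tibble(long)
}

#' Per-period mHQ records
#'
#' Computes one mHQ per concentration record (site, metal, period), the
#' alternative to aggregating concentrations first: averaging these gives a
#' per-metal index that weights months on the index scale rather than the
#' concentration scale (slightly smaller, by concavity of the square root).
#'
#' @param totals Concentration-record tibble (`site`, `metal`, `period`, `c`).
#' @inheritParams mhq_table
#' @return Tibble `site`, `metal`, `period`, `mhq`.
#' @export
mhq_records <- function(totals, guidelines = default_guidelines()) {
  g <- match_metals(guidelines, unique(totals$metal), "guideline")
  gi <- match(totals$metal, g$metal)
  tibble::tibble(site = totals$site, metal = totals$metal,
                 period = totals$period,
                 mhq = mhq(totals$c, g$tel[gi], g$pel[gi], g$sel[gi]))
}

#' Ecological contamination index (ECI)
#'
#' Site-level aggregate of the per-metal modified hazard quotients,
#' \deqn{ECI = B_n \sum_{i=1}^{n} mHQ_i}
#' where the weight `bn` is the reciprocal of the leading eigenvalue of a
#' correlation-matrix PCA of the site's metal concentrations (see
#' [bn_weight()]). The eigenvalue measures how much common (source-driven)
#' variance the metals share, so its reciprocal down-weights sites whose
#' apparent contamination is dominated by a single common factor.
#'
#' @param mhqs Numeric vector of per-metal mHQ values for one site.
#' @param bn Positive scalar weight B_n.
#' @return A list of class `"eci_result"`: `eci`, `bn`, `sum_mhq`, `n_metals`,
#'   `contributions` (named percentages of the mHQ sum, totalling 100) and
#'   `class` (label per [classify_eci()]).
#' @examples
#' eci(c(Cd = 2.946, Pb = 2.783, Cu = 1.270, Cr = 0.955, Ni = 0.461),
#'     bn = 1 / 1.705)
#' @export
eci <- function(mhqs, bn) {
  if (!length(mhqs)) stop("at least one mHQ is required", call. = FALSE)
  if (any(mhqs < 0)) stop("mHQ values must be non-negative", call. = FALSE)
  if (!is.numeric(bn) || length(bn) != 1L || bn <= 0) {
    stop("bn must be a positive scalar", call. = FALSE)
  }
  s <- sum(mhqs)
  if (s > 0) {
    contrib <- mhqs / s * 100
  } else {
    warning("all mHQ values are zero; contributions reported as uniform",
            call. = FALSE)
    contrib <- rep(100 / length(mhqs), length(mhqs))
    names(contrib) <- names(mhqs)
  }
  value <- bn * s
  structure(list(eci = value, bn = bn, sum_mhq = s, n_metals = length(mhqs),
                 contributions = contrib, class = classify_eci(value)),
            class = "eci_result")
}

#' @export
print.eci_result <- function(x, ...) {
  cat(sprintf("ECI = %.4g (Bn = %.4g x sum mHQ = %.4g over %d metals): %s\n",
              x$eci, x$bn, x$sum_mhq, x$n_metals, x$class))
  top <- names(sort(x$contributions, decreasing = TRUE))[1]
  if (!is.null(top)) {
    cat(sprintf("  top contributor: %s (%.1f%%)\n", top, max(x$contributions)))
  }
  invisible(x)
}

#' Contamination classification of the ecological contamination index
#'
#' Maps ECI values to the seven-step contamination scale: below 2
#' uncontaminated, unit-wide left-closed classes up to 7, above 7 extremely
#' contaminated. Boundary values belong to the upper class.
#'
#' @param x Non-negative ECI value(s).
#' @return Character vector of contamination labels.
#' @export
classify_eci <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("ECI must be non-negative", call. = FALSE)
  eci_contamination_classes$label[
    findInterval(x, eci_contamination_classes$lower, left.open = FALSE)]
}

#' @rdname classify_eci
#' @format NULL
#' @export
eci_contamination_classes <- tibble::tibble(
  lower = c(0, 2, 3, 4, 5, 6, 7),
  label = c("Uncontaminated",
            "Uncontaminated to slightly contaminated",
            "Slightly to moderately contaminated",
            "Moderately to considerably contaminated",
            "Considerably to highly contaminated",
            "Highly contaminated",
            "Extremely contaminated"))

#' ECI for every site of an mHQ table
#'
#' @param mhq_tbl Tibble from [mhq_table()].
#' @param bn Named numeric vector of per-site B_n weights (names matching the
#'   sites of `mhq_tbl`), or a single scalar applied to all sites.
#' @return Tibble with one row per site: `site`, `eci`, `bn`, `sum_mhq`,
#'   `n_metals`, `class`, `top_contributor`.
#' @export
eci_table <- function(mhq_tbl, bn) {
  sites <- unique(mhq_tbl$site)
  if (length(bn) == 1L && is.null(names(bn))) bn <- setNames(rep(bn, length(sites)), sites)
  miss <- setdiff(sites, names(bn))
  if (length(miss)) {
    stop("no bn weight for site(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(sites, function(s) {
    sub <- mhq_tbl[mhq_tbl$site == s, ]
    r <- eci(setNames(sub$mhq, sub$metal), bn[[s]])
    tibble::tibble(site = s, eci = r$eci, bn = r$bn, sum_mhq = r$sum_mhq,
                   n_metals = r$n_metals, class = r$class,
                   top_contributor = names(sort(r$contributions, decreasing = TRUE))[1])
  })
  dplyr::bind_rows(rows)
}

#' Rank metals by index value within each site
#'
#' Orders metals by descending index value (mHQ by default) per site,
#' producing the "pollution sequence" strings used to compare indices. Ties
#' are broken alphabetically and flagged.
#'
#' @param tbl Tibble with columns `site`, `metal` and the value column.
#' @param value Name of the value column (default `"mhq"`).
#' @return Tibble with one row per site: `site`, `ordering` (list column of
#'   metal vectors, most severe first), `sequence` (e.g. `"Cd > Pb > ..."`)
#'   and logical `tied`.
#' @export
rank_metals <- function(tbl, value = "mhq") {
  if (!value %in% names(tbl)) stop("no column '", value, "' in table", call. = FALSE)
  rows <- lapply(unique(tbl$site), function(s) {
    sub <- tbl[tbl$site == s, ]
    ord <- order(-sub[[value]], sub$metal)
    tibble::tibble(site = s, ordering = list(sub$metal[ord]),
                   sequence = paste(sub$metal[ord], collapse = " > "),
                   tied = anyDuplicated(sub[[value]]) > 0)
  })
  dplyr::bind_rows(rows)
}
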