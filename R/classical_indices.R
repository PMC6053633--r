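#' Contamination factor
#'
#' CF = C / B, the measured concentration over its crustal/regional
#' background.
#'
#' @param c Concentration(s), mg/kg.
#' @param background Background concentration(s), mg/kg; positive.
#' @return Numeric CF value(s).
#' @export
contamination_factor <- function(c, background) {
  if (any(background <= 0, na.rm = TRUE)) {
    stop("background must be positive", call. = FALSE)
  }
  c / background
}

#' Per-metal share of the degree of contamination
#'
#' %DC_i = CF_i / sum(CF) * 100: each metal's percentage contribution to the
#' site's summed contamination factors.
#'
#' @param cf Numeric vector of contamination factors for one site.
#' @return Percentages summing to 100.
#' @export
percent_dc <- function(cf) {
  s <- sum(cf)
  if (s <= 0) stop("sum of contamination factors must be positive", call. = FALSE)
  cf / s * 100
}

#' Modified degree of contamination and pollution load index
#'
#' `modified_degree_contamination()` is the arithmetic mean of the CFs;
#' `pollution_load_index()` their geometric mean. By the AM-GM inequality
#' PLI <= mCd for any positive CF set.
#'
#' @param cf Numeric vector of contamination factors (PLI requires all > 0).
#' @return A single index value.
#' @export
modified_degree_contamination <- function(cf) {
  if (!length(cf)) stop("at least one CF required", call. = FALSE)
  mean(cf)
}

#' @rdname modified_degree_contamination
#' @export
pollution_load_index <- function(cf) {
  if (!length(cf)) stop("at least one CF required", call. = FALSE)
  if (any(cf <= 0)) stop("PLI requires all CF > 0", call. = FALSE)
  exp(mean(log(cf)))
}

#' Hakanson potential ecological risk
#'
#' Per-metal risk Er = Tr * CF (toxic-response factor times contamination
#' factor), the site risk index RI = sum(Er), and each metal's percentage
#' share %Ri.
#'
#' @param cf Named numeric vector of contamination factors.
#' @param tr Toxic-response factors, matched to `cf` by name when both are
#'   named, else by position.
#' @return List with `er` (per-metal), `ri` (scalar), `pct_ri` (percentages
#'   summing to 100).
#' @export
ecological_risk <- function(cf, tr) {
  if (!is.null(names(cf)) && !is.null(names(tr))) {
    miss <- setdiff(names(cf), names(tr))
    if (length(miss)) {
      stop("no toxic-response factor for metal(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    tr <- tr[names(cf)]
  }
  er <- tr * cf
  ri <- sum(er)
  list(er = er, ri = ri, pct_ri = if (ri > 0) er / ri * 100 else er * NA_real_)
}

#' Speciation-based risk indices from Tessier fractions
#'
#' Per record: the risk assessment code RAC = (F1 + F2) / (F1 + ... + F5) *
#' 100, the percentage of metal in the bioavailable exchangeable +
#' carbonate-bound pools, and the individual contamination factor
#' ICF = (F1 + F2 + F3 + F4) / F5, the non-residual over residual ratio.
#' ICF is `NA` (flagged) when the residual fraction is zero.
#'
#' @param records Fraction-record tibble (see [read_fraction_table()]).
#' @return The input with columns `rac`, `icf` and logical `icf_undefined`
#'   appended.
#' @export
speciation_indices <- function(records) {
  tot <- records$f1 + records$f2 + records$f3 + records$f4 + records$f5
  if (any(tot <= 0)) stop("total fraction mass must be positive", call. = FALSE)
  out <- records
  out$rac <- (records$f1 + records$f2) / tot * 100
  out$icf_undefined <- records$f5 == 0
  out$icf <- ifelse(out$icf_undefined, NA_real_,
                    (records$f1 + records$f2 + records$f3 + records$f4) / records$f5)
  # all mass residual: non-residual pool is empty, ICF is 0, not undefined
  out
}

#' Effect-level hazard quotient
#'
#' HQ = C / level for a chosen effect level (TEL by default): the classical
#' single-guideline quotient the mHQ generalises.
#'
#' @param c Concentration(s), mg/kg.
#' @param level Effect level(s), mg/kg; positive.
#' @return Numeric quotient(s).
#' @export
effect_level_quotient <- function(c, level) {
  if (any(level <= 0, na.rm = TRUE)) stop("effect level must be positive", call. = FALSE)
  c / level
}

#' Classical comparison-index table
#'
#' Computes the selected classical indices for every site of a concentration
#' matrix: per-metal CF, %DC, Er, %Ri and HQ, and the site aggregates mCd,
#' PLI and RI (reported with `metal = "ALL"`).
#'
#' @param concentrations Site-by-metal matrix from
#'   [aggregate_concentrations()].
#' @param constants Background/toxic-response tibble from [read_constants()].
#' @param guidelines Guideline tibble (used by `hq`).
#' @param indices Subset of `c("cf", "dc", "er", "ri", "mcd", "pli", "hq")`.
#' @param hq_level Which effect level the HQ uses: `"tel"`, `"pel"` or
#'   `"sel"`.
#' @return Tibble with columns `index`, `site`, `metal`, `value`.
#' @export
classical_indices <- function(concentrations, constants = default_constants(),
                              guidelines = default_guidelines(),
                              indices = c("cf", "dc", "er", "ri", "mcd", "pli", "hq"),
                              hq_level = c("tel", "pel", "sel")) {
  indices <- match.arg(indices, several.ok = TRUE)
  hq_level <- match.arg(hq_level)
  metals <- colnames(concentrations)
  k <- match_metals(constants, metals, "constants")
  rows <- list()
  add <- function(index, site, metal, value) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      index = index, site = site, metal = metal, value = unname(value))
  }
  for (s in rownames(concentrations)) {
    cf <- setNames(contamination_factor(concentrations[s, metals], k$background), metals)
    if ("cf" %in% indices) add("cf", s, metals, cf)
    if ("dc" %in% indices) add("dc", s, metals, percent_dc(cf))
    if (any(c("er", "ri") %in% indices)) {
      risk <- ecological_risk(cf, setNames(k$tr, metals))
      if ("er" %in% indices) add("er", s, metals, risk$er)
      if ("ri" %in% indices) {
        add("ri_pct", s, metals, risk$pct_ri)
        add("ri", s, "ALL", risk$ri)
      }
    }
    if ("mcd" %in% indices) add("mcd", s, "ALL", modified_degree_contamination(cf))
    if ("pli" %in% indices) add("pli", s, "ALL", pollution_load_index(cf))
    if ("hq" %in% indices) {
      g <- match_metals(guidelines, metals, "guideline")
      add("hq", s, metals,
          effect_level_quotient(concentrations[s, metals], g[[hq_level]]))
    }
  }
  dplyr::bind_rows(rows)
}
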