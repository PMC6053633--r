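#' Run the full sediment-quality assessment pipeline
#'
#' One call from raw records to classified indices: aggregates the periodic
#' concentrations, fits (or accepts) per-site factor models for the ECI
#' weight, computes mHQ, ECI and the selected classical indices, ranks metals
#' within sites and sites by ECI, and assembles a rank-concordance report
#' across indices. Deterministic given its inputs; the constants actually
#' used are echoed in the result's `manifest`.
#'
#' @param data Fraction-record tibble (speciation input; totals are formed by
#'   [fraction_totals()]) or concentration-record tibble (`site`, `metal`,
#'   `period`, `c`).
#' @param guidelines,constants Tibbles from [read_guidelines()] /
#'   [read_constants()]; defaults are the bundled sets.
#' @param aggregation How periods collapse to one index per (site, metal):
#'   `"mean"`/`"median"` aggregate the concentrations first and compute the
#'   indices once; `"period_mean"` computes an mHQ per period and averages
#'   the indices (classical indices still use mean concentrations).
#' @param bn Per-site ECI weights. `"pca"` (default) derives each site's B_n
#'   from the leading eigenvalue of its own correlation PCA of the
#'   periods-by-metals data; alternatively a named numeric vector of
#'   eigenvalues (inverted internally) or of ready weights via
#'   `bn_is_eigenvalue`.
#' @param bn_component Which component's eigenvalue to invert when
#'   `bn = "pca"`.
#' @param bn_is_eigenvalue When `bn` is numeric: interpret the values as
#'   eigenvalues (`TRUE`, default) or as ready B_n weights.
#' @param rotate Varimax-rotate the per-site models before reading off the
#'   eigenvalue (the default reads the unrotated PC eigenvalue).
#' @param indices Classical index selection, see [classical_indices()].
#' @return A list of class `"sedqual_run"`: `concentrations` (site-by-metal
#'   matrix), `mhq`, `eci`, `classical`, `models` (per-site factor models or
#'   `NULL`), `speciation` (per-record RAC/ICF when `data` held fractions),
#'   `metal_rankings`, `site_ranking`, `concordance` and `manifest`.
#' @examples
#' run <- run_pipeline(case_study_concentrations(),
#'                     bn = sapply(case_study_pca(), function(m) m$eigenvalues[1]))
#' run$eci
#' @export
run_pipeline <- function(data, guidelines = default_guidelines(),
                         constants = default_constants(),
                         aggregation = c("mean", "median", "period_mean"),
                         bn = "pca", bn_component = 1L, bn_is_eigenvalue = TRUE,
                         rotate = FALSE,
                         indices = c("cf", "dc", "er", "ri", "mcd", "pli", "hq")) {
  aggregation <- match.arg(aggregation)
  speciation <- NULL
  if (all(paste0("f", 1:5) %in% names(data))) {
    speciation <- speciation_indices(data)
    totals <- fraction_totals(data)
  } else if ("c" %in% names(data)) {
    totals <- data
  } else {
    stop("data must carry either fraction columns f1..f5 or totals column c",
         call. = FALSE)
  }
  if (!length(unique(totals$metal))) stop("empty metal selection", call. = FALSE)
  conc <- aggregate_concentrations(
    totals, method = if (aggregation == "median") "median" else "mean")

  models <- NULL
  if (identical(bn, "pca")) {
    models <- site_pca(totals, retain = "kaiser", rotate = rotate)
    bn_w <- vapply(models, bn_weight, numeric(1), component = bn_component)
  } else if (is.numeric(bn)) {
    bn_w <- if (bn_is_eigenvalue) 1 / bn else bn
    if (any(bn_w <= 0)) stop("bn weights must be positive", call. = FALSE)
  } else {
    stop("bn must be \"pca\" or a numeric vector", call. = FALSE)
  }

  mhq_tbl <- if (aggregation == "period_mean") {
    per <- mhq_records(totals, guidelines)
    agg <- dplyr::summarise(dplyr::group_by(per, .data$site, .data$metal),
                            mhq = mean(.data$mhq), .groups = "drop")
    agg$severity <- classify_mhq(agg$mhq)
    gi <- match(agg$metal, guidelines$metal)
    agg$partial_guidelines <- is.na(guidelines$tel[gi]) |
      is.na(guidelines$pel[gi]) | is.na(guidelines$sel[gi])
    agg
  } else {
    mhq_table(conc, guidelines)
  }
  eci_tbl <- eci_table(mhq_tbl, bn_w)
  cls <- classical_indices(conc, constants, guidelines, indices = indices)

  rank_inputs <- list(mhq = mhq_tbl)
  for (ix in intersect(c("cf", "dc", "er", "hq"), unique(cls$index))) {
    sub <- cls[cls$index == ix & cls$metal != "ALL", ]
    rank_inputs[[ix]] <- tibble::tibble(site = sub$site, metal = sub$metal,
                                        value = sub$value)
  }
  rankings <- lapply(names(rank_inputs), function(nm) {
    tbl <- rank_inputs[[nm]]
    r <- rank_metals(tbl, value = if (nm == "mhq") "mhq" else "value")
    r$index <- nm
    r
  })
  rankings <- dplyr::bind_rows(rankings)[c("index", "site", "ordering", "sequence", "tied")]

  structure(list(
    concentrations = conc,
    mhq = mhq_tbl,
    eci = eci_tbl,
    classical = cls,
    models = models,
    speciation = speciation,
    metal_rankings = rankings,
    site_ranking = rank_sites_by_eci(eci_tbl),
    concordance = concordance(rankings),
    manifest = list(aggregation = aggregation,
                    bn = bn_w, bn_source = if (is.null(models)) "supplied" else "pca",
                    bn_component = bn_component, rotate = rotate,
                    guidelines = guidelines, constants = constants,
                    indices = indices)), class = "sedqual_run")
}

#' @export
print.sedqual_run <- function(x, ...) {
  cat("sedqual pipeline run:", nrow(x$eci), "sites,",
      ncol(x$concentrations), "metals; aggregation:",
      x$manifest$aggregation, "\n\nSite ECIs:\n")
  print(x$eci[c("site", "eci", "class")])
  cat("\nSite severity ranking:", paste(x$site_ranking$site, collapse = " > "), "\n")
  invisible(x)
}

#' Rank sites by ecological contamination index
#'
#' @param eci_tbl Tibble from [eci_table()] (columns `site`, `eci`).
#' @return The table sorted by descending ECI with a rank column and a
#'   logical `tied` flag (ties keep their input order).
#' @examples
#' rank_sites_by_eci(tibble::tibble(
#'   site = c("QUE", "QUR", "OKT", "DOU", "STB"),
#'   eci = c(4.06, 3.80, 3.46, 5.06, 3.73)))
#' @export
rank_sites_by_eci <- function(eci_tbl) {
  ord <- order(-eci_tbl$eci)
  out <- eci_tbl[ord, ]
  out$rank <- seq_len(nrow(out))
  out$tied <- duplicated(out$eci) | duplicated(out$eci, fromLast = TRUE)
  out
}

#' Rank-concordance report across indices
#'
#' Compares the per-site metal orderings produced by different indices:
#' exact-match flags and Spearman rank correlations for every index pair at
#' every site. This is the quantitative form of the "pollution sequence"
#' comparison used to validate a new index against the classical suite.
#'
#' @param rankings Tibble with columns `index`, `site`, `ordering` (list
#'   column of metal vectors, most severe first), as produced inside
#'   [run_pipeline()], or a named list of such orderings for a single site.
#' @return A tibble with one row per (site, index pair): `site`, `index_a`,
#'   `index_b`, `spearman`, `exact_match`.
#' @examples
#' concordance(list(mhq = c("Cd", "Pb", "Cu", "Cr", "Ni"),
#'                  cf = c("Cd", "Pb", "Cu", "Cr", "Ni")))
#' @export
concordance <- function(rankings) {
  if (is.list(rankings) && !is.data.frame(rankings)) {
    rankings <- tibble::tibble(index = names(rankings), site = "ALL",
                               ordering = unname(rankings))
  }
  if (length(unique(rankings$index)) < 2) {
    stop("at least two indices are required", call. = FALSE)
  }
  rows <- list()
  for (s in unique(rankings$site)) {
    sub <- rankings[rankings$site == s, ]
    idx <- sub$index
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a >= b) next
      oa <- sub$ordering[[a]]; ob <- sub$ordering[[b]]
      if (!setequal(oa, ob) || length(oa) != length(ob)) {
        stop("orderings for indices ", idx[a], " and ", idx[b], " at site ", s,
             " cover different metal sets", call. = FALSE)
      }
      # rank of each metal under each index: position in the descending list;
      # orderings are strict permutations, so the closed form is exact
      ra <- match(sort(oa), oa)
      rb <- match(sort(oa), ob)
      n <- length(ra)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        site = s, index_a = idx[a], index_b = idx[b],
        spearman = 1 - 6 * sum((ra - rb)^2) / (n * (n^2 - 1)),
        exact_match = identical(oa, ob))
    }
  }
  dplyr::bind_rows(rows)
}

#' Write the result tables of a pipeline run
#'
#' Serialises the run's mHQ, ECI, classical-index and ranking tables as
#' delimited text into a directory, together with a plain-text manifest of
#' every constant used (guidelines, backgrounds, toxic-response factors,
#' B_n weights).
#'
#' @param run A `"sedqual_run"` object.
#' @param dir Output directory (created if needed).
#' @param sep Field separator.
#' @param digits Significant digits for numeric output.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir, sep = ",", digits = 4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, file) {
    df <- as.data.frame(df)
    df$ordering <- NULL  # list column, already rendered in `sequence`
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = digits)
    write.table(df, file.path(dir, file), sep = sep, row.names = FALSE,
                quote = FALSE)
  }
  emit(run$mhq, "mhq.csv")
  emit(run$eci, "eci.csv")
  emit(run$classical, "classical_indices.csv")
  emit(run$metal_rankings, "metal_rankings.csv")
  emit(run$site_ranking, "site_ranking.csv")
  emit(run$concordance, "concordance.csv")
  man <- run$manifest
  lines <- c(
    paste0("aggregation: ", man$aggregation),
    paste0("bn_source: ", man$bn_source),
    paste0("bn_component: ", man$bn_component),
    paste0("rotate: ", man$rotate),
    paste0("bn[", names(man$bn), "]: ", signif(man$bn, 6)),
    paste0("guideline[", man$guidelines$metal, "] tel/pel/sel: ",
           man$guidelines$tel, "/", man$guidelines$pel, "/", man$guidelines$sel),
    paste0("constant[", man$constants$metal, "] background/tr: ",
           man$constants$background, "/", man$constants$tr),
    paste0("indices: ", paste(man$indices, collapse = ",")))
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(dir)
}
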