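# bundled case-study survey: five Equatorial Atlantic coastal ecosystems
# (QUE, DOU, STB, OKT, QUR), five metals, six sampling months. Stored as
# plain CSV under extdata; loaders verify the files' md5 sums so silent
# edits of the reference numbers cannot pass unnoticed.

fixture_md5 <- c(
  estuary_monthly_metals.csv = "89d93a6a759468f5345716ceb6ba9602",
  estuary_pca_loadings.csv = "f7302db3db977339c922bfd0ba3f3e45")

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "sedqual", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(fixture_md5[[file]]))) {
    stop("bundled data file ", file, " fails its checksum; reinstall the package",
         call. = FALSE)
  }
  path
}

#' Case-study monthly metal concentrations
#'
#' The bundled survey dataset: monthly mean total concentrations (and
#' standard deviations), mg/kg dry weight, of Cd, Cr, Cu, Ni and Pb in
#' benthic sediments of five tropical coastal ecosystems — Qua Iboe Estuary
#' (QUE), Douglas Creek (DOU), Stubbs Creek (STB), Okorotip Creek (OKT) and
#' Qua Iboe River (QUR) — over six months spanning the wet (Jun-Aug) and dry
#' (Nov-Jan) seasons.
#'
#' @return A tibble of 150 concentration records: `site`, `metal`, `period`,
#'   `c`, `sd`.
#' @seealso [case_study_pca()] for the matching per-site PCA summaries.
#' @export
case_study_concentrations <- function() {
  read_concentration_table(fixture_path("estuary_monthly_metals.csv"))
}

#' Case-study per-site PCA summaries
#'
#' The two-component rotated correlation-PCA summaries that accompany the
#' case-study survey: per site, the loadings of the five metals on PC1 and
#' PC2, the component eigenvalues, percentage variability and cumulative
#' percentage. PC1 was interpreted as the anthropogenic contamination
#' component and its eigenvalue is the source of the ECI weight B_n for
#' these sites.
#'
#' @return A named list (one element per site) of `"factor_model"` objects
#'   with `metals`, `eigenvalues`, `loadings`, `variability`, `cumulative`
#'   and `rotation = "varimax"`.
#' @examples
#' case_study_pca()$DOU$eigenvalues[1]  # 1.705
#' @export
case_study_pca <- function() {
  df <- read_delimited(fixture_path("estuary_pca_loadings.csv"))
  metals <- c("cd", "cr", "cu", "ni", "pb")
  models <- lapply(split(df, df$site), function(sub) {
    sub <- sub[order(sub$component), ]
    L <- t(as.matrix(sub[metals]))
    dimnames(L) <- list(c("Cd", "Cr", "Cu", "Ni", "Pb"), sub$component)
    structure(list(metals = rownames(L),
                   eigenvalues = sub$eigenvalue,
                   loadings = L,
                   variability = sub$variability,
                   cumulative = sub$cumulative,
                   rotation = "varimax",
                   n_obs = NA_integer_), class = "factor_model")
  })
  models[unique(df$site)]
}
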