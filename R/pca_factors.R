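#' Column-standardize an observations-by-variables matrix
#'
#' Centres each column to mean zero and scales to sample standard deviation
#' one, the preprocessing that turns a covariance PCA into a
#' correlation-matrix PCA.
#'
#' @param x Numeric matrix, observations in rows, variables (metals) in
#'   columns; at least two rows.
#' @return Matrix of z-scores with the same dimnames.
#' @export
standardize_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("at least two observations are required", call. = FALSE)
  s <- apply(x, 2, sd)
  zero <- s == 0 | is.na(s)
  if (any(zero)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[zero] %||% which(zero), collapse = ", "), call. = FALSE)
  }
  scale(x, center = TRUE, scale = s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlation-matrix principal component analysis
#'
#' Fits a PCA on the correlation matrix of `x` via the singular value
#' decomposition of the standardized data. Eigenvalues are returned in
#' descending order and sum to the number of variables; loadings are
#' eigenvectors scaled by the square root of their eigenvalue, so that
#' squared loadings summed over components give each variable's communality.
#' Column signs follow the convention that each component's
#' largest-magnitude loading is positive.
#'
#' With fewer observations than variables the trailing eigenvalues are
#' exactly zero; they are kept (and reported) but never retained by
#' [retain_components()].
#'
#' @param x Observations-by-metals matrix (rows e.g. monthly records of one
#'   site).
#' @return An object of class `"factor_model"`: a list with `metals`,
#'   `eigenvalues`, `loadings` (metals x components), `variability`
#'   (percent of total variance per component), `cumulative`, `rotation`
#'   (`"none"`) and `n_obs`.
#' @examples
#' fit <- fit_pca(matrix(rnorm(30), 6, 5))
#' sum(fit$eigenvalues)  # 5
#' @export
fit_pca <- function(x) {
  z <- standardize_matrix(x)
  p <- ncol(z)
  sv <- svd(z)
  k <- length(sv$d)
  ev <- c(sv$d^2 / (nrow(z) - 1), rep(0, p - k))
  ev[ev < .Machine$double.eps * p] <- 0
  loadings <- matrix(0, p, p)
  loadings[, seq_len(k)] <- sv$v %*% diag(sqrt(ev[seq_len(k)]), k, k)
  rownames(loadings) <- colnames(z)
  colnames(loadings) <- paste0("PC", seq_len(p))
  loadings <- fix_signs(loadings)
  structure(list(
    metals = colnames(z),
    eigenvalues = ev,
    loadings = loadings,
    variability = ev / p * 100,
    cumulative = cumsum(ev / p * 100),
    rotation = "none",
    n_obs = nrow(z)), class = "factor_model")
}

fix_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (length(i) && L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("Correlation PCA of %d metals (%d observations), rotation: %s\n",
              length(x$metals), x$n_obs, x$rotation))
  tab <- rbind(Eigenvalue = x$eigenvalues,
               `Variability (%)` = x$variability,
               `Cumulative %` = x$cumulative)
  colnames(tab) <- colnames(x$loadings)
  print(round(x$loadings, 3))
  print(round(tab, 3))
  invisible(x)
}

#' Retain leading principal components
#'
#' Keeps either the components with eigenvalue above one (Kaiser criterion,
#' the default) or a fixed number `k`. At least one component is always
#' retained; zero eigenvalues never are.
#'
#' @param model A [fit_pca()] model.
#' @param rule `"kaiser"` or `"fixed"`.
#' @param k Number of components when `rule = "fixed"`.
#' @return The model restricted to the retained components (eigenvalues,
#'   loadings, variability, cumulative all subset).
#' @export
retain_components <- function(model, rule = c("kaiser", "fixed"), k = NULL) {
  rule <- match.arg(rule)
  p <- length(model$eigenvalues)
  keep <- if (rule == "kaiser") {
    max(1L, sum(model$eigenvalues > 1))
  } else {
    if (is.null(k) || k < 1 || k > p) {
      stop("k must be between 1 and the number of components (", p, ")",
           call. = FALSE)
    }
    as.integer(k)
  }
  keep <- min(keep, sum(model$eigenvalues > 0))
  idx <- seq_len(keep)
  model$eigenvalues <- model$eigenvalues[idx]
  model$loadings <- model$loadings[, idx, drop = FALSE]
  model$variability <- model$variability[idx]
  model$cumulative <- model$cumulative[idx]
  model
}

#' Varimax rotation of retained loadings
#'
#' Orthogonally rotates the retained loadings towards simple structure
#' (maximal variance of squared loadings per component). Communalities — the
#' row sums of squared loadings — are invariant under the rotation. Kaiser
#' row-normalization is applied by default. A single retained component
#' cannot be rotated and is returned unchanged with a warning.
#'
#' Rotated "eigenvalues" are reported as the column sums of squared rotated
#' loadings, with components reordered so they descend.
#'
#' @param model A (typically reduced, see [retain_components()]) factor
#'   model.
#' @param normalize Kaiser row-normalization toggle.
#' @return The model with rotated loadings, updated per-component variance
#'   shares and `rotation = "varimax"`.
#' @export
varimax_rotate <- function(model, normalize = TRUE) {
  L <- model$loadings
  if (ncol(L) < 2) {
    warning("only one retained component; varimax rotation is the identity",
            call. = FALSE)
    model$rotation <- "varimax"
    return(model)
  }
  rot <- varimax(L, normalize = normalize, eps = 1e-10)
  Lr <- unclass(rot$loadings)
  ssq <- colSums(Lr^2)
  ord <- order(-ssq)
  Lr <- fix_signs(Lr[, ord, drop = FALSE])
  colnames(Lr) <- colnames(L)
  p <- length(model$metals)
  model$loadings <- Lr
  model$eigenvalues <- ssq[ord]
  model$variability <- ssq[ord] / p * 100
  model$cumulative <- cumsum(model$variability)
  model$rotation <- "varimax"
  model
}

#' ECI weight from a factor model
#'
#' B_n is the reciprocal of the model's leading eigenvalue (by default), the
#' weight applied to the site's summed modified hazard quotients in [eci()].
#' Any retained component can be selected instead.
#'
#' @param model A factor model, or a single positive eigenvalue.
#' @param component Which component's eigenvalue to invert.
#' @return Positive scalar B_n.
#' @examples
#' bn_weight(1.705)  # 0.58651
#' @export
bn_weight <- function(model, component = 1L) {
  ev <- if (inherits(model, "factor_model")) {
    if (component > length(model$eigenvalues)) {
      stop("component ", component, " not retained", call. = FALSE)
    }
    model$eigenvalues[component]
  } else {
    model[component]
  }
  if (!is.finite(ev) || ev <= 0) {
    stop("eigenvalue must be positive and finite", call. = FALSE)
  }
  1 / ev
}

#' Per-site factor models from periodic concentration records
#'
#' Builds, for each site, the periods-by-metals concentration matrix and fits
#' a correlation PCA on it — the per-site factor model whose leading
#' eigenvalue feeds [bn_weight()].
#'
#' @param records Concentration-record tibble (`site`, `metal`, `period`,
#'   `c`).
#' @param retain Retention rule passed to [retain_components()]; `NULL` keeps
#'   all components.
#' @param rotate Apply varimax to the retained loadings.
#' @return Named list of factor models, one per site.
#' @export
site_pca <- function(records, retain = "kaiser", rotate = FALSE) {
  sites <- unique(records$site)
  metals <- unique(records$metal)
  models <- lapply(sites, function(s) {
    sub <- records[records$site == s, ]
    wide <- tidyr::pivot_wider(sub[c("period", "metal", "c")],
                               names_from = "metal", values_from = "c")
    m <- as.matrix(wide[metals])
    rownames(m) <- wide$period
    fit <- fit_pca(m)
    if (!is.null(retain)) fit <- retain_components(fit, rule = retain)
    if (rotate) fit <- varimax_rotate(fit)
    fit
  })
  setNames(models, sites)
}
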