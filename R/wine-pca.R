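# Mean-centered PCA of the annual vintage table, with a deterministic
# sign convention and trend reporting on the component scores.

.pca_default_cols <- c("pvad", "ph", "tta", "wb100", "veraison_doy",
                       "harvest_doy", "production", "yield")

#' Principal component analysis of a vintage table
#'
#' Eigendecomposition of the covariance (centered only) or correlation
#' (centered and standardized, the default — the variables mix units:
#' % vol, g/L, day-of-year) matrix of the vintage variables. Components
#' are ordered by decreasing eigenvalue. Sign convention: within each
#' component the loading of largest magnitude is made positive; PC1 is
#' additionally flipped, if needed, so the probable-alcohol (pvad)
#' loading is positive — positive PC1 then reads as hot-vintage years
#' (high alcohol and pH, low acidity, early phenology). Rows with
#' missing values in the selected columns are dropped (listwise) with a
#' message.
#'
#' @param table Vintage data.frame with a `year` column.
#' @param n_components Number of components to retain (default all).
#' @param scaling `"center+standardize"` (default) or `"center"`.
#' @param columns Variables to include; defaults to the standard vintage
#'   variables present in the table.
#' @return Object of class `pc_decomposition`: list with `loadings`
#'   (variable x component), `explained_fraction`, `eigenvalues`,
#'   `scores` (data.frame `year` + components), `center`, `scale`,
#'   `n_dropped`.
#' @export
run_pca <- function(table, n_components = NULL,
                    scaling = c("center+standardize", "center"),
                    columns = NULL) {
  scaling <- match.arg(scaling)
  if (is.null(columns))
    columns <- intersect(.pca_default_cols, names(table))
  if (length(columns) < 2L) stop("PCA needs at least 2 variables")
  X <- as.matrix(table[, columns, drop = FALSE])
  storage.mode(X) <- "double"
  complete <- stats::complete.cases(X)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(n_dropped, " row(s) with missing values dropped")
  X <- X[complete, , drop = FALSE]
  years <- table$year[complete]

  p <- ncol(X)
  if (is.null(n_components)) n_components <- p
  if (nrow(X) < n_components + 1L)
    stop("insufficient data: need at least n_components + 1 complete rows")

  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (scaling == "center+standardize") {
    scl <- apply(Xc, 2, stats::sd)
    if (any(scl == 0)) stop("constant variable(s): ",
                            paste(columns[scl == 0], collapse = ", "),
                            " cannot be standardized")
    Xc <- sweep(Xc, 2, scl, "/")
  } else {
    scl <- rep(1, p)
  }

  C <- crossprod(Xc) / (nrow(Xc) - 1)
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  rank <- sum(ev > max(ev) * 1e-10)
  if (rank < p) warning("covariance matrix is rank deficient (rank ",
                        rank, " of ", p, ")")
  if (n_components > rank)
    stop("n_components exceeds the rank of the data (", rank, ")")

  V <- eig$vectors[, seq_len(n_components), drop = FALSE]
  rownames(V) <- columns
  colnames(V) <- paste0("PC", seq_len(n_components))
  # sign convention: largest-|loading| entry positive per component
  for (k in seq_len(n_components)) {
    top <- which.max(abs(V[, k]))
    if (V[top, k] < 0) V[, k] <- -V[, k]
  }
  if ("pvad" %in% columns && V["pvad", 1] < 0) V[, 1] <- -V[, 1]

  scores <- Xc %*% V
  out <- list(
    loadings = V,
    eigenvalues = ev,
    explained_fraction = ev[seq_len(n_components)] / sum(ev),
    scores = data.frame(year = years, scores, check.names = FALSE),
    center = ctr, scale = scl, scaling = scaling,
    n_dropped = n_dropped, columns = columns
  )
  class(out) <- "pc_decomposition"
  out
}

#' @export
print.pc_decomposition <- function(x, ...) {
  k <- ncol(x$loadings)
  cat("PCA (", x$scaling, ") of ", length(x$columns), " variables, ",
      nrow(x$scores), " years\n", sep = "")
  cat("Explained variance: ",
      paste(sprintf("PC%d %.1f%%", seq_len(k),
                    100 * x$explained_fraction), collapse = ", "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Trend report for a component score series
#'
#' Runs the Mann-Kendall test and Theil-Sen estimator on the annual score
#' series of one principal component.
#'
#' @param decomp A [run_pca()] result.
#' @param component Component number (default 1).
#' @param alpha Confidence level parameter for the slope CI.
#' @return A `trend_result` (see [mann_kendall()]) with the Theil-Sen
#'   slope computed against calendar year.
#' @export
score_trend_report <- function(decomp, component = 1L, alpha = 0.05) {
  stopifnot(inherits(decomp, "pc_decomposition"))
  col <- paste0("PC", component)
  if (!col %in% names(decomp$scores)) stop("component not retained: ", col)
  s <- decomp$scores[[col]]
  yr <- decomp$scores$year
  mk <- mann_kendall(s, alpha = alpha)
  ts <- theil_sen(s, yr, alpha = alpha)
  mk$sen_slope <- ts$slope
  mk$sen_intercept <- ts$intercept
  mk$slope_ci <- ts$ci
  mk
}
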