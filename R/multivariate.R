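#' Pairwise Pearson correlation screening
#'
#' Correlation matrix of a trait table with two-sided p-values from the
#' t transform with n - 2 degrees of freedom.  Pairwise deletion: each
#' pair uses its complete rows and needs at least `min_n` of them (entries
#' are `NA` otherwise).  Zero-variance columns yield `NA` entries and a
#' warning.
#'
#' @param table numeric data.frame or matrix (rows = species, columns =
#'   traits).
#' @param min_n minimum complete pairs (default 3).
#' @return list with symmetric matrices `r` (unit diagonal), `p`, and `n`
#'   (pairs used).
#' @export
pearson_matrix <- function(table, min_n = 3) {
  x <- as.matrix(table)
  if (!is.numeric(x)) stop_invalid("trait table must be numeric")
  k <- ncol(x)
  if (k < 2L) stop_invalid("need at least 2 traits")
  traits <- colnames(x) %||% paste0("V", seq_len(k))
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  degenerate <- character()
  for (i in seq_len(k)) for (j in i:k) {
    ok <- stats::complete.cases(x[, i], x[, j])
    m <- sum(ok)
    n[i, j] <- n[j, i] <- m
    if (i == j) { r[i, i] <- 1; p[i, i] <- 0; next }
    if (m < min_n) next
    si <- stats::sd(x[ok, i]); sj <- stats::sd(x[ok, j])
    if (si == 0 || sj == 0) {
      degenerate <- union(degenerate, traits[c(i, j)[c(si, sj) == 0]])
      next
    }
    rij <- stats::cor(x[ok, i], x[ok, j])
    r[i, j] <- r[j, i] <- rij
    tstat <- rij * sqrt((m - 2) / max(1 - rij^2, .Machine$double.eps))
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tstat), df = m - 2)
  }
  if (length(degenerate))
    warning("zero-variance trait(s): ", paste(degenerate, collapse = ", "))
  list(r = r, p = p, n = n)
}

#' Principal component analysis of the species trait table
#'
#' Eigendecomposition of the correlation matrix (default, because the
#' traits mix units: s, cm, Hz, dimensionless) or covariance matrix of the
#' listwise-complete rows.  Scores are the centered (and scaled) data
#' projected on the eigenvectors.  Component signs follow a deterministic
#' convention -- each loading vector's largest-magnitude entry is positive
#' -- so results are reproducible across platforms.  Rank-deficient
#' tables are allowed; trailing components get zero variance.
#'
#' @param table numeric data.frame or matrix (rows = species).
#' @param standardize correlation-matrix PCA if `TRUE` (default),
#'   covariance-matrix PCA otherwise.
#' @param columns optional character vector restricting the analysis to a
#'   subset of trait columns.
#' @return An object of class `"trait_pca"`: list with `loadings`
#'   (trait x component), `scores` (species x component),
#'   `explained` (variance fractions, summing to 1), `sdev`,
#'   `standardized`, `center`, `scale`.
#' @export
pca_traits <- function(table, standardize = TRUE, columns = NULL) {
  x <- as.matrix(table)
  if (!is.null(columns)) {
    missing_cols <- setdiff(columns, colnames(x))
    if (length(missing_cols))
      stop_invalid("unknown trait column(s): ", paste(missing_cols, collapse = ", "))
    x <- x[, columns, drop = FALSE]
  }
  if (ncol(x) < 2L) stop_invalid("need at least 2 traits")
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2L) stop_invalid("need at least 2 complete rows")
  ctr <- colMeans(x)
  scl <- if (standardize) apply(x, 2, stats::sd) else rep(1, ncol(x))
  if (any(scl == 0)) stop_invalid("zero-variance trait; drop it before PCA")
  z <- scale(x, center = ctr, scale = scl)
  S <- if (standardize) stats::cor(x) else stats::cov(x)
  eig <- eigen(S, symmetric = TRUE)
  vals <- pmax(eig$values, 0)  # clamp numerically negative eigenvalues
  vecs <- eig$vectors
  for (j in seq_len(ncol(vecs))) {  # sign convention
    lead <- which.max(abs(vecs[, j]))
    if (vecs[lead, j] < 0) vecs[, j] <- -vecs[, j]
  }
  comp <- paste0("PC", seq_along(vals))
  dimnames(vecs) <- list(colnames(x), comp)
  scores <- z %*% vecs
  dimnames(scores) <- list(rownames(x), comp)
  structure(list(loadings = vecs, scores = scores,
                 explained = vals / sum(vals), sdev = sqrt(vals),
                 standardized = standardize, center = ctr, scale = scl),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  pct <- 100 * x$explained
  cat(sprintf("<trait_pca> %d traits, %d species; %s\n",
              nrow(x$loadings), nrow(x$scores),
              paste(sprintf("%s = %.1f%%", names(pct) %||% colnames(x$loadings),
                            pct)[seq_len(min(4, length(pct)))], collapse = ", ")))
  invisible(x)
}
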