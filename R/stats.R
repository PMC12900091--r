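#' Two-group MANOVA with Wilks' Lambda
#'
#' Tests whether the multivariate feature means of two groups differ.
#' Wilks' Lambda is the ratio of within-group to total generalized variance,
#' \deqn{\Lambda = \det(W) / \det(W + B)}
#' with W and B the within- and between-group sums-of-squares-and-
#' cross-products matrices about the group means (no df scaling; Lambda is
#' invariant to that choice). For two groups the F transform is exact via the
#' Hotelling T-squared identity:
#' \deqn{F = \frac{1 - \Lambda}{\Lambda} \cdot \frac{n - d - 1}{d}}
#' on (d, n - d - 1) degrees of freedom.
#'
#' @param X Numeric matrix or data frame, cases x d features.
#' @param y Two-level group labels aligned with the rows of `X`.
#' @return A `manova_result`: list with `lambda`, `F`, `df1`, `df2`, `p`.
#' @export
manova_wilks <- function(X, y) {
  X <- as.matrix(X)
  if (!is.numeric(X) || ncol(X) < 1L) stop("X must be a numeric matrix with d >= 1")
  y <- as.character(y)
  if (length(y) != nrow(X)) stop("labels must align with rows of X")
  groups <- unique(y)
  if (length(groups) != 2L) stop("exactly two groups are required")
  n <- nrow(X); d <- ncol(X)
  if (any(table(y) < 2L)) stop("both groups need at least 2 cases")
  if (n < d + 2L) stop("need n >= d + 2 cases for the F approximation")
  grand <- colMeans(X)
  W <- matrix(0, d, d)
  B <- matrix(0, d, d)
  for (g in groups) {
    Xg <- X[y == g, , drop = FALSE]
    mg <- colMeans(Xg)
    C <- sweep(Xg, 2, mg)
    W <- W + crossprod(C)
    B <- B + nrow(Xg) * tcrossprod(mg - grand)
  }
  detW <- det(W)
  detT <- det(W + B)
  if (!is.finite(detW) || detW <= 0 || !is.finite(detT) || detT <= 0)
    stop("singular within-group scatter matrix; reduce the feature set")
  lambda <- detW / detT
  lambda <- min(lambda, 1)  # guard rounding just above 1
  df1 <- d
  df2 <- n - d - 1
  Fstat <- (1 - lambda) / lambda * df2 / df1
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  structure(list(lambda = lambda, F = Fstat, df1 = df1, df2 = df2, p = p),
            class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("Wilks' Lambda = %.3f [F(%d, %d) = %.2f], p = %.3g\n",
              x$lambda, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' MANOVA across feature representations
#'
#' Runs [manova_wilks()] on each supplied feature table (e.g. Avg-RGB,
#' Avg-MSI, Phasor-RGB, Phasor-MSI) and collects the results into one table.
#' Phasor tables must carry exactly the two dependent variables g_avg and
#' s_avg (never the STD); averaging tables use one dependent variable per
#' band.
#'
#' @param tables Named list of feature tables (data frames with `case_id`,
#'   `label`, feature columns). All must share the same case set and labels.
#' @return Data frame with one row per representation: `analysis`, `d`,
#'   `lambda`, `F`, `df1`, `df2`, `p`.
#' @export
manova_suite <- function(tables) {
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a named list")
  ids <- lapply(tables, function(t) paste(t$case_id, t$label))
  if (length(unique(ids)) != 1L)
    stop("all tables must share the same cases and labels")
  rows <- lapply(names(tables), function(nm) {
    tab <- tables[[nm]]
    feat <- setdiff(names(tab), c("case_id", "label"))
    res <- manova_wilks(tab[feat], tab$label)
    data.frame(analysis = nm, d = res$df1, lambda = res$lambda, F = res$F,
               df1 = res$df1, df2 = res$df2, p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
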