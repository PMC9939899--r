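#' Univariate Welch t-test screen
#'
#' Two-sided Welch (unequal-variance) t-test of every column against the
#' two-level response label; columns with `p <= alpha` are kept. Columns with
#' zero variance in both groups get the degenerate-variance convention
#' (p = 0 if the group means differ, p = 1 if equal).
#'
#' @param x patients x features numeric matrix.
#' @param labels two-level factor/character vector (e.g. OR/NOR).
#' @param alpha screening level (default 0.05).
#' @return List with `keep` (kept column names, ordered by p), `p` (named
#'   p-value vector) and `alpha`.
#' @export
ttest_screen <- function(x, labels, alpha = 0.05) {
  labels <- factor(labels)
  .assert(nlevels(labels) == 2, "labels must have exactly 2 levels")
  g1 <- labels == levels(labels)[1]
  .assert(sum(g1) >= 2 && sum(!g1) >= 2, "both groups need >= 2 members")
  .assert(all(is.finite(x)), "feature matrix must be finite")
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- colMeans(x[g1, , drop = FALSE]); m2 <- colMeans(x[!g1, , drop = FALSE])
  v1 <- apply(x[g1, , drop = FALSE], 2, var)
  v2 <- apply(x[!g1, , drop = FALSE], 2, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  names(p) <- colnames(x)
  keep <- names(p)[!is.na(p) & p <= alpha]
  list(keep = keep[order(p[keep])], p = p, alpha = alpha)
}

#' LASSO (L1-penalized logistic) feature selection
#'
#' Fits a binomial LASSO path on standardized columns; lambda is chosen by
#' seed-fixed stratified inner cross-validation at the deviance minimum.
#' Features with nonzero coefficients at the chosen lambda are returned. If
#' every coefficient shrinks to zero the selection falls back (with a
#' warning) to the single column with the strongest univariate t statistic.
#'
#' @param x patients x features matrix (>= 2 columns).
#' @param labels two-level response.
#' @param inner_folds inner CV folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @return List of class `SelectionResult`: `kept`, `coefficients` (nonzero,
#'   named), `lambda`, `fallback` flag.
#' @export
lasso_select <- function(x, labels, inner_folds = 5, seed = 1L) {
  .assert(ncol(x) >= 2, "lasso_select needs >= 2 columns")
  labels <- factor(labels)
  y <- as.integer(labels == levels(labels)[2])
  set.seed(seed)
  foldid <- integer(length(y))
  for (cl in 0:1) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(inner_folds), length(idx)))
  }
  # small-lambda tail non-convergence warnings from the path are benign here
  cv <- suppressWarnings(glmnet::cv.glmnet(x, y, family = "binomial",
                                           foldid = foldid, standardize = TRUE))
  cf <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
  kept <- names(cf)[cf != 0]
  fallback <- FALSE
  if (length(kept) == 0) {
    warning("LASSO shrank every coefficient to zero; falling back to the top t-test feature")
    tt <- ttest_screen(x, labels, alpha = 1)
    kept <- names(sort(tt$p))[1]
    cf <- setNames(rep(NA_real_, length(cf)), names(cf))
    fallback <- TRUE
  }
  structure(list(kept = kept, coefficients = cf[kept],
                 lambda = cv$lambda.min, fallback = fallback),
            class = "SelectionResult")
}

#' Two-stage feature selection: t-test screen then LASSO
#'
#' @param x patients x features matrix.
#' @param labels two-level response.
#' @param alpha t-screen level.
#' @param inner_folds,seed passed to [lasso_select()].
#' @return `SelectionResult` with added `t_pvalues` and per-stage `counts`.
#' @export
select_features <- function(x, labels, alpha = 0.05, inner_folds = 5, seed = 1L) {
  tt <- ttest_screen(x, labels, alpha = alpha)
  keep <- tt$keep
  if (length(keep) < 2) {
    # LASSO needs >= 2 columns: pad with the smallest p-values beyond alpha
    keep <- names(sort(tt$p))[seq_len(min(2, ncol(x)))]
  }
  sel <- lasso_select(x[, keep, drop = FALSE], labels,
                      inner_folds = inner_folds, seed = seed)
  sel$t_pvalues <- tt$p[sel$kept]
  sel$counts <- c(input = ncol(x), t_filter = length(tt$keep),
                  lasso = length(sel$kept))
  sel
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat("Feature selection:", length(x$kept), "feature(s) kept")
  if (!is.null(x$counts))
    cat(sprintf(" (input %d -> t-filter %d -> lasso %d)",
                x$counts["input"], x$counts["t_filter"], x$counts["lasso"]))
  cat("\n  lambda =", format(x$lambda, digits = 4),
      if (isTRUE(x$fallback)) " [fallback: top t-test feature]" else "", "\n")
  invisible(x)
}
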