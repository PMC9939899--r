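#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC = P(score_pos > score_neg) + 0.5 * P(tie)`, computed from ranks.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels two-level response; the second factor level (or `"OR"` if
#'   present) is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- .positive_mask(labels)
  .assert(any(pos) && any(!pos), "need both classes to compute an AUC")
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.positive_mask <- function(labels) {
  labels <- factor(labels)
  .assert(nlevels(labels) <= 2, "labels must be two-level")
  positive <- if ("OR" %in% levels(labels)) "OR" else levels(labels)[nlevels(labels)]
  labels == positive
}

# shrinkage LDA fallback for singular pooled covariance (p close to n)
.lda_shrink <- function(xtr, ytr, xte, gamma = 1e-3) {
  lev <- levels(ytr)
  mu <- lapply(lev, function(l) colMeans(xtr[ytr == l, , drop = FALSE]))
  n <- nrow(xtr); p <- ncol(xtr)
  Sp <- matrix(0, p, p)
  for (l in seq_along(lev)) {
    xs <- scale(xtr[ytr == lev[l], , drop = FALSE], center = mu[[l]], scale = FALSE)
    Sp <- Sp + crossprod(xs)
  }
  Sp <- Sp / (n - length(lev))
  tr <- mean(diag(Sp))
  repeat {
    S <- (1 - gamma) * Sp + gamma * tr * diag(p)
    ok <- tryCatch({ ch <- chol(S); TRUE }, error = function(e) FALSE)
    if (ok) break
    gamma <- min(1, gamma * 10)
  }
  Si <- chol2inv(chol(S))
  pri <- table(ytr)[lev] / n
  disc <- vapply(seq_along(lev), function(l) {
    w <- Si %*% mu[[l]]
    as.numeric(xte %*% w - 0.5 * sum(mu[[l]] * w) + log(pri[l]))
  }, numeric(nrow(xte)))
  if (is.null(dim(disc))) disc <- matrix(disc, nrow = 1)
  ex <- exp(disc - apply(disc, 1, max))
  post <- ex / rowSums(ex)
  colnames(post) <- lev
  post
}

.fit_score <- function(classifier, xtr, ytr, xte, seed) {
  pos <- if ("OR" %in% levels(ytr)) "OR" else levels(ytr)[nlevels(ytr)]
  xte <- matrix(xte, ncol = ncol(xtr), dimnames = list(NULL, colnames(xtr)))
  if (classifier == "LDA") {
    fit <- tryCatch(suppressWarnings(MASS::lda(xtr, grouping = ytr)),
                    error = function(e) NULL)
    post <- if (is.null(fit)) .lda_shrink(xtr, ytr, xte) else
      predict(fit, xte)$posterior
    score <- post[, pos]
    list(score = score, pred = ifelse(score > 0.5, pos,
                                      setdiff(levels(ytr), pos)))
  } else if (classifier == "SVM") {
    fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = 1, scale = TRUE)
    pr <- predict(fit, xte, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # orient the margin so positive values favour the positive class
    sgn <- if (startsWith(colnames(dv)[1], paste0(pos, "/"))) 1 else -1
    list(score = sgn * dv[, 1], pred = as.character(pr))
  } else if (classifier == "RF") {
    set.seed(seed)
    fit <- randomForest::randomForest(xtr, ytr, ntree = 500,
                                      mtry = max(1, floor(sqrt(ncol(xtr)))))
    score <- predict(fit, xte, type = "prob")[, pos]
    list(score = score, pred = ifelse(score > 0.5, pos,
                                      setdiff(levels(ytr), pos)))
  } else stop("unknown classifier: ", classifier, call. = FALSE)
}

#' Leave-one-out evaluation of a classifier on a feature matrix
#'
#' Each patient is scored by a model trained on the remaining `n - 1`; the
#' pooled held-out scores give one ROC/AUC. With `selection = TRUE` the
#' t-test + LASSO selection is refit inside every training fold
#' (`onepass = FALSE`, the default, leakage-free) or run once on the full
#' data before cross-validation (`onepass = TRUE`, the one-pass variant).
#'
#' @param x patients x features matrix.
#' @param labels two-level response (positive class `OR` if present).
#' @param classifier `"LDA"`, `"SVM"` or `"RF"`.
#' @param selection apply [select_features()]? If `FALSE` the matrix is used
#'   as-is.
#' @param onepass run selection once outside the folds (leakage-prone).
#' @param alpha t-screen level.
#' @param seed seed controlling fold-internal randomness.
#' @return Object of class `dynrad_eval`: `scores`, `pred`, `labels`, `auc`,
#'   `accuracy`, `kept` (per-fold kept features or the single pre-CV set).
#' @export
loocv_evaluate <- function(x, labels, classifier = c("LDA", "SVM", "RF"),
                           selection = TRUE, onepass = FALSE,
                           alpha = 0.05, seed = 1L) {
  classifier <- match.arg(classifier)
  labels <- factor(labels)
  n <- nrow(x)
  .assert(n >= 4, "need n >= 4 for leave-one-out")
  .assert(min(table(labels)) >= 2, "both classes need >= 2 patients")
  pos <- if ("OR" %in% levels(labels)) "OR" else levels(labels)[nlevels(labels)]

  kept_log <- vector("list", n)
  if (selection && onepass) {
    sel <- select_features(x, labels, alpha = alpha, seed = seed)
    x <- x[, sel$kept, drop = FALSE]
    kept_log <- list(sel$kept)
    selection <- FALSE
  }
  scores <- numeric(n); preds <- character(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; ytr <- droplevels(labels[-i])
    if (nlevels(ytr) < 2) {
      warning("fold ", i, " has a single class after hold-out; skipped")
      scores[i] <- NA_real_; preds[i] <- NA_character_
      next
    }
    if (selection) {
      sel <- select_features(xtr, ytr, alpha = alpha, seed = seed + i)
      xtr <- xtr[, sel$kept, drop = FALSE]
      kept_log[[i]] <- sel$kept
      xte <- x[i, sel$kept, drop = FALSE]
    } else {
      xte <- x[i, , drop = FALSE]
    }
    fs <- .fit_score(classifier, xtr, ytr, xte, seed = seed + i)
    scores[i] <- fs$score
    preds[i] <- fs$pred
  }
  ok <- !is.na(scores)
  structure(list(scores = scores, pred = preds, labels = labels,
                 auc = roc_auc(scores[ok], labels[ok]),
                 accuracy = mean(preds[ok] == as.character(labels[ok])),
                 kept = kept_log, classifier = classifier,
                 onepass = onepass),
            class = "dynrad_eval")
}

#' @export
print.dynrad_eval <- function(x, ...) {
  cat(sprintf("Leave-one-out %s: AUC = %.3f, accuracy = %.3f (n = %d%s)\n",
              x$classifier, x$auc, x$accuracy, length(x$scores),
              if (isTRUE(x$onepass)) ", one-pass selection" else ""))
  invisible(x)
}

.FEATURE_SET_ORDER <- c("RACR", "RCR", "SD", "DC", "P",
                        "AP", "DP", "PP", "PVP", "Multi_static")

.build_feature_set <- function(cohort, kind, times, degree) {
  phases <- cohort$features
  if (kind %in% names(phases)) return(phases[[kind]])
  if (kind == "Multi_static") {
    m <- do.call(cbind, lapply(names(phases), function(p) {
      b <- phases[[p]]; colnames(b) <- paste0(p, "_", colnames(b)); b
    }))
    return(m)
  }
  build_dynamic_matrix(phases, kinds = kind, times = times, degree = degree)
}

#' Compare feature sets across classifiers by leave-one-out AUC/accuracy
#'
#' Builds each requested feature set (per-phase static, the concatenated
#' `Multi_static` set, or any dynamic kind), removes constant columns, runs
#' [loocv_evaluate()] for every classifier, and returns the AUC and accuracy
#' grids (rows = feature sets, columns = classifiers).
#'
#' @param cohort a `dynrad_cohort` (or list with `features` and `cohort`).
#' @param kinds feature sets to evaluate, from
#'   `c("RACR","RCR","SD","DC","P", <phase names>, "Multi_static")`.
#' @param classifiers classifier subset.
#' @param alpha,onepass,seed passed to [loocv_evaluate()].
#' @param times,degree passed to [build_dynamic_matrix()].
#' @return Object of class `dynrad_grid`: list with matrices `auc` and
#'   `accuracy`, rows ordered RACR, RCR, SD, DC, P, AP, DP, PP, PVP,
#'   Multi_static.
#' @export
compare_feature_sets <- function(cohort,
                                 kinds = .FEATURE_SET_ORDER,
                                 classifiers = c("LDA", "RF", "SVM"),
                                 alpha = 0.05, onepass = FALSE, seed = 1L,
                                 times = NULL, degree = NULL) {
  labels <- factor(cohort$cohort$response, levels = c("NOR", "OR"))
  k <- length(cohort$features)
  times <- times %||% seq_len(k)
  kinds <- kinds[order(match(kinds, .FEATURE_SET_ORDER))]
  auc <- acc <- matrix(NA_real_, length(kinds), length(classifiers),
                       dimnames = list(kinds, classifiers))
  for (kd in kinds) {
    m <- .build_feature_set(cohort, kd, times, degree)
    m <- drop_constant_features(m)
    for (cl in classifiers) {
      ev <- loocv_evaluate(m, labels, classifier = cl, alpha = alpha,
                           onepass = onepass, seed = seed)
      auc[kd, cl] <- ev$auc
      acc[kd, cl] <- ev$accuracy
    }
  }
  structure(list(auc = auc, accuracy = acc), class = "dynrad_grid")
}

#' @export
print.dynrad_grid <- function(x, digits = 3, ...) {
  cat("Leave-one-out AUC:\n")
  print(round(x$auc, digits))
  cat("\nLeave-one-out accuracy:\n")
  print(round(x$accuracy, digits))
  best <- arrayInd(which.max(x$auc), dim(x$auc))
  cat(sprintf("\nBest AUC: %.3f (%s / %s)\n", max(x$auc),
              rownames(x$auc)[best[1]], colnames(x$auc)[best[2]]))
  invisible(x)
}
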