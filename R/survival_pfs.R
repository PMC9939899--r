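#' Univariate Cox screening of features against PFS
#'
#' One Cox proportional-hazards fit per feature (partial likelihood, Efron
#' tie handling); features with Wald `p < alpha` are kept. Constant or
#' non-convergent features are flagged and excluded.
#'
#' @param x patients x features matrix.
#' @param time follow-up time in days.
#' @param event 1 = progression/death, 0 = censored.
#' @param alpha significance level (default 0.05).
#' @return Data frame with `feature`, `beta`, `p`, `kept`, `flag`.
#' @export
cox_univariate_screen <- function(x, time, event, alpha = 0.05) {
  .assert(sum(event) >= 2, "need >= 2 events")
  y <- survival::Surv(time, event)
  res <- lapply(colnames(x), function(f) {
    v <- x[, f]
    if (diff(range(v)) < 1e-12)
      return(data.frame(feature = f, beta = NA_real_, p = NA_real_,
                        kept = FALSE, flag = "constant"))
    fit <- tryCatch(
      suppressWarnings(survival::coxph(y ~ v, ties = "efron",
                                       control = survival::coxph.control(iter.max = 100))),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(coef(fit)))
      return(data.frame(feature = f, beta = NA_real_, p = NA_real_,
                        kept = FALSE, flag = "non-convergent"))
    s <- summary(fit)
    p <- s$coefficients[1, "Pr(>|z|)"]
    data.frame(feature = f, beta = unname(coef(fit)), p = p,
               kept = is.finite(p) && p < alpha, flag = "")
  })
  do.call(rbind, res)
}

#' Random-survival-forest risk score
#'
#' Grows a random survival forest (log-rank splitting) and scores each
#' patient by the ensemble cumulative hazard summed over the event-time grid
#' (the usual random-survival-forest mortality measure; the terminal CHF
#' value alone is insensitive to *when* the hazard accrues). With
#' `loocv = TRUE` (default) each patient's score comes from a forest grown
#' without them; fold CHFs are evaluated on the common full-data event-time
#' grid so out-of-fold scores are comparable.
#'
#' @param x patients x features matrix (the Cox-screened set).
#' @param time,event survival outcome.
#' @param seed RNG seed; scores are deterministic given the seed.
#' @param loocv leave-one-out out-of-fold scores (default) or a single
#'   full-data fit.
#' @param num_trees trees per forest (default 500).
#' @param min_node minimal node size (default 3).
#' @return Numeric risk score per patient (higher = higher hazard).
#' @export
fit_risk_score <- function(x, time, event, seed = 1L, loocv = TRUE,
                           num_trees = 500, min_node = 3) {
  .assert(ncol(x) >= 1, "need >= 1 feature")
  .assert(sum(event) >= 2, "need >= 2 events")
  df <- data.frame(time = time, event = event, x, check.names = TRUE)
  fml <- survival::Surv(time, event) ~ .
  grid <- sort(unique(time[event == 1]))   # common event-time grid
  mortality <- function(fit, newdata) {
    pr <- predict(fit, data = newdata)
    chf <- pr$chf
    if (is.null(dim(chf))) chf <- matrix(chf, nrow = nrow(newdata))
    # evaluate the CHF step function on the common grid, then sum
    idx <- findInterval(grid, pr$unique.death.times)
    chf0 <- cbind(0, chf)
    rowSums(chf0[, idx + 1, drop = FALSE])
  }
  n <- nrow(df)
  if (!loocv) {
    fit <- ranger::ranger(fml, data = df, num.trees = num_trees,
                          mtry = max(1, floor(sqrt(ncol(x)))),
                          min.node.size = min_node, seed = seed,
                          splitrule = "logrank", num.threads = 1)
    return(mortality(fit, df))
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    tr <- df[-i, , drop = FALSE]
    .assert(sum(tr$event) >= 1, "zero events in a training fold")
    fit <- ranger::ranger(fml, data = tr, num.trees = num_trees,
                          mtry = max(1, floor(sqrt(ncol(x)))),
                          min.node.size = min_node, seed = seed + i,
                          splitrule = "logrank", num.threads = 1)
    scores[i] <- mortality(fit, df[i, , drop = FALSE])
  }
  scores
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time,event survival outcome.
#' @return Data frame `(time, n_risk, n_event, surv)`, one row per event time.
#' @export
kaplan_meier <- function(time, event) {
  .assert(length(time) > 0, "empty survival data")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' @param time,event survival outcome.
#' @param group two-level grouping (e.g. high/low risk).
#' @return List with `chi2`, `p` and a `flag` when the statistic is
#'   degenerate (no comparable risk sets -> p = 1).
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  .assert(nlevels(group) == 2 && all(table(group) > 0), "need two nonempty groups")
  .assert(sum(event) >= 1, "need at least one event")
  sd_fit <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ group),
    error = function(e) NULL)
  if (is.null(sd_fit) || !is.finite(sd_fit$chisq))
    return(list(chi2 = 0, p = 1, flag = "degenerate: no comparable risk sets"))
  list(chi2 = unname(sd_fit$chisq),
       p = pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE), flag = "")
}

#' Time-dependent ROC AUC (cumulative cases / dynamic controls)
#'
#' Kaplan-Meier-based estimator of AUC(t) in the Heagerty-Lumley-Pepe sense:
#' cases are subjects with an event by `horizon`, controls those event-free
#' beyond it; sensitivity and specificity are derived from the marginal KM
#' curve and conditional KM curves above each score cutpoint, and the AUC is
#' the trapezoidal area of the resulting ROC. With no censoring this reduces
#' exactly to [roc_auc()] against the event-by-t indicator.
#'
#' @param scores risk scores (higher = higher risk).
#' @param time,event survival outcome.
#' @param horizon evaluation time t (days).
#' @return AUC(t); `NA` with a warning when no cases or no controls exist
#'   at `horizon`.
#' @export
td_roc <- function(scores, time, event, horizon) {
  n <- length(scores)
  .assert(length(time) == n && length(event) == n, "length mismatch")
  if (!any(time <= horizon & event == 1) ||
      !any(time > horizon)) {
    warning("no cases or no controls at horizon ", horizon, "; AUC undefined")
    return(NA_real_)
  }
  km_at <- function(tt, ee, t0) {
    if (length(tt) == 0) return(1)
    km <- kaplan_meier(tt, ee)
    s <- c(1, km$surv)[findInterval(t0, km$time) + 1]
    s
  }
  S_t <- km_at(time, event, horizon)
  cuts <- sort(unique(scores))
  # ROC points from P(X > c) split by the KM survival conditional on X > c
  fp <- tp <- numeric(length(cuts) + 2)
  fp[1] <- 1; tp[1] <- 1
  for (ci in seq_along(cuts)) {
    above <- scores > cuts[ci]
    px <- mean(above)
    Sc <- if (any(above)) km_at(time[above], event[above], horizon) else 1
    tp[ci + 1] <- if (S_t < 1) (1 - Sc) * px / (1 - S_t) else 0
    fp[ci + 1] <- if (S_t > 0) Sc * px / S_t else 0
  }
  fp[length(cuts) + 2] <- 0; tp[length(cuts) + 2] <- 0
  tp <- pmin(pmax(tp, 0), 1); fp <- pmin(pmax(fp, 0), 1)
  # traverse in construction order (cuts ascending -> fp/tp non-increasing);
  # re-sorting would scramble float-level FP ties and bias the area
  -sum(diff(fp) * (head(tp, -1) + tp[-1]) / 2)
}

#' PFS risk-score workflow
#'
#' Composition of the survival stages: univariate Cox screen of the dynamic
#' features, random-survival-forest risk score (leave-one-out by default),
#' median split into high/low risk (scores equal to the median go to the
#' low-risk group), Kaplan-Meier curves per group, log-rank test, and
#' time-dependent ROC AUCs at the requested horizons.
#'
#' @param x patients x dynamic-features matrix (typically the RCR set).
#' @param time,event survival outcome in days.
#' @param horizons AUC(t) horizons (default 90, 180, 270, 360 days).
#' @param alpha Cox screening level.
#' @param seed RNG seed.
#' @param loocv,num_trees passed to [fit_risk_score()].
#' @return Object of class `dynrad_pfs`: `screen` (Cox table), `kept`,
#'   `risk`, `group`, `km` (list high/low), `logrank_chi2`, `logrank_p`,
#'   `tdauc` (named by horizon).
#' @export
pfs_pipeline <- function(x, time, event, horizons = c(90, 180, 270, 360),
                         alpha = 0.05, seed = 1L, loocv = TRUE,
                         num_trees = 500) {
  screen <- cox_univariate_screen(x, time, event, alpha = alpha)
  kept <- screen$feature[screen$kept]
  if (length(kept) == 0) {
    # nothing under alpha: fall back to the single smallest Cox p
    ok <- which(is.finite(screen$p))
    .assert(length(ok) > 0, "Cox screen failed for every feature")
    kept <- screen$feature[ok[which.min(screen$p[ok])]]
  }
  risk <- fit_risk_score(x[, kept, drop = FALSE], time, event, seed = seed,
                         loocv = loocv, num_trees = num_trees)
  med <- median(risk)
  group <- factor(ifelse(risk > med, "high", "low"), levels = c("high", "low"))
  km <- list(high = kaplan_meier(time[group == "high"], event[group == "high"]),
             low = kaplan_meier(time[group == "low"], event[group == "low"]))
  lr <- logrank_test(time, event, group)
  tdauc <- vapply(horizons, function(h) td_roc(risk, time, event, h), numeric(1))
  names(tdauc) <- paste0("t", horizons)
  structure(list(screen = screen, kept = kept, risk = risk, group = group,
                 km = km, logrank_chi2 = lr$chi2, logrank_p = lr$p,
                 tdauc = tdauc),
            class = "dynrad_pfs")
}

#' @export
print.dynrad_pfs <- function(x, ...) {
  cat("PFS risk-score workflow\n")
  cat(sprintf("  Cox screen: %d feature(s) kept\n", length(x$kept)))
  cat(sprintf("  median split: %d high / %d low risk\n",
              sum(x$group == "high"), sum(x$group == "low")))
  cat(sprintf("  log-rank chi2 = %.2f, p = %.3g\n", x$logrank_chi2, x$logrank_p))
  cat("  time-dependent AUC:",
      paste(sprintf("%s = %.3f", names(x$tdauc), x$tdauc), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.dynrad_pfs <- function(x, ...) {
  step_xy <- function(km) {
    list(x = c(0, rep(km$time, each = 2)),
         y = c(1, 1, rep(km$surv, each = 2)[-(2 * nrow(km))]))
  }
  h <- step_xy(x$km$high); l <- step_xy(x$km$low)
  plot(NA, xlim = range(c(h$x, l$x)), ylim = c(0, 1),
       xlab = "days", ylab = "progression-free survival", ...)
  lines(h$x, h$y, col = "firebrick", lwd = 2)
  lines(l$x, l$y, col = "steelblue", lwd = 2)
  legend("topright", c("high risk", "low risk"), lwd = 2,
         col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}
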