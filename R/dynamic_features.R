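#' A static feature observed across ordered acquisition phases
#'
#' @param values numeric, the feature value at each phase.
#' @param times strictly increasing acquisition times (default ordinal 1..k).
#' @return List of class `PhaseSeries` with `values`, `times`, `k`.
#' @export
phase_series <- function(values, times = seq_along(values)) {
  .assert(length(values) >= 2, "need at least 2 phases")
  .assert(length(times) == length(values), "times and values lengths differ")
  .assert(all(diff(times) > 0), "times must be strictly increasing")
  .assert(all(is.finite(values)), "non-finite feature values")
  structure(list(values = as.numeric(values), times = as.numeric(times),
                 k = length(values)), class = "PhaseSeries")
}

.series_values <- function(series) {
  if (inherits(series, "PhaseSeries")) series$values else {
    .assert(is.numeric(series) && length(series) >= 2 && all(is.finite(series)),
            "series must be a PhaseSeries or a finite numeric vector (k >= 2)")
    as.numeric(series)
  }
}

# denominator guard shared by DC/RCR/RACR: near-zero denominators yield 0
.EPS_GUARD <- 1e-12
.guard_div <- function(num, den) {
  out <- ifelse(abs(den) < .EPS_GUARD, 0, num / abs(den))
  attr(out, "guarded") <- abs(den) < .EPS_GUARD & num != 0
  out
}

#' Dynamic feature transforms of a phase series
#'
#' The five transforms converting one static feature observed over `k`
#' ordered phases into dynamic features:
#' \describe{
#'   \item{`sd_feature`}{standard discrete feature, the mean absolute
#'     deviation `(1/k) * sum_i |f_i - fbar|`.}
#'   \item{`dc_feature`}{discrete change, `SD / |fbar|` (scale-free).}
#'   \item{`rcr_features`}{relative change rate `|f_j - f_i| / |f_i|` for
#'     every ordered phase pair `j < i` (`k(k-1)/2` values); by default the
#'     denominator is the later phase `i`, `denominator = "earlier"` uses
#'     `f_j`.}
#'   \item{`racr_features`}{relative average change rate
#'     `|f_j - f_i| / |fbar|` per pair.}
#'   \item{`poly_features`}{ordinary least-squares polynomial fit of the
#'     values on the phase times; the coefficients are the dynamic features.}
#' }
#' `fbar` is the arithmetic mean of the feature values across phases.
#' Denominators are taken in absolute value (radiomics features may be
#' negative) and denominators below `1e-12` in magnitude yield 0 with a
#' `guarded` attribute rather than Inf/NaN.
#'
#' @param series a [phase_series()] or plain numeric vector (k >= 2).
#' @param denominator for `rcr_features`: which phase of the pair divides.
#' @return `sd_feature`, `dc_feature`: a single number. `rcr_features`,
#'   `racr_features`: named vector over phase pairs (`RCR_1to2`, ...).
#'   `poly_features`: list of class `PolyFit` with `coefficients` (named
#'   `a0..ad`), `degree`, `rss`, `fitted`.
#' @export
sd_feature <- function(series) {
  f <- .series_values(series)
  mean(abs(f - mean(f)))
}

#' @rdname sd_feature
#' @export
dc_feature <- function(series) {
  f <- .series_values(series)
  as.numeric(.guard_div(sd_feature(f), mean(f)))
}

.pairs <- function(k) {
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]  # (j, i), j < i
}

#' @rdname sd_feature
#' @export
rcr_features <- function(series, denominator = c("later", "earlier")) {
  denominator <- match.arg(denominator)
  f <- .series_values(series)
  pr <- .pairs(length(f))
  den <- if (denominator == "later") f[pr[, 2]] else f[pr[, 1]]
  out <- .guard_div(abs(f[pr[, 1]] - f[pr[, 2]]), den)
  setNames(as.numeric(out), sprintf("RCR_%dto%d", pr[, 1], pr[, 2]))
}

#' @rdname sd_feature
#' @export
racr_features <- function(series) {
  f <- .series_values(series)
  pr <- .pairs(length(f))
  out <- .guard_div(abs(f[pr[, 1]] - f[pr[, 2]]), rep(mean(f), nrow(pr)))
  setNames(as.numeric(out), sprintf("RACR_%dto%d", pr[, 1], pr[, 2]))
}

#' @param degree polynomial degree `d`, `1 <= d <= k - 1`.
#' @rdname sd_feature
#' @export
poly_features <- function(series, degree = NULL) {
  if (inherits(series, "PhaseSeries")) {
    f <- series$values; t <- series$times
  } else {
    f <- .series_values(series); t <- seq_along(f)
  }
  k <- length(f)
  degree <- degree %||% (k - 1L)
  .assert(degree >= 1 && degree <= k - 1, "degree must be in [1, k-1]")
  .assert(!anyDuplicated(t), "repeated times: singular polynomial design")
  X <- outer(t, 0:degree, `^`)
  cf <- solve(crossprod(X), crossprod(X, f))
  fit <- as.numeric(X %*% cf)
  structure(list(coefficients = setNames(as.numeric(cf), paste0("a", 0:degree)),
                 degree = degree, rss = sum((f - fit)^2), fitted = fit),
            class = "PolyFit")
}

#' Build the dynamic feature matrix from per-phase static features
#'
#' Applies the requested transforms feature-wise to every patient's phase
#' series. Column names are deterministic: `<base>__SD`, `<base>__DC`,
#' `<base>__RCR_<j>to<i>`, `<base>__RACR_<j>to<i>`, `<base>__P_a<m>`.
#' Per base feature this yields 1 (SD), 1 (DC), `k(k-1)/2` (RCR and RACR)
#' and `degree + 1` (P) columns. Cells whose denominator fell under the
#' 1e-12 guard are flagged (not dropped) in the `guarded` attribute.
#'
#' @param phases named list of patients x features matrices, one per phase,
#'   in acquisition order; identical dimnames required.
#' @param kinds subset of `c("SD", "DC", "RCR", "RACR", "P")`.
#' @param times phase times (length `k`, strictly increasing); only the P
#'   transform uses them.
#' @param degree polynomial degree for P (default `k - 1`).
#' @param rcr_denominator `"later"` (as the change-rate definition divides by
#'   the later phase) or `"earlier"`.
#' @return Patients x dynamic-features matrix with attributes `provenance`
#'   (data frame: column, base, kind, detail) and `guarded` (logical matrix).
#' @export
build_dynamic_matrix <- function(phases, kinds = c("SD", "DC", "RCR", "RACR", "P"),
                                 times = seq_along(phases), degree = NULL,
                                 rcr_denominator = c("later", "earlier")) {
  rcr_denominator <- match.arg(rcr_denominator)
  kinds <- match.arg(kinds, c("SD", "DC", "RCR", "RACR", "P"), several.ok = TRUE)
  .assert(is.list(phases) && length(phases) >= 2, "need >= 2 phase matrices")
  k <- length(phases)
  .assert(length(times) == k && all(diff(times) > 0),
          "times must be strictly increasing, one per phase")
  dims <- dim(phases[[1]])
  pats <- rownames(phases[[1]]); feats <- colnames(phases[[1]])
  for (ph in seq_along(phases)) {
    m <- phases[[ph]]
    .assert(is.matrix(m) && identical(dim(m), dims),
            "phase matrices differ in shape")
    .assert(identical(rownames(m), pats) && identical(colnames(m), feats),
            "phase matrices differ in patient/feature names")
    bad <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("patient %s missing/non-finite value for feature %s in phase %s",
                   pats[bad[1, 1]] %||% bad[1, 1], feats[bad[1, 2]] %||% bad[1, 2],
                   names(phases)[ph] %||% ph), call. = FALSE)
  }
  n <- dims[1]; p <- dims[2]
  if (is.null(feats)) feats <- sprintf("feat%03d", seq_len(p))
  fbar <- Reduce(`+`, phases) / k
  guard <- function(den) abs(den) < .EPS_GUARD

  blocks <- list(); provs <- list(); gflags <- list()
  add <- function(block, base, kind, detail, gf) {
    i <- length(blocks) + 1L
    blocks[[i]] <<- block
    provs[[i]] <<- data.frame(column = colnames(block), base = base,
                              kind = kind, detail = detail,
                              stringsAsFactors = FALSE)
    gflags[[i]] <<- gf
  }

  if ("SD" %in% kinds || "DC" %in% kinds) {
    sdm <- Reduce(`+`, lapply(phases, function(m) abs(m - fbar))) / k
  }
  if ("SD" %in% kinds) {
    b <- sdm; colnames(b) <- paste0(feats, "__SD")
    add(b, feats, "SD", "", matrix(FALSE, n, p))
  }
  if ("DC" %in% kinds) {
    g <- guard(fbar)
    b <- ifelse(g, 0, sdm / abs(fbar)); colnames(b) <- paste0(feats, "__DC")
    add(b, feats, "DC", "abs-denominator", g & sdm != 0)
  }
  if (any(c("RCR", "RACR") %in% kinds)) {
    pr <- .pairs(k)
    for (r in seq_len(nrow(pr))) {
      j <- pr[r, 1]; i <- pr[r, 2]
      num <- abs(phases[[j]] - phases[[i]])
      if ("RCR" %in% kinds) {
        den <- if (rcr_denominator == "later") phases[[i]] else phases[[j]]
        g <- guard(den)
        b <- ifelse(g, 0, num / abs(den))
        colnames(b) <- sprintf("%s__RCR_%dto%d", feats, j, i)
        add(b, feats, "RCR", sprintf("pair %d,%d (den: %s)", j, i, rcr_denominator),
            g & num != 0)
      }
      if ("RACR" %in% kinds) {
        g <- guard(fbar)
        b <- ifelse(g, 0, num / abs(fbar))
        colnames(b) <- sprintf("%s__RACR_%dto%d", feats, j, i)
        add(b, feats, "RACR", sprintf("pair %d,%d", j, i), g & num != 0)
      }
    }
  }
  if ("P" %in% kinds) {
    d <- degree %||% (k - 1L)
    .assert(d >= 1 && d <= k - 1, "degree must be in [1, k-1]")
    X <- outer(as.numeric(times), 0:d, `^`)
    A <- solve(crossprod(X), t(X))           # (d+1) x k projector
    # stack phases as k x (n*p) and project once
    Y <- do.call(rbind, lapply(phases, as.vector))
    C <- A %*% Y                              # (d+1) x (n*p)
    for (m in 0:d) {
      b <- matrix(C[m + 1, ], n, p)
      colnames(b) <- sprintf("%s__P_a%d", feats, m)
      add(b, feats, "P", sprintf("coefficient a%d (degree %d)", m, d),
          matrix(FALSE, n, p))
    }
  }

  out <- do.call(cbind, blocks)
  rownames(out) <- pats
  prov <- do.call(rbind, provs)
  gf <- do.call(cbind, gflags)
  # order columns per base feature, preserving kind order within
  ord <- order(match(prov$base, feats))
  out <- out[, ord, drop = FALSE]
  attr(out, "provenance") <- prov[ord, , drop = FALSE]
  g2 <- gf[, ord, drop = FALSE]; colnames(g2) <- colnames(out)
  attr(out, "guarded") <- g2
  out
}
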