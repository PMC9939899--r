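# Independent oracles used across the suite. These are deliberately naive,
# direct-translation implementations kept separate from the package code.

# dynamic transforms, written directly from their definitions
oracle_sd <- function(f) {
  k <- length(f); fb <- mean(f)
  s <- 0
  for (i in seq_len(k)) s <- s + abs(f[i] - fb)
  s / k
}
oracle_dc <- function(f) oracle_sd(f) / abs(mean(f))
oracle_rcr <- function(f) {
  k <- length(f); out <- c()
  for (j in seq_len(k - 1)) for (i in (j + 1):k)
    out <- c(out, abs(f[j] - f[i]) / abs(f[i]))
  out
}
oracle_racr <- function(f) {
  k <- length(f); out <- c()
  for (j in seq_len(k - 1)) for (i in (j + 1):k)
    out <- c(out, abs(f[j] - f[i]) / abs(mean(f)))
  out
}
oracle_poly <- function(f, t, d) unname(coef(lm(f ~ poly(t, d, raw = TRUE))))

# AUC by brute-force pair counting
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  wins <- 0
  for (a in sp) for (b in sn) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(sp) * length(sn))
}

# GLCM co-occurrence counting by explicit triple loop over voxels
oracle_glcm_counts <- function(lev, mask, off, ng) {
  d <- dim(lev)
  P <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
    if (x2 >= 1 && x2 <= d[1] && y2 >= 1 && y2 <= d[2] && z2 >= 1 && z2 <= d[3] &&
        mask[x, y, z] && mask[x2, y2, z2]) {
      P[lev[x, y, z], lev[x2, y2, z2]] <- P[lev[x, y, z], lev[x2, y2, z2]] + 1
      P[lev[x2, y2, z2], lev[x, y, z]] <- P[lev[x2, y2, z2], lev[x, y, z]] + 1
    }
  }
  P
}

# contrast straight from the definition sum_{i,j} (i-j)^2 p(i,j)
oracle_glcm_contrast <- function(P) {
  p <- P / sum(P)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    s <- s + (i - j)^2 * p[i, j]
  s
}

# Kaplan-Meier product-limit by hand
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1; out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# small helper: a quick synthetic cohort for tests
quick_cohort <- function(n = 40, p = 20, effect = 1, seed = 1, ...) {
  simulate_feature_cohort(sim_config(n_patients = n, n_features = p,
                                     n_informative = min(10, p),
                                     effect_size = effect, seed = seed, ...))
}
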