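test_that("transforms reproduce hand-computed values", {
  expect_equal(sd_feature(c(1, 2, 3, 4)), 1.0)          # fbar 2.5, mean |dev| = 1
  expect_equal(dc_feature(c(1, 2, 3, 4)), 0.4)          # 1.0 / 2.5
  expect_equal(unname(rcr_features(c(2, 4))["RCR_1to2"]), 0.5)    # |2-4|/4
  expect_equal(unname(racr_features(c(2, 4))["RACR_1to2"]), 2 / 3) # |2-4|/3
  pf <- poly_features(phase_series(c(1, 2, 3, 4), 1:4), degree = 1)
  expect_equal(unname(pf$coefficients), c(0, 1), tolerance = 1e-12)
  expect_equal(pf$rss, 0, tolerance = 1e-12)
})

test_that("constant series map to exactly zero (P: zero slope coefficients)", {
  cs <- rep(3.7, 4)
  expect_identical(sd_feature(cs), 0)
  expect_identical(dc_feature(cs), 0)
  expect_true(all(rcr_features(cs) == 0))
  expect_true(all(racr_features(cs) == 0))
  pf <- poly_features(cs, degree = 1)
  expect_equal(unname(pf$coefficients), c(3.7, 0), tolerance = 1e-12)
})

test_that("transforms agree with direct-translation oracles on random series", {
  set.seed(42)
  for (r in 1:100) {
    k <- sample(2:6, 1)
    f <- rnorm(k, sd = 10) + 5   # keeps |fbar| and |f_i| away from the guard
    f[abs(f) < 0.1] <- 0.5
    expect_equal(sd_feature(f), oracle_sd(f), tolerance = 1e-12)
    expect_equal(dc_feature(f), oracle_dc(f), tolerance = 1e-12)
    expect_equal(unname(rcr_features(f)), oracle_rcr(f), tolerance = 1e-12)
    expect_equal(unname(racr_features(f)), oracle_racr(f), tolerance = 1e-12)
    d <- sample(seq_len(k - 1), 1)
    expect_equal(unname(poly_features(f, degree = d)$coefficients),
                 oracle_poly(f, seq_len(k), d), tolerance = 1e-8)
  }
})

test_that("SD/RCR/RACR are sign-flip invariant; RCR/RACR scale invariant", {
  set.seed(7)
  for (r in 1:20) {
    f <- abs(rnorm(4, 5, 2)) + 0.5
    expect_equal(sd_feature(-f), sd_feature(f))
    expect_equal(rcr_features(-f), rcr_features(f))
    expect_equal(racr_features(-f), racr_features(f))
    c0 <- runif(1, 0.1, 100)
    expect_equal(rcr_features(c0 * f), rcr_features(f), tolerance = 1e-12)
    expect_equal(racr_features(c0 * f), racr_features(f), tolerance = 1e-12)
  }
})

test_that("RACR equals RCR numerator over |mean| (shared-numerator identity)", {
  f <- c(3, 8, 5, 2)
  pr <- cbind(c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4))
  num <- abs(f[pr[, 1]] - f[pr[, 2]])
  expect_equal(unname(racr_features(f)), num / abs(mean(f)))
})

test_that("near-zero denominators are guarded to 0, not Inf/NaN", {
  f <- c(1, 0, 2, 3)          # later-phase denominator 0 for pair (1,2)
  r <- rcr_features(f)
  expect_identical(unname(r["RCR_1to2"]), 0)
  expect_true(all(is.finite(r)))
  f2 <- c(-1, 1, -1, 1)       # fbar = 0
  expect_identical(dc_feature(f2), 0)
  expect_true(all(is.finite(racr_features(f2))))
})

test_that("rcr_denominator switch divides by the earlier phase", {
  f <- c(2, 4)
  expect_equal(unname(rcr_features(f, denominator = "earlier")), 1)  # |2-4|/2
})

test_that("poly fit saturates at degree k-1 and rejects repeated times", {
  f <- c(2, 9, 4, 7)
  expect_equal(poly_features(f, degree = 3)$rss, 0, tolerance = 1e-8)
  expect_error(poly_features(phase_series(c(1, 2), c(1, 2)), degree = 2), "degree")
  expect_error(phase_series(c(1, 2, 3), c(1, 1, 2)), "increasing")
})

test_that("build_dynamic_matrix emits the documented column structure", {
  cc <- quick_cohort(n = 12, p = 5, seed = 3)
  m <- build_dynamic_matrix(cc$features, kinds = c("SD", "DC", "RCR", "RACR", "P"))
  # per base feature: 1 + 1 + 6 + 6 + 4 = 18 columns for k = 4
  expect_equal(ncol(m), 5 * 18)
  expect_true(all(c("feat001__SD", "feat001__DC", "feat001__RCR_1to2",
                    "feat001__RCR_3to4", "feat001__RACR_2to3", "feat001__P_a0",
                    "feat001__P_a3") %in% colnames(m)))
  prov <- attr(m, "provenance")
  expect_equal(nrow(prov), ncol(m))
  expect_setequal(unique(prov$kind), c("SD", "DC", "RCR", "RACR", "P"))
  m2 <- build_dynamic_matrix(cc$features, kinds = c("SD", "DC"))
  expect_equal(ncol(m2), 10)
})

test_that("dynamic matrix matches per-series transforms cell by cell", {
  cc <- quick_cohort(n = 8, p = 4, seed = 9)
  m <- build_dynamic_matrix(cc$features, kinds = c("SD", "DC", "RCR", "RACR", "P"))
  for (i in c(1, 5)) for (f in c("feat001", "feat004")) {
    series <- vapply(cc$features, function(ph) ph[i, f], numeric(1))
    expect_equal(unname(m[i, paste0(f, "__SD")]), sd_feature(series), tolerance = 1e-12)
    expect_equal(unname(m[i, paste0(f, "__DC")]), dc_feature(series), tolerance = 1e-12)
    expect_equal(unname(m[i, paste0(f, "__RCR_2to4")]),
                 unname(rcr_features(series)["RCR_2to4"]), tolerance = 1e-12)
    expect_equal(unname(m[i, paste0(f, "__RACR_1to3")]),
                 unname(racr_features(series)["RACR_1to3"]), tolerance = 1e-12)
    expect_equal(unname(m[i, paste0(f, "__P_a2")]),
                 unname(poly_features(series)$coefficients["a2"]), tolerance = 1e-10)
  }
})

test_that("row order is equivariant and missing phases are reported by name", {
  cc <- quick_cohort(n = 10, p = 4, seed = 2)
  m <- build_dynamic_matrix(cc$features, kinds = "RCR")
  perm <- sample(nrow(m))
  feats_p <- lapply(cc$features, function(ph) ph[perm, , drop = FALSE])
  m2 <- build_dynamic_matrix(feats_p, kinds = "RCR")
  expect_equal(m2, m[perm, ], ignore_attr = TRUE)

  feats_bad <- cc$features
  feats_bad$AP[3, 2] <- NA
  expect_error(build_dynamic_matrix(feats_bad, kinds = "SD"), "pt003.*feat002.*AP")
})
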