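#' Extraction settings for static radiomics features
#'
#' @param bin_width grey-level discretization bin width (HU after
#'   normalization), default 25.
#' @param resample_spacing target isotropic voxel spacing in mm, default
#'   `c(1, 1, 1)`; `NULL` disables resampling.
#' @param normalize z-normalize intensities over the whole volume before
#'   intensity features (default `TRUE`).
#' @param normalize_scale multiplier applied after z-normalization (default 100).
#' @param voxel_array_shift constant added after normalization so intensity
#'   features operate on positive values (default 1000).
#' @return A list of class `ExtractionSettings`.
#' @export
extraction_settings <- function(bin_width = 25, resample_spacing = c(1, 1, 1),
                                normalize = TRUE, normalize_scale = 100,
                                voxel_array_shift = 1000) {
  .assert(bin_width > 0, "bin_width must be positive")
  if (!is.null(resample_spacing))
    .assert(all(resample_spacing > 0), "resample_spacing must be positive")
  structure(list(bin_width = bin_width, resample_spacing = resample_spacing,
                 normalize = normalize, normalize_scale = normalize_scale,
                 voxel_array_shift = voxel_array_shift),
            class = "ExtractionSettings")
}

# trilinear resampling of a 3-D array to a new spacing
.resample_trilinear <- function(a, spacing, new_spacing) {
  d <- dim(a)
  nd <- pmax(2L, as.integer(round(d * spacing / new_spacing)))
  # sample at centres of the new grid expressed in old voxel coordinates
  coords <- lapply(1:3, function(ax) {
    ((seq_len(nd[ax]) - 0.5) * new_spacing[ax]) / spacing[ax] + 0.5
  })
  g <- lapply(1:3, function(ax) pmin(pmax(coords[[ax]], 1), d[ax]))
  i0 <- lapply(1:3, function(ax) pmin(floor(g[[ax]]), d[ax] - 1L))
  fr <- lapply(1:3, function(ax) g[[ax]] - i0[[ax]])
  out <- array(0, dim = nd)
  # accumulate the 8 corner contributions with outer-product weights
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - fr[[1]] else fr[[1]]
    wy <- if (dy == 0) 1 - fr[[2]] else fr[[2]]
    wz <- if (dz == 0) 1 - fr[[3]] else fr[[3]]
    sub <- a[i0[[1]] + dx, i0[[2]] + dy, i0[[3]] + dz, drop = FALSE]
    w <- outer(outer(wx, wy), wz)
    out <- out + sub * array(w, dim = nd)
  }
  out
}

.resample_nearest <- function(a, spacing, new_spacing) {
  d <- dim(a)
  nd <- pmax(2L, as.integer(round(d * spacing / new_spacing)))
  coords <- lapply(1:3, function(ax) {
    ix <- round(((seq_len(nd[ax]) - 0.5) * new_spacing[ax]) / spacing[ax] + 0.5)
    pmin(pmax(ix, 1L), d[ax])
  })
  a[coords[[1]], coords[[2]], coords[[3]], drop = FALSE]
}

#' Preprocess an image volume and ROI mask for feature extraction
#'
#' Applies whole-volume z-normalization (then `normalize_scale` and
#' `voxel_array_shift`) and resamples both image (trilinear) and mask
#' (nearest neighbour, re-binarized) to the target spacing.
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()] on the same grid.
#' @param settings an [extraction_settings()].
#' @return List with preprocessed `volume` and `mask`.
#' @export
preprocess <- function(volume, mask, settings = extraction_settings()) {
  .assert(identical(dim(volume$voxels), dim(mask$voxels)),
          "mask and volume shapes differ")
  .assert(sum(mask$voxels) >= 1, "mask is empty")
  v <- volume$voxels
  if (isTRUE(settings$normalize)) {
    s <- sd(as.vector(v))
    .assert(s > 0, "zero image variance: cannot z-normalize")
    v <- (v - mean(v)) / s * settings$normalize_scale + settings$voxel_array_shift
  }
  sp <- volume$spacing
  m <- mask$voxels
  if (!is.null(settings$resample_spacing) &&
      !isTRUE(all.equal(sp, as.numeric(settings$resample_spacing)))) {
    v <- .resample_trilinear(v, sp, settings$resample_spacing)
    m <- .resample_nearest(m + 0, sp, settings$resample_spacing) >= 0.5
    sp <- as.numeric(settings$resample_spacing)
  }
  .assert(sum(m) >= 1, "mask empty after resampling")
  list(volume = image_volume(v, spacing = sp, origin = volume$origin,
                             phase = volume$phase),
       mask = structure(list(voxels = array(m, dim = dim(v)), spacing = sp,
                             origin = volume$origin), class = "RoiMask"))
}

#' Fixed-bin-width grey-level discretization
#'
#' `level(v) = floor((v - min) / bin_width) + 1`, anchored at the ROI minimum
#' (the fixed-bin-size convention). A constant ROI maps to a single level.
#'
#' @param x numeric vector of ROI intensities.
#' @param bin_width bin width.
#' @return Integer grey levels starting at 1.
#' @export
discretize <- function(x, bin_width = 25) {
  .assert(length(x) > 0 && all(is.finite(x)), "need nonempty finite intensities")
  as.integer(floor((x - min(x)) / bin_width)) + 1L
}

# ---- first-order -----------------------------------------------------------

.firstorder <- function(x, bin_width, shift_applied = TRUE) {
  n <- length(x)
  m <- mean(x)
  lev <- discretize(x, bin_width)
  pr <- tabulate(lev) / n
  pr <- pr[pr > 0]
  qs <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  inb <- x[x >= qs[1] & x <= qs[4]]
  c(firstorder_Mean = m,
    firstorder_Median = median(x),
    firstorder_Minimum = min(x),
    firstorder_Maximum = max(x),
    firstorder_Range = max(x) - min(x),
    firstorder_Variance = mean((x - m)^2),
    firstorder_Skewness = if (mean((x - m)^2) == 0) 0 else
      mean((x - m)^3) / mean((x - m)^2)^1.5,
    firstorder_Kurtosis = if (mean((x - m)^2) == 0) 0 else
      mean((x - m)^4) / mean((x - m)^2)^2,
    firstorder_Energy = sum(x^2),
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_Entropy = -sum(pr * log2(pr)),
    firstorder_Uniformity = sum(pr^2),
    firstorder_MeanAbsoluteDeviation = mean(abs(x - m)),
    firstorder_RobustMeanAbsoluteDeviation =
      if (length(inb)) mean(abs(inb - mean(inb))) else 0,
    firstorder_10Percentile = qs[1],
    firstorder_90Percentile = qs[4],
    firstorder_InterquartileRange = qs[3] - qs[2])
}

# ---- shape -----------------------------------------------------------------

.shape_features <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  nv <- nrow(idx)
  voxvol <- prod(spacing)
  out <- c(shape_VoxelVolume = nv * voxvol)
  # exposed-face surface area approximation
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  faces <- 0
  ax_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3], spacing[1] * spacing[2])
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
  for (s in seq_along(shifts)) {
    sh <- shifts[[s]]
    nb <- pad[2:(d[1] + 1) + sh[1], 2:(d[2] + 1) + sh[2], 2:(d[3] + 1) + sh[3], drop = FALSE]
    faces <- faces + sum(core & !nb) * ax_area[ceiling(s / 2)]
  }
  out["shape_SurfaceArea"] <- faces
  vol <- nv * voxvol
  out["shape_Sphericity"] <- (36 * pi * vol^2)^(1 / 3) / faces
  if (nv < 2) {
    out[c("shape_Elongation", "shape_Flatness", "shape_Maximum3DDiameter")] <- NA_real_
    attr(out, "flag") <- "single-voxel ROI: shape anisotropy undefined"
    return(out)
  }
  phys <- sweep(idx, 2, spacing, `*`)
  cv <- cov(phys) * (nv - 1) / nv
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  ev[ev < 0] <- 0
  out["shape_Elongation"] <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_
  out["shape_Flatness"] <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_
  # max 3-D diameter on surface voxels only
  surf <- core & !(
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1), drop = FALSE] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1), drop = FALSE] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3], drop = FALSE] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2), drop = FALSE])
  sidx <- which(array(surf, d), arr.ind = TRUE)
  sphys <- sweep(sidx, 2, spacing, `*`)
  if (nrow(sphys) > 2000) sphys <- sphys[sample.int(nrow(sphys), 2000), ]
  out["shape_Maximum3DDiameter"] <- sqrt(max(as.matrix(dist(sphys))^2))
  out
}

# ---- GLCM ------------------------------------------------------------------

# the 13 unique 3-D direction offsets (half of the 26-neighbourhood)
.glcm_offsets <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  keep <- offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
    (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)
  as.matrix(offs[keep, ])
}

# co-occurrence counts of in-mask voxel pairs at a single offset (symmetric)
.glcm_count <- function(lev, mask, off, ng) {
  d <- dim(mask)
  sl <- function(ax, lo) {
    r <- seq_len(d[ax] - abs(off[ax]))
    if (off[ax] >= 0 && lo) r else if (off[ax] >= 0) r + off[ax] else
      if (lo) r - off[ax] else r
  }
  a1 <- lev[sl(1, TRUE), sl(2, TRUE), sl(3, TRUE), drop = FALSE]
  a2 <- lev[sl(1, FALSE), sl(2, FALSE), sl(3, FALSE), drop = FALSE]
  m1 <- mask[sl(1, TRUE), sl(2, TRUE), sl(3, TRUE), drop = FALSE]
  m2 <- mask[sl(1, FALSE), sl(2, FALSE), sl(3, FALSE), drop = FALSE]
  ok <- m1 & m2
  if (!any(ok)) return(matrix(0, ng, ng))
  tab <- table(factor(a1[ok], levels = seq_len(ng)),
               factor(a2[ok], levels = seq_len(ng)))
  m <- matrix(as.numeric(tab), ng, ng)
  m + t(m)  # symmetric accumulation
}

.glcm_stats <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  if (tot == 0) return(NULL)
  p <- P / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mx <- sum(seq_len(ng) * px); my <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mx)^2 * px)); sy <- sqrt(sum((seq_len(ng) - my)^2 * py))
  eps <- 2.2e-16
  # difference distribution
  kdiff <- 0:(ng - 1)
  pdiff <- vapply(kdiff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  HY <- -sum(py[py > 0] * log2(py[py > 0]))
  HXY <- -sum(p[p > 0] * log2(p[p > 0]))
  pxy <- outer(px, py)
  HXY1 <- -sum(p * log2(pxy + eps))
  HXY2 <- -sum(pxy * log2(pxy + eps))
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- if (HXY2 >= HXY) sqrt(1 - 2^(-2 * (HXY2 - HXY))) else 0
  # MCC: sqrt of the second-largest eigenvalue of
  # Q(i,j) = sum_k p(i,k) p(j,k) / (p_x(i) p_y(k))
  if (ng > 1) {
    Q <- sweep(p, 2, py + eps, `/`) %*% t(p)
    Q <- sweep(Q, 1, px + eps, `/`)
    evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(evq[2], 0))
  } else mcc <- 1
  corr <- if (sx > 0 && sy > 0) sum((i - mx) * (j - my) * p) / (sx * sy) else 1
  c(glcm_Contrast = sum((i - j)^2 * p),
    glcm_Correlation = corr,
    glcm_JointEntropy = HXY,
    glcm_DifferenceEntropy = -sum(pdiff[pdiff > 0] * log2(pdiff[pdiff > 0])),
    glcm_Idn = sum(pdiff / (1 + kdiff / ng)),
    glcm_Idmn = sum(pdiff / (1 + (kdiff / ng)^2)),
    glcm_Imc1 = imc1,
    glcm_Imc2 = imc2,
    glcm_MCC = mcc,
    glcm_ClusterShade = sum((i + j - mx - my)^3 * p),
    glcm_ClusterProminence = sum((i + j - mx - my)^4 * p))
}

glcm_features <- function(lev_arr, mask, n_levels = max(lev_arr[mask])) {
  if (sum(mask) < 2) {
    nm <- c("glcm_Contrast", "glcm_Correlation", "glcm_JointEntropy",
            "glcm_DifferenceEntropy", "glcm_Idn", "glcm_Idmn", "glcm_Imc1",
            "glcm_Imc2", "glcm_MCC", "glcm_ClusterShade", "glcm_ClusterProminence")
    out <- setNames(rep(NA_real_, length(nm)), nm)
    attr(out, "flag") <- "fewer than 2 ROI voxels: GLCM undefined"
    return(out)
  }
  offs <- .glcm_offsets()
  acc <- NULL
  nd <- 0
  for (r in seq_len(nrow(offs))) {
    P <- .glcm_count(lev_arr, mask, offs[r, ], n_levels)
    st <- .glcm_stats(P)
    if (is.null(st)) next
    acc <- if (is.null(acc)) st else acc + st
    nd <- nd + 1
  }
  if (nd == 0) {
    nm <- c("glcm_Contrast", "glcm_Correlation", "glcm_JointEntropy",
            "glcm_DifferenceEntropy", "glcm_Idn", "glcm_Idmn", "glcm_Imc1",
            "glcm_Imc2", "glcm_MCC", "glcm_ClusterShade", "glcm_ClusterProminence")
    out <- setNames(rep(NA_real_, length(nm)), nm)
    attr(out, "flag") <- "no co-occurring in-mask voxel pairs: GLCM undefined"
    return(out)
  }
  acc / nd  # direction-averaged
}

#' Extract static radiomics features from one phase
#'
#' Computes the in-house feature families: first-order intensity statistics,
#' shape descriptors of the mask, and direction-averaged grey-level
#' co-occurrence (GLCM) texture features over the 13 unique 3-D directions
#' at distance 1 with symmetric accumulation. Inputs are preprocessed with
#' [preprocess()] unless `preprocessed = TRUE`.
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()].
#' @param settings an [extraction_settings()].
#' @param preprocessed set `TRUE` if `preprocess()` has already been applied.
#' @return Named numeric vector (class `StaticFeatureVector`) with family
#'   prefixes `firstorder_`, `shape_`, `glcm_`; undefined features are `NaN`
#'   with a `flags` attribute giving the reason.
#' @export
extract_static_features <- function(volume, mask,
                                    settings = extraction_settings(),
                                    preprocessed = FALSE) {
  if (!preprocessed) {
    pp <- preprocess(volume, mask, settings)
    volume <- pp$volume; mask <- pp$mask
  }
  mvox <- mask$voxels
  x <- volume$voxels[mvox]
  flags <- character()
  fo <- .firstorder(x, settings$bin_width)
  sh <- .shape_features(mvox, mask$spacing)
  if (!is.null(attr(sh, "flag"))) flags <- c(flags, attr(sh, "flag"))
  lev <- array(1L, dim = dim(mvox))
  lev[mvox] <- discretize(x, settings$bin_width)
  if (sum(mvox) < 2) {
    gl <- glcm_features(lev, mvox & FALSE)  # forces the undefined path
  } else {
    gl <- glcm_features(lev, mvox, n_levels = max(lev[mvox]))
  }
  if (!is.null(attr(gl, "flag"))) flags <- c(flags, attr(gl, "flag"))
  out <- c(fo, sh[names(sh)], gl[names(gl)])
  attr(out, "flags") <- flags
  class(out) <- c("StaticFeatureVector", class(out))
  out
}

#' Drop features constant across patients
#'
#' Removes columns whose range across patients is below `tol` (features with
#' the same value in all patients carry no information).
#'
#' @param x patients x features numeric matrix.
#' @param tol range tolerance (default 1e-12).
#' @param quiet suppress the removal message.
#' @return The matrix without constant columns; attribute `n_removed` gives
#'   the count.
#' @export
drop_constant_features <- function(x, tol = 1e-12, quiet = TRUE) {
  .assert(is.matrix(x) && nrow(x) >= 2, "need a matrix with >= 2 patients")
  rng <- apply(x, 2, function(col) diff(range(col)))
  keep <- rng > tol & is.finite(rng)
  .assert(any(keep), "no informative features: all columns constant")
  if (!quiet) message(sum(!keep), " constant feature(s) removed")
  out <- x[, keep, drop = FALSE]
  prov <- attr(x, "provenance")
  if (!is.null(prov)) attr(out, "provenance") <- prov[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}
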