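GLCM_NAMES <- c("autocorrelation", "cluster_prominence", "cluster_shade",
                "cluster_tendency", "contrast", "correlation",
                "difference_average", "difference_entropy",
                "difference_variance", "dissimilarity", "joint_energy",
                "joint_entropy", "imc1", "imc2", "inverse_difference",
                "inverse_difference_norm", "inverse_difference_moment",
                "inverse_difference_moment_norm", "inverse_variance",
                "joint_average", "max_probability", "sum_entropy")

GLRLM_NAMES <- c("short_run_emphasis", "long_run_emphasis",
                 "gl_nonuniformity", "run_length_nonuniformity",
                 "run_percentage", "low_gl_run_emphasis",
                 "high_gl_run_emphasis", "short_run_low_gl_emphasis",
                 "short_run_high_gl_emphasis", "long_run_low_gl_emphasis",
                 "long_run_high_gl_emphasis")

GLSZM_NAMES <- c("small_area_emphasis", "large_area_emphasis",
                 "gl_nonuniformity", "size_zone_nonuniformity",
                 "zone_percentage", "low_gl_zone_emphasis",
                 "high_gl_zone_emphasis", "small_area_low_gl_emphasis",
                 "small_area_high_gl_emphasis", "large_area_low_gl_emphasis",
                 "large_area_high_gl_emphasis")

NGTDM_NAMES <- c("coarseness", "contrast", "busyness", "complexity",
                 "strength")

NGLDM_NAMES <- c("low_dependence_emphasis", "high_dependence_emphasis",
                 "gl_nonuniformity", "dependence_nonuniformity",
                 "dependence_entropy")

# Guard for degenerate denominators; coarseness on a flat region returns
# 1/TEXTURE_EPS, the documented cap.
TEXTURE_EPS <- 1e-6

#' Compute the five texture matrices of a discretized region
#'
#' Conventions: GLCM at distance 1 over the 13 unique 3D directions,
#' symmetric, each direction normalized to sum 1 then averaged; GLRLM run
#' counts averaged over the same 13 directions; GLSZM zones are
#' 26-connected; NGTDM and NGLDM use the 26-neighbourhood and count only
#' in-region neighbours (NGLDM dependence at grey-level tolerance 0).
#'
#' @param levels 3D integer array: 0 outside the region, `1..nlevels` inside
#'   (a region embedded in its bounding box, as built by [region_levels()]).
#' @param nlevels number of grey levels.
#' @return list of class `apv_texture_matrices` with elements `glcm`,
#'   `glrlm`, `glszm`, `ngtdm` (columns `n_i`, `s_i`), `ngldm`, `nlevels`,
#'   `nvox`.
#' @export
texture_matrices <- function(levels, nlevels = max(levels)) {
  storage.mode(levels) <- "integer"
  nvox <- sum(levels > 0L)
  if (nvox == 0L)
    stop_apv("apv_empty_region_error", "no in-region voxels")
  structure(list(glcm = cpp_glcm(levels, nlevels),
                 glrlm = cpp_glrlm(levels, nlevels),
                 glszm = cpp_glszm(levels, nlevels),
                 ngtdm = cpp_ngtdm(levels, nlevels),
                 ngldm = cpp_ngldm(levels, nlevels),
                 nlevels = as.integer(nlevels), nvox = nvox),
            class = "apv_texture_matrices")
}

#' Embed one region of a volume as a discretized level array
#'
#' @param vol an `apv_volume` (or one wavelet channel).
#' @param map the paired label map.
#' @param id region id.
#' @param spec a [discretization_spec()].
#' @return 3D integer array over the region's padded bounding box (0 =
#'   outside region), with attribute `nlevels`; NULL for an empty region.
#' @export
region_levels <- function(vol, map, id, spec = discretization_spec()) {
  rv <- region_voxels(vol, map, id)
  if (rv$n == 0L) return(NULL)
  lev <- discretize(rv$intensities, spec)
  d <- rv$bbox["hi", ] - rv$bbox["lo", ] + 1L
  arr <- array(0L, d)
  arr[cbind(rv$coords[, 1] - rv$bbox["lo", 1] + 1L,
            rv$coords[, 2] - rv$bbox["lo", 2] + 1L,
            rv$coords[, 3] - rv$bbox["lo", 3] + 1L)] <- as.integer(lev)
  structure(arr, nlevels = attr(lev, "nlevels"))
}

glcm_features <- function(P, nlevels) {
  L <- nlevels
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(L) * px); muy <- sum(seq_len(L) * py)
  sx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(L) - muy)^2 * py))
  # diagonal and cross-diagonal marginals
  k_diff <- 0:(L - 1)
  pxmy <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), 1)
  k_sum <- 2:(2 * L)
  pxpy <- vapply(k_sum, function(k) sum(P[(i + j) == k]), 1)
  nz <- P[P > 0]
  HXY <- -sum(nz * log2(nz))
  pp <- outer(px, py)
  sel <- pp > 0
  HXY1 <- -sum(P[sel] * log2(pp[sel]))
  HXY2 <- -sum(pp[sel] * log2(pp[sel]))
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  HY <- -sum(py[py > 0] * log2(py[py > 0]))
  da <- sum(k_diff * pxmy)
  corr <- if (sx * sy > TEXTURE_EPS)
    (sum(i * j * P) - mux * muy) / (sx * sy) else 0
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))
  offdiag <- abs(i - j) > 0
  c(autocorrelation = sum(i * j * P),
    cluster_prominence = sum((i + j - mux - muy)^4 * P),
    cluster_shade = sum((i + j - mux - muy)^3 * P),
    cluster_tendency = sum((i + j - mux - muy)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    difference_average = da,
    difference_entropy = -sum(pxmy[pxmy > 0] * log2(pxmy[pxmy > 0])),
    difference_variance = sum((k_diff - da)^2 * pxmy),
    dissimilarity = sum(abs(i - j) * P),
    joint_energy = sum(P^2),
    joint_entropy = HXY,
    imc1 = imc1,
    imc2 = imc2,
    inverse_difference = sum(P / (1 + abs(i - j))),
    inverse_difference_norm = sum(P / (1 + abs(i - j) / L)),
    inverse_difference_moment = sum(P / (1 + (i - j)^2)),
    inverse_difference_moment_norm = sum(P / (1 + (i - j)^2 / L^2)),
    inverse_variance = sum(P[offdiag] / (i - j)[offdiag]^2),
    joint_average = mux,
    max_probability = max(P),
    sum_entropy = -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0])))
}

# Shared form of the run-length / size-zone families: R is a levels x size
# count matrix, nvox the number of in-region voxels.
rl_features <- function(R, nvox, prefix_names) {
  Nr <- sum(R)
  L <- nrow(R); J <- ncol(R)
  ivec <- seq_len(L); jvec <- seq_len(J)
  ri <- rowSums(R); rj <- colSums(R)
  i2 <- ivec^2; j2 <- jvec^2
  vals <- c(sum(t(R) / j2) / Nr,                     # short/small emphasis
            sum(t(R) * j2) / Nr,                     # long/large emphasis
            sum(ri^2) / Nr,                          # grey-level nonunif.
            sum(rj^2) / Nr,                          # length/size nonunif.
            Nr / nvox,                               # run/zone percentage
            sum(R / i2) / Nr,                        # low grey level
            sum(R * i2) / Nr,                        # high grey level
            sum(outer(1 / i2, 1 / j2) * R) / Nr,     # short + low
            sum(outer(i2, 1 / j2) * R) / Nr,         # short + high
            sum(outer(1 / i2, j2) * R) / Nr,         # long + low
            sum(outer(i2, j2) * R) / Nr)             # long + high
  names(vals) <- prefix_names
  vals
}

ngtdm_features <- function(M, nvox) {
  n_i <- M[, 1]; s_i <- M[, 2]
  N <- sum(n_i)
  if (N == 0)
    return(structure(rep(NA_real_, 5), names = NGTDM_NAMES))
  p_i <- n_i / N
  lev <- seq_along(p_i)
  nzl <- which(p_i > 0)
  Ngp <- length(nzl)
  ps <- sum(p_i * s_i)
  coars <- 1 / max(ps, TEXTURE_EPS)
  contr <- if (Ngp > 1) {
    (sum(outer(p_i[nzl], p_i[nzl]) *
           outer(lev[nzl], lev[nzl], `-`)^2) / (Ngp * (Ngp - 1))) *
      (sum(s_i) / N)
  } else 0
  denom_b <- sum(abs(outer(lev[nzl] * p_i[nzl], lev[nzl] * p_i[nzl], `-`)))
  busy <- if (denom_b > TEXTURE_EPS) ps / denom_b else 0
  pairs <- expand.grid(a = nzl, b = nzl)
  pairs <- pairs[pairs$a != pairs$b, ]
  compl <- if (nrow(pairs)) {
    with(pairs, sum(abs(a - b) *
                      (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
                      (p_i[a] + p_i[b]))) / N
  } else 0
  ss <- sum(s_i)
  stren <- if (ss > TEXTURE_EPS) {
    with(pairs, sum((p_i[a] + p_i[b]) * (a - b)^2)) / ss
  } else 0
  c(coarseness = coars, contrast = contr, busyness = busy,
    complexity = compl, strength = stren)
}

ngldm_features <- function(M) {
  Ns <- sum(M)
  L <- nrow(M); K <- ncol(M)
  # dependence size d = dependent neighbours + the voxel itself
  dvec <- seq_len(K)
  ivec <- seq_len(L)
  rd <- colSums(M); ri <- rowSums(M)
  p <- M[M > 0] / Ns
  c(low_dependence_emphasis = sum(t(M) / dvec^2) / Ns,
    high_dependence_emphasis = sum(t(M) * dvec^2) / Ns,
    gl_nonuniformity = sum(ri^2) / Ns,
    dependence_nonuniformity = sum(rd^2) / Ns,
    dependence_entropy = -sum(p * log2(p)))
}

#' Texture features from the five matrices
#'
#' @param mats an `apv_texture_matrices` object.
#' @return named numeric vector of 54 values
#'   (22 GLCM + 11 GLRLM + 11 GLSZM + 5 NGTDM + 5 NGLDM), names prefixed
#'   `glcm.`, `glrlm.`, `glszm.`, `ngtdm.`, `ngldm.`.
#' @export
texture_features <- function(mats) {
  g <- glcm_features(mats$glcm, mats$nlevels)
  r <- rl_features(mats$glrlm, mats$nvox, GLRLM_NAMES)
  z <- rl_features(mats$glszm, mats$nvox, GLSZM_NAMES)
  t5 <- ngtdm_features(mats$ngtdm, mats$nvox)
  d5 <- ngldm_features(mats$ngldm)
  c(stats::setNames(g, paste0("glcm.", GLCM_NAMES)),
    stats::setNames(r, paste0("glrlm.", GLRLM_NAMES)),
    stats::setNames(z, paste0("glszm.", GLSZM_NAMES)),
    stats::setNames(t5, paste0("ngtdm.", NGTDM_NAMES)),
    stats::setNames(d5, paste0("ngldm.", NGLDM_NAMES)))
}
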