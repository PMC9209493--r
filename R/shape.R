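SHAPE_NAMES <- c("volume_mm3", "voxel_count", "surface_area_mm2",
                 "sphericity", "compactness", "max_diameter_3d",
                 "elongation", "flatness")

#' Shape descriptors of a voxel region
#'
#' Volume is voxel count times physical voxel volume; surface area counts
#' exposed voxel faces (6-connectivity) weighted by their physical face
#' area, so a single 1 mm voxel has volume 1 mm^3 and area 6 mm^2.
#' Sphericity is `pi^(1/3) (6V)^(2/3) / A`; compactness is
#' `V / (sqrt(pi) A^(3/2))`. Elongation and flatness are
#' `sqrt(lambda2/lambda1)` and `sqrt(lambda3/lambda1)` of the voxel-centre
#' covariance eigenvalues (both defined as 1 for regions too small to span
#' a direction). The maximum 3D diameter is the largest pairwise distance
#' between boundary voxel centres; for very large regions the boundary set
#' is deterministically thinned to bound the quadratic scan.
#'
#' @param coords n x 3 integer matrix of 0-based voxel indices.
#' @param spacing numeric length-3 voxel size in mm.
#' @param max_boundary cap on boundary voxels entering the diameter scan.
#' @return named numeric vector of length 8.
#' @export
shape_features <- function(coords, spacing = c(1, 1, 1),
                           max_boundary = 800L) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (n < 1L)
    stop_apv("apv_empty_region_error", "empty region has no shape")
  voxvol <- prod(spacing)
  V <- n * voxvol

  # embed in bounding box with a 1-voxel pad, count exposed faces per axis
  lo <- apply(coords, 2, min)
  d <- apply(coords, 2, max) - lo + 3L
  mask <- array(0L, d)
  mask[cbind(coords[, 1] - lo[1] + 2L, coords[, 2] - lo[2] + 2L,
             coords[, 3] - lo[3] + 2L)] <- 1L
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  A <- 0
  exposed <- array(FALSE, d)
  for (a in 1:3) {
    dm <- abs(apply(mask, setdiff(1:3, a), diff))
    A <- A + sum(dm) * face_area[a]
    # a voxel is boundary if any 6-neighbour along this axis is background
    sh <- function(k) {
      idx <- lapply(1:3, function(j) seq_len(d[j]))
      idx[[a]] <- pmin(pmax(idx[[a]] + k, 1L), d[a])
      do.call(`[`, c(list(mask), idx))
    }
    exposed <- exposed | (mask == 1L & (sh(1L) == 0L | sh(-1L) == 0L))
  }

  bidx <- which(exposed)
  bc <- (arrayInd(bidx, d) - 2L)  # back to region-local 0-based coords
  bc <- sweep(bc, 2, -lo)         # restore absolute voxel indices
  if (nrow(bc) > max_boundary) {
    keep <- unique(as.integer(round(seq(1, nrow(bc), length.out = max_boundary))))
    bc <- bc[keep, , drop = FALSE]
  }
  phys <- sweep(bc, 2, spacing, `*`)
  if (nrow(phys) == 1L) {
    maxdiam <- max(spacing)  # single voxel: use its largest edge
  } else {
    g <- rowSums(phys^2)
    # max pairwise distance via |x-y|^2 = |x|^2 + |y|^2 - 2 x.y
    d2 <- outer(g, g, `+`) - 2 * tcrossprod(phys)
    maxdiam <- sqrt(max(d2, 0))
  }

  if (n > 1L) {
    ev <- sort(eigen(stats::cov(sweep(coords, 2, spacing, `*`)),
                     symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
    flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  } else {
    elong <- flat <- 1
  }

  c(volume_mm3 = V,
    voxel_count = as.numeric(n),
    surface_area_mm2 = A,
    sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    compactness = V / (sqrt(pi) * A^1.5),
    max_diameter_3d = maxdiam,
    elongation = elong,
    flatness = flat)
}

#' Box-counting fractal dimension of a voxel set
#'
#' Least-squares slope of `log N(s)` against `log(1/s)` over dyadic box
#' sizes `s = 1, 2, 4, ...` up to half the largest bounding-box extent,
#' where `N(s)` is the number of occupied boxes at size `s`.
#'
#' @param coords n x 3 integer matrix of 0-based voxel indices.
#' @return the fitted dimension, or `NA_real_` when fewer than 2 voxels or
#'   fewer than 2 usable box sizes make the slope undefined.
#' @export
fractal_dimension <- function(coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  if (nrow(coords) < 2L) return(NA_real_)
  coords <- sweep(coords, 2, apply(coords, 2, min))
  ext <- max(apply(coords, 2, max)) + 1L
  sizes <- 2^(0:floor(log2(max(ext - 1L, 1L))))
  if (length(sizes) < 2L) return(NA_real_)
  counts <- vapply(sizes, function(s) {
    boxes <- floor(coords / s)
    nrow(unique(boxes))
  }, 1L)
  xs <- log(1 / sizes)
  ys <- log(counts)
  sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
}
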