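#' Resample a volume and its label map to an isotropic grid
#'
#' Intensities are resampled with trilinear interpolation, labels with
#' nearest-neighbour, so no label id absent from the input can appear in the
#' output. Output voxel `i` (0-based) sits at physical offset `i * target`
#' along each axis from the input's first voxel centre. When the input is
#' already at the target spacing the grids are returned unchanged.
#'
#' @param vol an `apv_volume`.
#' @param map the paired `apv_labelmap` (may be NULL to resample a volume
#'   alone).
#' @param target isotropic target spacing in mm (default 1).
#' @return list with elements `volume` and `labelmap` (NULL if `map` was).
#' @export
resample_isotropic <- function(vol, map = NULL, target = 1.0) {
  if (!is.finite(target) || target <= 0)
    stop_apv("apv_validation_error", "target spacing must be positive")
  if (!is.null(map)) check_aligned(vol, map)
  if (max(abs(vol$spacing - target)) < 1e-9)
    return(list(volume = vol, labelmap = map))

  d_in <- dim(vol$grid)
  # cover the physical extent spanned by input voxel centres
  d_out <- pmax(1L, as.integer(floor((d_in - 1L) * vol$spacing / target)) + 1L)
  src <- lapply(1:3, function(a) (seq_len(d_out[a]) - 1) * target / vol$spacing[a])

  out_vol <- apv_volume(trilinear_sample(vol$grid, src),
                        spacing = rep(target, 3), origin = vol$origin)
  out_map <- NULL
  if (!is.null(map)) {
    nn <- lapply(1:3, function(a) pmin(pmax(round(src[[a]]) + 1, 1), d_in[a]))
    out_map <- apv_labelmap(map$grid[nn[[1]], nn[[2]], nn[[3]], drop = FALSE],
                            spacing = rep(target, 3), origin = map$origin)
  }
  list(volume = out_vol, labelmap = out_map)
}

# Trilinear interpolation of `grid` at continuous 0-based per-axis source
# coordinates (list of 3 vectors); samples the full outer product grid.
trilinear_sample <- function(grid, src) {
  d <- dim(grid)
  lo <- w <- vector("list", 3)
  for (a in 1:3) {
    s <- pmin(pmax(src[[a]], 0), d[a] - 1)
    f <- pmin(floor(s), d[a] - 1 - (d[a] > 1))       # keep f+1 in range
    lo[[a]] <- as.integer(f) + 1L
    w[[a]] <- s - f
  }
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, d[a]))
  out <- array(0, vapply(src, length, 1L))
  for (ca in 0:1) for (cb in 0:1) for (cc in 0:1) {
    ia <- if (ca) hi[[1]] else lo[[1]]
    ib <- if (cb) hi[[2]] else lo[[2]]
    ic <- if (cc) hi[[3]] else lo[[3]]
    wa <- if (ca) w[[1]] else 1 - w[[1]]
    wb <- if (cb) w[[2]] else 1 - w[[2]]
    wc <- if (cc) w[[3]] else 1 - w[[3]]
    wt <- outer(outer(wa, wb), wc)
    if (any(wt > 0)) out <- out + wt * grid[ia, ib, ic, drop = FALSE]
  }
  out
}
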