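#' Extract the full per-region feature row for one subject
#'
#' Computes the catalogue's features over every region of the chosen region
#' set, on the original channel and (where the catalogue asks for them) the
#' 8 stationary-wavelet sub-band channels. The result is a flat named vector
#' in deterministic column order `region__channel__family__name`, regions in
#' region-table order, features in catalogue order. Empty regions yield a
#' fully masked (NA) block; regions below the catalogue's texture voxel
#' minimum have their texture families masked.
#'
#' @param vol an `apv_volume` (assumed already isotropic; see
#'   [resample_isotropic()]).
#' @param map the paired `apv_labelmap`.
#' @param regions region table (see [default_region_table()]).
#' @param cat an `apv_catalogue` (default [default_catalogue()]).
#' @param region_set `"ALL115"` to use every region in `regions`, `"WM45"`
#'   or `"CTX70"` to restrict to that subset of the table.
#' @return named numeric vector of length `nrow(cat) * n_regions`, NA where
#'   masked.
#' @export
extract_subject_features <- function(vol, map, regions = default_region_table(),
                                     cat = default_catalogue(),
                                     region_set = c("ALL115", "WM45", "CTX70")) {
  region_set <- match.arg(region_set)
  check_aligned(vol, map)
  if (region_set != "ALL115")
    regions <- regions[regions$set == region_set, , drop = FALSE]
  if (!nrow(regions))
    stop_apv("apv_validation_error", "region set is empty")

  spec <- attr(cat, "discretization")
  min_tex <- attr(cat, "min_voxels_texture")
  channels <- unique(cat$channel)
  texture_fams <- c("glcm", "glrlm", "glszm", "ngtdm", "ngldm")

  grids <- list(original = vol$grid)
  if (any(channels != "original")) {
    bank <- wavelet_bank(vol)
    for (ch in intersect(channels, WAVELET_CHANNELS))
      grids[[ch]] <- bank[[ch]]$grid
  }

  # lookup keys in catalogue order, reused for every region
  keys <- ifelse(cat$family %in% texture_fams,
                 paste0(cat$family, ".", cat$name), cat$name)
  out <- vector("list", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    id <- regions$id[r]
    idx <- which(map$grid == id)
    n <- length(idx)
    vals <- rep(NA_real_, nrow(cat))
    if (n > 0L) {
      coords <- arrayInd(idx, dim(map$grid)) - 1L
      lo <- apply(coords, 2, min)
      d <- apply(coords, 2, max) - lo + 1L
      local <- cbind(coords[, 1] - lo[1] + 1L, coords[, 2] - lo[2] + 1L,
                     coords[, 3] - lo[3] + 1L)
      shape_vals <- if (any(cat$family == "shape"))
        shape_features(coords, vol$spacing) else NULL
      for (ch in channels) {
        rows_ch <- which(cat$channel == ch & cat$family != "shape")
        if (!length(rows_ch) && ch != "original") next
        x <- grids[[ch]][idx]
        chvals <- NULL
        if (any(cat$family[rows_ch] == "firstorder"))
          chvals <- firstorder_features(x, spec)
        if (n >= min_tex && any(cat$family[rows_ch] %in% texture_fams)) {
          lev <- discretize(x, spec)
          arr <- array(0L, d)
          arr[local] <- as.integer(lev)
          chvals <- c(chvals,
                      texture_features(
                        texture_matrices(arr, attr(lev, "nlevels"))))
        }
        if (!is.null(chvals)) {
          hit <- match(keys[rows_ch], names(chvals))
          vals[rows_ch[!is.na(hit)]] <- chvals[hit[!is.na(hit)]]
        }
      }
      if (!is.null(shape_vals)) {
        rows_sh <- which(cat$family == "shape")
        vals[rows_sh] <- shape_vals[match(cat$name[rows_sh],
                                          names(shape_vals))]
      }
    }
    out[[r]] <- vals
  }
  colnames_out <- as.vector(vapply(seq_len(nrow(regions)), function(r)
    paste(regions$name[r], cat$channel, cat$family, cat$name, sep = "__"),
    character(nrow(cat))))
  stats::setNames(unlist(out), colnames_out)
}

#' Extract features for a cohort of subjects
#'
#' @param subjects list of entries with elements `id`, `volume`
#'   (`apv_volume`), `labelmap` (`apv_labelmap`), e.g. the `subjects`
#'   element of [make_cohort()].
#' @param regions,cat,region_set as in [extract_subject_features()].
#' @return numeric matrix, one row per subject (rownames = subject ids).
#' @export
extract_cohort_features <- function(subjects,
                                    regions = default_region_table(),
                                    cat = default_catalogue(),
                                    region_set = c("ALL115", "WM45", "CTX70")) {
  region_set <- match.arg(region_set)
  rows <- lapply(subjects, function(s)
    extract_subject_features(s$volume, s$labelmap, regions, cat, region_set))
  ids <- vapply(subjects, `[[`, "", "id")
  mat <- do.call(rbind, rows)
  rownames(mat) <- ids
  mat
}
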