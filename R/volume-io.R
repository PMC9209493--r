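#' 3D intensity volume
#'
#' A minimal container for an aligned 3D intensity grid with physical voxel
#' spacing. Voxel indices are 0-based in physical-coordinate arithmetic:
#' the centre of voxel `(i,j,k)` sits at `origin + spacing * (i,j,k)`.
#'
#' @param grid 3D numeric array of intensities (arbitrary units).
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, physical coordinate of voxel (0,0,0) in mm.
#' @return An object of class `apv_volume`.
#' @export
apv_volume <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L)
    stop_apv("apv_format_error", "volume grid must be 3D, got %dD",
             length(dim(grid)))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_apv("apv_format_error", "spacing must be 3 finite positive values")
  structure(list(grid = grid, spacing = spacing, origin = as.numeric(origin)),
            class = "apv_volume")
}

#' @export
print.apv_volume <- function(x, ...) {
  cat(sprintf("<apv_volume> %s voxels, spacing %s mm\n",
              paste(dim(x$grid), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Integer label map paired with a volume
#'
#' @param grid 3D array of non-negative integer region ids; 0 = background.
#' @param spacing,origin as in [apv_volume()].
#' @return An object of class `apv_labelmap`.
#' @export
apv_labelmap <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L)
    stop_apv("apv_format_error", "label grid must be 3D, got %dD",
             length(dim(grid)))
  if (any(grid != round(grid)) || any(grid < 0))
    stop_apv("apv_format_error",
             "label map must contain non-negative integers")
  v <- apv_volume(grid + 0, spacing, origin)   # reuse validation
  structure(list(grid = array(as.integer(grid), dim(grid)),
                 spacing = v$spacing, origin = v$origin),
            class = "apv_labelmap")
}

#' @export
print.apv_labelmap <- function(x, ...) {
  ids <- setdiff(sort(unique(as.vector(x$grid))), 0L)
  cat(sprintf("<apv_labelmap> %s voxels, %d regions\n",
              paste(dim(x$grid), collapse = "x"), length(ids)))
  invisible(x)
}

#' Region ids present in a label map
#' @param map an `apv_labelmap`.
#' @return sorted integer vector of nonzero ids.
#' @export
label_ids <- function(map) {
  setdiff(sort(unique(as.vector(map$grid))), 0L)
}

#' Read a 3D NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [apv_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop_apv("apv_format_error", "file not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop_apv("apv_format_error",
                             "unreadable NIfTI file %s: %s", path,
                             conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L)
    stop_apv("apv_format_error",
             "expected a 3D image, got %dD (%s)", length(d), path)
  hdr <- RNifti::niftiHeader(img)
  apv_volume(array(as.numeric(img), d),
             spacing = RNifti::pixdim(img)[1:3],
             origin = c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z))
}

#' Write a volume or label map as NIfTI-1
#'
#' @param vol an `apv_volume` or `apv_labelmap`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$grid)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label map and validate its ids against a region table
#'
#' @param path NIfTI path.
#' @param regions a region table from [read_region_table()] or
#'   [default_region_table()].
#' @return An [apv_labelmap()] whose nonzero ids all appear in `regions`.
#' @export
read_labelmap <- function(path, regions) {
  v <- read_volume(path)
  g <- v$grid
  if (any(abs(g - round(g)) > 1e-6) || any(g < 0))
    stop_apv("apv_format_error",
             "label map %s contains non-integer or negative values", path)
  map <- apv_labelmap(round(g), v$spacing, v$origin)
  unknown <- setdiff(label_ids(map), regions$id)
  if (length(unknown))
    stop_apv("apv_validation_error",
             "label map contains ids absent from the region table: %s",
             paste(unknown, collapse = ", "))
  map
}

#' Read a region table (TSV with columns id, name, hemisphere, set)
#'
#' @param path TSV path.
#' @return data.frame with columns `id`, `name`, `hemisphere`, `set`.
#' @export
read_region_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "hemisphere", "set")
  if (!all(need %in% names(tab)))
    stop_apv("apv_format_error", "region table must have columns %s",
             paste(need, collapse = ", "))
  if (anyDuplicated(tab$id))
    stop_apv("apv_validation_error", "region table ids must be unique")
  bad <- setdiff(unique(tab$hemisphere), c("left", "right", "none"))
  if (length(bad))
    stop_apv("apv_validation_error", "unknown hemisphere codes: %s",
             paste(bad, collapse = ", "))
  tab$id <- as.integer(tab$id)
  tab
}

#' The default 115-region parcellation table
#'
#' 45 white-matter/subcortical regions (`WM45`) plus 70 cortical parcels
#' (`CTX70`), following the common automated T1w segmentation convention
#' (whole-brain subcortical segmentation plus per-hemisphere cortical
#' parcellation). Region ids are the label values expected in label maps.
#'
#' @param set one of `"ALL115"` (default), `"WM45"`, `"CTX70"`.
#' @return data.frame with columns `id`, `name`, `hemisphere`, `set`.
#' @export
default_region_table <- function(set = c("ALL115", "WM45", "CTX70")) {
  set <- match.arg(set)
  tab <- read_region_table(system.file("extdata", "regions115.tsv",
                                       package = "apvtools", mustWork = TRUE))
  if (set != "ALL115") tab <- tab[tab$set == set, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Extract the voxel set of one region
#'
#' @param vol an `apv_volume`.
#' @param map the paired `apv_labelmap` (same shape).
#' @param id nonzero region id.
#' @return list with `intensities` (numeric), `coords` (n x 3 integer matrix
#'   of 0-based voxel indices), `bbox` (2 x 3 matrix of 0-based index ranges,
#'   or NULL for an empty region) and `n` voxels.
#' @export
region_voxels <- function(vol, map, id) {
  if (id == 0) stop_apv("apv_validation_error", "region id must be nonzero")
  check_aligned(vol, map)
  idx <- which(map$grid == id)
  if (!length(idx))
    return(list(intensities = numeric(0),
                coords = matrix(integer(0), 0, 3), bbox = NULL, n = 0L))
  coords <- arrayInd(idx, dim(map$grid)) - 1L
  bbox <- rbind(lo = apply(coords, 2, min), hi = apply(coords, 2, max))
  list(intensities = as.numeric(vol$grid[idx]), coords = coords,
       bbox = bbox, n = length(idx))
}

check_aligned <- function(vol, map) {
  if (!identical(dim(vol$grid), dim(map$grid)))
    stop_apv("apv_alignment_error",
             "volume (%s) and label map (%s) shapes differ",
             paste(dim(vol$grid), collapse = "x"),
             paste(dim(map$grid), collapse = "x"))
  if (max(abs(vol$spacing - map$spacing)) > 1e-6)
    stop_apv("apv_alignment_error", "volume and label map spacing differ")
  invisible(TRUE)
}
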