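WAVELET_CHANNELS <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
ALL_CHANNELS <- c("original", WAVELET_CHANNELS)

#' The default per-region feature catalogue
#'
#' An ordered table of feature identifiers: 8 shape descriptors on the
#' original channel plus, for each of the 9 channels (original + 8
#' stationary-wavelet sub-bands), 18 first-order, 22 GLCM, 11 GLRLM,
#' 11 GLSZM, 5 NGTDM and 5 NGLDM features — 8 + 9 x 72 = 656 features per
#' region. Shape appears only on the original channel (filtering a binary
#' support has no meaning). Attributes carry the discretization spec, the
#' minimum region size for texture features, and the wavelet family.
#'
#' @param channels channels to include (default all 9).
#' @param families feature families to include.
#' @param bins grey levels for discretization (default 32).
#' @param min_voxels_texture regions smaller than this get masked texture
#'   values (default 27).
#' @return data.frame of class `apv_catalogue` with columns `channel`,
#'   `family`, `name`.
#' @export
feature_catalogue <- function(channels = ALL_CHANNELS,
                              families = c("shape", "firstorder", "glcm",
                                           "glrlm", "glszm", "ngtdm",
                                           "ngldm"),
                              bins = 32L, min_voxels_texture = 27L) {
  channels <- match.arg(channels, ALL_CHANNELS, several.ok = TRUE)
  families <- match.arg(families, several.ok = TRUE)
  fam_names <- list(shape = SHAPE_NAMES, firstorder = FIRSTORDER_NAMES,
                    glcm = GLCM_NAMES, glrlm = GLRLM_NAMES,
                    glszm = GLSZM_NAMES, ngtdm = NGTDM_NAMES,
                    ngldm = NGLDM_NAMES)
  rows <- list()
  if ("shape" %in% families && "original" %in% channels)
    rows[[1]] <- data.frame(channel = "original", family = "shape",
                            name = SHAPE_NAMES, stringsAsFactors = FALSE)
  for (ch in channels)
    for (fam in setdiff(families, "shape"))
      rows[[length(rows) + 1L]] <-
        data.frame(channel = ch, family = fam, name = fam_names[[fam]],
                   stringsAsFactors = FALSE)
  cat_df <- do.call(rbind, rows)
  rownames(cat_df) <- NULL
  if (anyDuplicated(paste(cat_df$channel, cat_df$family, cat_df$name)))
    stop_apv("apv_validation_error", "catalogue has duplicate feature ids")
  structure(cat_df,
            discretization = discretization_spec(bins = bins),
            min_voxels_texture = as.integer(min_voxels_texture),
            wavelet = "coif1",
            class = c("apv_catalogue", "data.frame"))
}

#' @rdname feature_catalogue
#' @export
default_catalogue <- function() feature_catalogue()

#' Content hash of a catalogue
#'
#' @param cat an `apv_catalogue`.
#' @return hex string fingerprinting the ordered feature ids and specs.
#' @export
catalogue_hash <- function(cat) {
  fnv1a_hash(list(cat$channel, cat$family, cat$name,
                  unclass(attr(cat, "discretization")),
                  attr(cat, "min_voxels_texture"), attr(cat, "wavelet")))
}

catalogue_to_list <- function(cat) {
  list(channel = cat$channel, family = cat$family, name = cat$name,
       discretization = unclass(attr(cat, "discretization")),
       min_voxels_texture = attr(cat, "min_voxels_texture"),
       wavelet = attr(cat, "wavelet"),
       hash = catalogue_hash(cat))
}

catalogue_from_list <- function(x) {
  cat_df <- data.frame(channel = unlist(x$channel),
                       family = unlist(x$family),
                       name = unlist(x$name), stringsAsFactors = FALSE)
  spec <- discretization_spec(mode = x$discretization$mode,
                              bins = x$discretization$bins %||% 32L,
                              width = x$discretization$width)
  structure(cat_df, discretization = spec,
            min_voxels_texture = as.integer(x$min_voxels_texture),
            wavelet = x$wavelet,
            class = c("apv_catalogue", "data.frame"))
}

#' Write / read a catalogue as JSON
#' @param cat an `apv_catalogue`.
#' @param path JSON path.
#' @return `path` invisibly; `read_catalogue` returns the catalogue.
#' @export
write_catalogue <- function(cat, path) {
  jsonlite::write_json(catalogue_to_list(cat), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_catalogue
#' @export
read_catalogue <- function(path) {
  catalogue_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}
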