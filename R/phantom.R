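#' Specification of a synthetic multi-region brain phantom cohort
#'
#' Subjects are cubic grids holding a central "brain" ellipsoid tiled into
#' seeded-Voronoi regions. Group-dependent signal is planted per region as
#' (i) atrophy — the region is eroded inward to a target volume fraction,
#' (ii) an intensity shift in units of the noise sd, and (iii) correlated
#' Gaussian texture generated by Gaussian smoothing of white noise with
#' kernel sd equal to the requested correlation length (voxels).
#'
#' @param grid voxels per axis (cubic; >= 32 recommended for texture work).
#' @param n_regions number of Voronoi regions (>= 2).
#' @param groups ordered character vector of group labels.
#' @param effects data.frame with columns `group`, `region`, `vol_scale`
#'   (in (0, 1.5]), `int_shift` (noise-sd units), `tex_len` (voxels);
#'   regions/groups not listed get no effect.
#' @param noise_sd white-noise standard deviation (intensity units).
#' @param base_intensity mean tissue intensity.
#' @param seed seed fixing the region geometry and cohort randomness.
#' @return list of class `apv_phantom_spec`.
#' @export
phantom_spec <- function(grid = 64L, n_regions = 8L,
                         groups = c("nADrp", "MCI_AD", "AD"),
                         effects = NULL, noise_sd = 1.0,
                         base_intensity = 100, seed = 1L) {
  if (n_regions < 2L)
    stop_apv("apv_validation_error", "need >= 2 regions")
  if (is.null(effects))
    effects <- data.frame(group = character(0), region = integer(0),
                          vol_scale = numeric(0), int_shift = numeric(0),
                          tex_len = numeric(0), stringsAsFactors = FALSE)
  if (any(effects$vol_scale <= 0 | effects$vol_scale > 1.5))
    stop_apv("apv_validation_error", "vol_scale must lie in (0, 1.5]")
  structure(list(grid = as.integer(grid), n_regions = as.integer(n_regions),
                 groups = groups, effects = effects,
                 noise_sd = noise_sd, base_intensity = base_intensity,
                 seed = as.integer(seed)),
            class = "apv_phantom_spec")
}

#' The default strong-signal study phantom
#'
#' The reference condition used throughout the end-to-end validation:
#' 64-voxel grid, 8 regions, disease signal planted in regions 1-3 as an
#' intensity shift of 1 noise-sd plus atrophy to 70% volume in the `AD`
#' group and half that shift (85% volume) in `MCI_AD`.
#'
#' @param seed geometry/cohort seed.
#' @return an `apv_phantom_spec`.
#' @export
study_phantom_spec <- function(seed = 1L) {
  eff <- rbind(
    data.frame(group = "AD", region = 1:3, vol_scale = 0.7,
               int_shift = 1.0, tex_len = 0, stringsAsFactors = FALSE),
    data.frame(group = "MCI_AD", region = 1:3, vol_scale = 0.85,
               int_shift = 0.5, tex_len = 0, stringsAsFactors = FALSE))
  phantom_spec(grid = 64L, n_regions = 8L,
               groups = c("nADrp", "MCI_AD", "AD"),
               effects = eff, seed = seed)
}

# Base Voronoi tiling of the central ellipsoid; deterministic in spec$seed.
phantom_base_labels <- function(spec) {
  n <- spec$grid
  set.seed(spec$seed)
  ax <- seq_len(n) - (n + 1) / 2
  semi <- n * c(0.45, 0.42, 0.40)
  inside <- outer(outer((ax / semi[1])^2, (ax / semi[2])^2, `+`),
                  (ax / semi[3])^2, `+`) <= 1
  idx <- which(inside)
  coords <- arrayInd(idx, c(n, n, n))
  # Voronoi sites drawn inside the ellipsoid, re-drawn until all regions
  # are non-empty (guaranteed to terminate for sane region counts)
  for (attempt in 1:20) {
    sites <- coords[sample(nrow(coords), spec$n_regions), , drop = FALSE]
    d2 <- matrix(0, nrow(coords), spec$n_regions)
    for (r in seq_len(spec$n_regions))
      d2[, r] <- (coords[, 1] - sites[r, 1])^2 +
        (coords[, 2] - sites[r, 2])^2 + (coords[, 3] - sites[r, 3])^2
    lab <- max.col(-d2, ties.method = "first")
    if (length(unique(lab)) == spec$n_regions) {
      grid <- array(0L, c(n, n, n))
      grid[idx] <- lab
      return(grid)
    }
  }
  stop_apv("apv_geometry_error", "could not seat %d non-empty regions",
           spec$n_regions)
}

# Erode a region (6-connectivity boundary peeling) to ~frac of its volume.
# The final partial layer is removed in deterministic index order. Eroded
# voxels become background (0), mimicking atrophy-driven boundary loss.
erode_region <- function(grid, id, frac) {
  target <- max(1L, round(sum(grid == id) * frac))
  d <- dim(grid)
  repeat {
    idx <- which(grid == id)
    excess <- length(idx) - target
    if (excess <= 0L) break
    co <- arrayInd(idx, d)
    boundary <- rep(FALSE, length(idx))
    for (a in 1:3) for (s in c(-1L, 1L)) {
      nb <- co
      nb[, a] <- nb[, a] + s
      ok <- nb[, a] >= 1L & nb[, a] <= d[a]
      val <- rep(0L, length(idx))
      val[ok] <- grid[nb[ok, , drop = FALSE]]
      boundary <- boundary | val != id
    }
    bidx <- idx[boundary]
    if (!length(bidx)) break   # solid block smaller than a full layer
    if (length(bidx) > excess) bidx <- sort(bidx)[seq_len(excess)]
    grid[bidx] <- 0L
  }
  grid
}

#' Generate one subject's label map
#'
#' The base tiling is fixed by the spec seed; a subject seed adds a mild
#' (about 5%) jitter to the atrophy target so region volumes vary across
#' subjects the way segmentation volumes do.
#'
#' @param spec an `apv_phantom_spec`.
#' @param group the subject's group (drives atrophy scaling).
#' @param subject_seed optional per-subject seed for the atrophy jitter.
#' @return an `apv_labelmap` at 1 mm isotropic spacing.
#' @export
make_labelmap <- function(spec, group = spec$groups[1], subject_seed = NULL) {
  grid <- phantom_base_labels(spec)   # note: reseeds the RNG from spec$seed
  eff <- spec$effects[spec$effects$group == group &
                        spec$effects$vol_scale < 1, , drop = FALSE]
  if (!is.null(subject_seed)) set.seed(subject_seed)
  for (r in seq_len(nrow(eff))) {
    frac <- eff$vol_scale[r]
    if (!is.null(subject_seed)) frac <- min(frac * runif(1, 0.95, 1.05), 1)
    grid <- erode_region(grid, eff$region[r], frac)
  }
  apv_labelmap(grid)
}

# Smoothed standard-normal field with kernel sd = len voxels, rescaled to
# unit marginal sd.
correlated_field <- function(d, len) {
  w <- array(rnorm(prod(d)), d)
  if (len <= 0) return(w)
  half <- max(1L, ceiling(3 * len))
  kern <- exp(-((-half:half)^2) / (2 * len^2))
  kern <- kern / sum(kern)
  f <- w
  for (a in 1:3) f <- filter_axis(f, kern, a)
  f / sd(f)
}

#' Generate one phantom subject
#'
#' Intensity model per voxel of region r:
#' `base + shift_r(group) * noise_sd + noise_sd * texture + noise_sd * white`
#' where `texture` is the unit-variance correlated field (only when the
#' region has a positive correlation length for this group). Background
#' voxels hold dimmer noise around 0.
#'
#' @param spec an `apv_phantom_spec`.
#' @param group group label (must be in `spec$groups`).
#' @param subject_seed integer seed for this subject's randomness.
#' @param noise_seed optional separate seed for the intensity noise; with
#'   the same `subject_seed` and a different `noise_seed` the subject keeps
#'   its anatomy (label map) but gets a fresh acquisition — a test-retest
#'   rescan.
#' @return list with `volume` (`apv_volume`) and `labelmap`.
#' @export
make_subject <- function(spec, group, subject_seed = 1L, noise_seed = NULL) {
  if (!group %in% spec$groups)
    stop_apv("apv_label_error", "unknown group %s", group)
  map <- make_labelmap(spec, group, subject_seed)
  set.seed(if (is.null(noise_seed)) derive_seed(subject_seed, 1) else
    noise_seed)
  d <- dim(map$grid)
  vol <- array(rnorm(prod(d), 0, 0.1 * spec$noise_sd), d)
  eff <- spec$effects[spec$effects$group == group, , drop = FALSE]
  for (id in seq_len(spec$n_regions)) {
    idx <- which(map$grid == id)
    if (!length(idx)) next
    e <- eff[eff$region == id, , drop = FALSE]
    shift <- if (nrow(e)) e$int_shift[1] else 0
    tex_len <- if (nrow(e)) e$tex_len[1] else 0
    vals <- spec$base_intensity + shift * spec$noise_sd +
      rnorm(length(idx), 0, spec$noise_sd)
    if (tex_len > 0) {
      lo <- apply(arrayInd(idx, d), 2, min)
      hi <- apply(arrayInd(idx, d), 2, max)
      fdim <- hi - lo + 1L
      # texture fields need room for the smoothing kernel
      fdim <- pmax(fdim, as.integer(ceiling(6 * tex_len + 1)))
      field <- correlated_field(fdim, tex_len)
      loc <- sweep(arrayInd(idx, d), 2, lo - 1L)
      vals <- vals + spec$noise_sd * field[loc]
    }
    vol[idx] <- vals
  }
  list(volume = apv_volume(vol), labelmap = map)
}

#' Generate a seeded phantom cohort
#'
#' Subject seeds are derived deterministically from the cohort seed, so the
#' whole cohort is bit-reproducible from `(spec, seed)`.
#'
#' @param spec an `apv_phantom_spec`.
#' @param n_per_group subjects per group (>= 1).
#' @param seed cohort seed (defaults to `spec$seed`).
#' @return list of class `apv_cohort`: `subjects` (each with `id`, `group`,
#'   `volume`, `labelmap`), `groups` (per subject), `truth` (data.frame of
#'   signal-bearing (region, property) pairs from the effect map), `spec`.
#' @export
make_cohort <- function(spec, n_per_group = 10L, seed = spec$seed) {
  if (n_per_group < 1L)
    stop_apv("apv_validation_error", "n_per_group must be >= 1")
  subjects <- list()
  i <- 0L
  for (g in spec$groups) for (k in seq_len(n_per_group)) {
    i <- i + 1L
    subjects[[i]] <- c(list(id = sprintf("%s_%03d", g, k), group = g),
                       make_subject(spec, g, derive_seed(seed, i)))
  }
  eff <- spec$effects
  truth_rows <- function(sel, property) {
    if (!any(sel)) return(NULL)
    data.frame(region = eff$region[sel], property = property,
               group = eff$group[sel], stringsAsFactors = FALSE)
  }
  truth <- rbind(truth_rows(eff$vol_scale != 1, "volume"),
                 truth_rows(eff$int_shift != 0, "intensity"),
                 truth_rows(eff$tex_len > 0, "texture"))
  structure(list(subjects = subjects,
                 groups = vapply(subjects, `[[`, "", "group"),
                 truth = truth, spec = spec, seed = seed),
            class = "apv_cohort")
}

#' Region table matching a phantom spec
#'
#' @param spec an `apv_phantom_spec`.
#' @param set set label to assign (default `"WM45"`-style single set named
#'   `"PHANTOM"`).
#' @return region table data.frame usable with the extraction functions.
#' @export
phantom_region_table <- function(spec, set = "PHANTOM") {
  data.frame(id = seq_len(spec$n_regions),
             name = sprintf("region%02d", seq_len(spec$n_regions)),
             hemisphere = "none", set = set, stringsAsFactors = FALSE)
}
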