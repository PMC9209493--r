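test_that("default catalogue totals 656 with the documented breakdown", {
  cat_df <- default_catalogue()
  expect_equal(nrow(cat_df), 656)
  expect_equal(sum(cat_df$family == "shape"), 8)
  expect_true(all(cat_df$channel[cat_df$family == "shape"] == "original"))
  per_channel <- table(cat_df$channel[cat_df$family != "shape"])
  expect_true(all(per_channel == 72))
  expect_length(per_channel, 9)
  expect_false(anyDuplicated(paste(cat_df$channel, cat_df$family,
                                   cat_df$name)) > 0)
})

test_that("catalogue JSON round trip preserves the hash", {
  cat_df <- feature_catalogue(channels = c("original", "LHL"),
                              families = c("firstorder", "glcm"), bins = 16)
  f <- tempfile(fileext = ".json")
  write_catalogue(cat_df, f)
  back <- read_catalogue(f)
  expect_equal(catalogue_hash(back), catalogue_hash(cat_df))
  expect_equal(nrow(back), nrow(cat_df))
})

test_that("discretization follows the half-open bin convention", {
  expect_equal(as.vector(discretize(c(0, 0.5, 1.0),
                                    discretization_spec(bins = 2))),
               c(1L, 2L, 2L))
  const <- discretize(rep(3.5, 10))
  expect_true(all(const == 1L))
  expect_equal(attr(const, "nlevels"), 1L)
  expect_error(discretize(numeric(0)), class = "apv_empty_region_error")

  # per-level counts match a direct histogram; data built with the exact
  # range [0, 32] so the bin edges are floating-point exact
  set.seed(21)
  x <- c(0, 32, sample(0:31, 98, TRUE) + runif(98, 0.05, 0.95))
  lev <- discretize(x, discretization_spec(bins = 32))
  breaks <- 0:32
  hist_counts <- as.vector(table(cut(x, breaks, right = FALSE)))
  hist_counts[32] <- hist_counts[32] + sum(x == 32)
  expect_equal(tabulate(lev, 32), hist_counts)
})

test_that("first-order features match direct formulas", {
  fo <- firstorder_features(c(1, 2, 3))
  expect_equal(fo[["mean"]], 2)
  expect_equal(fo[["skewness"]], 0)

  fo_const <- firstorder_features(rep(7, 30))
  expect_equal(fo_const[["sd"]], 0)
  expect_equal(fo_const[["entropy"]], 0)
  expect_equal(fo_const[["uniformity"]], 1)

  set.seed(8)
  x <- rnorm(50, 5, 2)
  fo <- firstorder_features(x)
  qs <- quantile(x, c(.1, .25, .75, .9), names = FALSE)
  m2 <- mean((x - mean(x))^2)
  lev <- discretize(x)
  p <- tabulate(lev, 32) / 50; p <- p[p > 0]
  direct <- c(mean(x), median(x), sd(x), var(x), min(x), max(x),
              max(x) - min(x), qs[1], qs[4], qs[3] - qs[2],
              mean((x - mean(x))^3) / m2^1.5, mean((x - mean(x))^4) / m2^2,
              sum(x^2), sqrt(mean(x^2)), mean(abs(x - mean(x))),
              -sum(p * log2(p)), sum(p^2),
              mean(x[x >= qs[1] & x <= qs[4]]))
  expect_equal(unname(fo), direct, tolerance = 1e-10)
  expect_length(fo, 18)
})

test_that("shape features: unit voxel, cube, sphericity closed form", {
  sv <- shape_features(matrix(c(0, 0, 0), 1, 3))
  expect_equal(sv[["volume_mm3"]], 1)
  expect_equal(sv[["surface_area_mm2"]], 6)

  cube <- as.matrix(expand.grid(0:9, 0:9, 0:9))
  sc <- shape_features(cube)
  expect_equal(sc[["volume_mm3"]], 1000)
  expect_equal(sc[["surface_area_mm2"]], 600)
  expect_equal(sc[["sphericity"]], pi^(1 / 3) * 6000^(2 / 3) / 600,
               tolerance = 1e-12)
  expect_equal(sc[["elongation"]], 1, tolerance = 1e-12)
  expect_equal(sc[["max_diameter_3d"]], sqrt(3 * 81), tolerance = 1e-12)
  expect_error(shape_features(matrix(numeric(0), 0, 3)),
               class = "apv_empty_region_error")
})

test_that("fractal dimension hits the space-filling and planar limits", {
  cube <- as.matrix(expand.grid(0:31, 0:31, 0:31))
  expect_equal(fractal_dimension(cube), 3, tolerance = 0.15)
  plane <- as.matrix(expand.grid(0:31, 0:31, 0))
  expect_equal(fractal_dimension(plane), 2, tolerance = 0.15)
  expect_true(is.na(fractal_dimension(matrix(c(1, 1, 1), 1, 3))))

  # fixed sparse pattern equals explicit box counting
  set.seed(13)
  pts <- unique(matrix(sample(0:15, 3 * 60, TRUE), ncol = 3))
  sizes <- c(1, 2, 4, 8)
  counts <- vapply(sizes, function(s) nrow(unique(floor(pts / s))), 1L)
  xs <- log(1 / sizes); ys <- log(counts)
  slope <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  expect_equal(fractal_dimension(pts), slope, tolerance = 1e-12)
})

test_that("wavelet bank: 8 channels, constants annihilated, impulse response", {
  vol <- apv_volume(array(3.7, c(8, 8, 8)))
  wb <- wavelet_bank(vol)
  expect_named(wb, c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  for (ch in names(wb)[-1])
    expect_lt(max(abs(wb[[ch]]$grid)), 1e-12)
  expect_equal(max(wb$LLL$grid) - min(wb$LLL$grid), 0, tolerance = 1e-12)
  expect_equal(wb$LLL$grid[4, 4, 4], 3.7 * sqrt(2)^3, tolerance = 1e-12)

  # single impulse: response equals the separable outer product of taps
  n <- 13
  imp <- array(0, c(n, n, n)); c0 <- 7
  imp[c0, c0, c0] <- 1
  wb2 <- wavelet_bank(apv_volume(imp))
  lo <- apvtools:::COIF1_LO; hi <- apvtools:::COIF1_HI
  # closed-form 1D impulse response: with the impulse away from the
  # boundary, y[i] = kern[c0 - i + 1 + padL] on the filter's support
  sep_response <- function(kern, x) {
    padL <- (length(kern) - 1) %/% 2
    r <- numeric(n)
    for (i in seq_len(n)) {
      k <- x - i + 1 + padL
      if (k >= 1 && k <= length(kern)) r[i] <- kern[k]
    }
    r
  }
  r_lo <- sep_response(lo, c0); r_hi <- sep_response(hi, c0)
  expected <- outer(outer(r_hi, r_lo), r_hi)  # HLH channel
  expect_equal(wb2$HLH$grid, array(expected, c(n, n, n)), tolerance = 1e-12)
  expect_error(wavelet_bank(apv_volume(array(1, c(4, 8, 8)))),
               class = "apv_size_error")
})

test_that("toy GLCM matches the pair-enumeration example", {
  # 2x2x1 grid [[1,1],[1,2]]; restrict to the single x-direction by hand
  lev <- array(c(1L, 1L, 1L, 2L), c(2, 2, 1))
  # horizontal pairs: (1,1) and (1,2); symmetric counts -> 4 entries
  P_manual <- matrix(c(0.5, 0.25, 0.25, 0), 2, 2)
  cnt <- matrix(0, 2, 2)
  for (y in 1:2) {
    a <- lev[1, y, 1]; b <- lev[2, y, 1]
    cnt[a, b] <- cnt[a, b] + 1; cnt[b, a] <- cnt[b, a] + 1
  }
  expect_equal(cnt / sum(cnt), P_manual)
  # the full 13-direction implementation agrees with the brute-force oracle
  expect_equal(texture_matrices(lev, 2)$glcm, oracle_glcm(lev, 2),
               tolerance = 1e-12)
})

test_that("constant region: GLCM mass at (1,1), NGTDM differences 0", {
  lev <- array(1L, c(4, 4, 4))
  tm <- texture_matrices(lev, 1)
  expect_equal(sum(tm$glcm), 1, tolerance = 1e-12)
  expect_equal(tm$glcm[1, 1], 1, tolerance = 1e-12)
  expect_equal(sum(tm$ngtdm[, 2]), 0)
  tf <- texture_features(tm)
  expect_equal(tf[["glcm.contrast"]], 0)
  expect_equal(tf[["glcm.joint_energy"]], 1)
  # coarseness returns the documented epsilon-guard cap
  expect_equal(tf[["ngtdm.coarseness"]], 1e6)
})

test_that("direction-averaged matrices are rotation invariant", {
  set.seed(31)
  lev <- random_levels(c(5, 5, 5), 4)
  rot <- aperm(lev[, , dim(lev)[3]:1], c(3, 2, 1))  # 90-degree rotation
  tm1 <- texture_matrices(lev, 4)
  tm2 <- texture_matrices(rot, 4)
  expect_equal(tm1$glcm, tm2$glcm, tolerance = 1e-12)
  expect_equal(tm1$glrlm, tm2$glrlm, tolerance = 1e-12)
  f1 <- texture_features(tm1); f2 <- texture_features(tm2)
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("all texture matrices and features equal brute-force oracles", {
  set.seed(97)
  for (rep in 1:3) {
    d <- sample(4:6, 3, TRUE)
    L <- sample(3:5, 1)
    lev <- random_levels(d, L, density = 0.75)
    if (sum(lev > 0) < 8) next
    tm <- texture_matrices(lev, L)
    expect_equal(tm$glcm, oracle_glcm(lev, L), tolerance = 1e-10)
    expect_equal(tm$glrlm, oracle_glrlm(lev, L), tolerance = 1e-10)
    expect_equal(tm$glszm, oracle_glszm(lev, L), tolerance = 1e-10)
    expect_equal(unname(tm$ngtdm), unname(oracle_ngtdm(lev, L)),
                 tolerance = 1e-10)
    expect_equal(tm$ngldm[, 1:ncol(oracle_ngldm(lev, L))],
                 oracle_ngldm(lev, L), tolerance = 1e-10)
    tf <- texture_features(tm)
    expect_equal(tf[paste0("glcm.", apvtools:::GLCM_NAMES)],
                 oracle_glcm_features(tm$glcm), tolerance = 1e-8)
    expect_equal(unname(tf[paste0("glrlm.", apvtools:::GLRLM_NAMES)]),
                 unname(oracle_rl_features(tm$glrlm, tm$nvox,
                                           apvtools:::GLRLM_NAMES)),
                 tolerance = 1e-8)
    expect_equal(unname(tf[paste0("glszm.", apvtools:::GLSZM_NAMES)]),
                 unname(oracle_rl_features(tm$glszm, tm$nvox,
                                           apvtools:::GLSZM_NAMES)),
                 tolerance = 1e-8)
    expect_equal(tf[paste0("ngtdm.", apvtools:::NGTDM_NAMES)],
                 oracle_ngtdm_features(tm$ngtdm, tm$nvox), tolerance = 1e-8)
    expect_equal(tf[paste0("ngldm.", apvtools:::NGLDM_NAMES)],
                 oracle_ngldm_features(tm$ngldm), tolerance = 1e-8)
  }
})

test_that("intensity features are shift invariant under min-max binning", {
  set.seed(5)
  x <- rnorm(80)
  lev1 <- discretize(x)
  lev2 <- discretize(x + 42)
  expect_identical(as.vector(lev1), as.vector(lev2))
  # entropy/uniformity (level-based) identical under the shift
  f1 <- firstorder_features(x); f2 <- firstorder_features(x + 42)
  expect_equal(f1[["entropy"]], f2[["entropy"]])
  expect_equal(f1[["uniformity"]], f2[["uniformity"]])
  expect_equal(f1[["sd"]], f2[["sd"]])
})

test_that("extraction: block structure, masking of empty/small regions", {
  spec <- phantom_spec(grid = 36, n_regions = 4, groups = "A", seed = 2)
  s <- make_subject(spec, "A", 3)
  rt <- phantom_region_table(spec)
  # add a region id absent from the map: its whole block must be masked
  rt2 <- rbind(rt, data.frame(id = 99L, name = "ghost", hemisphere = "none",
                              set = "PHANTOM"))
  cat_df <- default_catalogue()
  row <- extract_subject_features(s$volume, s$labelmap, rt2, cat_df)
  expect_length(row, 656 * 5)
  ghost <- row[grepl("^ghost__", names(row))]
  expect_length(ghost, 656)
  expect_true(all(is.na(ghost)))
  # non-empty regions are fully populated
  expect_false(anyNA(row[!grepl("^ghost__", names(row))]))
  # deterministic column order
  expect_equal(names(row)[1], "region01__original__shape__volume_mm3")

  # a tiny region (< 27 voxels) keeps first-order but masks texture
  g <- array(0L, c(12, 12, 12))
  g[1:2, 1:2, 1:2] <- 1L                     # 8 voxels
  g[5:10, 5:10, 5:10] <- 2L                  # 216 voxels
  map <- apv_labelmap(g)
  vol <- apv_volume(array(rnorm(12^3), c(12, 12, 12)))
  rt3 <- data.frame(id = 1:2, name = c("tiny", "big"), hemisphere = "none",
                    set = "PHANTOM")
  row2 <- extract_subject_features(vol, map, rt3,
                                   feature_catalogue(channels = "original"))
  tiny <- row2[grepl("^tiny__", names(row2))]
  expect_false(anyNA(tiny[grepl("firstorder|shape", names(tiny))]))
  expect_true(all(is.na(tiny[grepl("glcm|glrlm|glszm|ngtdm|ngldm",
                                   names(tiny))])))
  expect_false(anyNA(row2[grepl("^big__", names(row2))]))
})
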