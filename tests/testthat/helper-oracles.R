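# Brute-force oracles, written as plain nested loops independent of the
# package's vectorized/C++ implementations. `levels` arrays follow the same
# convention: 0 outside the region, 1..L inside.

DIRS13 <- rbind(c(1,0,0), c(0,1,0), c(0,0,1),
                c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1),
                c(1,1,1), c(1,1,-1), c(1,-1,1), c(1,-1,-1))

in_bounds <- function(p, d) all(p >= 1) && all(p <= d)

oracle_glcm <- function(lev, L) {
  d <- dim(lev)
  avg <- matrix(0, L, L)
  used <- 0
  for (k in seq_len(nrow(DIRS13))) {
    cnt <- matrix(0, L, L)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- lev[x, y, z]
      if (a == 0) next
      q <- c(x, y, z) + DIRS13[k, ]
      if (!in_bounds(q, d)) next
      b <- lev[q[1], q[2], q[3]]
      if (b == 0) next
      cnt[a, b] <- cnt[a, b] + 1
      cnt[b, a] <- cnt[b, a] + 1
    }
    if (sum(cnt) > 0) {
      avg <- avg + cnt / sum(cnt)
      used <- used + 1
    }
  }
  if (used > 0) avg / used else avg
}

oracle_glrlm <- function(lev, L) {
  d <- dim(lev)
  runs <- list()
  for (k in seq_len(nrow(DIRS13))) {
    dir <- DIRS13[k, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- lev[x, y, z]
      if (a == 0) next
      p <- c(x, y, z) - dir
      if (in_bounds(p, d) && lev[p[1], p[2], p[3]] == a) next
      len <- 1
      q <- c(x, y, z) + dir
      while (in_bounds(q, d) && lev[q[1], q[2], q[3]] == a) {
        len <- len + 1
        q <- q + dir
      }
      runs[[length(runs) + 1]] <- c(a, len)
    }
  }
  runs <- do.call(rbind, runs)
  R <- matrix(0, L, max(runs[, 2]))
  for (i in seq_len(nrow(runs)))
    R[runs[i, 1], runs[i, 2]] <- R[runs[i, 1], runs[i, 2]] + 1
  R / 13
}

oracle_glszm <- function(lev, L) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0 || seen[x, y, z]) next
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (o in seq_len(nrow(offsets))) {
        q <- v + offsets[o, ]
        if (in_bounds(q, d) && !seen[q[1], q[2], q[3]] &&
            lev[q[1], q[2], q[3]] == a) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  zones <- do.call(rbind, zones)
  Z <- matrix(0, L, max(zones[, 2]))
  for (i in seq_len(nrow(zones)))
    Z[zones[i, 1], zones[i, 2]] <- Z[zones[i, 1], zones[i, 2]] + 1
  Z
}

oracle_ngtdm <- function(lev, L) {
  d <- dim(lev)
  n_i <- s_i <- numeric(L)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    nb <- c()
    for (o in seq_len(nrow(offsets))) {
      q <- c(x, y, z) + offsets[o, ]
      if (in_bounds(q, d) && lev[q[1], q[2], q[3]] > 0)
        nb <- c(nb, lev[q[1], q[2], q[3]])
    }
    if (!length(nb)) next
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(nb))
  }
  cbind(n_i, s_i)
}

oracle_ngldm <- function(lev, L) {
  d <- dim(lev)
  M <- matrix(0, L, 27)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    dep <- 0
    for (o in seq_len(nrow(offsets))) {
      q <- c(x, y, z) + offsets[o, ]
      if (in_bounds(q, d) && lev[q[1], q[2], q[3]] == a) dep <- dep + 1
    }
    M[a, dep + 1] <- M[a, dep + 1] + 1
  }
  M
}

# direct-formula recomputation of the GLCM panel (loop form)
oracle_glcm_features <- function(P) {
  L <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:L) * px); muy <- sum((1:L) * py)
  sx <- sqrt(sum(((1:L) - mux)^2 * px)); sy <- sqrt(sum(((1:L) - muy)^2 * py))
  acc <- stats::setNames(numeric(22), paste0("glcm.", apvtools:::GLCM_NAMES))
  pxy_d <- numeric(L); pxy_s <- numeric(2 * L - 1)
  for (i in 1:L) for (j in 1:L) {
    pxy_d[abs(i - j) + 1] <- pxy_d[abs(i - j) + 1] + P[i, j]
    pxy_s[i + j - 1] <- pxy_s[i + j - 1] + P[i, j]
  }
  da <- sum((0:(L - 1)) * pxy_d)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  HXY <- ent(P); HX <- ent(px); HY <- ent(py)
  HXY1 <- 0; HXY2 <- 0
  for (i in 1:L) for (j in 1:L) if (px[i] * py[j] > 0) {
    HXY1 <- HXY1 - P[i, j] * log2(px[i] * py[j])
    HXY2 <- HXY2 - px[i] * py[j] * log2(px[i] * py[j])
  }
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    acc["glcm.autocorrelation"] <- acc["glcm.autocorrelation"] + i * j * p
    acc["glcm.cluster_prominence"] <- acc["glcm.cluster_prominence"] +
      (i + j - mux - muy)^4 * p
    acc["glcm.cluster_shade"] <- acc["glcm.cluster_shade"] +
      (i + j - mux - muy)^3 * p
    acc["glcm.cluster_tendency"] <- acc["glcm.cluster_tendency"] +
      (i + j - mux - muy)^2 * p
    acc["glcm.contrast"] <- acc["glcm.contrast"] + (i - j)^2 * p
    acc["glcm.dissimilarity"] <- acc["glcm.dissimilarity"] + abs(i - j) * p
    acc["glcm.joint_energy"] <- acc["glcm.joint_energy"] + p^2
    acc["glcm.inverse_difference"] <- acc["glcm.inverse_difference"] +
      p / (1 + abs(i - j))
    acc["glcm.inverse_difference_norm"] <-
      acc["glcm.inverse_difference_norm"] + p / (1 + abs(i - j) / L)
    acc["glcm.inverse_difference_moment"] <-
      acc["glcm.inverse_difference_moment"] + p / (1 + (i - j)^2)
    acc["glcm.inverse_difference_moment_norm"] <-
      acc["glcm.inverse_difference_moment_norm"] + p / (1 + (i - j)^2 / L^2)
    if (i != j)
      acc["glcm.inverse_variance"] <- acc["glcm.inverse_variance"] +
        p / (i - j)^2
  }
  acc["glcm.correlation"] <- if (sx * sy > 1e-6)
    (acc[["glcm.autocorrelation"]] - mux * muy) / (sx * sy) else 0
  acc["glcm.difference_average"] <- da
  acc["glcm.difference_entropy"] <- ent(pxy_d)
  acc["glcm.difference_variance"] <- sum(((0:(L - 1)) - da)^2 * pxy_d)
  acc["glcm.joint_entropy"] <- HXY
  acc["glcm.imc1"] <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  acc["glcm.imc2"] <- sqrt(max(1 - exp(-2 * (HXY2 - HXY)), 0))
  acc["glcm.joint_average"] <- mux
  acc["glcm.max_probability"] <- max(P)
  acc["glcm.sum_entropy"] <- ent(pxy_s)
  acc
}

oracle_rl_features <- function(R, nvox, prefix) {
  Nr <- sum(R)
  out <- stats::setNames(numeric(11), prefix)
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    r <- R[i, j]
    out[1] <- out[1] + r / j^2
    out[2] <- out[2] + r * j^2
    out[6] <- out[6] + r / i^2
    out[7] <- out[7] + r * i^2
    out[8] <- out[8] + r / (i^2 * j^2)
    out[9] <- out[9] + r * i^2 / j^2
    out[10] <- out[10] + r * j^2 / i^2
    out[11] <- out[11] + r * i^2 * j^2
  }
  out[3] <- sum(rowSums(R)^2)
  out[4] <- sum(colSums(R)^2)
  out[1:11] <- out[1:11] / Nr
  out[5] <- Nr / nvox
  out
}

oracle_ngtdm_features <- function(M, nvox) {
  n_i <- M[, 1]; s_i <- M[, 2]
  N <- sum(n_i)
  p_i <- n_i / N
  nz <- which(p_i > 0)
  Ngp <- length(nz)
  ps <- sum(p_i * s_i)
  coars <- 1 / max(ps, 1e-6)
  contr <- 0
  if (Ngp > 1) {
    for (i in nz) for (j in nz)
      contr <- contr + p_i[i] * p_i[j] * (i - j)^2
    contr <- contr / (Ngp * (Ngp - 1)) * sum(s_i) / N
  }
  denb <- 0; compl <- 0; stren <- 0
  for (i in nz) for (j in nz) {
    denb <- denb + abs(i * p_i[i] - j * p_i[j])
    if (i != j) {
      compl <- compl + abs(i - j) *
        (p_i[i] * s_i[i] + p_i[j] * s_i[j]) / (p_i[i] + p_i[j])
      stren <- stren + (p_i[i] + p_i[j]) * (i - j)^2
    }
  }
  busy <- if (denb > 1e-6) ps / denb else 0
  compl <- compl / N
  stren <- if (sum(s_i) > 1e-6) stren / sum(s_i) else 0
  stats::setNames(c(coars, contr, busy, compl, stren),
                  paste0("ngtdm.", apvtools:::NGTDM_NAMES))
}

oracle_ngldm_features <- function(M) {
  Ns <- sum(M)
  lde <- hde <- 0
  for (i in seq_len(nrow(M))) for (d in seq_len(ncol(M))) {
    lde <- lde + M[i, d] / d^2
    hde <- hde + M[i, d] * d^2
  }
  p <- M[M > 0] / Ns
  stats::setNames(
    c(lde / Ns, hde / Ns, sum(rowSums(M)^2) / Ns, sum(colSums(M)^2) / Ns,
      -sum(p * log2(p))),
    paste0("ngldm.", apvtools:::NGLDM_NAMES))
}

# random small discretized region embedded in a box, with in-region mask
random_levels <- function(d, L, density = 0.8) {
  arr <- array(0L, d)
  n <- prod(d)
  inside <- sample(n, ceiling(density * n))
  arr[inside] <- sample.int(L, length(inside), replace = TRUE)
  arr
}

# small 2-group feature fixture with one informative column
toy_feature_matrix <- function(n_per = 20, p = 25, shift = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
              dimnames = list(paste0("s", seq_len(2 * n_per)),
                              paste0("f", seq_len(p))))
  X[, 1] <- X[, 1] + rep(c(0, shift), each = n_per)
  feature_matrix(X, rep(c("nADrp", "AD"), each = n_per))
}
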