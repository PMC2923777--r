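# Independent oracles and small fixture builders used across the suite.

# Brute-force peak scan: loops over supra-threshold voxels and compares each
# against all its in-mask neighbours (out-of-mask treated as -Inf).
peaks_oracle <- function(spm, mask, threshold, connectivity = 26) {
  dm <- dim(spm)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 18) off <- off[rowSums(abs(off)) <= 2, , drop = FALSE]
  cand <- which(mask & spm > threshold, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    v <- cand[i, ]
    ok <- TRUE
    for (r in seq_len(nrow(off))) {
      nb <- v + off[r, ]
      if (any(nb < 1) || any(nb > dm)) next
      if (!mask[nb[1], nb[2], nb[3]]) next
      if (spm[nb[1], nb[2], nb[3]] >= spm[v[1], v[2], v[3]]) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

# Flood-fill count of supra-threshold connected components (26-connectivity),
# an oracle for one_per_excursion peak counts.
excursion_count_oracle <- function(spm, mask, threshold) {
  dm <- dim(spm)
  supra <- which(mask & spm > threshold)
  if (length(supra) == 0) return(0L)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  remaining <- supra
  ncomp <- 0L
  crd_all <- arrayInd(seq_len(prod(dm)), dm)
  while (length(remaining) > 0) {
    ncomp <- ncomp + 1L
    frontier <- remaining[1]
    remaining <- remaining[-1]
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        crd <- crd_all[v, ]
        for (r in seq_len(nrow(off))) {
          nb <- crd + off[r, ]
          if (any(nb < 1) || any(nb > dm)) next
          lin <- nb[1] + (nb[2] - 1) * dm[1] + (nb[3] - 1) * dm[1] * dm[2]
          hit <- match(lin, remaining)
          if (!is.na(hit)) {
            nxt <- c(nxt, lin)
            remaining <- remaining[-hit]
          }
        }
      }
      frontier <- nxt
    }
  }
  ncomp
}

# Direct per-voxel recomputation of the derivative covariance determinant,
# looping voxel by voxel and volume by volume.
rpv_oracle <- function(res, mask) {
  dm <- dim(res)[1:3]
  T <- dim(res)[4]
  r <- res
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (!mask[i, j, k]) next
    ss <- sum(r[i, j, k, ]^2)
    if (ss > 0) r[i, j, k, ] <- r[i, j, k, ] / sqrt(ss)
  }
  rpv <- array(NA_real_, dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (!mask[i, j, k]) next
    if (i == dm[1] || j == dm[2] || k == dm[3]) next
    if (!mask[i + 1, j, k] || !mask[i, j + 1, k] || !mask[i, j, k + 1]) next
    dx <- r[i + 1, j, k, ] - r[i, j, k, ]
    dy <- r[i, j + 1, k, ] - r[i, j, k, ]
    dz <- r[i, j, k + 1, ] - r[i, j, k, ]
    L <- matrix(c(sum(dx * dx), sum(dx * dy), sum(dx * dz),
                  sum(dx * dy), sum(dy * dy), sum(dy * dz),
                  sum(dx * dz), sum(dy * dz), sum(dz * dz)), 3, 3)
    rpv[i, j, k] <- (4 * log(2))^(-3 / 2) * sqrt(max(det(L), 0))
  }
  rpv
}

# Evidence of the free-pattern model for n = 2 by numerical integration of
# the likelihood against the Beta(a1, a2) prior over the simplex.
evidence_alt_quad_n2 <- function(d, alpha = c(0.5, 0.5)) {
  k <- sum(d)
  f <- function(th) {
    exp(lgamma(k + 1) - lgamma(d[1] + 1) - lgamma(d[2] + 1) +
          d[1] * log(th) + d[2] * log(1 - th)) *
      stats::dbeta(th, alpha[1], alpha[2])
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-12)$value
}

# all compositions of k into n non-negative parts
compositions <- function(k, n) {
  if (n == 1) return(matrix(k, 1, 1))
  out <- NULL
  for (i in 0:k) {
    sub <- compositions(k - i, n - 1)
    out <- rbind(out, cbind(i, sub))
  }
  unname(out)
}

# smooth supra-threshold-rich random field on a small lattice
random_smooth_field <- function(dm, fwhm = 3, scale = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- gauss_smooth(array(rnorm(prod(dm)), dm), fwhm)
  f / sd(f) * scale / 2
}

# long counts tibble for I subjects with fixed per-subject totals,
# drawn multinomially around theta
make_counts <- function(I, k_i, theta, resels = NULL, seed = 1) {
  set.seed(seed)
  n <- length(theta)
  if (is.null(resels)) resels <- rep(100 / n, n)
  purrr::map_dfr(seq_len(I), function(i) {
    d <- as.vector(rmultinom(1, k_i, theta))
    tibble::tibble(subject = i, region = seq_len(n), d = d, resels = resels)
  })
}

# Voronoi with seeds at opposite cube corners: expected labels from the
# perpendicular-bisector rule, checked voxel by voxel
voronoi_oracle_corners <- function(dm) {
  sc <- rbind(c(1, 1, 1), dm)
  lab <- voronoi_parcellation(dm, 2, seed_voxels = sc)
  crd <- arrayInd(seq_len(prod(dm)), dm)
  d1 <- rowSums(sweep(crd, 2, sc[1, ])^2)
  d2 <- rowSums(sweep(crd, 2, sc[2, ])^2)
  expected <- ifelse(d1 <= d2, 1L, 2L)   # ties go to the lowest seed index
  list(lab = as.vector(lab), expected = expected)
}
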