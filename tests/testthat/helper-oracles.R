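# Independent brute-force oracles used to check the vectorised
# implementations, plus small fixture builders. These deliberately share no
# code with the package internals.

# Direct triple-loop convolution with a truncated, renormalised Gaussian
# kernel and mirror-reflected (edge-repeating) borders.
oracle_gaussian <- function(a, sigma, support) {
  k <- -support:support
  w <- exp(-(k^2) / (2 * sigma^2))
  w <- w / sum(w)
  refl <- function(i, n) {
    j <- (i - 1) %% (2 * n)
    j <- ifelse(j < 0, j + 2 * n, j)
    ifelse(j >= n, 2 * n - 1 - j, j) + 1
  }
  d <- dim(a)
  out <- array(0, d)
  for (x in seq_len(d[1])) {
    for (y in seq_len(d[2])) {
      for (z in seq_len(d[3])) {
        acc <- 0
        for (i in k) for (j in k) for (l in k) {
          acc <- acc + w[i + support + 1] * w[j + support + 1] * w[l + support + 1] *
            a[refl(x + i, d[1]), refl(y + j, d[2]), refl(z + l, d[3])]
        }
        out[x, y, z] <- acc
      }
    }
  }
  out
}

# Queue-based breadth-first flood fill of the band-restricted component(s)
# containing the seed voxels; 6- or 26-connectivity.
oracle_flood_fill <- function(values, seed_idx, lo, hi, connectivity = 6L) {
  d <- dim(values)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  elig <- values >= lo & values <= hi
  visited <- array(FALSE, d)
  frontier <- seed_idx[elig[seed_idx] | TRUE]  # seeds always in
  visited[seed_idx] <- TRUE
  while (length(frontier)) {
    nxt <- integer(0)
    co <- arrayInd(frontier, d)
    for (r in seq_len(nrow(offs))) {
      ni <- cbind(co[, 1] + offs$dx[r], co[, 2] + offs$dy[r], co[, 3] + offs$dz[r])
      ok <- ni[, 1] >= 1 & ni[, 1] <= d[1] & ni[, 2] >= 1 & ni[, 2] <= d[2] &
        ni[, 3] >= 1 & ni[, 3] <= d[3]
      lin <- ni[ok, 1] + (ni[ok, 2] - 1) * d[1] + (ni[ok, 3] - 1) * d[1] * d[2]
      lin <- lin[elig[lin] & !visited[lin]]
      visited[lin] <- TRUE
      nxt <- c(nxt, lin)
    }
    frontier <- unique(nxt)
  }
  visited
}

# Iterated 6-neighbour min-filter erosion (the peeling oracle).
oracle_erode <- function(mask, n) {
  d <- dim(mask)
  for (it in seq_len(n)) {
    out <- array(FALSE, d)
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      if (!mask[x, y, z]) next
      keep <- TRUE
      for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
        nx <- x + o[1]; ny <- y + o[2]; nz <- z + o[3]
        if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] || nz < 1 || nz > d[3] ||
            !mask[nx, ny, nz]) { keep <- FALSE; break }
      }
      out[x, y, z] <- keep
    }
    mask <- out
  }
  mask
}

# Exhaustive two-sample permutation p-value for |difference in means|.
oracle_permutation_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  obs <- abs(mean(a) - mean(b))
  combs <- utils::combn(length(pooled), n1)
  stats <- apply(combs, 2, function(ix)
    abs(mean(pooled[ix]) - mean(pooled[-ix])))
  mean(stats >= obs - 1e-12)
}

# A reduced leg phantom that keeps unit tests fast; geometry scaled so the
# default protocol constants still apply at the working resolution.
small_phantom_spec <- function(fat_fraction = 0.10, hu_noise_sd = 30,
                               rng_seed = 1L, ...) {
  phantom_spec(shape_vox = c(96L, 96L, 40L), voxel_size_mm = 0.082,
               skin_thickness_vox = 2L,
               inclusion_radius_vox = c(4L, 6L),
               inclusion_length_vox = c(8L, 12L),
               fat_fraction = fat_fraction, hu_noise_sd = hu_noise_sd,
               rng_seed = rng_seed, ...)
}

# Two paired vectors with an exactly prescribed Pearson correlation.
make_exact_r <- function(r, n = 30L, seed = 1L) {
  set.seed(seed)
  u <- scale(seq_len(n))[, 1]
  w <- rnorm(n)
  w <- residuals(lm(w ~ u))
  w <- w / sqrt(sum(w^2) / (n - 1))
  u <- u / sqrt(sum(u^2) / (n - 1))
  list(x = u, y = r * u + sqrt(1 - r^2) * w)
}
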