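# Independent brute-force oracles. These deliberately re-derive every
# quantity with naive loops over raw pixels / matrix cells, sharing no
# code path with the package implementation.

oracle_hs <- function(values) {
  n <- length(values)
  mu <- sum(values) / n
  v <- sum((values - mu)^2) / n
  skew <- if (v > 0) (sum((values - mu)^3) / n) / v^1.5 else 0
  kurt <- if (v > 0) (sum((values - mu)^4) / n) / v^2 - 3 else 0
  tally <- integer(256)
  for (x in values) tally[x + 1] <- tally[x + 1] + 1
  H <- tally / n
  perc <- function(q) {
    acc <- 0
    for (k in 0:255) {
      acc <- acc + tally[k + 1]
      if (acc >= q * n) return(k)
    }
  }
  win_peak <- function(r) {
    best_k <- 0; best_m <- -1
    for (k in 0:(256 - r)) {
      m <- sum(tally[(k + 1):(k + r)])
      if (m > best_m) { best_m <- m; best_k <- k }
    }
    c(best_k, best_m / n)
  }
  w1 <- win_peak(1); w10 <- win_peak(10)
  c(Mean = mu, Variance = v, Skewness = skew, Kurtosis = kurt,
    Perc01 = perc(0.01), Perc10 = perc(0.10), Perc50 = perc(0.50),
    Perc90 = perc(0.90), Perc99 = perc(0.99),
    Domn01 = w1[1], Domn10 = w10[1], Maxm01 = w1[2], Maxm10 = w10[2])
}

oracle_cooccurrence <- function(plane, mask, offset = c(0, 1),
                                symmetric = TRUE, K = 256) {
  counts <- matrix(0, K, K)
  nr <- nrow(plane); nc <- ncol(plane)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      i2 <- i + offset[1]; j2 <- j + offset[2]
      if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc &&
          mask[i, j] && mask[i2, j2]) {
        k <- plane[i, j] + 1; l <- plane[i2, j2] + 1
        counts[k, l] <- counts[k, l] + 1
        if (symmetric) counts[l, k] <- counts[l, k] + 1
      }
    }
  }
  counts / sum(counts)
}

oracle_glcm <- function(p) {
  K <- nrow(p)
  lv <- 0:(K - 1)
  mu_k <- 0; mu_l <- 0
  for (k in 1:K) for (l in 1:K) {
    mu_k <- mu_k + lv[k] * p[k, l]
    mu_l <- mu_l + lv[l] * p[k, l]
  }
  var_k <- 0; var_l <- 0; asm <- 0; contrast <- 0; idm <- 0
  sos <- 0; ent <- 0; cross <- 0
  for (k in 1:K) for (l in 1:K) {
    pkl <- p[k, l]
    asm <- asm + pkl^2
    contrast <- contrast + (lv[k] - lv[l])^2 * pkl
    idm <- idm + pkl / (1 + (lv[k] - lv[l])^2)
    sos <- sos + (lv[k] - mu_k)^2 * pkl
    var_k <- var_k + (lv[k] - mu_k)^2 * pkl
    var_l <- var_l + (lv[l] - mu_l)^2 * pkl
    cross <- cross + lv[k] * lv[l] * pkl
    if (pkl > 0) ent <- ent - pkl * log(pkl)
  }
  correlat <- if (sqrt(var_k) * sqrt(var_l) > 0) {
    (cross - mu_k * mu_l) / (sqrt(var_k) * sqrt(var_l))
  } else 0
  p_sum <- numeric(2 * K - 1)   # sums 0 .. 2(K-1)
  p_dif <- numeric(K)           # |k-l| 0 .. K-1
  for (k in 1:K) for (l in 1:K) {
    p_sum[lv[k] + lv[l] + 1] <- p_sum[lv[k] + lv[l] + 1] + p[k, l]
    p_dif[abs(lv[k] - lv[l]) + 1] <- p_dif[abs(lv[k] - lv[l]) + 1] + p[k, l]
  }
  sum_averg <- 0
  for (m in seq_along(p_sum)) sum_averg <- sum_averg + (m - 1) * p_sum[m]
  sum_varnc <- 0; sum_entrp <- 0
  for (m in seq_along(p_sum)) {
    sum_varnc <- sum_varnc + (m - 1 - sum_averg)^2 * p_sum[m]
    if (p_sum[m] > 0) sum_entrp <- sum_entrp - p_sum[m] * log(p_sum[m])
  }
  dif_mean <- 0
  for (m in seq_along(p_dif)) dif_mean <- dif_mean + (m - 1) * p_dif[m]
  dif_varnc <- 0; dif_entrp <- 0
  for (m in seq_along(p_dif)) {
    dif_varnc <- dif_varnc + (m - 1 - dif_mean)^2 * p_dif[m]
    if (p_dif[m] > 0) dif_entrp <- dif_entrp - p_dif[m] * log(p_dif[m])
  }
  c(AngScMom = asm, Contrast = contrast, Correlat = correlat,
    SumOfSqs = sos, InvDefMom = idm, SumAverg = sum_averg,
    SumVarnc = sum_varnc, SumEntrp = sum_entrp, Entropy = ent,
    DifVarnc = dif_varnc, DifEntrp = dif_entrp)
}

# even-odd ray casting, written independently of pracma
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

random_masked_plane <- function(seed, K = 256, shape = c(8, 8),
                                mask_prob = 0.8) {
  withr::with_seed(seed, {
    plane <- matrix(sample(0:(K - 1), prod(shape), replace = TRUE),
                    shape[1], shape[2])
    mask <- matrix(stats::runif(prod(shape)) < mask_prob, shape[1], shape[2])
    if (!any(mask)) mask[1, 1] <- TRUE
    # ensure at least one horizontal pair
    mask[1, 1] <- TRUE; mask[1, 2] <- TRUE
    list(plane = plane, mask = mask)
  })
}

tiny_design <- function(seed = 1) {
  cohort_design(n_nonpregnant = 6, n_pregnant_per_subgroup = 5,
                n_sessions_nonpregnant = 4, seed = seed,
                image_shape = c(64, 64))
}
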