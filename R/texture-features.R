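#' Texture-extraction configuration
#'
#' @param gray_levels number of gray levels K for the co-occurrence matrix
#'   (default 256, the full 8-bit range; planes are right-shifted to
#'   `0..K-1` only when a reduction is requested explicitly).
#' @param offset integer `(row, col)` pixel displacement between the pixel
#'   of interest and its neighbour; `c(0, 1)` (default) is the horizontal
#'   direction at distance d = 1.
#' @param log_base base of the logarithm in the entropy features
#'   (default `exp(1)`, natural log).
#' @param window_radii window widths r for the Domn/Maxm histogram peak
#'   features (default `c(1, 10)`).
#' @return an object of class `texture_config`.
#' @export
texture_config <- function(gray_levels = 256, offset = c(0L, 1L),
                           log_base = exp(1), window_radii = c(1L, 10L)) {
  stopifnot(gray_levels >= 2, gray_levels <= 256,
            length(offset) == 2L, all(offset == as.integer(offset)),
            any(offset != 0), log_base > 0, log_base != 1,
            all(window_radii >= 1))
  structure(list(gray_levels = as.integer(gray_levels),
                 offset = as.integer(offset),
                 log_base = log_base,
                 window_radii = as.integer(window_radii)),
            class = "texture_config")
}

#' Feature name sets
#'
#' @return character vector of feature names for one approach.
#' @name feature_names
NULL

#' @rdname feature_names
#' @export
hs_feature_names <- function() {
  c("Mean", "Variance", "Skewness", "Kurtosis",
    "Perc01", "Perc10", "Perc50", "Perc90", "Perc99",
    "Domn01", "Domn10", "Maxm01", "Maxm10")
}

#' @rdname feature_names
#' @export
glcm_feature_names <- function() {
  c("AngScMom", "Contrast", "Correlat", "SumOfSqs", "InvDefMom",
    "SumAverg", "SumVarnc", "SumEntrp", "Entropy", "DifVarnc", "DifEntrp")
}

reduce_levels <- function(values, gray_levels) {
  if (gray_levels == 256L) return(values)
  floor(values * gray_levels / 256)
}

#' Normalized gray-level histogram over a region of interest
#'
#' Counts the gray levels of the masked pixels and divides by the ROI
#' pixel count, so probabilities sum to one. All first-order statistics
#' are computed from this histogram; pixel arrangement is ignored.
#'
#' @param plane a `component_plane` or integer matrix with values in
#'   `0..K-1`.
#' @param mask logical matrix of the same shape; `TRUE` marks ROI pixels.
#' @param gray_levels number of levels K (default 256).
#' @return object of class `roi_histogram`: list with `H` (length-K
#'   probability vector for levels `0..K-1`), `K`, and `n_pixels`.
#' @export
roi_histogram <- function(plane, mask, gray_levels = 256) {
  v <- if (inherits(plane, "component_plane")) plane$values else plane
  if (!all(dim(v) == dim(mask))) stop("plane and mask shapes differ", call. = FALSE)
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  x <- v[mask]
  if (min(x) < 0 || max(x) > gray_levels - 1) {
    stop("plane values outside 0..K-1", call. = FALSE)
  }
  counts <- tabulate(x + 1L, nbins = gray_levels)
  structure(list(H = counts / length(x), counts = counts,
                 K = as.integer(gray_levels), n_pixels = length(x)),
            class = "roi_histogram")
}

#' First-order histogram-statistics features
#'
#' The 13 HS features of the normalized gray-level histogram:
#' mean, variance, skewness and excess kurtosis (standardized central
#' moments; defined as 0 for a degenerate histogram), the 1/10/50/90/99
#' percentiles (each the smallest level at which the cumulative histogram
#' reaches the quantile), and the windowed histogram peaks: `Domn_r` is
#' the level at which the probability mass of the width-r window starting
#' there is maximal (smallest level on ties) and `Maxm_r` is that maximal
#' mass, for r = 1 and r = 10.
#'
#' @param hist a [roi_histogram()].
#' @param window_radii window widths (default `c(1, 10)`).
#' @return named numeric vector of 13 features.
#' @export
hs_features <- function(hist, window_radii = c(1L, 10L)) {
  H <- hist$H
  n <- hist$n_pixels
  # percentiles and window peaks use the integer counts: cumulative
  # probabilities hit exact rational ties (e.g. 0.50) that floating-point
  # partial sums cannot resolve reliably
  counts <- hist$counts
  if (is.null(counts)) counts <- round(H * n)
  k <- seq_along(H) - 1
  mu <- sum(k * H)
  v <- sum((k - mu)^2 * H)
  if (v > 0) {
    skew <- sum((k - mu)^3 * H) / v^1.5
    kurt <- sum((k - mu)^4 * H) / v^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  cumc <- cumsum(counts)
  perc <- function(q) k[which(cumc >= q * n)[1]]
  out <- c(Mean = mu, Variance = v, Skewness = skew, Kurtosis = kurt,
           Perc01 = perc(0.01), Perc10 = perc(0.10), Perc50 = perc(0.50),
           Perc90 = perc(0.90), Perc99 = perc(0.99))
  for (r in window_radii) {
    win <- if (r == 1L) counts else {
      cs <- c(0, cumc)
      cs[(1 + r):length(cs)] - cs[1:(length(cs) - r)]
    }
    i <- which.max(win)   # smallest index on ties
    out[sprintf("Domn%02d", r)] <- i - 1
    out[sprintf("Maxm%02d", r)] <- win[i] / n
  }
  out[hs_feature_names()]
}

#' Gray-level co-occurrence matrix over a region of interest
#'
#' Counts ordered pairs of gray levels at a fixed pixel displacement,
#' requiring both endpoints inside the ROI. The symmetric variant (GLCM)
#' also counts each pair under the reversed displacement, making the
#' matrix symmetric; the asymmetric variant (GLCH) counts the forward
#' displacement only. Normalisation divides by the total pair count.
#'
#' @param plane `component_plane` or integer matrix, values `0..K-1`.
#' @param mask logical ROI matrix of the same shape.
#' @param offset integer `(row, col)` displacement, default horizontal
#'   `c(0, 1)` at distance 1.
#' @param symmetric `TRUE` for GLCM, `FALSE` for GLCH.
#' @param gray_levels number of gray levels K (default 256).
#' @return object of class `cooccurrence`: list with dense `p` (K x K
#'   probability matrix), `counts` (K x K integer matrix), `offset`,
#'   `symmetric`, `n_pairs`.
#' @export
build_cooccurrence <- function(plane, mask, offset = c(0L, 1L),
                               symmetric = TRUE, gray_levels = 256) {
  v <- if (inherits(plane, "component_plane")) plane$values else plane
  if (!all(dim(v) == dim(mask))) stop("plane and mask shapes differ", call. = FALSE)
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  K <- as.integer(gray_levels)
  pairs <- cooccurrence_pairs(v, mask, offset)
  if (length(pairs$k) == 0L) {
    stop("no valid co-occurring pixel pairs inside the ROI for this offset",
         call. = FALSE)
  }
  idx <- pairs$k * K + pairs$l + 1L
  counts <- tabulate(idx, nbins = K * K)
  if (symmetric) {
    counts <- counts + tabulate(pairs$l * K + pairs$k + 1L, nbins = K * K)
  }
  counts <- matrix(counts, K, K, byrow = TRUE)  # row = k, col = l
  structure(list(counts = counts, p = counts / sum(counts),
                 offset = as.integer(offset), symmetric = symmetric,
                 n_pairs = sum(counts), K = K),
            class = "cooccurrence")
}

# ordered (k, l) gray-level pairs with both endpoints in the mask
cooccurrence_pairs <- function(v, mask, offset) {
  di <- offset[1]; dj <- offset[2]
  nr <- nrow(v); nc <- ncol(v)
  ri <- seq_len(nr); rj <- seq_len(nc)
  si <- ri + di; sj <- rj + dj
  keep_i <- si >= 1 & si <= nr
  keep_j <- sj >= 1 & sj <= nc
  a <- v[ri[keep_i], rj[keep_j], drop = FALSE]
  b <- v[si[keep_i], sj[keep_j], drop = FALSE]
  ok <- mask[ri[keep_i], rj[keep_j], drop = FALSE] &
        mask[si[keep_i], sj[keep_j], drop = FALSE]
  list(k = as.integer(a[ok]), l = as.integer(b[ok]))
}

#' Haralick features of a normalized co-occurrence matrix
#'
#' The 11 second-order texture features: angular second moment (energy),
#' contrast, correlation, sum of squares (marginal variance), inverse
#' difference moment (homogeneity), sum average, sum variance, sum
#' entropy, entropy, difference variance, and difference entropy. Gray
#' levels enter the formulas on their native `0..K-1` scale; entropies use
#' the configured logarithm (natural by default) with `0 log 0 = 0`;
#' correlation is defined as 0 when either marginal standard deviation is
#' 0.
#'
#' @param com a [build_cooccurrence()] result.
#' @param log_base logarithm base for the entropy features.
#' @return named numeric vector of 11 features.
#' @export
glcm_features <- function(com, log_base = exp(1)) {
  p <- com$p
  K <- com$K
  nz <- which(p > 0)
  pv <- p[nz]
  # column-major: row index = k (first level), col index = l (second level)
  kk <- (nz - 1L) %% K          # level of pixel of interest, 0-based
  ll <- (nz - 1L) %/% K         # level of neighbour, 0-based
  lg <- function(x) log(x, base = log_base)

  mu_k <- sum(kk * pv)
  mu_l <- sum(ll * pv)
  sd_k <- sqrt(sum((kk - mu_k)^2 * pv))
  sd_l <- sqrt(sum((ll - mu_l)^2 * pv))

  asm <- sum(pv^2)
  contrast <- sum((kk - ll)^2 * pv)
  correlat <- if (sd_k * sd_l > 0) {
    (sum(kk * ll * pv) - mu_k * mu_l) / (sd_k * sd_l)
  } else 0
  sum_of_sqs <- sum((kk - mu_k)^2 * pv)
  inv_def_mom <- sum(pv / (1 + (kk - ll)^2))

  p_sum <- rowsum(pv, kk + ll)                 # distribution of k + l
  s_vals <- as.numeric(rownames(p_sum))
  p_sum <- as.numeric(p_sum)
  sum_averg <- sum(s_vals * p_sum)
  sum_varnc <- sum((s_vals - sum_averg)^2 * p_sum)
  sum_entrp <- -sum(p_sum * lg(p_sum))

  p_dif <- rowsum(pv, abs(kk - ll))            # distribution of |k - l|
  d_vals <- as.numeric(rownames(p_dif))
  p_dif <- as.numeric(p_dif)
  dif_mean <- sum(d_vals * p_dif)
  dif_varnc <- sum((d_vals - dif_mean)^2 * p_dif)
  dif_entrp <- -sum(p_dif * lg(p_dif))

  entropy <- -sum(pv * lg(pv))

  c(AngScMom = asm, Contrast = contrast, Correlat = correlat,
    SumOfSqs = sum_of_sqs, InvDefMom = inv_def_mom, SumAverg = sum_averg,
    SumVarnc = sum_varnc, SumEntrp = sum_entrp, Entropy = entropy,
    DifVarnc = dif_varnc, DifEntrp = dif_entrp)
}

#' Extract the full feature vector set for one thermal frame
#'
#' Decomposes the frame into its ten color-component planes and computes,
#' inside the ROI, the 13 histogram-statistics features plus the 11
#' Haralick features on both the symmetric (GLCM) and asymmetric (GLCH)
#' co-occurrence matrix — 35 features per component, 350 values per frame.
#'
#' @param frame a `thermal_frame` (see [read_frame()] / [generate_cohort()]):
#'   list with `image` (H x W x 3, 0..255), `mask` (logical), `meta`.
#' @param cfg a [texture_config()].
#' @param color_cfg a [color_config()].
#' @return data.frame with columns `component`, `approach`
#'   (`HS`/`GLCM`/`GLCH`), `feature`, `value`.
#' @export
extract_frame_features <- function(frame, cfg = texture_config(),
                                   color_cfg = color_config()) {
  planes <- transform_all(frame$image, color_cfg)
  out <- vector("list", length(planes))
  for (i in seq_along(planes)) {
    pl <- planes[[i]]
    vals <- reduce_levels(pl$values, cfg$gray_levels)
    hist <- roi_histogram(vals, frame$mask, cfg$gray_levels)
    hs <- hs_features(hist, cfg$window_radii)
    glcm <- glcm_features(
      build_cooccurrence(vals, frame$mask, cfg$offset, TRUE, cfg$gray_levels),
      cfg$log_base)
    glch <- glcm_features(
      build_cooccurrence(vals, frame$mask, cfg$offset, FALSE, cfg$gray_levels),
      cfg$log_base)
    out[[i]] <- data.frame(
      component = pl$component_id,
      approach = rep(c("HS", "GLCM", "GLCH"), c(length(hs), length(glcm), length(glch))),
      feature = c(names(hs), names(glcm), names(glch)),
      value = unname(c(hs, glcm, glch)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Extract features for every frame of a cohort
#'
#' @param cohort a [generate_cohort()] result (or compatible list with
#'   `frames` and `metadata`).
#' @param cfg a [texture_config()].
#' @param color_cfg a [color_config()].
#' @return data.frame: one row per frame x component x feature, carrying
#'   the frame metadata columns (`mare_id`, `group`, `subgroup`, `month`,
#'   `session`) plus `component`, `approach`, `feature`, `value`.
#' @export
extract_cohort_features <- function(cohort, cfg = texture_config(),
                                    color_cfg = color_config()) {
  stopifnot(length(cohort$frames) == nrow(cohort$metadata))
  res <- vector("list", length(cohort$frames))
  for (i in seq_along(cohort$frames)) {
    ft <- extract_frame_features(cohort$frames[[i]], cfg, color_cfg)
    meta <- cohort$metadata[i, c("mare_id", "group", "subgroup", "month", "session")]
    res[[i]] <- cbind(meta[rep(1L, nrow(ft)), , drop = FALSE], ft,
                      row.names = NULL)
  }
  do.call(rbind, res)
}
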