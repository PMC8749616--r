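#' Cohort design
#'
#' Describes the longitudinal imaging design the generator emulates:
#' a non-pregnant group imaged at four sessions, and two pregnant
#' subgroups imaged every two months on interleaved schedules (even
#' gestation months for subgroup A, odd for subgroup B). The defaults
#' give 14 x 4 + 13 x 4 + 13 x 4 = 160 frames.
#'
#' @param n_nonpregnant non-pregnant mares (default 14).
#' @param n_pregnant_per_subgroup pregnant mares per subgroup (default 13).
#' @param months_subgroup_a,months_subgroup_b gestation months at imaging,
#'   strictly increasing, within 4..11 (defaults `c(4,6,8,10)` and
#'   `c(5,7,9,11)`).
#' @param n_sessions_nonpregnant imaging sessions for the non-pregnant
#'   group (default 4).
#' @param seed integer seed governing the whole cohort.
#' @param image_shape `(rows, cols)` of each frame, at least 64 x 64.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_nonpregnant = 14,
                          n_pregnant_per_subgroup = 13,
                          months_subgroup_a = c(4, 6, 8, 10),
                          months_subgroup_b = c(5, 7, 9, 11),
                          n_sessions_nonpregnant = 4,
                          seed = 1L,
                          image_shape = c(112, 112)) {
  check_months <- function(m, nm) {
    if (any(diff(m) <= 0)) stop(sprintf("`%s` must be strictly increasing", nm), call. = FALSE)
    if (any(m < 4 | m > 11)) stop(sprintf("`%s` must lie within 4..11", nm), call. = FALSE)
  }
  stopifnot(n_nonpregnant >= 1, n_pregnant_per_subgroup >= 1,
            n_sessions_nonpregnant >= 1, length(image_shape) == 2,
            all(image_shape >= 64))
  check_months(months_subgroup_a, "months_subgroup_a")
  check_months(months_subgroup_b, "months_subgroup_b")
  stopifnot_scalar_number(seed, "seed")
  structure(list(n_nonpregnant = as.integer(n_nonpregnant),
                 n_pregnant_per_subgroup = as.integer(n_pregnant_per_subgroup),
                 months_subgroup_a = as.integer(months_subgroup_a),
                 months_subgroup_b = as.integer(months_subgroup_b),
                 n_sessions_nonpregnant = as.integer(n_sessions_nonpregnant),
                 seed = as.integer(seed),
                 image_shape = as.integer(image_shape)),
            class = "cohort_design")
}

#' Thermal effect model for the synthetic generator
#'
#' Parameterizes the surface-temperature field of a synthetic flank
#' thermogram: a baseline temperature, spatially correlated smooth noise
#' (ambient and anatomical gradients), and a pregnancy effect that grows
#' with gestation month `m` as (i) an elliptical Gaussian hot spot of
#' amplitude `hotspot_amp(m)` and scale `hotspot_radius(m)` over the
#' caudal abdomen, and (ii) fine-grain pixel noise of SD
#' `heterogeneity_sd(m)` emulating the increasingly heterogeneous heat
#' emission of the pregnant flank. Both effects are zero for non-pregnant
#' animals and must be non-decreasing in month. All temperatures are
#' clipped into the camera measurement range.
#'
#' Defaults (degrees Celsius, months 4..11): baseline 28.0, smooth noise
#' SD 0.3 at correlation length 3 px, hot-spot amplitude `0.2 (m - 3)`
#' (about 0.2-1.6 degrees, the magnitude reported for conventional
#' abdominal IRT in late gestation), hot-spot radius `5 + 1.5 (m - 4)` px,
#' and fine-grain SD `0.3 sqrt(1.8 * 1.3^(m-4) - 1)`, chosen so the total
#' within-ROI temperature variance grows geometrically (about 30% per
#' month) — a log-linear texture-heterogeneity progression mirroring the
#' super-linear growth of fetal and uterine tissue. Camera range
#' 10.0-40.0.
#'
#' @param base_temp baseline flank temperature, degrees C.
#' @param ambient_drift_sd SD of a per-session additive ambient offset
#'   (default 0: acquisition in a closed space).
#' @param smooth_noise_sd SD of the spatially correlated noise, degrees C.
#' @param smooth_corr_len correlation length (Gaussian kernel sigma), px.
#' @param hotspot_amp function month -> amplitude in degrees C.
#' @param hotspot_radius function month -> Gaussian scale in px.
#' @param heterogeneity_sd function month -> fine-grain noise SD, degrees C.
#' @param camera_range length-2 measurement range, degrees C.
#' @param mare_intercept_sd SD of the per-mare Gaussian random intercept
#'   on `base_temp`, degrees C (default 0.5).
#' @param hotspot_center hot-spot center as `(row, col)` fractions of the
#'   image (default centered).
#' @param hotspot_aspect row/col aspect ratio of the elliptical spot.
#' @return object of class `effect_model`.
#' @export
effect_model <- function(base_temp = 28.0,
                         ambient_drift_sd = 0.0,
                         smooth_noise_sd = 0.3,
                         smooth_corr_len = 3,
                         hotspot_amp = function(m) 0.2 * (m - 3),
                         hotspot_radius = function(m) 5 + 1.5 * (m - 4),
                         heterogeneity_sd = function(m) 0.3 * sqrt(1.8 * 1.3^(m - 4) - 1),
                         camera_range = c(10.0, 40.0),
                         mare_intercept_sd = 0.5,
                         hotspot_center = c(0.5, 0.5),
                         hotspot_aspect = 0.7) {
  for (nm in c("base_temp", "ambient_drift_sd", "smooth_noise_sd",
               "smooth_corr_len", "mare_intercept_sd", "hotspot_aspect")) {
    stopifnot_scalar_number(get(nm), nm)
  }
  if (any(!is.finite(camera_range)) || length(camera_range) != 2 ||
      camera_range[1] >= camera_range[2]) {
    stop("`camera_range` must be a finite (min, max) with min < max", call. = FALSE)
  }
  months <- 4:11
  for (f in list(hotspot_amp, hotspot_radius, heterogeneity_sd)) {
    vals <- vapply(months, f, numeric(1))
    if (any(!is.finite(vals))) stop("effect functions must be finite on months 4..11", call. = FALSE)
    if (any(diff(vals) < 0)) stop("effect functions must be non-decreasing in month", call. = FALSE)
  }
  structure(list(base_temp = base_temp, ambient_drift_sd = ambient_drift_sd,
                 smooth_noise_sd = smooth_noise_sd,
                 smooth_corr_len = smooth_corr_len,
                 hotspot_amp = hotspot_amp, hotspot_radius = hotspot_radius,
                 heterogeneity_sd = heterogeneity_sd,
                 camera_range = camera_range,
                 mare_intercept_sd = mare_intercept_sd,
                 hotspot_center = hotspot_center,
                 hotspot_aspect = hotspot_aspect),
            class = "effect_model")
}

# separable Gaussian smoothing via banded kernel matrices; the result is
# rescaled to the requested empirical SD afterwards, so no normalisation
# is applied here
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * sigma^2))
    k / rowSums(k)
  }
  band(nrow(x)) %*% x %*% t(band(ncol(x)))
}

#' Generate a synthetic surface-temperature field
#'
#' Builds one flank temperature matrix: baseline plus smooth correlated
#' noise, plus (for a pregnant animal) the month-dependent elliptical hot
#' spot and fine-grain heterogeneity noise of the [effect_model()], all
#' clipped into the camera range. Deterministic for a fixed seed.
#'
#' @param shape `(rows, cols)`, each at least 64.
#' @param effect an [effect_model()].
#' @param month gestation month 4..11, or `NULL`/`NA` for non-pregnant.
#' @param rng_seed integer seed.
#' @return numeric matrix of temperatures in degrees C.
#' @export
generate_temperature_field <- function(shape, effect, month = NULL,
                                       rng_seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 64))
  if (!inherits(effect, "effect_model")) stop("`effect` must be an effect_model", call. = FALSE)
  pregnant <- !(is.null(month) || is.na(month))
  if (pregnant) stopifnot(month >= 4, month <= 11)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  withr::with_seed(as.integer(rng_seed), {
    field <- matrix(effect$base_temp, nr, nc)
    if (effect$smooth_noise_sd > 0) {
      sm <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                            effect$smooth_corr_len)
      s <- stats::sd(as.vector(sm))
      if (s > 0) field <- field + sm / s * effect$smooth_noise_sd
    }
    if (pregnant) {
      amp <- effect$hotspot_amp(month)
      rad <- effect$hotspot_radius(month)
      if (amp > 0 && rad > 0) {
        cr <- effect$hotspot_center[1] * nr
        cc <- effect$hotspot_center[2] * nc
        rr <- rad * effect$hotspot_aspect
        g <- exp(-(outer((seq_len(nr) - cr)^2 / (2 * rr^2),
                         (seq_len(nc) - cc)^2 / (2 * rad^2), "+")))
        field <- field + amp * g
      }
      het <- effect$heterogeneity_sd(month)
      if (het > 0) field <- field + matrix(stats::rnorm(nr * nc, sd = het), nr, nc)
    }
    clip_range(field, effect$camera_range[1], effect$camera_range[2])
  })
}

#' False-color palette specification
#'
#' Piecewise-linear mapping from normalized temperature fractions in
#' `[0, 1]` to RGB triples, emulating a camera's false-color rendering.
#' Control-point fractions must start at 0, end at 1, and be strictly
#' increasing.
#'
#' @param fractions numeric vector of control-point positions.
#' @param colors matrix with `length(fractions)` rows and 3 columns
#'   (R, G, B in 0..255).
#' @param name palette label.
#' @return object of class `palette_spec`.
#' @export
palette_spec <- function(fractions, colors, name = "custom") {
  colors <- as.matrix(colors)
  stopifnot(length(fractions) >= 2, nrow(colors) == length(fractions),
            ncol(colors) == 3, all(colors >= 0), all(colors <= 255))
  if (fractions[1] != 0 || fractions[length(fractions)] != 1 ||
      any(diff(fractions) <= 0)) {
    stop("control-point fractions must start at 0, end at 1, and be strictly increasing",
         call. = FALSE)
  }
  structure(list(fractions = fractions, colors = unname(colors), name = name),
            class = "palette_spec")
}

#' Default rainbow thermal palette
#'
#' Five control points blue - cyan - green - magenta - red, so low
#' temperatures render blue, medium-high temperatures magenta, and the
#' hottest pixels red, matching the annotation conventions of thermal
#' cameras.
#'
#' @return a [palette_spec()].
#' @export
default_thermal_palette <- function() {
  palette_spec(
    fractions = c(0, 0.25, 0.5, 0.75, 1),
    colors = rbind(c(0, 0, 255), c(0, 255, 255), c(0, 255, 0),
                   c(255, 0, 255), c(255, 0, 0)),
    name = "rainbow5")
}

#' Render a temperature field as an 8-bit false-color image
#'
#' Normalizes temperatures into the camera range, looks each pixel up in
#' the piecewise-linear palette, and rounds channels half away from zero
#' to integers 0..255.
#'
#' @param field numeric temperature matrix, degrees C.
#' @param palette a [palette_spec()].
#' @param range length-2 `(min, max)` camera range, degrees C.
#' @return integer H x W x 3 array with values 0..255.
#' @export
render_thermal_image <- function(field, palette = default_thermal_palette(),
                                 range = c(10.0, 40.0)) {
  if (length(range) != 2 || !all(is.finite(range)) || range[1] >= range[2]) {
    stop("degenerate temperature range: need finite min < max", call. = FALSE)
  }
  tn <- clip01((field - range[1]) / (range[2] - range[1]))
  img <- array(0L, dim = c(nrow(field), ncol(field), 3L))
  for (ch in 1:3) {
    vals <- stats::approx(palette$fractions, palette$colors[, ch],
                          xout = as.vector(tn))$y
    img[, , ch] <- matrix(as.integer(round_half_away(vals)),
                          nrow(field), ncol(field))
  }
  img
}

#' Rasterize a polygonal ROI into a binary mask
#'
#' A pixel belongs to the ROI when its center lies inside the polygon
#' under the even-odd rule. Coordinates are 0-based `(row, col)`: pixel
#' `(i, j)` occupies the unit square `[i, i+1) x [j, j+1)` and has its
#' center at `(i + 0.5, j + 0.5)`.
#'
#' @param shape `(rows, cols)` of the image.
#' @param polygon numeric matrix with >= 3 rows of `(row, col)` vertices
#'   inside the image bounds.
#' @return logical matrix with at least one `TRUE` pixel.
#' @export
generate_roi_mask <- function(shape, polygon) {
  polygon <- as.matrix(polygon)
  stopifnot(length(shape) == 2, ncol(polygon) == 2)
  if (nrow(polygon) < 3) stop("polygon needs at least 3 vertices", call. = FALSE)
  if (any(polygon[, 1] < 0) || any(polygon[, 1] > shape[1]) ||
      any(polygon[, 2] < 0) || any(polygon[, 2] > shape[2])) {
    stop("polygon vertices must lie inside the image bounds", call. = FALSE)
  }
  centers_r <- rep(seq_len(shape[1]) - 0.5, times = shape[2])
  centers_c <- rep(seq_len(shape[2]) - 0.5, each = shape[1])
  inside <- pracma::inpolygon(centers_c, centers_r,
                              polygon[, 2], polygon[, 1],
                              boundary = FALSE)
  mask <- matrix(inside, shape[1], shape[2])
  if (!any(mask)) {
    stop("polygon produced an empty ROI mask (degenerate or sub-pixel polygon)",
         call. = FALSE)
  }
  mask
}

#' Default flank-shaped ROI polygon
#'
#' A convex pentagon covering the central flank region of the image,
#' standing in for the manually annotated area bounded by the vertical
#' line behind the tuber coxae, the dorsal abdominal edge, the last rib,
#' and the lower 2/3 of the abdomen height.
#'
#' @param shape `(rows, cols)` of the image.
#' @return numeric matrix of `(row, col)` vertices.
#' @export
default_flank_roi <- function(shape) {
  fr <- rbind(c(0.15, 0.25), c(0.20, 0.82), c(0.72, 0.86),
              c(0.85, 0.45), c(0.50, 0.14))
  cbind(fr[, 1] * shape[1], fr[, 2] * shape[2])
}

thermal_frame <- function(image, mask, meta = list()) {
  if (!all(dim(image)[1:2] == dim(mask))) {
    stop("image and mask shapes differ", call. = FALSE)
  }
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  structure(list(image = image, mask = mask, meta = meta),
            class = "thermal_frame")
}

#' Generate a full synthetic thermal cohort
#'
#' Produces one false-color frame per mare and imaging occasion following
#' the [cohort_design()]: non-pregnant mares at every session, pregnant
#' mares of each subgroup at their scheduled gestation months. Each mare
#' receives a Gaussian random intercept on the baseline temperature, each
#' session an optional ambient offset, and each frame its own
#' deterministic child seed, so a fixed design seed reproduces the cohort
#' bit for bit.
#'
#' @param design a [cohort_design()].
#' @param effect an [effect_model()].
#' @param palette a [palette_spec()].
#' @param roi polygon of `(row, col)` vertices (default
#'   [default_flank_roi()] for the design's image shape).
#' @return object of class `thermal_cohort`: list with `frames` (list of
#'   `thermal_frame`) and `metadata` (data.frame with columns `mare_id`,
#'   `group`, `subgroup`, `month`, `session`).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_design(n_nonpregnant = 1,
#'   n_pregnant_per_subgroup = 1, n_sessions_nonpregnant = 1,
#'   months_subgroup_a = 4, months_subgroup_b = 5, seed = 7))
#' coh$metadata
generate_cohort <- function(design = cohort_design(),
                            effect = effect_model(),
                            palette = default_thermal_palette(),
                            roi = NULL) {
  if (!inherits(design, "cohort_design")) stop("`design` must be a cohort_design", call. = FALSE)
  shape <- design$image_shape
  if (is.null(roi)) roi <- default_flank_roi(shape)
  mask <- generate_roi_mask(shape, roi)

  mare <- function(prefix, i) sprintf("%s%02d", prefix, i)
  rows <- list()
  for (i in seq_len(design$n_nonpregnant)) {
    for (s in seq_len(design$n_sessions_nonpregnant)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mare_id = mare("NP", i), group = "NP", subgroup = "-",
        month = NA_integer_, session = s, stringsAsFactors = FALSE)
    }
  }
  for (sub in c("A", "B")) {
    months <- if (sub == "A") design$months_subgroup_a else design$months_subgroup_b
    for (i in seq_len(design$n_pregnant_per_subgroup)) {
      for (s in seq_along(months)) {
        rows[[length(rows) + 1L]] <- data.frame(
          mare_id = mare(paste0("P", sub), i), group = "P", subgroup = sub,
          month = months[s], session = s, stringsAsFactors = FALSE)
      }
    }
  }
  metadata <- do.call(rbind, rows)

  mares <- unique(metadata$mare_id)
  n_sessions <- max(metadata$session)
  # per-frame child seeds are sampled (not derived arithmetically):
  # consecutive integer seeds give correlated Mersenne-Twister start
  # states, which would induce spurious systematic differences between
  # the row-contiguous animal groups
  draws <- withr::with_seed(design$seed, list(
    intercepts = stats::rnorm(length(mares), 0, effect$mare_intercept_sd),
    drifts = if (effect$ambient_drift_sd > 0) {
      stats::rnorm(n_sessions, 0, effect$ambient_drift_sd)
    } else rep(0, n_sessions),
    frame_seeds = sample.int(2147483646L, nrow(metadata))
  ))
  names(draws$intercepts) <- mares

  frames <- vector("list", nrow(metadata))
  for (r in seq_len(nrow(metadata))) {
    m <- metadata[r, ]
    eff <- effect
    eff$base_temp <- effect$base_temp + draws$intercepts[[m$mare_id]] +
      draws$drifts[m$session]
    fseed <- draws$frame_seeds[r]
    field <- generate_temperature_field(shape, eff,
                                        month = if (is.na(m$month)) NULL else m$month,
                                        rng_seed = fseed)
    img <- render_thermal_image(field, palette, effect$camera_range)
    frames[[r]] <- thermal_frame(img, mask, meta = as.list(m))
  }
  structure(list(frames = frames, metadata = metadata,
                 design = design, roi = roi),
            class = "thermal_cohort")
}

#' @export
print.thermal_cohort <- function(x, ...) {
  cat(sprintf("<thermal_cohort: %d frames (%d non-pregnant, %d pregnant), %d x %d px>\n",
              nrow(x$metadata), sum(x$metadata$group == "NP"),
              sum(x$metadata$group == "P"),
              x$design$image_shape[1], x$design$image_shape[2]))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Frames go out as 8-bit RGB PNG, the shared mask as a 0/255
#' single-channel PNG, and the metadata (with `image_path`, `mask_path`
#' columns) as CSV.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the metadata data.frame with path columns.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mask_path <- file.path(dir, "roi_mask.png")
  png::writePNG(cohort$frames[[1]]$mask * 1.0, mask_path)
  meta <- cohort$metadata
  meta$image_path <- sprintf("%s_s%d.png", meta$mare_id, meta$session)
  meta$mask_path <- basename(mask_path)
  for (r in seq_len(nrow(meta))) {
    png::writePNG(cohort$frames[[r]]$image / 255,
                  file.path(dir, meta$image_path[r]))
  }
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}
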