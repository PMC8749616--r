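png_header_info <- function(path) {
  hdr <- readBin(path, "raw", n = 26)
  if (length(hdr) < 26 ||
      !identical(hdr[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))) {
    stop(sprintf("'%s' is not a PNG file", path), call. = FALSE)
  }
  list(bit_depth = as.integer(hdr[25]), color_type = as.integer(hdr[26]))
}

read_image_255 <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    info <- png_header_info(path)
    if (info$bit_depth != 8) {
      stop(sprintf("'%s' has bit depth %d; only 8-bit images are supported",
                   path, info$bit_depth), call. = FALSE)
    }
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    img <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (!is.null(bits) && any(bits != 8)) {
      stop(sprintf("'%s' has bit depth %s; only 8-bit images are supported",
                   path, paste(bits, collapse = "/")), call. = FALSE)
    }
  } else {
    stop(sprintf("unsupported image format '%s' (PNG or TIFF expected)", ext),
         call. = FALSE)
  }
  round_half_away(img * 255)
}

#' Read one thermal frame from disk
#'
#' Loads an exported 8-bit RGB thermogram and its binary ROI mask
#' (single-channel 0/255 PNG) and validates their compatibility.
#'
#' @param image_path path to the 8-bit RGB PNG/TIFF image.
#' @param mask_path path to the single-channel mask PNG.
#' @param meta optional list or one-row data.frame of frame metadata
#'   (`mare_id`, `group`, `subgroup`, `month`, `session`).
#' @return a `thermal_frame`.
#' @export
read_frame <- function(image_path, mask_path, meta = list()) {
  img <- read_image_255(image_path)
  if (!is_rgb_array(img)) {
    stop(sprintf("'%s' is not an RGB image", image_path), call. = FALSE)
  }
  m <- read_image_255(mask_path)
  if (!is.matrix(m)) {
    if (is.array(m) && length(dim(m)) == 3) {
      stop(sprintf("mask '%s' must be single-channel", mask_path), call. = FALSE)
    }
    m <- as.matrix(m)
  }
  if (!all(dim(img)[1:2] == dim(m))) {
    stop("image and mask shapes differ", call. = FALSE)
  }
  mask <- m > 127
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  if (is.data.frame(meta)) meta <- as.list(meta[1, ])
  thermal_frame(img, mask, meta)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' @param dir directory with `metadata.csv`, frame PNGs and mask PNG.
#' @return a `thermal_cohort`-compatible list with `frames` and
#'   `metadata`.
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    stop(sprintf("missing metadata table '%s'; run the simulate step first",
                 meta_path), call. = FALSE)
  }
  metadata <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  frames <- lapply(seq_len(nrow(metadata)), function(r) {
    read_frame(file.path(dir, metadata$image_path[r]),
               file.path(dir, metadata$mask_path[r]),
               metadata[r, setdiff(names(metadata), c("image_path", "mask_path"))])
  })
  list(frames = frames, metadata = metadata)
}

format_numeric_cols <- function(df, digits = 9) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- formatC(df[[nm]], digits = digits, format = "g")
    }
  }
  df
}

#' Write a pipeline artifact CSV with provenance header
#'
#' Prepends `# seed:` and `# config_hash:` comment lines so every
#' artifact records how it was produced; numeric columns are formatted at
#' nine significant digits so a write-read-write cycle is byte-stable.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param seed integer seed recorded in the header.
#' @param config_hash provenance hash recorded in the header.
#' @return invisibly, `path`.
#' @export
write_artifact_csv <- function(df, path, seed = NA, config_hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seed: %s", seed),
               sprintf("# config_hash: %s", config_hash)), con)
  utils::write.csv(format_numeric_cols(df), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a pipeline artifact CSV
#'
#' @param path artifact path.
#' @return data.frame with attributes `seed` and `config_hash`.
#' @export
read_artifact_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("missing artifact '%s'; run the upstream pipeline step first",
                 path), call. = FALSE)
  }
  hdr <- readLines(path, n = 2)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "seed") <- sub("^# seed: ", "", hdr[1])
  attr(df, "config_hash") <- sub("^# config_hash: ", "", hdr[2])
  df
}

#' Bundled reference accuracy table
#'
#' The reference table of two-decimal sensitivity, specificity, PPV and
#' NPV values for the 13 selected color/feature combinations across
#' gestation months 4-11 and the three thresholds, distributed with the
#' package to validate the confusion-matrix arithmetic (rates are
#' multiples of 1/14 for sensitivity and 1/13 for specificity).
#'
#' @return data.frame with columns `component`, `approach`, `feature`,
#'   `month`, `threshold_k`, `Se`, `Sp`, `PPV`, `NPV`.
#' @export
reference_accuracy_table <- function() {
  utils::read.csv(system.file("extdata", "accuracy_reference.csv",
                              package = "thermotex"),
                  stringsAsFactors = FALSE)
}

#' Bundled reference stage counts
#'
#' Per-approach survivor counts of the selection cascade for the original
#' 40-mare flank-thermogram cohort, used as inputs to the stage-count
#' bookkeeping: 127/110/110 combinations after criterion 1, 77/76/76
#' after criterion 2, and 5 HS + 8 GLCM finally selected.
#'
#' @return named list with `after_c1`, `after_c2`, `final`.
#' @export
reference_stage_counts <- function() {
  list(after_c1 = c(HS = 127, GLCM = 110, GLCH = 110),
       after_c2 = c(HS = 77, GLCM = 76, GLCH = 76),
       final = c(HS = 5, GLCM = 8))
}
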