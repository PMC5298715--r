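read_image_array <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  x
}

#' Read a registered colour/NIR image pair
#'
#' Reads PNG or TIFF files (8- or 16-bit; both readers map intensities to the
#' unit interval). An alpha channel on the colour image is dropped; a
#' multi-channel NIR file is averaged to one channel.
#'
#' @param rgb_path,nir_path Image file paths.
#' @return List with `rgb` (H x W x 3 array) and `nir` (H x W matrix).
#' @export
read_image_pair <- function(rgb_path, nir_path) {
  rgb <- read_image_array(rgb_path)
  if (length(dim(rgb)) != 3 || dim(rgb)[3] < 3) {
    stop("colour image must have at least 3 channels", call. = FALSE)
  }
  rgb <- rgb[, , 1:3, drop = FALSE]
  nir <- read_image_array(nir_path)
  if (length(dim(nir)) == 3) {
    nir <- apply(nir, c(1, 2), mean)
  }
  if (!identical(dim(rgb)[1:2], dim(nir))) {
    stop("pair is not registered: image dimensions differ", call. = FALSE)
  }
  list(rgb = rgb, nir = nir)
}

#' Write a binary mask as a single-channel PNG (0/255)
#'
#' @param mask Binary (0/1 or logical) matrix.
#' @param path Output PNG path.
#' @export
write_mask <- function(mask, path) {
  m <- (mask > 0.5) * 1
  png::writePNG(m, path)
  invisible(path)
}

#' Read a binary mask PNG
#'
#' @param path PNG path; any channel value above 0.5 counts as foreground.
#' @return 0/1 numeric matrix.
#' @export
read_mask <- function(path) {
  x <- read_image_array(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  (x > 0.5) * 1
}

#' Write a synthetic scene to disk as a PNG triplet plus JSON sidecar
#'
#' Writes `<prefix>_rgb.png`, `<prefix>_nir.png`, `<prefix>_truth.png` and
#' `<prefix>_config.json` under `dir`.
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the four paths written.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_rgb.png", "_nir.png",
                                           "_truth.png", "_config.json")))
  png::writePNG(scene$pair$rgb, paths[1])
  png::writePNG(scene$pair$nir, paths[2])
  png::writePNG(scene$truth, paths[3])
  jsonlite::write_json(unclass(scene$config), paths[4], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Write a benchmark report as CSV and a per-method JSON summary
#'
#' @param report Output of [run_benchmark()].
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the summary tibble.
#' @export
write_benchmark_report <- function(report, csv_path = NULL,
                                   json_path = NULL) {
  summ <- summarize_benchmark(report)
  if (!is.null(csv_path)) {
    utils::write.csv(report, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(summ, json_path, dataframe = "rows", digits = NA)
  }
  invisible(summ)
}
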