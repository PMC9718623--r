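#' Read an RGB image file
#'
#' Reads PNG (always available), or TIFF/JPEG when the corresponding
#' reader package is installed. Grayscale rasters are expanded to three
#' channels; an alpha channel is dropped.
#'
#' @param path Image path (extension decides the reader).
#' @return H x W x 3 array in \[0,1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(
    ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package 'tiff' is required to read TIFF files")
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("package 'jpeg' is required to read JPEG files")
      jpeg::readJPEG(path)
    },
    stop("unsupported image extension: ", ext)
  )
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a grayscale raster or RGB array as PNG
#'
#' @param x Matrix in \[0,1\] (or 0/1 mask) or H x W x 3 array.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_image_png <- function(x, path) {
  png::writePNG(pmin(pmax(x, 0), 1), path)
  invisible(path)
}

#' Segment every image in a directory
#'
#' Applies [segment_image()] to each PNG/TIFF/JPEG under `in_dir`
#' (recursively) and writes, per image, the mask (`*_mask.png`, 0/255),
#' the 8-bit saliency map (`*_saliency.png`, optional) and the
#' colour-mapped segmented image (`*_colormap.png`), plus a run log CSV
#' with one row per image.
#'
#' @param in_dir Input directory.
#' @param out_dir Output directory.
#' @param n_segments,alpha,sigma_c,sigma_s Passed to [segment_image()].
#' @param save_saliency Also write the saliency raster; default FALSE.
#' @return Tibble log: `image`, `n_nodes`, `threshold`, `mask_area_px`.
#' @export
segment_directory <- function(in_dir, out_dir, n_segments = 200L,
                              alpha = 0.99, sigma_c = 10, sigma_s = 0.1,
                              save_saliency = FALSE) {
  paths <- list.files(in_dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                      recursive = TRUE, full.names = TRUE,
                      ignore.case = TRUE)
  paths <- paths[!grepl("_mask\\.|_saliency\\.|_colormap\\.", paths)]
  if (!length(paths)) stop("no images found under ", in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- purrr::map(paths, function(p) {
    img <- read_image(p)
    res <- segment_image(img, n_segments, alpha, sigma_c, sigma_s)
    stem <- file.path(out_dir, tools::file_path_sans_ext(basename(p)))
    write_image_png(res$mask, paste0(stem, "_mask.png"))
    write_image_png(res$colormapped, paste0(stem, "_colormap.png"))
    if (save_saliency) {
      write_image_png(res$saliency_raster, paste0(stem, "_saliency.png"))
    }
    tibble::tibble(image = basename(p), n_nodes = res$graph$n_nodes,
                   threshold = res$threshold, mask_area_px = sum(res$mask))
  })
  log <- dplyr::bind_rows(log)
  utils::write.csv(log, file.path(out_dir, "segmentation_log.csv"),
                   row.names = FALSE)
  log
}
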